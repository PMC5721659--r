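# End-to-end pipeline over a simulated (or supplied) set of plastomes:
# structure -> census -> divergence -> data sets/filters/partitions -> ORF
# integrity -> distance trees. Every stage writes its table under `out_dir`
# and a log records the exact parameter set and seed.

#' Run the full comparative-plastome pipeline
#'
#' Simulates a genome panel under `config` (unless `sim` is supplied), then
#' runs every analysis stage with the given parameters, writing
#' tab-separated tables, BED/newick/FASTA artifacts and a parameter log
#' under `out_dir`.
#'
#' @param out_dir output directory.
#' @param config a [sim_config()]; its seed drives all randomness.
#' @param sim optional pre-computed [evolve_plastomes()] result.
#' @param window_len,step sliding-window geometry (defaults 600/200).
#' @param hotspot_threshold hotspot threshold in percent, strict
#'   (default 20).
#' @param min_subset minimum stand-alone partition subset length
#'   (default 200).
#' @param bootstrap_reps bootstrap replicates for the complete unfiltered
#'   tree (default 100; 0 skips the bootstrap).
#' @param ir_min_len minimum repeat length for IR detection; by default
#'   adapted to the genome size (`min(10000, n/8)`).
#' @param write_genomes also write per-leaf GenBank/FASTA files (default
#'   FALSE to keep runs light).
#' @return invisibly, a list with the key in-memory results (`sim`,
#'   `summary`, `hotspots`, `trees`, `rf`) and `paths` of artifacts.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), sim = NULL,
                         window_len = 600L, step = 200L,
                         hotspot_threshold = 20, min_subset = 200L,
                         bootstrap_reps = 100L, write_genomes = FALSE,
                         ir_min_len = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths <<- c(paths, p)
    p
  }

  if (is.null(sim)) sim <- evolve_plastomes(config)
  if (write_genomes) write_simulation(sim, file.path(out_dir, "genomes"))

  ## structure + junctions
  parts <- lapply(sim$records, function(r) {
    ml <- ir_min_len %||% min(10000L, nchar(r$sequence) %/% 8L)
    partition_regions(r, find_inverted_repeat(r, min_len = ml))
  })
  struct_tab <- do.call(rbind, lapply(names(parts), function(tx) {
    p <- parts[[tx]]
    data.frame(taxon = tx, genome = p$genome_length,
               lsc = p$lengths[["LSC"]], irb = p$lengths[["IRb"]],
               ssc = p$lengths[["SSC"]], ira = p$lengths[["IRa"]],
               gc = round_half_up(gc_content(sim$records[[tx]]$sequence), 1))
  }))
  put("structure.tsv", function(p) utils::write.table(
    struct_tab, p, sep = "\t", quote = FALSE, row.names = FALSE))
  junc_tab <- do.call(rbind, lapply(names(parts), function(tx)
    cbind(taxon = tx, junction_report(sim$records[[tx]], parts[[tx]]))))
  put("junctions.tsv", function(p) utils::write.table(
    junc_tab, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## census + cross-genome summaries
  census_tab <- do.call(rbind, lapply(names(parts), function(tx) {
    cen <- gene_census(sim$records[[tx]], parts[[tx]])
    cn <- coding_noncoding_lengths(sim$records[[tx]])
    data.frame(taxon = tx, unique_genes = cen$unique_genes,
               total_genes = cen$total_genes,
               duplicated_in_ir = cen$duplicated_in_ir, cds = cen$cds,
               trna = cen$trna, rrna = cen$rrna,
               one_intron = cen$one_intron, two_intron = cen$two_intron,
               coding_bp = cn$coding_bp, noncoding_bp = cn$noncoding_bp,
               coding_percent = round_half_up(cn$coding_percent, 1))
  }))
  put("census.tsv", function(p) utils::write.table(
    census_tab, p, sep = "\t", quote = FALSE, row.names = FALSE))
  summary_tab <- do.call(rbind, lapply(
    list(LSC = struct_tab$lsc, SSC = struct_tab$ssc, IR = struct_tab$irb,
         coding = census_tab$coding_bp,
         noncoding = census_tab$noncoding_bp),
    function(v) data.frame(mean = region_length_summary(v)$mean,
                           sd = region_length_summary(v)$sd)))
  summary_tab <- cbind(region = rownames(summary_tab), summary_tab)
  put("region_summary.tsv", function(p) utils::write.table(
    summary_tab, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## divergence on the one-IR alignment
  bundle <- build_datasets(sim$alignment)
  windows <- window_scan(bundle$complete, window_len, step)
  put("windows.tsv", function(p) write_window_table(windows, p))
  hot <- call_hotspots(windows, hotspot_threshold,
                       attr(bundle$complete, "labels"))
  put("hotspots.bed", function(p) hotspots_to_bed(hot, "alignment", p))
  ident <- pairwise_identity(bundle$complete, rownames(sim$alignment)[[1L]],
                             window_len, step)
  put("identity.tsv", function(p) utils::write.table(
    ident, p, sep = "\t", quote = FALSE, row.names = FALSE))
  sites <- classify_sites(bundle$complete)
  put("site_classes.tsv", function(p) utils::write.table(
    data.frame(class = names(sites$counts), count = sites$counts,
               percent = sites$percent),
    p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## partitions
  scheme <- build_partitions(bundle$complete, min_subset)
  put("partitions_raxml.txt", function(p) write_partitions_raxml(scheme, p))
  put("partitions.nex", function(p) write_partitions_nexus(scheme, p))

  ## ORF integrity
  orf_tab <- do.call(rbind, lapply(sim$records, scan_record_orfs))
  put("orf_scan.tsv", function(p) utils::write.table(
    orf_tab, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## trees: all data sets x all filter modes
  trees <- list(); rf <- list()
  for (ds in c("complete", "coding", "noncoding")) {
    for (fm in c("unfiltered", "light", "strict")) {
      key <- paste(ds, fm, sep = "_")
      flt <- filter_alignment(bundle[[ds]], fm)
      tr <- neighbor_joining(jc_distance(flt))
      trees[[key]] <- tr
      rf[[key]] <- robinson_foulds(tr, sim$tree)
      put(paste0("nj_", key, ".nwk"), function(p) write_newick(tr, p))
    }
  }
  rf_tab <- data.frame(dataset = names(rf),
                       rf_to_truth = unlist(rf, use.names = FALSE))
  put("rf_to_truth.tsv", function(p) utils::write.table(
    rf_tab, p, sep = "\t", quote = FALSE, row.names = FALSE))
  if (bootstrap_reps > 0L) {
    bs <- bootstrap_support(bundle$complete, bootstrap_reps,
                            seed = config$seed)
    put("nj_complete_unfiltered_boot.nwk",
        function(p) write_newick(bs$tree, p))
  }

  ## log
  put("pipeline_log.txt", function(p) writeLines(c(
    sprintf("plastomics %s | R %s", as.character(utils::packageVersion("plastomics")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", config$seed),
    sprintf("window_len: %d step: %d hotspot_threshold: %s", window_len,
            step, format(hotspot_threshold)),
    sprintf("min_subset: %d bootstrap_reps: %d", min_subset,
            bootstrap_reps),
    sprintf("taxa: %s", paste(names(sim$records), collapse = ","))), p))

  invisible(list(sim = sim, summary = summary_tab, hotspots = hot,
                 trees = trees, rf = rf_tab, paths = paths))
}
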