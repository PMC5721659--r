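# Evolution of the ancestral genome along the guide tree, producing leaf
# genomes, the true alignment and the full ground-truth bundle.

DNA_BASES <- c("A", "C", "G", "T")

new_codon_counter <- function() {
  env <- new.env(parent = emptyenv())
  env$next_id <- 1e12
  env
}

set_oriented_chars <- function(row, cols, strand, positions, new_chars) {
  # positions are 1-based along the degapped, strand-oriented sequence
  cn <- cols[row[cols] != "-"]
  if (strand == "-") cn <- rev(cn)
  for (i in seq_along(positions)) {
    ch <- new_chars[[i]]
    row[cn[[positions[[i]]]]] <- if (strand == "-") DNA_COMPLEMENT[[ch]] else ch
  }
  row
}

oriented_gene_seq <- function(row, cols, strand) {
  v <- row[cols]
  v <- v[v != "-"]
  if (!length(v)) return("")
  if (strand == "-") collapse_chars(rev(DNA_COMPLEMENT[v])) else
    collapse_chars(v)
}

#' Evolve a set of plastomes along the guide tree
#'
#' Runs the full simulation: builds the ancestor (unless one is supplied),
#' applies Jukes-Cantor substitutions, codon-safe indels and the configured
#' disruptions along every branch, mirrors the IRb into the IRa per leaf,
#' and assembles the ground-truth bundle. Fully reproducible under
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param ancestor optional [build_ancestor()] result to reuse.
#' @return list of class `plastome_simulation`: `records` (named list of
#'   annotated [plastome()]s), `alignment` (true [plastome_alignment()] of
#'   the full genomes, with `labels`, `category`, `region` and `ref_map`
#'   attributes), `tree`, `ir_truth` (per-leaf data.frame of true region
#'   coordinates), `hotspots` (data.frame of true hotspot intervals in
#'   ancestor and alignment coordinates), `disruptions` (realised
#'   disruption table), `branch_subs` (realised and expected substitution
#'   counts per edge), `ancestor`, `config`.
#' @export
evolve_plastomes <- function(config, ancestor = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(ancestor)) ancestor <- build_ancestor(config$plan)
  anc <- ancestor
  meta <- anc$meta
  n0 <- length(anc$reduced)
  meta$anc_pos <- seq_len(n0) - 1L
  hotspots <- config$hotspots %||%
    auto_hotspots(meta, config$n_hotspots, config$hotspot_mult)
  meta$mult <- site_multipliers(meta, config$rates, hotspots)

  tree <- ape::reorder.phylo(config$tree, "cladewise")
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("guide tree needs at least 3 leaves")
  rows <- list()
  rows[[as.character(ntip + 1L)]] <- anc$reduced
  counter <- new_codon_counter()
  gcp <- anc$plan$gc
  pbase <- c(A = (1 - gcp) / 2, C = gcp / 2, G = gcp / 2, T = (1 - gcp) / 2)
  cods <- sense_codons()
  wcod <- codon_weights(gcp)
  nedge <- nrow(tree$edge)
  branch_subs <- data.frame(parent = tree$edge[, 1L],
                            child = tree$edge[, 2L],
                            length = tree$edge.length,
                            expected = NA_real_, realized = NA_integer_)

  for (e in seq_len(nedge)) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    t_br <- tree$edge.length[[e]]
    row <- rows[[as.character(par)]]
    len <- length(row)
    nongap <- row != "-"

    ## -- substitutions (exact JC kernel per branch) ----------------------
    pc <- 0.75 * (1 - exp(-4 / 3 * t_br * meta$mult))
    pc[!nongap | meta$protect] <- 0
    hit <- which(stats::runif(len) < pc)
    changed <- 0L
    if (length(hit)) {
      in_cds <- !is.na(meta$codon_id[hit])
      h_nc <- hit[!in_cds]
      if (length(h_nc)) {
        cur <- match(row[h_nc], DNA_BASES)
        off <- sample.int(3L, length(h_nc), replace = TRUE)
        row[h_nc] <- DNA_BASES[(cur - 1L + off) %% 4L + 1L]
        changed <- changed + length(h_nc)
      }
      for (h in hit[in_cds]) {
        cc <- codon_columns(meta, h, meta$codon_id[[h]])
        if (length(cc) != 3L || any(row[cc] == "-")) next
        cur <- match(row[[h]], DNA_BASES)
        newb <- DNA_BASES[(cur - 1L + sample.int(3L, 1L)) %% 4L + 1L]
        tmp <- row[cc]; tmp[cc == h] <- newb
        if (!codon_is_stop(tmp, meta$cds_strand[[h]])) {
          row[[h]] <- newb
          changed <- changed + 1L
        }
      }
    }
    branch_subs$expected[[e]] <- sum(pc)
    branch_subs$realized[[e]] <- changed

    ## -- indels ----------------------------------------------------------
    pending <- list()
    nc_ok <- nongap & meta$category %in% c("spacer", "intron") &
      !meta$protect
    idx_nc <- which(nc_ok)
    n_ev <- stats::rpois(1L, t_br * config$indel_rate * length(idx_nc))
    for (ev in seq_len(n_ev)) {
      anchor <- idx_nc[[sample.int(length(idx_nc), 1L)]]
      ilen <- 1L + stats::rgeom(1L, config$indel_geom_p)
      if (stats::runif(1L) < 0.5) {           # deletion
        cols <- integer(0); j <- anchor
        while (length(cols) < ilen && j <= len) {
          if (nc_ok[[j]] && row[[j]] != "-") cols <- c(cols, j)
          else if (!nc_ok[[j]]) break
          j <- j + 1L
        }
        if (length(cols)) row[cols] <- "-"
      } else {                                 # insertion
        chars <- sample(DNA_BASES, ilen, replace = TRUE, prob = pbase)
        pending[[length(pending) + 1L]] <- list(
          after = anchor, chars = chars,
          meta = list(region = rep(meta$region[[anchor]], ilen),
                      category = rep(meta$category[[anchor]], ilen),
                      label = rep(meta$label[[anchor]], ilen),
                      mult = rep(meta$mult[[anchor]], ilen)))
      }
    }
    idx_cds <- which(nongap & !is.na(meta$codon_id) & !meta$protect)
    n_ev_cds <- if (length(idx_cds))
      stats::rpois(1L, t_br * config$cds_indel_rate * length(idx_cds)) else 0L
    for (ev in seq_len(n_ev_cds)) {
      h <- idx_cds[[sample.int(length(idx_cds), 1L)]]
      id0 <- meta$codon_id[[h]]
      ncod <- 1L + stats::rgeom(1L, 0.5)
      if (stats::runif(1L) < 0.5) {           # whole-codon deletion
        for (ci in seq_len(ncod) - 1L) {
          cc <- codon_columns(meta, h, id0 + ci, reach = 6000L + 3L * ncod)
          if (length(cc) != 3L || any(meta$protect[cc])) break
          row[cc] <- "-"
        }
      } else {                                 # whole-codon insertion
        cc <- codon_columns(meta, h, id0)
        if (length(cc) != 3L) next
        strand <- meta$cds_strand[[h]]
        new_cods <- sample(cods, ncod, replace = TRUE, prob = wcod)
        coding_chars <- unlist(strsplit(new_cods, ""), use.names = FALSE)
        genomic <- if (strand == "+") coding_chars else
          rev(unname(DNA_COMPLEMENT[coding_chars]))
        ids <- counter$next_id + seq_len(ncod) - 1L
        counter$next_id <- counter$next_id + ncod
        frame_g <- if (strand == "+") rep(0:2, ncod) else
          rev(rep(0:2, ncod))
        id_g <- if (strand == "+") rep(ids, each = 3L) else
          rev(rep(ids, each = 3L))
        pending[[length(pending) + 1L]] <- list(
          after = max(cc), chars = genomic,
          meta = list(region = rep(meta$region[[h]], 3L * ncod),
                      category = rep("CDS", 3L * ncod),
                      label = rep(meta$label[[h]], 3L * ncod),
                      feature_id = rep(meta$feature_id[[h]], 3L * ncod),
                      codon_id = id_g, frame = frame_g,
                      cds_strand = rep(strand, 3L * ncod),
                      mult = rep(meta$mult[[h]], 3L * ncod)))
      }
    }

    rows[[as.character(child)]] <- row
    if (length(pending)) {
      sp <- splice_columns(rows, meta, pending, as.character(child))
      rows <- sp$rows; meta <- sp$meta
    }
  }

  ## -- collect leaves, drop all-gap columns ------------------------------
  leaf_rows <- stats::setNames(
    lapply(seq_len(ntip), function(i) rows[[as.character(i)]]),
    tree$tip.label)
  keep <- Reduce(`|`, lapply(leaf_rows, function(r) r != "-"))
  leaf_rows <- lapply(leaf_rows, `[`, keep)
  for (fld in names(meta)) meta[[fld]] <- meta[[fld]][keep]

  ## -- disruptions -------------------------------------------------------
  placed <- anc$layout$placed
  disr_out <- list()
  dis <- config$disruptions
  if (!is.null(dis) && nrow(dis)) {
    for (di in seq_len(nrow(dis))) {
      tx <- dis$taxon[[di]]; gene <- dis$gene[[di]]
      if (!tx %in% names(leaf_rows) || !gene %in% placed$name) next
      fid <- which(placed$name == gene)[[1L]]
      strand <- placed$strand[[fid]]
      cols_g <- which(!is.na(meta$feature_id) & meta$feature_id == fid &
                        meta$category == "CDS")
      row <- leaf_rows[[tx]]
      type <- dis$type[[di]]; dlen <- dis$length[[di]]
      detail <- type
      if (type == "frameshift_insertion") {
        cn <- cols_g[row[cols_g] != "-"]
        anchor <- cn[[max(2L, floor(length(cn) * 0.4))]]
        chars <- sample(DNA_BASES, dlen, replace = TRUE, prob = pbase)
        ins <- list(list(after = anchor, chars = chars,
                         meta = list(region = rep(meta$region[[anchor]], dlen),
                                     category = rep("CDS", dlen),
                                     label = rep(gene, dlen),
                                     feature_id = rep(fid, dlen),
                                     mult = rep(meta$mult[[anchor]], dlen))))
        sp <- splice_columns(leaf_rows, meta, ins, tx)
        leaf_rows <- sp$rows; meta <- sp$meta
        cols_g <- which(!is.na(meta$feature_id) & meta$feature_id == fid &
                          meta$category == "CDS")
        row <- leaf_rows[[tx]]
        detail <- sprintf("%d bp insertion", dlen)
      } else if (type == "frameshift_deletion") {
        cn <- cols_g[row[cols_g] != "-"]
        start <- max(2L, floor(length(cn) * 0.4))
        row[cn[start:(start + dlen - 1L)]] <- "-"
        detail <- sprintf("%d bp deletion", dlen)
      } else if (type == "nonsense") {
        ids <- sort(unique(meta$codon_id[cols_g]))
        ids <- ids[ids < 1e12]  # ancestral codons only
        ord <- order(abs(seq_along(ids) - length(ids) / 2))
        done <- FALSE
        for (id in ids[ord]) {
          cc <- cols_g[!is.na(meta$codon_id[cols_g]) &
                         meta$codon_id[cols_g] == id]
          if (length(cc) != 3L || any(row[cc] == "-") ||
              any(meta$protect[cc])) next
          cod <- if (strand == "+") row[cc] else rev(DNA_COMPLEMENT[row[cc]])
          for (stp in STOP_CODONS) {
            sv <- strsplit(stp, "")[[1L]]
            dif <- which(cod != sv)
            if (length(dif) == 1L) {
              j <- dif[[1L]]
              gcol <- if (strand == "+") cc[[j]] else cc[[4L - j]]
              row[[gcol]] <- if (strand == "+") sv[[j]] else
                DNA_COMPLEMENT[[sv[[j]]]]
              detail <- sprintf("%s->%s", collapse_chars(cod), stp)
              done <- TRUE
              break
            }
          }
          if (done) break
        }
      }
      leaf_rows[[tx]] <- row
      # guarantee a premature stop for frameshift disruptions
      s <- oriented_gene_seq(leaf_rows[[tx]], cols_g, strand)
      rep_ <- scan_orf(s)
      if (startsWith(type, "frameshift") && !length(rep_$internal_stops)) {
        q <- 3L * floor(0.7 * nchar(s) / 3L) + 1L
        leaf_rows[[tx]] <- set_oriented_chars(leaf_rows[[tx]], cols_g,
                                              strand, q:(q + 2L),
                                              c("T", "A", "A"))
        detail <- paste0(detail, "+forced_stop")
      }
      disr_out[[length(disr_out) + 1L]] <-
        data.frame(taxon = tx, gene = gene, type = type, length = dlen,
                   detail = detail, stringsAsFactors = FALSE)
    }
  }
  disruptions <- if (length(disr_out)) do.call(rbind, disr_out) else
    data.frame(taxon = character(0), gene = character(0),
               type = character(0), length = integer(0),
               detail = character(0))

  ## -- assemble alignment, records, truth --------------------------------
  irb_cols <- which(meta$region == "IRb")
  K <- length(irb_cols)
  mat_red <- do.call(rbind, leaf_rows)
  mirror <- t(apply(mat_red[, irb_cols, drop = FALSE], 1L, function(r)
    rev(unname(DNA_COMPLEMENT[r]))))
  mat <- cbind(mat_red, mirror)
  labels <- c(meta$label, rev(meta$label[irb_cols]))
  category <- c(meta$category, rev(meta$category[irb_cols]))
  region <- c(meta$region, rep("IRa", K))
  ref_row <- mat[1L, ]
  ref_map <- ifelse(ref_row != "-", cumsum(ref_row != "-") - 1L, NA_integer_)
  aln <- plastome_alignment(mat, labels = labels, category = category,
                            region = region, ref_map = ref_map)

  records <- list()
  ir_truth <- list()
  for (tx in names(leaf_rows)) {
    row <- leaf_rows[[tx]]
    ng <- row != "-"
    cum <- cumsum(ng)
    nred_leaf <- cum[[length(cum)]]
    lsc_len <- sum(ng[meta$region == "LSC"])
    irb_len <- sum(ng[irb_cols])
    ssc_len <- nred_leaf - lsc_len - irb_len
    reduced_seq <- collapse_chars(row[ng])
    irb_seq <- substr(reduced_seq, lsc_len + 1L, lsc_len + irb_len)
    full_seq <- paste0(reduced_seq, revcomp(irb_seq))
    before <- c(0L, cum)  # before[col] = non-gaps strictly before col

    feats <- list()
    map_part <- function(s, e) {
      base_cols <- which(!is.na(meta$anc_pos) & meta$anc_pos >= s &
                           meta$anc_pos < e)
      if (!length(base_cols)) return(NULL)
      rng <- range(base_cols)
      cols <- rng[[1L]]:rng[[2L]]
      plen <- sum(ng[cols])
      if (!plen) return(NULL)
      st <- before[[rng[[1L]]]]
      c(st, st + plen)
    }
    mirror_part <- function(p, b0, blen) {
      c(nred_leaf + b0 + blen - p[[2L]], nred_leaf + b0 + blen - p[[1L]])
    }
    for (fi in seq_len(nrow(placed))) {
      parts0 <- anc$layout$parts[[fi]]
      mapped <- lapply(seq_len(nrow(parts0)), function(pe)
        map_part(parts0[pe, 1L], parts0[pe, 2L]))
      mapped <- Filter(Negate(is.null), mapped)
      if (!length(mapped)) next
      pm <- do.call(rbind, mapped)
      feats[[length(feats) + 1L]] <-
        plastome_feature(placed$name[[fi]], placed$kind[[fi]], pm,
                         placed$strand[[fi]])
      if (placed$region[[fi]] == "IRB") {
        mm <- do.call(rbind, lapply(mapped, mirror_part, b0 = lsc_len,
                                    blen = irb_len))
        mm <- mm[order(mm[, 1L]), , drop = FALSE]
        feats[[length(feats) + 1L]] <-
          plastome_feature(placed$name[[fi]], placed$kind[[fi]], mm,
                           if (placed$strand[[fi]] == "+") "-" else "+")
      }
    }
    records[[tx]] <- plastome(tx, full_seq, feats)
    ir_truth[[tx]] <- data.frame(
      taxon = tx, genome_length = nred_leaf + irb_len,
      lsc_len = lsc_len, ssc_len = ssc_len, ir_len = irb_len,
      irb_start = lsc_len, irb_end = lsc_len + irb_len,
      ira_start = nred_leaf, ira_end = nred_leaf + irb_len)
  }
  ir_truth <- do.call(rbind, ir_truth)
  rownames(ir_truth) <- NULL

  hot_truth <- do.call(rbind, lapply(hotspots, function(h) {
    cols <- which(!is.na(meta$anc_pos) & meta$anc_pos >= h$start &
                    meta$anc_pos < h$end)
    data.frame(anc_start = h$start, anc_end = h$end, mult = h$mult,
               col_start = min(cols) - 1L, col_end = max(cols))
  }))

  structure(list(records = records, alignment = aln, tree = tree,
                 ir_truth = ir_truth, hotspots = hot_truth,
                 disruptions = disruptions, branch_subs = branch_subs,
                 ancestor = anc, config = config),
            class = "plastome_simulation")
}

#' @export
print.plastome_simulation <- function(x, ...) {
  cat(sprintf("<plastome_simulation> %d leaves, alignment %d x %d\n",
              length(x$records), nrow(x$alignment), ncol(x$alignment)))
  invisible(x)
}

#' Write all simulation artifacts to a directory
#'
#' Emits one GenBank and one FASTA file per leaf genome, the true alignment
#' (aligned FASTA), the guide tree (newick) and a JSON ground-truth file
#' (region coordinates, hotspot intervals, disruptions, branch substitution
#' counts).
#'
#' @param sim an [evolve_plastomes()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tx in names(sim$records)) {
    gb <- file.path(dir, paste0(tx, ".gb"))
    fa <- file.path(dir, paste0(tx, ".fasta"))
    write_genbank(sim$records[[tx]], gb)
    write_fasta(stats::setNames(sim$records[[tx]]$sequence, tx), fa)
    paths <- c(paths, gb, fa)
  }
  aln_path <- file.path(dir, "true_alignment.fasta")
  write_alignment(sim$alignment, aln_path)
  tree_path <- file.path(dir, "guide_tree.nwk")
  write_newick(sim$tree, tree_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(ir_truth = sim$ir_truth,
                            hotspots = sim$hotspots,
                            disruptions = sim$disruptions,
                            branch_subs = sim$branch_subs,
                            seed = sim$config$seed),
                       truth_path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, alignment = aln_path, tree = tree_path,
              truth = truth_path))
}
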