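# Per-genome and cross-genome summary features: gene censuses, coding /
# noncoding partition of the genome length, region-length dispersions.

#' Gene census of an annotated plastome
#'
#' Unique genes are distinct gene names; a gene is counted as duplicated in
#' the inverted repeat when it is annotated at least twice with one copy
#' fully inside each repeat. Intron counts derive from multi-part features
#' (`parts - 1`), taken once per unique gene.
#'
#' @param record an annotated [plastome()] record.
#' @param partition optional [partition_regions()] result; computed from the
#'   record when absent (needed only for the IR-duplication count).
#' @return list of class `gene_census` with fields `unique_genes`,
#'   `total_genes`, `duplicated_in_ir`, `cds`, `trna`, `rrna`, `one_intron`,
#'   `two_intron`.
#' @export
gene_census <- function(record, partition = NULL) {
  feats <- record$features
  if (!length(feats)) {
    return(structure(list(unique_genes = 0L, total_genes = 0L,
                          duplicated_in_ir = 0L, cds = 0L, trna = 0L,
                          rrna = 0L, one_intron = 0L, two_intron = 0L),
                     class = "gene_census"))
  }
  names_ <- vapply(feats, `[[`, "", "name")
  kinds <- vapply(feats, `[[`, "", "kind")
  introns <- vapply(feats, `[[`, 0L, "intron_count")
  uniq <- !duplicated(names_)

  dup_ir <- 0L
  if (any(duplicated(names_))) {
    if (is.null(partition)) {
      ml <- min(10000L, nchar(record$sequence) %/% 8L)
      ip <- find_inverted_repeat(record, min_len = ml)
      if (!is.null(ip)) partition <- partition_regions(record, ip)
    }
    if (!is.null(partition)) {
      n <- partition$genome_length
      inside <- function(span, iv) {
        # feature fully inside region interval (circle arithmetic)
        circ_fwd(iv$start, span[1L], n) + (span[2L] - span[1L]) <=
          interval_length(iv)
      }
      for (nm in unique(names_[duplicated(names_)])) {
        ix <- which(names_ == nm)
        spans <- lapply(feats[ix], feature_span)
        in_b <- vapply(spans, inside, TRUE, iv = partition$irb)
        in_a <- vapply(spans, inside, TRUE, iv = partition$ira)
        if (any(in_b) && any(in_a)) dup_ir <- dup_ir + 1L
      }
    }
  }

  per_gene_introns <- tapply(introns, names_, max)
  structure(list(
    unique_genes = sum(uniq),
    total_genes = length(feats),
    duplicated_in_ir = dup_ir,
    cds = sum(uniq & kinds == "CDS"),
    trna = sum(uniq & kinds == "tRNA"),
    rrna = sum(uniq & kinds == "rRNA"),
    one_intron = sum(per_gene_introns == 1L),
    two_intron = sum(per_gene_introns == 2L)
  ), class = "gene_census")
}

#' @export
print.gene_census <- function(x, ...) {
  cat(sprintf(paste0("<gene_census> %d unique (%d CDS, %d tRNA, %d rRNA), ",
                     "%d duplicated in IR, %d total\n"),
              x$unique_genes, x$cds, x$trna, x$rrna, x$duplicated_in_ir,
              x$total_genes))
  invisible(x)
}

#' Coding and noncoding lengths of a genome
#'
#' Coding length is the union of all exon intervals of CDS/tRNA/rRNA
#' features (overlapping annotations counted once); noncoding is the
#' remainder of the genome.
#'
#' @param record an annotated [plastome()] record.
#' @return list with `coding_bp`, `noncoding_bp`, `coding_percent`.
#' @export
coding_noncoding_lengths <- function(record) {
  n <- nchar(record$sequence)
  if (!length(record$features))
    return(list(coding_bp = 0L, noncoding_bp = n, coding_percent = 0))
  parts <- do.call(rbind, lapply(record$features, `[[`, "parts"))
  # split intervals that wrap the origin
  wraps <- parts[, "end"] > n
  if (any(wraps)) {
    extra <- cbind(start = 0L, end = parts[wraps, "end"] - n)
    parts[wraps, "end"] <- n
    parts <- rbind(parts, extra)
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = parts[, "start"] + 1L,
                                         end = parts[, "end"]))
  coding <- sum(IRanges::width(ir))
  list(coding_bp = coding, noncoding_bp = n - coding,
       coding_percent = 100 * coding / n)
}

#' Cross-sample summary of region lengths
#'
#' Mean and sample standard deviation (denominator n-1) of per-sample region
#' lengths, rounded half away from zero to the nearest bp - the convention
#' under which the dispersion of plastome region lengths is conventionally
#' reported.
#'
#' @param lengths numeric vector of per-sample lengths in bp (>= 2 samples).
#' @param region_class label, one of `"LSC"`, `"SSC"`, `"IR"`, `"coding"`,
#'   `"noncoding"`, `"full"`.
#' @return list with `region_class`, `n`, `lengths`, `mean`, `sd` (rounded
#'   integers) and `mean_raw`, `sd_raw`.
#' @export
region_length_summary <- function(lengths, region_class = "LSC") {
  region_class <- match.arg(region_class,
                            c("LSC", "SSC", "IR", "coding", "noncoding",
                              "full"))
  if (length(lengths) < 2L) stop("need at least 2 samples")
  m <- mean(lengths)
  s <- stats::sd(lengths)
  list(region_class = region_class, n = length(lengths), lengths = lengths,
       mean = as.integer(round_half_up(m)), sd = as.integer(round_half_up(s)),
       mean_raw = m, sd_raw = s)
}

#' Region lengths across a list of quadripartite partitions
#'
#' @param partitions list of [partition_regions()] results.
#' @param region_class `"LSC"`, `"SSC"` or `"IR"` (IRb length).
#' @return numeric vector of lengths, one per sample.
#' @export
region_lengths <- function(partitions, region_class = c("LSC", "SSC", "IR")) {
  region_class <- match.arg(region_class)
  key <- c(LSC = "LSC", SSC = "SSC", IR = "IRb")[[region_class]]
  vapply(partitions, function(p) unname(p$lengths[[key]]), 0)
}

#' Published region-length and composition table for the Cornales study set
#'
#' Loads the packaged summary of the 16 deposited plastomes (15 Cornales
#' individuals plus the Fouquieria diguetii outgroup, GenBank
#' MG524990-MG525005): full, LSC, SSC, IR, coding and noncoding lengths and
#' GC percentages. Cross-genome summaries conventionally exclude the
#' outgroup row.
#'
#' @param include_outgroup keep the Fouquieria row (default FALSE).
#' @return data.frame, one row per plastome.
#' @export
cornales_summary <- function(include_outgroup = FALSE) {
  path <- system.file("extdata", "cornales_plastome_summary.tsv",
                      package = "plastomics", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!include_outgroup) tab <- tab[tab$order == "Cornales", ]
  tab
}
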