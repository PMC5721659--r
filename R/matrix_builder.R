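# Construction of the three phylogenetic data sets (complete / coding /
# noncoding, with the second inverted-repeat copy removed), the three
# alignment filtering strategies, and functional partition subsets.

CODING_CATEGORIES <- c("CDS", "tRNA", "rRNA")

#' Build the complete / coding / noncoding data sets
#'
#' Coding columns are those labelled as CDS exons, tRNAs or rRNAs; noncoding
#' columns are introns and intergenic spacers. When requested, every column
#' tagged as the second repeat copy (`IRa`) is dropped from all three data
#' sets first, to avoid duplicated signal.
#'
#' @param aln a [plastome_alignment()] carrying `category` (and, if
#'   `drop_second_ir`, `region`) attributes.
#' @param drop_second_ir drop `IRa` columns (default TRUE).
#' @return list of class `dataset_bundle` with elements `complete`, `coding`,
#'   `noncoding` (each a [plastome_alignment()]).
#' @export
build_datasets <- function(aln, drop_second_ir = TRUE) {
  category <- attr(aln, "category")
  if (is.null(category)) stop("alignment lacks per-column provenance")
  if (drop_second_ir) {
    region <- attr(aln, "region")
    if (is.null(region)) stop("drop_second_ir requires a region attribute")
    aln <- aln_subset(aln, which(region != "IRa"))
    category <- attr(aln, "category")
  }
  coding_cols <- category %in% CODING_CATEGORIES
  structure(list(complete = aln,
                 coding = aln_subset(aln, which(coding_cols)),
                 noncoding = aln_subset(aln, which(!coding_cols))),
            class = "dataset_bundle")
}

#' Strict alignment filter: drop every column containing a gap
#'
#' @param aln a [plastome_alignment()].
#' @return the gap-free columns, order preserved (possibly zero columns).
#' @export
filter_strict <- function(aln) {
  keep <- colSums(unclass(aln) == "-") == 0L
  aln_subset(aln, which(keep))
}

#' Light alignment filter
#'
#' A deterministic two-step trim: (1) drop columns whose gap fraction
#' exceeds `max_gap_fraction`; (2) drop maximal runs, at least
#' `min_conserved_block` columns long, of consecutive columns that both
#' contain a gap and fall below `min_conservation` in majority-state
#' frequency (poorly aligned gappy blocks). Gap-free columns are never
#' removed, so the light filter always retains a superset of the strict
#' filter's columns.
#'
#' @param aln a [plastome_alignment()].
#' @param max_gap_fraction columns with a higher gap fraction are dropped
#'   (default 0.5).
#' @param min_conserved_block minimum run length for step 2 (default 10).
#' @param min_conservation majority-state frequency below which a gappy
#'   column counts as poorly aligned (default 0.5).
#' @return the filtered [plastome_alignment()].
#' @export
filter_light <- function(aln, max_gap_fraction = 0.5,
                         min_conserved_block = 10L, min_conservation = 0.5) {
  m <- unclass(aln)
  nt <- nrow(m)
  gap_frac <- colSums(m == "-") / nt
  keep1 <- gap_frac <= max_gap_fraction
  aln1 <- aln_subset(aln, which(keep1))
  m1 <- unclass(aln1)
  if (!ncol(m1)) return(aln1)
  cnt <- column_state_counts(aln1)
  nongap <- colSums(m1 != "-")
  has_gap <- nongap < nt
  maj <- apply(cnt, 2L, max) / pmax(nongap, 1L)
  poor <- has_gap & maj < min_conservation
  r <- rle(poor)
  drop_run <- r$values & r$lengths >= min_conserved_block
  keep2 <- inverse.rle(list(lengths = r$lengths, values = !drop_run))
  aln_subset(aln1, which(keep2))
}

#' Apply a named filtering strategy
#'
#' @param aln a [plastome_alignment()].
#' @param mode `"unfiltered"`, `"light"` or `"strict"`.
#' @param ... passed to [filter_light()].
#' @return the filtered alignment.
#' @export
filter_alignment <- function(aln, mode = c("unfiltered", "light", "strict"),
                             ...) {
  mode <- match.arg(mode)
  switch(mode,
         unfiltered = aln,
         light = filter_light(aln, ...),
         strict = filter_strict(aln))
}

#' Build functional partition subsets from column provenance
#'
#' One subset per gene, intron or spacer label; any subset shorter than
#' `min_subset` columns, or containing no variable site, is merged into a
#' pooled subset for its functional category (CDS, tRNA, rRNA, intron,
#' spacer).
#'
#' @param aln a [plastome_alignment()] with `labels` and `category`
#'   attributes.
#' @param min_subset minimum stand-alone subset size in columns (default
#'   200).
#' @return list of class `partition_scheme`: `subsets` (named list of sorted
#'   column index vectors), `category` (per subset), `merged_small`
#'   (labels that were pooled).
#' @export
build_partitions <- function(aln, min_subset = 200L) {
  labels <- attr(aln, "labels")
  category <- attr(aln, "category")
  if (is.null(labels) || is.null(category))
    stop("alignment lacks per-column provenance")
  fl <- site_flags(aln)
  cols_by_label <- split(seq_len(ncol(aln)), labels)
  subsets <- list(); subset_cat <- character(0); merged <- character(0)
  pooled <- list()
  for (lab in names(cols_by_label)) {
    cols <- cols_by_label[[lab]]
    cat_ <- category[cols[[1L]]]
    if (length(cols) >= min_subset && any(fl$variable[cols])) {
      subsets[[lab]] <- cols
      subset_cat[lab] <- cat_
    } else {
      pooled[[cat_]] <- c(pooled[[cat_]], cols)
      merged <- c(merged, lab)
    }
  }
  for (cat_ in names(pooled)) {
    nm <- paste0("pooled_", cat_)
    subsets[[nm]] <- sort(pooled[[cat_]])
    subset_cat[nm] <- cat_
  }
  structure(list(subsets = subsets, category = subset_cat,
                 merged_small = merged, n_columns = ncol(aln)),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("<partition_scheme> %d subsets over %d columns (%d merged)\n",
              length(x$subsets), x$n_columns, length(x$merged_small)))
  invisible(x)
}

# contiguous ranges of a sorted integer vector, as "a-b" pieces (1-based)
index_ranges <- function(cols) {
  brk <- c(TRUE, diff(cols) != 1L)
  grp <- cumsum(brk)
  vapply(split(cols, grp), function(ix) {
    if (length(ix) == 1L) as.character(ix[[1L]])
    else paste0(ix[[1L]], "-", ix[[length(ix)]])
  }, "")
}

#' Write a partition scheme as RAxML-style partition text
#'
#' One line per subset: `DNA, name = start-end[, start-end...]` (1-based
#' inclusive column ranges).
#'
#' @param scheme a [build_partitions()] result.
#' @param path output path.
#' @export
write_partitions_raxml <- function(scheme, path) {
  lines <- vapply(names(scheme$subsets), function(nm) {
    sprintf("DNA, %s = %s", nm,
            paste(index_ranges(scheme$subsets[[nm]]), collapse = ", "))
  }, "")
  writeLines(lines, path)
  invisible(NULL)
}

#' Write a partition scheme as a NEXUS sets block
#'
#' @param scheme a [build_partitions()] result.
#' @param path output path.
#' @export
write_partitions_nexus <- function(scheme, path) {
  body <- vapply(names(scheme$subsets), function(nm) {
    sprintf("  charset %s = %s;", nm,
            paste(index_ranges(scheme$subsets[[nm]]), collapse = " "))
  }, "")
  writeLines(c("#NEXUS", "begin sets;", body, "end;"), path)
  invisible(NULL)
}
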