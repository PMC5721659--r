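# Alignment container and divergence statistics: per-column site
# classification, the sliding-window mutation-event proportion
# 100 * (NS + ID) / L, hotspot calling above a strict threshold, and
# windowed pairwise identity.

UNAMBIG <- c("A", "C", "G", "T")

#' Construct an alignment matrix
#'
#' @param x named character vector of equal-length aligned sequences, or a
#'   character matrix (rows = taxa) of single characters.
#' @param labels optional per-column provenance label (feature, intron or
#'   spacer name).
#' @param category optional per-column functional category
#'   (`CDS`/`tRNA`/`rRNA`/`intron`/`spacer`).
#' @param region optional per-column region tag (`LSC`/`IRb`/`SSC`/`IRa`).
#' @param ref_map optional per-column coordinate on a reference sample.
#' @return character matrix of class `plastome_alignment` with the provenance
#'   attributes attached.
#' @export
plastome_alignment <- function(x, labels = NULL, category = NULL,
                               region = NULL, ref_map = NULL) {
  if (!is.matrix(x)) {
    stopifnot(is.character(x), !is.null(names(x)))
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) stop("aligned sequences differ in length")
    x <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(x) <- names(lens)
  }
  if (anyDuplicated(rownames(x))) stop("taxa must be unique")
  for (a in c("labels", "category", "region", "ref_map")) {
    v <- get(a)
    if (!is.null(v)) {
      stopifnot(length(v) == ncol(x))
      attr(x, a) <- v
    }
  }
  class(x) <- c("plastome_alignment", class(x))
  x
}

#' Read an aligned FASTA file into a `plastome_alignment`
#' @param path aligned FASTA.
#' @return a [plastome_alignment()].
#' @export
read_alignment <- function(path) plastome_alignment(read_fasta(path))

#' Write a `plastome_alignment` to aligned FASTA
#' @param aln a [plastome_alignment()].
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln, 1L, paste, collapse = "")
  write_fasta(seqs, path)
}

# subset columns, carrying provenance attributes along
aln_subset <- function(aln, cols) {
  out <- unclass(aln)[, cols, drop = FALSE]
  for (a in c("labels", "category", "region", "ref_map")) {
    v <- attr(aln, a)
    if (!is.null(v)) attr(out, a) <- v[cols]
  }
  class(out) <- c("plastome_alignment", class(out))
  out
}

# per-column state counts over unambiguous non-gap characters
column_state_counts <- function(aln) {
  m <- unclass(aln)
  do.call(rbind, lapply(UNAMBIG, function(b) .colSums(m == b, nrow(m), ncol(m))))
}

# per-column flags used by both classification and window statistics
site_flags <- function(aln) {
  cnt <- column_state_counts(aln)
  covered <- colSums(cnt)
  n_states <- colSums(cnt > 0L)
  list(
    classifiable = covered >= 2L,
    constant = covered >= 2L & n_states == 1L,
    variable = n_states >= 2L,
    informative = colSums(cnt >= 2L) >= 2L & n_states >= 2L,
    gap_pattern = {
      g <- unclass(aln) == "-"
      as.vector(2^(seq_len(nrow(aln)) - 1L) %*% g)  # exact for <= 53 taxa
    }
  )
}

#' Classify alignment columns
#'
#' Using unambiguous non-gap states only: a column is constant when one state
#' is present (in at least two taxa), variable with two or more states,
#' parsimony-informative when at least two states each occur in at least two
#' taxa, and a singleton when variable but not informative. Columns with
#' fewer than two unambiguous bases are unclassifiable.
#'
#' @param aln a [plastome_alignment()] with >= 2 taxa.
#' @return list of class `site_classes`: counts `total`, `constant`,
#'   `variable`, `parsimony_informative`, `singleton` and their percentages
#'   of the total length.
#' @export
classify_sites <- function(aln) {
  if (nrow(aln) < 2L) stop("site classification needs at least 2 taxa")
  fl <- site_flags(aln)
  n <- ncol(aln)
  counts <- c(total = n,
              constant = sum(fl$constant),
              variable = sum(fl$variable),
              parsimony_informative = sum(fl$informative),
              singleton = sum(fl$variable & !fl$informative))
  structure(list(counts = counts,
                 percent = round_half_up(100 * counts / n, 1)),
            class = "site_classes")
}

#' @export
print.site_classes <- function(x, ...) {
  cat(sprintf(
    "<site_classes> %d sites: %d variable (%.1f%%), %d informative (%.1f%%)\n",
    x$counts[["total"]], x$counts[["variable"]], x$percent[["variable"]],
    x$counts[["parsimony_informative"]],
    x$percent[["parsimony_informative"]]))
  invisible(x)
}

# indel events within a column range: maximal runs of an identical non-empty
# gap pattern; an event straddling the range boundary counts in this range
indel_events_in <- function(gap_pattern, from, to) {
  r <- rle(gap_pattern[from:to])
  sum(r$values != 0)
}

#' Count substitution sites and indel events in a window
#'
#' `NS` is the number of variable columns (variation among non-gap,
#' unambiguous states); `ID` the number of indel events, an event being a
#' maximal run of consecutive columns sharing an identical gap
#' presence/absence pattern across taxa that differs from the all-present
#' pattern. An event straddling the window boundary counts in each window it
#' touches.
#'
#' @param aln a [plastome_alignment()].
#' @param window [seq_interval()] or `c(start, end)` in 0-based half-open
#'   alignment columns.
#' @return named vector `c(NS = ..., ID = ...)`.
#' @export
count_window_events <- function(aln, window) {
  if (inherits(window, "seq_interval")) window <- c(window$start, window$end)
  if (window[2L] <= window[1L]) stop("empty window")
  if (window[1L] < 0L || window[2L] > ncol(aln)) stop("window out of range")
  fl <- site_flags(aln)
  cols <- (window[1L] + 1L):window[2L]
  c(NS = sum(fl$variable[cols]),
    ID = indel_events_in(fl$gap_pattern, cols[1L], cols[length(cols)]))
}

#' Sliding-window scan of the mutation-event proportion
#'
#' Windows start at 0, `step`, 2*`step`, ... while `start + window_len` fits,
#' plus one truncated window covering any remaining tail. The proportion of
#' mutation events is `100 * (NS + ID) / L` with `L` the aligned window
#' length (gap columns included).
#'
#' @param aln a [plastome_alignment()].
#' @param window_len window length in alignment columns (default 600).
#' @param step step size (default 200).
#' @return data.frame with `start`, `end`, `NS`, `ID`, `L`, `proportion`.
#' @export
window_scan <- function(aln, window_len = 600L, step = 200L) {
  len <- ncol(aln)
  if (len < window_len) {
    warning("alignment shorter than window length; returning one window")
    starts <- 0L
  } else {
    starts <- seq.int(0L, len - window_len, by = step)
    tail_end <- starts[length(starts)] + window_len
    if (tail_end < len) starts <- c(starts, starts[length(starts)] + step)
  }
  ends <- pmin(starts + window_len, len)
  fl <- site_flags(aln)
  ns <- integer(length(starts)); id <- integer(length(starts))
  for (i in seq_along(starts)) {
    cols <- (starts[i] + 1L):ends[i]
    ns[i] <- sum(fl$variable[cols])
    id[i] <- indel_events_in(fl$gap_pattern, cols[1L], cols[length(cols)])
  }
  L <- ends - starts
  data.frame(start = starts, end = ends, NS = ns, ID = id, L = L,
             proportion = round_half_up(100 * (ns + id) / L, 2))
}

#' Call mutational hotspots from a window scan
#'
#' Windows whose proportion strictly exceeds the threshold are merged when
#' overlapping or adjacent; each merged region reports its peak proportion
#' and the provenance labels it overlaps.
#'
#' @param windows result of [window_scan()].
#' @param threshold percent threshold, strict (default 20).
#' @param labels optional per-column label vector (e.g.
#'   `attr(aln, "labels")`) used to annotate regions.
#' @return data.frame with `start`, `end`, `peak_proportion`, `features`
#'   (comma-separated labels); zero rows when nothing qualifies.
#' @export
call_hotspots <- function(windows, threshold = 20, labels = NULL) {
  qual <- windows[windows$proportion > threshold, , drop = FALSE]
  empty <- data.frame(start = integer(0), end = integer(0),
                      peak_proportion = numeric(0), features = character(0))
  if (!nrow(qual)) return(empty)
  qual <- qual[order(qual$start), , drop = FALSE]
  regions <- list()
  cur <- c(qual$start[1L], qual$end[1L]); peak <- qual$proportion[1L]
  if (nrow(qual) > 1L) {
    for (i in 2:nrow(qual)) {
      if (qual$start[i] <= cur[2L]) {
        cur[2L] <- max(cur[2L], qual$end[i])
        peak <- max(peak, qual$proportion[i])
      } else {
        regions[[length(regions) + 1L]] <- c(cur, peak)
        cur <- c(qual$start[i], qual$end[i]); peak <- qual$proportion[i]
      }
    }
  }
  regions[[length(regions) + 1L]] <- c(cur, peak)
  out <- do.call(rbind, regions)
  feats <- vapply(seq_len(nrow(out)), function(i) {
    if (is.null(labels)) return(NA_character_)
    lab <- unique(labels[(out[i, 1L] + 1L):out[i, 2L]])
    paste(lab[!is.na(lab)], collapse = ",")
  }, "")
  data.frame(start = as.integer(out[, 1L]), end = as.integer(out[, 2L]),
             peak_proportion = out[, 3L], features = feats)
}

#' Windowed percent identity to a reference taxon
#'
#' Identity per window is `matches / (matches + mismatches)` over columns
#' where neither the reference nor the query has a gap.
#'
#' @param aln a [plastome_alignment()].
#' @param ref_taxon reference row name.
#' @param window_len,step window geometry (defaults 600/200).
#' @return data.frame with `taxon`, `start`, `end`, `identity` (percent;
#'   `NA` when a window has no comparable columns).
#' @export
pairwise_identity <- function(aln, ref_taxon, window_len = 600L,
                              step = 200L) {
  if (!ref_taxon %in% rownames(aln)) stop("unknown taxon: ", ref_taxon)
  len <- ncol(aln)
  starts <- if (len < window_len) 0L else seq.int(0L, len - window_len, step)
  ends <- pmin(starts + window_len, len)
  ref <- unclass(aln)[ref_taxon, ]
  others <- setdiff(rownames(aln), ref_taxon)
  res <- list()
  for (tx in others) {
    q <- unclass(aln)[tx, ]
    comparable <- ref != "-" & q != "-"
    match_ <- comparable & ref == q
    cm <- cumsum(comparable); mm <- cumsum(match_)
    nc <- cm[ends] - c(0, cm)[starts + 1L]
    nm <- mm[ends] - c(0, mm)[starts + 1L]
    res[[tx]] <- data.frame(taxon = tx, start = starts, end = ends,
                            identity = ifelse(nc > 0, 100 * nm / nc, NA_real_))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a window table as tab-separated text
#' @param windows result of [window_scan()].
#' @param path output path.
#' @export
write_window_table <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Write hotspot regions as BED (labels in the name field)
#' @param hotspots result of [call_hotspots()].
#' @param chrom chromosome/sample name for the first BED column.
#' @param path output path.
#' @export
hotspots_to_bed <- function(hotspots, chrom, path) {
  if (nrow(hotspots)) {
    tab <- data.frame(chrom = chrom, start = hotspots$start,
                      end = hotspots$end,
                      name = ifelse(is.na(hotspots$features), ".",
                                    hotspots$features),
                      score = hotspots$peak_proportion)
  } else {
    tab <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}
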