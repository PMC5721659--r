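# Internal helpers shared across modules. Sequences are handled either as
# single upper-case strings (I/O boundary) or as character vectors of single
# bases (hot paths); intervals are 0-based half-open throughout.

DNA_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", N = "N",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", "-" = "-"
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes and gap characters are complemented to their
#' counterparts; case is normalised to upper.
#'
#' @param x single character string over the IUPAC nucleotide alphabet.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(revcomp_chars(chars(x)), collapse = "")
}

# character-vector version, used in hot paths
revcomp_chars <- function(v) {
  out <- DNA_COMPLEMENT[rev(toupper(v))]
  if (anyNA(out)) stop("non-IUPAC character in sequence")
  unname(out)
}

complement_chars <- function(v) {
  out <- DNA_COMPLEMENT[toupper(v)]
  if (anyNA(out)) stop("non-IUPAC character in sequence")
  unname(out)
}

chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

collapse_chars <- function(v) paste(v, collapse = "")

# round half away from zero (round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Construct a 0-based half-open sequence interval
#'
#' @param start,end integers, 0-based half-open; `end` may exceed the sequence
#'   length to denote an interval that wraps the origin of a circular
#'   sequence (use together with `seq_len`).
#' @param strand `"+"` or `"-"`.
#' @return a list with class `seq_interval`.
#' @export
seq_interval <- function(start, end, strand = "+") {
  stopifnot(start >= 0, end > start, strand %in% c("+", "-"))
  structure(list(start = as.integer(start), end = as.integer(end),
                 strand = strand),
            class = "seq_interval")
}

interval_length <- function(iv) iv$end - iv$start

# extract interval (possibly wrapping: end > nchar(seq)) from circular string
extract_circular <- function(seq_str, start, end) {
  n <- nchar(seq_str)
  stopifnot(end > start, end - start <= n)
  if (end <= n) {
    substr(seq_str, start + 1L, end)
  } else {
    paste0(substr(seq_str, start + 1L, n), substr(seq_str, 1L, end - n))
  }
}

# position membership on a circle for a (start, end) pair with end possibly > n
circ_contains <- function(start, end, pos, n) {
  p <- pos %% n
  s <- start %% n
  e <- end
  if (e > n) {
    p >= s | p < (e - n)
  } else {
    p >= s & p < e
  }
}

# signed forward distance from a to b on a circle of size n (0 <= d < n)
circ_fwd <- function(a, b, n) (b - a) %% n

`%||%` <- function(a, b) if (is.null(a)) b else a
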