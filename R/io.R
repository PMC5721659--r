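# Annotated-genome data model and flat-file I/O.
#
# A `plastome` is a linearised circular genome: a single nucleotide string, a
# circular flag and a list of features. Coordinates are 0-based half-open
# internally; the GenBank 1-based inclusive convention exists only at the I/O
# boundary.

#' Create an annotated plastid genome record
#'
#' @param id accession or sample identifier.
#' @param sequence nucleotide string (IUPAC alphabet; case-insensitive).
#' @param features list of features built with [plastome_feature()].
#' @param circular logical; plastomes are circular.
#' @return an object of class `plastome`.
#' @export
plastome <- function(id, sequence, features = list(), circular = TRUE) {
  sequence <- toupper(sequence)
  stopifnot(nchar(sequence) > 0L)
  if (grepl("[^ACGTNRYSWKMBVDH]", sequence))
    stop("sequence contains non-IUPAC characters")
  n <- nchar(sequence)
  for (f in features) {
    if (any(f$parts[, "end"] > n + n) || any(f$parts[, "start"] < 0))
      stop("feature interval out of range for '", f$name, "'")
  }
  structure(list(id = id, sequence = sequence, circular = circular,
                 features = features),
            class = "plastome")
}

#' Create a feature annotation
#'
#' @param name gene symbol (e.g. `"rbcL"`); matching is case-sensitive.
#' @param kind one of `"CDS"`, `"tRNA"`, `"rRNA"`.
#' @param parts integer matrix with columns `start`, `end` (0-based half-open
#'   exon intervals, in annotation order) or a single `c(start, end)` pair.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `plastome_feature`; `intron_count` is
#'   `nrow(parts) - 1`.
#' @export
plastome_feature <- function(name, kind, parts, strand = "+") {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA"))
  if (is.null(dim(parts))) parts <- matrix(parts, ncol = 2L)
  colnames(parts) <- c("start", "end")
  storage.mode(parts) <- "integer"
  stopifnot(nrow(parts) >= 1L, all(parts[, "end"] > parts[, "start"]),
            strand %in% c("+", "-"))
  structure(list(name = name, kind = kind, strand = strand,
                 parts = parts, intron_count = nrow(parts) - 1L),
            class = "plastome_feature")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %s bp, %s, %d features\n", x$id,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear", length(x$features)))
  invisible(x)
}

feature_span <- function(f) c(min(f$parts[, "start"]), max(f$parts[, "end"]))

feature_length <- function(f) sum(f$parts[, "end"] - f$parts[, "start"])

## ---------------------------------------------------------------------------
## GenBank flat file
## ---------------------------------------------------------------------------

# recursive-descent parser for GenBank location strings; returns list(parts
# matrix 0-based half-open in genomic order, strand)
parse_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  parse1 <- function(s, strand) {
    if (startsWith(s, "complement(")) {
      inner <- substr(s, 12L, nchar(s) - 1L)
      return(parse1(inner, if (strand == "+") "-" else "+"))
    }
    if (startsWith(s, "join(") || startsWith(s, "order(")) {
      inner <- substr(s, regexpr("(", s, fixed = TRUE) + 1L, nchar(s) - 1L)
      pieces <- split_toplevel(inner)
      res <- lapply(pieces, parse1, strand = strand)
      parts <- do.call(rbind, lapply(res, `[[`, "parts"))
      strands <- vapply(res, `[[`, "", "strand")
      return(list(parts = parts, strand = strands[[1L]]))
    }
    if (grepl("^\\d+\\.\\.\\d+$", s)) {
      ab <- as.integer(strsplit(s, "..", fixed = TRUE)[[1L]])
      return(list(parts = matrix(c(ab[1L] - 1L, ab[2L]), ncol = 2L),
                  strand = strand))
    }
    if (grepl("^\\d+$", s)) {
      a <- as.integer(s)
      return(list(parts = matrix(c(a - 1L, a), ncol = 2L), strand = strand))
    }
    stop("cannot parse location element: '", s, "'")
  }
  res <- parse1(loc, "+")
  ord <- order(res$parts[, 1L])
  res$parts <- res$parts[ord, , drop = FALSE]
  colnames(res$parts) <- c("start", "end")
  res
}

# split "a,b,c" at commas not nested inside parentheses
split_toplevel <- function(s) {
  depth <- 0L
  cut <- integer(0)
  cs <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (i in seq_along(cs)) {
    if (cs[i] == "(") depth <- depth + 1L
    else if (cs[i] == ")") depth <- depth - 1L
    else if (cs[i] == "," && depth == 0L) cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(cs))
  mapply(function(a, b) paste(cs[a:b], collapse = ""), starts, ends)
}

#' Read a GenBank flat file
#'
#' Parses the sequence block and all `CDS`, `tRNA` and `rRNA` features
#' (untyped `gene` lines duplicate these and are skipped), including
#' `join()`/`complement()` spans. Coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path path to a GenBank flat file.
#' @return a [plastome()] record.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[[1L]]))
    stop("malformed GenBank record: expected LOCUS at line 1 of ", path)
  id <- strsplit(trimws(sub("^LOCUS", "", lines[[1L]])), "\\s+")[[1L]][1L]
  acc <- grep("^VERSION|^ACCESSION", lines, value = TRUE)
  if (length(acc))
    id <- strsplit(trimws(sub("^\\S+", "", acc[[1L]])), "\\s+")[[1L]][1L]
  circular <- grepl("circular", lines[[1L]], ignore.case = TRUE)

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("missing sequence: no ORIGIN block in ", path)
  ostart <- ostart[[1L]]

  seq_lines <- lines[(ostart + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("missing sequence: empty ORIGIN block in ", path)

  features <- list()
  if (length(fstart) && fstart[[1L]] < ostart) {
    flines <- lines[(fstart[[1L]] + 1L):(ostart - 1L)]
    # a new feature starts with a key in column 6; continuations are indented
    is_key <- grepl("^ {5}\\S", flines)
    idx <- cumsum(is_key)
    for (grp in split(seq_along(flines)[idx > 0], idx[idx > 0])) {
      first <- flines[grp[[1L]]]
      key <- strsplit(trimws(first), "\\s+")[[1L]][1L]
      if (!key %in% c("CDS", "tRNA", "rRNA")) next
      body <- c(sub("^\\s*\\S+\\s*", "", first), trimws(flines[grp[-1L]]))
      qual_at <- grep("^/", body)
      loc <- paste(body[seq_len(if (length(qual_at)) qual_at[[1L]] - 1L
                                else length(body))], collapse = "")
      quals <- body[qual_at]
      getq <- function(q) {
        hit <- grep(paste0("^/", q, "="), quals, value = TRUE)
        if (!length(hit)) return(NULL)
        gsub('^/[^=]+="?|"$', "", hit[[1L]])
      }
      name <- getq("gene") %||% getq("standard_name") %||% getq("product")
      if (is.null(name)) next
      pl <- tryCatch(parse_location(loc), error = function(e)
        stop("malformed record near feature '", name, "': ", conditionMessage(e)))
      features[[length(features) + 1L]] <-
        plastome_feature(name, key, pl$parts, pl$strand)
    }
  }
  plastome(id, sequence, features, circular)
}

format_location <- function(f) {
  spans <- sprintf("%d..%d", f$parts[, "start"] + 1L, f$parts[, "end"])
  loc <- if (length(spans) > 1L)
    paste0("join(", paste(spans, collapse = ","), ")") else spans
  if (f$strand == "-") loc <- paste0("complement(", loc, ")")
  loc
}

#' Write a GenBank flat file
#'
#' Emits a minimal record (LOCUS, FEATURES with typed gene features and
#' `/gene` qualifiers, ORIGIN) that [read_genbank()] round-trips to an equal
#' record.
#'
#' @param record a [plastome()] record.
#' @param path output file path.
#' @export
write_genbank <- function(record, path) {
  n <- nchar(record$sequence)
  out <- c(sprintf("LOCUS       %-17s %d bp    DNA     %s PLN 01-JAN-1970",
                   record$id, n,
                   if (record$circular) "circular" else "linear"),
           sprintf("ACCESSION   %s", record$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  for (f in record$features) {
    out <- c(out,
             sprintf("     %-16s%s", f$kind, format_location(f)),
             sprintf('                     /gene="%s"', f$name))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(record$sequence)
  starts <- seq(1L, n, by = 60L)
  for (st in starts) {
    blk <- substr(s, st, min(st + 59L, n))
    tens <- substring(blk, seq(1L, nchar(blk), 10L),
                      pmin(seq(10L, nchar(blk) + 9L, 10L), nchar(blk)))
    out <- c(out, sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(NULL)
}

## ---------------------------------------------------------------------------
## FASTA
## ---------------------------------------------------------------------------

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (may contain gap characters, e.g. an alignment).
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path; lines wrapped at 70 columns.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(NULL)
}

## ---------------------------------------------------------------------------
## Sequence accessors
## ---------------------------------------------------------------------------

#' Extract the spliced sequence of an annotated feature
#'
#' Exon parts are concatenated in annotation order; minus-strand features are
#' reverse-complemented after concatenation (the `complement(join())`
#' semantics). Ambiguity codes are preserved.
#'
#' @param record a [plastome()] record.
#' @param feature a [plastome_feature()] (or its index in `record$features`).
#' @return nucleotide string.
#' @export
extract_feature_sequence <- function(record, feature) {
  if (is.numeric(feature)) feature <- record$features[[feature]]
  n <- nchar(record$sequence)
  pieces <- apply(feature$parts, 1L, function(p) {
    if (p[[2L]] > n && !record$circular)
      stop("feature interval out of range")
    extract_circular(record$sequence, p[[1L]], p[[2L]])
  })
  s <- paste(pieces, collapse = "")
  if (feature$strand == "-") revcomp(s) else s
}

#' GC content of a sequence, in percent
#'
#' Ambiguity codes and `N` are excluded from both numerator and denominator.
#'
#' @param sequence nucleotide string.
#' @return percent GC among unambiguous bases.
#' @export
gc_content <- function(sequence) {
  v <- chars(sequence)
  gc <- sum(v == "G" | v == "C")
  at <- sum(v == "A" | v == "T")
  if (gc + at == 0L) stop("sequence has no unambiguous bases")
  100 * gc / (gc + at)
}
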