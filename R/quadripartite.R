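# Inverted-repeat detection and quadripartite partitioning.
#
# Plastome IRs are a near-perfect reverse-complement pair >= 20 kb; detection
# is seed-and-extend on exact k-mer matches between the sequence and its
# reverse complement (k-mers hashed to 2-bit integers, runs found along
# constant diagonals), followed by character-level extension. A quadratic
# brute-force oracle backs this in the tests for sequences <= 1 kb.

KMER_K <- 21L

encode_bases <- function(v) {
  code <- c(A = 0, C = 1, G = 2, T = 3)
  unname(code[v])  # non-ACGT -> NA, poisons the k-mers it touches
}

kmer_values <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  val <- numeric(n - k + 1L)
  for (j in seq_len(k)) val <- val * 4 + codes[j:(n - k + j)]
  val  # exact in doubles: 4^21 < 2^53
}

# maximal runs of consecutive i with m[i+1] == m[i] + 1 (same diagonal)
diagonal_runs <- function(m) {
  ok <- !is.na(m)
  i <- seq_along(m)
  d <- i - m
  brk <- !ok | c(TRUE, ok[-length(ok)] == FALSE | d[-1L] != d[-length(d)])
  grp <- cumsum(brk)
  keep <- which(ok)
  if (!length(keep)) return(NULL)
  sp <- split(keep, grp[keep])
  do.call(rbind, lapply(sp, function(ix) {
    c(i0 = ix[[1L]], i1 = ix[[length(ix)]], d = d[ix[[1L]]])
  }))
}

# scan a linear character vector for the maximal reverse-complement pair
ir_scan_linear <- function(v, min_len, max_mismatch_frac = 0, k = KMER_K) {
  n <- length(v)
  codes <- encode_bases(v)
  kf <- kmer_values(codes, k)
  kr <- kmer_values(rev(3 - codes), k)  # reverse complement in 2-bit space
  kr[is.na(kr)] <- -1  # ambiguous k-mers must never seed a match
  m <- match(kf, kr)
  runs <- diagonal_runs(m)
  if (is.null(runs)) return(NULL)
  seed_span <- max(k + 4L, min(50L, min_len))
  runs <- runs[runs[, "i1"] - runs[, "i0"] + k >= seed_span, , drop = FALSE]
  if (!nrow(runs)) return(NULL)

  cmp <- DNA_COMPLEMENT
  # merge runs sharing a diagonal when the intervening characters verify
  merged <- list()
  for (d in unique(runs[, "d"])) {
    rs <- runs[runs[, "d"] == d, , drop = FALSE]
    rs <- rs[order(rs[, "i0"]), , drop = FALSE]
    cur <- rs[1L, ]
    flush <- function(r) merged[[length(merged) + 1L]] <<- r
    if (nrow(rs) > 1L) {
      for (r in 2:nrow(rs)) {
        # unverified characters strictly between the two runs' char spans
        lo <- cur[["i1"]] - 1L + k       # 0-based, first unverified
        hi <- rs[r, "i0"] - 2L           # 0-based, last unverified
        mm <- if (hi >= lo) {
          p <- lo:hi
          sum(v[p + 1L] != cmp[v[n - (p - d)]])
        } else 0L
        span <- rs[r, "i1"] - cur[["i0"]] + k
        if (mm <= max_mismatch_frac * span) {
          cur[["i1"]] <- rs[r, "i1"]
        } else {
          flush(cur); cur <- rs[r, ]
        }
      }
    }
    flush(cur)
  }

  best <- NULL
  for (run in merged) {
    i0 <- run[["i0"]]; i1 <- run[["i1"]]; d <- run[["d"]]
    a0 <- i0 - 1L; a1 <- i1 - 1L + k          # A on seq, 0-based half-open
    b0 <- n - (a1 - d); b1 <- n - (a0 - d) + 0L  # partner, 0-based half-open
    A <- c(a0, a1); B <- c(b0, b1)
    if (B[1L] < A[1L]) { tmp <- A; A <- B; B <- tmp }
    if (B[1L] < A[2L]) next  # self-overlapping palindrome
    # outward extension: A left + B right move together
    while (A[1L] > 0L && B[2L] < n &&
           v[A[1L]] == cmp[v[B[2L] + 1L]]) {
      A[1L] <- A[1L] - 1L; B[2L] <- B[2L] + 1L
    }
    # inward extension: A right + B left
    while (B[1L] - A[2L] > 0L &&
           v[A[2L] + 1L] == cmp[v[B[1L]]]) {
      A[2L] <- A[2L] + 1L; B[1L] <- B[1L] - 1L
    }
    len <- A[2L] - A[1L]
    if (len < min_len) next
    if (is.null(best) || len > best$length)
      best <- list(ir1 = A, ir2 = B, length = len)
  }
  best
}

#' Locate the inverted-repeat pair of a plastome
#'
#' Searches the circular sequence for the maximal-length pair of disjoint
#' intervals where one equals the reverse complement of the other (allowing at
#' most `max_mismatch_frac` mismatches). Circularity is handled by repeating
#' the linear scan from three equally spaced origins, so that a repeat copy
#' never straddles every cut.
#'
#' @param record a [plastome()] record (or a plain sequence string).
#' @param min_len minimum acceptable repeat length in bp (default 10000).
#' @param max_mismatch_frac allowed mismatch fraction; 0 means exact repeats,
#'   the mode plastome IRs justify.
#' @return `NULL` when no pair of length >= `min_len` exists, otherwise a list
#'   with `ir1`, `ir2` ([seq_interval()]s; `end` may exceed the genome length
#'   when a copy wraps the origin) and `length`.
#' @export
find_inverted_repeat <- function(record, min_len = 10000L,
                                 max_mismatch_frac = 0) {
  seq_str <- if (inherits(record, "plastome")) record$sequence else
    toupper(record)
  n <- nchar(seq_str)
  if (n < 2L * min_len)
    stop("sequence shorter than twice min_len (", 2L * min_len, " bp)")
  v <- chars(seq_str)
  circular <- !inherits(record, "plastome") || record$circular
  cuts <- if (circular) unique(c(0L, n %/% 3L, (2L * n) %/% 3L)) else 0L
  best <- NULL
  for (cut in cuts) {
    vr <- if (cut == 0L) v else c(v[(cut + 1L):n], v[1:cut])
    hit <- ir_scan_linear(vr, min_len, max_mismatch_frac)
    if (!is.null(hit)) {
      if (is.null(best) || hit$length > best$length) {
        shift <- function(ab) {
          s <- (ab[1L] + cut) %% n
          c(s, s + (ab[2L] - ab[1L]))
        }
        best <- list(ir1 = shift(hit$ir1), ir2 = shift(hit$ir2),
                     length = hit$length)
      }
      # a pair clear of the cut cannot be an artifact of linearisation;
      # trying further rotations can only rediscover it
      if (hit$ir1[1L] > 0L && hit$ir2[2L] < n) break
    }
  }
  if (is.null(best)) return(NULL)
  if (best$ir1[1L] > best$ir2[1L]) best[c("ir1", "ir2")] <- best[c("ir2", "ir1")]
  list(ir1 = seq_interval(best$ir1[1L], best$ir1[2L]),
       ir2 = seq_interval(best$ir2[1L], best$ir2[2L]),
       length = best$length)
}

#' Partition a plastome into LSC / IRb / SSC / IRa
#'
#' The two single-copy gaps between the repeat copies are labelled LSC
#' (longer) and SSC (shorter); regions are reported in the canonical
#' orientation LSC -> IRb -> SSC -> IRa starting at the LSC origin.
#'
#' @param record a [plastome()] record.
#' @param ir_pair result of [find_inverted_repeat()].
#' @return object of class `quadripartite`: list with `lsc`, `irb`, `ssc`,
#'   `ira` ([seq_interval()]s on the circle; `end` may exceed the genome
#'   length for a wrapping region) and `lengths`.
#' @export
partition_regions <- function(record, ir_pair) {
  n <- nchar(record$sequence)
  i1 <- ir_pair$ir1; i2 <- ir_pair$ir2
  l1 <- interval_length(i1); l2 <- interval_length(i2)
  gapA <- circ_fwd(i1$end %% n, i2$start, n)  # after ir1, before ir2
  gapB <- circ_fwd(i2$end %% n, i1$start, n)  # after ir2, before ir1
  if (gapA == 0 || gapB == 0 || gapA + gapB + l1 + l2 != n)
    stop("IR pair overlaps or does not tile with two single-copy gaps")
  if (gapA == gapB)
    stop("single-copy gaps have equal length; LSC/SSC labels would be ",
         "arbitrary - supply an explicit orientation")
  # LSC is the longer gap; IRb is the repeat copy that follows the LSC
  if (gapA > gapB) {
    lsc_start <- i1$end %% n; lsc_len <- gapA
    irb <- i2; ssc_len <- gapB; ira <- i1
  } else {
    lsc_start <- i2$end %% n; lsc_len <- gapB
    irb <- i1; ssc_len <- gapA; ira <- i2
  }
  mk <- function(s, len) seq_interval(s %% n, (s %% n) + len)
  lsc <- mk(lsc_start, lsc_len)
  irb <- mk(irb$start, interval_length(irb))
  ssc <- mk(irb$end %% n, ssc_len)
  ira <- mk(ssc$end %% n, interval_length(ira))
  part <- structure(list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                         genome_length = n,
                         lengths = c(LSC = lsc_len, IRb = interval_length(irb),
                                     SSC = ssc_len, IRa = interval_length(ira))),
                    class = "quadripartite")
  sb <- extract_circular(record$sequence, irb$start, irb$end)
  sa <- extract_circular(record$sequence, ira$start, ira$end)
  if (nchar(sb) != nchar(sa))
    stop("IR copies differ in length")
  part$ir_identical <- identical(sb, revcomp(sa))
  part
}

#' @export
print.quadripartite <- function(x, ...) {
  cat(sprintf("<quadripartite> LSC %s | IRb %s | SSC %s | IRa %s bp\n",
              x$lengths[["LSC"]], x$lengths[["IRb"]], x$lengths[["SSC"]],
              x$lengths[["IRa"]]))
  invisible(x)
}

JUNCTION_NAMES <- c("LSC/IRb", "IRb/SSC", "SSC/IRa", "IRa/LSC")

#' Report gene-junction relationships at the four region boundaries
#'
#' For each junction the annotated feature containing the boundary is
#' reported with its intrusion depth (`overlap_bp`, the bp it extends into the
#' shorter side); a feature ending exactly at the boundary is classed
#' `abuts`, and when no feature touches it the flanking intergenic spacer is
#' named (`within_spacer`).
#'
#' @param record an annotated [plastome()] record.
#' @param partition a [partition_regions()] result.
#' @return data.frame with columns `junction`, `feature`, `overlap_bp`,
#'   `location_class`.
#' @export
junction_report <- function(record, partition) {
  n <- partition$genome_length
  jpos <- c(partition$irb$start, partition$ssc$start %% n,
            partition$ira$start %% n, (partition$ira$end) %% n)
  names(jpos) <- JUNCTION_NAMES
  feats <- record$features
  spans <- lapply(feats, feature_span)
  out <- data.frame(junction = JUNCTION_NAMES, feature = NA_character_,
                    overlap_bp = 0L, location_class = NA_character_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(jpos)) {
    p <- jpos[[j]]
    best <- NULL
    abutter <- NULL
    for (fi in seq_along(feats)) {
      fs <- spans[[fi]][1L]; fe <- spans[[fi]][2L]
      len_f <- fe - fs
      a <- circ_fwd(fs, p, n)
      if (a == 0L || a == len_f %% n || fe %% n == p) {
        abutter <- feats[[fi]]$name
      } else if (a < len_f) {
        ov <- min(a, len_f - a)
        if (is.null(best) || ov > best$ov)
          best <- list(name = feats[[fi]]$name, ov = ov)
      }
    }
    if (!is.null(best)) {
      out$feature[j] <- best$name
      out$overlap_bp[j] <- best$ov
      out$location_class[j] <- "spans_junction"
    } else if (!is.null(abutter)) {
      out$feature[j] <- abutter
      out$location_class[j] <- "abuts"
    } else if (length(feats)) {
      # nearest feature end before p and nearest feature start after p
      dist_before <- vapply(spans, function(s) circ_fwd(s[2L] %% n, p, n), 0)
      dist_after <- vapply(spans, function(s) circ_fwd(p, s[1L], n), 0)
      left <- feats[[which.min(dist_before)]]$name
      right <- feats[[which.min(dist_after)]]$name
      out$feature[j] <- paste0(left, "-", right)
      out$location_class[j] <- "within_spacer"
    } else {
      out$feature[j] <- "intergenic"
      out$location_class[j] <- "within_spacer"
    }
  }
  out
}

#' Write the four quadripartite regions as BED intervals
#'
#' Wrapping regions are split at the origin into two BED lines.
#'
#' @param partition a [partition_regions()] result.
#' @param sample sample name for the BED name field prefix.
#' @param path output path.
#' @export
partition_to_bed <- function(partition, sample, path) {
  n <- partition$genome_length
  rows <- list()
  for (reg in c("lsc", "irb", "ssc", "ira")) {
    iv <- partition[[reg]]
    nm <- paste0(sample, ":", toupper(reg))
    if (iv$end <= n) {
      rows[[length(rows) + 1L]] <- c(sample, iv$start, iv$end, nm)
    } else {
      rows[[length(rows) + 1L]] <- c(sample, iv$start, n, nm)
      rows[[length(rows) + 1L]] <- c(sample, 0L, iv$end - n, nm)
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}
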