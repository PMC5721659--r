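# Reading-frame integrity scanning (premature internal stop codons,
# frameshift-causing indels) and Nei-Gojobori (1986) dN/dS estimation with a
# permutation contrast of per-lineage omegas.
#
# Translation uses the plastid/bacterial genetic code (NCBI table 11).

genetic_code_11 <- function() Biostrings::getGeneticCode("11")

split_codons <- function(s) {
  v <- chars(s)
  n3 <- length(v) %/% 3L
  if (n3 == 0L) return(character(0))
  idx <- seq_len(n3 * 3L)
  apply(matrix(v[idx], nrow = 3L), 2L, paste, collapse = "")
}

#' Scan a coding sequence for premature internal stop codons
#'
#' Translation starts from the annotated frame (the first base). Internal
#' stops are any of TAA/TAG/TGA before the final codon; a length not
#' divisible by three is flagged. Codons containing ambiguity codes are never
#' called stops.
#'
#' @param cds_sequence nucleotide string (length >= 3).
#' @param gene optional gene name carried into the report.
#' @param sample optional sample id carried into the report.
#' @return list of class `orf_report`: `cds_length`, `internal_stops`
#'   (0-based codon indices), `terminal_stop_present`, `length_mod3`,
#'   `translatable`.
#' @export
scan_orf <- function(cds_sequence, gene = NA_character_,
                     sample = NA_character_) {
  s <- toupper(cds_sequence)
  if (nchar(s) < 3L) stop("coding sequence shorter than one codon")
  if (grepl("[^ACGTNRYSWKMBVDH]", s))
    stop("non-nucleotide characters in coding sequence")
  codons <- split_codons(s)
  is_stop <- codons %in% STOP_CODONS
  internal <- which(is_stop[-length(is_stop)]) - 1L  # 0-based codon indices
  structure(list(
    sample = sample, gene = gene, cds_length = nchar(s),
    internal_stops = internal,
    terminal_stop_present = is_stop[[length(is_stop)]] &&
      nchar(s) %% 3L == 0L,
    length_mod3 = nchar(s) %% 3L,
    translatable = length(internal) == 0L && nchar(s) %% 3L == 0L
  ), class = "orf_report")
}

#' @export
print.orf_report <- function(x, ...) {
  cat(sprintf("<orf_report> %s/%s: %d bp, %d internal stop(s)%s\n",
              x$sample, x$gene, x$cds_length, length(x$internal_stops),
              if (x$length_mod3) sprintf(", length %% 3 = %d", x$length_mod3)
              else ""))
  invisible(x)
}

#' Scan every annotated CDS of a record
#'
#' @param record an annotated [plastome()] record.
#' @return data.frame with one row per CDS feature: `sample`, `gene`,
#'   `cds_length`, `n_internal_stops`, `terminal_stop`, `translatable`.
#' @export
scan_record_orfs <- function(record) {
  cds <- Filter(function(f) f$kind == "CDS", record$features)
  rows <- lapply(cds, function(f) {
    rep_ <- scan_orf(extract_feature_sequence(record, f), gene = f$name,
                     sample = record$id)
    data.frame(sample = record$id, gene = f$name,
               cds_length = rep_$cds_length,
               n_internal_stops = length(rep_$internal_stops),
               terminal_stop = rep_$terminal_stop_present,
               translatable = rep_$translatable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Characterise gene disruptions against an intact reference
#'
#' Given a per-gene alignment, each taxon's indels relative to the reference
#' are classified by length and phase (`length %% 3 != 0` marks a
#' frameshift), and point-nonsense changes (a reference sense codon read as
#' a stop in the query, in frame) are reported with codon context.
#'
#' @param gene_alignment a [plastome_alignment()] of one gene's sequences.
#' @param intact_reference_taxon row name of a taxon whose degapped sequence
#'   is translatable (error otherwise).
#' @return data.frame with `taxon`, `type`
#'   (`insertion`/`deletion`/`point_nonsense`), `position` (0-based
#'   alignment column), `length`, `phase`, `frameshift`, `detail`.
#' @export
characterize_disruption <- function(gene_alignment, intact_reference_taxon) {
  aln <- gene_alignment
  if (!intact_reference_taxon %in% rownames(aln))
    stop("unknown reference taxon")
  ref <- unclass(aln)[intact_reference_taxon, ]
  ref_seq <- paste(ref[ref != "-"], collapse = "")
  ref_rep <- scan_orf(ref_seq)
  if (length(ref_rep$internal_stops))
    stop("reference taxon itself has internal stop codons")
  ref_cols <- which(ref != "-")
  out <- list()
  for (tx in setdiff(rownames(aln), intact_reference_taxon)) {
    q <- unclass(aln)[tx, ]
    state <- ifelse(ref != "-" & q == "-", "deletion",
                    ifelse(ref == "-" & q != "-", "insertion", "match"))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ev <- which(r$values != "match")
    for (k in ev) {
      len <- r$lengths[[k]]
      # phase is the downstream frame shift: +len for insertions,
      # -len (mod 3) for deletions
      ph <- if (r$values[[k]] == "deletion") (3L - len %% 3L) %% 3L else
        len %% 3L
      out[[length(out) + 1L]] <- data.frame(
        taxon = tx, type = r$values[[k]], position = starts[[k]] - 1L,
        length = len, phase = ph, frameshift = len %% 3L != 0L,
        detail = sprintf("%d bp %s", len, r$values[[k]]),
        stringsAsFactors = FALSE)
    }
    # point nonsense: reference codons read in the query where the local
    # frame is intact (zero cumulative indel shift up to the codon)
    shift_at <- cumsum(ifelse(state == "insertion", 1L,
                              ifelse(state == "deletion", -1L, 0L)))
    n_codon <- length(ref_cols) %/% 3L
    for (ci in seq_len(max(n_codon - 1L, 0L))) {
      cols <- ref_cols[(3L * ci - 2L):(3L * ci)]
      if (shift_at[[cols[[1L]]]] %% 3L != 0L) next
      qc <- paste(q[cols], collapse = "")
      rc <- paste(ref[cols], collapse = "")
      if (qc %in% STOP_CODONS && !(rc %in% STOP_CODONS)) {
        out[[length(out) + 1L]] <- data.frame(
          taxon = tx, type = "point_nonsense", position = cols[[1L]] - 1L,
          length = 3L, phase = 0L, frameshift = FALSE,
          detail = sprintf("%s->%s at codon %d", rc, qc, ci - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(taxon = character(0), type = character(0),
                      position = integer(0), length = integer(0),
                      phase = integer(0), frameshift = logical(0),
                      detail = character(0)))
  do.call(rbind, out)
}

## ---------------------------------------------------------------------------
## Nei-Gojobori (1986) counting
## ---------------------------------------------------------------------------

.ng86 <- new.env(parent = emptyenv())

# per-codon synonymous site fractions and per-pair difference tables,
# averaged over minimal substitution paths (paths through stop codons
# excluded; all-paths fallback when every path is blocked)
ng86_tables <- function() {
  if (!is.null(.ng86$S)) return(as.list(.ng86))
  gc <- genetic_code_11()
  codons <- names(gc)
  sense <- codons[gc != "*"]
  nts <- c("A", "C", "G", "T")
  syn_sites <- setNames(numeric(length(sense)), sense)
  for (cd in sense) {
    v <- strsplit(cd, "")[[1L]]
    s <- 0
    for (p in 1:3) for (alt in setdiff(nts, v[[p]])) {
      w <- v; w[[p]] <- alt
      mut <- paste(w, collapse = "")
      if (gc[[mut]] != "*" && gc[[mut]] == gc[[cd]]) s <- s + 1 / 3
      # changes to stop codons count as nonsynonymous
    }
    syn_sites[[cd]] <- s
  }
  ns <- length(sense)
  Sd <- matrix(0, ns, ns, dimnames = list(sense, sense))
  Nd <- Sd
  perms <- list(`1` = list(1L), `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (a in sense) for (b in sense) {
    if (a == b) next
    va <- strsplit(a, "")[[1L]]; vb <- strsplit(b, "")[[1L]]
    diffp <- which(va != vb)
    k <- length(diffp)
    paths <- lapply(perms[[as.character(k)]], function(ord) diffp[ord])
    eval_path <- function(path) {
      cur <- va; sd <- 0; nd <- 0
      for (p in path) {
        nxt <- cur; nxt[[p]] <- vb[[p]]
        c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
        if (gc[[c2]] == "*") return(NULL)  # blocked path
        if (gc[[c1]] == gc[[c2]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- Filter(Negate(is.null), lapply(paths, eval_path))
    if (!length(res)) {
      # all paths blocked: average over all paths, counting the blocked
      # steps as nonsynonymous
      res <- lapply(paths, function(path) {
        cur <- va; sd <- 0; nd <- 0
        for (p in path) {
          nxt <- cur; nxt[[p]] <- vb[[p]]
          if (gc[[paste(cur, collapse = "")]] ==
              gc[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        c(sd, nd)
      })
    }
    mres <- Reduce(`+`, res) / length(res)
    Sd[a, b] <- mres[[1L]]; Nd[a, b] <- mres[[2L]]
  }
  assign("S", syn_sites, envir = .ng86)
  assign("Sd", Sd, envir = .ng86)
  assign("Nd", Nd, envir = .ng86)
  assign("sense", sense, envir = .ng86)
  as.list(.ng86)
}

#' Nei-Gojobori (1986) dN/dS between two in-frame coding sequences
#'
#' Fractional synonymous/nonsynonymous site counting, difference counting
#' averaged with equal weights over minimal substitution paths (paths through
#' stop codons excluded), and Jukes-Cantor correction. Codons containing
#' gaps or ambiguity codes in either sequence are skipped; terminal stop
#' codons are ignored.
#'
#' @param cds_a,cds_b aligned coding sequences of equal length divisible by
#'   3, with no internal stop codons.
#' @return list of class `dnds_estimate`: `N`, `S` (site counts), `Nd`,
#'   `Sd` (differences), `pN`, `pS`, `dN`, `dS`, `omega` (`NA` when
#'   `dS == 0`), `codons_compared`.
#' @export
ng86_dnds <- function(cds_a, cds_b) {
  a <- toupper(cds_a); b <- toupper(cds_b)
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("length not divisible by 3")
  ca <- split_codons(a); cb <- split_codons(b)
  gc <- genetic_code_11()
  known_a <- ca %in% names(gc); known_b <- cb %in% names(gc)
  ia <- which(known_a & gc[ca] == "*")
  ib <- which(known_b & gc[cb] == "*")
  if (any(ia < length(ca)) || any(ib < length(cb)))
    stop("internal stop codon present")
  tb <- ng86_tables()
  use <- known_a & known_b & gc[ca] != "*" & gc[cb] != "*"
  if (!any(use)) stop("no comparable sense codons")
  ca <- ca[use]; cb <- cb[use]
  S <- (sum(tb$S[ca]) + sum(tb$S[cb])) / 2
  N <- 3 * length(ca) - S
  Sd <- sum(tb$Sd[cbind(ca, cb)])
  Nd <- sum(tb$Nd[cbind(ca, cb)])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (Nd == 0 && Sd > 0) 0  # dN is exactly zero
  else if (is.na(dS) || is.na(dN) || dS == 0) NA_real_
  else dN / dS
  structure(list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                 dN = dN, dS = dS, omega = omega,
                 codons_compared = length(ca)),
            class = "dnds_estimate")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("<dnds_estimate> dN = %.4f, dS = %.4f, omega = %s (%d codons)\n",
              x$dN, x$dS,
              if (is.na(x$omega)) "undefined" else sprintf("%.4f", x$omega),
              x$codons_compared))
  invisible(x)
}

#' Permutation contrast of per-lineage omegas between clades
#'
#' Each group member's omega is estimated by NG86 against a common outgroup
#' reference; the group difference statistic is the sample-size-weighted
#' between-group variance of mean omegas, assessed by permuting member
#' labels.
#'
#' @param seqs named character vector of aligned in-frame coding sequences
#'   (gaps allowed; gapped codons are skipped pairwise).
#' @param groups named list of character vectors of taxon names.
#' @param outgroup name (in `seqs`) of the reference sequence.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed.
#' @return list with `group_omega` (mean omega per group), `omega_by_taxon`,
#'   `statistic`, `p_value`, `n_perm`.
#' @export
clade_omega_contrast <- function(seqs, groups, outgroup, n_perm = 999L,
                                 seed = 1L) {
  stopifnot(outgroup %in% names(seqs))
  members <- unlist(groups, use.names = FALSE)
  stopifnot(all(members %in% names(seqs)))
  omega <- vapply(members, function(tx)
    ng86_dnds(seqs[[tx]], seqs[[outgroup]])$omega, 0)
  labels <- rep(names(groups), vapply(groups, length, 0L))
  keep <- !is.na(omega)
  if (!all(keep)) {
    omega <- omega[keep]; labels <- labels[keep]
  }
  if (!length(omega) || !all(names(groups) %in% labels))
    stop("a group has no member with a defined omega")
  stat <- function(om, lab) {
    gm <- tapply(om, lab, mean)
    gn <- tapply(om, lab, length)
    sum(gn * (gm - mean(om))^2)
  }
  obs <- stat(omega, labels)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    stat(omega, sample(labels)), 0)
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(group_omega = tapply(omega, labels, mean),
       omega_by_taxon = omega, statistic = obs, p_value = p, n_perm = n_perm)
}

#' Random in-frame coding sequence
#'
#' Sense codons drawn uniformly; no internal stops.
#'
#' @param n_codons number of codons.
#' @return nucleotide string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

#' Evolve a coding sequence under a simple mutation-selection codon model
#'
#' Nucleotide changes are proposed uniformly at `mut` expected proposals per
#' site; proposals creating a stop codon are rejected, synonymous proposals
#' are always accepted and nonsynonymous ones with probability `omega`. The
#' realised dN/dS of a pair diverged this way is therefore `omega` (up to
#' counting-method bias).
#'
#' @param cds in-frame coding sequence without internal stops.
#' @param omega nonsynonymous acceptance probability.
#' @param mut expected proposals per nucleotide site.
#' @return the mutated sequence.
#' @export
evolve_cds <- function(cds, omega, mut) {
  v <- chars(cds)
  n <- length(v)
  stopifnot(n %% 3L == 0L)
  gc <- genetic_code_11()
  n_prop <- stats::rpois(1L, mut * n)
  pos <- sample.int(n, n_prop, replace = TRUE)
  for (p in pos) {
    newb <- sample(setdiff(c("A", "C", "G", "T"), v[[p]]), 1L)
    c0 <- (p - 1L) %/% 3L
    cc <- (3L * c0 + 1L):(3L * c0 + 3L)
    old_cod <- paste(v[cc], collapse = "")
    tmp <- v[cc]; tmp[cc == p] <- newb
    new_cod <- paste(tmp, collapse = "")
    if (gc[[new_cod]] == "*") next
    syn <- gc[[new_cod]] == gc[[old_cod]]
    if (syn || stats::runif(1L) < omega) v[[p]] <- newb
  }
  collapse_chars(v)
}

#' Locate an unannotated gene by an intact reference sequence
#'
#' Local pairwise alignment of a reference coding sequence against both
#' strands of a genome; used for genes (such as ycf15) deliberately absent
#' from annotations.
#'
#' @param record a [plastome()] record.
#' @param ref_seq intact reference nucleotide sequence of the gene.
#' @return list with `interval` ([seq_interval()] on the genome), `strand`
#'   and `score`, or `NULL` if no credible match (score below 60% of the
#'   self-match score).
#' @export
locate_gene_by_reference <- function(record, ref_seq) {
  ref <- Biostrings::DNAString(toupper(ref_seq))
  subj <- Biostrings::DNAString(record$sequence)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  aln_f <- Biostrings::pairwiseAlignment(ref, subj, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
  aln_r <- Biostrings::pairwiseAlignment(ref,
                                         Biostrings::reverseComplement(subj),
                                         type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
  self <- 2 * nchar(ref_seq)
  use_rev <- Biostrings::score(aln_r) > Biostrings::score(aln_f)
  best <- if (use_rev) aln_r else aln_f
  if (Biostrings::score(best) < 0.6 * self) return(NULL)
  sub <- Biostrings::subject(best)
  st <- Biostrings::start(sub) - 1L
  en <- Biostrings::end(sub)
  n <- nchar(record$sequence)
  if (use_rev) {
    iv <- seq_interval(n - en, n - st, strand = "-")
  } else {
    iv <- seq_interval(st, en, strand = "+")
  }
  list(interval = iv, strand = iv$strand, score = Biostrings::score(best))
}
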