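# Shared fixtures (computed once per test run) and independent brute-force
# oracles used across the suite.

.fixtures <- new.env(parent = emptyenv())

# one down-scaled simulated study reused by many tests: 15 taxa,
# ~15.7 kb genomes (LSC 8.6 kb, SSC 1.85 kb, IR 2.6 kb), full feature
# complement subset, default rates and disruptions
shared_sim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- evolve_plastomes(
      sim_config(plan = cornales_plan(scale = 0.1), seed = 101L))
  .fixtures$sim
}

random_alignment <- function(n_taxa, n_cols, gap_frac = 0.1, seed = 1L) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * n_cols, replace = TRUE),
              nrow = n_taxa)
  if (gap_frac > 0)
    m[sample(length(m), round(gap_frac * length(m)))] <- "-"
  rownames(m) <- paste0("t", seq_len(n_taxa))
  plastome_alignment(m)
}

## -- brute-force oracles ----------------------------------------------------

# maximal reverse-complement pair by O(n^2) dynamic programming over the
# sequence and its reverse complement (longest common substring)
brute_ir <- function(seq_str, min_len) {
  v <- strsplit(toupper(seq_str), "")[[1L]]
  n <- length(v)
  rc <- rev(chartr("ACGT", "TGCA", v))
  best <- NULL
  L_prev <- integer(n)
  for (p in seq_len(n)) {
    L_cur <- integer(n)
    for (q in seq_len(n)) {
      if (v[[p]] == rc[[q]]) {
        L_cur[[q]] <- if (q > 1L) L_prev[[q - 1L]] + 1L else 1L
        l <- L_cur[[q]]
        if (l >= min_len) {
          a <- c(p - l, p)                  # interval on seq, 0-based
          b <- c(n - q, n - q + l)          # rc interval mapped to seq
          if (b[[1L]] < a[[1L]]) { tmp <- a; a <- b; b <- tmp }
          if (b[[1L]] >= a[[2L]] &&
              (is.null(best) || l > best$len))
            best <- list(len = l, ir1 = a, ir2 = b)
        }
      }
    }
    L_prev <- L_cur
  }
  best
}

# per-window substitution-site and indel-event counts by direct enumeration
# (string-based, independent of the packaged numeric encoding)
brute_window_events <- function(aln, start, end) {
  m <- unclass(aln)
  ns <- 0L
  for (j in (start + 1L):end) {
    col <- m[, j]
    states <- unique(col[col %in% c("A", "C", "G", "T")])
    if (length(states) >= 2L) ns <- ns + 1L
  }
  pats <- apply(m[, (start + 1L):end, drop = FALSE] == "-", 2L, paste,
                collapse = "")
  all_present <- paste(rep("FALSE", nrow(m)), collapse = "")
  id <- 0L; prev <- all_present
  for (p in pats) {
    if (p != all_present && p != prev) id <- id + 1L
    prev <- p
  }
  c(NS = ns, ID = id)
}

# non-trivial bipartitions of an unrooted tree by direct recursion on the
# edge table; each bipartition canonicalised as a sorted label string
brute_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  desc <- function(node) {
    if (node <= ntip) return(tree$tip.label[[node]])
    unlist(lapply(kids[[as.character(node)]], desc))
  }
  parts <- character(0)
  for (node in unique(tree$edge[, 2L])) {
    if (node <= ntip) next
    side <- sort(desc(node))
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    other <- sort(setdiff(tree$tip.label, side))
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    parts <- c(parts, key)
  }
  unique(parts)
}

brute_rf <- function(t1, t2) {
  b1 <- brute_bipartitions(t1)
  b2 <- brute_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}
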