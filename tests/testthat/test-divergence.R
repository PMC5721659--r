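# Site classification, window event counts, the mutation-event proportion,
# hotspot calling and pairwise identity.

test_that("site classes follow their definitions on hand columns", {
  aln <- plastome_alignment(rbind(
    t1 = c("A", "A", "A", "A", "-"),
    t2 = c("A", "A", "G", "C", "A"),
    t3 = c("G", "A", "G", "-", "-"),
    t4 = c("G", "G", "G", "-", "-")))
  sc <- classify_sites(aln)
  # col1 {A,A,G,G} PI; col2 {A,A,A,G} singleton; col3 {A,G,G,G} singleton;
  # col4 {A,C} variable 2 taxa = PI? each state once -> singleton;
  # col5 single base -> unclassifiable
  expect_equal(unname(sc$counts[["variable"]]), 4L)
  expect_equal(unname(sc$counts[["parsimony_informative"]]), 1L)
  expect_equal(unname(sc$counts[["singleton"]]), 3L)
  expect_equal(unname(sc$counts[["constant"]]), 0L)
  expect_error(classify_sites(aln[1, , drop = FALSE]), "2 taxa")
})

test_that("classification matches an exhaustive per-column oracle on a
           random alignment", {
  aln <- random_alignment(4L, 1000L, gap_frac = 0.15, seed = 31L)
  sc <- classify_sites(aln)
  m <- unclass(aln)
  oracle_var <- 0L; oracle_pi <- 0L; oracle_const <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j][m[, j] %in% c("A", "C", "G", "T")]
    tab <- table(col)
    if (length(col) >= 2L && length(tab) == 1L) oracle_const <- oracle_const + 1L
    if (length(tab) >= 2L) {
      oracle_var <- oracle_var + 1L
      if (sum(tab >= 2L) >= 2L) oracle_pi <- oracle_pi + 1L
    }
  }
  expect_equal(unname(sc$counts[["variable"]]), oracle_var)
  expect_equal(unname(sc$counts[["parsimony_informative"]]), oracle_pi)
  expect_equal(unname(sc$counts[["constant"]]), oracle_const)
})

test_that("window event counts follow the substitution/indel definitions", {
  a <- plastome_alignment(c(x = "ACGT", y = "ACGT"))
  expect_equal(unname(count_window_events(a, c(0L, 4L))), c(0L, 0L))
  b <- plastome_alignment(c(x = "ACGT", y = "A-GA"))
  expect_equal(unname(count_window_events(b, c(0L, 4L))), c(1L, 1L))
  # a shared multi-column gap is one event
  c_ <- plastome_alignment(c(x = "AAAAAA", y = "A---AA", z = "A---AA"))
  expect_equal(unname(count_window_events(c_, c(0L, 6L))["ID"]), 1L)
  expect_error(count_window_events(b, c(2L, 2L)), "empty")
})

test_that("window event counts equal brute-force enumeration on small
           random alignments", {
  for (seed in 1:10) {
    aln <- random_alignment(5L, 50L, gap_frac = 0.2, seed = seed)
    for (w in list(c(0L, 50L), c(0L, 17L), c(13L, 42L), c(49L, 50L))) {
      expect_equal(unname(count_window_events(aln, w)),
                   unname(brute_window_events(aln, w[[1L]], w[[2L]])),
                   info = sprintf("seed %d window %d-%d", seed, w[1], w[2]))
    }
  }
})

test_that("window_scan geometry, the proportion formula and monotonicity
           hold", {
  aln <- random_alignment(4L, 1500L, gap_frac = 0.05, seed = 77L)
  w <- window_scan(aln, 600L, 200L)
  expect_equal(w$start, c(0L, 200L, 400L, 600L, 800L, 1000L))
  expect_equal(w$end, c(600L, 800L, 1000L, 1200L, 1400L, 1500L))
  expect_equal(w$L, w$end - w$start)
  # stored proportions are the formula value rounded to 2 decimals
  expect_true(all(abs(w$proportion - 100 * (w$NS + w$ID) / w$L) <=
                    0.005 + 1e-9))
  # single truncated window with a warning when too short
  short <- random_alignment(4L, 100L, gap_frac = 0, seed = 1L)
  expect_warning(ws <- window_scan(short, 600L, 200L), "shorter")
  expect_equal(nrow(ws), 1L)
  expect_equal(ws$L, 100L)
  # adding a substitution never decreases the proportion
  m <- unclass(aln)
  const_cols <- which(apply(m[, 1:600, drop = FALSE], 2L,
                            function(cl) length(unique(cl)) == 1L &&
                              all(cl != "-")))
  if (length(const_cols)) {
    m2 <- m
    m2[1L, const_cols[[1L]]] <-
      setdiff(c("A", "C", "G", "T"), m[1L, const_cols[[1L]]])[[1L]]
    w2 <- window_scan(plastome_alignment(m2), 600L, 200L)
    expect_gte(w2$proportion[[1L]], w$proportion[[1L]])
  }
  # direct formula example: NS 100, ID 30, L 600
  expect_equal(round(100 * (100 + 30) / 600, 2), 21.67)
})

test_that("hotspot calling merges qualifying windows and recovers planted
           regions", {
  # all windows at or below threshold -> empty
  flat <- data.frame(start = c(0, 200), end = c(600, 800), NS = c(10, 20),
                     ID = 0, L = 600,
                     proportion = c(5, 20))
  expect_equal(nrow(call_hotspots(flat, 20)), 0L)  # strict >
  # two separated qualifying groups merge into exactly two regions
  w <- data.frame(start = seq(0, 2000, 200), end = seq(600, 2600, 200))
  w$NS <- 0; w$ID <- 0; w$L <- 600
  w$proportion <- c(30, 31, 5, 5, 5, 5, 5, 28, 29, 5, 5)
  hot <- call_hotspots(w, 20)
  expect_equal(nrow(hot), 2L)
  expect_equal(hot$start, c(0L, 1400L))
  expect_equal(hot$peak_proportion, c(31, 29))
  # planted elevated-rate regions in the shared simulation are recovered
  sim <- shared_sim()
  bundle <- build_datasets(sim$alignment)
  ws <- window_scan(bundle$complete)
  called <- call_hotspots(ws, 20, attr(bundle$complete, "labels"))
  expect_gte(nrow(called), 1L)
  truth <- sim$hotspots
  recall <- mean(vapply(seq_len(nrow(truth)), function(i)
    any(called$start < truth$col_end[[i]] &
          called$end > truth$col_start[[i]]), TRUE))
  expect_gte(recall, 0.8)
})

test_that("pairwise identity behaves on identical, single-difference and
           simulated pairs", {
  a <- paste(rep("ACGT", 50), collapse = "")
  aln <- plastome_alignment(c(r = a, q = a))
  pid <- pairwise_identity(aln, "r", 100L, 100L)
  expect_true(all(pid$identity == 100))
  v <- chars(a); v[5] <- "T"
  aln2 <- plastome_alignment(c(r = a, q = collapse_chars(v)))
  pid2 <- pairwise_identity(aln2, "r", 100L, 100L)
  expect_equal(pid2$identity[[1L]], 99)
  expect_error(pairwise_identity(aln2, "zz"), "unknown taxon")
  # simulated pair at known divergence
  set.seed(5)
  n <- 20000L
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  d <- 0.05
  flip <- which(stats::runif(n) < d)
  y <- x
  y[flip] <- vapply(x[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  aln3 <- plastome_alignment(rbind(r = x, q = y))
  pid3 <- pairwise_identity(aln3, "r", n, n)
  expect_equal(pid3$identity[[1L]], 100 * (1 - d),
               tolerance = 3 * 100 * sqrt(d * (1 - d) / n) / (100 * (1 - d)))
})
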