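# Data-set construction, the three filtering strategies, partition subsets.

toy_labelled_aln <- function() {
  m <- rbind(t1 = chars("AAATTGGGC"), t2 = chars("AAATTGGGC"),
             t3 = chars("AACTTGGAC"))
  plastome_alignment(
    m,
    labels = c("g1", "g1", "g1", "s1", "s1", "g2", "g2", "g2", "s2"),
    category = c("CDS", "CDS", "CDS", "spacer", "spacer", "tRNA", "tRNA",
                 "tRNA", "spacer"),
    region = rep("LSC", 9L))
}

test_that("build_datasets splits coding/noncoding by provenance and drops
           the second repeat copy", {
  aln <- toy_labelled_aln()
  b <- build_datasets(aln, drop_second_ir = FALSE)
  expect_equal(ncol(b$coding), 6L)
  expect_equal(ncol(b$noncoding), 3L)
  expect_equal(ncol(b$coding) + ncol(b$noncoding), ncol(b$complete))
  expect_error(build_datasets(plastome_alignment(unclass(aln)[, ])),
               "provenance")
  # second IR dropped from all three
  sim <- shared_sim()
  full <- sim$alignment
  bundle <- build_datasets(full)
  n_ira <- sum(attr(full, "region") == "IRa")
  expect_equal(ncol(bundle$complete), ncol(full) - n_ira)
  expect_equal(ncol(bundle$coding) + ncol(bundle$noncoding),
               ncol(bundle$complete))
  # no column lost or duplicated: per-taxon non-gap character multisets of
  # complete equal those of coding + noncoding
  for (tx in rownames(full)[c(1L, 6L)]) {
    expect_equal(table(c(bundle$coding[tx, ], bundle$noncoding[tx, ])),
                 table(bundle$complete[tx, ]))
  }
})

test_that("the strict filter drops exactly the gap-containing columns", {
  aln <- plastome_alignment(c(a = "AC-GT", b = "ACGGT", c = "ACGG-"))
  f <- filter_strict(aln)
  expect_equal(ncol(f), 3L)
  expect_true(all(unclass(f) != "-"))
  # gapless alignment -> identity
  g <- random_alignment(4L, 200L, gap_frac = 0, seed = 2L)
  expect_equal(dim(filter_strict(g)), dim(g))
  # random alignment -> equals the brute-force column filter
  for (seed in 1:5) {
    r <- random_alignment(5L, 300L, gap_frac = 0.1, seed = seed)
    keep <- which(apply(unclass(r), 2L, function(cl) all(cl != "-")))
    expect_identical(unclass(filter_strict(r))[, ],
                     unclass(r)[, keep, drop = FALSE][, ])
  }
})

test_that("the light filter removes gappy columns and gappy low-conservation
           blocks but always retains the strict set", {
  # fully conserved, gapless -> identity
  m <- matrix("A", 4L, 50L, dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(ncol(filter_light(plastome_alignment(m))), 50L)
  # a column with 3/4 gaps is removed under max_gap_fraction = 0.5
  m2 <- m; m2[1:3, 10L] <- "-"
  expect_equal(ncol(filter_light(plastome_alignment(m2))), 49L)
  # a planted poorly aligned gappy block (every column half-gapped with no
  # majority state) is removed while the conserved flanks survive
  nt <- 6L
  flank1 <- matrix("A", nt, 40L)
  block <- matrix(rep(c("-", "-", "-", "A", "C", "G"), 50L), nt)
  flank2 <- matrix("G", nt, 40L)
  m3 <- cbind(flank1, block, flank2)
  rownames(m3) <- paste0("t", seq_len(nt))
  lf <- filter_light(plastome_alignment(m3))
  expect_equal(ncol(lf), 80L)
  # superset property: light >= strict on arbitrary inputs
  for (seed in 1:8) {
    r <- random_alignment(6L, 400L, gap_frac = 0.25, seed = seed)
    n_strict <- ncol(filter_strict(r))
    n_light <- ncol(filter_light(r))
    expect_gte(n_light, n_strict)
  }
  # dispatcher
  r <- random_alignment(4L, 100L, gap_frac = 0.2, seed = 3L)
  expect_identical(ncol(filter_alignment(r, "unfiltered")), ncol(r))
  expect_identical(unclass(filter_alignment(r, "strict"))[, ],
                   unclass(filter_strict(r))[, ])
})

test_that("partition subsets follow the minimum-size/invariant merging rule
           and partition the columns", {
  # genes 250/150/300 bp and spacers 500/100 bp; gene2 and spacer2 pooled
  widths <- c(gene1 = 250L, spacer1 = 500L, gene2 = 150L, spacer2 = 100L,
              gene3 = 300L)
  cats <- c(gene1 = "CDS", spacer1 = "spacer", gene2 = "CDS",
            spacer2 = "spacer", gene3 = "CDS")
  labels <- rep(names(widths), widths)
  category <- rep(unname(cats), widths)
  set.seed(12)
  n <- sum(widths)
  m <- rbind(a = sample(c("A", "C", "G", "T"), n, TRUE),
             b = sample(c("A", "C", "G", "T"), n, TRUE))
  aln <- plastome_alignment(m, labels = labels, category = category)
  sch <- build_partitions(aln, min_subset = 200L)
  expect_setequal(names(sch$subsets),
                  c("gene1", "gene3", "spacer1", "pooled_CDS",
                    "pooled_spacer"))
  expect_setequal(sch$merged_small, c("gene2", "spacer2"))
  all_cols <- sort(unlist(sch$subsets, use.names = FALSE))
  expect_identical(all_cols, seq_len(n))  # disjoint + exhaustive
  # no merging when everything is large and variable
  widths2 <- c(g1 = 300L, g2 = 300L)
  aln2 <- plastome_alignment(
    rbind(a = sample(c("A", "C"), 600L, TRUE),
          b = sample(c("G", "T"), 600L, TRUE)),
    labels = rep(names(widths2), widths2), category = rep("CDS", 600L))
  sch2 <- build_partitions(aln2, 200L)
  expect_equal(length(sch2$subsets), 2L)
  expect_length(sch2$merged_small, 0L)
})

test_that("partition subsets are stable across runs and export to RAxML and
           NEXUS formats", {
  sim <- shared_sim()
  bundle <- build_datasets(sim$alignment)
  s1 <- build_partitions(bundle$complete, 200L)
  s2 <- build_partitions(bundle$complete, 200L)
  expect_identical(s1$subsets, s2$subsets)
  all_cols <- sort(unlist(s1$subsets, use.names = FALSE))
  expect_identical(all_cols, seq_len(ncol(bundle$complete)))
  p1 <- withr::local_tempfile(fileext = ".txt")
  write_partitions_raxml(s1, p1)
  lines <- readLines(p1)
  expect_equal(length(lines), length(s1$subsets))
  expect_true(all(grepl("^DNA, ", lines)))
  p2 <- withr::local_tempfile(fileext = ".nex")
  write_partitions_nexus(s1, p2)
  expect_equal(readLines(p2)[[1L]], "#NEXUS")
})
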