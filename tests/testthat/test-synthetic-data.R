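# The simulator: determinism, ground-truth consistency, divergence
# patterns, degenerate inputs.

test_that("the ancestor respects its plan: lengths, GC, mirrored repeat,
           valid ORFs", {
  plan <- cornales_plan(scale = 0.1)
  anc <- build_ancestor(plan, seed = 55L)
  n <- nchar(anc$record$sequence)
  expect_equal(n, plan$lsc_len + plan$ssc_len + 2L * plan$ir_len)
  # full-size default plan lands in the canonical size band
  full_plan <- cornales_plan()
  expect_true(full_plan$lsc_len + full_plan$ssc_len +
                2L * full_plan$ir_len >= 150000L)
  expect_true(full_plan$lsc_len + full_plan$ssc_len +
                2L * full_plan$ir_len <= 165000L)
  # GC within one point of target at this size
  expect_lt(abs(gc_content(anc$record$sequence) / 100 - plan$gc), 0.01)
  # IRa is the exact reverse complement of IRb
  L <- plan$lsc_len; I <- plan$ir_len
  irb <- substr(anc$record$sequence, L + 1L, L + I)
  ira <- substr(anc$record$sequence, n - I + 1L, n)
  expect_identical(ira, revcomp(irb))
  # every CDS is a translatable ORF with a terminal stop
  orf <- scan_record_orfs(anc$record)
  expect_true(all(orf$translatable))
  expect_true(all(orf$terminal_stop))
  # degenerate plans error
  expect_error(cornales_plan(ssc_len = 0L), "positive")
  expect_error(build_ancestor(cornales_plan(scale = 0.1, lsc_len = 2000L)),
               "infeasible")
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(plan = cornales_plan(scale = 0.08), seed = 77L,
                    disruptions = NULL)
  s1 <- evolve_plastomes(cfg)
  s2 <- evolve_plastomes(cfg)
  expect_identical(lapply(s1$records, `[[`, "sequence"),
                   lapply(s2$records, `[[`, "sequence"))
  expect_identical(unclass(s1$alignment)[, ], unclass(s2$alignment)[, ])
  expect_identical(s1$branch_subs$realized, s2$branch_subs$realized)
})

test_that("ground truth is self-consistent: degapped rows equal genomes and
           feature coordinates map correctly", {
  sim <- shared_sim()
  aln <- sim$alignment
  for (tx in rownames(aln)) {
    degapped <- paste(aln[tx, ][aln[tx, ] != "-"], collapse = "")
    expect_identical(degapped, sim$records[[tx]]$sequence)
  }
  # annotated CDS in evolved leaves start with ATG and end with a stop
  # (first/last codons are immutable by design)
  for (tx in rownames(aln)[c(4L, 11L)]) {
    rec <- sim$records[[tx]]
    dis_genes <- sim$disruptions$gene[sim$disruptions$taxon == tx]
    for (f in rec$features) {
      if (f$kind != "CDS" || f$name %in% dis_genes) next
      s <- extract_feature_sequence(rec, f)
      expect_identical(substr(s, 1L, 3L), "ATG")
      expect_true(substr(s, nchar(s) - 2L, nchar(s)) %in%
                    c("TAA", "TAG", "TGA"))
    }
  }
})

test_that("zero-length branches copy the ancestor exactly", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  cfg <- sim_config(tree = tr, plan = cornales_plan(scale = 0.08),
                    seed = 5L, disruptions = NULL)
  sim <- evolve_plastomes(cfg)
  seqs <- vapply(sim$records, `[[`, "", "sequence")
  expect_equal(length(unique(seqs)), 1L)
  expect_true(all(unclass(sim$alignment) != "-"))
  expect_identical(unname(seqs[[1L]]), sim$ancestor$record$sequence)
})

test_that("a two-leaf tree at total length 0.1 matches the JC expectation",
{
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0,c:0.0001);")
  cfg <- sim_config(tree = tr, plan = cornales_plan(scale = 0.3),
                    rates = c(ir = 1, coding = 1, noncoding = 1),
                    indel_rate = 0, cds_indel_rate = 0, n_hotspots = 0L,
                    seed = 13L, disruptions = NULL)
  sim <- evolve_plastomes(cfg)
  a <- chars(sim$records[["a"]]$sequence)
  b <- chars(sim$records[["b"]]$sequence)
  # protected first/last CDS codons depress the rate at a tiny fraction of
  # sites; compare over the unprotected fraction via the whole-genome p
  p_obs <- mean(a != b)
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  n <- length(a)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  # allow the small protected-codon deficit plus sampling error
  expect_lt(abs(p_obs - p_exp), 3 * se + 0.004)
})

test_that("realized substitution counts track their expectation within
           binomial error", {
  sim <- shared_sim()
  bs <- sim$branch_subs
  big <- bs[bs$expected > 50, ]
  for (i in seq_len(nrow(big))) {
    sd_ <- sqrt(big$expected[[i]])
    expect_lt(abs(big$realized[[i]] - big$expected[[i]]),
              4 * sd_ + 2,
              label = sprintf("edge %d realized-vs-expected", i))
  }
})

test_that("simulated divergence reproduces the designed rate contrasts:
           noncoding > coding and single-copy > IR", {
  sim <- shared_sim()
  bundle <- build_datasets(sim$alignment)
  var_cod <- classify_sites(bundle$coding)$percent[["variable"]]
  var_non <- classify_sites(bundle$noncoding)$percent[["variable"]]
  expect_gt(var_non, var_cod)
  reg <- attr(bundle$complete, "region")
  ir_cols <- which(reg == "IRb")
  sc_cols <- which(reg %in% c("LSC", "SSC"))
  var_ir <- classify_sites(aln_sub <- bundle$complete[, ir_cols,
                                                      drop = FALSE])
  var_sc <- classify_sites(bundle$complete[, sc_cols, drop = FALSE])
  expect_gt(var_sc$percent[["variable"]], var_ir$percent[["variable"]])
})

test_that("simulation artifacts are written and the truth file re-parses", {
  sim <- shared_sim()
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$ir_truth), length(sim$records))
  aln2 <- read_alignment(file.path(dir, "true_alignment.fasta"))
  expect_identical(dim(aln2), dim(sim$alignment))
})
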