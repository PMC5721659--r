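# ORF scanning, disruption characterisation, NG86 dN/dS and the clade
# omega contrast.

test_that("scan_orf flags internal stops, terminal stops and frame", {
  r1 <- scan_orf("ATGAAATAA")
  expect_length(r1$internal_stops, 0L)
  expect_true(r1$terminal_stop_present)
  expect_true(r1$translatable)
  r2 <- scan_orf("ATGTAAAAATAA")
  expect_equal(r2$internal_stops, 1L)  # 0-based codon index
  expect_false(r2$translatable)
  r3 <- scan_orf("ATGAAAA")
  expect_equal(r3$length_mod3, 1L)
  expect_false(r3$translatable)
  expect_error(scan_orf("AT"), "shorter")
  expect_error(scan_orf("ATG!!!"), "non-nucleotide")
  # ambiguity codes never called as stops
  expect_length(scan_orf("ATGTRAAAATAA")$internal_stops, 0L)
})

test_that("simulated panels contain internal stops in exactly the disrupted
           genes", {
  sim <- shared_sim()
  orf <- do.call(rbind, lapply(sim$records, scan_record_orfs))
  stops <- orf[orf$n_internal_stops > 0L, ]
  dis <- sim$disruptions
  expect_setequal(paste(stops$sample, stops$gene),
                  paste(dis$taxon, dis$gene))
  # sensitivity 1.0: every injected disruption produced a stop
  expect_true(all(paste(dis$taxon, dis$gene) %in%
                    paste(stops$sample, stops$gene)))
  # intact copies everywhere else
  clean <- orf[!(paste(orf$sample, orf$gene) %in%
                   paste(dis$taxon, dis$gene)), ]
  expect_true(all(clean$n_internal_stops == 0L))
  expect_true(all(clean$terminal_stop))
})

test_that("disruption characterisation classifies indels and point
           nonsense against an intact reference", {
  # hand case: 1 bp deletion in codon 2 -> frameshift, phase 2 at the right
  # position
  aln <- plastome_alignment(c(ref = "ATGAAAGGG", q = "ATGA-AGGG"))
  ev <- characterize_disruption(aln, "ref")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "deletion")
  expect_equal(ev$length, 1L)
  expect_true(ev$frameshift)
  expect_equal(ev$phase, 2L)  # -1 bp shifts the downstream frame by +2
  # point nonsense with codon context, in frame
  aln2 <- plastome_alignment(c(ref = "ATGTGGAAATAA",
                               q   = "ATGTGAAAATAA"))
  ev2 <- characterize_disruption(aln2, "ref")
  nz <- ev2[ev2$type == "point_nonsense", ]
  expect_equal(nrow(nz), 1L)
  expect_match(nz$detail, "TGG->TGA")
  # reference with internal stop is rejected
  aln3 <- plastome_alignment(c(ref = "ATGTAAAAATAA", q = "ATGAAAAAATAA"))
  expect_error(characterize_disruption(aln3, "ref"), "internal stop")
})

test_that("a planted frameshift insertion is recovered as one event of the
           right length and phase", {
  sim <- shared_sim()
  # rebuild the rpl22 alignment from the true whole-genome alignment
  cols <- which(attr(sim$alignment, "labels") == "rpl22" &
                  attr(sim$alignment, "region") != "IRa")
  sub <- sim$alignment[, cols, drop = FALSE]
  strand <- sim$config$plan$features$strand[
    sim$config$plan$features$name == "rpl22"]
  seqs <- apply(sub, 1L, function(r) {
    s <- paste(r, collapse = "")
    if (strand == "-") s <- chartr("ACGT-", "TGCA-", s)
    s
  })
  if (strand == "-")
    seqs <- vapply(seqs, function(s)
      paste(rev(strsplit(s, "")[[1L]]), collapse = ""), "")
  aln <- plastome_alignment(seqs)
  ref <- "Nyssa_wenshanensis"  # undisrupted lineage
  ev <- characterize_disruption(aln, ref)
  ins19 <- ev[ev$taxon == "Cornus_capitata_1" & ev$type == "insertion" &
                ev$length == 19L, ]
  expect_equal(nrow(ins19), 1L)
  expect_equal(ins19$phase, 19L %% 3L)
  expect_true(ins19$frameshift)
  del1 <- ev[ev$taxon == "Alangium_alpinum" & ev$type == "deletion" &
               ev$length == 1L, ]
  expect_gte(nrow(del1), 1L)
  nz <- ev[ev$taxon == "Mastixia_caudatilimba" &
             ev$type == "point_nonsense", ]
  expect_gte(nrow(nz), 1L)
})

test_that("NG86 counting reproduces hand-computed site and difference
           values", {
  # single synonymous third-position change
  e1 <- ng86_dnds("ATGGAAAAA", "ATGGAGAAA")
  expect_equal(e1$Nd, 0); expect_equal(e1$Sd, 1)
  expect_equal(e1$omega, 0)
  # identical sequences: omega undefined
  e2 <- ng86_dnds("TTTAAAGGG", "TTTAAAGGG")
  expect_equal(e2$dN, 0); expect_equal(e2$dS, 0)
  expect_true(is.na(e2$omega))
  # hand-checked codon pairs (sites average the two sequences; paths through
  # stops excluded)
  e3 <- ng86_dnds("AAA", "AGG")  # two paths, each 1 syn + 1 nonsyn
  expect_equal(e3$Nd, 1); expect_equal(e3$Sd, 1)
  expect_equal(e3$N, 2.5); expect_equal(e3$S, 0.5)
  e4 <- ng86_dnds("TAT", "TGG")  # one path blocked by TAG
  expect_equal(e4$Nd, 2); expect_equal(e4$Sd, 0)
  expect_true(is.na(e4$omega))   # dS = 0
  e5 <- ng86_dnds("TTT", "TTC")
  expect_equal(e5$S, 1 / 3, tolerance = 1e-12)
  expect_equal(e5$N, 8 / 3, tolerance = 1e-12)
  # errors
  expect_error(ng86_dnds("ATG", "ATGAAA"), "length")
  expect_error(ng86_dnds("ATGA", "ATGC"), "divisible")
  expect_error(ng86_dnds("ATGTAAAAA", "ATGAAAAAA"), "internal stop")
})

test_that("NG86 invariants: symmetry, N+S identity, gapped codons skipped", {
  set.seed(19)
  for (i in 1:10) {
    a <- random_cds(40L)
    b <- evolve_cds(a, omega = 0.5, mut = 0.2)
    eab <- ng86_dnds(a, b); eba <- ng86_dnds(b, a)
    expect_equal(eab$Nd, eba$Nd); expect_equal(eab$Sd, eba$Sd)
    expect_equal(eab$N, eba$N, tolerance = 1e-9)
    expect_equal(eab$N + eab$S, 3 * eab$codons_compared, tolerance = 1e-9)
  }
  ag <- ng86_dnds("ATG---AAA", "ATGAAAAAA")
  expect_equal(ag$codons_compared, 2L)
})

test_that("NG86 recovers the generating omega of a codon-model simulation",
{
  set.seed(23)
  om <- replicate(25, {
    a <- random_cds(300L)
    ng86_dnds(a, evolve_cds(a, omega = 0.35, mut = 0.3))$omega
  })
  expect_gte(mean(om), 0.25)
  expect_lte(mean(om), 0.45)
})

test_that("the clade omega contrast is degenerate for a single group and
           detects a strong omega difference", {
  set.seed(29)
  a <- random_cds(300L)
  out <- evolve_cds(a, 0.35, 0.3)
  g1 <- vapply(1:4, function(i) evolve_cds(a, 0.1, 0.15), "")
  g2 <- vapply(1:4, function(i) evolve_cds(a, 0.9, 0.15), "")
  seqs <- c(g1, g2, out)
  names(seqs) <- c(paste0("m", 1:8), "og")
  # one group against itself: statistic 0, p = 1
  ct1 <- clade_omega_contrast(seqs, list(g = paste0("m", 1:4)), "og",
                              n_perm = 99L, seed = 1L)
  expect_equal(ct1$p_value, 1)
  ct2 <- clade_omega_contrast(seqs,
                              list(low = paste0("m", 1:4),
                                   high = paste0("m", 5:8)),
                              "og", n_perm = 499L, seed = 1L)
  expect_lt(ct2$p_value, 0.05)
  expect_lt(ct2$group_omega[["low"]], ct2$group_omega[["high"]])
})

test_that("an unannotated gene is located by its reference sequence", {
  set.seed(31)
  gene <- random_cds(80L)
  left <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  rec_f <- plastome("locf", paste0(left, gene, right))
  hit_f <- locate_gene_by_reference(rec_f, gene)
  expect_equal(hit_f$interval$start, 500L)
  expect_equal(hit_f$interval$end, 500L + nchar(gene))
  expect_equal(hit_f$strand, "+")
  rec_r <- plastome("locr", paste0(left, revcomp(gene), right))
  hit_r <- locate_gene_by_reference(rec_r, gene)
  expect_equal(hit_r$strand, "-")
  expect_equal(hit_r$interval$start, 500L)
})
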