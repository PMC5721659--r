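# Simulation study design: the default quadripartite genome plan, guide
# tree, disruption set and configuration container.
#
# The defaults emulate a conserved asterid-grade plastome panel: ~156.5 kb
# genomes (LSC 86 kb, SSC 18.5 kb, IR 26 kb), 114 unique genes (79 CDS, 31
# tRNA, 4 rRNA; 16 duplicated in the IR; 17 one-intron and 2 two-intron
# genes), GC 37.9%, noncoding evolving faster than coding and the IR slower
# than single-copy regions, with localized noncoding hotspots and a set of
# reading-frame disruptions of rpl22 in designated lineages.

sim_gene_table <- function() {
  cds <- function(name, len, region, introns = 0L)
    data.frame(name = name, kind = "CDS", region = region, length = len,
               introns = introns, stringsAsFactors = FALSE)
  trna <- function(name, region, introns = 0L)
    data.frame(name = name, kind = "tRNA", region = region, length = 74L,
               introns = introns, stringsAsFactors = FALSE)
  rrna <- function(name, len)
    data.frame(name = name, kind = "rRNA", region = "IRB", length = len,
               introns = 0L, stringsAsFactors = FALSE)

  lsc_cds <- rbind(
    cds("psbA", 1062, "LSC"), cds("matK", 1530, "LSC"),
    cds("rps16", 261, "LSC", 1L), cds("psbK", 186, "LSC"),
    cds("psbI", 111, "LSC"), cds("atpA", 1524, "LSC"),
    cds("atpF", 555, "LSC", 1L), cds("atpH", 246, "LSC"),
    cds("atpI", 744, "LSC"), cds("rps2", 711, "LSC"),
    cds("rpoC2", 4140, "LSC"), cds("rpoC1", 2031, "LSC", 1L),
    cds("rpoB", 3213, "LSC"), cds("petN", 90, "LSC"),
    cds("psbM", 105, "LSC"), cds("psbD", 1062, "LSC"),
    cds("psbC", 1386, "LSC"), cds("psbZ", 189, "LSC"),
    cds("rps14", 303, "LSC"), cds("psaB", 2205, "LSC"),
    cds("psaA", 2253, "LSC"), cds("ycf3", 507, "LSC", 2L),
    cds("rps4", 606, "LSC"), cds("ndhJ", 477, "LSC"),
    cds("ndhK", 678, "LSC"), cds("ndhC", 363, "LSC"),
    cds("atpE", 402, "LSC"), cds("atpB", 1497, "LSC"),
    cds("rbcL", 1428, "LSC"), cds("accD", 1467, "LSC"),
    cds("psaI", 111, "LSC"), cds("ycf4", 555, "LSC"),
    cds("cemA", 690, "LSC"), cds("petA", 963, "LSC"),
    cds("psbJ", 123, "LSC"), cds("psbL", 117, "LSC"),
    cds("psbF", 120, "LSC"), cds("psbE", 252, "LSC"),
    cds("petL", 96, "LSC"), cds("petG", 114, "LSC"),
    cds("psaJ", 135, "LSC"), cds("rpl33", 201, "LSC"),
    cds("rps18", 306, "LSC"), cds("rpl20", 354, "LSC"),
    cds("rps12", 372, "LSC"), cds("clpP", 591, "LSC", 2L),
    cds("psbB", 1527, "LSC"), cds("psbT", 108, "LSC"),
    cds("psbN", 132, "LSC"), cds("psbH", 222, "LSC"),
    cds("petB", 648, "LSC", 1L), cds("petD", 483, "LSC", 1L),
    cds("rpoA", 1014, "LSC"), cds("rps11", 417, "LSC"),
    cds("rpl36", 114, "LSC"), cds("rps8", 399, "LSC"),
    cds("rpl14", 369, "LSC"), cds("rpl16", 408, "LSC", 1L),
    cds("rps3", 657, "LSC"), cds("rpl22", 429, "LSC"),
    cds("infA", 234, "LSC"), cds("rps19", 279, "LSC"))

  lsc_trna <- rbind(
    trna("trnH-GUG", "LSC"), trna("trnK-UUU", "LSC", 1L),
    trna("trnQ-UUG", "LSC", 1L), trna("trnS-GCU", "LSC", 1L),
    trna("trnG-UCC", "LSC", 1L), trna("trnR-UCU", "LSC"),
    trna("trnC-GCA", "LSC"), trna("trnD-GUC", "LSC"),
    trna("trnY-GUA", "LSC"), trna("trnE-UUC", "LSC"),
    trna("trnT-GGU", "LSC"), trna("trnS-UGA", "LSC"),
    trna("trnG-GCC", "LSC"), trna("trnfM-CAU", "LSC"),
    trna("trnM-CAU", "LSC"), trna("trnS-GGA", "LSC"),
    trna("trnT-UGU", "LSC"), trna("trnL-UAA", "LSC", 1L),
    trna("trnF-GAA", "LSC"), trna("trnV-UAC", "LSC", 1L),
    trna("trnW-CCA", "LSC"), trna("trnP-UGG", "LSC"),
    trna("trnP-GGG", "LSC"))

  ir_feats <- rbind(
    cds("rpl2", 1491, "IRB", 1L), cds("rpl23", 282, "IRB"),
    trna("trnI-CAU", "IRB"), trna("trnL-CAA", "IRB"),
    cds("ycf2", 6837, "IRB"), cds("ndhB", 1533, "IRB", 1L),
    cds("rps7", 468, "IRB"), trna("trnV-GAC", "IRB"),
    rrna("rrn16", 1491L), trna("trnI-GAU", "IRB", 1L),
    trna("trnA-UGC", "IRB", 1L), rrna("rrn23", 2811L),
    rrna("rrn4.5", 102L), rrna("rrn5", 120L),
    trna("trnR-ACG", "IRB"), trna("trnN-GUU", "IRB"))

  ssc_feats <- rbind(
    cds("ycf1", 5301, "SSC"),  # spans the IRb/SSC junction
    cds("rpl32", 174, "SSC"), trna("trnL-UAG", "SSC"),
    cds("ccsA", 960, "SSC"), cds("ndhD", 1503, "SSC"),
    cds("psaC", 246, "SSC"), cds("ndhE", 306, "SSC"),
    cds("ndhG", 531, "SSC"), cds("ndhI", 504, "SSC"),
    cds("ndhA", 1092, "SSC", 1L), cds("ndhH", 1182, "SSC"),
    cds("rps15", 273, "SSC"), cds("ndhF", 2241, "SSC"))

  tab <- rbind(lsc_cds, lsc_trna, ir_feats, ssc_feats)
  # deterministic strand assignment (about a third on the minus strand);
  # ndhF on minus as in real plastomes
  tab$strand <- ifelse(seq_len(nrow(tab)) %% 3L == 0L, "-", "+")
  tab$strand[tab$name == "ndhF"] <- "-"
  tab$intron_len <- ifelse(tab$introns > 0L, 500L, 0L)
  tab
}

#' Default quadripartite genome plan
#'
#' Region lengths, GC target and the feature table (79 CDS, 31 tRNA, 4 rRNA;
#' 16 features inside the IR are annotated in both copies, giving 114 unique
#' and 130 total genes). `rps19` spans the LSC/IRb junction by `rps19_ir`
#' bp, `ycf1` spans the IRb/SSC junction with `ycf1_ir` bp inside the
#' repeat, and `ndhF` ends exactly at the SSC/IRa junction. `scale` < 1
#' shrinks region lengths and keeps a proportional subset of features
#' (junction, disruption and intron marker genes are always retained).
#'
#' @param lsc_len,ssc_len,ir_len region lengths in bp; the defaults follow
#'   `scale`, while explicitly supplied values are used as given.
#' @param gc target GC fraction (default 0.379).
#' @param scale proportional down-scaling factor in (0, 1].
#' @param rps19_ir,ycf1_ir junction overlaps in bp.
#' @return list of class `genome_plan`.
#' @export
cornales_plan <- function(lsc_len = as.integer(round(86000 * scale)),
                          ssc_len = as.integer(round(18500 * scale)),
                          ir_len = as.integer(round(26000 * scale)),
                          gc = 0.379, scale = 1,
                          rps19_ir = 52L, ycf1_ir = 1100L) {
  if (ssc_len <= 0L || lsc_len <= 0L || ir_len <= 0L)
    stop("region lengths must be positive")
  if (scale < 0.08)
    stop("scale below 0.08 leaves no room for the retained gene set")
  feats <- sim_gene_table()
  if (scale < 1) {
    keep_names <- c("rps19", "ycf1", "ndhF", "rpl22", "ycf3", "clpP",
                    "rbcL", "matK", "rpl2", "rrn16", "trnI-CAU")
    base_keep <- feats$name %in% keep_names
    extra <- which(!base_keep)
    n_extra <- max(4L, round(length(extra) * scale))
    keep <- base_keep
    pick <- unique(round(seq(1L, length(extra),
                             length.out = min(n_extra, length(extra)))))
    keep[extra[pick]] <- TRUE
    feats <- feats[keep, , drop = FALSE]
    # shrink long genes and introns so the scaled regions stay feasible
    sh <- max(scale, 0.15)
    long <- feats$kind == "CDS" & feats$length > 600L
    feats$length[long] <-
      pmax(150L, as.integer(floor(feats$length[long] * sh / 3) * 3))
    long_r <- feats$kind == "rRNA" & feats$length > 600L
    feats$length[long_r] <-
      pmax(150L, as.integer(round(feats$length[long_r] * sh)))
    feats$intron_len <- ifelse(feats$introns > 0L,
                               pmax(100L, as.integer(round(500 * sh))), 0L)
    rps19_ir <- min(rps19_ir,
                    max(10L, feats$length[feats$name == "rps19"] %/% 4L))
    ycf1_len <- feats$length[feats$name == "ycf1"]
    ycf1_ir <- min(as.integer(round(ycf1_ir * sh)), ycf1_len - 150L,
                   ir_len %/% 3L)
    for (reg in c("LSC", "IRB", "SSC"))
      if (sum(feats$region == reg) < 2L)
        stop("scaled plan lost region ", reg)
  }
  structure(list(lsc_len = as.integer(lsc_len),
                 ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len), gc = gc,
                 features = feats,
                 rps19_ir = if ("rps19" %in% feats$name) rps19_ir else 0L,
                 ycf1_ir = if ("ycf1" %in% feats$name) ycf1_ir else 0L),
            class = "genome_plan")
}

#' Default 15-taxon guide tree
#'
#' A fixed rooted topology with branch lengths (substitutions/site at the
#' noncoding single-copy rate) emulating a conserved ordinal-level plastome
#' panel: two Cornus capitata individuals, sister species pairs and three
#' deeper clades. Total tree length about 0.11.
#'
#' @return a `phylo` tree with 15 tips.
#' @export
cornales_tree <- function() {
  txt <- paste0(
    "(((((Cornus_capitata_1:0.0006,Cornus_capitata_2:0.0006):0.004,",
    "Cornus_controversa:0.0046):0.005,(Alangium_alpinum:0.0028,",
    "Alangium_chinense:0.0028):0.0068):0.0028,Curtisia_dentata:0.0088):",
    "0.0035,(((((Nyssa_wenshanensis:0.0018,Nyssa_sinensis:0.0018):0.0038,",
    "Camptotheca_acuminata:0.0056):0.0028,Davidia_involucrata:0.0074):",
    "0.0022,(Mastixia_caudatilimba:0.0054,Diplopanax_stachyanthus:0.0054):",
    "0.0036):0.0022,((Hydrangea_heteromalla:0.0044,Hydrangea_aspera:",
    "0.0044):0.0036,Deutzia_crassifolia:0.0072):0.0042):0.0035);")
  ape::read.tree(text = txt)
}

#' Default gene-disruption specification
#'
#' Frameshift insertions/deletions and one point-nonsense change in rpl22,
#' mirroring the kind of lineage-specific reading-frame losses seen in
#' conserved plastome panels: 19-bp insertions in both Cornus capitata
#' individuals, a 5-bp insertion in C. controversa, 1-bp deletions in both
#' Alangium species, a 1-bp insertion in Curtisia and a single
#' stop-generating substitution in Mastixia.
#'
#' @return data.frame with `taxon`, `gene`, `type`
#'   (`frameshift_insertion` / `frameshift_deletion` / `nonsense`), `length`.
#' @export
cornales_disruptions <- function() {
  data.frame(
    taxon = c("Cornus_capitata_1", "Cornus_capitata_2", "Cornus_controversa",
              "Alangium_alpinum", "Alangium_chinense", "Curtisia_dentata",
              "Mastixia_caudatilimba"),
    gene = "rpl22",
    type = c("frameshift_insertion", "frameshift_insertion",
             "frameshift_insertion", "frameshift_deletion",
             "frameshift_deletion", "frameshift_insertion", "nonsense"),
    length = c(19L, 19L, 5L, 1L, 1L, 1L, 0L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param tree guide `phylo` tree with branch lengths (substitutions/site at
#'   the base, i.e. noncoding single-copy, rate).
#' @param plan a [cornales_plan()] genome plan.
#' @param rates named rate multipliers: `ir` (default 0.3), `coding` (0.5),
#'   `noncoding` (1); a site's rate is the product of its region and
#'   category multipliers and any hotspot multiplier.
#' @param indel_rate noncoding indel events per site per unit branch length
#'   (default 0.02).
#' @param cds_indel_rate in-frame (codon-aligned, length divisible by 3)
#'   indel rate inside CDS (default 0.002).
#' @param indel_geom_p geometric length parameter for noncoding indels
#'   (default 0.35; mean length about 2.9 bp).
#' @param hotspot_mult rate multiplier inside hotspot intervals (default 10).
#' @param n_hotspots number of automatically placed noncoding single-copy
#'   hotspot intervals (default 9).
#' @param hotspots optional explicit list of `list(start, end, mult)` in
#'   ancestor coordinates, overriding automatic placement.
#' @param disruptions data.frame as [cornales_disruptions()], or `NULL` for
#'   none.
#' @param seed integer seed fixing all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(tree = cornales_tree(), plan = cornales_plan(),
                       rates = c(ir = 0.3, coding = 0.5, noncoding = 1),
                       indel_rate = 0.02, cds_indel_rate = 0.002,
                       indel_geom_p = 0.35, hotspot_mult = 10,
                       n_hotspots = 9L, hotspots = NULL,
                       disruptions = cornales_disruptions(), seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(rates > 0))
  structure(list(tree = tree, plan = plan, rates = rates,
                 indel_rate = indel_rate, cds_indel_rate = cds_indel_rate,
                 indel_geom_p = indel_geom_p, hotspot_mult = hotspot_mult,
                 n_hotspots = as.integer(n_hotspots), hotspots = hotspots,
                 disruptions = disruptions, seed = as.integer(seed)),
            class = "sim_config")
}
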