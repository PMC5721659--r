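# Seeded simulator of quadripartite plastomes evolved along a known tree.
#
# Evolution operates on the "reduced" genome (LSC + IRb + SSC); the second
# repeat copy is derived per leaf as the exact reverse complement of its
# IRb, i.e. the two copies evolve as one mirrored process (IR
# co-conversion). Substitutions follow the Jukes-Cantor kernel per branch
# with per-site rate multipliers (region x category x hotspot); indels are
# geometric-length events recorded directly into the growing true
# alignment. Background indels never break a reading frame: inside CDS they
# are codon-aligned with lengths divisible by three, and the first and last
# codons of every CDS are immutable. Frameshifts and premature stops enter
# only through the explicit disruption specification.

SENSE_CODONS <- NULL  # initialised lazily

sense_codons <- function() {
  gc <- genetic_code_11()
  names(gc)[gc != "*"]
}

# codon sampling weights that realise (approximately) a per-base GC target,
# with one correction step for the exclusion of the AT-rich stop codons
codon_weights <- function(gc_target) {
  cods <- sense_codons()
  w_for <- function(g) {
    p <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    vapply(strsplit(cods, ""), function(v) prod(p[v]), 0)
  }
  w <- w_for(gc_target)
  gc_per_base <- sum(w * vapply(strsplit(cods, ""),
                                function(v) sum(v %in% c("G", "C")), 0)) /
    (3 * sum(w))
  w_for(max(0.01, min(0.99, gc_target - (gc_per_base - gc_target))))
}

place_in_window <- function(extents, wstart, wend, pin_start = FALSE,
                            pin_end = FALSE) {
  nf <- length(extents)
  free <- (wend - wstart) - sum(extents)
  slots <- nf + 1L
  open <- rep(TRUE, slots)
  if (pin_start) open[1L] <- FALSE
  if (pin_end) open[slots] <- FALSE
  nopen <- sum(open)
  if (free < nopen) stop("infeasible genome plan: features exceed region")
  gaps <- integer(slots)
  base <- free %/% nopen; rem <- free %% nopen
  gaps[open] <- base + c(rep(1L, rem), rep(0L, nopen - rem))
  starts <- wstart + cumsum(c(0L, extents)) [seq_len(nf)] +
    cumsum(gaps[seq_len(nf)])
  starts
}

# lay the plan out on the reduced genome; returns feature placements and the
# per-position metadata vectors that drive evolution
layout_plan <- function(plan) {
  L <- plan$lsc_len; I <- plan$ir_len; S <- plan$ssc_len
  n_red <- L + I + S
  ft <- plan$features
  ft$extent <- ft$length + ft$introns * ft$intron_len

  lsc <- ft[ft$region == "LSC", , drop = FALSE]
  if ("rps19" %in% lsc$name)  # pinned across the LSC/IRb junction
    lsc <- rbind(lsc[lsc$name != "rps19", ], lsc[lsc$name == "rps19", ])
  irb <- ft[ft$region == "IRB", , drop = FALSE]
  ssc <- ft[ft$region == "SSC", , drop = FALSE]
  if ("ycf1" %in% ssc$name)
    ssc <- rbind(ssc[ssc$name == "ycf1", ], ssc[ssc$name != "ycf1", ])
  if ("ndhF" %in% ssc$name)
    ssc <- rbind(ssc[ssc$name != "ndhF", ], ssc[ssc$name == "ndhF", ])

  pad <- max(20L, I %/% 300L)
  lsc$start <- place_in_window(lsc$extent, 0L, L + plan$rps19_ir,
                               pin_end = plan$rps19_ir > 0L)
  irb$start <- place_in_window(irb$extent, L + plan$rps19_ir + pad,
                               L + I - plan$ycf1_ir - pad)
  ssc$start <- place_in_window(ssc$extent, L + I - plan$ycf1_ir, n_red,
                               pin_start = plan$ycf1_ir > 0L,
                               pin_end = "ndhF" %in% ssc$name)
  placed <- rbind(lsc, irb, ssc)
  placed <- placed[order(placed$start), , drop = FALSE]
  rownames(placed) <- NULL

  region <- rep(c("LSC", "IRb", "SSC"), times = c(L, I, S))
  category <- rep("spacer", n_red)
  label <- rep(NA_character_, n_red)
  feature_id <- rep(NA_integer_, n_red)
  codon_id <- rep(NA_real_, n_red)
  frame <- rep(NA_integer_, n_red)
  cds_strand <- rep(NA_character_, n_red)
  protect <- rep(FALSE, n_red)

  parts_list <- vector("list", nrow(placed))
  for (fi in seq_len(nrow(placed))) {
    f <- placed[fi, ]
    k <- f$introns
    exon_lens <- rep(f$length %/% (k + 1L), k + 1L)
    exon_lens[1L] <- exon_lens[1L] + f$length - sum(exon_lens)
    pos <- f$start
    parts <- matrix(0L, nrow = k + 1L, ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))
    for (e in seq_len(k + 1L)) {
      parts[e, ] <- c(pos, pos + exon_lens[[e]])
      idx <- (pos + 1L):(pos + exon_lens[[e]])
      category[idx] <- f$kind
      label[idx] <- f$name
      feature_id[idx] <- fi
      pos <- pos + exon_lens[[e]]
      if (e <= k) {
        iidx <- (pos + 1L):(pos + f$intron_len)
        category[iidx] <- "intron"
        label[iidx] <- paste0(f$name, "_intron", e)
        feature_id[iidx] <- fi
        pos <- pos + f$intron_len
      }
    }
    parts_list[[fi]] <- parts
    if (f$kind == "CDS") {
      exon_idx <- unlist(lapply(seq_len(nrow(parts)), function(e)
        (parts[e, 1L] + 1L):parts[e, 2L]))
      ci <- if (f$strand == "+") seq_along(exon_idx) - 1L else
        rev(seq_along(exon_idx) - 1L)
      codon_id[exon_idx] <- fi * 1e7 + ci %/% 3L
      frame[exon_idx] <- ci %% 3L
      cds_strand[exon_idx] <- f$strand
      ncod <- f$length %/% 3L
      protect[exon_idx[ci %/% 3L %in% c(0L, ncod - 1L)]] <- TRUE
    }
  }

  # spacer labels: flanked by the nearest features
  sp <- which(category == "spacer")
  if (length(sp)) {
    r <- rle(!is.na(label))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (g in which(!r$values)) {
      prev_name <- if (starts[[g]] > 1L) label[[starts[[g]] - 1L]] else "origin"
      next_name <- if (ends[[g]] < n_red) label[[ends[[g]] + 1L]] else "end"
      label[starts[[g]]:ends[[g]]] <- paste0(prev_name, "-", next_name)
    }
  }

  list(placed = placed, parts = parts_list, n_red = n_red,
       meta = list(region = region, category = category, label = label,
                   feature_id = feature_id, codon_id = codon_id,
                   frame = frame, cds_strand = cds_strand,
                   protect = protect))
}

auto_hotspots <- function(meta, n_hotspots, mult) {
  eligible <- meta$category %in% c("spacer", "intron") & meta$region != "IRb"
  r <- rle(eligible)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 300L)
  if (!length(runs) || n_hotspots < 1L) return(list())
  pick <- runs[unique(round(seq(1L, length(runs),
                                length.out = min(n_hotspots, length(runs)))))]
  lapply(pick, function(g) {
    len <- min(800L, r$lengths[[g]])
    mid <- (starts[[g]] + ends[[g]]) %/% 2L
    s <- max(starts[[g]], mid - len %/% 2L)
    list(start = s - 1L, end = s - 1L + len, mult = mult)  # 0-based
  })
}

#' Build the ancestral quadripartite genome of a simulation
#'
#' Draws a random sequence at the plan's GC target, writes a valid open
#' reading frame (ATG ... sense codons ... TAA, plastid/bacterial code) into
#' every CDS, sets the IRa to the exact reverse complement of the IRb, and
#' emits annotations for all features plus mirrored copies of the
#' IR-internal ones.
#'
#' @param plan a [cornales_plan()] genome plan.
#' @param config optional [sim_config()]; used for hotspot placement. When
#'   given, its plan is used and `plan` is ignored.
#' @param seed optional integer seed (`NULL` leaves the RNG state alone).
#' @return list of class `ancestor_genome`: `record` (annotated
#'   [plastome()]), `reduced` (character vector LSC+IRb+SSC), `meta`
#'   (per-position metadata), `layout`, `hotspots` (0-based ancestor
#'   intervals), `mult` (per-site rate multipliers).
#' @export
build_ancestor <- function(plan = cornales_plan(), config = NULL,
                           seed = NULL) {
  if (!is.null(config)) plan <- config$plan
  if (!is.null(seed)) set.seed(seed)
  lay <- layout_plan(plan)
  meta <- lay$meta
  n_red <- lay$n_red
  gcp <- plan$gc
  p <- c(A = (1 - gcp) / 2, C = gcp / 2, G = gcp / 2, T = (1 - gcp) / 2)
  genome <- sample(names(p), n_red, replace = TRUE, prob = p)

  cods <- sense_codons()
  w <- codon_weights(gcp)
  middle <- cods[!cods %in% "ATG"]
  wm <- w[match(middle, cods)]
  for (fi in seq_len(nrow(lay$placed))) {
    f <- lay$placed[fi, ]
    if (f$kind != "CDS") next
    ncod <- f$length %/% 3L
    orf <- c("ATG", sample(middle, ncod - 2L, replace = TRUE, prob = wm),
             "TAA")
    orf_chars <- unlist(strsplit(orf, ""), use.names = FALSE)
    exon_idx <- unlist(lapply(seq_len(nrow(lay$parts[[fi]])), function(e)
      (lay$parts[[fi]][e, 1L] + 1L):lay$parts[[fi]][e, 2L]))
    genome[exon_idx] <- if (f$strand == "+") orf_chars else
      rev(complement_chars(orf_chars))
  }

  # break reverse-complement matches at the repeat flanks so that the
  # maximal detected pair coincides exactly with the planted coordinates
  genome <- break_ir_flanks(genome, plan, meta)

  full_seq <- paste0(collapse_chars(genome),
                     collapse_chars(revcomp_chars(
                       genome[(plan$lsc_len + 1L):(plan$lsc_len + plan$ir_len)])))

  feats <- vector("list", 0L)
  for (fi in seq_len(nrow(lay$placed))) {
    f <- lay$placed[fi, ]
    feats[[length(feats) + 1L]] <-
      plastome_feature(f$name, f$kind, lay$parts[[fi]], f$strand)
  }
  # mirrored annotations for features fully inside the IRb
  A0 <- n_red  # IRa block starts here in the full genome
  LI <- plan$lsc_len + plan$ir_len
  for (fi in seq_len(nrow(lay$placed))) {
    f <- lay$placed[fi, ]
    if (f$region != "IRB") next
    parts <- lay$parts[[fi]]
    mirrored <- cbind(start = A0 + LI - parts[, "end"],
                      end = A0 + LI - parts[, "start"])
    mirrored <- mirrored[order(mirrored[, "start"]), , drop = FALSE]
    feats[[length(feats) + 1L]] <-
      plastome_feature(f$name, f$kind, mirrored,
                       if (f$strand == "+") "-" else "+")
  }
  record <- plastome("ancestor", full_seq, feats)

  structure(list(record = record, reduced = genome, meta = meta,
                 layout = lay, plan = plan),
            class = "ancestor_genome")
}

# replace the base at `idx` (1-based) with one that differs from
# `forbidden`; when the position is coding, the altered codon must not
# become a stop
adjust_base <- function(genome, idx, forbidden, meta) {
  for (alt in setdiff(DNA_BASES, c(genome[[idx]], forbidden))) {
    if (is.na(meta$codon_id[[idx]])) { genome[[idx]] <- alt; return(genome) }
    cc <- codon_columns(meta, idx, meta$codon_id[[idx]])
    tmp <- genome[cc]; tmp[cc == idx] <- alt
    if (!codon_is_stop(tmp, meta$cds_strand[[idx]])) {
      genome[[idx]] <- alt
      return(genome)
    }
  }
  genome
}

# the maximal exact reverse-complement pair must stop at the planted
# boundaries: position L pairs outward with position 1 (via the circle),
# and the first SSC base pairs inward with the last SSC base
break_ir_flanks <- function(genome, plan, meta) {
  L <- plan$lsc_len; I <- plan$ir_len; S <- plan$ssc_len
  n_red <- L + I + S
  if (genome[[L]] == DNA_COMPLEMENT[[genome[[1L]]]])
    genome <- adjust_base(genome, 1L, DNA_COMPLEMENT[[genome[[L]]]], meta)
  if (genome[[L + I + 1L]] == DNA_COMPLEMENT[[genome[[n_red]]]])
    genome <- adjust_base(genome, L + I + 1L,
                          DNA_COMPLEMENT[[genome[[n_red]]]], meta)
  genome
}

site_multipliers <- function(meta, rates, hotspots) {
  mult <- rep(rates[["noncoding"]], length(meta$region))
  mult[meta$region == "IRb"] <- rates[["ir"]]
  coding <- meta$category %in% CODING_CATEGORIES
  mult[coding] <- mult[coding] * rates[["coding"]] / rates[["noncoding"]]
  for (h in hotspots) {
    idx <- (h$start + 1L):h$end
    mult[idx] <- mult[idx] * h$mult
  }
  mult
}

# insert new columns into every stored row; `ins` is a list of
# list(after = 0-based column, chars, meta = list of per-field vectors)
splice_columns <- function(rows, meta_df, ins, owner) {
  if (!length(ins)) return(list(rows = rows, meta = meta_df))
  p <- vapply(ins, `[[`, 0L, "after")
  ord <- order(p)
  ins <- ins[ord]; p <- p[ord]
  lens <- vapply(ins, function(x) length(x$chars), 0L)
  cum <- cumsum(lens)
  old_len <- length(meta_df$region)
  new_len <- old_len + cum[[length(cum)]]
  shift <- c(0L, cum)[findInterval(seq_len(old_len) - 1L, p) + 1L]
  newpos <- seq_len(old_len) + shift
  slot_start <- p + c(0L, cum[-length(cum)]) + 1L
  slots <- lapply(seq_along(ins), function(i)
    slot_start[[i]]:(slot_start[[i]] + lens[[i]] - 1L))
  for (nm in names(rows)) {
    nr <- rep("-", new_len)
    nr[newpos] <- rows[[nm]]
    if (nm == owner)
      for (i in seq_along(ins)) nr[slots[[i]]] <- ins[[i]]$chars
    rows[[nm]] <- nr
  }
  blank <- list(region = NA_character_, category = NA_character_,
                label = NA_character_, feature_id = NA_integer_,
                codon_id = NA_real_, frame = NA_integer_,
                cds_strand = NA_character_, protect = FALSE,
                anc_pos = NA_integer_, mult = 0)
  for (fld in names(meta_df)) {
    v <- rep(blank[[fld]], new_len)
    v[newpos] <- meta_df[[fld]]
    for (i in seq_along(ins)) {
      mv <- ins[[i]]$meta[[fld]]
      v[slots[[i]]] <- if (is.null(mv)) blank[[fld]] else mv
    }
    meta_df[[fld]] <- v
  }
  list(rows = rows, meta = meta_df)
}

# columns of one codon, searched locally around column h
codon_columns <- function(meta, h, id, reach = 6000L) {
  lo <- max(1L, h - reach); hi <- min(length(meta$codon_id), h + reach)
  idx <- lo:hi
  idx[!is.na(meta$codon_id[idx]) & meta$codon_id[idx] == id]
}

codon_is_stop <- function(chars3, strand) {
  cd <- if (strand == "+") paste(chars3, collapse = "") else
    paste(rev(DNA_COMPLEMENT[chars3]), collapse = "")
  cd %in% STOP_CODONS
}
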