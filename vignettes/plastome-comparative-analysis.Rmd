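---
title: "Comparative analysis of quadripartite plastomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of quadripartite plastomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

## The analysis this package implements

Angiosperm plastid genomes (plastomes) are circular molecules of roughly
120–160 kb organised in a quadripartite architecture: a large single-copy
region (LSC), a small single-copy region (SSC), and two identical inverted
repeats (IRb, IRa) separating them. Comparative plastome studies of a clade
typically proceed through the same sequence of steps, and `plastomics`
implements each of them as a tested, composable function:

1. **Structure** — locate the IR pair, partition the genome into
   LSC/IRb/SSC/IRa, and describe which genes span the four region junctions
   (`find_inverted_repeat()`, `partition_regions()`, `junction_report()`).
2. **Inventory** — census the annotated genes (unique versus IR-duplicated,
   CDS/tRNA/rRNA, intron content), split the genome length into coding and
   noncoding fractions, and summarise region-length dispersion across
   samples (`gene_census()`, `coding_noncoding_lengths()`,
   `region_length_summary()`).
3. **Divergence** — classify alignment columns (constant, variable,
   parsimony-informative, singleton), scan the alignment in sliding windows
   with the mutation-event proportion, call mutational hotspots, and
   compute windowed identity to a reference (`classify_sites()`,
   `window_scan()`, `call_hotspots()`, `pairwise_identity()`).
4. **Reading-frame integrity** — detect premature internal stop codons and
   the frameshift indels or point-nonsense changes that cause them, and ask
   whether disrupted lineages evolve faster, via Nei–Gojobori (1986)
   dN/dS and a permutation contrast (`scan_orf()`,
   `characterize_disruption()`, `ng86_dnds()`, `clade_omega_contrast()`).
5. **Matrix building** — derive the three standard data sets (complete,
   coding, noncoding; one IR copy removed), apply three filtering
   strategies (none, light, strict), and emit functional partition subsets
   (`build_datasets()`, `filter_light()`, `filter_strict()`,
   `build_partitions()`).
6. **Topology recovery** — Jukes–Cantor distances, neighbor joining,
   column-resampling bootstrap, and Robinson–Foulds comparison
   (`jc_distance()`, `neighbor_joining()`, `bootstrap_support()`,
   `robinson_foulds()`).

A seeded simulator (`cornales_plan()`, `build_ancestor()`,
`evolve_plastomes()`) generates quadripartite genomes evolved along a known
tree with ground truth for every stage, so that each method can be tested
for *recovery* rather than merely for internal consistency.

## The mutation-event proportion and hotspot calling

For a window of aligned length $L$, with $NS$ substitution sites and $ID$
indel events, the proportion of mutation events is

$$P = \frac{NS + ID}{L} \times 100\%.$$

The scan uses 600 bp windows advanced in 200 bp steps (both configurable),
plus one truncated tail window, and a region is a hotspot when $P$ strictly
exceeds 20%. Three conventions require decisions the formula itself does
not make:

* **$NS$ on a multiple alignment.** The formula originated in pairwise
  comparisons. On a multiple alignment we count each *variable column*
  once, regardless of how many states segregate there; this is monotone,
  cheap, and consistent with treating one column as one site. The
  alternative (mean pairwise differences) weights deep splits more heavily.
* **$ID$ as events, not columns.** An indel event is a maximal run of
  consecutive columns sharing one identical gap presence/absence pattern
  across taxa that differs from the all-present pattern. A 19 bp insertion
  is thus one event, and a deletion shared by several taxa counts once. An
  event straddling a window boundary counts in each window it touches.
* **$L$ includes gap columns** — it is the aligned length, so indel-rich
  windows are not silently rescaled.

Columns that carry an unambiguous base in fewer than two taxa are
unclassifiable and contribute to neither $NS$ nor the site classes.

## Inverted-repeat detection

Plastome IRs are long (20–30 kb) and essentially exact, so the default
detector looks for the maximal pair of disjoint intervals in which one
interval equals the reverse complement of the other, with zero mismatches
(a mismatch fraction is available as a flag). The search is seed-and-extend:
21-mers of the sequence are hashed into 2-bit integers and matched against
the 21-mers of the reverse complement; exact matches on a common diagonal
form runs, runs are merged across chance k-mer collisions, and the best
candidate is extended base-by-base in both directions. A quadratic
dynamic-programming oracle verifies the detector on short sequences in the
test suite.

Circularity is handled by a rotation ensemble rather than by doubling the
sequence: the linear scan is repeated from cuts at 0, $n/3$ and $2n/3$.
Since each repeat copy is shorter than $n/3$, at least one cut leaves both
copies unwrapped, and a pair found clear of its cut cannot be a
linearisation artifact, so the scan stops early in the common case. This
avoids the duplicated k-mer content (and consequent ambiguous matching) of
a doubled string.

The two single-copy gaps between the repeats are labelled LSC (longer) and
SSC (shorter); a tie raises an error rather than assigning arbitrary
labels. Junction reports give, for each of the four boundaries, the
spanning feature and its intrusion depth in bp (the length of the feature's
shorter side), an `abuts` class for features ending exactly at a boundary,
and the flanking spacer name when no feature touches it.

## Alignment filtering

The strict filter removes every column containing at least one gap. The
light filter is a deterministic, parameterised trim in the spirit of
Gblocks (an exact Gblocks reimplementation is out of scope): first drop
columns whose gap fraction exceeds 0.5, then drop maximal runs of at least
10 consecutive columns that *both* contain a gap *and* have a majority
non-gap state frequency below 0.5. Restricting the second step to
gap-containing columns makes the light filter's output provably a superset
of the strict filter's — a nesting the test suite asserts on arbitrary
inputs — while still removing the poorly aligned gappy blocks the light
strategy targets. Both parameters are exposed so users can tighten or
loosen the trim; the scientific claim being tested downstream is that the
choice does not alter the recovered topology.

Partition subsets are built one per gene, intron or spacer; subsets shorter
than 200 columns, or without a single variable site, are pooled into one
subset per functional category (CDS, tRNA, rRNA, intron, spacer). The
scheme is emitted as RAxML-style partition text and a NEXUS sets block for
external model-selection tools; model selection itself is out of scope.

## dN/dS by counting, not maximum likelihood

Branch-model maximum-likelihood estimates of $\omega = d_N/d_S$ require a
codon-model likelihood machine; this package instead implements the
Nei–Gojobori (1986) counting method, which preserves the scientific
question — *do stop-codon-containing lineages evolve under different
selective pressure?* — as a testable property. Conventions: synonymous site
fractions count, per codon position, the fraction of the three possible
changes that are synonymous, with changes to stop codons counted as
nonsynonymous; differences between codons are averaged with equal weight
over all minimal substitution paths, excluding paths that pass through a
stop codon (if every path is blocked, all paths are used); the
Jukes–Cantor correction maps proportions to rates. When $d_N = 0$ exactly,
$\omega$ is 0 whenever any synonymous divergence exists; when $d_S = 0$,
$\omega$ is undefined (`NA`), never infinite. The implementation was
verified against an independent implementation on randomly diverged
300-codon pairs and hand-computed 1–3 codon cases.

The clade contrast estimates each group member's $\omega$ against a common
outgroup, takes the size-weighted between-group variance of group means as
the statistic, and assesses it by permuting member labels (999 permutations
by default, seeded). Simulations under a shared $\omega$ calibrate the
test's type-I error; simulations at $\omega$ 0.1 versus 0.9 give it power.

## The synthetic study design

The simulator's defaults describe a conserved, ordinal-level plastome
panel. The genome plan places 114 unique genes — 79 CDS, 31 tRNA, 4 rRNA,
of which 16 lie inside the IR and are annotated in both copies (130 total),
with 17 one-intron genes and two two-intron genes (*ycf3*, *clpP*) — on a
156.5 kb genome (LSC 86 kb, SSC 18.5 kb, IR 26 kb) at GC 37.9%. Three
junction behaviours are built in: *rps19* spans the LSC/IRb boundary by
52 bp, *ycf1* spans IRb/SSC with 1.1 kb inside the repeat, and *ndhF* ends
exactly at SSC/IRa. Every CDS is written as a valid open reading frame
(ATG, sense codons drawn with GC-matched weights, terminal stop).

Evolution runs along a fixed 15-taxon guide tree (total length ≈ 0.11
substitutions/site at the base rate) with the exact Jukes–Cantor transition
kernel per branch and per-site rate multipliers: inverted repeat 0.3×,
coding 0.5×, noncoding 1×, and 10× inside nine automatically placed
noncoding single-copy hotspot intervals. These multipliers encode the
empirical regularities of plastomes — IRs more conserved than single-copy
regions, coding more conserved than noncoding, and localized hotspots —
and the simulator's outputs are tested for reproducing exactly those
contrasts. Indels are Poisson events with geometric lengths (rate 0.02
events/site/unit branch length in noncoding, mean length ≈ 2.9 bp); inside
CDS they are codon-aligned with lengths divisible by three (rate 0.002),
and the first and last codons of every CDS are immutable, so background
evolution never breaks a reading frame. Frameshifts and premature stops
enter only through an explicit disruption list; the default list disrupts
*rpl22* in seven individuals of six species (19, 19, 5 and 1 bp insertions,
two 1 bp deletions, one single-base nonsense change), emulating
lineage-specific pseudogenisation events. After any frameshift the gene is
verified to contain a premature stop; in the rare case the shifted frame
reaches the terminus without one, a stop is placed deterministically and
recorded.

The two repeat copies evolve as a single mirrored process: mutations are
applied to the IRb and the IRa is derived as its exact reverse complement
per leaf (IR co-conversion). The flanking bases at the planted boundaries
are adjusted (codon-safely) so that the *maximal* reverse-complement pair
coincides exactly with the planted coordinates in the ancestor — without
this, chance complementarity at the flanks would extend the detected pair
by a few bases and make "exact recovery" ill-posed.

What the simulator does **not** emulate: genome rearrangement and gene-order
change (the target clade shows none), codon-usage bias and site-specific
selection heterogeneity, rate variation across branches beyond the region
multipliers, sequencing or assembly error, and ambiguity codes. Passing
recovery tests on these simulations therefore demonstrates correctness of
the implementations under the stated generative model, not robustness to
every artifact of real data; real alignments additionally depend on the
external aligner used to produce them.

## Topology recovery and the invariance property

Distance trees (Jukes–Cantor + neighbor joining) stand in for
maximum-likelihood and Bayesian inference, which are out of scope: the
claim under test is *topological invariance* — that complete, coding and
noncoding data sets, under all three filtering strategies, recover the same
(true) topology — and a consistent distance method suffices for that.
Saturated pairs ($p \ge 3/4$) are flagged missing rather than fabricated;
NJ refuses incomplete matrices; negative branch-length estimates are
truncated at zero. Bootstrap support resamples columns with replacement
under a fixed seed. The invariance property is asserted over 50 replicate
panels simulated at one-twelfth scale (regions and gene lengths shrunk
proportionally, divergence unchanged), where a replicate passes when all
nine data-set × filter combinations are Robinson–Foulds 0 from the truth;
the packaged acceptance script recomputes the rate from scratch.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open everywhere inside the package; GenBank's
  1-based inclusive convention exists only at the I/O boundary.
* Region-length dispersions use the sample standard deviation (n−1) rounded
  half away from zero to whole bp — the convention that reproduces the
  published values for this study system exactly.
* Ambiguity codes are preserved in sequences and treated as missing in all
  statistics (site classes, distances, GC, ORF scanning).
* Window proportions are reported to two decimals; the hotspot threshold is
  strict (> 20).
* The mutation-event denominator, window geometry, hotspot threshold,
  filter parameters and partition minimum (600/200/20%/0.5/10/0.5/200) are
  defaults mirroring standard practice for this analysis and are all
  configurable.
* Degenerate inputs fail loudly: empty windows, single-taxon alignments,
  equal-length single-copy gaps, missing distance entries, saturated JC
  pairs, reference sequences with internal stops, zero-length regions in a
  genome plan.

## Problem sizes used in the packaged checks

The test suite and acceptance script exercise the full-scale design
(156.5 kb, 15 taxa) for structure, census, junction and hotspot checks, and
down-scaled panels (8–10% scale, same divergence and tree) for
replicate-heavy properties: 100 genomes for exact IR recovery, 50
replicates for topology invariance, 20 for hotspot recall and the
rate-homogeneous null, 50 for $\omega$ recovery and 200 for permutation
calibration. These sizes were chosen so the whole battery runs comfortably
on a single CPU while keeping every Monte-Carlo band (binomial error at the
stated replicate counts) well inside the asserted tolerances.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- sim_config(plan = cornales_plan(scale = 0.1), seed = 1)
res <- run_pipeline("plastomics-run", config = cfg)
res$rf            # Robinson-Foulds distance to the true tree, 9 matrices
res$hotspots      # called hotspot regions with overlapping features
```

## Known limitations

* The GenBank writer emits a minimal record (LOCUS/FEATURES/ORIGIN with
  typed gene features); qualifiers beyond `/gene` are not preserved.
* The IR detector's mismatch-tolerant mode merges seed runs under the
  stated budget but does not optimise mismatch placement during extension;
  plastome IRs do not need it, and the exact mode is the tested default.
* NG86 is a counting method: at high divergence it underestimates rates,
  and its $\omega$ is not numerically comparable to branch-model ML
  estimates — the package compares lineages with the same estimator
  instead of reproducing ML values.
* Trans-spliced genes are parsed as annotated (each copy counted once per
  annotation) but the simulator does not generate them.
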