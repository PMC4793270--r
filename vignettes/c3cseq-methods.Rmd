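---
title: "Calling chromatin interactions from capture-3C sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling chromatin interactions from capture-3C sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c3cseq)
library(dplyr)
```

# The experiment this package models

Capture-based 3C sequencing asks whether noncoding regions — typically GWAS
risk loci — physically touch the promoters of distant genes. Crosslinked
chromatin is digested with EcoRI, religated so that spatially proximal
fragments become covalently joined, and the library is enriched with capture
probes tiling the restriction sites of the loci of interest ("baits").
Paired-end reads then report contacts between a bait and any other
restriction fragment in the genome. The analysis problem is to turn tens of
millions of read pairs into a short list of bait–fragment contacts that
exceed what random religation would produce.

`c3cseq` implements the complete downstream analysis: restriction-map and
bait-design construction, read-pair filtering and classification, per-probe
capture-efficiency normalization, a permutation test for significant
cis-interactions, and the surrounding quantifications (replicate
reproducibility, 3C-qPCR contact frequencies, eQTL regression, motif allele
scoring, epigenomic overlap annotation). Because raw libraries of this kind
are rarely deposited, the package also ships a synthetic proximity-ligation
generator with known ground truth, so every stage is testable end to end.

# Coordinate and naming conventions

All internal coordinates are 0-based half-open; human-facing report tables
print 1-based inclusive positions, and BED/BEDPE outputs keep the standard
0-based half-open convention. A cut site is the 0-based start of the
recognition motif (`GAATTC`), not the nick position: every distance the
method uses is "distance to the nearest EcoRI site", so one consistent
anchor suffices. Fragments are the half-open intervals between consecutive
site starts and tile each chromosome exactly once.

Bait probes are the two 250 bp flanks of each in-locus cut site, named
`<prefix>E<k><side>`: sites are numbered 1..n in coordinate order within a
locus, `U`/`D` are the upstream/downstream flanks, and the prefix letters
`A`, `B`, ... order multiple loci on one chromosome (no prefix when a locus
is alone on its chromosome). Lowercase (soft-masked) sequence matches the
motif — capture arrays do target masked regions — and repeat handling is
delegated to the downstream probe filter; `N` never matches.

# Read-pair filtering

A pair is *informative* (on-target) when at least one end lies inside a
target locus within 250 bp of a locus cut site; the anchoring end is
assigned to the U or D flank interval that contains it, with ties at the
site itself resolving to D. Informative pairs are cis when both ends map to
the same chromosome, trans otherwise. Pairs with an unmapped end are
tallied and dropped; coordinate-and-strand duplicates (after canonical end
ordering, so end-swapped copies compare equal) are removed, standing proxy
for sequence-identical duplicates when only coordinates are available. A
pair whose both ends are bait-proximal contributes one count to each bait's
profile — bait-by-bait heatmaps show exactly this symmetric signal — but is
counted once in the library accounting, which conserves every input pair
across the categories unmapped / duplicate / off-target / cis / trans.

The 5'-most aligned coordinate anchors all distance measurements: 3C
junction reads begin at ligated restriction ends, and no better anchor is
available from coordinate tables.

# Probe normalization and masking

Capture efficiency differs between probes. It is proxied by each probe's
raw on-target read total; totals are rescaled so that every retained probe
sums to the median of the retained set (`factor = median / total`). The
lowest 22% of probes by raw total (count-based rank, `floor(0.22 * P)`,
ties broken by name so the ordering is total) are removed as
low-efficiency, along with probes overlapping an optional repeat track.
The median is recomputed on the retained set — removed probes are declared
unusable, so they should not set the scale. Fragments within ±25 kb of a
bait's own cut site carry self- and near-ligation signal orders of
magnitude above everything else; they are flagged masked (never deleted)
and excluded from significance testing and heatmaps.

# The permutation test

For one bait, let `N` be its total reads over the `M` mappable (unmasked,
same-chromosome) fragments. Each of 1000 permutations redistributes the
`N` reads uniformly among the `M` fragments (a multinomial draw) and sums
them over sliding windows (window 1 by default, so windows are fragments).
Two thresholds are combined:

* a candidate count `T0`, the smallest count whose pooled permuted
  exceedance fraction is at most 5% (the "top fifth percentile");
* the final threshold `T`, the smallest count `c >= T0` with estimated
  false discovery rate `FDR(c) = E_perm[#windows >= c] / max(1, #observed
  windows >= c)` at most 0.01.

If no count satisfies both, nothing is called. Per-window empirical
p-values use the pooled add-one estimator `(1 + #permuted >= c) /
(n_perm * W + 1)`. Significance is computed on raw integer counts: the
permutation null conserves the integer read total, and probe normalization
rescales whole profiles, which cannot change a within-profile call.
Trans fragments are not tested — the method calls cis-interactions only —
and the uniform null carries no distance-decay model; the conservative
±25 kb mask handles the bait-proximal regime instead. With window > 1,
windows slide over consecutive *mappable* fragments, so a window may span
the masked gap; at the default window 1 this has no effect.

The seed is part of the configuration; multi-bait calling consumes one
seeded stream per-bait in bait-table order, per-permutation within a bait,
making every run byte-reproducible.

# The synthetic generator

`sim_config()` / `simulate_genome()` / `simulate_pairs()` emulate a
multi-locus capture design: by default two 1 Mb chromosomes with
exponentially spaced cut sites (mean 4096 bp, ≈ 244 sites/Mb — about 500
sites over 2 Mb, the scale of a multi-locus capture panel), three target
loci of 17, 12 and 10 consecutive sites (the sizes of realistic small and
mid LD-block loci; 10 is the smallest locus the design supports), and
100,000 read pairs. On-target pairs anchor in a bait chosen proportionally
to a log-normal capture-efficiency factor (log-SD 0.5); the cis partner
fragment is drawn with weight `length * (distance + 1 kb)^-1` — the
canonical inverse-distance polymer-ligation decay with a 1 kb stabilizer —
and planted (bait, fragment) pairs receive a multiplicative fold weight.
Ten percent of on-target pairs are trans (uniform on other chromosomes),
half of all pairs are off-target, and each emitted pair is duplicated with
probability 0.05.

Two generator properties matter for testing. First, off-target ends are
rejection-sampled away from bait-proximal windows, so the generated
category of every pair is exactly what the classifier will assign; without
this, ~1% of "off-target" ends would land in bait flanks by chance and the
recovered trans fraction would drift from its configured value. Second,
the generator reports its emitted-duplicate count by applying the
pipeline's own canonical-tuple definition to the final table, so chance
coordinate collisions between independent pairs cannot break the exact
duplicate-accounting identity.

An optional library-specific component (`clonal_rate`, default off) seeds
clonal amplification clusters: extra copies of a pair with coordinates
jittered by up to 5 bp, which exact-coordinate deduplication cannot
collapse. This models the PCR-jackpot artifacts that motivate min-count
filtering in replicate comparisons.

What the generator does **not** model: read-level sequence (no FASTQ, no
sequencing error), mappability gaps, TAD-structured block contacts,
GC/fragment-length capture biases beyond the per-probe factor, and
inter-chromosomal distance structure. Passing tests therefore demonstrate
the pipeline's correctness under a clean polymer-decay contact model, not
robustness to every artifact of real libraries.

# Validation experiments and their sizes

The test suite runs every stage against independent oracles (naive
sliding-window motif scans, brute-force nearest-site and all-pairs overlap
scans, normal-equation least squares, a loop-based reimplementation of the
permutation threshold fed the same permutation matrix). The heavier
calibration experiments use these problem sizes, chosen to give stable
Monte-Carlo estimates at desk scale:

* **FDR control** — 20 null baits, 50,000 reads over 500 fragments each,
  1000 permutations: the mean called fraction must stay within twice the
  nominal FDR of 0.01.
* **Planted-peak recovery** — 50 seeded simulations on a 600 kb
  chromosome (mean spacing 16 kb, one 10-site locus, 160,000 pairs,
  efficiency variation and off-target/trans/duplicate rates disabled) so
  that the tested bait's unmasked profile reaches a mean depth of at least
  100 reads/fragment deterministically. The 8-fold enrichment is planted
  at a representative-length fragment 50–150 kb from the bait: the local
  null of a few-hundred-bp fragment is so small that even an 8-fold
  enrichment of it stays below any uniform-null threshold, so tiny
  fragments cannot carry this experiment by construction. Probe filtering
  is not applied: the experiment measures caller power on a given profile,
  and significance operates on raw per-bait counts.
* **Generator fidelity** — one default-design library of 100,000 pairs:
  recovered trans fraction within 3 binomial SD of the configured 0.10;
  log–log distance-decay slope within ±0.3 of −1. The decay measurement
  takes one distance per cis pair (a pair anchored at both ends would
  otherwise contribute its short within-locus distance twice and steepen
  the fit).
* **Replicate reproducibility** — 100 paired libraries sharing genome,
  efficiency factors and truth, on an 8 Mb + 2 Mb genome with the clonal
  component enabled (rate 0.02, mean cluster 5).

# A known negative result: min-count filtering and Pearson r

Replicate agreement in this assay is conventionally summarized by Pearson
correlation over fragments with at least 1 (or at least 3) reads in both
libraries, with the expectation that the stricter filter *raises* the
correlation. Under this package's replicate model — two libraries Poisson-
resampled from a shared contact intensity — the opposite happens,
consistently and for a structural reason: the extra cells admitted at
min-count 1 have tiny intensities and form a tight blob at the low end of
the dynamic range. A tight blob at one extreme *anchors* the regression
and inflates raw Pearson r, while the min-count-3 filter truncates
genuinely correlated dynamic range; so r(min 3) lands slightly below
r(min 1) at every depth, masked or unmasked, with or without a moderate
clonal-artifact component. For the stricter filter to help, the low-count
cells must be dominated by *discordant* library-specific artifacts — tens
of reads in one library against near-zero in the other — and real
libraries evidently contain such artifacts at magnitudes this generator
deliberately does not fabricate. The corresponding acceptance check is
therefore expected to fail under the synthetic model, and the package
documents rather than hides this: it is a statement about what min-count
filtering does and does not buy on clean data.

# Integrative analyses

* **3C-qPCR** uses the ΔΔCt method: the ligation ratio of a primer pair is
  `E^-(mean Ct_3C − mean Ct_control)` against a randomly ligated control
  library, normalized by the same ratio for an adjacent-fragment reference
  pair. PCR efficiency defaults to `E = 2` (perfect doubling),
  configurable. Replicate scatter propagates to a standard error by the
  delta method on the mean Cts.
* **eQTL regression** is ordinary least squares of expression (RPKM) on
  additive genotype dosage (0/1/2) with a two-sided t test at n − 2
  degrees of freedom; no covariates, matching the method's plain design.
  Benjamini–Hochberg-adjusted values are reported as a labeled extra
  column, never replacing raw p-values. A perfect fit saturates at the
  smallest representable double rather than reporting zero.
* **Motif allele scoring** scans a position weight matrix over every
  window covering the SNP on both strands, takes each allele's maximum
  log2-odds score against the background, and reports the difference —
  the standard maximum-affinity disruption convention. The matrix is
  user-supplied (JASPAR text), since the relevant binding model depends
  on the factor under study.
* **Overlap annotation** uses any-overlap (≥ 1 bp, half-open) semantics
  against named interval tracks, preserving feature order.

# Numerical and degenerate-input choices

Empty sequence digests to an empty site list; an undigested chromosome is
one fragment; a cut site at coordinate 0 drops its empty leading fragment.
Probes with zero totals that survive the percentile filter are removed
with a warning before factors are computed; if every probe is removed,
normalization refuses to proceed. Profiles with fewer than 2 mappable
fragments or zero reads are significance errors, not silent skips.
Constant expression returns slope 0 with p = 1; a monomorphic genotype is
an error. Exclusion radius 0 masks exactly the fragment starting at the
bait's cut site. All tie-breaks (probe-filter ranking, anchor-side
assignment) are deterministic and documented at the function level.

# A worked pipeline run

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 7, n_pairs = 2e4)
genome <- simulate_genome(cfg)
library3c <- simulate_pairs(genome, cfg)

report <- run_pipeline(library3c$pairs, genome$map, genome$baits,
                       genome$loci, pipeline_config(seed = 7))
glance(report$calls)      # per-bait thresholds
report$significant        # called bait-fragment interactions
plot_contact_profile(report$calls, report$significant$bait[1])
```

# Limitations

The caller's uniform null is conservative far from the bait and relies on
the ±25 kb mask near it; a distance-decay-aware background (as in
dedicated capture-Hi-C callers) would gain power at intermediate ranges
but is out of scope here, as is trans-interaction calling, multi-enzyme
digestion, and ICE-style matrix balancing. The eQTL module fits marginal
per-SNP models without population-structure covariates. The generator's
clean contact model is a tool for verifying the pipeline, not a simulator
of every failure mode of real proximity-ligation libraries.
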