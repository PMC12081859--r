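---
title: "Methods: base-pair CTCF footprinting and loop-extrusion estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: base-pair CTCF footprinting and loop-extrusion estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The assay and the data model

MNase-based proximity ligation (MNase HiChIP, Micro-C, RCMC) digests
chromatin with micrococcal nuclease, which degrades DNA not protected by a
bound protein. Each read pair records one ligation event between two
protected digestion fragments. With the per-side 5'/3' mapped-end columns
(`pos5`, `pos3`, `read_len`) present in the pairs file, both fragments can
be reconstructed exactly: the fragment start is the smaller of the two
mapped ends, the fragment end the larger, so the fragment length is
`|pos3 - pos5| + 1`. Fragments longer than the read cannot be measured —
with 150 bp reads the observed length saturates at 150 and the fragment is
flagged *censored*. A ligation junction that falls inside the read leaves
roughly 25 aligned bp on each side, so pairs whose longer fragment is at
most 125 bp are treated as *observed ligations*: both fragment lengths are
known exactly. All binding-site scanning uses only these pairs.

Coordinates: pairs positions are 1-based (the 4DN convention); every
interval held internally (fragments, motifs, BED input) is 0-based
half-open. Point quantities — read 5' ends, scan positions, peak centers —
are reported 1-based, consistent with the pairs convention.

# The quadrant statistic

Protein binding confines MNase cuts to the protein's margins. At a bound
CTCF site the read 5' ends therefore pile up just upstream of the motif on
the + strand and just downstream on the − strand. Around a candidate
position we partition read 5' ends within a 75 bp half-window into four
quadrants — Q1 downstream/+, Q2 upstream/+, Q3 upstream/−, Q4
downstream/− (a 5' end exactly at the candidate counts as upstream) — and
summarize enrichment with

$$\hat\alpha = \frac{\min(n_2, n_4)}{\max(n_1, n_3)}.$$

The min/max construction requires *both* signature quadrants to exceed
*both* off-pattern quadrants, so a one-sided pile-up (a common artifact)
does not score. $\hat\alpha$ is capped at 32 (the top of the evaluation
grid); a zero numerator gives 0.

**Empirical null.** Without binding, each read falls in any quadrant with
probability 1/4. For every total count $N$ from 5 to 500 we draw $10^6$
multinomial samples (the count is configurable), compute
$\log_2\hat\alpha$, and tabulate tail probabilities on a grid from 0 to 5
in steps of 0.01. Observed statistics are converted to nominal p-values by
looking up the grid point at or below the observed value — a conservative
rounding — with totals above 500 binned at 500, totals below 5 deemed
untestable, and p-values floored at the table resolution ($1/n_{samples}$,
so a $10^6$-sample table resolves the $10^{-5}$ decision threshold with
an order of magnitude to spare). Because only the four counts are needed,
scanning is a table lookup per position.

**Scanning and peaks.** By default every bp within 150 bp of a supplied
motif is scored (a genome-wide per-bp scan is the same computation on a
denser position set). Positions with $p < 10^{-5}$ — the threshold at
which the precision/recall analysis yields about 5% FDR — are merged into
peaks while gaps are at most 20 bp; the peak center is the position with
maximal $\hat\alpha$, ties broken by larger total count, then smaller
coordinate. The merge rule and tie-breaks are package decisions: any
reasonable grouping gives the same centers on clean signal, and the
tie-break makes output deterministic.

# Single-molecule footprint classification

Fragments overlapping a 35 bp CTCF motif are expressed in motif-oriented
coordinates (0 = oriented motif start; − strand motifs are reflected).
Three rules, all from fragment geometry:

* `protein_class`: length ≥ 120 bp → `nucleosome`; shorter → `tf`.
* `motif_span` (TF only): the motif holds a 19 bp core module preceded by
  a 10 bp upstream module. Oriented starts near 0 protect
  core + upstream; starts near 10 protect the core alone. The split is at
  the upstream-module midpoint (`rel_start <= 5`), a deterministic
  boundary between the two observed start modes. The module offsets
  (upstream `[0,10)`, core `[10,29)`) are configurable; their placement
  inside the motif is a documented assumption, only the lengths being
  established.
* `cohesin_extended` (TF only): oriented fragment end at least 48 bp from
  the motif start, i.e. protection extending well past the motif —
  the cohesin-docking signature.

The margin filter used by the extrusion analyses ("start and end at least
5 bp from motif start and end") admits two readings; the default requires
the fragment to begin at least 5 bp *outside* the oriented motif start and
end at least 5 bp past its end (`rel_start <= -5` and `rel_end >= 40`),
with the weaker `|rel_start| >= 5` reading selectable
(`margin_mode = "distance"`). Aggregate footprint structure is summarized
by a bivariate normal kernel density over (oriented start, oriented end),
computed with `MASS::kde2d`; the default kernel sd is 2 bp per axis
(floored at 0.5 bp) — footprint edges are few-bp features and the data are
integers, so sub-bp bandwidths would just reproduce the integer lattice.

# Loop-extrusion estimators

For a + strand binding site, *left* fragments of long-range pairs are its
anchored contacts and "downstream" means increasing coordinates; both are
mirrored for − strand sites. The qualifying set for extrusion estimates
applies four filters: TF-scale length (< 120 bp), boundary margins (above),
extended fragment end (≥ 48 bp), and interaction length > 10 kb
(midpoint-to-midpoint; the anchor point is not fixed by convention
elsewhere, and midpoints are symmetric under strand flips).

* **Fully-extruded fraction.** Per site with at least 50 qualifying
  fragments, the share of partners overlapping a downstream convergent
  (opposite-strand) motif; any downstream convergent motif counts by
  default, with a nearest-only mode and an overlap slack window available.
  Because the estimate conditions on CTCF occupying the anchor, it is
  multiplied by the assumed occupancy (0.5, i.e. halved) to give the
  unconditional rate. The genome-wide summary reports the mean, the
  pooled estimate, and a nearest-rank 1st–99th percentile range.
  Trans pairs, which cannot arise from extrusion, provide the
  random-ligation background for the convergent-overlap rate.
* **Extruded loop size.** The mean $\log_{10}$ interaction length of
  qualifying fragments (equivalently the geometric mean in bp), optionally
  after excluding convergent contacts. Chromatin context comes from a
  ChromHMM-style segmentation collapsed to three categories (active,
  polycomb/bivalent, quiescent) over the 1 Mb motif-oriented downstream
  window — the DNA a cohesin anchored at the site would extrude through —
  and each category is represented by the top 20% of sites by category
  fraction (nearest-rank; ceiling of qN, ties by site id).
* **Cohesin effect.** `log10(length) ~ class + (1 | site)` fitted by REML
  with `lme4`, estimating the shift in interaction length for
  cohesin-extended TF fragments against nucleosome fragments at the same
  sites while absorbing locus-level baselines in a random intercept. In a
  balanced design the fixed effect equals the mean within-site class
  difference, which the tests use as a closed-form oracle.

# The synthetic pairs generator

The generator emits pairs records with full ground truth (per-motif
occupancy draws, per-fragment class, per-pair loop status) and exists so
every stage can be benchmarked without external data. Its defaults are the
study conditions used by the tests:

* **Occupancy.** Occupied motifs bind CTCF on 50% of molecules; decoys
  never bind. Bound molecules carry one of three footprints: core only
  (`[10, 29)`), core + upstream (`[0, 35)`), or CTCF + cohesin
  (`[-8, 52)`) with default mixture 0.3 / 0.4 / 0.3. The cohesin
  footprint's upstream edge sits 8 bp before the motif and its end ~17 bp
  past it: the protected region must clear the 5 bp margin and the 48 bp
  extended-end threshold the classifiers use, which is exactly what the
  real cohesin-bearing fragments that survive those filters do.
* **Unbound molecules** carry a 147 bp nucleosome drawn from a phased
  array (offsets −145/0/+145 bp, weights 0.4/0.2/0.4) or unstructured
  cuts (uniform 60–140 bp fragments within ±250 bp). The array reproduces
  the motif dip + flanking peaks of nucleosome-sized coverage around
  binding sites.
* **Noise.** Fragment boundaries get rounded Gaussian jitter (sd 2 bp
  default) and optional one-sided geometric over-trimming (off by
  default); MNase digestion noise is not characterized in detail anywhere,
  and a few-bp Gaussian spread is the simplest model reproducing observed
  footprint-edge widths.
* **Contacts.** Interaction lengths mix a truncated power law (exponent
  −1 on 0.5 kb–1 Mb, generic contact-decay background) with a log-normal
  loop component. A long-range contact extruding downstream of the
  oriented anchor is captured at a downstream convergent motif with
  probability `spike_prob` — the injected fully-extruded probability, and
  by construction the quantity the per-site estimator measures. The
  captured partner shows plain full-motif protection rather than a
  cohesin-extended end: most real fully-extruded ligations carry the
  cohesin signature on the extruding side only, and the far anchor is
  often an adjacent non-TF fragment.
* **Censoring.** Read 5'/3' ends follow from fragment boundaries and a
  random read strand; fragments longer than the read length are truncated
  exactly as in real data.

What the generator does *not* emulate: sequencing error, mappability and
duplicate structure, ChIP enrichment bias, cell-to-cell occupancy
correlation, and fine-scale digestion sequence bias. Passing benchmarks
therefore demonstrate correctness and calibration of the estimators under
the stated generative model, not performance on any particular real
library.

# Problem sizes and numerical choices

The package's benchmark (`detection_benchmark()`) uses 1,000 occupied
motifs and 1,000 decoys spaced 3 kb on a ~6.1 Mb synthetic chromosome,
800 pairs per motif (over 300 observed-ligation fragments per occupied
site), and a 1e6-sample null table over totals 5–500 — about 0.5 bn
multinomial draws, a few minutes of compute. Calibration tests scan
~200k positions spaced one full window (151 bp) apart on protein-free
pairs so neighbouring tests share no reads. Estimator-recovery tests use
440 fully-occupied sites spaced 20 kb with a 12% injected
convergent-capture probability, and 200 simulated sites for the
mixed-model check. The tests treat Monte-Carlo tolerances explicitly:
enumeration oracles to 3 standard errors, binomial recovery to 3 standard
errors plus a computed allowance for chance partner–motif overlap.

Degenerate inputs: zero-extent fragments (`pos5 == pos3`) are flagged and
excluded; positions with fewer than 5 reads are reported untested rather
than given a p-value; empty peak sets propagate as empty tables; an
all-identical footprint cloud gets a floored kernel bandwidth instead of a
collapsed density.

# Known limitations

* The null table is exchangeable-multinomial: local coverage structure
  that violates read exchangeability (e.g. unremoved duplicates) is not
  modelled; the p-values are nominal, and no multiple-testing correction
  is applied beyond the fixed threshold.
* The fully-extruded estimator conditions on one CTCF-anchored end and
  cannot see loops anchored by neither motif; the occupancy adjustment is
  a single scalar.
* Interaction lengths use fragment midpoints; other anchor conventions
  shift P(s) curves by a fragment-scale constant.
* With motif-guided scanning, binding sites farther than 150 bp from any
  supplied motif are invisible; use the dense position mode when motif
  annotation is in doubt.
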