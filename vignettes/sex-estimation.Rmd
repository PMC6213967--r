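---
title: "Sex estimation from methylation array distributions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex estimation from methylation array distributions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylsex)
```

## The model

Each probe on a methylation array yields a beta-value
β = M / (M + U + offset) in [0, 1] (`compute_beta()`, offset default 100,
the conventional stabiliser for Illumina intensities) and a detection
p-value measuring signal confidence against background. `methylsex` never
models individual probes. It classifies samples by the *shape* of the
per-chromosome value distributions, summarised as proportion vectors over
fixed bins:

* chrX beta-values: females carry substantial intermediate mass
  (X-inactivation methylates one X copy, so probes average the active and
  inactive alleles), males are bimodal like autosomes;
* chrY beta-values and detection p-values: present chrY behaves like an
  autosome with small p-values; absent chrY yields background-only
  signal — diffuse beta-values and large p-values.

For one sex chromosome, a sample's feature vector is the concatenation of
its beta-bin proportions and detection-p-bin proportions. Test feature
vectors are stacked with those of a labelled reference panel, columns are
mean-centred, and PCA is run per chromosome (PCA.X, PCA.Y); k-means with
k = 2 on the component scores splits the joint set, each cluster takes
the sex of the majority of its reference members, and every test sample
inherits the sex of its cluster. The final call combines the two
chromosomes: (f, f) → F, (m, m) → M, any conflict → N. An N-call is the
method's deliberate refusal to force a binary answer: female-like chrX
with male-like chrY is the XXY (Klinefelter) signature, the mirror image
is the X0 (Turner) signature, and either can also indicate a mosaic.
The method cannot distinguish a true XXY from an XX/XY mosaic — both
produce the same distributional signature — and does not attempt to.

Working on distributions has two practical consequences. First, raw idat
files and normalisation are unnecessary: per-site variation barely moves
the binned proportions. Second, because clustering is anchored by the
reference panel, a test cohort composed entirely of one sex is still
classified correctly — the opposite-sex cluster is populated by the
references.

## Assumptions

* At least one chrX and one chrY probe must be shared between the value
  matrices and the manifest; when platforms differ (e.g. EPIC data
  against an HM450k-derived panel) the probe intersection is used and
  the dropped count reported.
* The reference panel must separate cleanly: if either k-means cluster
  contains no reference sample the estimation stops with an error, and if
  a cluster's reference members are less than 90% one sex every call from
  that axis carries a warning. The 90% figure is a plumbing guard, not a
  biological constant.
* Proportions, not counts, are compared, so chrX and chrY may have very
  different probe numbers.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| beta bins | 10 of width 0.1 | estimation-time beta resolution; wider bins smooth small distribution shifts |
| detection-p edges | 0, 10⁻⁵, 10⁻², 1 | detected / marginal / undetected probes |
| fine panel bins | 100 beta, 18 detp decades | storage resolution of panels; any requested scheme whose edges lie on these can be served exactly |
| `offset` in `compute_beta()` | 100 | intensity-scale stabiliser (signal units) |
| QC `p_cutoff`, `max_fail_frac` | 0.01, 0.05 | a sample fails when **more than** 5% of chrX probes have p ≥ 0.01; missing p-values count as failures since they convey no confidence |
| `retention_fraction` | 0.875 | fraction of each concordant reference group kept, nearest to the cluster centres |
| `seed` | 1 | drives the k-means restarts (chrX axis uses `seed`, chrY `seed + 1`); simulation seeds live in `sim_config()` |

Samples failing QC are flagged but never dropped by `estimate_sex()`;
exclusion is an explicit user (or CLI `--drop-qc-failures`) decision,
because a borderline sample's call is often still informative.

Occasionally a sample with a slightly shifted but otherwise typical
distribution is called N at the default resolution; re-estimating at
wider beta bins (e.g. `bin_scheme(beta_edges = seq(0, 1, 0.2))`) smooths
such shifts. No automatic re-estimation is performed — the user rebins
explicitly and compares.

## Binning conventions and numerical choices

* Intervals are left-open/right-closed, (e₁, e₂], …, matching the usual
  description "0 < β ≤ 0.1"; the first interval additionally contains its
  lower edge so β = 0 is never lost, and every proportion vector sums to
  1 exactly (verified to 10⁻⁹ in the tests).
* Missing values are excluded per metric before binning — a probe with a
  missing beta but a valid detection p still contributes to the p
  profile. A sample × chromosome with zero usable probes is an error,
  never a silent zero vector.
* Re-binning a fine panel is exact bin-union arithmetic: coarse
  proportions are sums of contained fine proportions, so they equal
  direct binning of the raw values at the coarse scheme (a tested
  invariant). Requested edges must coincide with fine edges; alignment is
  checked per edge against the nearest fine edge with relative tolerance
  10⁻⁹ (decade p-value edges are far below any workable absolute
  tolerance), and a misaligned edge is an error naming the edge — no
  interpolation, ever.
* PCA mean-centres but does not variance-scale: all features are
  proportions on a common scale, and scaling would inflate near-constant
  bins. All components with non-negligible variance are retained and
  k-means runs on the full score matrix — a rotation of the centred
  feature space — with 25 restarts under the given seed; `pc1_only = TRUE`
  reproduces clustering on the first component alone. Cluster indices are
  arbitrary, so sex is always derived from reference majorities and
  clusters are relabelled (1 = female-majority); PC1 signs are oriented
  so female references average negative, making plots comparable across
  runs.

## The reference panel

`build_reference()` curates a labelled cohort: per-chromosome
PCA + k-means on the fine profiles, keep samples concordant on both axes
(in the cluster holding the majority of their own label on chrX *and*
chrY), then within each concordant group keep the
⌊`retention_fraction` · n⌋ samples closest to their cluster centres,
measured as the Euclidean distance in the product of the two axes'
clustering spaces, √(d²ₓ + d²ᵧ). Trimming the periphery removes samples
whose profiles are least typical of their sex before they become anchors.
The default 0.875 reflects the retention behaviour this family of methods
exhibits on large curated cohorts (≈ 87–88% of concordant samples).
The 2 × 4 label-by-cluster concordance table is returned with the panel.

Panels are serialised as an inspectable, diff-able tab-separated bundle
(`panel_meta.tsv` + one samples × bins table per chromosome and metric),
not as opaque binaries. `default_reference()` builds the package's
default panel — from the synthetic generator, deterministically under a
seed — because a real curated panel is data, not method; users with
labelled cohorts should build their own.

## What the synthetic generator does and does not emulate

`simulate_cohort()` draws beta-values from three-component Beta mixtures
(low/intermediate/high methylation; weights 0.46/0.08/0.46 for a present
chromosome, 0.25/0.50/0.25 for a female-pattern chrX at the default
`female_intermediate_weight = 0.5`, a single diffuse Beta(2, 2) for an
absent chromosome) plus Gaussian noise (sd 0.02) clamped to [0, 1], and
detection p-values on the log10 scale from a detected/background
two-component model (97% detected at log₁₀p ~ N(−12, 3) for present
chromosomes; 7% for absent ones, background near 10⁻¹). These values
were chosen once to reproduce the qualitative distribution shapes that
motivate the method — trimodal female chrX, bimodal male chrX,
near-degenerate small male chrY p-values, large female chrY p-values —
not fitted to any dataset. Probe counts default to 1000 chrX, 400 chrY
and 2000 autosomal probes; autosomes carry no signal and exist to
exercise manifest filtering realistically.

The generator deliberately ignores probe-level biology: type I/II
chemistry, cross-reactive probes, batch and tissue effects, and
probe-specific methylation states. Probes are i.i.d. within a
chromosome class. Passing tests therefore demonstrate that the
*algorithm* recovers the distributional signatures it targets, with
clean margins; they do not demonstrate performance on real arrays, where
the signatures are the same in kind but noisier, and where the published
evidence for this family of methods lives. Lowering
`female_intermediate_weight` towards the male value (0.08) collapses the
chrX separation continuously; the test suite drives it to the collapse
point and verifies the failure is an explicit low-purity warning or
did-not-separate error, never a silent wrong answer.

## Problem sizes

The test suite and acceptance script use a 100 XX + 100 XY simulated
cohort for reference building and disjoint cohorts of 100–120 samples
(including 10 XXY and 10 X0) for estimation — sizes at which the
end-to-end run takes seconds while keeping ≥ 10 samples in every
karyotype group. k-means uses 25 restarts throughout.

## Known limitations

* Calls are relative to the reference panel; a panel built from one
  platform classifies another only through the shared probe set.
* N-calls flag, but cannot type, abnormalities: XXY vs XX/XY mosaicism is
  indistinguishable here, and mosaic fraction is not quantified.
* Signal-intensity-based estimation (median chrX/chrY intensity cut-offs)
  is out of scope, as are idat parsing, GEO retrieval and normalisation.
* The default panel is synthetic. It makes the package self-contained
  and its tests hermetic, but real deployments should build a panel from
  a labelled cohort of the target platform.
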