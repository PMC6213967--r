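# methylsex

Sex inference and sex-chromosome abnormality detection for DNA-methylation
microarray data (Illumina HM450k / EPIC-style matrices).

## The problem

Sex is one of the strongest influences on the genomic distribution of DNA
methylation, and public methylation datasets routinely contain mislabelled
samples, as well as samples with atypical sex-chromosome arrangements
(Klinefelter XXY, Turner X0). Intensity-based sex checks force a binary
male/female answer and silently misplace exactly those atypical samples.
`methylsex` is aimed at anyone doing QC on methylation array cohorts —
especially cohorts assembled from public repositories where raw idat files
are unavailable and only beta-value and detection p-value matrices exist.

## The method

Two biological facts give each sex chromosome its own signature in a
sample's *distribution* of values, regardless of tissue:

* **chrX** — in females, X-inactivation methylates one of the two X
  copies, so many chrX probes average to intermediate beta-values
  (β ≈ 0.5). Males show the usual bimodal distribution (β near 0 or 1).
* **chrY** — in samples without a Y, chrY probes measure background only:
  detection p-values are large and beta-values are diffuse.

For each sample, the proportions of chrX and chrY probes falling into
beta-value bins (default: 10 bins of width 0.1) and detection p-value bins
(default: p ≤ 10⁻⁵, 10⁻⁵ < p ≤ 0.01, 0.01 < p ≤ 1) are computed. The
combined beta + detection-p profiles of each chromosome, concatenated with
the corresponding profiles of a curated male/female **reference panel**,
are mean-centred and submitted to PCA (PCA.X and PCA.Y), followed by
k-means clustering (k = 2) on the component scores. Each test sample is
assigned the sex of the reference samples it clusters with, per
chromosome, and the final call is

* **F** if chrX and chrY both say female,
* **M** if both say male,
* **N** if they conflict — a candidate mislabel, mosaic, or aneuploidy.
  Female-like chrX with male-like chrY is the Klinefelter (XXY) signature;
  male-like chrX with female-like chrY is the Turner (X0) signature.

Anchoring the clustering on the reference panel makes the calls valid even
for test cohorts consisting of a single sex. Reference panels are stored
as fine proportion tables (100 beta bins, 18 detection-p decade bins) and
re-binned exactly — by summing contained fine bins — to whatever scheme
the user requests. Working with distributions rather than raw intensities
means no idat files and no normalisation are needed.

A detection-p QC filter flags samples with detection p ≥ 0.01 at more
than 5% of chrX probes; flags are attached to every call but never drop a
sample silently.

The package also ships a synthetic cohort generator
(`simulate_cohort()`) for the XX, XY, XXY and X0 karyotypes which
reproduces these distributional signatures with known truth, so the whole
pipeline is testable without downloading anything.

## Worked example

```r
library(methylsex)

# a reference panel (synthetic, deterministic; or build_reference() on
# your own labelled cohort)
panel <- default_reference(seed = 101)

# a small cohort with known karyotypes: 5 XX, 5 XY, one XXY, one X0
cohort <- simulate_cohort(sim_config(n_XX = 5, n_XY = 5,
                                     n_XXY = 1, n_X0 = 1, seed = 202))
calls <- estimate_sex(cohort$matrix, cohort$annot, panel, seed = 303)
summary(calls)
#> Sex estimation of 12 samples
#>   F: 5   M: 5   N: 2
#>   QC failures: 0
#>   reference cluster purity  chrX: 1.000/1.000  chrY: 1.000/1.000
#>   N-samples (conflicting chrX/chrY): XXY_001, X0_001

as.data.frame(calls)[c(1, 6, 11, 12), 1:6]
#>    sample_id predicted sex_chrX sex_chrY  X.PC1  Y.PC1
#> 1     XX_001         F        f        f -0.156 -0.690
#> 6     XY_001         M        m        m  0.159  0.684
#> 11   XXY_001         N        f        m -0.159  0.683
#> 12    X0_001         N        m        f  0.158 -0.689
```

All five XX samples are called F and all five XY samples M. The XXY
sample lands with the females on the chrX axis (negative X.PC1) but with
the males on the chrY axis (positive Y.PC1) — the Klinefelter signature —
and the X0 sample shows the mirror-image Turner signature; both are
flagged N rather than forced into a binary call. `plot(calls)` draws the
X.PC1/Y.PC1 scatter with the reference underlay;
`plot_sex_distribution()` draws a sample's binned distributions against
the reference envelopes; `detect_label_mismatch()` compares calls with
recorded labels, reporting discordant samples and N-samples separately.

A command-line interface wrapping these functions (subcommands
`simulate`, `build-ref`, `qc`, `estimate`, `plot`) is installed at
`system.file("cli/methylsex.R", package = "methylsex")`.

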