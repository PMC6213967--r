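#' Configuration for the synthetic methylation cohort generator
#'
#' The generator emulates the sex-specific distributional structure that
#' sex estimation exploits, for the four karyotypes of interest:
#'
#' * a chromosome *present* in the karyotype in active copies (male chrX,
#'   any chrY that exists, autosomes) yields the usual bimodal beta-value
#'   distribution (most probes near 0 or 1) and small detection p-values;
#' * a female-pattern chrX (XX and XXY) carries substantial intermediate
#'   beta-value mass — one X is largely inactivated by methylation, so many
#'   probes average to ~0.5 across the two copies;
#' * a chromosome *absent* from the karyotype (chrY in XX and X0) yields
#'   diffuse, noise-like beta-values and large detection p-values, because
#'   its probes measure background only.
#'
#' Beta-values are drawn from three-component Beta mixtures
#' (low/intermediate/high methylation) plus bounded Gaussian noise clamped
#' to `[0, 1]`; detection p-values are generated on the log10 scale from a
#' detected/undetected two-component model.
#'
#' @param n_XX,n_XY,n_XXY,n_X0 Number of samples of each karyotype.
#' @param n_probes_chrX,n_probes_chrY,n_probes_autosome Probe counts per
#'   chromosome class; defaults 1000/400/2000.
#' @param female_intermediate_weight Mixture weight of the intermediate
#'   beta component on a female-pattern chrX; default 0.5. Lowering it
#'   towards the male value (0.08) shrinks the separation between sexes.
#' @param noise_sd Standard deviation of the additive beta-value noise;
#'   default 0.02.
#' @param missing_rate Fraction of entries independently set to `NA` in
#'   each matrix; default 0.
#' @param seed Integer seed; cohorts are bit-reproducible given the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_XX = 0L, n_XY = 0L, n_XXY = 0L, n_X0 = 0L,
                       n_probes_chrX = 1000L, n_probes_chrY = 400L,
                       n_probes_autosome = 2000L,
                       female_intermediate_weight = 0.5,
                       noise_sd = 0.02, missing_rate = 0, seed = 1L) {
  counts <- c(XX = n_XX, XY = n_XY, XXY = n_XXY, X0 = n_X0)
  if (any(counts < 0L)) stop("karyotype counts must be non-negative")
  if (sum(counts) == 0L) stop("at least one sample is required")
  if (n_probes_chrX < 1L || n_probes_chrY < 1L)
    stop("at least one probe per sex chromosome is required")
  if (female_intermediate_weight < 0 || female_intermediate_weight > 1)
    stop("female_intermediate_weight must be in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  w <- female_intermediate_weight
  structure(list(
    counts = counts,
    n_probes = c(chrX = n_probes_chrX, chrY = n_probes_chrY,
                 autosome = n_probes_autosome),
    # beta mixture components: shape pairs for low/mid/high methylation
    beta_shapes = list(low = c(1.5, 18), mid = c(12, 12), high = c(18, 1.5)),
    beta_weights = list(
      present = c(low = 0.46, mid = 0.08, high = 0.46),
      xci = c(low = (1 - w) / 2, mid = w, high = (1 - w) / 2),
      absent = NULL),           # absent: single diffuse Beta(2, 2)
    # detection-p model: log10 p ~ Normal, mixed over detected/background
    detp_model = list(
      present = list(p_detected = 0.97, detected = c(-12, 3),
                     background = c(-1.2, 0.8)),
      absent = list(p_detected = 0.07, detected = c(-12, 3),
                    background = c(-0.8, 0.6))),
    noise_sd = noise_sd, missing_rate = missing_rate,
    seed = as.integer(seed)),
    class = "sim_config")
}

# chromosome pattern per karyotype: present / xci / absent
karyotype_pattern <- function(karyotype) {
  switch(karyotype,
         XX = c(chrX = "xci", chrY = "absent"),
         XY = c(chrX = "present", chrY = "present"),
         XXY = c(chrX = "xci", chrY = "present"),
         X0 = c(chrX = "present", chrY = "absent"),
         stop("unknown karyotype ", karyotype))
}

#' Simulate a methylation cohort with known karyotypes
#'
#' Draws probe-by-sample beta-value and detection p-value matrices under
#' the generative model described in [sim_config()], together with a probe
#' manifest and per-sample truth (karyotype and the sex call it should
#' produce: XX is F, XY is M, XXY and X0 are N).
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `matrix`
#'   (a [methylation_matrix()]), `annot` (a [probe_annotation()]) and
#'   `truth` (data.frame `sample_id`, `karyotype`, `expected_call`).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_XX = 3, n_XY = 3, seed = 7))
#' cohort$truth
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  karyos <- rep(names(config$counts), config$counts)
  n_samp <- length(karyos)
  sample_ids <- sprintf("%s_%03d", karyos, stats::ave(seq_len(n_samp),
                                                      karyos, FUN = seq_along))
  np <- config$n_probes
  probe_ids <- c(sprintf("cgX%05d", seq_len(np["chrX"])),
                 sprintf("cgY%05d", seq_len(np["chrY"])),
                 sprintf("cgA%05d", seq_len(np["autosome"])))
  chrom <- rep(c("chrX", "chrY", "autosome"), np[c("chrX", "chrY", "autosome")])
  annot <- probe_annotation(probe_ids, chrom)

  beta <- matrix(NA_real_, nrow = length(probe_ids), ncol = n_samp,
                 dimnames = list(probe_ids, sample_ids))
  detp <- beta

  blocks <- split(seq_along(probe_ids), chrom)
  for (j in seq_len(n_samp)) {
    pat <- c(karyotype_pattern(karyos[j]), autosome = "present")
    for (cn in c("chrX", "chrY", "autosome")) {
      idx <- blocks[[cn]]
      cls <- pat[[cn]]
      beta[idx, j] <- draw_beta(length(idx), cls, config)
      detp[idx, j] <- draw_detp(length(idx), cls, config)
    }
  }
  if (config$missing_rate > 0) {
    beta[stats::runif(length(beta)) < config$missing_rate] <- NA_real_
    detp[stats::runif(length(detp)) < config$missing_rate] <- NA_real_
  }
  truth <- data.frame(
    sample_id = sample_ids,
    karyotype = karyos,
    expected_call = c(XX = "F", XY = "M", XXY = "N", X0 = "N")[karyos],
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  structure(list(matrix = methylation_matrix(beta, detp),
                 annot = annot, truth = truth, config = config),
            class = "sim_cohort")
}

draw_beta <- function(n, cls, config) {
  if (cls == "absent") {
    b <- stats::rbeta(n, 2, 2)
  } else {
    w <- config$beta_weights[[cls]]
    comp <- sample.int(3L, n, replace = TRUE, prob = w)
    sh <- config$beta_shapes
    b <- numeric(n)
    for (k in 1:3) {
      sel <- comp == k
      if (any(sel)) b[sel] <- stats::rbeta(sum(sel), sh[[k]][1L], sh[[k]][2L])
    }
  }
  if (config$noise_sd > 0) b <- b + stats::rnorm(n, 0, config$noise_sd)
  pmin(1, pmax(0, b))
}

draw_detp <- function(n, cls, config) {
  mod <- config$detp_model[[if (cls == "absent") "absent" else "present"]]
  detected <- stats::runif(n) < mod$p_detected
  logp <- numeric(n)
  logp[detected] <- stats::rnorm(sum(detected), mod$detected[1L],
                                 mod$detected[2L])
  logp[!detected] <- stats::rnorm(sum(!detected), mod$background[1L],
                                  mod$background[2L])
  logp <- pmin(0, logp)
  10^logp
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort: ", nrow(x$truth), " samples (",
      paste(sprintf("%s=%d", names(x$config$counts), x$config$counts),
            collapse = ", "), "), ",
      nrow(x$matrix$beta), " probes\n", sep = "")
  invisible(x)
}

#' Flip a subset of F/M labels, returning the corrupted labels
#'
#' Test fixture for mislabel-detection: swaps `k` randomly chosen `F`/`M`
#' labels (N-truth samples are never eligible) and reports which.
#'
#' @param labels Character vector of `"F"`/`"M"`/`"N"` truth labels.
#' @param k Number of labels to flip.
#' @param seed Integer seed.
#' @return A list with `labels` (corrupted vector) and `flipped` (integer
#'   indices of the flipped entries).
#' @export
flip_labels <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  eligible <- which(labels %in% c("F", "M"))
  if (k > length(eligible))
    stop("k exceeds the number of F/M-labelled samples")
  set.seed(seed)
  idx <- if (k == 0L) integer(0) else sort(sample(eligible, k))
  labels[idx] <- ifelse(labels[idx] == "F", "M", "F")
  list(labels = labels, flipped = idx)
}

#' Write a simulated cohort to tab-separated files
#'
#' Writes `beta.tsv`, `detp.tsv`, `manifest.tsv` and `truth.tsv` into a
#' directory, in the formats read back by [read_matrix()] and
#' [read_manifest()].
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$matrix$beta, file.path(dir, "beta.tsv"))
  write_matrix(cohort$matrix$detp, file.path(dir, "detp.tsv"))
  utils::write.table(cohort$annot, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
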