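#' PCA followed by k-means clustering against reference labels
#'
#' The per-axis workhorse of the estimator. Columns of the feature matrix
#' (concatenated beta-value and detection p-value bin proportions for one
#' sex chromosome) are mean-centred and rotated by principal component
#' analysis; k-means with k = 2 is then run on the retained component
#' scores. Cluster indices themselves carry no meaning: each cluster is
#' assigned the sex of the majority of the reference samples it contains,
#' and clusters are relabelled so that cluster 1 is the female-majority
#' cluster. The first-component score is sign-oriented so that female
#' reference samples average negative, making plots comparable across runs.
#'
#' @param features Numeric matrix, samples x bins; rownames are sample IDs.
#' @param ref_sex Character vector, one per row: `"f"` or `"m"` for
#'   reference samples, `"none"` for test samples.
#' @param seed Integer seed for the k-means restarts.
#' @param pc1_only If `TRUE`, cluster on the first component score alone
#'   instead of the full score matrix.
#' @return A data.frame with one row per input row: `sample_id`, `cluster`
#'   (1 = female-majority), `assigned_sex` (`"f"`/`"m"`), `pc1`,
#'   `dist_to_centre`, `is_ref`; attribute `purity` holds each cluster's
#'   reference purity. If either cluster's references are less than 90% one
#'   sex a warning is raised and recorded in attribute `purity_warning`.
#' @export
pca_cluster <- function(features, ref_sex, seed = 1L, pc1_only = FALSE) {
  if (!is.matrix(features) || nrow(features) < 2L)
    stop("features must be a matrix with at least two rows")
  ref_sex <- as.character(ref_sex)
  if (length(ref_sex) != nrow(features))
    stop("ref_sex must have one entry per feature row")
  if (!all(ref_sex %in% c("f", "m", "none")))
    stop("ref_sex entries must be 'f', 'm' or 'none'")
  if (sum(ref_sex == "f") < 1L || sum(ref_sex == "m") < 1L)
    stop("at least one reference sample of each sex is required")

  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > max(pc$sdev[1L] * 1e-8, 1e-12)
  if (!any(keep)) stop("feature matrix has no variance")
  scores <- pc$x[, keep, drop = FALSE]
  km_space <- if (pc1_only) scores[, 1L, drop = FALSE] else scores

  set.seed(seed)
  km <- stats::kmeans(km_space, centers = 2L, nstart = 25L, iter.max = 100L)

  f_in <- tabulate(km$cluster[ref_sex == "f"], nbins = 2L)
  m_in <- tabulate(km$cluster[ref_sex == "m"], nbins = 2L)
  if (any(f_in + m_in == 0L))
    stop("reference samples did not split across the two clusters")
  cl_sex <- ifelse(f_in >= m_in, "f", "m")
  if (cl_sex[1L] == cl_sex[2L])
    stop("reference samples did not separate by sex: both clusters are ",
         "majority-", cl_sex[1L])
  fem_cl <- which(cl_sex == "f")
  new_cluster <- ifelse(km$cluster == fem_cl, 1L, 2L)
  purity <- pmax(f_in, m_in) / (f_in + m_in)
  purity <- purity[c(fem_cl, 3L - fem_cl)]  # index 1 = female cluster
  names(purity) <- c("cluster1_f", "cluster2_m")
  purity_warning <- any(purity < 0.9)
  if (purity_warning)
    warning("cluster reference purity below 90%; axis assignments may be unreliable")

  pc1 <- scores[, 1L]
  if (mean(pc1[ref_sex == "f"]) > 0) pc1 <- -pc1
  centres <- km$centers[km$cluster, , drop = FALSE]
  dist_to_centre <- sqrt(rowSums((km_space - centres)^2))

  out <- data.frame(sample_id = rownames(features),
                    cluster = new_cluster,
                    assigned_sex = ifelse(new_cluster == 1L, "f", "m"),
                    pc1 = unname(pc1),
                    dist_to_centre = unname(dist_to_centre),
                    is_ref = ref_sex != "none",
                    stringsAsFactors = FALSE)
  attr(out, "purity") <- purity
  attr(out, "purity_warning") <- purity_warning
  out
}

#' Combine per-chromosome sex assignments into the final call
#'
#' The final call is `F` when both the chrX- and chrY-derived assignments
#' are female, `M` when both are male, and `N` when they conflict. An
#' N-call flags a candidate mislabelled sample, mosaic, or sex-chromosome
#' aneuploidy: a female-like chrX with a male-like chrY is the Klinefelter
#' (XXY) signature, the reverse is the Turner (X0) signature.
#'
#' @param sex_x,sex_y Character vectors of `"f"`/`"m"` assignments from the
#'   chrX and chrY analyses (recycled to a common length).
#' @return Character vector of calls in `{"F", "M", "N"}`.
#' @examples
#' combine_calls(c("f", "m", "f", "m"), c("f", "m", "m", "f"))
#' @export
combine_calls <- function(sex_x, sex_y) {
  n <- max(length(sex_x), length(sex_y))
  sex_x <- rep_len(as.character(sex_x), n)
  sex_y <- rep_len(as.character(sex_y), n)
  if (!all(c(sex_x, sex_y) %in% c("f", "m")))
    stop("per-chromosome assignments must be 'f' or 'm'")
  ifelse(sex_x == sex_y, ifelse(sex_x == "f", "F", "M"), "N")
}

#' Estimate the sex of methylation array samples
#'
#' The main entry point. Builds binned beta-value / detection p-value
#' distribution profiles of the test samples on each sex chromosome,
#' re-bins the reference panel to the same scheme, and for each chromosome
#' jointly analyses test and reference profiles with [pca_cluster()]. Each
#' test sample receives a per-chromosome sex (the sex of the reference
#' samples it clusters with) and a combined call: `F` (female), `M` (male),
#' or `N` when the two chromosomes disagree. Anchoring the clustering on
#' the reference panel keeps the method valid even when the test cohort is
#' heavily biased towards one sex.
#'
#' QC results (fraction of chrX probes failing detection) are attached to
#' every call but never drop a sample; filtering is left to the caller.
#'
#' @param test A [methylation_matrix()] of the samples to classify.
#' @param annot A [probe_annotation()].
#' @param panel A [sex_reference] panel (see [build_reference()] /
#'   [default_reference()]).
#' @param scheme A [bin_scheme()] whose edges align with the panel's fine
#'   bins; default the 10-beta-bin / 3-detp-bin scheme.
#' @param seed Integer seed; the chrX axis uses `seed`, the chrY axis
#'   `seed + 1`.
#' @param pc1_only Cluster on the first component only (default `FALSE`,
#'   full score space).
#' @return An object of class `sex_calls`: a data.frame with one row per
#'   test sample and columns `sample_id`, `predicted` (`F`/`M`/`N`),
#'   `sex_chrX`, `sex_chrY`, `X.PC1`, `Y.PC1`, `frac_chrX_detp_failed`,
#'   `qc_passed`, `warnings`; attributes carry the reference coordinates
#'   (for plotting), the scheme, the seed and per-axis cluster purities.
#' @seealso [plot_sex_estimation()], [plot_sex_distribution()],
#'   [detect_label_mismatch()]
#' @export
estimate_sex <- function(test, annot, panel, scheme = bin_scheme(),
                         seed = 1L, pc1_only = FALSE) {
  stopifnot(inherits(panel, "sex_reference"))
  if (!inherits(test, "methylation_matrix"))
    stop("test must be a methylation_matrix")
  if (ncol(test$beta) == 0L) stop("empty test set")

  prof <- build_profiles(test, annot, scheme)
  ref <- rebin(panel, scheme)
  n_ref <- length(panel$sex)
  n_test <- length(prof$sample_ids)
  ref_ids <- paste0(".ref_", rownames(ref$chrX_beta))

  feats <- function(p, chr, ids) {
    m <- cbind(p[[paste0(chr, "_beta")]], p[[paste0(chr, "_detp")]])
    rownames(m) <- ids
    m
  }
  ref_sex <- c(panel$sex, rep("none", n_test))
  axes <- list()
  for (chr in c("chrX", "chrY")) {
    f <- rbind(feats(ref, chr, ref_ids), feats(prof, chr, prof$sample_ids))
    ax_seed <- if (chr == "chrX") seed else seed + 1L
    axes[[chr]] <- pca_cluster(f, ref_sex, seed = ax_seed, pc1_only = pc1_only)
  }
  ax <- axes$chrX
  ay <- axes$chrY
  test_rows <- !ax$is_ref

  warn <- character(n_test)
  if (isTRUE(attr(ax, "purity_warning")))
    warn <- paste0(warn, "chrX cluster purity < 90%;")
  if (isTRUE(attr(ay, "purity_warning")))
    warn <- paste0(warn, "chrY cluster purity < 90%;")

  qc <- qc_filter(test, annot)
  qc <- qc[match(prof$sample_ids, qc$sample_id), ]

  calls <- data.frame(
    sample_id = prof$sample_ids,
    predicted = combine_calls(ax$assigned_sex[test_rows],
                              ay$assigned_sex[test_rows]),
    sex_chrX = ax$assigned_sex[test_rows],
    sex_chrY = ay$assigned_sex[test_rows],
    X.PC1 = ax$pc1[test_rows],
    Y.PC1 = ay$pc1[test_rows],
    frac_chrX_detp_failed = qc$frac_chrX_failed,
    qc_passed = qc$passed,
    warnings = warn,
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  attr(calls, "reference") <- data.frame(
    sample_id = rownames(ref$chrX_beta),
    sex = panel$sex,
    X.PC1 = ax$pc1[!test_rows],
    Y.PC1 = ay$pc1[!test_rows],
    stringsAsFactors = FALSE)
  attr(calls, "scheme") <- scheme
  attr(calls, "seed") <- seed
  attr(calls, "purity") <- list(chrX = attr(ax, "purity"),
                                chrY = attr(ay, "purity"))
  class(calls) <- c("sex_calls", "data.frame")
  calls
}

#' @export
print.sex_calls <- function(x, n = 10L, ...) {
  cat("Sex calls for ", nrow(x), " sample(s): ",
      sum(x$predicted == "F"), " F, ", sum(x$predicted == "M"), " M, ",
      sum(x$predicted == "N"), " N\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more row(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.sex_calls <- function(object, ...) {
  out <- list(n = nrow(object),
              calls = table(factor(object$predicted, c("F", "M", "N"))),
              qc_failed = sum(!object$qc_passed),
              purity = attr(object, "purity"),
              n_samples = object$sample_id[object$predicted == "N"])
  class(out) <- "summary.sex_calls"
  out
}

#' @export
print.summary.sex_calls <- function(x, ...) {
  cat("Sex estimation of", x$n, "samples\n")
  cat("  F:", x$calls[["F"]], "  M:", x$calls[["M"]], "  N:", x$calls[["N"]], "\n")
  cat("  QC failures:", x$qc_failed, "\n")
  pu <- x$purity
  cat(sprintf("  reference cluster purity  chrX: %.3f/%.3f  chrY: %.3f/%.3f\n",
              pu$chrX[1L], pu$chrX[2L], pu$chrY[1L], pu$chrY[2L]))
  if (length(x$n_samples))
    cat("  N-samples (conflicting chrX/chrY):",
        paste(x$n_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Compare sex calls with recorded sample labels
#'
#' Splits disagreements into the two categories that matter for QC:
#' *discordant* samples, predicted `F` or `M` opposite to a recorded label
#' (candidate mislabels), and *N-samples*, whose chrX/chrY assignments
#' conflict (candidate aneuploidies or mosaics) — the latter are reported
#' separately and never counted as discordant.
#'
#' @param calls A `sex_calls` object (or data.frame with `sample_id` and
#'   `predicted`).
#' @param labels Recorded labels: a named character vector (names = sample
#'   IDs) or a data.frame with columns `sample_id` and `label`; values in
#'   `{"F", "M", "unknown"}`.
#' @return A list with data.frames `discordant` (sample_id, label,
#'   predicted) and `n_samples` (sample_id, label).
#' @export
detect_label_mismatch <- function(calls, labels) {
  if (is.data.frame(labels)) {
    lab <- stats::setNames(as.character(labels$label),
                           as.character(labels$sample_id))
  } else {
    lab <- as.character(labels)
    names(lab) <- names(labels)
  }
  if (is.null(names(lab))) stop("labels must carry sample IDs")
  unknown_ids <- setdiff(names(lab), calls$sample_id)
  if (length(unknown_ids))
    stop("labels refer to unknown sample IDs: ",
         paste(utils::head(unknown_ids, 3L), collapse = ", "))
  if (!all(lab %in% c("F", "M", "unknown")))
    stop("labels must be 'F', 'M' or 'unknown'")
  lab <- lab[match(calls$sample_id, names(lab))]
  pred <- calls$predicted
  is_n <- pred == "N"
  disc <- !is_n & !is.na(lab) & lab %in% c("F", "M") & pred != lab
  list(discordant = data.frame(sample_id = calls$sample_id[disc],
                               label = unname(lab[disc]),
                               predicted = pred[disc],
                               stringsAsFactors = FALSE),
       n_samples = data.frame(sample_id = calls$sample_id[is_n],
                              label = unname(ifelse(is.na(lab[is_n]),
                                                    "unknown", lab[is_n])),
                              stringsAsFactors = FALSE))
}
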