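#' Probe-to-chromosome annotation
#'
#' Normalises a probe manifest into the three-way annotation the estimator
#' needs: chrX, chrY, or autosome. Chromosome tokens `"X"`/`"chrX"` and
#' `"Y"`/`"chrY"` (case-insensitive) are recognised; every other token is
#' treated as autosomal.
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param chromosome Character vector of chromosome tokens, same length.
#' @return A data.frame with columns `probe_id` (character) and `chromosome`
#'   (factor with levels autosome, chrX, chrY), classed `probe_annotation`.
#' @export
probe_annotation <- function(probe_id, chromosome) {
  probe_id <- as.character(probe_id)
  chromosome <- as.character(chromosome)
  if (length(probe_id) != length(chromosome))
    stop("probe_id and chromosome must have the same length")
  if (anyDuplicated(probe_id))
    stop("duplicate probe IDs in annotation: ",
         paste(utils::head(probe_id[duplicated(probe_id)], 3L), collapse = ", "))
  tok <- toupper(sub("^CHR", "", toupper(chromosome)))
  chr <- ifelse(tok == "X", "chrX", ifelse(tok == "Y", "chrY", "autosome"))
  out <- data.frame(probe_id = probe_id,
                    chromosome = factor(chr, levels = c("autosome", "chrX", "chrY")),
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_annotation", "data.frame")
  out
}

#' Methylation matrix pair (beta-values and detection p-values)
#'
#' Bundles the two probe-by-sample matrices the method consumes. Both must
#' share dimnames (probe IDs as rownames, sample IDs as colnames) and hold
#' values in `[0, 1]` where present; either matrix may be omitted only by
#' passing a matrix of `NA`s.
#'
#' @param beta Numeric matrix of beta-values, probes x samples.
#' @param detp Numeric matrix of detection p-values, probes x samples.
#' @return A list with elements `beta` and `detp`, classed
#'   `methylation_matrix`.
#' @export
methylation_matrix <- function(beta, detp) {
  if (!is.matrix(beta) || !is.matrix(detp))
    stop("beta and detp must be matrices")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta must have probe IDs as rownames and sample IDs as colnames")
  if (!identical(dimnames(beta), dimnames(detp)))
    stop("beta and detp must share probe and sample IDs")
  if (anyDuplicated(rownames(beta))) stop("duplicate probe IDs")
  if (anyDuplicated(colnames(beta))) stop("duplicate sample IDs")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) stop("beta values outside [0, 1]")
  rng <- range(detp, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) stop("detection p-values outside [0, 1]")
  structure(list(beta = beta, detp = detp), class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("Methylation matrix: ", nrow(x$beta), " probes x ", ncol(x$beta),
      " samples\n", sep = "")
  invisible(x)
}

#' Per-chromosome binned distribution profiles
#'
#' Turns a methylation matrix into the per-sample distribution profiles the
#' estimator operates on: for every sample, the proportions of chrX and chrY
#' probes in each beta-value bin and each detection p-value bin of `scheme`.
#' A female sample typically shows substantial chrX mass at intermediate
#' beta-values (X-inactivation) and high chrY detection p-values (no Y);
#' a male sample shows the reverse.
#'
#' Probes present in the matrix but absent from the annotation (or vice
#' versa) are dropped; the intersection is used, so e.g. EPIC data can be
#' profiled against an HM450k-derived panel. Missing values are excluded per
#' metric before binning.
#'
#' @param mat A [methylation_matrix()].
#' @param annot A [probe_annotation()].
#' @param scheme A [bin_scheme()]; defaults to the 10-beta-bin / 3-detp-bin
#'   estimation scheme.
#' @return An object of class `sex_profiles`: a list with samples x bins
#'   proportion matrices `chrX_beta`, `chrX_detp`, `chrY_beta`, `chrY_detp`,
#'   an `n_used` matrix of per-metric probe counts, and the `scheme`.
#' @export
build_profiles <- function(mat, annot, scheme = bin_scheme()) {
  stopifnot(inherits(mat, "methylation_matrix"), inherits(scheme, "bin_scheme"))
  if (!inherits(annot, "probe_annotation"))
    annot <- probe_annotation(annot$probe_id, annot$chromosome)
  common <- intersect(rownames(mat$beta), annot$probe_id)
  n_drop <- nrow(mat$beta) - length(common)
  if (n_drop > 0L)
    message("build_profiles: ", n_drop,
            " probe(s) absent from the annotation were dropped")
  chr <- annot$chromosome[match(common, annot$probe_id)]
  probes <- list(chrX = common[chr == "chrX"], chrY = common[chr == "chrY"])
  for (cn in names(probes))
    if (length(probes[[cn]]) == 0L)
      stop("no overlapping ", cn, " probes between matrix and annotation")
  samples <- colnames(mat$beta)
  out <- list()
  n_used <- matrix(0L, nrow = length(samples), ncol = 4L,
                   dimnames = list(samples, c("chrX_beta", "chrX_detp",
                                              "chrY_beta", "chrY_detp")))
  for (cn in c("chrX", "chrY")) {
    for (metric in c("beta", "detp")) {
      edges <- if (metric == "beta") scheme$beta_edges else scheme$detp_edges
      block <- mat[[metric]][probes[[cn]], , drop = FALSE]
      prop <- matrix(NA_real_, nrow = length(samples), ncol = n_bins(edges),
                     dimnames = list(samples, bin_labels(edges)))
      key <- paste0(cn, "_", metric)
      for (j in seq_along(samples)) {
        v <- block[, j]
        prop[j, ] <- tryCatch(bin_proportions(v, edges), error = function(e)
          stop("sample ", samples[j], ", ", cn, " ", metric, ": ",
               conditionMessage(e), call. = FALSE))
        n_used[j, key] <- sum(!is.na(v))
      }
      out[[key]] <- prop
    }
  }
  structure(c(out, list(n_used = n_used, scheme = scheme,
                        sample_ids = samples)),
            class = "sex_profiles")
}

bin_labels <- function(edges) {
  sprintf("(%.3g,%.3g]", edges[-length(edges)], edges[-1L])
}

#' @export
print.sex_profiles <- function(x, ...) {
  cat("Sex-chromosome distribution profiles: ", length(x$sample_ids),
      " samples\n", sep = "")
  cat("  beta bins: ", ncol(x$chrX_beta), "; detp bins: ", ncol(x$chrX_detp),
      "\n", sep = "")
  invisible(x)
}

#' Detection p-value quality-control filter
#'
#' Flags samples whose chrX probes fail detection too often. A probe fails
#' when its detection p-value is at or above `p_cutoff` (missing p-values
#' count as failures, since an absent p-value conveys no confidence); a
#' sample fails QC when the failing fraction exceeds `max_fail_frac`
#' (strictly greater — a sample at exactly the threshold passes).
#'
#' @param mat A [methylation_matrix()].
#' @param annot A [probe_annotation()].
#' @param p_cutoff Detection p-value at or above which a probe is deemed
#'   unreliable; default 0.01.
#' @param max_fail_frac Maximum tolerated failing fraction of chrX probes;
#'   default 0.05.
#' @return A data.frame with columns `sample_id`, `frac_chrX_failed`,
#'   `passed`.
#' @examples
#' \dontrun{qc <- qc_filter(mat, annot); mat_clean <- mat[, qc$passed]}
#' @export
qc_filter <- function(mat, annot, p_cutoff = 0.01, max_fail_frac = 0.05) {
  stopifnot(inherits(mat, "methylation_matrix"))
  if (!inherits(annot, "probe_annotation"))
    annot <- probe_annotation(annot$probe_id, annot$chromosome)
  x_probes <- intersect(rownames(mat$detp),
                        annot$probe_id[annot$chromosome == "chrX"])
  if (length(x_probes) == 0L) stop("no chrX probes available for QC")
  detp <- mat$detp[x_probes, , drop = FALSE]
  failed <- is.na(detp) | detp >= p_cutoff
  frac <- colMeans(failed)
  data.frame(sample_id = colnames(detp),
             frac_chrX_failed = unname(frac),
             passed = unname(frac <= max_fail_frac),
             stringsAsFactors = FALSE)
}
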