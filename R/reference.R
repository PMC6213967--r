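#' Build a male/female reference panel from labelled profiles
#'
#' Curates a labelled cohort into the reference panel that anchors every
#' estimation run. The cohort's fine-binned profiles are analysed per sex
#' chromosome with [pca_cluster()]; samples are kept only when, on both
#' axes, they fall in the cluster holding the majority of their own label
#' (the "1/1" cell for females, "2/2" for males). Within each concordant
#' group, the `retention_fraction` of samples closest to their cluster
#' centres (Euclidean distance in the product of the two axes' clustering
#' spaces) is retained, discarding peripheral samples whose profiles are
#' least typical of their sex.
#'
#' @param profiles A `sex_profiles` object built at the [fine_bin_scheme()]
#'   (100 beta bins, 18 detection p-value decade bins).
#' @param labels Character vector of `"f"`/`"m"`, one per profile sample.
#' @param retention_fraction Fraction of each concordant group to retain
#'   (`floor(retention_fraction * n)` samples); default 0.875.
#' @param seed Integer seed (chrX axis uses `seed`, chrY `seed + 1`).
#' @return An object of class `sex_reference` holding the retained samples'
#'   fine proportion matrices, their sex labels, the fine scheme, build
#'   metadata, and the label-by-cluster `concordance` table.
#' @export
build_reference <- function(profiles, labels, retention_fraction = 0.875,
                            seed = 1L) {
  stopifnot(inherits(profiles, "sex_profiles"))
  labels <- as.character(labels)
  if (length(labels) != length(profiles$sample_ids))
    stop("labels must have one entry per profile sample")
  if (!all(labels %in% c("f", "m")))
    stop("labels must be 'f' or 'm'")
  if (sum(labels == "f") < 4L || sum(labels == "m") < 4L)
    stop("at least 4 labelled samples per sex are required")
  if (retention_fraction <= 0 || retention_fraction > 1)
    stop("retention_fraction must be in (0, 1]")
  check_fine_scheme(profiles$scheme)

  feat_x <- cbind(profiles$chrX_beta, profiles$chrX_detp)
  feat_y <- cbind(profiles$chrY_beta, profiles$chrY_detp)
  rownames(feat_x) <- rownames(feat_y) <- profiles$sample_ids
  ax <- pca_cluster(feat_x, labels, seed = seed)
  ay <- pca_cluster(feat_y, labels, seed = seed + 1L)

  cell <- factor(paste(ax$cluster, ay$cluster, sep = "/"),
                 levels = c("1/1", "1/2", "2/1", "2/2"))
  concordance <- table(label = factor(ifelse(labels == "f", "Female", "Male"),
                                      levels = c("Female", "Male")),
                       cluster = cell)

  own_cell <- ifelse(labels == "f", "1/1", "2/2")
  concordant <- as.character(cell) == own_cell
  dist <- sqrt(ax$dist_to_centre^2 + ay$dist_to_centre^2)

  keep <- logical(length(labels))
  for (sx in c("f", "m")) {
    grp <- which(concordant & labels == sx)
    if (length(grp) == 0L)
      stop("no concordant ", if (sx == "f") "female" else "male",
           " samples; cannot build a reference")
    n_keep <- max(1L, floor(retention_fraction * length(grp)))
    keep[grp[order(dist[grp])[seq_len(n_keep)]]] <- TRUE
  }
  if (sum(keep & labels == "f") < 2L || sum(keep & labels == "m") < 2L)
    stop("fewer than 2 retained samples of a sex; cannot build a reference")

  panel <- structure(list(
    chrX_beta = profiles$chrX_beta[keep, , drop = FALSE],
    chrX_detp = profiles$chrX_detp[keep, , drop = FALSE],
    chrY_beta = profiles$chrY_beta[keep, , drop = FALSE],
    chrY_detp = profiles$chrY_detp[keep, , drop = FALSE],
    sex = labels[keep],
    scheme = profiles$scheme,
    meta = list(seed = seed, retention_fraction = retention_fraction,
                n_input = length(labels), n_concordant = sum(concordant)),
    concordance = concordance),
    class = "sex_reference")
  rownames(panel$chrX_beta) <- rownames(panel$chrX_detp) <-
    rownames(panel$chrY_beta) <- rownames(panel$chrY_detp) <-
    profiles$sample_ids[keep]
  panel
}

check_fine_scheme <- function(scheme) {
  fine <- fine_bin_scheme()
  ok <- length(scheme$beta_edges) == length(fine$beta_edges) &&
    length(scheme$detp_edges) == length(fine$detp_edges) &&
    all(edges_align(scheme$beta_edges, fine$beta_edges)) &&
    all(edges_align(scheme$detp_edges, fine$detp_edges))
  if (!ok)
    stop("profiles must be built at the fine bin scheme (fine_bin_scheme())")
  invisible(TRUE)
}

edges_align <- function(a, b) {
  (a == b) | (abs(a - b) <= 1e-9 * pmax(abs(a), abs(b)))
}

#' @export
print.sex_reference <- function(x, ...) {
  cat("Reference panel: ", sum(x$sex == "f"), " female + ",
      sum(x$sex == "m"), " male samples\n", sep = "")
  cat("  fine bins: ", ncol(x$chrX_beta), " beta, ", ncol(x$chrX_detp),
      " detection-p\n", sep = "")
  cat("  retention fraction: ", x$meta$retention_fraction,
      ", seed: ", x$meta$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.sex_reference <- function(object, ...) {
  print(object)
  cat("Label-by-cluster concordance of the input cohort:\n")
  print(object$concordance)
  invisible(object)
}

#' Re-bin a reference panel to a coarser aligned scheme
#'
#' Collapses the panel's fine proportion tables to the bins of `scheme` by
#' summing the contained fine bins. Every requested edge must coincide with
#' a fine-bin edge (beta edges on multiples of 0.01; detection p-value
#' edges among the decade edges); a misaligned edge is an error — no
#' interpolation is ever performed, so re-binned proportions are exactly
#' what direct binning of the raw values at the coarse scheme would give.
#'
#' @param panel A `sex_reference`.
#' @param scheme Target [bin_scheme()].
#' @return A `sex_profiles` object at `scheme` with the panel's samples.
#' @export
rebin <- function(panel, scheme) {
  stopifnot(inherits(panel, "sex_reference"), inherits(scheme, "bin_scheme"))
  map_b <- match_edges(scheme$beta_edges, panel$scheme$beta_edges, "beta")
  map_p <- match_edges(scheme$detp_edges, panel$scheme$detp_edges, "detp")
  collapse <- function(fine, map) {
    out <- vapply(seq_len(length(map) - 1L), function(j)
      rowSums(fine[, map[j]:(map[j + 1L] - 1L), drop = FALSE]),
      numeric(nrow(fine)))
    out <- matrix(out, nrow = nrow(fine))
    rownames(out) <- rownames(fine)
    out
  }
  res <- list(
    chrX_beta = collapse(panel$chrX_beta, map_b),
    chrX_detp = collapse(panel$chrX_detp, map_p),
    chrY_beta = collapse(panel$chrY_beta, map_b),
    chrY_detp = collapse(panel$chrY_detp, map_p))
  colnames(res$chrX_beta) <- colnames(res$chrY_beta) <-
    bin_labels(scheme$beta_edges)
  colnames(res$chrX_detp) <- colnames(res$chrY_detp) <-
    bin_labels(scheme$detp_edges)
  structure(c(res, list(n_used = NULL, scheme = scheme,
                        sample_ids = rownames(panel$chrX_beta))),
            class = "sex_profiles")
}

# Map each coarse edge to the index of the coinciding fine edge.
match_edges <- function(coarse, fine, what) {
  idx <- integer(length(coarse))
  for (i in seq_along(coarse)) {
    j <- which.min(abs(fine - coarse[i]))
    if (!edges_align(coarse[i], fine[j]))
      stop(what, " edge ", format(coarse[i]),
           " does not align with the panel's fine bin edges")
    idx[i] <- j
  }
  if (any(diff(idx) <= 0L))
    stop(what, " edges collapse onto the same fine edge")
  idx
}

#' Write a reference panel as a plain-text bundle
#'
#' Serialises a panel into a directory of tab-separated files:
#' `panel_meta.tsv` (sample IDs, sex labels, build parameters and fine-edge
#' definitions in `#key=value` header lines) and one samples-by-bins table
#' per chromosome and metric (`chrX_beta.tsv`, `chrX_detp.tsv`,
#' `chrY_beta.tsv`, `chrY_detp.tsv`, header = bin upper edges).
#'
#' @param panel A `sex_reference`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(panel, dir) {
  stopifnot(inherits(panel, "sex_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta_path <- file.path(dir, "panel_meta.tsv")
  con <- file(meta_path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#format=methylsex_panel_v1"),
    paste0("#seed=", panel$meta$seed),
    paste0("#retention_fraction=", format(panel$meta$retention_fraction)),
    paste0("#n_input=", panel$meta$n_input),
    paste0("#n_concordant=", panel$meta$n_concordant),
    paste0("#beta_edges=", paste(format(panel$scheme$beta_edges, trim = TRUE,
                                        digits = 15), collapse = ",")),
    paste0("#detp_edges=", paste(format(panel$scheme$detp_edges, trim = TRUE,
                                        digits = 15), collapse = ","))),
    con)
  utils::write.table(
    data.frame(sample_id = rownames(panel$chrX_beta), sex = panel$sex),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("chrX_beta", "chrX_detp", "chrY_beta", "chrY_detp")) {
    m <- panel[[nm]]
    edges <- if (grepl("beta", nm)) panel$scheme$beta_edges else
      panel$scheme$detp_edges
    df <- data.frame(sample_id = rownames(m),
                     signif(m, 10), check.names = FALSE)
    colnames(df)[-1L] <- format(edges[-1L], trim = TRUE, digits = 15)
    utils::write.table(df, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a reference panel bundle written by [write_reference()]
#'
#' @param dir Directory containing the panel bundle.
#' @return A `sex_reference`.
#' @export
read_reference <- function(dir) {
  meta_path <- file.path(dir, "panel_meta.tsv")
  if (!file.exists(meta_path)) stop("not a panel bundle: missing ", meta_path)
  lines <- readLines(meta_path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  getv <- function(k) vals[match(k, keys)]
  scheme <- bin_scheme(
    beta_edges = as.numeric(strsplit(getv("beta_edges"), ",")[[1L]]),
    detp_edges = as.numeric(strsplit(getv("detp_edges"), ",")[[1L]]))
  samp <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  read_block <- function(nm) {
    df <- utils::read.table(file.path(dir, paste0(nm, ".tsv")), header = TRUE,
                            sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    edges <- if (grepl("beta", nm)) scheme$beta_edges else scheme$detp_edges
    colnames(m) <- bin_labels(edges)
    m[match(samp$sample_id, rownames(m)), , drop = FALSE]
  }
  panel <- structure(list(
    chrX_beta = read_block("chrX_beta"),
    chrX_detp = read_block("chrX_detp"),
    chrY_beta = read_block("chrY_beta"),
    chrY_detp = read_block("chrY_detp"),
    sex = samp$sex,
    scheme = scheme,
    meta = list(seed = as.integer(getv("seed")),
                retention_fraction = as.numeric(getv("retention_fraction")),
                n_input = as.integer(getv("n_input")),
                n_concordant = as.integer(getv("n_concordant"))),
    concordance = NULL),
    class = "sex_reference")
  panel
}

#' Default synthetic reference panel
#'
#' Builds the panel shipped with the package: a simulated labelled cohort of
#' 100 XX and 100 XY samples (see [simulate_cohort()]) profiled at the fine
#' scheme and curated with [build_reference()]. The panel is synthetic — it
#' reproduces the qualitative sex-specific distribution shapes of real
#' methylation arrays, not any real cohort — and is fully determined by
#' `seed`, so identical calls return identical panels. Users with labelled
#' cohorts of their own should build a real panel instead.
#'
#' @param seed Integer seed controlling both the simulation and the
#'   panel build.
#' @param n_per_sex Number of simulated samples per sex; default 100.
#' @param retention_fraction Passed to [build_reference()].
#' @return A `sex_reference`.
#' @export
default_reference <- function(seed = 101L, n_per_sex = 100L,
                              retention_fraction = 0.875) {
  cohort <- simulate_cohort(sim_config(n_XX = n_per_sex, n_XY = n_per_sex,
                                       seed = seed))
  prof <- build_profiles(cohort$matrix, cohort$annot, fine_bin_scheme())
  labels <- ifelse(cohort$truth$karyotype == "XX", "f", "m")
  build_reference(prof, labels, retention_fraction = retention_fraction,
                  seed = seed + 1L)
}
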