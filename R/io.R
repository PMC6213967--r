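#' Read a probe-by-sample value matrix from tab-separated text
#'
#' Reads one half of a methylation matrix (beta-values or detection
#' p-values) from a series-matrix-like layout: first column probe IDs,
#' header row of sample IDs, tab-separated. Gzip-compressed files are read
#' transparently. Blank fields, `NA` and `NaN` tokens become missing
#' values. Ragged rows, duplicate probe or sample IDs, non-numeric fields
#' and values outside `[0, 1]` are errors reported with their line number.
#'
#' @param path Path to the file (plain or `.gz`).
#' @return Numeric matrix, probes x samples, with dimnames.
#' @seealso [write_matrix()], [methylation_matrix()]
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)  # gzip-transparent
  if (length(lines) < 2L) stop(path, ": need a header and at least one probe row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  if (length(samples) == 0L) stop(path, ": no sample columns")
  if (anyDuplicated(samples))
    stop(path, ": duplicate sample IDs in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  n_col <- length(header)
  body <- fields[-1L]
  probes <- character(length(body))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_col)
      stop(path, ": line ", i + 1L, " has ", length(row),
           " fields, expected ", n_col)
    probes[i] <- row[1L]
    v <- row[-1L]
    v[v %in% c("", "NA", "NaN", "na", "nan")] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- is.na(num) & !is.na(v)
    if (any(bad))
      stop(path, ": line ", i + 1L, ": non-numeric value '",
           v[which(bad)[1L]], "'")
    out_of_range <- !is.na(num) & (num < 0 | num > 1)
    if (any(out_of_range))
      stop(path, ": line ", i + 1L, ": value ",
           num[which(out_of_range)[1L]], " outside [0, 1]")
    vals[i, ] <- num
  }
  if (anyDuplicated(probes))
    stop(path, ": duplicate probe IDs: ",
         paste(utils::head(unique(probes[duplicated(probes)]), 3L),
               collapse = ", "))
  dimnames(vals) <- list(probes, samples)
  vals
}

#' Write a probe-by-sample matrix as tab-separated text
#'
#' Values are printed with 6 significant digits, the precision to which
#' read/write round-trips are guaranteed.
#'
#' @param m Numeric matrix with probe rownames and sample colnames.
#' @param path Output path; a `.gz` suffix writes gzip-compressed text.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(probe_id = rownames(m), signif(m, 6), check.names = FALSE)
  colnames(df)[-1L] <- colnames(m)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe manifest
#'
#' Tab-separated file with columns `probe_id` and `chromosome`; chromosome
#' tokens `X`/`chrX`/`Y`/`chrY` are recognised, anything else is treated as
#' autosomal.
#'
#' @param path Path to the manifest file.
#' @return A [probe_annotation()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("probe_id", "chromosome")
  if (!all(need %in% colnames(df)))
    stop(path, ": manifest must have columns probe_id and chromosome")
  probe_annotation(df$probe_id, df$chromosome)
}

#' Read a beta + detection-p matrix pair into a methylation matrix
#'
#' Convenience wrapper around [read_matrix()]; the two files must agree on
#' probe and sample IDs (order included).
#'
#' @param beta_path,detp_path Paths to the two matrices.
#' @return A [methylation_matrix()].
#' @export
read_methylation <- function(beta_path, detp_path) {
  methylation_matrix(read_matrix(beta_path), read_matrix(detp_path))
}

#' Read recorded sex labels
#'
#' Tab-separated file with columns `sample_id` and `label` (`F`, `M`, or
#' `unknown`).
#'
#' @param path Path to the labels file.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(df)))
    stop(path, ": labels file must have columns sample_id and label")
  stats::setNames(as.character(df$label), df$sample_id)
}

#' Write sex calls as a tab-separated results table
#'
#' @param calls A `sex_calls` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  df <- as.data.frame(calls)
  df$X.PC1 <- signif(df$X.PC1, 6)
  df$Y.PC1 <- signif(df$Y.PC1, 6)
  df$frac_chrX_detp_failed <- signif(df$frac_chrX_detp_failed, 6)
  names(df)[names(df) == "predicted"] <- "predicted_sex"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
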