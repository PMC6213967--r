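# Shared fixtures, built once per test run (simulation + fine profiling of
# the 200-sample labelled cohort is the expensive part).
.fx <- new.env(parent = emptyenv())

fx_ref_cohort <- function() {
  if (is.null(.fx$ref_cohort))
    .fx$ref_cohort <- simulate_cohort(sim_config(n_XX = 100, n_XY = 100,
                                                 seed = 42))
  .fx$ref_cohort
}

fx_ref_labels <- function() {
  ifelse(fx_ref_cohort()$truth$karyotype == "XX", "f", "m")
}

fx_ref_profiles <- function() {
  if (is.null(.fx$ref_profiles)) {
    co <- fx_ref_cohort()
    .fx$ref_profiles <- build_profiles(co$matrix, co$annot, fine_bin_scheme())
  }
  .fx$ref_profiles
}

fx_panel <- function() {
  if (is.null(.fx$panel))
    .fx$panel <- build_reference(fx_ref_profiles(), fx_ref_labels(),
                                 seed = 7)
  .fx$panel
}

# disjoint test cohort covering all four karyotypes
fx_test_cohort <- function() {
  if (is.null(.fx$test_cohort))
    .fx$test_cohort <- simulate_cohort(
      sim_config(n_XX = 40, n_XY = 40, n_XXY = 10, n_X0 = 10, seed = 43))
  .fx$test_cohort
}

fx_calls <- function() {
  if (is.null(.fx$calls)) {
    co <- fx_test_cohort()
    .fx$calls <- estimate_sex(co$matrix, co$annot, fx_panel(), seed = 44)
  }
  .fx$calls
}

# tiny hand-built methylation matrix: 4 chrX + 3 chrY + 2 autosomal probes
tiny_matrix <- function() {
  probes <- c(paste0("x", 1:4), paste0("y", 1:3), paste0("a", 1:2))
  beta <- matrix(c(0.05, 0.45, 0.55, 0.95, 0.02, 0.5, 0.98, 0.1, 0.9,
                   0.10, 0.50, 0.60, 0.90, 0.03, 0.4, 0.97, 0.2, 0.8),
                 ncol = 2, dimnames = list(probes, c("s1", "s2")))
  detp <- matrix(1e-8, nrow = 9, ncol = 2, dimnames = dimnames(beta))
  list(mat = methylation_matrix(beta, detp),
       annot = probe_annotation(probes, c(rep("chrX", 4), rep("chrY", 3),
                                          rep("1", 2))))
}

# brute-force per-value binning oracle (left-open/right-closed, first bin
# closed below)
brute_bin <- function(values, edges) {
  v <- values[!is.na(values)]
  counts <- numeric(length(edges) - 1L)
  for (x in v) {
    for (i in seq_len(length(edges) - 1L)) {
      if ((x > edges[i] && x <= edges[i + 1L]) || (i == 1L && x == edges[1L])) {
        counts[i] <- counts[i] + 1
        break
      }
    }
  }
  counts / length(v)
}

intermediate_mass <- function(beta_props, edges = seq(0, 1, by = 0.1)) {
  mid <- which(edges[-length(edges)] >= 0.2 & edges[-1L] <= 0.8)
  rowSums(beta_props[, mid, drop = FALSE])
}
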