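test_that("combine_calls implements the two-chromosome truth table", {
  expect_equal(combine_calls("f", "f"), "F")
  expect_equal(combine_calls("m", "m"), "M")
  expect_equal(combine_calls("f", "m"), "N")
  expect_equal(combine_calls("m", "f"), "N")
  expect_equal(combine_calls(c("f", "m", "f", "m"), c("f", "m", "m", "f")),
               c("F", "M", "N", "N"))
  expect_error(combine_calls("f", "x"), "'f' or 'm'")
})

test_that("pca_cluster assigns reference samples their own label", {
  prof <- fx_ref_profiles()
  labels <- fx_ref_labels()
  ax <- pca_cluster(cbind(prof$chrX_beta, prof$chrX_detp), labels, seed = 3)
  expect_equal(ax$assigned_sex, labels)
  expect_true(all(attr(ax, "purity") == 1))
  expect_false(attr(ax, "purity_warning"))
  # cluster 1 is the female-majority cluster; female PC1 averages negative
  expect_true(all(ax$cluster[labels == "f"] == 1L))
  expect_lt(mean(ax$pc1[labels == "f"]), mean(ax$pc1[labels == "m"]))
  expect_lt(mean(ax$pc1[labels == "f"]), 0)
})

test_that("pca_cluster places a test sample with its own sex, duplicates alike", {
  prof <- fx_ref_profiles()
  labels <- fx_ref_labels()
  feat <- cbind(prof$chrX_beta, prof$chrX_detp)
  xy <- simulate_cohort(sim_config(n_XY = 1, seed = 91))
  tprof <- build_profiles(xy$matrix, xy$annot, fine_bin_scheme())
  trow <- cbind(tprof$chrX_beta, tprof$chrX_detp)
  f2 <- rbind(feat, trow, trow)
  rownames(f2) <- c(rownames(feat), "t1", "t2")
  ax <- pca_cluster(f2, c(labels, "none", "none"), seed = 3)
  expect_equal(ax$assigned_sex[ax$sample_id %in% c("t1", "t2")], c("m", "m"))
  expect_equal(ax$pc1[ax$sample_id == "t1"], ax$pc1[ax$sample_id == "t2"])
  expect_error(pca_cluster(feat, rep("f", nrow(feat))), "each sex")
})

test_that("estimate_sex recovers every simulated karyotype", {
  co <- fx_test_cohort()
  calls <- fx_calls()
  expect_s3_class(calls, "sex_calls")
  expect_equal(nrow(calls), nrow(co$truth))
  expect_equal(calls$predicted, co$truth$expected_call)
  # aneuploidy signatures: XXY is female-like chrX + male-like chrY,
  # X0 is male-like chrX + female-like chrY
  xxy <- calls[co$truth$karyotype == "XXY", ]
  expect_true(all(xxy$sex_chrX == "f" & xxy$sex_chrY == "m"))
  x0 <- calls[co$truth$karyotype == "X0", ]
  expect_true(all(x0$sex_chrX == "m" & x0$sex_chrY == "f"))
  expect_true(all(calls$qc_passed))
})

test_that("estimate_sex is reproducible and order-invariant", {
  co <- fx_test_cohort()
  pan <- fx_panel()
  again <- estimate_sex(co$matrix, co$annot, pan, seed = 44)
  expect_identical(as.data.frame(fx_calls()), as.data.frame(again))
  set.seed(1)
  perm <- sample(ncol(co$matrix$beta))
  shuffled <- methylation_matrix(co$matrix$beta[, perm],
                                 co$matrix$detp[, perm])
  calls_p <- estimate_sex(shuffled, co$annot, pan, seed = 44)
  reord <- calls_p[match(fx_calls()$sample_id, calls_p$sample_id), ]
  expect_equal(reord$predicted, fx_calls()$predicted)
  expect_equal(reord$X.PC1, fx_calls()$X.PC1, tolerance = 1e-8)
})

test_that("an all-male test set is still classified correctly", {
  males <- simulate_cohort(sim_config(n_XY = 100, seed = 45))
  calls <- estimate_sex(males$matrix, males$annot, fx_panel(), seed = 46)
  expect_true(all(calls$predicted == "M"))
})

test_that("calls on clean cohorts are stable under wider beta bins", {
  co <- fx_test_cohort()
  wide <- bin_scheme(beta_edges = seq(0, 1, by = 0.2))
  calls5 <- estimate_sex(co$matrix, co$annot, fx_panel(), scheme = wide,
                         seed = 44)
  expect_equal(calls5$predicted, fx_calls()$predicted)
})

test_that("stronger X-inactivation signal widens the chrX separation", {
  margin <- function(w, seed) {
    co <- simulate_cohort(sim_config(n_XX = 15, n_XY = 15, seed = seed,
                                     female_intermediate_weight = w))
    calls <- estimate_sex(co$matrix, co$annot, fx_panel(), seed = 48)
    f <- co$truth$karyotype == "XX"
    mean(calls$X.PC1[!f]) - mean(calls$X.PC1[f])
  }
  expect_gt(margin(0.5, 47), margin(0.2, 47))
})

test_that("collapsing the sex difference degrades gracefully", {
  # female chrX intermediate weight at the male level: chrX no longer
  # separates the labelled cohort, and the build must say so (low-purity
  # warning or a failure to split the references) instead of crashing
  co <- simulate_cohort(sim_config(n_XX = 20, n_XY = 20, seed = 49,
                                   female_intermediate_weight = 0.08))
  prof <- build_profiles(co$matrix, co$annot, fine_bin_scheme())
  labels <- ifelse(co$truth$karyotype == "XX", "f", "m")
  expect_condition(
    pca_cluster(cbind(prof$chrX_beta, prof$chrX_detp), labels, seed = 50),
    regexp = "purity|separate|split")
})

test_that("detect_label_mismatch separates discordant from N-samples", {
  co <- fx_test_cohort()
  calls <- fx_calls()
  truth <- co$truth$expected_call
  flip <- flip_labels(truth, k = 5, seed = 51)
  labels <- stats::setNames(ifelse(flip$labels == "N", "unknown",
                                   flip$labels), co$truth$sample_id)
  res <- detect_label_mismatch(calls, labels)
  expect_setequal(res$discordant$sample_id,
                  co$truth$sample_id[flip$flipped])
  expect_equal(nrow(res$discordant), 5L)
  # every N-call is listed separately, never as discordant
  expect_setequal(res$n_samples$sample_id,
                  calls$sample_id[calls$predicted == "N"])
  expect_false(any(res$n_samples$sample_id %in% res$discordant$sample_id))
  expect_error(detect_label_mismatch(calls, c(nosuch = "F")), "unknown sample")
  # a label on an N-called sample is not discordant even if it is F or M
  lab_n <- stats::setNames(rep("F", nrow(calls)), calls$sample_id)
  res2 <- detect_label_mismatch(calls, lab_n)
  expect_false(any(res2$discordant$predicted == "N"))
})
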