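test_that("identity rebin returns the stored fine tables", {
  pan <- fx_panel()
  re <- rebin(pan, fine_bin_scheme())
  expect_equal(unname(re$chrX_beta), unname(pan$chrX_beta))
  expect_equal(unname(re$chrY_detp), unname(pan$chrY_detp))
})

test_that("rebin equals direct binning of the raw values at the coarse scheme", {
  co <- fx_ref_cohort()
  labels <- fx_ref_labels()
  pan <- fx_panel()
  for (scheme in list(bin_scheme(),
                      bin_scheme(beta_edges = seq(0, 1, by = 0.2)))) {
    direct <- build_profiles(co$matrix, co$annot, scheme)
    re <- rebin(pan, scheme)
    ids <- re$sample_ids
    for (block in c("chrX_beta", "chrX_detp", "chrY_beta", "chrY_detp"))
      expect_equal(unname(re[[block]]),
                   unname(direct[[block]][ids, , drop = FALSE]),
                   tolerance = 1e-12)
    expect_true(all(abs(rowSums(re$chrX_beta) - 1) < 1e-9))
  }
})

test_that("misaligned edges are rejected by name, never interpolated", {
  pan <- fx_panel()
  expect_error(rebin(pan, bin_scheme(beta_edges = c(0, 0.155, 1))), "0.155")
  expect_error(rebin(pan, bin_scheme(detp_edges = c(0, 3e-4, 1))), "detp")
  # aligned decade edges are fine
  expect_silent(rebin(pan, bin_scheme(detp_edges = c(0, 1e-8, 1e-2, 1))))
})

test_that("build_reference recovers the labelled structure of the cohort", {
  pan <- fx_panel()
  conc <- pan$concordance
  n_f <- sum(fx_ref_labels() == "f")
  n_m <- sum(fx_ref_labels() == "m")
  expect_equal(sum(conc), n_f + n_m)
  expect_gte(conc["Female", "1/1"], ceiling(0.99 * n_f))
  expect_gte(conc["Male", "2/2"], ceiling(0.99 * n_m))
  # floor(retention_fraction * n) retained per concordant cluster
  expect_equal(sum(pan$sex == "f"), floor(0.875 * conc["Female", "1/1"]))
  expect_equal(sum(pan$sex == "m"), floor(0.875 * conc["Male", "2/2"]))
  expect_true(all(abs(rowSums(pan$chrX_beta) - 1) < 1e-9))
})

test_that("retention keeps exactly the samples closest to the cluster centres", {
  prof <- fx_ref_profiles()
  labels <- fx_ref_labels()
  half <- build_reference(prof, labels, retention_fraction = 0.5, seed = 7)
  full <- build_reference(prof, labels, retention_fraction = 1.0, seed = 7)
  # sort-based oracle: recompute the per-axis distances with the same seeds
  ax <- pca_cluster(cbind(prof$chrX_beta, prof$chrX_detp), labels, seed = 7)
  ay <- pca_cluster(cbind(prof$chrY_beta, prof$chrY_detp), labels, seed = 8)
  dist <- sqrt(ax$dist_to_centre^2 + ay$dist_to_centre^2)
  cell <- paste(ax$cluster, ay$cluster, sep = "/")
  for (sx in c("f", "m")) {
    own <- if (sx == "f") "1/1" else "2/2"
    grp <- which(labels == sx & cell == own)
    retained <- prof$sample_ids[grp] %in%
      rownames(half$chrX_beta)[half$sex == sx]
    expect_equal(sum(retained), floor(0.5 * length(grp)))
    expect_lte(max(dist[grp][retained]), min(dist[grp][!retained]))
    # retention 1.0 keeps every concordant sample
    expect_setequal(rownames(full$chrX_beta)[full$sex == sx],
                    prof$sample_ids[grp])
  }
})

test_that("build_reference is reproducible and validates its inputs", {
  prof <- fx_ref_profiles()
  labels <- fx_ref_labels()
  p1 <- build_reference(prof, labels, seed = 7)
  p2 <- build_reference(prof, labels, seed = 7)
  expect_identical(p1, p2)
  expect_error(build_reference(prof, labels, retention_fraction = 0), "\\(0, 1]")
  expect_error(build_reference(prof, rep("f", length(labels))), "4 labelled")
  coarse <- build_profiles(fx_ref_cohort()$matrix, fx_ref_cohort()$annot,
                           bin_scheme())
  expect_error(build_reference(coarse, labels), "fine")
})

test_that("panel bundles round-trip through the tab-separated format", {
  pan <- fx_panel()
  dir <- withr::local_tempdir()
  write_reference(pan, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "panel_meta.tsv", "chrX_beta.tsv", "chrX_detp.tsv",
    "chrY_beta.tsv", "chrY_detp.tsv")))))
  back <- read_reference(dir)
  expect_equal(back$sex, pan$sex)
  expect_equal(back$scheme$beta_edges, pan$scheme$beta_edges)
  expect_equal(back$scheme$detp_edges, pan$scheme$detp_edges)
  expect_equal(back$chrX_beta, pan$chrX_beta, tolerance = 1e-8)
  expect_equal(back$chrY_detp, pan$chrY_detp, tolerance = 1e-8)
  expect_equal(back$meta$retention_fraction, pan$meta$retention_fraction)
})
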