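test_that("build_profiles produces per-chromosome proportion vectors", {
  tm <- tiny_matrix()
  prof <- build_profiles(tm$mat, tm$annot)
  expect_s3_class(prof, "sex_profiles")
  expect_equal(dim(prof$chrX_beta), c(2L, 10L))
  expect_equal(dim(prof$chrY_detp), c(2L, 3L))
  # all detp simulated at 1e-8 <= 1e-5: whole mass in the first detp bin
  expect_equal(unname(prof$chrY_detp[1, ]), c(1, 0, 0))
  expect_equal(unname(prof$n_used[1, ]), c(4L, 4L, 3L, 3L))
  # s1 chrX betas 0.05/0.45/0.55/0.95 -> bins 1, 5, 6, 10
  expect_equal(unname(prof$chrX_beta[1, ]),
               c(0.25, 0, 0, 0, 0.25, 0.25, 0, 0, 0, 0.25))
})

test_that("every profile row is a proper distribution", {
  prof <- fx_ref_profiles()
  for (block in c("chrX_beta", "chrX_detp", "chrY_beta", "chrY_detp")) {
    m <- prof[[block]]
    expect_true(all(m >= 0))
    expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  }
})

test_that("profiles are deterministic and permutation-invariant", {
  tm <- tiny_matrix()
  # identical value vectors give identical profile rows
  beta <- tm$mat$beta[, c(1, 1)]
  colnames(beta) <- c("a", "b")
  detp <- tm$mat$detp[, c(1, 1)]
  colnames(detp) <- c("a", "b")
  prof <- build_profiles(methylation_matrix(beta, detp), tm$annot)
  expect_equal(prof$chrX_beta[1, ], prof$chrX_beta[2, ],
               ignore_attr = TRUE)
  # permuting probe order leaves profiles unchanged
  perm <- rev(seq_len(nrow(tm$mat$beta)))
  mat2 <- methylation_matrix(tm$mat$beta[perm, ], tm$mat$detp[perm, ])
  prof0 <- build_profiles(tm$mat, tm$annot)
  prof2 <- build_profiles(mat2, tm$annot)
  expect_equal(prof2$chrX_beta, prof0$chrX_beta)
  # permuting sample order permutes profile rows correspondingly
  mat3 <- methylation_matrix(tm$mat$beta[, 2:1], tm$mat$detp[, 2:1])
  prof3 <- build_profiles(mat3, tm$annot)
  expect_equal(prof3$chrX_beta, prof0$chrX_beta[2:1, ])
})

test_that("female chrX profiles carry more intermediate mass than male ones", {
  co <- fx_ref_cohort()
  prof <- build_profiles(co$matrix, co$annot, bin_scheme())
  f <- fx_ref_labels() == "f"
  mass <- intermediate_mass(prof$chrX_beta)
  expect_gt(min(mass[f]), max(mass[!f]))
})

test_that("missing chromosomes are reported by name", {
  tm <- tiny_matrix()
  no_y <- probe_annotation(tm$annot$probe_id,
                           ifelse(tm$annot$chromosome == "chrY", "1",
                                  as.character(tm$annot$chromosome)))
  expect_error(build_profiles(tm$mat, no_y), "chrY")
})

test_that("qc_filter applies the strict >5% chrX failure rule", {
  n <- 100
  probes <- sprintf("x%03d", 1:n)
  mk <- function(n_fail) {
    detp <- matrix(1e-6, nrow = n, ncol = 1,
                   dimnames = list(probes, "s"))
    detp[seq_len(n_fail), 1] <- 0.5
    beta <- matrix(0.5, nrow = n, ncol = 1, dimnames = dimnames(detp))
    methylation_matrix(beta, detp)
  }
  annot <- probe_annotation(probes, rep("X", n))
  qc6 <- qc_filter(mk(6), annot)
  expect_equal(qc6$frac_chrX_failed, 0.06)
  expect_false(qc6$passed)
  qc5 <- qc_filter(mk(5), annot)
  expect_equal(qc5$frac_chrX_failed, 0.05)
  expect_true(qc5$passed)   # exactly 5% is retained
  qc0 <- qc_filter(mk(0), annot)
  expect_equal(qc0$frac_chrX_failed, 0)
  expect_true(qc0$passed)
  # a probe at exactly the cutoff fails; missing p-values count as failures
  m <- mk(0)
  m$detp[1, 1] <- 0.01
  m$detp[2, 1] <- NA
  expect_equal(qc_filter(m, annot)$frac_chrX_failed, 0.02)
  expect_error(qc_filter(mk(0), probe_annotation(probes, rep("1", n))),
               "chrX")
})
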