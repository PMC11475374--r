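test_that("default preset reproduces the study design", {
  co <- generate_cohort(paper_like_preset(), seed = 1)
  expect_equal(nrow(co), 60L)
  expect_equal(length(unique(co$mouse_id)), 15L)
  expect_setequal(unique(co$roi), c("genu", "midbody", "splenium", "fornix"))
  tr <- cohort_truth(co)
  expect_equal(sum(tr$group == 1), 48L)
  expect_equal(sum(tr$group == 2), 12L)
  expect_equal(as.vector(table(co$genotype)[c("Control", "Pten", "Rictor",
                                              "Tsc2")]) / 4,
               c(6, 3, 3, 3))
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- paper_like_preset()
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(cohort_truth(a), cohort_truth(b))
  c <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a$fAW_WMTI, c$fAW_WMTI))
  # generation does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generate_cohort(cfg, seed = 7)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("latent tissue fractions close to 1 and observations validate", {
  co <- generate_cohort(paper_like_preset(), seed = 2)
  tr <- cohort_truth(co)
  expect_true(all(abs(tr$fA_M + tr$fA_U + tr$fM + tr$fE - 1) < 1e-12))
  expect_equal(nrow(validate_cohort(as.data.frame(co))), 0L)
})

test_that("noiseless generation satisfies the central calibration identity", {
  cfg <- noiseless_variant(synthetic_config(fA_U_group = c(0.05, 0.25),
                                            s_true = 0.8))
  co <- generate_cohort(cfg, seed = 3)
  tr <- cohort_truth(co)
  # EM observes the latent fractions exactly
  expect_equal(co$fA_EM, tr$fA_M, tolerance = 1e-12)
  expect_equal(co$fM_EM, tr$fM, tolerance = 1e-12)
  # calibrating with (s_true, U = group fA_U) recovers fA_M exactly
  U <- cfg$fA_U_group[tr$group]
  cal <- apply_calibration(co$fAW_WMTI, co$fM_EM, s = 0.8, U = U)
  expect_equal(cal, tr$fA_M, tolerance = 1e-10)
})

test_that("injected outlier rates are recovered by the filter counts", {
  cfg <- synthetic_config(outlier_rates = c(neg = 0.1, gt1 = 0.08, nan = 0.06),
                          voxel_count_range = c(40L, 60L))
  co <- generate_cohort(cfg, seed = 4)
  tr <- cohort_truth(co)
  # aggregate rates within ~3 binomial SDs of the configured rates
  n_vox_expected <- 60 * 50 # 60 ROIs x mean voxel count
  for (cat in c("neg", "gt1", "nan")) {
    k <- sum(tr[[paste0("rejected_", cat)]])
    p <- cfg$outlier_rates[[cat]]
    expect_lt(abs(k - n_vox_expected * p), 3 * sqrt(n_vox_expected * p * (1 - p)) +
                0.1 * n_vox_expected * p)
  }
})

test_that("impossible tissue configurations fail loudly", {
  cfg <- synthetic_config(fA_M_mean = c(Control = 0.5, Pten = 0.5,
                                        Rictor = 0.5, Tsc2 = 0.5),
                          fM_mean = c(Control = 0.45, Pten = 0.45,
                                      Rictor = 0.45, Tsc2 = 0.45),
                          fA_U_group = c(0.2, 0.2))
  expect_error(generate_cohort(cfg, seed = 5), "extracellular fraction")
})

test_that("s_true can be routed through the relaxation model", {
  sf <- signal_fractions(nu = 0.475)
  t2 <- synthetic_t2_profile(sf, TE = 19, s_target = 0.89)
  cfg <- noiseless_variant(synthetic_config(
    s_true = list(sf = sf, t2 = t2, TE = 19), fA_U_group = c(0, 0.2)))
  co <- generate_cohort(cfg, seed = 6)
  expect_equal(provenance(co)$s_true, 0.89, tolerance = 1e-9)
  fit <- fit_combo(assign_truth_groups(co), "WMTI",
                   calibration_combo(c("U2", "s")))
  expect_equal(fit$s, 0.89, tolerance = 1e-4)
})

test_that("multiple DWI channels carry their own scalings", {
  cfg <- noiseless_variant(synthetic_config(
    models = list(WMTI = list(s_true = 0.7), NODDI = list(s_true = 1.1)),
    fA_U_group = c(0, 0.2)))
  co <- generate_cohort(cfg, seed = 7)
  expect_setequal(dwi_models(co), c("WMTI", "NODDI"))
  co <- assign_truth_groups(co)
  expect_equal(fit_combo(co, "WMTI", calibration_combo(c("U2", "s")))$s,
               0.7, tolerance = 1e-4)
  expect_equal(fit_combo(co, "NODDI", calibration_combo(c("U2", "s")))$s,
               1.1, tolerance = 1e-4)
})
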