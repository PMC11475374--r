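test_that("calibration arithmetic, RSS and BIC match hand evaluation", {
  expect_equal(apply_calibration(0.5, 0, s = 1, U = 0), 0.5)
  expect_equal(apply_calibration(0.5, 0.3, s = 0.8, U = 0.1),
               0.7 * 0.8 * 0.5 - 0.1, tolerance = 1e-15)
  expect_equal(apply_calibration(0.5, 0.3, s = 0.8, U = 0.7 * 0.8 * 0.5), 0)

  expect_equal(rss(c(0.3, 0.4), c(0.2, 0.6)), 0.05)
  expect_equal(rss(c(1, 2), c(1, 2)), 0)
  v1 <- runif(5); v2 <- runif(5); p <- sample(5)
  expect_equal(rss(v1, v2), rss(v1[p], v2[p]))
  expect_error(rss(1:3, 1:2), "length mismatch")

  expect_equal(bic(2, 60, 0.6), 2 * log(60) + 60 * log(0.01), tolerance = 1e-12)
  expect_equal(bic(0, 60, 0.6), 60 * log(0.01), tolerance = 1e-12)
  expect_equal(bic(3, 60, 0.6) - bic(2, 60, 0.6), log(60), tolerance = 1e-12)
  expect_identical(as.numeric(bic(2, 60, 0)), -Inf)
  expect_true(attr(bic(2, 60, 0), "perfect_fit"))
})

test_that("delta BIC is zero for the baseline and has the right sign", {
  co <- assign_truth_groups(generate_cohort(paper_like_preset(), seed = 8))
  base <- fit_combo(co, "WMTI", calibration_combo())
  expect_equal(delta_bic(base, base), 0)
  best <- fit_combo(co, "WMTI", calibration_combo(c("U2", "s")))
  expect_lt(delta_bic(best, base), 0)
  # identical RSS with k = 2 costs exactly 2 ln n
  fake <- base; fake$k <- 2L
  fake$BIC <- as.numeric(bic(2, base$n, base$RSS))
  expect_equal(delta_bic(fake, base), 2 * log(60), tolerance = 1e-12)
  small <- base; small$n <- 10L
  expect_error(delta_bic(small, base), "n mismatch")
})

test_that("noiseless cohorts are recovered exactly", {
  cfg <- noiseless_variant(synthetic_config(fA_U_group = c(0, 0.2),
                                            s_true = 0.75))
  co <- assign_truth_groups(generate_cohort(cfg, seed = 1))
  fit <- fit_combo(co, "WMTI", calibration_combo(c("U2", "s")))
  expect_equal(fit$U2, 0.2, tolerance = 1e-4)
  expect_equal(fit$s, 0.75, tolerance = 1e-4)
  expect_lt(fit$RSS, 1e-10)
  expect_true(fit$perfect_fit || fit$RSS < 1e-10)

  base <- fit_combo(co, "WMTI", calibration_combo())
  d <- dwi_axonal_volume(co$fAW_WMTI, co$fM_EM)
  expect_equal(base$RSS, rss(co$fA_EM, d), tolerance = 1e-12)
  expect_gt(base$RSS, 0)
  # the true-combo BIC cannot be worse than the baseline's
  expect_lte(as.numeric(bic(2, fit$n, max(fit$RSS, .Machine$double.eps))),
             base$BIC)
})

test_that("fits never lose to the exhaustive grid oracle", {
  combos <- all_combos()
  for (i in 1:4) {
    cfg <- synthetic_config(
      fA_U_group = c(0, runif(1, 0.05, 0.3)),
      s_true = runif(1, 0.55, 1.2),
      voxel_noise_sd = 0.03, em_noise_sd = 0.02)
    co <- assign_truth_groups(generate_cohort(cfg, seed = 100 + i))
    for (cb in combos) {
      fit <- fit_combo(co, "WMTI", cb)
      n_grid <- if (length(cb$free) == 3) 41L else 201L
      oracle <- grid_rss_oracle(co, "WMTI", cb, n_grid)
      expect_lte(fit$RSS, oracle + 1e-9)
    }
  }
})

test_that("nested combinations never fit worse", {
  co <- assign_truth_groups(generate_cohort(paper_like_preset(), seed = 21))
  combos <- all_combos()
  fits <- lapply(combos, function(cb) fit_combo(co, "WMTI", cb))
  for (a in names(combos)) {
    for (b in names(combos)) {
      if (all(combos[[a]]$free %in% combos[[b]]$free)) {
        expect_lte(fits[[b]]$RSS, fits[[a]]$RSS + 1e-9)
      }
    }
  }
  # and every solution respects bounds and the volume constraint
  for (f in fits) {
    expect_true(f$U1 >= 0 && f$U1 <= 1 && f$U2 >= 0 && f$U2 <= 1)
    expect_true(f$s >= 0 && f$s <= 2)
    cal <- apply_calibration(co$fAW_WMTI, co$fM_EM, s = f$s,
                             U = ifelse(co$group == 1, f$U1, f$U2))
    expect_lte(max(cal + co$fM_EM - 1), 1e-9)
  }
})

test_that("stochastic recovery stays within the noise-derived tolerance", {
  grid <- expand.grid(U2 = c(0.1, 0.2), s = c(0.6, 0.8, 1.1))
  err_u2 <- err_s <- c()
  for (r in seq_len(nrow(grid))) {
    for (rep in 1:5) {
      cfg <- synthetic_config(fA_U_group = c(0, grid$U2[r]),
                              s_true = grid$s[r], voxel_noise_sd = 0.02)
      co <- assign_truth_groups(generate_cohort(cfg, seed = 1000 * r + rep))
      fit <- fit_combo(co, "WMTI", calibration_combo(c("U2", "s")))
      err_u2 <- c(err_u2, abs(fit$U2 - grid$U2[r]))
      err_s <- c(err_s, abs(fit$s - grid$s[r]))
    }
  }
  expect_lt(mean(err_u2), 0.05)
  expect_lt(mean(err_s), 0.05)
})

test_that("select_best ranks by delta BIC with parsimony tie-breaks", {
  co <- assign_truth_groups(generate_cohort(paper_like_preset(), seed = 31))
  ranked <- select_best(co, "WMTI")
  expect_equal(ranked[[1]]$combo$name, "{U2,s}")
  dbic <- vapply(ranked, `[[`, 0, "delta_BIC")
  expect_true(all(diff(dbic) >= -1e-12))
  expect_equal(dbic[["{}"]], 0)
  # pure-scaling cohort: {s} wins
  cfg_s <- synthetic_config(fA_U_group = c(0, 0), s_true = 0.7)
  co_s <- assign_truth_groups(generate_cohort(cfg_s, seed = 32))
  expect_equal(select_best(co_s, "WMTI")[[1]]$combo$name, "{s}")
  # zero-effect cohort: baseline wins
  co_0 <- assign_truth_groups(generate_cohort(zero_effect_preset(), seed = 33))
  expect_equal(select_best(co_0, "WMTI")[[1]]$combo$name, "{}")
})

test_that("leave-one-out removes whole mice and reports fold spread", {
  co <- assign_truth_groups(generate_cohort(paper_like_preset(), seed = 41))
  combo <- calibration_combo(c("U2", "s"))
  loo <- leave_one_out(co, "WMTI", combo)
  expect_length(loo$per_fold, 15)
  expect_equal(nrow(loo$estimates), 15)
  for (m in names(loo$per_fold)) {
    expect_equal(loo$per_fold[[m]]$n, 56) # 60 - 4 ROIs of one mouse
  }
  # SD equals direct recomputation from the fold estimates
  expect_equal(loo$sd[["U2"]], sd(loo$estimates[, "U2"]), tolerance = 1e-12)
  expect_equal(loo$sd[["s"]], sd(loo$estimates[, "s"]), tolerance = 1e-12)

  # noiseless cohort: zero spread
  co0 <- assign_truth_groups(generate_cohort(
    noiseless_variant(paper_like_preset()), seed = 42))
  loo0 <- leave_one_out(co0, "WMTI", combo)
  expect_lt(max(loo0$sd), 1e-6)
})

test_that("hybrid calibration fixes s and recovers the offset", {
  cfg <- noiseless_variant(synthetic_config(fA_U_group = c(0, 0.2),
                                            s_true = 0.75))
  co <- assign_truth_groups(generate_cohort(cfg, seed = 51))
  hyb <- hybrid_fit(co, "WMTI", free = "U2", fixed_s = 0.75)
  expect_equal(hyb$U2, 0.2, tolerance = 1e-4)
  expect_equal(hyb$s, 0.75)
  expect_equal(hyb$k, 1L)

  # equivalent to a grid over U2 with s clamped
  noisy <- assign_truth_groups(generate_cohort(
    synthetic_config(fA_U_group = c(0, 0.2), s_true = 0.75), seed = 52))
  h2 <- hybrid_fit(noisy, "WMTI", free = "U2", fixed_s = 0.8)
  oracle <- grid_rss_oracle(noisy, "WMTI",
                            calibration_combo("U2", fixed_s = 0.8), 2001L)
  expect_lte(h2$RSS, oracle + 1e-9)
  # mismatched fixed s can only fit worse than the free {U2,s} fit
  free_fit <- fit_combo(noisy, "WMTI", calibration_combo(c("U2", "s")))
  expect_gte(h2$RSS, free_fit$RSS - 1e-12)
  expect_error(hybrid_fit(co, "WMTI", free = c("U2", "s"), fixed_s = 1),
               "fixed in hybrid")
})

test_that("external slope/offset regressions convert to s and U", {
  conv <- convert_external_slope_offset(slope = 0.7, offset = 0,
                                        fM_EM = 0.3, fA_U = 0)
  expect_equal(conv$s_equiv, 1)
  expect_equal(conv$U_equiv, 0)
  conv2 <- convert_external_slope_offset(0.7, 0.1, 0.3, 0.05)
  expect_equal(conv2$s_equiv, 1)
  expect_equal(conv2$U_equiv, 0.05, tolerance = 1e-12)
  expect_error(convert_external_slope_offset(0, 0.1, 0.3, 0), "nonzero")
})
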