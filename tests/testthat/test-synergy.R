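test_that("median-effect fit recovers noiseless generative parameters", {
  tab <- gen_dose_response(1, 2, c(0.25, 0.5, 1, 2, 4))
  fit <- median_effect(tab)
  expect_equal(fit$Dm, 1, tolerance = 1e-10)
  expect_equal(fit$m, 2, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-10)

  fit2 <- median_effect(gen_dose_response(10, 0.8, c(1, 3, 10, 30, 100)))
  expect_equal(unname(coef(fit2)), c(10, 0.8), tolerance = 1e-10)

  # two points: exact interpolating line
  fit3 <- median_effect(dose_response(c(1, 4), c(0.3, 0.7)))
  expect_equal(predict(fit3, c(1, 4)), c(0.3, 0.7), tolerance = 1e-10)

  expect_error(median_effect(dose_response(c(2, 2, 2) + 0, c(0.2, 0.5, 0.8))),
               "distinct doses")
  expect_error(median_effect(dose_response(c(1, 2, 4), c(0.5, 0.5, 0.5))),
               "flat")
})

test_that("noisy median-effect fits stay within 5% median relative error", {
  errs <- vapply(1:200, function(s) {
    tab <- gen_dose_response(2, 1.5, c(0.25, 0.5, 1, 2, 4, 8),
                             noise_sigma = 0.05, seed = s)
    fit <- median_effect(tab)
    max(abs(fit$Dm - 2) / 2, abs(fit$m - 1.5) / 1.5)
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("dose_for_effect inverts the fitted curve", {
  fit <- median_effect(gen_dose_response(1, 1, c(0.1, 0.3, 1, 3, 10)))
  expect_equal(dose_for_effect(fit, 0.5), fit$Dm, tolerance = 1e-12)
  expect_equal(dose_for_effect(fit, 0.75), 3, tolerance = 1e-10)
  # inverse map at arbitrary levels
  fas <- c(0.1, 0.25, 0.5, 0.9)
  expect_equal(predict(fit, dose_for_effect(fit, fas)), fas, tolerance = 1e-10)
  expect_lt(dose_for_effect(fit, 0.25), dose_for_effect(fit, 0.75))
  expect_error(dose_for_effect(fit, 1), "inside")
})

test_that("DRI and CI follow their defining identities", {
  expect_equal(compute_dri(10, 5), 2)
  expect_equal(compute_dri(7, 7), 1)
  expect_equal(compute_dri(7.78, 0.55), 14.145, tolerance = 1e-3)
  expect_error(compute_dri(-1, 2), "> 0")
  expect_equal(compute_ci(2, 2), 1)
  expect_equal(round(compute_ci(3.162, 3.020), 3), 0.647)
  expect_error(compute_ci(0, 1), "> 0")
})

test_that("classification uses the standard CI convention", {
  expect_identical(classify_synergy(0.647), "synergism")
  expect_identical(classify_synergy(1.0), "additive")
  expect_identical(classify_synergy(1.5), "antagonism")
  expect_identical(classify_synergy(c(0.5, 1.01, 1.2)),
                   c("synergism", "additive", "antagonism"))
})

test_that("Loewe-additive construction yields CI = 1; scaled yields the target", {
  fit_a <- median_effect(gen_dose_response(1, 2, c(0.25, 0.5, 1, 2, 4)))
  fit_b <- median_effect(gen_dose_response(4, 2, c(1, 2, 4, 8, 16)))
  doses <- c(0.4, 0.8, 1.6, 3.2, 6.4)
  for (tgt in c(1, 0.5)) {
    combo <- gen_combo_table(fit_a, fit_b, ratio_a = 0.5, ci_target = tgt,
                             doses = doses)
    fit_c <- median_effect(combo)
    sc <- synergy_curve(fit_a, fit_b, fit_c, ratio_a = 0.5)
    expect_equal(sc$ci, rep(tgt, 3), tolerance = 0.02)
    expect_true(all(abs(1 / sc$dri_a + 1 / sc$dri_b - sc$ci) < 1e-12))
  }
  # unequal slopes: construction solved numerically, still near-additive
  fit_b2 <- median_effect(gen_dose_response(4, 1.4, c(1, 2, 4, 8, 16)))
  combo2 <- gen_combo_table(fit_a, fit_b2, ratio_a = 1 / 3, ci_target = 1,
                            doses = doses)
  sc2 <- synergy_curve(fit_a, fit_b2, median_effect(combo2), ratio_a = 1 / 3)
  expect_equal(sc2$ci, rep(1, 3), tolerance = 0.05)
  expect_true(all(sc2$call != "antagonism" | sc2$ci <= 1.05))
})
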