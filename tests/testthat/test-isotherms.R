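test_that("isotherm forms evaluate correctly on their domains", {
  lang <- isotherm_model("langmuir", q_max = 1000, b = 0.01)
  # Henry limit: q ~ q_max * b * ce at low concentration
  expect_equal(eval_isotherm(lang, 0.001), 1000 * 0.01 * 0.001,
               tolerance = 1e-4)
  # Freundlich with exponent 1 is linear with K = K_F
  fr <- isotherm_model("freundlich", K_F = 123, one_over_n = 1)
  li <- isotherm_model("linear", K = 123)
  ce <- c(0.01, 0.1, 0.5, 2)
  expect_equal(eval_isotherm(fr, ce), eval_isotherm(li, ce))
  # BET diverges monotonically approaching saturation
  bet <- isotherm_model("bet", q_m = 500, K_B = 50, c_s = 1.0)
  ce_near <- c(0.9, 0.99, 0.999, 0.9999)
  q_near <- eval_isotherm(bet, ce_near)
  expect_true(all(diff(q_near) > 0))
  expect_gt(q_near[4], 1e5)
  expect_error(eval_isotherm(bet, 1.0), "c_s")
  # all models pass through the origin and increase strictly
  for (m in list(lang, fr, li, bet)) {
    expect_equal(eval_isotherm(m, 0), 0)
    grid <- seq(0.01, 0.9, by = 0.01)
    expect_true(all(diff(eval_isotherm(m, grid)) > 0))
  }
})

test_that("parameter validation rejects non-positive values", {
  expect_error(isotherm_model("linear", K = -1), "positive")
  expect_error(isotherm_model("freundlich", K_F = 1), "one_over_n")
})

test_that("the eligibility rule needs five points spanning a factor of five", {
  expect_true(check_eligibility(seq(0.05, 0.6, length.out = 6))$eligible)
  four <- check_eligibility(c(0.1, 0.2, 0.4, 0.8))
  expect_false(four$eligible)
  expect_match(four$reason, "fewer than 5")
  narrow <- check_eligibility(c(0.10, 0.2, 0.3, 0.4, 0.45))
  expect_false(narrow$eligible)
  expect_match(narrow$reason, "span 4.5")
  # complete-removal points are excluded before the count
  with_zero <- check_eligibility(c(0, 0.1, 0.2, 0.4, 0.8))
  expect_false(with_zero$eligible)
  expect_match(with_zero$reason, "complete-removal")
})

test_that("noiseless synthetic data returns the generating parameters", {
  cases <- list(
    isotherm_model("freundlich", K_F = 2000, one_over_n = 1.2),
    isotherm_model("freundlich", K_F = 3.0, one_over_n = 1.2),
    isotherm_model("langmuir", q_max = 800, b = 2.0),
    isotherm_model("bet", q_m = 500, K_B = 50, c_s = 1.5),
    isotherm_model("linear", K = 20000)
  )
  for (truth in cases) {
    ds <- generate_batch(batch_truth(truth, noise_cv = 0))
    fit <- fit_isotherm(sorption_point(ds), truth$kind, force = TRUE)
    expect_equal(unlist(fit$model$parameters),
                 unlist(truth$parameters),
                 tolerance = 1e-3, label = truth$kind)
    expect_gt(fit$r_squared, 0.999999)
  }
})

test_that("the multilayer flag follows the Freundlich exponent and BET fit", {
  fr <- fit_isotherm(sorption_point(generate_batch(batch_truth(
    isotherm_model("freundlich", K_F = 2000, one_over_n = 1.2),
    noise_cv = 0))), "freundlich", force = TRUE)
  expect_true(fr$multilayer_flag)
  fr2 <- fit_isotherm(sorption_point(generate_batch(batch_truth(
    isotherm_model("freundlich", K_F = 2000, one_over_n = 0.8),
    noise_cv = 0))), "freundlich", force = TRUE)
  expect_false(fr2$multilayer_flag)
  bet <- fit_isotherm(sorption_point(generate_batch(batch_truth(
    isotherm_model("bet", q_m = 500, K_B = 50, c_s = 1.5),
    noise_cv = 0))), "bet", force = TRUE)
  expect_true(bet$multilayer_flag)
})

test_that("ineligible series only fit under force and stay marked", {
  pts <- list(ce = c(0.1, 0.2, 0.4), q = c(200, 380, 700))
  expect_error(fit_isotherm(pts, "linear"), "eligible")
  fit <- fit_isotherm(pts, "linear", force = TRUE)
  expect_false(fit$eligible)
})

test_that("Freundlich fit of linear-truth data returns an exponent of 1 within SE", {
  for (seed in 1:5) {
    ds <- generate_batch(batch_truth(isotherm_model("linear", K = 2000),
                                     noise_cv = 0.02, seed = seed))
    fit <- fit_isotherm(sorption_point(ds), "freundlich", force = TRUE)
    n_hat <- fit$model$parameters$one_over_n
    se <- fit$std_errors[["one_over_n"]]
    expect_lt(abs(n_hat - 1), 3 * se + 0.05)
  }
})

test_that("Langmuir truth with small noise never fits worse than linear", {
  ce <- c(0.02, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0)
  truth <- isotherm_model("langmuir", q_max = 800, b = 2)
  for (seed in 1:10) {
    q <- withr::with_seed(seed,
      eval_isotherm(truth, ce) * exp(rnorm(length(ce), 0, 0.02)))
    pts <- list(ce = ce, q = q)
    rss_lang <- fit_isotherm(pts, "langmuir")$rss
    rss_lin <- fit_isotherm(pts, "linear")$rss
    expect_lte(rss_lang, rss_lin * (1 + 1e-8))
  }
})

test_that("Langmuir parameters are recovered from noisy points, median error under 20%", {
  ce <- c(0.02, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0)
  truth <- isotherm_model("langmuir", q_max = 800, b = 2)
  errs <- vapply(1:50, function(seed) {
    q <- withr::with_seed(seed,
      eval_isotherm(truth, ce) * exp(rnorm(length(ce), 0, 0.05)))
    fit <- fit_isotherm(list(ce = ce, q = q), "langmuir")
    max(abs(unlist(fit$model$parameters) / c(800, 2) - 1))
  }, numeric(1))
  expect_lt(median(errs), 0.2)
})

test_that("model ranking reports AICc ties as a set", {
  ds <- generate_batch(batch_truth(
    isotherm_model("langmuir", q_max = 800, b = 2), noise_cv = 0.03,
    seed = 3))
  ranked <- fit_isotherms(sorption_point(ds), force = TRUE)
  expect_true(all(c("kind", "rss", "aicc") %in% names(ranked$table)))
  expect_true(length(ranked$best) >= 1)
  expect_true(all(ranked$best %in% ranked$table$kind))
})
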