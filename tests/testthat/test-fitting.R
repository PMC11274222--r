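test_that("initial guesses sit near the trace's observable anchors", {
  tr <- make_fo_trace(1.0, 200, y0 = 0.3, times = 0:1000)
  g <- initial_guesses(tr, "FO1")
  expect_lt(abs(g$y0 - 0.3), 1e-2)          # trace floor = y0 + A e^-5
  expect_gt(g$amplitudes[1], 0.5)

  flat <- kinetic_trace(0:99, rep(1.0, 100), radical = "DPPH")
  gs <- initial_guesses(flat, "SO")
  expect_equal(gs$ar0, 1.0)
  expect_equal(gs$k, 1e-6)                  # zero slope hits the floor

  short <- kinetic_trace(0:3, c(1, 0.9, 0.85, 0.84), radical = "DPPH")
  expect_error(initial_guesses(short, "FO3"),
               class = "radkin_insufficient_data_error")
  expect_error(fit_kinetics(short, "FO3"),
               class = "radkin_insufficient_data_error")
})

test_that("noiseless second-order traces are recovered essentially exactly", {
  tr <- make_so_trace(k = 0.01, ar0 = 1.0, aah0 = 1.5, times = 0:1000)
  fit <- fit_kinetics(tr, "SO")
  est <- coef(fit)
  expect_true(fit$converged)
  expect_lt(abs(est[["k"]] - 0.01) / 0.01, 1e-4)
  expect_lt(abs(est[["ar0"]] - 1.0), 1e-4)
  expect_lt(abs(est[["aah0"]] - 1.5) / 1.5, 1e-4)
  expect_gte(fit$r_squared, 1 - 1e-10)
  expect_lt(fit$regression_pvalue, 1e-10)
})

test_that("noiseless biexponential traces are recovered fastest-first", {
  tr <- make_fo_trace(c(0.5, 0.4), c(50, 500), 0.2, times = 0:1000)
  fit <- fit_kinetics(tr, "FO2")
  est <- coef(fit)
  expect_true(fit$converged)
  expect_lt(abs(est[["t1"]] - 50) / 50, 1e-3)
  expect_lt(abs(est[["t2"]] - 500) / 500, 1e-3)
  expect_lt(abs(est[["a1"]] - 0.5) / 0.5, 1e-3)
  expect_lt(abs(est[["a2"]] - 0.4) / 0.4, 1e-3)
  expect_lt(est[["t1"]], est[["t2"]])
})

test_that("permuting the component order of the start leaves the fit invariant", {
  tr <- make_fo_trace(c(0.5, 0.4), c(50, 500), 0.2, times = 0:1000,
                      sigma = 0.002, seed = 9)
  s1 <- fo_params(c(0.45, 0.45), c(30, 600), 0.15)
  s2 <- fo_params(c(0.45, 0.45), c(600, 30), 0.15)  # constructor canonicalizes
  f1 <- fit_kinetics(tr, "FO2", start = s1)
  f2 <- fit_kinetics(tr, "FO2", start = s2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("a constant trace yields the zero-variance convention", {
  flat <- kinetic_trace(0:200, rep(0.8, 201), radical = "DPPH")
  fit <- fit_kinetics(flat, "FO1")
  expect_equal(fit$r_squared, 0)
  expect_equal(fit$regression_pvalue, 1)
  expect_lt(coef(fit)[["a1"]], 1e-6)
})

test_that("refitting a model's own noiseless output is idempotent", {
  tr <- make_so_trace(k = 0.01, ar0 = 1.1219, aah0 = 1.7, times = 0:1000,
                      sigma = 0.005, seed = 4)
  fit1 <- fit_kinetics(tr, "SO")
  clean <- kinetic_trace(tr$times, predict(fit1), radical = "DPPH")
  fit2 <- fit_kinetics(clean, "SO")
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-6)
})

test_that("nested exponential models dominate in residual sum of squares", {
  traces <- list(
    make_fo_trace(0.9, 150, 0.2, sigma = 0.005, seed = 2),
    make_fo_trace(c(0.5, 0.4), c(50, 500), 0.2, sigma = 0.005, seed = 3),
    make_so_trace(k = 0.01, ar0 = 1.1219, aah0 = 1.7, sigma = 0.005, seed = 5)
  )
  for (tr in traces) {
    cmp <- fit_all(tr)
    rss <- vapply(cmp$fits, `[[`, numeric(1), "residual_sum_squares")
    expect_lte(rss[["FO2"]], rss[["FO1"]] + 1e-12)
    expect_lte(rss[["FO3"]], rss[["FO2"]] + 1e-12)
  }
})

test_that("fit quality statistics behave as advertised under noise", {
  # any converged fit with R^2 >= 0.9 at n = 1001 has a vanishing p-value
  tr <- make_so_trace(k = 0.01, ar0 = 1.1219, aah0 = 1.7, sigma = 0.005,
                      seed = 8)
  for (m in c("FO1", "FO2", "SO")) {
    fit <- fit_kinetics(tr, m)
    if (fit$converged && fit$r_squared >= 0.9)
      expect_lt(fit$regression_pvalue, 1e-5)
  }
  fit <- fit_kinetics(tr, "SO")
  expect_true(all(is.finite(fit$param_std_errors)))
  expect_true(all(fit$param_std_errors > 0))
})

test_that("model selection follows R^2 with the nested parsimony guard", {
  # second-order truth: SO wins outright
  so_tr <- make_so_trace(k = 0.01, ar0 = 1.0, aah0 = 1.5, times = 0:1000)
  expect_equal(fit_all(so_tr)$selected, "SO")
  # single-exponential truth: FO1 kept, extra components buy < delta R^2
  fo1_tr <- make_fo_trace(0.9, 200, 0.2, sigma = 0.002, seed = 6)
  cmp <- fit_all(fo1_tr)
  expect_equal(cmp$selected, "FO1")
  # well-separated biexponential truth: FO2 wins in most seeds
  sel <- vapply(1:10, function(s) {
    tr <- make_fo_trace(c(0.5, 0.4), c(50, 5000), 0.2, sigma = 0.002, seed = s)
    fit_all(tr)$selected
  }, character(1))
  expect_gte(mean(sel == "FO2"), 0.8)
})

test_that("antioxidant level estimation works from the SO fit only", {
  tr <- make_so_trace(k = 0.01, ar0 = 1.0, aah0 = 1.5, times = 0:1000)
  so_fit <- fit_kinetics(tr, "SO")
  est <- estimate_antioxidant_level(so_fit)
  expect_lt(abs(est$aah0 - 1.5) / 1.5, 1e-4)
  expect_equal(est$trajectory$aah[1], est$aah0, tolerance = 1e-12)
  expect_equal(nrow(est$trajectory), length(tr$times))
  fo_fit <- fit_kinetics(tr, "FO1")
  expect_error(estimate_antioxidant_level(fo_fit),
               class = "radkin_wrong_model_error")
})

test_that("decay_fit methods are mutually consistent", {
  tr <- make_so_trace(sigma = 0.005, seed = 12, times = 0:500)
  fit <- fit_kinetics(tr, "SO")
  expect_equal(fitted(fit) + residuals(fit), tr$absorbance)
  expect_equal(deviance(fit), sum(residuals(fit)^2))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, 0), coef(fit)[["ar0"]])
  sim <- simulate(fit, seed = 99)
  expect_s3_class(sim, "kinetic_trace")
  expect_equal(sim$times, tr$times)
  js <- jsonlite::parse_json(fit_to_json(fit))
  expect_equal(js$model, "SO")
  expect_equal(js$params$k, coef(fit)[["k"]], tolerance = 1e-12)
})
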