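test_that("fo_model reproduces its boundary values and a frozen hand evaluation", {
  p1 <- fo_params(1.0, 100, y0 = 0.1)
  expect_equal(fo_model(0, p1), 1.1)
  expect_equal(fo_model(1e9, p1), 0.1, tolerance = 1e-12)
  # 0.2 + 0.5 e^-2 + 0.4 e^-0.2, evaluated by hand
  p2 <- fo_params(c(0.5, 0.4), c(50, 500), y0 = 0.2)
  expect_equal(fo_model(100, p2), 0.5951599428, tolerance = 1e-9)
  expect_error(fo_model(NaN, p1), class = "radkin_validation_error")
})

test_that("an FO2 model with one zero amplitude equals the FO1 model exactly", {
  p1 <- fo_params(0.7, 120, y0 = 0.15)
  p2 <- fo_params(c(0.7, 0), c(120, 900), y0 = 0.15)
  tt <- seq(0, 1000, by = 7)
  expect_identical(fo_model(tt, p2), fo_model(tt, p1))
})

test_that("so_model hits its closed-form anchors", {
  expect_equal(so_model(0, so_params(0.02, 0.9, 1.4)), 0.9)
  expect_equal(so_model(0, so_params(0.02, 1.4, 0.9)), 1.4)
  # equal-concentration law at k t ar0 = 1
  expect_equal(so_model(100, so_params(0.01, 1.0, 1.0)), 0.5, tolerance = 1e-9)
  # unequal case, frozen closed-form value (ODE-oracle confirmed)
  expect_equal(so_model(100, so_params(0.01, 1.0, 1.5)), 0.3394244393,
               tolerance = 1e-9)
})

test_that("so_model tends to the stoichiometric excess at long times", {
  expect_equal(so_model(1e9, so_params(0.01, 1.0, 1.5)), 0, tolerance = 1e-12)
  expect_equal(so_model(1e9, so_params(0.01, 1.5, 1.0)), 0.5, tolerance = 1e-9)
})

test_that("so_model is continuous across the equal-concentration boundary", {
  tt <- seq(0, 1000, by = 1)
  for (k in c(1e-3, 1e-2)) {
    ar0 <- 1.0
    near <- so_model(tt, so_params(k, ar0, ar0 * (1 + 1e-6)))
    equal <- ar0 / (1 + k * tt * ar0)
    expect_lt(max(abs(near - equal)), 1e-4 * ar0)
  }
})

test_that("radical consumed equals antioxidant consumed (1:1 conservation)", {
  tt <- seq(0, 1000, length.out = 101)
  for (p in list(so_params(0.01, 1.0, 1.5), so_params(0.005, 1.5, 1.0),
                 so_params(0.02, 1.1219, 1.1219))) {
    ar <- so_model(tt, p)
    aah <- so_antioxidant(tt, p)
    expect_lt(max(abs((p$ar0 - ar) - (p$aah0 - aah))), 1e-12)
    expect_true(all(aah >= -1e-12))
  }
  # stoichiometry > 1: each antioxidant quenches several radicals
  p <- so_params(0.01, 1.0, 1.5)
  aah2 <- so_antioxidant(500, p, stoichiometry = 2)
  consumed_r <- 1.0 - so_model(500, p)
  expect_equal(1.5 - aah2, consumed_r / 2, tolerance = 1e-12)
})

test_that("so_antioxidant boundary values follow conservation", {
  p <- so_params(0.01, 1.0, 1.5)
  expect_equal(so_antioxidant(0, p), 1.5)
  expect_equal(so_antioxidant(1e9, p), 0.5, tolerance = 1e-9)
})

test_that("both second-order trajectories are non-increasing in time", {
  tt <- seq(0, 1000, by = 1)
  for (p in list(so_params(1e-4, 1.0, 2.0), so_params(0.1, 1.0, 0.5),
                 so_params(0.01, 1.1219, 1.1219))) {
    expect_true(all(diff(so_model(tt, p)) <= 1e-15))
    expect_true(all(diff(so_antioxidant(tt, p)) <= 1e-15))
  }
  # multi-exponential decay is non-increasing when amplitudes are >= 0
  expect_true(all(diff(fo_model(tt, fo_params(c(0.5, 0.4), c(50, 500), 0.2))) <= 0))
})

test_that("closed form agrees with the adaptive ODE oracle", {
  grid <- 0:1000
  p <- so_params(0.01, 1.0, 1.5)
  rel <- abs(so_model(grid, p) - integrate_so(p, grid)) /
    pmax(abs(integrate_so(p, grid)), .Machine$double.xmin)
  expect_lt(max(rel), 1e-6)
  # classic equal-concentration law
  pe <- so_params(0.01, 1.0, 1.0)
  rel_eq <- abs(integrate_so(pe, grid) - 1 / (1 + 0.01 * grid)) /
    (1 / (1 + 0.01 * grid))
  expect_lt(max(rel_eq), 1e-6)
})

test_that("integrate_so handles the trivial grid and rejects bad input", {
  p <- so_params(0.01, 1.0, 1.5)
  expect_equal(integrate_so(p, 0), 1.0, tolerance = 1e-9)
  expect_error(integrate_so(p, c(1, 2)), class = "radkin_validation_error")
  expect_error(integrate_so(p, c(0, 2, 1)), class = "radkin_validation_error")
})

test_that("parameter constructors reject invalid values", {
  expect_error(so_params(0, 1, 1), class = "radkin_validation_error")
  expect_error(so_params(0.1, -1, 1), class = "radkin_validation_error")
  expect_error(fo_params(c(0.5, 0.4), 50, 0.1), class = "radkin_validation_error")
  expect_error(fo_params(0.5, -3, 0.1), class = "radkin_validation_error")
  expect_error(fo_params(-0.5, 3, 0.1), class = "radkin_validation_error")
  # canonical ordering: fastest component first
  p <- fo_params(c(0.4, 0.5), c(500, 50), 0.2)
  expect_equal(p$time_constants, c(50, 500))
  expect_equal(p$amplitudes, c(0.5, 0.4))
})
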