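test_that("simulation is deterministic and leaves the caller's RNG alone", {
  cfg <- simulation_config("SO", so_params(0.01, 1.1219, 1.7), seed = 21)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  tr1 <- simulate_trace(cfg)
  tr2 <- simulate_trace(cfg)
  after <- runif(1)
  expect_identical(tr1$absorbance, tr2$absorbance)
  expect_identical(before, after)
})

test_that("noiseless simulation is the model evaluated on the grid", {
  p <- so_params(0.01, 1.1219, 1.7)
  cfg <- simulation_config("SO", p, noise_sigma = 0, radical = "DPPH")
  tr <- simulate_trace(cfg)
  expect_equal(tr$absorbance[1], 1.1219)  # t = 0 is exactly ar0
  expect_lt(max(abs(tr$absorbance - so_model(tr$times, p))), 1e-12)
  pf <- fo_params(c(0.5, 0.4), c(50, 500), 0.2)
  cfg2 <- simulation_config("FO2", pf, noise_sigma = 0)
  tr2 <- simulate_trace(cfg2)
  expect_lt(max(abs(tr2$absorbance - fo_model(tr2$times, pf))), 1e-12)
})

test_that("simulated noise has the configured standard deviation", {
  p <- so_params(0.01, 1.1219, 1.7)
  sds <- vapply(1:10, function(s) {
    cfg <- simulation_config("SO", p, noise_sigma = 0.005, seed = s)
    tr <- simulate_trace(cfg)
    sd(tr$absorbance - so_model(tr$times, p))
  }, numeric(1))
  # chi-square bounds on the SD of 1001 normal draws are far inside this band
  expect_true(all(sds > 0.004 & sds < 0.006))
})

test_that("config validation catches mismatched truth parameters", {
  expect_error(simulation_config("SO", fo_params(1, 100, 0.1)),
               class = "radkin_validation_error")
  expect_error(simulation_config("FO2", fo_params(1, 100, 0.1)),
               class = "radkin_validation_error")
  expect_error(simulation_config("SO", so_params(0.01, 1, 1.5),
                                 noise_sigma = -1),
               class = "radkin_validation_error")
  expect_error(simulation_config("SO", so_params(0.01, 1, 1.5),
                                 duration = 5, dt = 1),
               class = "radkin_validation_error")
})

test_that("the default study has the 16 cells of the dilution scheme", {
  study <- simulate_study(study_design(duration = 50, noise_sigma = 0), seed = 1)
  expected <- c(paste0("KDPPH", c("1.0", "1.5", "2.0", "2.5")),
                paste0("KGL", c("1.0", "1.5", "2.0", "2.5")),
                paste0("ODPPH", c("1.0", "1.5", "2.0", "2.5")),
                paste0("OGL", c("1.0", "1.5", "2.0", "2.5")))
  expect_setequal(names(study$traces), expected)
  expect_equal(nrow(study$manifest), 16)
  # aah0 proportional to dilution within each (source, radical) cell
  m <- study$manifest
  for (src in c("FLOWER", "FRUIT")) for (rad in c("DPPH", "GLV")) {
    cell <- m[m$source == src & m$radical == rad, ]
    cell <- cell[order(cell$dilution_level), ]
    expect_true(all(diff(cell$aah0) > 0))
  }
})

test_that("terminal percent remaining decreases with dilution level (noiseless)", {
  study <- simulate_study(study_design(noise_sigma = 0), seed = 1)
  m <- study$manifest
  for (src in c("FLOWER", "FRUIT")) for (rad in c("DPPH", "GLV")) {
    ids <- m[m$source == src & m$radical == rad, ]
    ids <- ids[order(ids$dilution_level), "sample_id"]
    terminal <- vapply(ids, function(id) {
      pr <- trace_to_percent(study$traces[[id]])
      pr$percent_remaining[nrow(pr)]
    }, numeric(1))
    expect_true(all(diff(terminal) < 0))
  }
})

test_that("flower infusions quench DPPH further than fruit in every matched cell", {
  # flower rate constant is 10x the fruit one in the default design
  study <- simulate_study(study_design(noise_sigma = 0), seed = 1)
  for (lev in c("1.0", "1.5", "2.0", "2.5")) {
    kt <- trace_to_percent(study$traces[[paste0("KDPPH", lev)]])
    ot <- trace_to_percent(study$traces[[paste0("ODPPH", lev)]])
    expect_lt(kt$percent_remaining[nrow(kt)], ot$percent_remaining[nrow(ot)])
  }
})

test_that("calibration simulation is exact at zero noise and seeded otherwise", {
  truth <- calibration_curve("DPPH", DPPH_CAL$slope, DPPH_CAL$intercept)
  pts <- simulate_calibration(truth, c(0.02, 0.05, 0.1))
  expect_equal(pts$absorbance, DPPH_CAL$slope * pts$concentration + DPPH_CAL$intercept)
  refit <- fit_calibration(pts$concentration, pts$absorbance, "DPPH")
  expect_equal(refit$r_squared, 1.0, tolerance = 1e-12)
  noisy <- simulate_calibration(truth, seq(0.01, 0.12, length.out = 20),
                                noise_sigma = 0.01, seed = 5)
  noisy2 <- simulate_calibration(truth, seq(0.01, 0.12, length.out = 20),
                                 noise_sigma = 0.01, seed = 5)
  expect_identical(noisy, noisy2)
  refit_noisy <- fit_calibration(noisy$concentration, noisy$absorbance, "DPPH")
  expect_gte(refit_noisy$r_squared, 0.99)
})

test_that("sample specs enforce the fixed dilution scheme volumes", {
  sp <- sample_spec("FLOWER", 1.5e-3)
  expect_equal(sp$infusion_volume_ml + sp$water_volume_ml, 10)
  expect_equal(sp$radical_solution_ml, 3.0)
  expect_equal(sample_acronym(sp, "DPPH"), "KDPPH1.5")
  expect_equal(sample_acronym(sample_spec("FRUIT", 2.5e-3), "GLV"), "OGL2.5")
  expect_error(sample_spec("FLOWER", 3e-3), class = "radkin_validation_error")
  expect_error(sample_spec("FLOWER", 1e-3, infusion_volume_ml = 2),
               class = "radkin_validation_error")
})

test_that("a zero-noise study refit end-to-end selects the generating SO model", {
  design <- study_design(noise_sigma = 0, duration = 300,
                         dilution_levels = c(1.0e-3, 2.5e-3))
  study <- simulate_study(design, seed = 2)
  for (tr in study$traces)
    expect_equal(fit_all(tr)$selected, "SO")
})
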