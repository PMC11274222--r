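#' Configuration for simulating one absorbance-time trace
#'
#' Ground-truth model and parameters, sampling grid (default: 1000 s at 1 s
#' intervals, the assay's recording scheme), additive Gaussian instrument
#' noise (default sigma 0.005 AU, a typical UV-Vis repeatability figure),
#' and a seed.
#'
#' @param truth_model `"FO1"`, `"FO2"`, `"FO3"` or `"SO"`.
#' @param truth_params matching [fo_params()] or [so_params()].
#' @param duration total time in seconds (default 1000).
#' @param dt sampling interval in seconds (default 1); `duration/dt` must
#'   give at least 10 points.
#' @param noise_sigma additive Gaussian noise SD in AU, `>= 0`.
#' @param seed integer seed.
#' @param radical `"DPPH"` or `"GLV"`.
#' @param sample_id identifier for the simulated trace.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(truth_model = c("SO", "FO1", "FO2", "FO3"),
                              truth_params, duration = 1000, dt = 1,
                              noise_sigma = 0.005, seed = 1L,
                              radical = c("DPPH", "GLV"),
                              sample_id = "sim") {
  truth_model <- match.arg(truth_model)
  radical <- match.arg(radical)
  expected <- if (truth_model == "SO") "so_params" else "fo_params"
  if (!inherits(truth_params, expected))
    stop_radkin(sprintf("truth_params must be a %s for model %s",
                        expected, truth_model), "radkin_validation_error")
  if (truth_model != "SO" && truth_params$order != fo_order(truth_model))
    stop_radkin("fo_params order does not match truth_model",
                "radkin_validation_error")
  check_scalar(duration, "duration"); check_scalar(dt, "dt")
  check_scalar(noise_sigma, "noise_sigma")
  if (duration / dt < 9)
    stop_radkin("duration/dt must give at least 10 points",
                "radkin_validation_error")
  if (noise_sigma < 0)
    stop_radkin("noise_sigma must be >= 0", "radkin_validation_error")
  structure(list(truth_model = truth_model, truth_params = truth_params,
                 duration = duration, dt = dt, noise_sigma = noise_sigma,
                 seed = as.integer(seed), radical = radical,
                 sample_id = sample_id),
            class = "simulation_config")
}

#' Simulate one noisy absorbance-time trace
#'
#' `absorbance_i = truth(t_i) + N(0, noise_sigma^2)`, deterministic for a
#' fixed config and seed; the caller's RNG state is left untouched. Metadata
#' (wavelength, reference A0) is filled from the radical.
#'
#' @param cfg a [simulation_config()].
#' @return a [kinetic_trace()].
#' @examples
#' cfg <- simulation_config("SO", so_params(0.01, 1.1219, 1.7),
#'                          duration = 100, seed = 7)
#' tr <- simulate_trace(cfg)
#' @export
simulate_trace <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  tt <- seq(0, cfg$duration, by = cfg$dt)
  truth <- if (cfg$truth_model == "SO") so_model(tt, cfg$truth_params)
           else fo_model(tt, cfg$truth_params)
  noise <- if (cfg$noise_sigma > 0)
    with_seed(cfg$seed, rnorm(length(tt), 0, cfg$noise_sigma))
  else rep(0, length(tt))
  kinetic_trace(tt, truth + noise, radical = cfg$radical,
                sample_id = cfg$sample_id)
}

#' Study design: 2 sources x 4 dilutions x 2 radicals
#'
#' The 16-cell assay layout: flower (K) and fruit (O) infusions at dilution
#' levels 1.0, 1.5, 2.0 and 2.5 x 10^-3 g/mL, each reacted with DPPH and
#' galvinoxyl. Ground truth per cell is second-order: `ar0` is the radical's
#' reference A0; `aah0` is proportional to the dilution level
#' (`aah0 = aah0_per_dilution * dilution`, default 680 AU mL/g, spanning
#' 0.68-1.70 AU, i.e. radical excess at the lowest dilution through
#' antioxidant excess at the highest); `k` depends on source and radical.
#' The default rate constants encode the reported orderings: flower about
#' 10x fruit for DPPH and about 1000x for galvinoxyl, with galvinoxyl
#' quenched faster than DPPH by flower and slower by fruit.
#'
#' @param sources subset of `c("FLOWER", "FRUIT")`.
#' @param dilution_levels subset of `c(1.0, 1.5, 2.0, 2.5) * 1e-3` (g/mL).
#' @param radicals subset of `c("DPPH", "GLV")`.
#' @param aah0_per_dilution AU per (g/mL): the dilution-to-antioxidant map.
#' @param k_by_cell named list `FLOWER.DPPH`, `FRUIT.DPPH`, `FLOWER.GLV`,
#'   `FRUIT.GLV` of rate constants in 1/(AU s).
#' @param noise_sigma trace noise SD (AU).
#' @param duration,dt sampling grid (seconds).
#' @return object of class `study_design`.
#' @export
study_design <- function(sources = c("FLOWER", "FRUIT"),
                         dilution_levels = c(1.0, 1.5, 2.0, 2.5) * 1e-3,
                         radicals = c("DPPH", "GLV"),
                         aah0_per_dilution = 680,
                         k_by_cell = list(FLOWER.DPPH = 0.01,
                                          FRUIT.DPPH  = 0.001,
                                          FLOWER.GLV  = 0.05,
                                          FRUIT.GLV   = 5e-5),
                         noise_sigma = 0.005,
                         duration = 1000, dt = 1) {
  sources <- match.arg(sources, several.ok = TRUE)
  radicals <- match.arg(radicals, several.ok = TRUE)
  if (!all(vapply(dilution_levels, function(d)
    any(abs(d - c(1.0, 1.5, 2.0, 2.5) * 1e-3) < 1e-12), logical(1L))))
    stop_radkin("dilution levels must come from {1.0, 1.5, 2.0, 2.5} x 10^-3 g/mL",
                "radkin_validation_error")
  needed <- as.vector(outer(sources, radicals, paste, sep = "."))
  if (!all(needed %in% names(k_by_cell)))
    stop_radkin("k_by_cell must name every source.radical cell",
                "radkin_validation_error")
  structure(list(sources = sources,
                 dilution_levels = sort(dilution_levels),
                 radicals = radicals,
                 aah0_per_dilution = aah0_per_dilution,
                 k_by_cell = k_by_cell,
                 noise_sigma = noise_sigma,
                 duration = duration, dt = dt),
            class = "study_design")
}

#' Simulate a full study of traces with a ground-truth manifest
#'
#' One trace per (source, dilution, radical) cell of a [study_design()] —
#' 16 for the default design — with sample ids in the assay's acronym
#' convention (`KDPPH1.0` ... `OGL2.5`). Within each (source, radical) cell
#' the antioxidant level `aah0` increases strictly with dilution level, so
#' the terminal percent remaining decreases strictly. Per-trace seeds are
#' derived deterministically from `seed`.
#'
#' @param design a [study_design()].
#' @param seed integer master seed.
#' @return list with `traces` (named list of [kinetic_trace()]) and
#'   `manifest` (data.frame of per-cell ground truth: `sample_id`, `source`,
#'   `radical`, `dilution_level`, `k`, `ar0`, `aah0`, `noise_sigma`,
#'   `seed`).
#' @examples
#' study <- simulate_study(study_design(duration = 50, noise_sigma = 0),
#'                         seed = 1)
#' names(study$traces)
#' @export
simulate_study <- function(design, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  traces <- list()
  rows <- list()
  i <- 0L
  for (src in design$sources) for (rad in design$radicals)
    for (dil in design$dilution_levels) {
      i <- i + 1L
      spec <- sample_spec(src, dil)
      id <- sample_acronym(spec, rad)
      k <- design$k_by_cell[[paste(src, rad, sep = ".")]]
      ar0 <- radical_constants(rad)$a0
      aah0 <- design$aah0_per_dilution * dil
      cell_seed <- (as.integer(seed) * 1000L + i) %% .Machine$integer.max
      cfg <- simulation_config("SO", so_params(k, ar0, aah0),
                               duration = design$duration, dt = design$dt,
                               noise_sigma = design$noise_sigma,
                               seed = cell_seed, radical = rad,
                               sample_id = id)
      traces[[id]] <- simulate_trace(cfg)
      rows[[i]] <- data.frame(sample_id = id, source = src, radical = rad,
                              dilution_level = dil, k = k, ar0 = ar0,
                              aah0 = aah0, noise_sigma = design$noise_sigma,
                              seed = cell_seed)
    }
  list(traces = traces, manifest = do.call(rbind, rows))
}

#' Simulate noisy calibration points from a known line
#'
#' `A_i = slope * c_i + intercept + N(0, sigma^2)`, seeded and
#' deterministic. A fixture generator for [fit_calibration()].
#'
#' @param cal a [calibration_curve()] giving the true line.
#' @param concentrations at least 3 standard concentrations.
#' @param noise_sigma absorbance noise SD (AU).
#' @param seed integer seed.
#' @return data.frame with columns `concentration` and `absorbance`.
#' @export
simulate_calibration <- function(cal, concentrations, noise_sigma = 0,
                                 seed = 1L) {
  stopifnot(inherits(cal, "calibration_curve"))
  check_finite(concentrations, "concentrations")
  if (length(concentrations) < 3L)
    stop_radkin("need at least 3 calibration concentrations",
                "radkin_validation_error")
  y <- cal$slope * concentrations + cal$intercept
  if (noise_sigma > 0)
    y <- y + with_seed(seed, rnorm(length(y), 0, noise_sigma))
  data.frame(concentration = concentrations, absorbance = y)
}

#' Write a simulated study to disk
#'
#' Trace CSVs with JSON sidecars (the [write_trace()] dialect) plus a
#' `manifest.json` listing every cell's ground-truth parameters, for
#' recovery scoring.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(study$traces))
    write_trace(study$traces[[id]], file.path(dir, paste0(id, ".csv")))
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
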