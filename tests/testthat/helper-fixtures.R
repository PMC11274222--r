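# Fixture builders shared across test files. All synthetic, generated in
# code; the printed assay constants live here in one place.

DPPH_A0 <- 1.1219
GLV_A0 <- 1.1720
DPPH_CAL <- list(slope = 8.6885, intercept = 0.0315)
GLV_CAL <- list(slope = 18.465, intercept = 0.0471)

make_so_trace <- function(k = 0.01, ar0 = 1.0, aah0 = 1.5, times = 0:1000,
                          sigma = 0, seed = 1, radical = "DPPH") {
  p <- so_params(k, ar0, aah0)
  y <- so_model(times, p)
  if (sigma > 0) {
    cfg <- simulation_config("SO", p, duration = max(times),
                             dt = diff(times)[1], noise_sigma = sigma,
                             seed = seed, radical = radical)
    return(simulate_trace(cfg))
  }
  kinetic_trace(times, y, radical = radical)
}

make_fo_trace <- function(amplitudes = c(0.5, 0.4), tcs = c(50, 500),
                          y0 = 0.2, times = 0:1000, sigma = 0, seed = 1,
                          radical = "DPPH") {
  p <- fo_params(amplitudes, tcs, y0)
  if (sigma > 0) {
    model <- paste0("FO", length(amplitudes))
    cfg <- simulation_config(model, p, duration = max(times),
                             dt = diff(times)[1], noise_sigma = sigma,
                             seed = seed, radical = radical)
    return(simulate_trace(cfg))
  }
  kinetic_trace(times, fo_model(times, p), radical = radical)
}
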