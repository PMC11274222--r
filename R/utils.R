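#' @keywords internal
#' @noRd
stop_radkin <- function(msg, class) {
  stop(structure(class = c(class, "radkin_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' @keywords internal
#' @noRd
check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_radkin(sprintf("%s must be finite numeric", what),
                "radkin_validation_error")
  invisible(x)
}

#' @keywords internal
#' @noRd
check_scalar <- function(x, what) {
  check_finite(x, what)
  if (length(x) != 1L)
    stop_radkin(sprintf("%s must be a single value", what),
                "radkin_validation_error")
  invisible(x)
}

# Radical assay constants: monitoring wavelength [nm] and the assay's
# reference initial absorbance A0 [AU].
#' @keywords internal
#' @noRd
radical_constants <- function(radical) {
  radical <- match.arg(radical, c("DPPH", "GLV"))
  switch(radical,
         DPPH = list(wavelength = 517, a0 = 1.1219, acronym = "DPPH"),
         GLV  = list(wavelength = 428, a0 = 1.1720, acronym = "GL"))
}
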