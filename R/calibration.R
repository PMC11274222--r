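#' Calibration curve between concentration and absorbance
#'
#' The assay's empirical linear map `A = slope * c + intercept` per radical.
#' The published lines are `y = 8.6885x + 0.0315` (DPPH, R^2 = 0.9994) and
#' `y = 18.465x + 0.0471` (galvinoxyl, R^2 = 0.9972); the concentration unit
#' of `x` is carried symbolically (the assay reports no unit), so conversion
#' to physical units is left to the caller.
#'
#' @param radical `"DPPH"` or `"GLV"`.
#' @param slope AU per concentration unit, `> 0`.
#' @param intercept AU.
#' @param r_squared coefficient of determination in `[0, 1]`.
#' @return an object of class `calibration_curve`.
#' @examples
#' dpph_cal <- calibration_curve("DPPH", 8.6885, 0.0315, 0.9994)
#' absorbance_to_concentration(0.9, dpph_cal)
#' @export
calibration_curve <- function(radical = c("DPPH", "GLV"), slope, intercept,
                              r_squared = NA_real_) {
  radical <- match.arg(radical)
  check_scalar(slope, "slope")
  check_scalar(intercept, "intercept")
  if (slope <= 0)
    stop_radkin("calibration slope must be > 0", "radkin_invalid_calibration_error")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop_radkin("r_squared must be in [0, 1]", "radkin_validation_error")
  structure(list(radical = radical, slope = slope, intercept = intercept,
                 r_squared = r_squared),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: A = %.4f c + %.4f  (R^2 = %s)\n",
              x$radical, x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "NA", format(x$r_squared))))
  invisible(x)
}

#' Convert absorbance to concentration via a calibration curve
#'
#' Inverts the linear calibration: `c = (A - intercept) / slope`. The result
#' may be negative for absorbances below the intercept; no clamping.
#'
#' @param a absorbance in AU (vectorised).
#' @param cal a [calibration_curve()].
#' @return concentration in the calibration's unit.
#' @export
absorbance_to_concentration <- function(a, cal) {
  stopifnot(inherits(cal, "calibration_curve"))
  check_finite(a, "a")
  (a - cal$intercept) / cal$slope
}

#' Fit a calibration line by ordinary least squares
#'
#' @param concentration numeric vector of standard concentrations (at least
#'   two distinct values, at least 3 points).
#' @param absorbance numeric vector of measured absorbances, same length.
#' @param radical `"DPPH"` or `"GLV"`.
#' @return a [calibration_curve()] with OLS slope/intercept and R^2.
#' @export
fit_calibration <- function(concentration, absorbance,
                            radical = c("DPPH", "GLV")) {
  radical <- match.arg(radical)
  check_finite(concentration, "concentration")
  check_finite(absorbance, "absorbance")
  if (length(concentration) != length(absorbance) || length(concentration) < 3L)
    stop_radkin("need >= 3 paired calibration points", "radkin_validation_error")
  if (length(unique(concentration)) < 2L)
    stop_radkin("all concentrations identical: degenerate calibration design",
                "radkin_degenerate_design_error")
  fit <- lm(absorbance ~ concentration)
  co <- coef(fit)
  tss <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else 0
  calibration_curve(radical, slope = unname(co[2L]),
                    intercept = unname(co[1L]),
                    r_squared = min(max(r2, 0), 1))
}

#' Read / write a calibration curve as JSON
#'
#' @param cal a [calibration_curve()].
#' @param path JSON file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a [calibration_curve()].
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_curve"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_curve(x$radical, x$slope, x$intercept, x$r_squared)
}
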