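#' Construct a kinetic absorbance-time trace
#'
#' A `kinetic_trace` holds one radical-quenching time series: absorbance
#' sampled at increasing times after mixing radical solution with the tested
#' antioxidant dilution. The assay monitors DPPH at 517 nm and galvinoxyl
#' (GLV) at 428 nm; the reference initial absorbance `a0_reference` defaults
#' to the assay constant for the radical (1.1219 AU for DPPH, 1.1720 AU for
#' GLV) and anchors the percent-remaining transform.
#'
#' @param times numeric vector of times in seconds, strictly increasing,
#'   all `>= 0`.
#' @param absorbance numeric vector of absorbances in AU, same length as
#'   `times`, all finite.
#' @param radical `"DPPH"` or `"GLV"`.
#' @param sample_id sample identifier, e.g. `"KDPPH1.0"` (flower, DPPH,
#'   dilution 1.0e-3 g/mL) or `"OGL2.5"`.
#' @param a0_reference reference initial absorbance in AU; defaults to the
#'   radical's assay constant.
#' @param wavelength monitoring wavelength in nm; defaults to (and must
#'   equal) 517 for DPPH and 428 for GLV.
#' @return an object of class `kinetic_trace`: a list with elements `times`,
#'   `absorbance`, `radical`, `wavelength`, `sample_id`, `a0_reference`.
#' @examples
#' tr <- kinetic_trace(0:10, 1.12 * exp(-(0:10) / 5), radical = "DPPH")
#' print(tr)
#' @export
kinetic_trace <- function(times, absorbance, radical = c("DPPH", "GLV"),
                          sample_id = "sample", a0_reference = NULL,
                          wavelength = NULL) {
  radical <- match.arg(radical)
  check_finite(times, "times")
  check_finite(absorbance, "absorbance")
  if (length(times) != length(absorbance))
    stop_radkin("times and absorbance must have the same length",
                "radkin_validation_error")
  if (length(times) < 3L)
    stop_radkin("a trace needs at least 3 points", "radkin_validation_error")
  if (any(diff(times) <= 0))
    stop_radkin("times must be strictly increasing", "radkin_validation_error")
  if (times[1L] < 0)
    stop_radkin("times must be non-negative", "radkin_validation_error")
  const <- radical_constants(radical)
  if (is.null(wavelength)) wavelength <- const$wavelength
  if (wavelength != const$wavelength)
    stop_radkin(sprintf("wavelength %s nm inconsistent with radical %s (%s nm)",
                        wavelength, radical, const$wavelength),
                "radkin_validation_error")
  if (is.null(a0_reference)) a0_reference <- const$a0
  check_scalar(a0_reference, "a0_reference")
  structure(list(times = as.numeric(times),
                 absorbance = as.numeric(absorbance),
                 radical = radical,
                 wavelength = wavelength,
                 sample_id = as.character(sample_id),
                 a0_reference = a0_reference),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %s  radical=%s (%g nm)  n=%d  t=[%g, %g] s\n",
              x$sample_id, x$radical, x$wavelength, length(x$times),
              min(x$times), max(x$times)))
  cat(sprintf("  A(first)=%.4f  A(last)=%.4f  A0 reference=%.4f AU\n",
              x$absorbance[1L], x$absorbance[length(x$absorbance)],
              x$a0_reference))
  invisible(x)
}

#' @export
as.data.frame.kinetic_trace <- function(x, ...) {
  data.frame(time_s = x$times, absorbance = x$absorbance)
}

#' @export
plot.kinetic_trace <- function(x, ...) {
  plot(x$times, x$absorbance, type = "l",
       xlab = "time [s]", ylab = "absorbance [AU]",
       main = x$sample_id, ...)
  invisible(x)
}

#' Percent of radical remaining
#'
#' The percent-remaining transform `R% = 100 * A_t / A_0`. Values above 100
#' are legal (noisy early points); no clamping is applied.
#'
#' @param a_t absorbance at time t, AU, `>= 0` (vectorised).
#' @param a_0 reference initial absorbance, AU, `> 0`.
#' @return percent remaining, same length as `a_t`.
#' @examples
#' percent_remaining(0.5610, 1.1219)
#' @export
percent_remaining <- function(a_t, a_0) {
  check_finite(a_t, "a_t")
  check_scalar(a_0, "a_0")
  if (a_0 <= 0)
    stop_radkin("a_0 must be > 0", "radkin_invalid_reference_error")
  if (any(a_t < 0))
    stop_radkin("a_t must be >= 0", "radkin_validation_error")
  100 * a_t / a_0
}

#' Convert a trace to percent-remaining form
#'
#' Applies [percent_remaining()] pointwise against the trace's
#' `a0_reference`.
#'
#' @param trace a [kinetic_trace()].
#' @return data.frame with columns `time_s` and `percent_remaining`.
#' @export
trace_to_percent <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  data.frame(time_s = trace$times,
             percent_remaining = percent_remaining(trace$absorbance,
                                                   trace$a0_reference))
}

#' Read / write a trace as CSV plus JSON metadata sidecar
#'
#' The on-disk dialect is a two-column CSV (`time_s,absorbance`) next to a
#' JSON sidecar `<path>.json` holding `radical`, `wavelength`, `sample_id`
#' and `a0_reference`.
#'
#' @param trace a [kinetic_trace()].
#' @param path CSV file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [kinetic_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  meta <- list(radical = trace$radical, wavelength = trace$wavelength,
               sample_id = trace$sample_id, a0_reference = trace$a0_reference)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path))
    stop_radkin(sprintf("trace file %s does not exist", path),
                "radkin_io_error")
  dat <- read.csv(path)
  if (!all(c("time_s", "absorbance") %in% names(dat)))
    stop_radkin(sprintf("trace file %s lacks time_s/absorbance columns", path),
                "radkin_io_error")
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop_radkin(sprintf("missing metadata sidecar %s", meta_path),
                "radkin_io_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  kinetic_trace(dat$time_s, dat$absorbance, radical = meta$radical,
                sample_id = meta$sample_id, a0_reference = meta$a0_reference,
                wavelength = meta$wavelength)
}
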