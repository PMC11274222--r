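#' @export
coef.decay_fit <- function(object, ...) {
  setNames(params_to_par(object$params), par_names(object$model))
}

#' @export
deviance.decay_fit <- function(object, ...) object$residual_sum_squares

#' @export
fitted.decay_fit <- function(object, ...) {
  model_eval(object$model, object$trace$times, params_to_par(object$params))
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$trace$absorbance - fitted(object)
}

#' Predict absorbance from a fitted kinetic model
#'
#' @param object a `decay_fit` from [fit_kinetics()].
#' @param times times in seconds at which to evaluate the fitted model;
#'   defaults to the fitted trace's grid.
#' @param ... unused.
#' @return numeric vector of predicted absorbances (AU).
#' @export
predict.decay_fit <- function(object, times = object$trace$times, ...) {
  check_finite(times, "times")
  model_eval(object$model, times, params_to_par(object$params))
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s model on %s (n = %d)%s\n",
              x$model, x$trace$sample_id, x$n_points,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(signif(coef(x), 6))
  cat(sprintf("R^2 = %.6f   RSS = %.4g   Pr(R^2 = 0) = %.3g\n",
              x$r_squared, x$residual_sum_squares, x$regression_pvalue))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  est <- coef(object)
  tab <- cbind(Estimate = est, `Std. Error` = object$param_std_errors)
  structure(list(model = object$model, coefficients = tab,
                 r_squared = object$r_squared,
                 regression_pvalue = object$regression_pvalue,
                 residual_sum_squares = object$residual_sum_squares,
                 n_points = object$n_points, converged = object$converged,
                 sigma = sqrt(object$residual_sum_squares /
                                max(object$n_points - length(est), 1L)),
                 sample_id = object$trace$sample_id),
            class = "summary.decay_fit")
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit: %s model, sample %s\n", x$model, x$sample_id))
  printCoefmat(x$coefficients, digits = 6)
  cat(sprintf("\nn = %d points, residual sigma = %.4g AU\n", x$n_points, x$sigma))
  cat(sprintf("R^2 = %.6f, Pr(R^2 = 0) = %.3g, converged: %s\n",
              x$r_squared, x$regression_pvalue, x$converged))
  invisible(x)
}

#' @importFrom stats printCoefmat
NULL

#' @export
plot.decay_fit <- function(x, ...) {
  plot(x$trace$times, x$trace$absorbance, pch = 16, cex = 0.3,
       col = "grey40", xlab = "time [s]", ylab = "absorbance [AU]",
       main = sprintf("%s: %s fit", x$trace$sample_id, x$model), ...)
  lines(x$trace$times, fitted(x), col = "red2", lwd = 2)
  invisible(x)
}

#' Simulate new traces from a fitted kinetic model
#'
#' Draws `nsim` traces from the fitted curve plus Gaussian noise at the
#' residual standard deviation, on the fitted trace's time grid.
#'
#' @param object a `decay_fit`.
#' @param nsim number of traces.
#' @param seed integer seed (required for reproducibility; `NULL` uses the
#'   current RNG state).
#' @param ... unused.
#' @return list of [kinetic_trace()] objects.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  sigma <- sqrt(object$residual_sum_squares /
                  max(object$n_points - length(coef(object)), 1L))
  draw <- function() {
    kinetic_trace(object$trace$times, mu + rnorm(length(mu), 0, sigma),
                  radical = object$trace$radical,
                  sample_id = paste0(object$trace$sample_id, "_sim"),
                  a0_reference = object$trace$a0_reference)
  }
  out <- if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
         else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  if (nsim == 1L) out[[1L]] else out
}

#' @importFrom graphics lines
NULL

#' Serialize a fit result to JSON (and back)
#'
#' Round-trippable JSON with a schema version field.
#'
#' @param fit a `decay_fit`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "decay_fit"))
  obj <- list(schema = "radkin/decay_fit/1",
              model = fit$model,
              params = setNames(as.list(coef(fit)), par_names(fit$model)),
              param_std_errors = as.list(fit$param_std_errors),
              r_squared = fit$r_squared,
              regression_pvalue = fit$regression_pvalue,
              residual_sum_squares = fit$residual_sum_squares,
              n_points = fit$n_points,
              converged = fit$converged)
  if (is.null(path))
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
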