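#' Fit all candidate kinetic models and select the best
#'
#' Fits FO1, FO2, FO3 and SO (see [fit_kinetics()]) and selects among the
#' converged fits by coefficient of determination, with a parsimony guard on
#' the nested exponential ladder: a higher-order FO model displaces a lower
#' one only if it improves R^2 by more than `delta_r2` (default 0.001, i.e.
#' extra parallel channels must buy a real improvement). The best FO model
#' then competes with SO on raw R^2. Non-converged fits are excluded from
#' selection; models the trace is too short to support are skipped.
#'
#' @param trace a [kinetic_trace()].
#' @param models subset of `c("FO1", "FO2", "FO3", "SO")` to fit.
#' @param delta_r2 minimum R^2 improvement for a higher-order nested FO
#'   model to be preferred.
#' @param restart_seed seed for the deterministic perturbed restarts.
#' @return object of class `kinetic_model_comparison`: list with `fits`
#'   (named list of `decay_fit`), `selected` (model name), and
#'   `selection_rationale`.
#' @examples
#' p <- so_params(k = 0.01, ar0 = 1.0, aah0 = 1.5)
#' tr <- kinetic_trace(seq(0, 500, 5), so_model(seq(0, 500, 5), p),
#'                     radical = "DPPH")
#' cmp <- fit_all(tr)
#' cmp$selected
#' @export
fit_all <- function(trace, models = c("FO1", "FO2", "FO3", "SO"),
                    delta_r2 = 0.001, restart_seed = 1L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  models <- match.arg(models, several.ok = TRUE)
  fits <- list()
  skipped <- character(0)
  lower_fit <- NULL
  for (m in c("FO1", "FO2", "FO3")) {
    if (!m %in% models) next
    if (length(trace$times) < model_npar(m) + 2L) {
      skipped <- c(skipped, m)
      next
    }
    starts <- list(params_to_par(initial_guesses(trace, m)))
    if (!is.null(lower_fit))
      starts <- c(starts, list(embed_lower_fo(lower_fit$params,
                                              max(trace$times) - min(trace$times))))
    fits[[m]] <- fit_from_starts(trace, m, starts, restarts = 5L,
                                 restart_seed = restart_seed)
    lower_fit <- fits[[m]]
  }
  if ("SO" %in% models) {
    if (length(trace$times) < model_npar("SO") + 2L) skipped <- c(skipped, "SO")
    else fits[["SO"]] <- fit_kinetics(trace, "SO", restart_seed = restart_seed)
  }
  conv <- names(fits)[vapply(fits, `[[`, logical(1L), "converged")]
  if (length(conv) == 0L)
    stop_radkin("no candidate model converged on this trace",
                "radkin_no_model_error")

  # parsimony ladder over the nested exponential family
  fo_conv <- intersect(c("FO1", "FO2", "FO3"), conv)
  best_fo <- NULL
  for (m in fo_conv) {
    if (is.null(best_fo) ||
        fits[[m]]$r_squared > fits[[best_fo]]$r_squared + delta_r2)
      best_fo <- m
  }
  cand <- c(best_fo, intersect("SO", conv))
  r2 <- vapply(cand, function(m) fits[[m]]$r_squared, numeric(1L))
  selected <- cand[which.max(r2)]
  rationale <- sprintf(
    "selected %s (R^2 = %.6f) among converged {%s}; nested FO ladder kept %s at delta_R^2 = %g%s",
    selected, fits[[selected]]$r_squared, paste(conv, collapse = ", "),
    if (is.null(best_fo)) "none" else best_fo, delta_r2,
    if (length(skipped)) paste0("; skipped (trace too short): ",
                                paste(skipped, collapse = ", ")) else "")
  structure(list(fits = fits, selected = selected,
                 selection_rationale = rationale,
                 sample_id = trace$sample_id),
            class = "kinetic_model_comparison")
}

#' @export
print.kinetic_model_comparison <- function(x, ...) {
  cat(sprintf("<kinetic_model_comparison> %s\n", x$sample_id))
  for (m in names(x$fits)) {
    f <- x$fits[[m]]
    cat(sprintf("  %-4s R^2 = %.6f  RSS = %.4g  converged = %-5s%s\n",
                m, f$r_squared, f$residual_sum_squares, f$converged,
                if (identical(m, x$selected)) "  <- selected" else ""))
  }
  cat(" ", x$selection_rationale, "\n")
  invisible(x)
}

#' Estimated antioxidant level from a second-order fit
#'
#' Returns the fitted initial antioxidant level AAH(0) together with the
#' implied antioxidant trajectory on the trace's time grid (see
#' [so_antioxidant()]). In a multicomponent infusion this is a pooled
#' estimate: only the collective amount of the antioxidants is identified,
#' not the individual species.
#'
#' @param fit a converged `decay_fit` with `model == "SO"`.
#' @param stoichiometry radicals quenched per antioxidant (default 1).
#' @return list with `aah0` (AU) and `trajectory`, a data.frame of `time_s`
#'   and `aah`.
#' @export
estimate_antioxidant_level <- function(fit, stoichiometry = 1) {
  stopifnot(inherits(fit, "decay_fit"))
  if (fit$model != "SO")
    stop_radkin("antioxidant level estimation requires a second-order (SO) fit",
                "radkin_wrong_model_error")
  if (!fit$converged)
    stop_radkin("SO fit did not converge; antioxidant level not identified",
                "radkin_wrong_model_error")
  traj <- so_antioxidant(fit$trace$times, fit$params,
                         stoichiometry = stoichiometry)
  list(aah0 = fit$params$aah0,
       trajectory = data.frame(time_s = fit$trace$times, aah = traj))
}

#' Serialize a model comparison to JSON
#'
#' @param cmp a `kinetic_model_comparison`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly.
#' @export
comparison_to_json <- function(cmp, path = NULL) {
  stopifnot(inherits(cmp, "kinetic_model_comparison"))
  obj <- list(schema = "radkin/model_comparison/1",
              sample_id = cmp$sample_id,
              selected = cmp$selected,
              selection_rationale = cmp$selection_rationale,
              fits = lapply(cmp$fits, function(f)
                jsonlite::parse_json(fit_to_json(f))))
  if (is.null(path)) jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
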