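# Internal parameter-vector layout per model:
#   FO<m>: c(a_1..a_m, t_1..t_m, y0)      (2m + 1 parameters)
#   SO:    c(k, ar0, aah0)                (3 parameters)

#' @keywords internal
#' @noRd
model_npar <- function(model) {
  switch(model, FO1 = 3L, FO2 = 5L, FO3 = 7L, SO = 3L)
}

#' @keywords internal
#' @noRd
fo_order <- function(model) as.integer(substring(model, 3L))

#' @keywords internal
#' @noRd
model_eval <- function(model, t, par) {
  if (model == "SO") {
    so_eval(t, par[1L], par[2L], par[3L])
  } else {
    m <- fo_order(model)
    y <- rep(par[2L * m + 1L], length(t))
    for (i in seq_len(m))
      y <- y + par[i] * exp(-t / par[m + i])
    y
  }
}

# Analytic Jacobian of the FO residual (model - data) wrt the parameter
# vector; the SO fit uses nls.lm's numeric differencing (3 parameters only).
#' @keywords internal
#' @noRd
fo_jacobian <- function(t, par, m) {
  J <- matrix(0, length(t), 2L * m + 1L)
  for (i in seq_len(m)) {
    e <- exp(-t / par[m + i])
    J[, i] <- e
    J[, m + i] <- par[i] * e * t / par[m + i]^2
  }
  J[, 2L * m + 1L] <- 1
  J
}

#' @keywords internal
#' @noRd
model_lower <- function(model) {
  if (model == "SO") rep(1e-12, 3L)
  else {
    m <- fo_order(model)
    c(rep(0, m), rep(1e-6, m), 0)
  }
}

#' Heuristic starting values for a kinetic fit
#'
#' For the exponential (FO) models the offset starts at the trace floor, the
#' total amplitude at first absorbance minus floor split equally across
#' components, and the time constants log-spaced over one hundredth to all
#' of the observed time span. For the second-order (SO) model Ar(0) starts
#' at the first absorbance, AAH(0) at 1.5 Ar(0), and k at the initial-slope
#' estimate `(-dA/dt) / (ar0 aah0)` over the first 10 points, floored at
#' 1e-6.
#'
#' @param trace a [kinetic_trace()].
#' @param model one of `"FO1"`, `"FO2"`, `"FO3"`, `"SO"`.
#' @return an [fo_params()] or [so_params()] object.
#' @export
initial_guesses <- function(trace, model = c("FO1", "FO2", "FO3", "SO")) {
  stopifnot(inherits(trace, "kinetic_trace"))
  model <- match.arg(model)
  n <- length(trace$times)
  if (n < model_npar(model) + 2L)
    stop_radkin(sprintf("trace of length %d too short to fit %s (%d parameters)",
                        n, model, model_npar(model)),
                "radkin_insufficient_data_error")
  a <- trace$absorbance
  tt <- trace$times
  if (model == "SO") {
    ar0 <- max(a[1L], 1e-6)
    aah0 <- 1.5 * ar0
    j <- min(10L, n)
    slope <- (a[1L] - a[j]) / (tt[j] - tt[1L])
    so_params(k = max(slope / (ar0 * aah0), 1e-6), ar0 = ar0, aah0 = aah0)
  } else {
    m <- fo_order(model)
    y0 <- max(min(a), 0)
    amp <- max(a[1L] - y0, 1e-6)
    span <- max(tt) - min(tt)
    tc <- if (m == 1L) span / 10 else
      exp(seq(log(span / 100), log(span), length.out = m))
    fo_params(rep(amp / m, m), tc, y0 = y0)
  }
}

#' @keywords internal
#' @noRd
params_to_par <- function(p) {
  if (inherits(p, "so_params")) c(p$k, p$ar0, p$aah0)
  else c(p$amplitudes, p$time_constants, p$y0)
}

#' @keywords internal
#' @noRd
par_to_params <- function(model, par) {
  if (model == "SO") so_params(par[1L], par[2L], par[3L])
  else {
    m <- fo_order(model)
    fo_params(par[seq_len(m)], par[m + seq_len(m)], par[2L * m + 1L])
  }
}

# Canonical parameter names, fastest FO component first.
#' @keywords internal
#' @noRd
par_names <- function(model) {
  if (model == "SO") c("k", "ar0", "aah0")
  else {
    m <- fo_order(model)
    c(paste0("a", seq_len(m)), paste0("t", seq_len(m)), "y0")
  }
}

# One Levenberg-Marquardt descent from a given start; returns par, rss,
# converged, and the nls.lm info code. Never throws on optimizer trouble.
#' @keywords internal
#' @noRd
lm_descend <- function(model, tt, a, par0) {
  lower <- model_lower(model)
  par0 <- pmax(par0, lower)
  resid_fn <- function(par) model_eval(model, tt, par) - a
  jac_fn <- if (model == "SO") NULL else {
    m <- fo_order(model)
    function(par) fo_jacobian(tt, par, m)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, maxfev = 20000)
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = par0, lower = lower, fn = resid_fn,
                         jac = jac_fn, control = ctrl)),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$par)))
    return(list(par = par0, rss = sum(resid_fn(par0)^2),
                converged = FALSE, info = 0L))
  list(par = pmax(fit$par, lower),
       rss = sum(resid_fn(fit$par)^2),
       converged = fit$info %in% 1:4,
       info = fit$info)
}

# Sort FO components fastest-first (ascending time constant) in a raw
# parameter vector, carrying a companion vector (std errors) along.
#' @keywords internal
#' @noRd
canonicalize_par <- function(model, par, companion = NULL) {
  if (model == "SO") return(list(par = par, companion = companion))
  m <- fo_order(model)
  ord <- order(par[m + seq_len(m)])
  idx <- c(ord, m + ord, 2L * m + 1L)
  list(par = par[idx],
       companion = if (is.null(companion)) NULL else companion[idx])
}

#' @keywords internal
#' @noRd
num_jacobian <- function(model, tt, par) {
  J <- matrix(0, length(tt), length(par))
  for (j in seq_along(par)) {
    h <- max(1e-8, 1e-7 * abs(par[j]))
    up <- dn <- par
    up[j] <- par[j] + h
    dn[j] <- max(par[j] - h, model_lower(model)[j])
    J[, j] <- (model_eval(model, tt, up) - model_eval(model, tt, dn)) /
      (up[j] - dn[j])
  }
  J
}

#' Fit a kinetic decay model to an absorbance-time trace
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of one of four
#' candidate laws to a [kinetic_trace()]: one to three parallel first-order
#' exponentials (`"FO1"`-`"FO3"`, see [fo_model()]) or the integrated
#' second-order rate law for unequal initial concentrations (`"SO"`, see
#' [so_model()]). Amplitudes, offsets and all rate parameters are
#' constrained non-negative. For `FO2`/`FO3` the optimizer is additionally
#' warm-started from the best lower-order fit with a zero extra amplitude,
#' which guarantees the nested-model RSS ordering. If no descent converges,
#' up to `restarts` log-normally perturbed restarts of the heuristic start
#' are tried (seeded, deterministic).
#'
#' Fit quality is summarised by `r_squared = 1 - RSS/TSS` (TSS about the
#' trace mean; 0 by convention on a zero-variance trace) and by the
#' overall-regression F test: `F = [(TSS - RSS)/(p - 1)] / [RSS/(n - p)]`,
#' whose upper-tail p-value is reported as `regression_pvalue` (the
#' probability that the coefficient of determination is zero; 1 by
#' convention on a zero-variance trace). Optimizer failure is reported via
#' `converged = FALSE`, never as an exception.
#'
#' @param trace a [kinetic_trace()].
#' @param model `"FO1"`, `"FO2"`, `"FO3"` or `"SO"`.
#' @param start optional [fo_params()] / [so_params()] starting values; when
#'   supplied they replace the heuristic (and warm) starts.
#' @param restarts perturbed restarts attempted when no start converges.
#' @param restart_seed integer seed making the restarts deterministic.
#' @return an object of class `decay_fit` with elements `model`, `params`
#'   (canonicalized, fastest component first), `param_std_errors`,
#'   `r_squared`, `regression_pvalue`, `residual_sum_squares`, `n_points`,
#'   `converged`, and the underlying `trace`. Methods: [coef()], [print()],
#'   [summary()], [predict()], [fitted()], [residuals()], [deviance()],
#'   [plot()], [simulate()].
#' @examples
#' p <- so_params(k = 0.01, ar0 = 1.0, aah0 = 1.5)
#' tr <- kinetic_trace(0:300, so_model(0:300, p), radical = "DPPH")
#' fit <- fit_kinetics(tr, "SO")
#' coef(fit)
#' @export
fit_kinetics <- function(trace, model = c("FO1", "FO2", "FO3", "SO"),
                         start = NULL, restarts = 5L, restart_seed = 1L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  model <- match.arg(model)
  starts <- if (!is.null(start)) {
    list(params_to_par(start))
  } else {
    s <- list(params_to_par(initial_guesses(trace, model)))
    if (model %in% c("FO2", "FO3")) {
      lower_model <- if (model == "FO3") "FO2" else "FO1"
      lower_fit <- fit_kinetics(trace, lower_model, restarts = restarts,
                                restart_seed = restart_seed)
      s <- c(s, list(embed_lower_fo(lower_fit$params,
                                    max(trace$times) - min(trace$times))))
    }
    s
  }
  fit_from_starts(trace, model, starts, restarts, restart_seed)
}

# Embed an order-(m-1) FO solution as an order-m start: extra component with
# zero amplitude, its time constant placed beyond the existing ones. The
# start then reproduces the lower-order model exactly.
#' @keywords internal
#' @noRd
embed_lower_fo <- function(p_lower, span) {
  tc_new <- max(max(p_lower$time_constants) * 10, span)
  c(p_lower$amplitudes, 0, p_lower$time_constants, tc_new, p_lower$y0)
}

#' @keywords internal
#' @noRd
fit_from_starts <- function(trace, model, starts, restarts, restart_seed) {
  n <- length(trace$times)
  npar <- model_npar(model)
  if (n < npar + 2L)
    stop_radkin(sprintf("trace of length %d too short to fit %s (%d parameters)",
                        n, model, npar),
                "radkin_insufficient_data_error")
  tt <- trace$times
  a <- trace$absorbance
  attempts <- lapply(starts, function(p0) lm_descend(model, tt, a, p0))
  ok <- vapply(attempts, `[[`, logical(1L), "converged")
  if (!any(ok) && restarts > 0L) {
    base <- starts[[1L]]
    extra <- with_seed(restart_seed, lapply(seq_len(restarts), function(i) {
      lm_descend(model, tt, a, base * exp(rnorm(length(base), 0, 0.3)))
    }))
    attempts <- c(attempts, extra)
    ok <- vapply(attempts, `[[`, logical(1L), "converged")
  }
  pool <- if (any(ok)) attempts[ok] else attempts
  best <- pool[[which.min(vapply(pool, `[[`, numeric(1L), "rss"))]]

  rss <- best$rss
  tss <- sum((a - mean(a))^2)
  if (tss <= .Machine$double.eps * max(1, sum(a^2))) {
    r2 <- 0
    pval <- 1
  } else {
    r2 <- max(0, min(1, 1 - rss / tss))
    fstat <- ((tss - rss) / (npar - 1)) / (rss / (n - npar))
    pval <- if (!is.finite(fstat)) 0
            else if (fstat <= 0) 1
            else pf(fstat, npar - 1, n - npar, lower.tail = FALSE)
  }

  se <- tryCatch({
    J <- if (model == "SO") num_jacobian(model, tt, best$par)
         else fo_jacobian(tt, best$par, fo_order(model))
    resvar <- rss / (n - npar)
    sqrt(diag(solve(crossprod(J))) * resvar)
  }, error = function(e) rep(NA_real_, npar))

  canon <- canonicalize_par(model, best$par, se)
  params <- par_to_params(model, canon$par)
  structure(list(model = model,
                 params = params,
                 param_std_errors = setNames(canon$companion, par_names(model)),
                 r_squared = r2,
                 regression_pvalue = pval,
                 residual_sum_squares = rss,
                 n_points = n,
                 converged = best$converged,
                 optim_info = best$info,
                 trace = trace),
            class = "decay_fit")
}
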