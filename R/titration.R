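# Forward model and nonlinear least-squares Ka estimation for UV-vis and
# fast-exchange NMR titrations of a 1:1 host-guest complex.

#' Construct a spectroscopic titration series
#'
#' A titration at constant total guest concentration: each sample holds the
#' guest at `guest_total` plus an increasing total host concentration, and
#' one observable is recorded per sample (absorbance at a fixed wavelength
#' for `mode = "uvvis"`, a population-averaged chemical shift for
#' `mode = "nmr"` under fast exchange). Samples are assumed individually
#' prepared, so no in-series dilution correction applies.
#'
#' @param host_totals total host concentrations (mol/L), non-negative and
#'   strictly increasing, length >= 4
#' @param observables observed signal at each point (AU or ppm)
#' @param guest_total constant total guest concentration (mol/L), > 0
#' @param mode `"uvvis"` or `"nmr"`
#' @param probe_label free-text probe identifier, e.g. `"283 nm"` or `"H(5)"`
#' @param slow_exchange logical; flag an NMR series in the slow-exchange
#'   regime (separate free/bound resonances). Such series cannot be described
#'   by the population-weighted model and [fit_titration()] refuses them.
#' @return an object of class `"spectro_titration"`
#' @export
spectro_titration <- function(host_totals, observables, guest_total,
                              mode = c("uvvis", "nmr"), probe_label = "",
                              slow_exchange = FALSE) {
  mode <- match.arg(mode)
  if (length(host_totals) != length(observables))
    stop("host_totals and observables must have equal length", call. = FALSE)
  if (length(host_totals) < 4L)
    stop("a titration series needs at least 4 points", call. = FALSE)
  if (any(host_totals < 0))
    stop("host_totals must be non-negative", call. = FALSE)
  if (any(diff(host_totals) <= 0))
    stop("host_totals must be strictly increasing", call. = FALSE)
  if (!is.numeric(guest_total) || length(guest_total) != 1L || guest_total <= 0)
    stop("'guest_total' must be a single positive concentration", call. = FALSE)
  structure(
    list(host_totals = as.numeric(host_totals),
         observables = as.numeric(observables),
         guest_total = guest_total, mode = mode,
         probe_label = probe_label, slow_exchange = isTRUE(slow_exchange)),
    class = "spectro_titration")
}

#' @export
print.spectro_titration <- function(x, ...) {
  cat(sprintf("%s titration (%s): %d points, guest %.4g M, host %.4g-%.4g M\n",
              x$mode, x$probe_label, length(x$host_totals), x$guest_total,
              min(x$host_totals), max(x$host_totals)))
  invisible(x)
}

#' Predict titration observables under the two-state 1:1 model
#'
#' Both UV-vis absorbance and fast-exchange NMR shifts are population
#' averages of the free and fully-bound guest signals:
#' \deqn{y_i = y_{free} + (y_{bound} - y_{free}) \, \frac{[HG]_i}{G_0}}
#' with \eqn{[HG]_i} from the exact 1:1 mass balance at each host total.
#' Molar absorptivities are folded into (`obs_free`, `obs_bound`).
#'
#' @param series a `"spectro_titration"` (only its design -- host totals and
#'   guest total -- is used)
#' @param ka association constant (1/M), >= 0
#' @param obs_free signal of the free guest (value at zero host)
#' @param obs_bound signal of the fully bound guest
#' @return numeric vector of predicted observables
#' @export
predict_observable <- function(series, ka, obs_free, obs_bound) {
  stopifnot(inherits(series, "spectro_titration"))
  if (ka < 0) stop("'ka' must be non-negative", call. = FALSE)
  frac <- .complex_1to1(series$host_totals, series$guest_total, ka) /
    series$guest_total
  obs_free + (obs_bound - obs_free) * frac
}

#' Fit an association constant to a titration series
#'
#' Minimises the sum of squared residuals over
#' \eqn{(\log_{10} K_a, y_{free}, y_{bound})} by Levenberg-Marquardt
#' ([minpack.lm::nls.lm]). Working in \eqn{\log_{10} K_a} enforces
#' positivity and conditions the problem across the 1e1-1e9 range typical
#' of host-guest chemistry. Starting values come from a grid search over
#' \eqn{\log_{10} K_a \in \{0, 1, \dots, 9\}} with `obs_free` set to the
#' first observable and `obs_bound` to the last; ties are broken towards the
#' lowest `ka`. Standard errors are asymptotic, from the Jacobian at the
#' optimum; see [profile_ka_uncertainty()] for a bootstrap alternative.
#'
#' @param series a `"spectro_titration"`; the observables must not be all
#'   equal (a flat series carries no binding information) and NMR series
#'   flagged `slow_exchange` are refused
#' @param max_iter maximum Levenberg-Marquardt iterations
#' @return an object of class `"binding_fit"`: list with `ka`, `ka_stderr`,
#'   `obs_free`, `obs_bound`, `residual_rms`, `n_iterations`, `converged`,
#'   `log10_ka`, `log10_ka_stderr`, `fitted`, `residuals` and the input
#'   `series`
#' @examples
#' ser <- generate_titration(guest_total = 4e-5, max_equiv = 3, ka = 1.05e5,
#'                           obs_free = 0.40, obs_bound = 0.80)
#' fit <- fit_titration(ser)
#' fit$ka
#' @export
fit_titration <- function(series, max_iter = 200L) {
  stopifnot(inherits(series, "spectro_titration"))
  if (series$mode == "nmr" && series$slow_exchange)
    stop(paste("slow-exchange NMR series cannot be fit by the",
               "population-weighted fast-exchange model"), call. = FALSE)
  y <- series$observables
  if (diff(range(y)) == 0)
    stop("unidentifiable model: observables are all equal", call. = FALSE)

  resid_fun <- function(p)
    predict_observable(series, ka = 10^p[1],
                       obs_free = p[2], obs_bound = p[3]) - y

  grid <- 0:9
  costs <- vapply(grid, function(lk)
    sum(resid_fun(c(lk, y[1], y[length(y)]))^2), numeric(1))
  lk0 <- grid[which(costs == min(costs))[1]]  # lowest ka among ties

  ctrl <- minpack.lm::nls.lm.control(maxiter = as.integer(max_iter),
                                     ftol = 1e-10, ptol = 1e-12)
  lm <- minpack.lm::nls.lm(par = c(lk0, y[1], y[length(y)]),
                           fn = resid_fun, control = ctrl)
  p <- lm$par
  res <- -resid_fun(p)            # observed - fitted
  converged <- lm$info %in% 1:3
  se <- .asymptotic_se(resid_fun, p)
  ka <- 10^p[1]
  structure(
    list(ka = ka,
         ka_stderr = log(10) * ka * se[1],   # delta method from log10 scale
         obs_free = p[2], obs_bound = p[3],
         obs_free_stderr = se[2], obs_bound_stderr = se[3],
         residual_rms = sqrt(mean(res^2)),
         n_iterations = lm$niter, converged = converged,
         log10_ka = p[1], log10_ka_stderr = se[1],
         fitted = predict_observable(series, ka, p[2], p[3]),
         residuals = res,
         message = lm$message, series = series),
    class = "binding_fit")
}

# asymptotic standard errors from a numeric Jacobian of the residual vector
.asymptotic_se <- function(resid_fun, p) {
  J <- .num_jacobian(resid_fun, p)
  res <- resid_fun(p)
  dof <- max(length(res) - length(p), 1L)
  s2 <- sum(res^2) / dof
  JtJ <- crossprod(J)
  cov <- tryCatch(s2 * solve(JtJ), error = function(e)
    matrix(NA_real_, length(p), length(p)))
  sqrt(pmax(diag(cov), 0))
}

.num_jacobian <- function(f, p, eps = 1e-7) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1)
    pp <- p; pp[j] <- p[j] + h
    pm <- p; pm[j] <- p[j] - h
    J[, j] <- (f(pp) - f(pm)) / (2 * h)
  }
  J
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("1:1 binding fit (%s, %s)\n", x$series$mode,
              x$series$probe_label))
  cat(sprintf("  Ka = %.4g +/- %.2g 1/M   (converged: %s, %d iterations)\n",
              x$ka, x$ka_stderr, x$converged, x$n_iterations))
  cat(sprintf("  obs_free = %.6g, obs_bound = %.6g, residual rms = %.3g\n",
              x$obs_free, x$obs_bound, x$residual_rms))
  invisible(x)
}

#' Residual-bootstrap confidence interval for a fitted Ka
#'
#' Resamples the fit residuals with replacement, adds them back to the
#' fitted curve, refits, and reports the 2.5-97.5 percentile interval of the
#' bootstrap Ka distribution. Deterministic for a fixed seed.
#'
#' Least-squares residuals underestimate the error scale in small series
#' (their variance is \eqn{(n - p)/n} of the noise variance), so the
#' resampled residuals are rescaled by \eqn{\sqrt{n/(n - p)}} before
#' resampling -- the standard degrees-of-freedom correction for regression
#' residual bootstraps.
#'
#' @param series the fitted `"spectro_titration"`
#' @param fit a converged `"binding_fit"` for `series`
#' @param n_boot number of bootstrap replicates; fewer than 50 triggers a
#'   recorded warning (the interval is then unreliable)
#' @param seed integer seed for the resampling stream
#' @param level confidence level (default 0.95)
#' @return list of class `"ka_interval"` with `lower`, `upper`, `level`,
#'   `n_boot`, `seed`, `ka_boot` (the bootstrap draws) and `warnings`
#' @export
profile_ka_uncertainty <- function(series, fit, n_boot = 200L, seed = 1L,
                                   level = 0.95) {
  stopifnot(inherits(series, "spectro_titration"), inherits(fit, "binding_fit"))
  if (!isTRUE(fit$converged))
    stop("bootstrap requires a converged fit", call. = FALSE)
  warnings <- character(0)
  if (n_boot < 50L)
    warnings <- c(warnings, sprintf(
      "n_boot = %d is below 50; percentile interval unreliable", n_boot))
  y <- series$observables
  n_pts <- length(y)
  res <- fit$residuals * sqrt(n_pts / max(n_pts - 3L, 1L))
  yhat <- y - fit$residuals
  p0 <- c(fit$log10_ka, fit$obs_free, fit$obs_bound)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 100L, ftol = 1e-10, ptol = 1e-12)
  ka_boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ystar <- yhat + sample(res, replace = TRUE)
      rf <- function(p)
        predict_observable(series, 10^p[1], p[2], p[3]) - ystar
      10^minpack.lm::nls.lm(par = p0, fn = rf, control = ctrl)$par[1]
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  # Efron order-statistic convention for bootstrap percentiles
  srt <- sort(ka_boot)
  lo_i <- max(floor((n_boot + 1) * alpha), 1L)
  hi_i <- min(n_boot + 1L - lo_i, n_boot)
  qs <- c(srt[lo_i], srt[hi_i])
  structure(list(lower = qs[1], upper = qs[2], level = level,
                 n_boot = n_boot, seed = seed, ka_boot = ka_boot,
                 warnings = warnings),
            class = "ka_interval")
}

#' @export
print.ka_interval <- function(x, ...) {
  cat(sprintf("Bootstrap %.0f%% interval for Ka: [%.4g, %.4g] (%d replicates, seed %d)\n",
              100 * x$level, x$lower, x$upper, x$n_boot, x$seed))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# run expr with a fixed seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  eval.parent(substitute(expr))
}
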