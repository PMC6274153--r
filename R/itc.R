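# Incremental-injection 1:1 ITC: forward heat model with cell-displacement
# bookkeeping, and least-squares estimation of (N, Ka, dH).

UCAL_PER_KCAL <- 1e9  # 1 kcal = 1e3 cal = 1e9 ucal

#' Describe an ITC titration experiment
#'
#' An overfill-cell calorimeter: each injection of titrant (host) displaces
#' an equal volume of cell solution. Concentrations are in mol/L and volumes
#' in litres; see [read_itc_experiment()] for the unit-suffixed user-facing
#' JSON format (uL / mM / degrees C).
#'
#' @param cell_volume active cell volume \eqn{V_0} (L), > 0
#' @param cell_conc guest concentration initially in the cell (mol/L), > 0
#' @param syringe_conc host concentration in the syringe (mol/L); must exceed
#'   `cell_conc` (the titrant is the concentrated species)
#' @param injection_volumes per-injection volumes (L), all > 0; the schedule
#'   may not inject more than one cell volume in total
#' @param temperature kelvin (default 298.15, i.e. 25 degrees C)
#' @param heats optional measured/simulated heats per injection (ucal)
#' @return an object of class `"itc_experiment"`
#' @export
itc_experiment <- function(cell_volume, cell_conc, syringe_conc,
                           injection_volumes, temperature = 298.15,
                           heats = NULL) {
  if (!is.numeric(cell_volume) || length(cell_volume) != 1L || cell_volume <= 0)
    stop("'cell_volume' must be a single positive volume (L)", call. = FALSE)
  if (!is.numeric(cell_conc) || length(cell_conc) != 1L || cell_conc <= 0)
    stop("'cell_conc' must be a single positive concentration", call. = FALSE)
  if (!is.numeric(syringe_conc) || length(syringe_conc) != 1L ||
      syringe_conc <= cell_conc)
    stop("'syringe_conc' must exceed 'cell_conc' (titrant is concentrated)",
         call. = FALSE)
  if (length(injection_volumes) < 1L || any(injection_volumes <= 0))
    stop("injection volumes must all be positive", call. = FALSE)
  if (sum(injection_volumes) > cell_volume)
    stop("cumulative injected volume exceeds the cell volume", call. = FALSE)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("'temperature' must be positive (kelvin)", call. = FALSE)
  if (!is.null(heats) && length(heats) != length(injection_volumes))
    stop("'heats' must have one value per injection", call. = FALSE)
  structure(
    list(cell_volume = cell_volume, cell_conc = cell_conc,
         syringe_conc = syringe_conc,
         injection_volumes = as.numeric(injection_volumes),
         temperature = temperature,
         heats = if (is.null(heats)) NULL else as.numeric(heats)),
    class = "itc_experiment")
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf(
    "ITC experiment: V0 = %.4g uL, cell %.4g mM guest, syringe %.4g mM host\n",
    x$cell_volume * 1e6, x$cell_conc * 1e3, x$syringe_conc * 1e3))
  cat(sprintf("  %d injections (%.3g uL total), T = %.2f K%s\n",
              length(x$injection_volumes), sum(x$injection_volumes) * 1e6,
              x$temperature,
              if (is.null(x$heats)) "" else ", heats attached"))
  invisible(x)
}

#' Per-injection total concentrations in the ITC cell
#'
#' Recursive overflow (displacement) model: injection i of volume
#' \eqn{dV_i} dilutes everything in the cell by \eqn{1 - dV_i/V_0} and
#' delivers \eqn{X_{syr} dV_i / V_0} of titrant, so
#' \deqn{M_i = M_{i-1}(1 - dV_i/V_0), \qquad
#'       X_i = X_{i-1}(1 - dV_i/V_0) + X_{syr}\, dV_i/V_0,}
#' with \eqn{M_0} the initial guest (cell) concentration and \eqn{X_0 = 0}.
#'
#' @param exp an `"itc_experiment"`
#' @return data.frame with columns `injection`, `host_total`, `guest_total`
#'   (concentrations in the cell after each injection, mol/L)
#' @export
track_cell_concentrations <- function(exp) {
  stopifnot(inherits(exp, "itc_experiment"))
  k <- length(exp$injection_volumes)
  M <- X <- numeric(k)
  m_prev <- exp$cell_conc; x_prev <- 0
  for (i in seq_len(k)) {
    f <- exp$injection_volumes[i] / exp$cell_volume
    M[i] <- m_prev * (1 - f)
    X[i] <- x_prev * (1 - f) + exp$syringe_conc * f
    m_prev <- M[i]; x_prev <- X[i]
  }
  data.frame(injection = seq_len(k), host_total = X, guest_total = M)
}

#' Simulate per-injection ITC heats for a 1:1 binding model
#'
#' With effective binding-site concentration \eqn{n M_i}, the complex
#' concentration after injection i is the 1:1 equilibrium solution
#' \eqn{c_i = c(X_i, n M_i, K_a)}. The heat evolved by injection i accounts
#' for the complex expelled by displacement:
#' \deqn{q_i = \Delta H \; V_0 \left(c_i - c_{i-1}(1 - dV_i/V_0)\right)}
#' converted to microcalories. Over a saturating schedule the cumulative
#' heat approaches \eqn{\Delta H V_0 n M_{final}} plus the expelled-complex
#' correction.
#'
#' @param exp an `"itc_experiment"`
#' @param n binding stoichiometry (sites per guest)
#' @param ka association constant (1/M), >= 0 (`Inf` = stoichiometric)
#' @param dh molar binding enthalpy (kcal/mol)
#' @param offset constant per-injection heat of dilution (ucal), default 0
#' @return numeric vector of heats (ucal), one per injection
#' @export
simulate_itc_heats <- function(exp, n = 1, ka, dh, offset = 0) {
  stopifnot(inherits(exp, "itc_experiment"))
  if (ka < 0) stop("'ka' must be non-negative", call. = FALSE)
  conc <- track_cell_concentrations(exp)
  k <- nrow(conc)
  q <- numeric(k)
  c_prev <- 0
  for (i in seq_len(k)) {
    f <- exp$injection_volumes[i] / exp$cell_volume
    ci <- .complex_1to1(conc$host_total[i], n * conc$guest_total[i], ka)
    q[i] <- dh * exp$cell_volume * (ci - c_prev * (1 - f)) * UCAL_PER_KCAL +
      offset
    c_prev <- ci
  }
  q
}

#' Fit the 1:1 ITC model to measured injection heats
#'
#' Least squares over \eqn{(n, \log_{10} K_a, \Delta H)} by
#' Levenberg-Marquardt. Initialisation: \eqn{n = 1},
#' \eqn{\Delta H = q_1 / (\text{moles injected in 1})}, and
#' \eqn{\log_{10} K_a} from a unit-spaced grid search. The derived
#' quantities are filled from the thermodynamic identities
#' \eqn{\Delta G = -RT \ln K_a} and \eqn{T\Delta S = \Delta H - \Delta G}
#' (identities, never fitted).
#'
#' When the final molar ratio does not reach the fitted \eqn{n}, the
#' saturation plateau is unobserved and the fit is flagged
#' `identifiability_low`.
#'
#' @param exp an `"itc_experiment"` carrying `heats`; at least 8 injections
#' @param fit_offset logical; also fit a constant per-injection heat of
#'   dilution (default FALSE, offset fixed at 0)
#' @param max_iter maximum Levenberg-Marquardt iterations
#' @return object of class `"itc_fit"`: list with `n`, `ka`, `dh` (kcal/mol),
#'   `dg`, `tds` (kcal/mol, from the identities), standard errors
#'   `n_stderr`, `ka_stderr`, `dh_stderr`, `offset`, `converged`,
#'   `identifiability_low`, `fitted`, `residuals`, `temperature` and the
#'   input `exp`
#' @examples
#' ex <- generate_itc(cell_conc = 5e-5, n = 1.12, ka = 4.95e4, dh = -11.08)
#' fit <- fit_itc(ex)
#' c(fit$n, fit$ka, fit$dh, fit$dg, fit$tds)
#' @export
fit_itc <- function(exp, fit_offset = FALSE, max_iter = 200L) {
  stopifnot(inherits(exp, "itc_experiment"))
  if (is.null(exp$heats))
    stop("experiment carries no heats to fit", call. = FALSE)
  if (length(exp$heats) < 8L)
    stop("ITC fitting needs at least 8 injections", call. = FALSE)
  q <- exp$heats
  if (all(q == 0))
    stop("unidentifiable model: all heats are zero", call. = FALSE)

  moles1 <- exp$syringe_conc * exp$injection_volumes[1]
  dh0 <- q[1] / UCAL_PER_KCAL / moles1
  resid_fun <- function(p)
    simulate_itc_heats(exp, n = p[1], ka = 10^p[2], dh = p[3],
                       offset = if (fit_offset) p[4] else 0) - q

  grid <- 1:9
  costs <- vapply(grid, function(lk)
    sum(resid_fun(c(1, lk, dh0, 0)[seq_len(3 + fit_offset)])^2), numeric(1))
  lk0 <- grid[which(costs == min(costs))[1]]

  p0 <- c(1, lk0, dh0)
  if (fit_offset) p0 <- c(p0, 0)
  ctrl <- minpack.lm::nls.lm.control(maxiter = as.integer(max_iter),
                                     ftol = 1e-12, ptol = 1e-12)
  lm <- minpack.lm::nls.lm(par = p0, fn = resid_fun, control = ctrl)
  p <- lm$par
  res <- -resid_fun(p)            # observed - fitted
  se <- .asymptotic_se(resid_fun, p)
  ka <- 10^p[2]
  dg <- delta_g_from_ka(ka, exp$temperature)
  conc <- track_cell_concentrations(exp)
  max_ratio <- max(conc$host_total / conc$guest_total)
  structure(
    list(n = p[1], ka = ka, dh = p[3],
         dg = dg, tds = tds_from_dh_dg(p[3], dg),
         n_stderr = se[1], ka_stderr = log(10) * ka * se[2],
         dh_stderr = se[3],
         offset = if (fit_offset) p[4] else 0,
         converged = lm$info %in% 1:3,
         identifiability_low = max_ratio < p[1],
         residual_rms = sqrt(mean(res^2)),
         n_iterations = lm$niter,
         fitted = q - res, residuals = res,
         temperature = exp$temperature,
         message = lm$message, exp = exp),
    class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("1:1 ITC fit\n")
  cat(sprintf("  N   = %.3f +/- %.3f\n", x$n, x$n_stderr))
  cat(sprintf("  Ka  = %.4g +/- %.2g 1/M\n", x$ka, x$ka_stderr))
  cat(sprintf("  dH  = %.2f +/- %.2f kcal/mol\n", x$dh, x$dh_stderr))
  cat(sprintf("  dG  = %.2f kcal/mol, TdS = %.2f kcal/mol (T = %.2f K)\n",
              x$dg, x$tds, x$temperature))
  if (x$identifiability_low)
    cat("  warning: saturation not reached (max molar ratio < N)\n")
  if (!x$converged) cat("  warning: optimizer did not converge --", x$message, "\n")
  invisible(x)
}
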