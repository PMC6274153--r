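# Exact 1:1 host-guest equilibrium and continuous-variation (Job) analysis.

#' Solve the 1:1 host-guest binding equilibrium
#'
#' Computes the unique physical root of the 1:1 mass balance
#' \deqn{K_a (H_0 - c)(G_0 - c) = c}
#' where \eqn{c} is the complex concentration. The root is evaluated in the
#' numerically stable conjugate form
#' \deqn{c = \frac{2 H_0 G_0}{S + \sqrt{S^2 - 4 H_0 G_0}}, \quad
#'       S = H_0 + G_0 + 1/K_a,}
#' which avoids the catastrophic cancellation the textbook
#' \eqn{(S - \sqrt{S^2 - 4H_0G_0})/2} form suffers when
#' \eqn{S^2 \gg 4 H_0 G_0} (weak binding or dilute solutions).
#'
#' The limits \eqn{K_a = 0} (no association, \eqn{c = 0}) and
#' \eqn{K_a = \infty} (stoichiometric binding,
#' \eqn{c = \min(H_0, G_0)}) are handled explicitly.
#'
#' @param total_host total host concentration \eqn{H_0} (mol/L), >= 0
#' @param total_guest total guest concentration \eqn{G_0} (mol/L), >= 0
#' @param ka association constant \eqn{K_a} (1/(mol/L)), >= 0; `Inf` allowed
#' @return an object of class `"equilibrium_state"`: a list with elements
#'   `total_host`, `total_guest`, `ka`, `complex_conc`, `free_host`,
#'   `free_guest` (all mol/L except `ka`)
#' @examples
#' st <- solve_equilibrium_1to1(1e-4, 1e-4, 1e4)
#' st$complex_conc            # ~3.8197e-5 M
#' bound_fraction(st)         # ~0.382
#' @seealso [bound_fraction()], [job_curve()]
#' @export
solve_equilibrium_1to1 <- function(total_host, total_guest, ka) {
  .check_scalar_nonneg(total_host, "total_host")
  .check_scalar_nonneg(total_guest, "total_guest")
  if (!is.numeric(ka) || length(ka) != 1L || is.na(ka) || ka < 0)
    stop("'ka' must be a single non-negative number", call. = FALSE)
  cc <- .complex_1to1(total_host, total_guest, ka)
  structure(
    list(total_host = total_host, total_guest = total_guest, ka = ka,
         complex_conc = cc,
         free_host = total_host - cc,
         free_guest = total_guest - cc),
    class = "equilibrium_state")
}

# vectorised core; H, G, ka recycled to the longest argument
.complex_1to1 <- function(H, G, ka) {
  len <- max(length(H), length(G), length(ka))
  H <- rep_len(H, len); G <- rep_len(G, len); ka <- rep_len(ka, len)
  cc <- numeric(len)
  inf <- is.infinite(ka)
  cc[inf] <- pmin(H[inf], G[inf])
  zero <- !inf & (ka == 0 | H == 0 | G == 0)
  cc[zero] <- 0
  gen <- !inf & !zero
  if (any(gen)) {
    S <- H[gen] + G[gen] + 1 / ka[gen]
    disc <- pmax(S * S - 4 * H[gen] * G[gen], 0)
    cc[gen] <- pmin(2 * H[gen] * G[gen] / (S + sqrt(disc)),
                    H[gen], G[gen])
  }
  cc
}

.check_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative number", name),
         call. = FALSE)
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("1:1 host-guest equilibrium state\n")
  cat(sprintf("  totals (M): host %.6g, guest %.6g; Ka = %.6g 1/M\n",
              x$total_host, x$total_guest, x$ka))
  cat(sprintf("  complex %.6g M; free host %.6g M; free guest %.6g M\n",
              x$complex_conc, x$free_host, x$free_guest))
  invisible(x)
}

#' Fraction of guest bound at equilibrium
#'
#' `complex_conc / total_guest`, the quantity population-weighted
#' spectroscopic observables are linear in.
#'
#' @param state an `"equilibrium_state"` from [solve_equilibrium_1to1()]
#' @return a fraction in \[0, 1\]
#' @export
bound_fraction <- function(state) {
  stopifnot(inherits(state, "equilibrium_state"))
  if (state$total_guest == 0)
    stop("bound fraction undefined: total_guest is 0", call. = FALSE)
  state$complex_conc / state$total_guest
}

# ---- generalised single-complex m:n equilibrium ----------------------------

#' Solve a single-complex m:n host-guest equilibrium
#'
#' Solves \eqn{\beta (H_0 - m c)^m (G_0 - n c)^n = c} for the extent of
#' complexation \eqn{c} by bisection on \eqn{c \in [0, \min(H_0/m, G_0/n)]};
#' the left side is decreasing and the right increasing in \eqn{c}, so the
#' root is unique. Included to demonstrate how a Job maximum discriminates
#' stoichiometry: an \eqn{H_mG_n} complex peaks at host mole fraction
#' \eqn{m/(m+n)}.
#'
#' @param total_host,total_guest total concentrations (mol/L)
#' @param beta overall formation constant (units \eqn{M^{-(m+n-1)}})
#' @param m,n integer stoichiometric coefficients, each in 1..3
#' @return complex concentration (mol/L)
#' @export
solve_equilibrium_mn <- function(total_host, total_guest, beta, m = 1L, n = 1L) {
  .check_scalar_nonneg(total_host, "total_host")
  .check_scalar_nonneg(total_guest, "total_guest")
  .check_scalar_nonneg(beta, "beta")
  if (!(m %in% 1:3) || !(n %in% 1:3))
    stop("'m' and 'n' must be integers in 1..3", call. = FALSE)
  .complex_mn(total_host, total_guest, beta, m, n)
}

.complex_mn <- function(H, G, beta, m, n) {
  if (m == 1L && n == 1L) return(.complex_1to1(H, G, beta))
  cmax <- min(H / m, G / n)
  if (cmax == 0 || beta == 0) return(0)
  if (is.infinite(beta)) return(cmax)
  f <- function(cc) beta * (H - m * cc)^m * (G - n * cc)^n - cc
  lo <- 0; hi <- cmax
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ---- Job (continuous variation) curves -------------------------------------

#' Simulate a continuous-variation (Job) curve
#'
#' At constant total concentration `total_conc`, each sample has
#' \eqn{H_0 = x C_{tot}} and \eqn{G_0 = (1 - x) C_{tot}} for host mole
#' fraction \eqn{x}; the complex concentration is solved at each grid point.
#' For a 1:1 complex the curve is symmetric about \eqn{x = 0.5}; an
#' \eqn{H_mG_n} complex peaks at \eqn{x = m/(m+n)}.
#'
#' @param total_conc constant host + guest total concentration (mol/L), > 0
#' @param mole_fractions host mole fractions in \[0, 1\]; default an
#'   11-point even grid, a typical continuous-variation series
#' @param ka association (or overall formation) constant
#' @param m,n complex stoichiometry (default 1:1)
#' @return an object of class `"job_curve"`: list with `total_conc`,
#'   `mole_fractions`, `complex_concs`, `ka`, `m`, `n` and `observable`
#'   (NULL unless attached by a generator or read from data)
#' @examples
#' jc <- job_curve(5e-5, ka = 1.30e4)
#' job_maximum(jc)   # 0.5 for any 1:1 curve
#' @export
job_curve <- function(total_conc, mole_fractions = seq(0, 1, length.out = 11),
                      ka, m = 1L, n = 1L) {
  if (!is.numeric(total_conc) || length(total_conc) != 1L || total_conc <= 0)
    stop("'total_conc' must be a single positive number", call. = FALSE)
  if (any(mole_fractions < 0 | mole_fractions > 1))
    stop("mole fractions must lie in [0, 1]", call. = FALSE)
  cc <- vapply(mole_fractions, function(x)
    .complex_mn(x * total_conc, (1 - x) * total_conc, ka, m, n), numeric(1))
  structure(
    list(total_conc = total_conc, mole_fractions = mole_fractions,
         complex_concs = cc, ka = ka, m = m, n = n, observable = NULL),
    class = "job_curve")
}

#' @export
print.job_curve <- function(x, ...) {
  cat(sprintf("Job curve: %d points, C_tot = %.4g M, %d:%d model, Ka = %.4g\n",
              length(x$mole_fractions), x$total_conc, x$m, x$n, x$ka))
  invisible(x)
}

#' Locate the maximum of a Job curve
#'
#' Finds the best grid point and refines the continuous-curve argmax by
#' golden-section search between its neighbours. Model-backed curves (those
#' built by [job_curve()] or [generate_job()]) are refined against the exact
#' equilibrium solution; purely empirical curves (observable only, no model)
#' fall back on the parabola through the three points around the grid maximum.
#'
#' The position of the maximum indicates binding stoichiometry: 0.5 for 1:1,
#' \eqn{m/(m+n)} for a single \eqn{H_mG_n} complex.
#'
#' @param curve a `"job_curve"`
#' @param tol absolute tolerance on the mole fraction (default 1e-8)
#' @return host mole fraction of the maximum
#' @export
job_maximum <- function(curve, tol = 1e-8) {
  stopifnot(inherits(curve, "job_curve"))
  x <- curve$mole_fractions
  y <- if (!is.null(curve$observable)) curve$observable else curve$complex_concs
  if (length(x) < 3L)
    stop("need at least 3 points to locate a Job maximum", call. = FALSE)
  if (diff(range(y)) == 0)
    stop("no maximum: Job curve is flat", call. = FALSE)
  i <- which.max(y)
  lo <- x[max(i - 1L, 1L)]
  hi <- x[min(i + 1L, length(x))]
  if (!is.null(curve$ka) && !is.null(curve$total_conc)) {
    f <- function(xx) .complex_mn(xx * curve$total_conc,
                                  (1 - xx) * curve$total_conc,
                                  curve$ka, curve$m, curve$n)
    .golden_max(f, lo, hi, tol = tol)
  } else {
    if (i == 1L || i == length(x))
      return(x[i])
    .parabola_vertex(x[(i - 1L):(i + 1L)], y[(i - 1L):(i + 1L)])
  }
}

.golden_max <- function(f, a, b, tol = 1e-8) {
  gr <- (sqrt(5) - 1) / 2
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- f(c1); fd <- f(d1)
  while (b - a > tol) {
    if (fc >= fd) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- f(c1)
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- f(d1)
    }
  }
  (a + b) / 2
}

.parabola_vertex <- function(x, y) {
  d21 <- (y[2] - y[1]) / (x[2] - x[1])
  d32 <- (y[3] - y[2]) / (x[3] - x[2])
  curv <- (d32 - d21) / (x[3] - x[1])
  if (curv >= 0) return(x[which.max(y)])
  0.5 * (x[1] + x[2] - d21 / curv)
}
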