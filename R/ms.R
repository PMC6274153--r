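# Monoisotopic mass arithmetic and protonated host-guest adduct assignment
# for ESI-MS stoichiometry confirmation.

# most-abundant-isotope masses (Da)
.MONO_MASSES <- c(C = 12.0,
                  H = 1.0078250319,
                  N = 14.0030740052,
                  O = 15.9949146221,
                  S = 31.97207069,
                  P = 30.97376151)

PROTON_MASS <- 1.00727646688  # Da; proton, not hydrogen atom

#' Parse a molecular formula string
#'
#' Hill-like notation, case-sensitive: an element symbol is one capital
#' letter optionally followed by one lowercase letter, with an optional
#' count (default 1). Repeated symbols are summed.
#'
#' @param formula e.g. `"C42H42N28O14"`
#' @return named integer vector of element counts
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L)
    stop("'formula' must be a single string", call. = FALSE)
  if (formula == "") return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop(sprintf("cannot parse formula '%s'", formula), call. = FALSE)
  sym <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  cnt[is.na(cnt)] <- 1L
  tapply_counts <- tapply(cnt, sym, sum)
  out <- as.integer(tapply_counts)
  names(out) <- names(tapply_counts)
  out
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of count times most-abundant-isotope mass over the embedded table
#' (12C, 1H, 14N, 16O, 32S, 31P). Monoisotopic -- not average -- masses are
#' what high-resolution ESI instruments report for small molecules.
#'
#' @param formula a formula string or a named count vector from
#'   [parse_formula()]; the empty formula has mass 0
#' @return mass in Da
#' @examples
#' monoisotopic_mass("C10H16N6S")   # cimetidine, 252.1157
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) return(0)
  if (is.null(names(counts)) || any(counts < 0))
    stop("formula must be a named vector of non-negative counts",
         call. = FALSE)
  unknown <- setdiff(names(counts), names(.MONO_MASSES))
  if (length(unknown) > 0L)
    stop(sprintf("unknown element symbol(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  sum(.MONO_MASSES[names(counts)] * counts)
}

#' m/z of a protonated host-guest adduct
#'
#' \deqn{m/z = \frac{a M_{host} + b M_{guest} + z \, m_{proton}}{z}}
#' for an \eqn{[aH + bG + zH^+]^{z+}} ion, using monoisotopic masses and
#' the proton mass (1.00727646688 Da) per charge. Full precision is
#' returned; round to 2 decimal places to compare with values printed in
#' the literature.
#'
#' @param host,guest formula strings or named count vectors
#' @param n_host,n_guest copies of each in the adduct (sum >= 1)
#' @param charge number of protons added, >= 1
#' @return mass-to-charge (Th)
#' @examples
#' round(adduct_mz("C42H42N28O14", "C10H16N6S", charge = 2), 2)  # 708.24
#' @export
adduct_mz <- function(host, guest, n_host = 1L, n_guest = 1L, charge = 1L) {
  if (charge < 1) stop("'charge' must be a positive integer", call. = FALSE)
  if (n_host < 0 || n_guest < 0 || n_host + n_guest < 1)
    stop("adduct must contain at least one molecule", call. = FALSE)
  (n_host * monoisotopic_mass(host) + n_guest * monoisotopic_mass(guest) +
     charge * PROTON_MASS) / charge
}

#' Assign an observed m/z peak to host-guest adduct compositions
#'
#' Enumerates compositions \eqn{(a, b)} with \eqn{0 \le a, b \le}
#' `max_n` and \eqn{a + b \ge 1}, computes the protonated adduct m/z at
#' the given charge, and returns those within `tol_ppm` of the observation,
#' sorted by absolute ppm error (ties towards the smaller total number of
#' molecules). An empty result means no composition explains the peak.
#'
#' @param obs_mz observed mass-to-charge (Th), > 0
#' @param charge charge state (protons), >= 1
#' @param host,guest formula strings or named count vectors
#' @param max_n maximum copies of host and of guest considered
#' @param tol_ppm match window in parts per million (default 30, a
#'   conservative external-calibration window)
#' @return data.frame with columns `n_host`, `n_guest`, `charge`,
#'   `calc_mz`, `obs_mz`, `error_ppm`
#' @examples
#' assign_peak(708.23, 2, "C42H42N28O14", "C10H16N6S")
#' @export
assign_peak <- function(obs_mz, charge, host, guest, max_n = 2L,
                        tol_ppm = 30) {
  if (obs_mz <= 0) stop("'obs_mz' must be positive", call. = FALSE)
  if (max_n < 1) stop("'max_n' must be at least 1", call. = FALSE)
  grid <- expand.grid(n_host = 0:max_n, n_guest = 0:max_n)
  grid <- grid[grid$n_host + grid$n_guest >= 1L, , drop = FALSE]
  calc <- mapply(function(a, b) adduct_mz(host, guest, a, b, charge),
                 grid$n_host, grid$n_guest)
  err <- (obs_mz - calc) / calc * 1e6
  keep <- abs(err) <= tol_ppm
  out <- data.frame(n_host = grid$n_host[keep], n_guest = grid$n_guest[keep],
                    charge = rep(charge, sum(keep)), calc_mz = calc[keep],
                    obs_mz = rep(obs_mz, sum(keep)),
                    error_ppm = err[keep], row.names = NULL)
  out[order(abs(out$error_ppm), out$n_host + out$n_guest), , drop = FALSE]
}

#' Molecular formulas of cucurbit[7]uril and three H2-antagonist guests
#'
#' Standard chemical identities of the host macrocycle and the drug guests
#' studied with it, as element-count formula strings. Reference identities,
#' not measured data.
#'
#' @return data.frame with columns `species`, `abbrev`, `formula`
#' @export
hg_formulas <- function() {
  data.frame(
    species = c("cucurbit[7]uril", "cimetidine", "famotidine", "nizatidine"),
    abbrev = c("CB7", "CT", "FT", "NT"),
    formula = c("C42H42N28O14", "C10H16N6S", "C8H15N7O2S3", "C12H21N5O2S2"),
    stringsAsFactors = FALSE)
}
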