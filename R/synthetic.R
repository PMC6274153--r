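# Seeded generators for titration, Job and ITC datasets with the
# statistical structure the fitting stages assume.

#' Generate a synthetic spectroscopic titration
#'
#' Evenly spaced host totals from 0 to `max_equiv * guest_total`, observables
#' from the two-state model of [predict_observable()] plus additive
#' homoscedastic Gaussian noise. Identical arguments and seed reproduce the
#' dataset bit for bit.
#'
#' @param guest_total constant guest concentration (mol/L)
#' @param max_equiv maximum host:guest equivalents (default 6, the widest
#'   design used in typical host-guest UV-vis titrations)
#' @param n_points points in the series (default 12), >= 4
#' @param ka generating association constant (1/M)
#' @param obs_free,obs_bound generating free/bound signals
#' @param mode `"uvvis"` or `"nmr"`
#' @param probe_label free-text probe identifier
#' @param noise_sigma Gaussian noise s.d. in signal units (default 0)
#' @param seed integer seed, or NULL for the current RNG stream
#' @return a `"spectro_titration"`
#' @export
generate_titration <- function(guest_total, max_equiv = 6, n_points = 12L,
                               ka, obs_free = 1.0, obs_bound = 0.5,
                               mode = c("uvvis", "nmr"), probe_label = "",
                               noise_sigma = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (n_points < 4L) stop("need at least 4 points", call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  host <- seq(0, max_equiv * guest_total, length.out = n_points)
  ser <- spectro_titration(host, rep(obs_free, n_points), guest_total,
                           mode = mode, probe_label = probe_label)
  y <- predict_observable(ser, ka, obs_free, obs_bound)
  if (noise_sigma > 0)
    y <- y + .with_seed(seed, stats::rnorm(n_points, 0, noise_sigma))
  ser$observables <- y
  ser
}

#' Generate a synthetic Job (continuous variation) dataset
#'
#' An 11-point (by default) mole-fraction grid at constant total
#' concentration; the observable is `baseline + response_coef * complex`
#' plus Gaussian noise, mirroring an absorbance read against a solvent
#' blank.
#'
#' @param total_conc constant host + guest concentration (mol/L)
#' @param ka generating association (formation) constant
#' @param n_points grid size (default 11)
#' @param m,n complex stoichiometry (default 1:1)
#' @param response_coef signal per molar complex (default 2e4 AU/M, a
#'   typical small-molecule molar response)
#' @param baseline signal at zero complex
#' @param noise_sigma Gaussian noise s.d. (signal units)
#' @param seed integer seed, or NULL
#' @return a `"job_curve"` with the `observable` field populated
#' @export
generate_job <- function(total_conc, ka, n_points = 11L, m = 1L, n = 1L,
                         response_coef = 2e4, baseline = 0,
                         noise_sigma = 0, seed = NULL) {
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  jc <- job_curve(total_conc,
                  mole_fractions = seq(0, 1, length.out = n_points),
                  ka = ka, m = m, n = n)
  y <- baseline + response_coef * jc$complex_concs
  if (noise_sigma > 0)
    y <- y + .with_seed(seed, stats::rnorm(length(y), 0, noise_sigma))
  jc$observable <- y
  jc
}

#' Generate a synthetic ITC experiment with heats
#'
#' Default schedule: 200 uL cell, 20 x 2 uL injections of 2 mM titrant at
#' 298.15 K -- a standard small-volume calorimeter protocol. Heats come
#' from [simulate_itc_heats()] plus Gaussian noise.
#'
#' @param cell_conc guest concentration in the cell (mol/L)
#' @param n,ka,dh generating stoichiometry, association constant (1/M) and
#'   enthalpy (kcal/mol)
#' @param syringe_conc titrant concentration (mol/L), default 2e-3
#' @param cell_volume cell volume (L), default 2e-4
#' @param injection_volumes per-injection volumes (L), default 20 x 2 uL
#' @param temperature kelvin
#' @param noise_sigma Gaussian noise s.d. on the heats (ucal)
#' @param seed integer seed, or NULL
#' @return an `"itc_experiment"` carrying `heats`
#' @export
generate_itc <- function(cell_conc, n = 1, ka, dh, syringe_conc = 2e-3,
                         cell_volume = 2e-4,
                         injection_volumes = rep(2e-6, 20),
                         temperature = 298.15, noise_sigma = 0, seed = NULL) {
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0", call. = FALSE)
  ex <- itc_experiment(cell_volume, cell_conc, syringe_conc,
                       injection_volumes, temperature)
  q <- simulate_itc_heats(ex, n = n, ka = ka, dh = dh)
  if (noise_sigma > 0)
    q <- q + .with_seed(seed, stats::rnorm(length(q), 0, noise_sigma))
  ex$heats <- q
  ex
}

#' Emulated study designs for the drug@CB[7] systems
#'
#' Named generator configurations mirroring the titration and calorimetry
#' designs used to characterise cimetidine (CT), famotidine (FT) and
#' nizatidine (NT) binding to cucurbit[7]uril, with the published fitted
#' parameters as generating truths:
#' \itemize{
#'   \item `"FT"`: UV-vis, 0.05 mM guest, 0-6 equivalents host, Ka 1.30e4,
#'     absorbance decreasing at 283 nm
#'   \item `"NT"`: UV-vis, 0.04 mM guest, 0-3 equivalents, Ka 1.05e5,
#'     absorbance increasing at 315 nm
#'   \item `"CT"`: fast-exchange 1H NMR, 1.0 mM guest, 0-3 equivalents,
#'     Ka 6.57e3, H(5) shifting upfield
#'   \item `"CT_itc"`, `"FT_itc"`, `"NT_itc"`: 2 mM host titrated into
#'     0.05 / 0.05 / 0.1 mM guest, 20 x 2 uL, 25 C, with the ITC-table
#'     (N, Ka, dH) as truths
#' }
#' Signal endpoints for the spectroscopic designs are plausible values of
#' the right sign and magnitude; the published record contains no raw
#' traces to copy.
#'
#' @param name one of the six design names
#' @return list with `type` (`"titration"` or `"itc"`) and `args`, the
#'   argument list for the matching generator
#' @seealso [generate_study()]
#' @export
study_design <- function(name = c("FT", "NT", "CT",
                                  "CT_itc", "FT_itc", "NT_itc")) {
  name <- match.arg(name)
  designs <- list(
    FT = list(type = "titration", args = list(
      guest_total = 5e-5, max_equiv = 6, n_points = 12L, ka = 1.30e4,
      obs_free = 1.00, obs_bound = 0.55, mode = "uvvis",
      probe_label = "283 nm")),
    NT = list(type = "titration", args = list(
      guest_total = 4e-5, max_equiv = 3, n_points = 12L, ka = 1.05e5,
      obs_free = 0.40, obs_bound = 0.80, mode = "uvvis",
      probe_label = "315 nm")),
    CT = list(type = "titration", args = list(
      guest_total = 1e-3, max_equiv = 3, n_points = 12L, ka = 6.57e3,
      obs_free = 7.60, obs_bound = 7.05, mode = "nmr",
      probe_label = "H(5)")),
    CT_itc = list(type = "itc", args = list(
      cell_conc = 5e-5, n = 0.99, ka = 1.44e4, dh = -13.23)),
    FT_itc = list(type = "itc", args = list(
      cell_conc = 5e-5, n = 1.12, ka = 4.95e4, dh = -11.08)),
    NT_itc = list(type = "itc", args = list(
      cell_conc = 1e-4, n = 0.95, ka = 1.34e4, dh = -15.60)))
  designs[[name]]
}

#' Generate a dataset from a named study design
#'
#' Convenience wrapper: looks up [study_design()] and calls the matching
#' generator. `noise_fraction` expresses the Gaussian noise s.d. as a
#' fraction of the dataset's dynamic range (|obs_bound - obs_free| for
#' titrations, max |heat| for ITC); 0.01 and 0.02 are realistic
#' spectroscopic and calorimetric choices.
#'
#' @param name a [study_design()] name
#' @param noise_fraction fraction of dynamic range (default 0, noiseless)
#' @param seed integer seed, or NULL
#' @return a `"spectro_titration"` or an `"itc_experiment"` with heats
#' @export
generate_study <- function(name, noise_fraction = 0, seed = NULL) {
  d <- study_design(name)
  if (d$type == "titration") {
    sigma <- noise_fraction * abs(d$args$obs_bound - d$args$obs_free)
    do.call(generate_titration,
            c(d$args, list(noise_sigma = sigma, seed = seed)))
  } else {
    clean <- do.call(generate_itc, d$args)
    sigma <- noise_fraction * max(abs(clean$heats))
    do.call(generate_itc,
            c(d$args, list(noise_sigma = sigma, seed = seed)))
  }
}
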