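# Reading and writing the tabular formats the fitting stages consume:
# titration CSVs, ITC JSON descriptors + heat CSVs, thermodynamic tables.
# User-facing files carry unit-suffixed keys (mM, uL, C); everything is
# converted to SI (mol/L, L, K) at parse time.

#' Read a titration series from CSV
#'
#' Expects a UTF-8 CSV with a header row and columns `host_total_M`,
#' `observable`. Series metadata comes either from a sidecar JSON (keys
#' `mode`, `guest_total_mM`, `probe_label`, optional `slow_exchange`) or
#' from the arguments, which override the sidecar.
#'
#' @param path CSV path
#' @param sidecar optional path to a JSON metadata file
#' @param mode,guest_total,probe_label,slow_exchange metadata overrides;
#'   `guest_total` in mol/L
#' @return a `"spectro_titration"`
#' @export
read_titration_csv <- function(path, sidecar = NULL, mode = NULL,
                               guest_total = NULL, probe_label = NULL,
                               slow_exchange = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("host_total_M", "observable")
  if (!all(need %in% names(df)))
    stop(sprintf("missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  meta <- list()
  if (!is.null(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pick <- function(arg, key, default = NULL) {
    if (!is.null(arg)) arg
    else if (!is.null(meta[[key]])) meta[[key]]
    else default
  }
  gt <- guest_total
  if (is.null(gt) && !is.null(meta$guest_total_mM)) gt <- meta$guest_total_mM / 1e3
  if (is.null(gt)) stop("guest_total not given (argument or sidecar)", call. = FALSE)
  spectro_titration(
    host_totals = df$host_total_M, observables = df$observable,
    guest_total = gt,
    mode = pick(mode, "mode", "uvvis"),
    probe_label = pick(probe_label, "probe_label", ""),
    slow_exchange = isTRUE(pick(slow_exchange, "slow_exchange", FALSE)))
}

#' Write a titration series to CSV (+ sidecar JSON)
#'
#' @param series a `"spectro_titration"`
#' @param path CSV destination; a sidecar `<path>.meta.json` is written
#'   beside it
#' @return `path`, invisibly
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "spectro_titration"))
  utils::write.csv(
    data.frame(host_total_M = series$host_totals,
               observable = series$observables),
    path, row.names = FALSE)
  jsonlite::write_json(
    list(mode = series$mode, guest_total_mM = series$guest_total * 1e3,
         probe_label = series$probe_label,
         slow_exchange = series$slow_exchange),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ITC experiment from a JSON descriptor (+ optional heats CSV)
#'
#' Descriptor keys are unit-suffixed: `cell_volume_uL`, `cell_conc_mM`,
#' `syringe_conc_mM`, `injection_volumes_uL`, `temperature_C`. The heats
#' CSV has columns `injection_index`, `heat_ucal`.
#'
#' @param json_path descriptor path
#' @param heats_csv optional heats CSV path
#' @return an `"itc_experiment"`
#' @export
read_itc_experiment <- function(json_path, heats_csv = NULL) {
  d <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  need <- c("cell_volume_uL", "cell_conc_mM", "syringe_conc_mM",
            "injection_volumes_uL")
  if (!all(need %in% names(d)))
    stop(sprintf("missing key(s): %s",
                 paste(setdiff(need, names(d)), collapse = ", ")),
         call. = FALSE)
  heats <- NULL
  if (!is.null(heats_csv)) {
    h <- utils::read.csv(heats_csv, stringsAsFactors = FALSE)
    if (!all(c("injection_index", "heat_ucal") %in% names(h)))
      stop("heats CSV needs columns injection_index, heat_ucal", call. = FALSE)
    heats <- h$heat_ucal[order(h$injection_index)]
  }
  itc_experiment(
    cell_volume = d$cell_volume_uL * 1e-6,
    cell_conc = d$cell_conc_mM / 1e3,
    syringe_conc = d$syringe_conc_mM / 1e3,
    injection_volumes = d$injection_volumes_uL * 1e-6,
    temperature = if (!is.null(d$temperature_C)) d$temperature_C + 273.15
                  else 298.15,
    heats = heats)
}

#' Write an ITC experiment to a JSON descriptor (+ heats CSV)
#'
#' @param exp an `"itc_experiment"`
#' @param json_path descriptor destination
#' @param heats_csv heats destination (written only if heats are attached)
#' @return `json_path`, invisibly
#' @export
write_itc_experiment <- function(exp, json_path, heats_csv = NULL) {
  stopifnot(inherits(exp, "itc_experiment"))
  jsonlite::write_json(
    list(cell_volume_uL = exp$cell_volume * 1e6,
         cell_conc_mM = exp$cell_conc * 1e3,
         syringe_conc_mM = exp$syringe_conc * 1e3,
         injection_volumes_uL = exp$injection_volumes * 1e6,
         temperature_C = exp$temperature - 273.15),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(exp$heats) && !is.null(heats_csv))
    utils::write.csv(
      data.frame(injection_index = seq_along(exp$heats),
                 heat_ucal = exp$heats),
      heats_csv, row.names = FALSE)
  invisible(json_path)
}
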