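# Thermodynamic conversions (Ka <-> dG, TdS) and identity auditing of
# tabulated binding parameters.

# gas constant, thermochemical kcal/(mol K)
R_KCAL <- 1.987204e-3

#' Gibbs free energy of binding from an association constant
#'
#' \eqn{\Delta G = -RT \ln K_a} with
#' \eqn{R = 1.987204 \times 10^{-3}} kcal/(mol K). The default temperature
#' is 298.15 K (25 degrees C, the condition typical titration and ITC
#' experiments are run at).
#'
#' @param ka association constant (1/M), > 0; vectorised
#' @param temperature kelvin, > 0
#' @return \eqn{\Delta G} in kcal/mol (negative for favourable binding)
#' @examples
#' round(delta_g_from_ka(1.05e5), 2)   # -6.85
#' round(delta_g_from_ka(6.57e3), 2)   # -5.21
#' @export
delta_g_from_ka <- function(ka, temperature = 298.15) {
  if (any(!is.finite(ka)) || any(ka <= 0))
    stop("'ka' must be positive and finite", call. = FALSE)
  if (any(temperature <= 0))
    stop("'temperature' must be positive (kelvin)", call. = FALSE)
  -R_KCAL * temperature * log(ka)
}

#' Association constant from a Gibbs free energy of binding
#'
#' Inverse of [delta_g_from_ka()]: \eqn{K_a = \exp(-\Delta G / RT)}.
#'
#' @param dg kcal/mol
#' @param temperature kelvin, > 0
#' @return association constant (1/M)
#' @export
ka_from_delta_g <- function(dg, temperature = 298.15) {
  if (any(temperature <= 0))
    stop("'temperature' must be positive (kelvin)", call. = FALSE)
  exp(-dg / (R_KCAL * temperature))
}

#' Entropy term from enthalpy and free energy
#'
#' The identity \eqn{T\Delta S = \Delta H - \Delta G}; bookkeeping, never a
#' fitted quantity.
#'
#' @param dh,dg kcal/mol
#' @return \eqn{T\Delta S} in kcal/mol
#' @export
tds_from_dh_dg <- function(dh, dg) dh - dg

#' Construct a thermodynamic record for auditing
#'
#' One row of a binding-parameter table: a labelled complex measured by one
#' method, with whichever of \eqn{N}, \eqn{K_a}, \eqn{\Delta H},
#' \eqn{T\Delta S} the method provides plus the reported \eqn{\Delta G}.
#' For end-point free-energy decompositions (`method = "mmgbsa"`) `dh`
#' holds the total interaction energy and `tds` its entropy term; the same
#' additive identity \eqn{\Delta G = \Delta H - T\Delta S} applies.
#'
#' @param label complex name, e.g. `"FT@CB7"`
#' @param method one of `"itc"`, `"uvvis"`, `"nmr"`, `"mmgbsa"`
#' @param dg Gibbs free energy (kcal/mol), required
#' @param ka association constant (1/M) or NA
#' @param dh enthalpy / total energy (kcal/mol) or NA
#' @param tds entropy term (kcal/mol) or NA
#' @param n stoichiometry or NA
#' @param temperature kelvin
#' @return object of class `"thermo_record"`
#' @export
thermo_record <- function(label, method = c("itc", "uvvis", "nmr", "mmgbsa"),
                          dg, ka = NA_real_, dh = NA_real_, tds = NA_real_,
                          n = NA_real_, temperature = 298.15) {
  method <- match.arg(method)
  if (!is.numeric(dg) || length(dg) != 1L || is.na(dg))
    stop("'dg' is required (kcal/mol)", call. = FALSE)
  structure(list(label = label, method = method, n = n, ka = ka,
                 dh = dh, dg = dg, tds = tds, temperature = temperature),
            class = "thermo_record")
}

#' Audit the thermodynamic identities of one record
#'
#' Checks, where the fields allow,
#' \itemize{
#'   \item `dg_vs_ka`: \eqn{\Delta G - (-RT \ln K_a)}
#'   \item `tds_identity`: \eqn{\Delta H - T\Delta S - \Delta G}
#' }
#' A check passes when its absolute residual is strictly below `tolerance`
#' (residuals are rounded at the ninth decimal first, so exact-at-tolerance
#' rounding discrepancies in a printed table are flagged rather than
#' excused). The record is never modified. If neither identity is
#' computable the report is returned empty and marked insufficient.
#'
#' @param record a `"thermo_record"`
#' @param tolerance kcal/mol (default 0.01, one unit in the last printed
#'   digit of a 2-dp table)
#' @return a `"thermo_audit"` data.frame with columns `label`, `method`,
#'   `identity`, `residual`, `pass`; attribute `insufficient` is TRUE when
#'   no identity could be evaluated
#' @examples
#' rec <- thermo_record("FT@CB7", "itc", dg = -6.40, ka = 4.95e4,
#'                      dh = -11.08, tds = -4.68)
#' audit_record(rec)
#' @export
audit_record <- function(record, tolerance = 0.01) {
  stopifnot(inherits(record, "thermo_record"))
  rows <- list()
  if (!is.na(record$ka)) {
    r <- record$dg - delta_g_from_ka(record$ka, record$temperature)
    rows[["dg_vs_ka"]] <- r
  }
  if (!is.na(record$dh) && !is.na(record$tds)) {
    r <- record$dh - record$tds - record$dg
    rows[["tds_identity"]] <- r
  }
  if (length(rows) == 0L) {
    out <- data.frame(label = character(0), method = character(0),
                      identity = character(0), residual = numeric(0),
                      pass = logical(0), stringsAsFactors = FALSE)
    attr(out, "insufficient") <- TRUE
  } else {
    resid <- unlist(rows)
    out <- data.frame(label = record$label, method = record$method,
                      identity = names(rows), residual = resid,
                      pass = round(abs(resid), 9) < tolerance,
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "insufficient") <- FALSE
  }
  class(out) <- c("thermo_audit", "data.frame")
  out
}

#' Audit a table of thermodynamic records
#'
#' Applies [audit_record()] to every row of a data.frame with columns
#' `label`, `method`, `n`, `ka`, `dh`, `dg`, `tds`, `temperature`
#' (missing fields as NA), e.g. the shipped table of published values from
#' [published_thermo()].
#'
#' @param table data.frame of records
#' @param tolerance kcal/mol
#' @return a `"thermo_audit"` data.frame, one row per evaluable identity
#' @examples
#' aud <- audit_thermo_table(published_thermo())
#' aud[!aud$pass, ]
#' @export
audit_thermo_table <- function(table, tolerance = 0.01) {
  needed <- c("label", "method", "dg")
  if (!all(needed %in% names(table)))
    stop("table must have at least columns label, method, dg", call. = FALSE)
  get_col <- function(col, i, default = NA_real_)
    if (col %in% names(table)) table[[col]][i] else default
  out <- lapply(seq_len(nrow(table)), function(i) {
    rec <- thermo_record(
      label = table$label[i], method = table$method[i], dg = table$dg[i],
      ka = get_col("ka", i), dh = get_col("dh", i), tds = get_col("tds", i),
      n = get_col("n", i),
      temperature = get_col("temperature", i, 298.15))
    audit_record(rec, tolerance = tolerance)
  })
  res <- do.call(rbind, lapply(out, function(x) as.data.frame(x)))
  class(res) <- c("thermo_audit", "data.frame")
  res
}

#' @export
print.thermo_audit <- function(x, digits = 4, ...) {
  if (isTRUE(attr(x, "insufficient"))) {
    cat("Thermodynamic audit: insufficient fields -- no identity evaluable\n")
    return(invisible(x))
  }
  cat("Thermodynamic identity audit\n")
  df <- as.data.frame(x)
  df$residual <- signif(df$residual, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Published binding thermodynamics of three H2-antagonist drugs with CB[7]
#'
#' The tabulated parameters for cimetidine (CT), famotidine (FT) and
#' nizatidine (NT) complexes with cucurbit[7]uril, as printed: ITC rows
#' (N, Ka, dH, dG, TdS at 25 C), spectroscopic rows (Ka and the dG derived
#' from it), and MM-GBSA end-point decompositions (total energy in `dh`,
#' entropy term in `tds`). Shipped as a plain-text fixture; intended as
#' input to [audit_thermo_table()], which flags the rows whose printed
#' values are not internally consistent at 0.01 kcal/mol.
#'
#' @return data.frame with columns `label`, `method`, `n`, `ka`, `dh`,
#'   `dg`, `tds`, `temperature`
#' @export
published_thermo <- function() {
  path <- system.file("extdata", "published_thermo.csv", package = "hgbind",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
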