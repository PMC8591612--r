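# Flory-Huggins solvent screening from Hansen solubility parameters.
#
# Nanoprecipitation of Kraft lignin is controlled by two solvent-side
# quantities: the polymer-solvent interaction parameter
# chi = V (delta_1 - delta_2)^2 / (R T), and the supersaturation level
# S = s_75 / s_21, the ratio of lignin solubility degrees before and after
# anti-solvent (water) dilution.  Lower chi means stronger solvent-lignin
# affinity; higher S drives faster nucleation and smaller particles.

#' Flory-Huggins interaction parameter from Hansen solubility parameters
#'
#' Computes `chi = V * (delta_a - delta_b)^2 / (R * T)`, where `V` is the
#' reference molar volume.  With `V` in cm^3/mol and the solubility
#' parameters in MPa^0.5 the product `V * (delta_a - delta_b)^2` is in
#' MPa cm^3/mol = J/mol, so dividing by `R * T` (J/mol) is dimensionless.
#'
#' For a solvent--solute pair the reference volume is conventionally the
#' solvent's molar volume.  For solvent--water pairs this package adopts the
#' molar volume of water (18.07 cm^3/mol) as the reference volume; see
#' [rank_solvents()] and the package vignette for the rationale.
#'
#' @param reference_volume Reference molar volume, cm^3/mol.
#' @param delta_a,delta_b Hansen (total) solubility parameters, MPa^0.5.
#' @param temperature Absolute temperature, K. Default 298.15.
#' @return A `chi_result` list with fields `chi`, `reference_volume`,
#'   `temperature`.
#' @examples
#' # acetone vs softwood Kraft lignin (delta_SKL = 27.4 MPa^0.5)
#' flory_huggins_chi(74.1, 20.0, 27.4)$chi
#' @export
flory_huggins_chi <- function(reference_volume, delta_a, delta_b,
                              temperature = 298.15) {
  .check_positive(reference_volume, "reference_volume")
  .check_positive(temperature, "temperature")
  .check_positive(delta_a, "delta_a")
  .check_positive(delta_b, "delta_b")
  chi <- reference_volume * (delta_a - delta_b)^2 /
    (lnp_constants[["R_gas"]] * temperature)
  structure(
    list(chi = chi, reference_volume = reference_volume,
         temperature = temperature),
    class = "chi_result"
  )
}

#' @export
print.chi_result <- function(x, ...) {
  cat(sprintf("Flory-Huggins chi = %s  (V = %g cm^3/mol, T = %g K)\n",
              format_chi(x$chi), x$reference_volume, x$temperature))
  invisible(x)
}

#' Display rounding for chi values
#'
#' One decimal, except values below 0.1 which are shown at two decimals
#' (so near-athermal pairs are not displayed as 0.0).
#'
#' @param chi Numeric vector of interaction parameters.
#' @return Character vector.
#' @export
format_chi <- function(chi) {
  ifelse(chi < 0.1, sprintf("%.2f", round(chi, 2)), sprintf("%.1f", round(chi, 1)))
}

#' Supersaturation level from solubility degrees
#'
#' Ratio of the solubility degree in concentrated organic solvent (75 wt%)
#' to that after dilution to 21 wt%: `S = s75 / s21`.
#'
#' @param s75 Solubility degree (dissolved/added fraction) at 75 wt% solvent.
#' @param s21 Solubility degree at 21 wt% solvent; must be > 0.
#' @param name Optional solvent name used in error messages.
#' @return Dimensionless supersaturation level.
#' @export
supersaturation <- function(s75, s21, name = NULL) {
  stopifnot(is.numeric(s75), is.numeric(s21))
  if (any(!is.finite(s21)) || any(s21 <= 0)) {
    lbl <- if (is.null(name)) "" else paste0(" for solvent '", name, "'")
    stop("s21 must be positive", lbl, call. = FALSE)
  }
  s75 / s21
}

#' Solvent property records
#'
#' Validates a table of solvent records: Hansen solubility parameter
#' `delta` (MPa^0.5), molar volume `molar_volume` (cm^3/mol), and the
#' solubility degrees `s75`/`s21` of 1 wt% lignin in 75 and 21 wt% aqueous
#' solvent.
#'
#' @param name Character vector of solvent names.
#' @param delta,molar_volume,s75,s21 Numeric vectors, one value per solvent.
#' @return A `data.frame` of class `solvent_record`.
#' @export
solvent_record <- function(name, delta, molar_volume, s75, s21) {
  stopifnot(length(name) == length(delta),
            length(delta) == length(molar_volume),
            length(s75) == length(s21), length(s75) == length(name))
  .check_positive(delta, "delta")
  .check_positive(molar_volume, "molar_volume")
  if (any(s75 < 0) || any(s21 < 0)) stop("solubility degrees must be >= 0")
  if (any(s75 > 1.1) || any(s21 > 1.1)) {
    stop("solubility degrees above 1.1 exceed the measurement-noise allowance")
  }
  out <- data.frame(name = as.character(name), delta = delta,
                    molar_volume = molar_volume, s75 = s75, s21 = s21,
                    stringsAsFactors = FALSE)
  class(out) <- c("solvent_record", "data.frame")
  out
}

#' Read a solvent property table from CSV
#'
#' Expects columns `name,delta_MPa05,V_cm3mol,s75,s21`.  The packaged
#' fixture `system.file("extdata", "solvent_table.csv", package =
#' "lnptools")` holds the aqueous acetone/THF/DXN/DMSO systems used for
#' lignin nanoprecipitation.
#'
#' @param path Path to a CSV file.
#' @return A `solvent_record` data frame.
#' @export
read_solvent_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "delta_MPa05", "V_cm3mol", "s75", "s21")
  if (!all(need %in% names(df))) {
    stop("solvent table must have columns: ", paste(need, collapse = ", "))
  }
  solvent_record(df$name, df$delta_MPa05, df$V_cm3mol, df$s75, df$s21)
}

#' Rank solvents by lignin affinity
#'
#' For each solvent computes the solvent--solute interaction parameter
#' (reference volume = solvent molar volume), the solvent--water
#' interaction parameter (reference volume = molar volume of water,
#' 18.07 cm^3/mol), and the supersaturation level, and returns the table
#' sorted by solvent--solute chi ascending (strongest solvent first).
#' Ties on unrounded chi are broken alphabetically by name.
#'
#' @param records A `solvent_record` data frame, e.g. from
#'   [read_solvent_table()].
#' @param delta_solute Hansen solubility parameter of the solute, MPa^0.5
#'   (softwood Kraft lignin: 27.4).
#' @param temperature Kelvin; default 298.15.
#' @param delta_water Hansen parameter of water, MPa^0.5; default 47.8.
#' @param v_water Molar volume of water, cm^3/mol; default 18.07.
#' @return Data frame with columns `name`, `chi_solvent_solute`,
#'   `chi_solvent_water`, `supersaturation`, sorted by affinity.
#' @export
rank_solvents <- function(records, delta_solute = 27.4, temperature = 298.15,
                          delta_water = 47.8, v_water = 18.07) {
  stopifnot(inherits(records, "data.frame"), nrow(records) >= 1)
  chi_ss <- vapply(seq_len(nrow(records)), function(i) {
    flory_huggins_chi(records$molar_volume[i], records$delta[i],
                      delta_solute, temperature)$chi
  }, numeric(1))
  chi_sw <- vapply(seq_len(nrow(records)), function(i) {
    flory_huggins_chi(v_water, records$delta[i], delta_water,
                      temperature)$chi
  }, numeric(1))
  S <- supersaturation(records$s75, records$s21)
  out <- data.frame(name = records$name,
                    chi_solvent_solute = chi_ss,
                    chi_solvent_water = chi_sw,
                    supersaturation = S,
                    stringsAsFactors = FALSE)
  out[order(out$chi_solvent_solute, out$name), , drop = FALSE]
}
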