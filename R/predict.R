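#' Evaluate an Abraham solvation equation
#'
#' Computes the predicted log10 partition coefficient for a solute from
#' its descriptors and one solvent system's process coefficients. For
#' water-to-solvent processes (and the gas-to-water V-form) the cavity
#' term is `v * V`; for gas-to-solvent processes (and the gas-to-water
#' L-form) it is `l * L`:
#' \deqn{\log P_s = c + eE + sS + aA + bB + vV}
#' \deqn{\log K_s = c + eE + sS + aA + bB + lL}
#'
#' A descriptor is only read where its coefficient is active (present
#' and nonzero), so e.g. evaluating a water-to-solvent record never
#' touches `L`.
#'
#' @param desc A [solute_descriptors] object.
#' @param coeffs A one-or-more-row coefficient data frame (see
#'   [read_coefficient_table()]).
#' @return Numeric vector of predicted log10 partition coefficients,
#'   named by `system_id`.
#' @examples
#' mono <- solute_descriptors(E = 1.14, S = 1.12, A = 0.61, B = 0.50,
#'                            V = 1.1705)
#' coefs <- bundled_coefficients()
#' predict_log_partition(mono,
#'   coefs[coefs$system_id == "methanol" &
#'         coefs$process_kind == "water_to_solvent", ])
#' @export
predict_log_partition <- function(desc, coeffs) {
  stopifnot(inherits(desc, "solute_descriptors"))
  coeffs <- validate_coefficient_table(as.data.frame(coeffs))
  vapply(seq_len(nrow(coeffs)), function(i) {
    predict_one(desc, coeffs[i, ])
  }, numeric(1L)) |> stats::setNames(coeffs$system_id)
}

term_map <- c(E = "e", S = "s", A = "a", B = "b", V = "v", L = "l")

predict_one <- function(desc, row) {
  v_act <- !is.na(row$v) && row$v != 0
  l_act <- !is.na(row$l) && row$l != 0
  if (v_act && l_act && row$process_kind != "auxiliary")
    stop("malformed coefficients: both v and l active for ", row$system_id)
  total <- row[["c"]]
  for (d in names(term_map)) {
    cf <- row[[term_map[[d]]]]
    if (is.na(cf) || cf == 0) next
    val <- desc$values[[d]]
    if (is.na(val))
      stop("incomplete descriptors: ", d, " required by ", row$system_id,
           " (", row$process_kind, ") but absent")
    total <- total + cf * val
  }
  total
}

#' Water-to-solvent partition coefficient from saturation solubilities
#'
#' The partition coefficient of a solute between water and a solvent can
#' be formed from its saturated molar concentrations in the two phases,
#' `Ps = Cs / Cw`, i.e. in logarithms `log Ps = log Cs - log Cw`.
#'
#' @param log_cs log10 saturated molar solubility in the organic solvent.
#' @param log_cw log10 aqueous molar solubility.
#' @return log10 water-to-solvent partition coefficient(s).
#' @examples
#' log_p_from_solubility(log10(1.384), -2.40)   # methanol, 2.541
#' @export
log_p_from_solubility <- function(log_cs, log_cw) {
  check_finite(log_cs, "log_cs")
  check_finite(log_cw, "log_cw")
  log_cs - log_cw
}

#' Gas-to-solvent partition coefficient from the water-to-solvent one
#'
#' Converts a water-to-solvent partition coefficient to the
#' gas-to-solvent scale through the gas-water partition coefficient:
#' `Ps = Ks / Kw`, i.e. `log Ks = log Ps + log Kw`.
#'
#' @param log_ps log10 water-to-solvent partition coefficient.
#' @param log_kw log10 dimensionless gas-water partition coefficient.
#' @return log10 gas-to-solvent partition coefficient(s).
#' @examples
#' log_k_from_log_p(2.541, 6.14)
#' @export
log_k_from_log_p <- function(log_ps, log_kw) {
  check_finite(log_ps, "log_ps")
  check_finite(log_kw, "log_kw")
  log_ps + log_kw
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite")
  invisible(x)
}
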