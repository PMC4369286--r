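#' Buchowski lambda-h temperature correction (mole-fraction scale)
#'
#' Adjusts a solid-solute mole-fraction solubility measured at `T` to a
#' reference temperature using the Buchowski lambda-h relation
#' \deqn{\ln[1 + \lambda(1 - x)/x] = \lambda h (1/T - 1/T_m)}
#' under the boundary condition of miscibility at the solute melting
#' point (`x = 1` at `T = Tm`, which the relation satisfies by
#' construction). A single measured point determines only one
#' parameter, so `h` is inferred per measurement at fixed `lambda`;
#' the default `lambda = 1` reduces the relation to
#' `ln(1/x) = h (1/T - 1/Tm)`.
#'
#' @param x Mole-fraction solubility measured at `T` (0 < x <= 1; x = 1
#'   only at `T = Tm`).
#' @param temperature Measurement temperature, K (must be below `Tm`).
#' @param Tm Solute melting temperature, K.
#' @param lambda Buchowski lambda parameter (> 0), default 1.
#' @param T_ref Target temperature, K (default 298.15).
#' @return Mole-fraction solubility at `T_ref`.
#' @examples
#' buchowski_correct_x(0.10, temperature = 293.15, Tm = 406)
#' @export
buchowski_correct_x <- function(x, temperature, Tm, lambda = 1,
                                T_ref = 298.15) {
  stopifnot(lambda > 0, Tm > 0)
  if (temperature == T_ref) return(x)
  if (x >= 1) {
    if (temperature == Tm && x == 1) return(1)
    stop("not a dilute solid solubility: x >= 1 below the melting point")
  }
  if (x <= 0) stop("mole fraction must be positive")
  if (temperature >= Tm) stop("above melting point")
  if (T_ref >= Tm) stop("reference temperature above melting point")
  h <- log(1 + lambda * (1 - x) / x) /
    (lambda * (1 / temperature - 1 / Tm))
  ex <- exp(lambda * h * (1 / T_ref - 1 / Tm))
  lambda / (ex - 1 + lambda)
}

#' Buchowski temperature correction of a molar solubility
#'
#' Wrapper around [buchowski_correct_x()] that converts a molarity to
#' mole fraction with the supplied solvent metadata, applies the
#' correction and converts back, so the correction itself operates on
#' the mole-fraction scale.
#'
#' @param molarity Molar solubility at `temperature`, mol/L.
#' @param temperature Measurement temperature, K.
#' @param Tm Solute melting temperature, K.
#' @param solute_molar_mass Solute molar mass, g/mol.
#' @param solvent_density Solvent density, g/cm^3.
#' @param solvent_molar_mass Solvent molar mass, g/mol.
#' @param lambda Buchowski lambda (default 1).
#' @param T_ref Target temperature, K (default 298.15).
#' @return Molar solubility at `T_ref`.
#' @export
buchowski_adjust <- function(molarity, temperature, Tm,
                             solute_molar_mass, solvent_density,
                             solvent_molar_mass, lambda = 1,
                             T_ref = 298.15) {
  if (temperature == T_ref) return(molarity)
  x <- molarity_to_mole_fraction(molarity, solute_molar_mass,
                                 solvent_density, solvent_molar_mass)
  x_ref <- buchowski_correct_x(x, temperature, Tm, lambda = lambda,
                               T_ref = T_ref)
  mole_fraction_to_molarity(x_ref, solute_molar_mass, solvent_density,
                            solvent_molar_mass)
}
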