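#' Excess molar refractivity by fragment offset
#'
#' Estimates the `E` descriptor of a target solute from a structural
#' analog with known `E` by carrying over the `E` difference observed
#' between a reference pair of compounds that differ by the same
#' structural fragment. For trans-cinnamic acid the analog is ethyl
#' cinnamate and the reference pair benzoic acid / ethyl benzoate.
#'
#' @param target_analog_e Known `E` of the structural analog.
#' @param e_with,e_without `E` values of the reference pair with and
#'   without the fragment of interest.
#' @return The estimated `E` at full precision; round to hundredths for
#'   reporting.
#' @examples
#' e_from_fragment_offset(1.102, e_with = 0.730, e_without = 0.689)
#' @export
e_from_fragment_offset <- function(target_analog_e, e_with, e_without) {
  check_finite(target_analog_e, "target_analog_e")
  check_finite(e_with, "e_with")
  check_finite(e_without, "e_without")
  target_analog_e + (e_with - e_without)
}

#' Excess molar refractivity of a carboxylic acid dimer
#'
#' Relates the `E` descriptor of the hydrogen-bonded dimer of an
#' aromatic carboxylic acid to that of its monomer through the linear
#' relation calibrated on liquid aromatic acids:
#' \deqn{E_{dimer} = -0.418 + 1.839\,E_{monomer}}
#' The relation was established for aromatic carboxylic acids; applying
#' it to other solute classes is not supported by its calibration set.
#'
#' @param e_monomer Monomer `E` value.
#' @return Dimer `E` at full precision; round to hundredths for
#'   reporting.
#' @examples
#' round(e_dimer_from_monomer(1.14), 2)   # 1.68
#' @export
e_dimer_from_monomer <- function(e_monomer) {
  check_finite(e_monomer, "e_monomer")
  -0.418 + 1.839 * e_monomer
}
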