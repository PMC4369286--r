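#' Read a measurement table
#'
#' Measurements are either saturation solubilities (in molarity, mole
#' fraction, mass fraction or mass ratio) or direct water-solvent
#' partition coefficients (`log_p`), one row per observation.
#'
#' @param path CSV with header
#'   `solvent,kind,value,unit,temperature_C,source`; `#` lines ignored.
#' @return Data frame with columns `solvent`, `kind`, `value`, `unit`,
#'   `temperature` (Kelvin), `species` (`NA` until classified; direct
#'   partition measurements are monomer by construction), `source`.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  needed <- c("solvent", "kind", "value", "unit", "temperature_C", "source")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L)
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(solvent = df$solvent, kind = df$kind, value = df$value,
                    unit = df$unit, temperature = df$temperature_C + 273.15,
                    species = ifelse(df$kind == "direct_log_p",
                                     "monomer", NA_character_),
                    source = df$source, stringsAsFactors = FALSE)
  validate_measurements(out)
}

validate_measurements <- function(df) {
  kinds <- c("solubility", "direct_log_p")
  units <- c("molarity", "mole_fraction", "mass_fraction", "mass_ratio",
             "log_p")
  if (!all(df$kind %in% kinds))
    stop("unknown measurement kind: ",
         paste(setdiff(df$kind, kinds), collapse = ", "))
  if (!all(df$unit %in% units))
    stop("unknown unit: ", paste(setdiff(df$unit, units), collapse = ", "))
  if (any(df$kind == "solubility" & df$unit == "log_p"))
    stop("solubility measurements cannot carry unit log_p")
  if (any(df$kind == "direct_log_p" & df$unit != "log_p"))
    stop("direct_log_p measurements must carry unit log_p")
  sol <- df$kind == "solubility"
  if (any(df$value[sol] <= 0))
    stop("solubility values must be positive: ",
         paste(df$solvent[sol & df$value <= 0], collapse = ", "))
  if (any(df$temperature < 270 | df$temperature > 320))
    stop("temperature outside supported range [270, 320] K: ",
         paste(df$solvent[df$temperature < 270 | df$temperature > 320],
               collapse = ", "))
  df
}

#' Read solvent metadata
#'
#' @param path CSV with header `name,beta,density_g_per_cm3,molar_mass`
#'   (Kamlet-Taft beta; density at 298 K in g/cm^3; molar mass in
#'   g/mol); `#` lines ignored.
#' @return Data frame with those columns.
#' @export
read_solvent_metadata <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  needed <- c("name", "beta", "density_g_per_cm3", "molar_mass")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L)
    stop("solvent metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.na(df$beta) & (df$beta < 0 | df$beta > 1.2)))
    stop("beta outside [0, 1.2]")
  if (any(!is.na(df$density_g_per_cm3) & df$density_g_per_cm3 <= 0))
    stop("density must be positive")
  df
}

#' Convert a solubility to molarity
#'
#' Converts mole-fraction, mass-fraction and mass-ratio solubilities to
#' molar concentration (mol/L), approximating the saturated-solution
#' density by the pure-solvent density (a documented error source for
#' concentrated solutions):
#' * mole fraction `x`: `C = 1000 rho x / (x M_solute + (1 - x) M_solvent)`
#' * mass fraction `w`: `C = 1000 rho w / M_solute`
#' * mass ratio `r` (g solute per g solvent): via `w = r / (1 + r)`
#' * molarity passes through unchanged.
#'
#' @param value Solubility value.
#' @param unit One of `molarity`, `mole_fraction`, `mass_fraction`,
#'   `mass_ratio`.
#' @param solute_molar_mass Solute molar mass, g/mol.
#' @param solvent_density Pure-solvent density at 298 K, g/cm^3.
#' @param solvent_molar_mass Solvent molar mass, g/mol (mole fraction
#'   only).
#' @return Molar concentration, mol/L.
#' @examples
#' to_molarity(0.05, "mole_fraction", solute_molar_mass = 148.16,
#'             solvent_density = 0.7857, solvent_molar_mass = 41.05)
#' @export
to_molarity <- function(value, unit, solute_molar_mass,
                        solvent_density = NA, solvent_molar_mass = NA) {
  stopifnot(length(unit) == 1L)
  if (unit == "log_p") stop("not a solubility")
  if (unit == "molarity") return(value)
  if (is.na(solvent_density))
    stop("insufficient solvent metadata: density required for unit ", unit)
  if (unit == "mole_fraction") {
    if (is.na(solvent_molar_mass))
      stop("insufficient solvent metadata: molar mass required for ",
           "mole_fraction")
    return(mole_fraction_to_molarity(value, solute_molar_mass,
                                     solvent_density, solvent_molar_mass))
  }
  if (unit == "mass_ratio") value <- value / (1 + value)
  if (unit %in% c("mass_fraction", "mass_ratio"))
    return(1000 * solvent_density * value / solute_molar_mass)
  stop("unknown unit: ", unit)
}

#' Convert between mole fraction and molarity
#'
#' Inverse pair of helpers used by the unit conversion and the
#' Buchowski temperature correction, both approximating the solution
#' density by the pure-solvent density.
#'
#' @param x Mole fraction of solute.
#' @param molarity Molar concentration, mol/L.
#' @param solute_molar_mass,solvent_molar_mass Molar masses, g/mol.
#' @param solvent_density Solvent density, g/cm^3.
#' @return The converted quantity.
#' @export
mole_fraction_to_molarity <- function(x, solute_molar_mass,
                                      solvent_density, solvent_molar_mass) {
  1000 * solvent_density * x /
    (x * solute_molar_mass + (1 - x) * solvent_molar_mass)
}

#' @rdname mole_fraction_to_molarity
#' @export
molarity_to_mole_fraction <- function(molarity, solute_molar_mass,
                                      solvent_density, solvent_molar_mass) {
  molarity * solvent_molar_mass /
    (1000 * solvent_density -
       molarity * (solute_molar_mass - solvent_molar_mass))
}

#' Average replicate solubility measurements
#'
#' @param values Non-empty numeric vector of molarities for one solvent.
#' @return List with `mean` (arithmetic mean) and `mean_deviation`
#'   (mean absolute deviation from the mean).
#' @examples
#' average_replicates(c(0.2, 0.3, 0.7))
#' @export
average_replicates <- function(values) {
  if (length(values) == 0L) stop("no measurements")
  check_finite(values, "values")
  m <- mean(values)
  list(mean = m, mean_deviation = mean(abs(values - m)))
}

#' Classify the saturated-solution solute species by solvent basicity
#'
#' At saturation a carboxylic acid is predominantly monomeric in
#' solvents that are good hydrogen-bond bases and predominantly dimeric
#' in weak ones; the decision variable is the Kamlet-Taft solvent
#' basicity beta with threshold 0.35. The rule applies to saturation
#' solubilities only -- direct partition measurements are monomer
#' regardless of solvent because they are made at (or extrapolated to)
#' low solute concentration.
#'
#' @param beta Kamlet-Taft beta value(s); `NA` allowed.
#' @param threshold Classification threshold (default 0.35).
#' @return Character vector: `"monomer"` (`beta > threshold`),
#'   `"dimer"` (`beta < threshold`), or `"unclassified"` (`beta`
#'   missing or exactly at the threshold; assign manually).
#' @examples
#' classify_solvent_species(c(0.66, 0.10, 0.35, NA))
#' @export
classify_solvent_species <- function(beta, threshold = 0.35) {
  ifelse(is.na(beta), "unclassified",
         ifelse(beta > threshold, "monomer",
                ifelse(beta < threshold, "dimer", "unclassified")))
}

#' Partition measurements by coefficient availability
#'
#' Splits a measurement table into solvents that have both a
#' water-to-solvent and a gas-to-solvent coefficient record (usable in
#' fits) and those that do not (excluded, preserved for reporting).
#'
#' @param measurements Measurement data frame (see
#'   [read_measurements()]).
#' @param coeff_table Coefficient data frame.
#' @return List with elements `kept` and `excluded`, both measurement
#'   data frames.
#' @export
filter_missing_coefficients <- function(measurements, coeff_table) {
  has_w <- coeff_table$system_id[coeff_table$process_kind ==
                                   "water_to_solvent"]
  has_g <- coeff_table$system_id[coeff_table$process_kind ==
                                   "gas_to_solvent"]
  ok <- measurements$solvent %in% intersect(has_w, has_g)
  list(kept = measurements[ok, , drop = FALSE],
       excluded = measurements[!ok, , drop = FALSE])
}
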