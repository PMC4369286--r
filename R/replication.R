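#' Configuration for the trans-cinnamic acid replication
#'
#' Collects the fixture paths and study constants used by
#' [run_replication()]. Defaults point at the bundled fixtures and the
#' published constants: aqueous `log Cw = -2.40`, monomer `B` held at
#' 0.50, Kamlet-Taft classification threshold 0.35, melting point
#' 406 K, and the fragment `E` values of ethyl cinnamate (1.102),
#' benzoic acid (0.730) and ethyl benzoate (0.689) from which the
#' monomer `E` is derived.
#'
#' @param which `"monomer"`, `"dimer"` or `"both"`.
#' @param solubilities,logp,coefficients,metadata Paths to the
#'   solubility, direct-partition, coefficient and solvent-metadata
#'   CSV fixtures.
#' @param logCw_monomer Fixed log10 aqueous solubility for the monomer
#'   fit.
#' @param B_monomer Fixed hydrogen-bond basicity for the monomer fit
#'   (the published analysis does not treat `B` as a monomer unknown).
#' @param beta_threshold Kamlet-Taft beta classification threshold.
#' @param Tm Solute melting temperature, K.
#' @param solute_molar_mass Solute molar mass, g/mol.
#' @param e_analog,e_with,e_without Fragment `E` inputs for the
#'   monomer `E` estimate.
#' @param auxiliary Optional list of [linear_constraint] objects added
#'   to the monomer system (e.g. a retention-data equation for `L`).
#' @return An object of class `replication_config`.
#' @export
replication_config <- function(which = c("both", "monomer", "dimer"),
                               solubilities = lferdesc_example("cinnamic_solubilities.csv"),
                               logp = lferdesc_example("cinnamic_logp.csv"),
                               coefficients = lferdesc_example("abraham_coefficients.csv"),
                               metadata = lferdesc_example("solvent_metadata.csv"),
                               logCw_monomer = -2.40,
                               B_monomer = 0.50,
                               beta_threshold = 0.35,
                               Tm = 406,
                               solute_molar_mass = 148.16,
                               e_analog = 1.102, e_with = 0.730,
                               e_without = 0.689,
                               auxiliary = list()) {
  which <- match.arg(which)
  for (p in c(solubilities, logp, coefficients, metadata))
    if (!file.exists(p)) stop("missing fixture: ", p)
  structure(list(which = which, solubilities = solubilities, logp = logp,
                 coefficients = coefficients, metadata = metadata,
                 logCw_monomer = logCw_monomer, B_monomer = B_monomer,
                 beta_threshold = beta_threshold, Tm = Tm,
                 solute_molar_mass = solute_molar_mass,
                 e_analog = e_analog, e_with = e_with,
                 e_without = e_without, auxiliary = auxiliary),
            class = "replication_config")
}

#' Determine the trans-cinnamic acid monomer and dimer descriptors
#'
#' Replication driver for the case study: curates the bundled
#' solubility table (unit pass-through, temperature correction at
#' 298.15 K, exclusion of solvents without Abraham coefficients,
#' Kamlet-Taft beta classification into monomer and dimer solvent
#' sets), derives `V` and `E` from structure, assembles the stacked
#' equation system for each species and solves it by least squares.
#'
#' The monomer system comprises two equations per polar-solvent
#' solubility, two per direct partition coefficient and the two
#' gas-to-water closures (plus any auxiliary constraints supplied in
#' the config; the published analysis also used one retention-data
#' equation whose coefficients are not available here). The dimer
#' system comprises two equations per non-polar-solvent solubility
#' plus the two closures, with `log Cw` of the dimer an additional
#' unknown.
#'
#' @param config A [replication_config] object.
#' @return An object of class `lfer_replication`: per requested species
#'   a list with `fit` (the `lfer_fit`), `descriptors` (full descriptor
#'   vector, estimated and fixed), `table` (per-solvent observed and
#'   calculated `log Ps` / `log Cs`), `stats` (AE/AAE/SD over the
#'   solubility set), `n_equations` and `excluded` solvents.
#' @examples
#' \donttest{
#' rep <- run_replication(replication_config("monomer"))
#' print(rep)
#' }
#' @export
run_replication <- function(config = replication_config()) {
  stopifnot(inherits(config, "replication_config"))
  meas <- read_measurements(config$solubilities)
  coefs <- read_coefficient_table(config$coefficients)
  meta <- read_solvent_metadata(config$metadata)

  ## curation: temperature correction (identity at 298.15 K here),
  ## water set aside as the aqueous reference, coefficient filter,
  ## beta classification
  meta_of <- function(sol, col) meta[[col]][match(sol, meta$name)]
  for (i in seq_len(nrow(meas))) {
    if (meas$kind[i] == "solubility" && meas$unit[i] == "molarity" &&
        meas$temperature[i] != 298.15) {
      meas$value[i] <- buchowski_adjust(
        meas$value[i], meas$temperature[i], config$Tm,
        config$solute_molar_mass,
        meta_of(meas$solvent[i], "density_g_per_cm3"),
        meta_of(meas$solvent[i], "molar_mass"))
      meas$temperature[i] <- 298.15
    }
  }
  water <- meas[meas$solvent == "water", , drop = FALSE]
  meas <- meas[meas$solvent != "water", , drop = FALSE]
  parts <- filter_missing_coefficients(meas, coefs)
  kept <- parts$kept
  kept$species <- classify_solvent_species(meta_of(kept$solvent, "beta"),
                                           config$beta_threshold)
  uncl <- unique(kept$solvent[kept$species == "unclassified"])
  if (length(uncl) > 0L)
    stop("solvent(s) could not be classified (beta missing or at the ",
         "threshold): ", paste(uncl, collapse = ", "))

  ## structure-derived descriptors
  E_mono <- round(e_from_fragment_offset(config$e_analog, config$e_with,
                                         config$e_without), 2)
  V_mono <- mcgowan_volume("C9H8O2", rings = 1)
  E_dim <- round(e_dimer_from_monomer(E_mono), 2)
  V_dim <- mcgowan_volume("C18H16O4", rings = 3)

  out <- list(excluded = unique(parts$excluded$solvent),
              water = water, config = config)

  if (config$which %in% c("monomer", "both")) {
    sol_m <- kept[kept$species == "monomer" & kept$kind == "solubility", ]
    direct <- read_measurements(config$logp)
    spec_m <- fit_spec(free = c("S", "A", "L", "logKw"),
                       fixed = list(E = E_mono, V = V_mono,
                                    B = config$B_monomer,
                                    logCw = config$logCw_monomer))
    cons_m <- assemble_equations(rbind(sol_m, direct), coefs, spec_m,
                                 aux = config$auxiliary)
    fit_m <- solve_least_squares(cons_m)
    out$monomer <- species_report(fit_m, spec_m, sol_m, coefs,
                                  logCw = config$logCw_monomer)
  }
  if (config$which %in% c("dimer", "both")) {
    sol_d <- kept[kept$species == "dimer" & kept$kind == "solubility", ]
    spec_d <- fit_spec(free = c("S", "A", "B", "L", "logKw", "logCw"),
                       fixed = list(E = E_dim, V = V_dim))
    cons_d <- assemble_equations(sol_d, coefs, spec_d)
    fit_d <- solve_least_squares(cons_d)
    out$dimer <- species_report(fit_d, spec_d, sol_d, coefs,
                                logCw = fit_d$estimates[["logCw"]])
  }
  structure(out, class = "lfer_replication")
}

## per-species descriptor vector, per-solvent table and solubility stats
species_report <- function(fit, spec, solubilities, coefs, logCw) {
  desc_vals <- c(fit$estimates, unlist(spec$fixed))
  desc_vals <- desc_vals[!duplicated(names(desc_vals))]
  full <- do.call(solute_descriptors,
                  c(as.list(desc_vals[intersect(names(desc_vals),
                                                c("E", "S", "A", "B", "V",
                                                  "L", "logKw", "logCw"))]),
                    list(fixed = names(spec$fixed))))
  obs_log_cs <- log10(solubilities$value)
  w_rows <- coefs[coefs$process_kind == "water_to_solvent", ]
  w_rows <- w_rows[match(solubilities$solvent, w_rows$system_id), ]
  calc_log_ps <- predict_log_partition(full, w_rows)
  tab <- data.frame(solvent = solubilities$solvent,
                    calc_log_ps = as.numeric(calc_log_ps),
                    obs_log_ps = obs_log_cs - logCw,
                    calc_log_cs = as.numeric(calc_log_ps) + logCw,
                    obs_log_cs = obs_log_cs,
                    stringsAsFactors = FALSE)
  list(fit = fit, descriptors = full, table = tab,
       stats = residual_stats(tab$obs_log_cs, tab$calc_log_cs),
       n_equations = fit$n_equations)
}

#' @export
print.lfer_replication <- function(x, digits = 3, ...) {
  cat("trans-cinnamic acid descriptor replication\n")
  if (length(x$excluded) > 0L)
    cat("Excluded (no Abraham coefficients):",
        paste(x$excluded, collapse = ", "), "\n")
  for (sp in intersect(c("monomer", "dimer"), names(x))) {
    r <- x[[sp]]
    cat("\n==", sp, "fit:", r$n_equations, "equations ==\n")
    vals <- r$descriptors$values
    vals <- vals[!is.na(vals)]
    print(round(vals, 4))
    cat(sprintf("Solubility set (n = %d): AE = %.*f, AAE = %.*f, SD = %.*f\n",
                nrow(r$table), digits, r$stats[["AE"]], digits,
                r$stats[["AAE"]], digits, r$stats[["SD"]]))
    print(data.frame(r$table[1],
                     round(r$table[-1], digits)), row.names = FALSE)
  }
  invisible(x)
}
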