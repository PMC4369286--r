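#' Read a table of Abraham process coefficients
#'
#' A process-coefficient record holds the regression coefficients
#' (c, e, s, a, b, and one of v or l) of a single solvent system's
#' Abraham equation. Water-to-solvent equations and the gas-to-water
#' V-form use the `v` coefficient (multiplying the McGowan volume V);
#' gas-to-solvent equations and the gas-to-water L-form use `l`
#' (multiplying the gas-hexadecane descriptor L). `auxiliary` records
#' may use any subset of terms.
#'
#' @param path CSV file with header
#'   `system_id,process_kind,c,e,s,a,b,v,l`; empty cells mark inactive
#'   terms. Lines starting with `#` are ignored.
#' @return A validated data frame of coefficient records.
#' @seealso [bundled_coefficients()] for the solvent compilation shipped
#'   with the package.
#' @export
read_coefficient_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  validate_coefficient_table(df)
}

#' Validate a coefficient table
#'
#' Checks column presence, process kinds, v/l exclusivity per kind and
#' uniqueness of `system_id` within each process kind.
#'
#' @param df Data frame of coefficient records.
#' @return The data frame, invisibly validated (returned unchanged).
#' @export
validate_coefficient_table <- function(df) {
  needed <- c("system_id", "process_kind", "c", "e", "s", "a", "b", "v", "l")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L)
    stop("coefficient table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  kinds <- c("water_to_solvent", "gas_to_solvent",
             "gas_to_water_V", "gas_to_water_L", "auxiliary")
  bad <- setdiff(unique(df$process_kind), kinds)
  if (length(bad) > 0L)
    stop("unknown process_kind: ", paste(bad, collapse = ", "))
  v_kind <- df$process_kind %in% c("water_to_solvent", "gas_to_water_V")
  l_kind <- df$process_kind %in% c("gas_to_solvent", "gas_to_water_L")
  v_act <- !is.na(df$v) & df$v != 0
  l_act <- !is.na(df$l) & df$l != 0
  if (any(v_act & l_act & df$process_kind != "auxiliary"))
    stop("malformed coefficients: both v and l active for ",
         paste(df$system_id[v_act & l_act], collapse = ", "))
  if (any(v_kind & !is.na(df$l) & df$l != 0))
    stop("l coefficient active on a V-form record: ",
         paste(df$system_id[v_kind & !is.na(df$l) & df$l != 0], collapse = ", "))
  if (any(l_kind & !is.na(df$v) & df$v != 0))
    stop("v coefficient active on an L-form record: ",
         paste(df$system_id[l_kind & !is.na(df$v) & df$v != 0], collapse = ", "))
  if (any(v_kind & is.na(df$v)))
    stop("v coefficient required for water_to_solvent / gas_to_water_V records")
  if (any(l_kind & is.na(df$l)))
    stop("l coefficient required for gas_to_solvent / gas_to_water_L records")
  key <- paste(df$system_id, df$process_kind, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate system_id within a process kind: ",
         paste(unique(df$system_id[duplicated(key)]), collapse = ", "))
  df
}

#' Construct a single process-coefficient record
#'
#' @param system_id Label for the solvent system (wet/dry qualifiers
#'   spelled out, e.g. `"octan-1-ol, wet"`).
#' @param process_kind One of `water_to_solvent`, `gas_to_solvent`,
#'   `gas_to_water_V`, `gas_to_water_L`, `auxiliary`.
#' @param c,e,s,a,b,v,l Equation coefficients; `NA` marks an inactive
#'   term.
#' @return A one-row coefficient data frame.
#' @export
process_coefficients <- function(system_id, process_kind, c = 0, e = 0,
                                 s = 0, a = 0, b = 0, v = NA, l = NA) {
  df <- data.frame(system_id = system_id, process_kind = process_kind,
                   c = c, e = e, s = s, a = a, b = b, v = v, l = l,
                   stringsAsFactors = FALSE)
  validate_coefficient_table(df)
}

#' Locate files bundled with the package
#'
#' Convenience accessor for the plain-text fixtures shipped under
#' `extdata`: the Abraham coefficient compilation, the trans-cinnamic
#' acid solubility and partition tables, the published fitted tables,
#' solvent metadata and the McGowan atomic volumes.
#'
#' @param file File name; with `NULL`, lists the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' lferdesc_example()
#' lferdesc_example("abraham_coefficients.csv")
#' @export
lferdesc_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "lferdesc")))
  path <- system.file("extdata", file, package = "lferdesc")
  if (path == "") stop("no bundled file named '", file, "'")
  path
}

#' Bundled Abraham solvent-coefficient compilation
#'
#' Loads the coefficient table transcribed from the published
#' water-to-solvent and gas-to-solvent Abraham compilations (dry
#' solvents unless marked wet), including the two gas-to-water closure
#' equations (V-form and L-form).
#'
#' @return A validated coefficient data frame.
#' @export
bundled_coefficients <- function() {
  read_coefficient_table(lferdesc_example("abraham_coefficients.csv"))
}
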