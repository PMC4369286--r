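#' Construct a set of Abraham solute descriptors
#'
#' Bundles the six Abraham solute descriptors with the two solute-level
#' partition/solubility unknowns used when descriptors are determined by
#' regression, and tracks per-field status (`fixed`, `free`, `absent`).
#'
#' The descriptors are: `E`, the excess molar refractivity in
#' (cm^3/mol)/10; `S`, the dipolarity/polarizability; `A` and `B`, the
#' hydrogen-bond acidity and basicity; `V`, the McGowan characteristic
#' volume in (cm^3/mol)/100; and `L`, the base-10 logarithm of the
#' gas-hexadecane partition coefficient at 298 K. `logKw` is the log10
#' dimensionless gas-water partition coefficient and `logCw` the log10
#' aqueous molar solubility.
#'
#' @param E,S,A,B,V,L,logKw,logCw Numeric descriptor values; `NA` marks a
#'   field as absent.
#' @param fixed Character vector naming the fields whose values are held
#'   constant during fitting. Fields supplied with a value but not listed
#'   here are flagged `free` (their value is a starting/true value, e.g.
#'   in simulations). All supplied fields are `fixed` by default.
#' @return An object of class `solute_descriptors`: a list with elements
#'   `values` (named numeric) and `status` (named character with levels
#'   fixed/free/absent).
#' @examples
#' solute_descriptors(E = 1.14, V = 1.1705, B = 0.50, logCw = -2.40)
#' @export
solute_descriptors <- function(E = NA, S = NA, A = NA, B = NA, V = NA,
                               L = NA, logKw = NA, logCw = NA,
                               fixed = NULL) {
  values <- c(E = as.numeric(E), S = as.numeric(S), A = as.numeric(A),
              B = as.numeric(B), V = as.numeric(V), L = as.numeric(L),
              logKw = as.numeric(logKw), logCw = as.numeric(logCw))
  present <- names(values)[!is.na(values)]
  if (is.null(fixed)) fixed <- present
  bad <- setdiff(fixed, names(values))
  if (length(bad) > 0L)
    stop("unknown descriptor field(s): ", paste(bad, collapse = ", "))
  missing_fixed <- setdiff(fixed, present)
  if (length(missing_fixed) > 0L)
    stop("field(s) flagged fixed but have no value: ",
         paste(missing_fixed, collapse = ", "))
  if (!is.na(values[["V"]]) && values[["V"]] <= 0)
    stop("V must be positive when set")
  status <- ifelse(is.na(values), "absent",
                   ifelse(names(values) %in% fixed, "fixed", "free"))
  names(status) <- names(values)
  structure(list(values = values, status = status),
            class = "solute_descriptors")
}

#' @export
print.solute_descriptors <- function(x, ...) {
  cat("Abraham solute descriptors\n")
  shown <- x$status != "absent"
  df <- data.frame(value = round(x$values[shown], 4),
                   status = x$status[shown])
  print(df)
  invisible(x)
}

#' Read or write solute descriptors as flat JSON
#'
#' The on-disk representation is a flat JSON object with one key per
#' descriptor field plus a `"fixed"` array naming the fields held
#' constant in fits.
#'
#' @param path File path.
#' @return `read_descriptors()` returns a [solute_descriptors] object;
#'   `write_descriptors()` returns `path` invisibly.
#' @export
read_descriptors <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixed <- obj[["fixed"]]
  fields <- intersect(names(obj), c("E", "S", "A", "B", "V", "L",
                                    "logKw", "logCw"))
  args <- lapply(fields, function(f) obj[[f]])
  names(args) <- fields
  do.call(solute_descriptors, c(args, list(fixed = fixed)))
}

#' @param desc A [solute_descriptors] object.
#' @rdname read_descriptors
#' @export
write_descriptors <- function(desc, path) {
  stopifnot(inherits(desc, "solute_descriptors"))
  present <- desc$status != "absent"
  obj <- as.list(desc$values[present])
  obj$fixed <- names(desc$status)[desc$status == "fixed"]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
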