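#' McGowan atomic volume contributions
#'
#' Loads the literature table of McGowan atomic volume contributions
#' (cm^3/mol) bundled with the package.
#'
#' @return Named numeric vector, element symbol -> volume in cm^3/mol.
#' @export
mcgowan_volume_table <- function() {
  df <- utils::read.csv(lferdesc_example("mcgowan_volumes.csv"),
                        comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(df$volume_cm3_per_mol, df$element)
}

#' Parse a Hill-notation molecular formula
#'
#' @param formula A formula string such as `"C9H8O2"`. One- and
#'   two-letter element symbols with optional counts are supported.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C18H16O4")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula))
    stop("cannot parse molecular formula: '", formula, "'")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1L]]
  tokens <- regmatches(formula, list(m))[[1L]]
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  tapply(counts, factor(elements, levels = unique(elements)), sum) |>
    c()
}

#' McGowan characteristic volume
#'
#' Computes the McGowan characteristic volume `V` (in (cm^3/mol)/100)
#' of a molecule from its elemental composition and ring count:
#' \deqn{V = [\sum_i n_i v_i - 6.56 B] / 100,\quad B = N_{atoms} - 1 + N_{rings}}
#' where `v_i` are atomic volume contributions and `B` the bond count
#' (every bond counted once regardless of order). For a hydrogen-bonded
#' carboxylic acid dimer treated as a single solute unit, the ring
#' closed by the two hydrogen bonds counts as one extra ring (its two
#' hydrogen bonds are the two extra bonds).
#'
#' @param composition A molecular formula string (Hill notation) or a
#'   named vector/map of element counts.
#' @param rings Number of rings (non-negative integer); always supplied
#'   explicitly, never perceived from structure.
#' @param volumes Atomic volume table; defaults to the bundled McGowan
#'   constants. Unknown elements fail loudly.
#' @return `V` in (cm^3/mol)/100.
#' @examples
#' mcgowan_volume("C9H8O2", rings = 1)     # trans-cinnamic acid, 1.1705
#' mcgowan_volume("C18H16O4", rings = 3)   # its H-bonded dimer, 2.2098
#' @export
mcgowan_volume <- function(composition, rings = 0,
                           volumes = mcgowan_volume_table()) {
  if (is.character(composition)) composition <- parse_formula(composition)
  composition <- unlist(composition)
  if (length(composition) == 0L || sum(composition) < 1)
    stop("empty molecule")
  if (any(composition < 0)) stop("negative element count")
  stopifnot(length(rings) == 1L, rings >= 0, rings == as.integer(rings))
  unknown <- setdiff(names(composition), names(volumes))
  if (length(unknown) > 0L)
    stop("no atomic volume for element(s): ",
         paste(unknown, collapse = ", "))
  n_atoms <- sum(composition)
  n_bonds <- n_atoms - 1 + rings
  if (n_bonds < 0) stop("inconsistent atom/ring counts")
  (sum(composition * volumes[names(composition)]) - 6.56 * n_bonds) / 100
}
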