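# Independent oracles used across the suite.

# Brute-force grid search minimizing the same weighted sum of squares
# as the linear solver, by iterative grid refinement. Only suitable for
# small systems (<= 3 unknowns).
grid_search_lsq <- function(X, y, w = rep(1, length(y)),
                            lower = -10, upper = 10, tol = 1e-5) {
  p <- ncol(X)
  stopifnot(p <= 3)
  lo <- rep(lower, p)
  hi <- rep(upper, p)
  best <- (lo + hi) / 2
  ssr <- function(b) sum(w * (y - drop(X %*% b))^2)
  repeat {
    grids <- lapply(seq_len(p), function(j) seq(lo[j], hi[j], length.out = 15))
    combos <- as.matrix(expand.grid(grids))
    vals <- apply(combos, 1, ssr)
    best <- combos[which.min(vals), ]
    step <- (hi - lo) / 14
    if (max(step) < tol) break
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  as.numeric(best)
}

# small helper: constraints object straight from a matrix (bypasses
# assembly, exercising only the solver)
constraints_from_matrix <- function(X, y, w = rep(1, length(y))) {
  spec <- fit_spec(free = colnames(X), fixed = list(E = 0, V = 1))
  structure(list(response = y, coeffs = X, weight = w,
                 provenance = data.frame(tag = rep("auxiliary", nrow(X)),
                                         solvent = NA_character_),
                 free = colnames(X), spec = spec),
            class = "lfer_constraints")
}

monomer_solvents <- function() {
  utils::read.csv(lferdesc_example("cinnamic_monomer_fit.csv"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

dimer_solvents <- function() {
  utils::read.csv(lferdesc_example("cinnamic_dimer_fit.csv"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

table1 <- function() read_measurements(lferdesc_example("cinnamic_solubilities.csv"))
table2 <- function() read_measurements(lferdesc_example("cinnamic_logp.csv"))
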