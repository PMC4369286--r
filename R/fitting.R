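#' Specify which unknowns a descriptor fit estimates
#'
#' @param free Ordered character vector of free unknowns, drawn from
#'   `S`, `A`, `B`, `L`, `logKw`, `logCw`.
#' @param fixed Named list/vector of fixed values. Must include `E` and
#'   `V` (both are always obtained from structure before fitting) and
#'   may fix any of `S`, `A`, `B`, `L`, `logKw`, `logCw`.
#' @return An object of class `fit_spec`.
#' @examples
#' fit_spec(free = c("S", "A", "L", "logKw"),
#'          fixed = list(E = 1.14, V = 1.1705, B = 0.50, logCw = -2.40))
#' @export
fit_spec <- function(free, fixed) {
  fixed <- as.list(fixed)
  allowed_free <- c("S", "A", "B", "L", "logKw", "logCw")
  bad <- setdiff(free, allowed_free)
  if (length(bad) > 0L)
    stop("cannot free unknown(s): ", paste(bad, collapse = ", "))
  if (!all(c("E", "V") %in% names(fixed)))
    stop("E and V must be fixed before any fit")
  overlap <- intersect(free, names(fixed))
  if (length(overlap) > 0L)
    stop("simultaneously fixed and free: ", paste(overlap, collapse = ", "))
  if (any(!vapply(fixed, function(x) is.finite(as.numeric(x)), logical(1L))))
    stop("fixed values must be finite numbers")
  structure(list(free = free, fixed = lapply(fixed, as.numeric)),
            class = "fit_spec")
}

#' Construct an auxiliary linear constraint
#'
#' A single assembled equation: a known response equated to a linear
#' combination of the free unknowns. Used for constraints that do not
#' arise from solubility/partition measurements, such as a
#' chromatographic retention-data equation constraining `L`.
#'
#' @param response Known response value.
#' @param coeffs Named numeric vector of coefficients over free
#'   unknowns.
#' @param weight Positive weight (default 1).
#' @param provenance Provenance tag (default `"auxiliary"`).
#' @param solvent Optional solvent label.
#' @return An object of class `linear_constraint`.
#' @export
linear_constraint <- function(response, coeffs, weight = 1,
                              provenance = "auxiliary", solvent = NA) {
  check_finite(response, "response")
  if (length(coeffs) == 0L || is.null(names(coeffs)) ||
      all(coeffs == 0))
    stop("constraint needs at least one nonzero named coefficient")
  stopifnot(weight > 0)
  structure(list(response = response, coeffs = coeffs, weight = weight,
                 provenance = provenance, solvent = solvent),
            class = "linear_constraint")
}

descriptor_coef <- function(row, d) {
  cf <- row[[term_map[[d]]]]
  if (is.na(cf)) 0 else cf
}

#' Assemble the stacked linear system for a descriptor fit
#'
#' Every curated saturation solubility contributes two equations: a
#' water-to-solvent form, `log Cs = (c + eE + sS + aA + bB + vV) +
#' log Cw`, and a gas-to-solvent form, `log Cs = (c + eE + sS + aA +
#' bB + lL) + log Cw - log Kw`. Every direct partition coefficient
#' likewise contributes a P-form (`log P = water-to-solvent equation`)
#' and a K-form (`log P = gas-to-solvent equation - log Kw`). Two
#' gas-to-water closure equations (the V-form and L-form correlations
#' for `log Kw`, response side `0 = RHS - log Kw`) tie `log Kw` to the
#' descriptors, and auxiliary constraints pass through unchanged.
#' Contributions of fixed descriptors are folded into the response;
#' free unknowns receive their equation coefficients (`S -> s`,
#' `A -> a`, `B -> b`, `L -> l`, `logCw -> +1`, `logKw -> -1`).
#'
#' @param measurements Curated measurement data frame: solubilities in
#'   molarity and/or direct `log_p` rows. Every solvent must have the
#'   required coefficient records (filtering is the data-curation
#'   step's job; a missing record here is a hard error).
#' @param coeff_table Coefficient data frame.
#' @param spec A [fit_spec] object.
#' @param aux List of [linear_constraint] objects (may be empty).
#' @param include_closures Append the gas-to-water closure equations
#'   found in `coeff_table` (default `TRUE`).
#' @return An object of class `lfer_constraints`: list with `response`,
#'   `coeffs` (matrix, one column per free unknown), `weight`, and a
#'   `provenance` data frame (tag and solvent per equation).
#' @export
assemble_equations <- function(measurements, coeff_table, spec,
                               aux = list(), include_closures = TRUE) {
  stopifnot(inherits(spec, "fit_spec"))
  coeff_table <- validate_coefficient_table(coeff_table)
  free <- spec$free
  fixed <- spec$fixed
  rows <- list(); resp <- numeric(0); prov <- character(0)
  solv <- character(0); wt <- numeric(0)

  get_row <- function(system_id, kind) {
    r <- coeff_table[coeff_table$system_id == system_id &
                       coeff_table$process_kind == kind, , drop = FALSE]
    if (nrow(r) != 1L)
      stop("no ", kind, " coefficients for solvent '", system_id, "'")
    r
  }

  ## one equation: obs = c + sum(desc terms) + sum(extra * unknown)
  ## extra: named +/-1 multipliers on logCw / logKw
  push <- function(obs, row, extra, tag, solvent) {
    cvec <- stats::setNames(numeric(length(free)), free)
    response <- obs - row[["c"]]
    for (d in names(term_map)) {
      cf <- descriptor_coef(row, d)
      if (cf == 0) next
      if (d %in% free) {
        cvec[d] <- cvec[d] + cf
      } else if (d %in% names(fixed)) {
        response <- response - cf * fixed[[d]]
      } else {
        stop("descriptor ", d, " required by '", row$system_id,
             "' is neither free nor fixed")
      }
    }
    for (u in names(extra)) {
      if (u %in% free) {
        cvec[u] <- cvec[u] + extra[[u]]
      } else if (u %in% names(fixed)) {
        response <- response - extra[[u]] * fixed[[u]]
      } else {
        stop(u, " must be either free or fixed")
      }
    }
    rows[[length(rows) + 1L]] <<- cvec
    resp[length(resp) + 1L] <<- response
    prov[length(prov) + 1L] <<- tag
    solv[length(solv) + 1L] <<- solvent
    wt[length(wt) + 1L] <<- 1
  }

  if (nrow(measurements) > 0L) {
    for (i in seq_len(nrow(measurements))) {
      m <- measurements[i, ]
      if (m$kind == "solubility") {
        if (m$unit != "molarity")
          stop("solubility for '", m$solvent,
               "' must be curated to molarity before assembly")
        log_cs <- log10(m$value)
        push(log_cs, get_row(m$solvent, "water_to_solvent"),
             c(logCw = 1), "solubility_logP", m$solvent)
        push(log_cs, get_row(m$solvent, "gas_to_solvent"),
             c(logCw = 1, logKw = -1), "solubility_logK", m$solvent)
      } else if (m$kind == "direct_log_p") {
        push(m$value, get_row(m$solvent, "water_to_solvent"),
             numeric(0), "direct_logP", m$solvent)
        push(m$value, get_row(m$solvent, "gas_to_solvent"),
             c(logKw = -1), "direct_logK", m$solvent)
      } else {
        stop("unknown measurement kind: ", m$kind)
      }
    }
  }

  if (include_closures) {
    for (ck in c("gas_to_water_V", "gas_to_water_L")) {
      r <- coeff_table[coeff_table$process_kind == ck, , drop = FALSE]
      if (nrow(r) == 0L) next
      if (nrow(r) > 1L) stop("multiple ", ck, " closure records")
      push(0, r, c(logKw = -1),
           if (ck == "gas_to_water_V") "kw_closure_V" else "kw_closure_L",
           r$system_id)
    }
  }

  for (ax in aux) {
    stopifnot(inherits(ax, "linear_constraint"))
    bad <- setdiff(names(ax$coeffs), free)
    if (length(bad) > 0L)
      stop("auxiliary constraint references non-free unknown(s): ",
           paste(bad, collapse = ", "))
    cvec <- stats::setNames(numeric(length(free)), free)
    cvec[names(ax$coeffs)] <- ax$coeffs
    rows[[length(rows) + 1L]] <- cvec
    resp[length(resp) + 1L] <- ax$response
    prov[length(prov) + 1L] <- ax$provenance
    solv[length(solv) + 1L] <- as.character(ax$solvent)
    wt[length(wt) + 1L] <- ax$weight
  }

  X <- if (length(rows) > 0L) do.call(rbind, rows) else
    matrix(numeric(0), nrow = 0, ncol = length(free),
           dimnames = list(NULL, free))
  colnames(X) <- free
  if (nrow(X) > 0L) {
    never <- free[colSums(X != 0) == 0L]
    if (length(never) > 0L)
      stop("unidentifiable unknown(s) appearing in no constraint: ",
           paste(never, collapse = ", "))
  }
  structure(list(response = resp, coeffs = X, weight = wt,
                 provenance = data.frame(tag = prov, solvent = solv,
                                         stringsAsFactors = FALSE),
                 free = free, spec = spec),
            class = "lfer_constraints")
}

#' @export
print.lfer_constraints <- function(x, ...) {
  cat("LFER constraint system:", length(x$response), "equations,",
      ncol(x$coeffs), "free unknowns (",
      paste(x$free, collapse = ", "), ")\n")
  print(table(x$provenance$tag))
  invisible(x)
}

#' Solve an assembled constraint system by weighted least squares
#'
#' Minimizes the weighted sum of squared residuals over the free
#' unknowns by a direct (deterministic) linear solve. Exact rank
#' deficiency aborts with the collinear unknowns named rather than
#' falling back to a pseudo-inverse; duplicate constraints are allowed
#' and act as weights.
#'
#' @param constraints An `lfer_constraints` object from
#'   [assemble_equations()].
#' @return An object of class `lfer_fit`: estimates, per-equation
#'   fitted values and residuals (observed - fitted), equation count,
#'   `AE` (mean residual), `AAE` (mean absolute residual), `SD`
#'   (sample standard deviation of residuals, n - 1 divisor),
#'   provenance table and design-matrix condition number.
#' @export
solve_least_squares <- function(constraints) {
  stopifnot(inherits(constraints, "lfer_constraints"))
  X <- constraints$coeffs
  y <- constraints$response
  w <- constraints$weight
  p <- ncol(X)
  if (nrow(X) < p)
    stop("underdetermined: ", nrow(X), " constraints for ", p, " unknowns")
  sw <- sqrt(w)
  Xw <- X * sw
  qrX <- qr(Xw)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("unidentifiable system: collinear unknown(s) ",
         paste(dropped, collapse = ", "))
  }
  est <- qr.coef(qrX, y * sw)
  fitted <- drop(X %*% est)
  resid <- y - fitted
  st <- residual_stats(y, fitted)
  structure(list(estimates = stats::setNames(as.numeric(est), colnames(X)),
                 fitted = fitted, residuals = resid,
                 n_equations = nrow(X),
                 AE = st[["AE"]], AAE = st[["AAE"]], SD = st[["SD"]],
                 provenance = constraints$provenance,
                 condition_number = kappa(Xw, exact = TRUE),
                 spec = constraints$spec),
            class = "lfer_fit")
}

#' @export
print.lfer_fit <- function(x, digits = 3, ...) {
  cat("LFER least-squares fit over", x$n_equations, "equations\n")
  cat("Estimates:\n")
  print(round(x$estimates, digits))
  cat(sprintf("AE = %.*f, AAE = %.*f, SD = %.*f (n - 1 divisor)\n",
              digits, x$AE, digits, x$AAE, digits, x$SD))
  cat(sprintf("Design condition number: %.3g\n", x$condition_number))
  invisible(x)
}

#' Residual summary statistics
#'
#' The three fit-quality statistics reported for descriptor
#' determinations: the average (signed) error, average absolute error,
#' and sample standard deviation of the residuals.
#'
#' @param observed,fitted Equal-length numeric vectors.
#' @return Named numeric vector: `AE = mean(observed - fitted)`,
#'   `AAE = mean(|observed - fitted|)`,
#'   `SD = sqrt(sum((observed - fitted)^2) / (n - 1))`.
#' @examples
#' residual_stats(c(1, 2, 3), c(1.1, 1.9, 3.0))
#' @export
residual_stats <- function(observed, fitted) {
  if (length(observed) != length(fitted))
    stop("observed and fitted must have equal length")
  if (length(observed) == 0L) stop("no residuals")
  r <- observed - fitted
  c(AE = mean(r), AAE = mean(abs(r)),
    SD = if (length(r) >= 2L) stats::sd(r) else NA_real_)
}
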