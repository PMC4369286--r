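mono_spec <- function(aux = TRUE)
  fit_spec(free = c("S", "A", "L", "logKw"),
           fixed = list(E = 1.14, V = 1.1705, B = 0.50, logCw = -2.40))

dimer_spec <- function()
  fit_spec(free = c("S", "A", "B", "L", "logKw", "logCw"),
           fixed = list(E = 1.68, V = 2.2098))

retention_aux <- function()
  # stand-in for a chromatographic retention equation constraining L
  linear_constraint(response = 5.8, coeffs = c(L = 1),
                    provenance = "auxiliary")

monomer_measurements <- function() {
  meas <- table1()
  sol <- meas[meas$solvent %in% monomer_solvents()$solvent, ]
  rbind(sol, table2())
}

test_that("equation counts follow 2 x measurements + closures + auxiliary", {
  coefs <- bundled_coefficients()
  cons <- assemble_equations(monomer_measurements(), coefs, mono_spec(),
                             aux = list(retention_aux()))
  expect_equal(length(cons$response), 45)
  expect_equal(sum(cons$provenance$tag == "solubility_logP"), 16)
  expect_equal(sum(cons$provenance$tag == "direct_logK"), 5)
  expect_equal(sum(grepl("closure", cons$provenance$tag)), 2)

  dim_meas <- table1()
  dim_meas <- dim_meas[dim_meas$solvent %in% dimer_solvents()$solvent, ]
  cons_d <- assemble_equations(dim_meas, coefs, dimer_spec())
  expect_equal(length(cons_d$response), 20)

  empty <- assemble_equations(table1()[0, ], coefs, mono_spec(),
                              include_closures = FALSE)
  expect_equal(length(empty$response), 0)
})

test_that("fixed contributions are folded and sign conventions hold", {
  # one solvent, hand-checkable coefficients
  tab <- rbind(
    process_coefficients("s1", "water_to_solvent", c = 0.5, e = 1, s = 2,
                         a = 3, b = 4, v = 5),
    process_coefficients("s1", "gas_to_solvent", c = -0.5, e = 1, s = 2,
                         a = 3, b = 4, l = 6))
  meas <- data.frame(solvent = "s1", kind = "solubility", value = 10,
                     unit = "molarity", temperature = 298.15,
                     species = NA, source = "x")
  spec <- fit_spec(free = c("S", "A", "L", "logKw"),
                   fixed = list(E = 2, V = 3, B = 0.5, logCw = -2))
  cons <- assemble_equations(meas, tab, spec, include_closures = FALSE)
  # P-form: log10(10) - c - e*E - b*B - v*V - logCw
  expect_equal(cons$response[1], 1 - 0.5 - 2 - 2 - 15 + 2)
  expect_equal(cons$coeffs[1, ], c(S = 2, A = 3, L = 0, logKw = 0))
  # K-form: response loses the l*L? no - L free: stays unknown side
  expect_equal(cons$response[2], 1 + 0.5 - 2 - 2 + 2)
  expect_equal(cons$coeffs[2, ], c(S = 2, A = 3, L = 6, logKw = -1))
})

test_that("a noiseless synthetic system is recovered exactly", {
  sc <- synthetic_scenario(n_solvents = 9, noise_sigma = 0, seed = 101)
  tab <- gen_coefficient_table(sc)
  meas <- gen_measurements(sc, tab)
  truth <- sc$true_descriptors
  spec <- fit_spec(free = c("S", "A", "B", "L", "logKw", "logCw"),
                   fixed = list(E = truth$values[["E"]],
                                V = truth$values[["V"]]))
  fit <- solve_least_squares(assemble_equations(meas, tab, spec))
  expect_equal(fit$estimates,
               truth$values[c("S", "A", "B", "L", "logKw", "logCw")],
               tolerance = 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("the linear solve agrees with a brute-force grid search", {
  set.seed(5)
  for (p in 2:3) {
    X <- matrix(stats::rnorm(8 * p), ncol = p,
                dimnames = list(NULL, c("S", "A", "B")[seq_len(p)]))
    beta <- stats::runif(p, -2, 2)
    y <- drop(X %*% beta) + stats::rnorm(8, 0, 0.3)
    fit <- solve_least_squares(constraints_from_matrix(X, y))
    oracle <- grid_search_lsq(X, y, lower = -5, upper = 5)
    expect_equal(unname(fit$estimates), oracle, tolerance = 1e-4)
  }
})

test_that("solutions satisfy the normal equations and residual orthogonality", {
  set.seed(9)
  X <- matrix(stats::rnorm(30 * 4), ncol = 4,
              dimnames = list(NULL, c("S", "A", "B", "L")))
  y <- stats::rnorm(30)
  fit <- solve_least_squares(constraints_from_matrix(X, y))
  # gradient of the objective is -2 X'r; orthogonality of residuals
  grad <- drop(crossprod(X, fit$residuals))
  norms <- sqrt(colSums(X^2)) * sqrt(sum(fit$residuals^2))
  expect_true(all(abs(grad) <= 1e-8 * pmax(norms, 1)))
})

test_that("constraints already satisfied exactly leave the solution unchanged", {
  set.seed(13)
  X <- matrix(stats::rnorm(12 * 2), ncol = 2,
              dimnames = list(NULL, c("S", "A")))
  y <- stats::rnorm(12)
  fit <- solve_least_squares(constraints_from_matrix(X, y))
  new_row <- c(S = 0.7, A = -1.3)
  X2 <- rbind(X, new_row)
  y2 <- c(y, sum(new_row * fit$estimates))
  fit2 <- solve_least_squares(constraints_from_matrix(X2, y2))
  expect_equal(fit2$estimates, fit$estimates, tolerance = 1e-10)
  # duplicated constraints act as weights: same as weight-2 original
  fit3 <- solve_least_squares(constraints_from_matrix(rbind(X, X[1, ]),
                                                      c(y, y[1])))
  fit4 <- solve_least_squares(
    constraints_from_matrix(X, y, w = c(2, rep(1, 11))))
  expect_equal(fit3$estimates, fit4$estimates, tolerance = 1e-10)
})

test_that("degenerate systems abort with named diagnoses", {
  X <- matrix(c(1, 2, 1, 2, 2, 4, 2, 4), ncol = 2,
              dimnames = list(NULL, c("S", "A")))  # A = 2 S
  expect_error(solve_least_squares(constraints_from_matrix(X, rep(1, 4))),
               "collinear")
  X1 <- matrix(1, nrow = 1, ncol = 2, dimnames = list(NULL, c("S", "A")))
  expect_error(solve_least_squares(constraints_from_matrix(X1, 1)),
               "underdetermined")
  # a free unknown appearing nowhere is unidentifiable at assembly time
  tab <- rbind(
    process_coefficients("s1", "water_to_solvent", c = 0, s = 1, a = 1,
                         v = 1),
    process_coefficients("s1", "gas_to_solvent", c = 0, s = 1, a = 1,
                         l = 1))
  meas <- data.frame(solvent = "s1", kind = "solubility", value = 1,
                     unit = "molarity", temperature = 298.15,
                     species = NA, source = "x")
  spec <- fit_spec(free = c("S", "A", "B", "L", "logKw", "logCw"),
                   fixed = list(E = 1, V = 1))
  expect_error(assemble_equations(meas, tab, spec, include_closures = FALSE),
               "unidentifiable")
})

test_that("residual statistics reproduce the published fit summaries", {
  t4 <- monomer_solvents()
  st4 <- residual_stats(t4$obs_log_cs, t4$calc_log_cs)
  expect_equal(round(unname(st4), 3), c(0.006, 0.055, 0.078))
  t5 <- dimer_solvents()
  st5 <- residual_stats(t5$obs_log_cs, t5$calc_log_cs)
  expect_equal(round(unname(st5), 3), c(0.003, 0.053, 0.084))
  # the SD divisor is n - 1: n in the denominator would give 0.075 / 0.079
  expect_equal(round(sqrt(mean((t4$obs_log_cs - t4$calc_log_cs)^2)), 3),
               0.075)
  expect_equal(round(sqrt(mean((t5$obs_log_cs - t5$calc_log_cs)^2)), 3),
               0.079)
  expect_equal(unname(residual_stats(1:4, 1:4)), c(0, 0, 0))
  expect_error(residual_stats(1:3, 1:2), "equal length")
})
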