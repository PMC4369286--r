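test_that("solubility unit conversions reach molarity", {
  expect_equal(to_molarity(1.384, "molarity", 148.16), 1.384)
  expect_equal(to_molarity(0, "mass_fraction", 148.16,
                           solvent_density = 0.8), 0)
  # independent hand evaluation of the mole-fraction closed form
  x <- 0.05; rho <- 0.7857; Mv <- 41.05; Ms <- 148.16
  by_hand <- 1000 * rho * x / (x * Ms + (1 - x) * Mv)
  expect_equal(to_molarity(x, "mole_fraction", Ms, rho, Mv), by_hand,
               tolerance = 1e-12)
  # mass ratio r reduces to mass fraction r/(1+r)
  r <- 0.25
  expect_equal(to_molarity(r, "mass_ratio", Ms, rho),
               to_molarity(r / (1 + r), "mass_fraction", Ms, rho),
               tolerance = 1e-12)
  expect_error(to_molarity(1, "log_p", Ms), "not a solubility")
  expect_error(to_molarity(0.1, "mole_fraction", Ms), "metadata")
})

test_that("unit conversion is monotone in the solubility value", {
  Ms <- 148.16; rho <- 0.9; Mv <- 78.11
  for (unit in c("molarity", "mole_fraction", "mass_fraction", "mass_ratio")) {
    v <- seq(0.01, if (unit == "molarity") 2 else 0.5, length.out = 20)
    out <- vapply(v, to_molarity, numeric(1), unit = unit,
                  solute_molar_mass = Ms, solvent_density = rho,
                  solvent_molar_mass = Mv)
    expect_true(all(diff(out) > 0), info = unit)
  }
})

test_that("mole fraction and molarity conversions are mutual inverses", {
  Ms <- 148.16; rho <- 0.789; Mv <- 46.07
  for (x in c(1e-4, 0.01, 0.1, 0.4)) {
    C <- mole_fraction_to_molarity(x, Ms, rho, Mv)
    expect_equal(molarity_to_mole_fraction(C, Ms, rho, Mv), x,
                 tolerance = 1e-12)
  }
})

test_that("Buchowski correction matches its closed form and round-trips", {
  # identity at the reference temperature
  expect_identical(buchowski_correct_x(0.123, 298.15, Tm = 406), 0.123)
  # miscibility boundary
  expect_equal(buchowski_correct_x(1, 406, Tm = 406, T_ref = 406), 1)
  # closed-form hand evaluation at lambda = 1
  x <- 0.10; T1 <- 293.15; Tm <- 406
  h <- log(1 / x) / (1 / T1 - 1 / Tm)
  expect_equal(buchowski_correct_x(x, T1, Tm),
               exp(-h * (1 / 298.15 - 1 / Tm)), tolerance = 1e-12)
  # round trip back to the measurement temperature
  x25 <- buchowski_correct_x(x, T1, Tm)
  expect_equal(buchowski_correct_x(x25, 298.15, Tm, T_ref = T1), x,
               tolerance = 1e-10)
  # solubility of a solid increases with temperature under h > 0
  temps <- seq(278, 318, by = 10)
  xs <- vapply(temps, function(t)
    buchowski_correct_x(0.05, 283.15, Tm, T_ref = t), numeric(1))
  expect_true(all(diff(xs) > 0))
  expect_error(buchowski_correct_x(0.1, 410, Tm = 406), "melting")
  expect_error(buchowski_correct_x(1.2, 293.15, Tm = 406), "not a dilute")
})

test_that("the molarity wrapper corrects through mole-fraction space", {
  C <- 0.7; T1 <- 292.65; Tm <- 406; Ms <- 148.16; rho <- 0.789; Mv <- 46.07
  x <- molarity_to_mole_fraction(C, Ms, rho, Mv)
  expected <- mole_fraction_to_molarity(
    buchowski_correct_x(x, T1, Tm), Ms, rho, Mv)
  expect_equal(buchowski_adjust(C, T1, Tm, Ms, rho, Mv), expected,
               tolerance = 1e-12)
  expect_identical(buchowski_adjust(C, 298.15, Tm, Ms, rho, Mv), C)
})

test_that("replicate averaging reports mean and mean absolute deviation", {
  expect_equal(average_replicates(c(0.5, 0.5)),
               list(mean = 0.5, mean_deviation = 0))
  expect_equal(average_replicates(c(1.0, 1.2)),
               list(mean = 1.1, mean_deviation = 0.1))
  expect_equal(average_replicates(c(0.2, 0.3, 0.7)),
               list(mean = 0.4, mean_deviation = 0.2))
  expect_error(average_replicates(numeric(0)), "no measurements")
  # zero deviation iff all replicates equal; mean within [min, max]
  set.seed(7)
  for (i in 1:10) {
    v <- stats::runif(sample(2:6, 1))
    out <- average_replicates(v)
    expect_true(out$mean >= min(v) && out$mean <= max(v))
    expect_equal(out$mean_deviation == 0, all(v == v[1]))
  }
})

test_that("solvent basicity classifies the saturated species", {
  expect_equal(classify_solvent_species(0.66), "monomer")   # methanol
  expect_equal(classify_solvent_species(0.10), "dimer")     # benzene
  expect_equal(classify_solvent_species(0.35), "unclassified")
  expect_equal(classify_solvent_species(NA), "unclassified")
  expect_equal(classify_solvent_species(c(0.47, 0.0, 0.36)),
               c("monomer", "dimer", "monomer"))
})

test_that("coefficient availability partitions the solubility table", {
  meas <- table1()
  coefs <- bundled_coefficients()
  parts <- filter_missing_coefficients(meas, coefs)
  # the four chlorinated solvents without Abraham parameters, plus water
  expect_setequal(parts$excluded$solvent,
                  c("pentachloroethane", "tetrachloroethane",
                    "tetrachloroethylene", "trichloroethylene", "water"))
  expect_equal(nrow(parts$kept) + nrow(parts$excluded), nrow(meas))
  # vacuous cases
  empty <- coefs[0, ]
  expect_equal(nrow(filter_missing_coefficients(meas, empty)$kept), 0)
  full <- rbind(coefs,
                process_coefficients(parts$excluded$solvent,
                                     "water_to_solvent", v = 1),
                process_coefficients(parts$excluded$solvent,
                                     "gas_to_solvent", l = 1))
  expect_equal(nrow(filter_missing_coefficients(meas, full)$excluded), 0)
})

test_that("classification plus filtering reproduces the published split", {
  meas <- table1()
  meas <- meas[meas$solvent != "water", ]
  coefs <- bundled_coefficients()
  meta <- read_solvent_metadata(lferdesc_example("solvent_metadata.csv"))
  parts <- filter_missing_coefficients(meas, coefs)
  expect_length(unique(parts$excluded$solvent), 4)
  beta <- meta$beta[match(parts$kept$solvent, meta$name)]
  cls <- classify_solvent_species(beta)
  expect_setequal(parts$kept$solvent[cls == "monomer"],
                  monomer_solvents()$solvent)
  expect_setequal(parts$kept$solvent[cls == "dimer"],
                  dimer_solvents()$solvent)
  # trifluoroethanol is an alcohol yet sits in the dimer set (beta = 0)
  expect_true("trifluoroethanol" %in% parts$kept$solvent[cls == "dimer"])
})

test_that("measurement validation enforces study invariants", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeLines(c("solvent,kind,value,unit,temperature_C,source",
               "benzene,solubility,-0.1,molarity,25,x"), path)
  expect_error(read_measurements(path), "positive")
  writeLines(c("solvent,kind,value,unit,temperature_C,source",
               "benzene,solubility,0.3,molarity,60,x"), path)
  expect_error(read_measurements(path), "temperature")
  writeLines(c("solvent,kind,value,unit,temperature_C,source",
               "benzene,direct_log_p,1.2,log_p,25,x"), path)
  m <- read_measurements(path)
  expect_equal(m$species, "monomer")  # direct partitions are monomer
})
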