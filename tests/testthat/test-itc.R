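test_that("free_ligand handles the degenerate limits", {
  m <- binding_model("sequential", Kd = c(1e-6, 1e-5), dH = c(-10, -20))
  expect_equal(free_ligand(0, 1e-6, m), 0)
  expect_equal(free_ligand(1e-5, 0, m), 1e-5)
})

test_that("free_ligand matches a refining grid scan of the mass balance", {
  # the two-step assembly constants, at mid-titration totals
  m <- assembly_truth()
  a_pkg <- free_ligand(10e-6, 2.5e-6, m)
  a_ora <- grid_scan_free_ligand(10e-6, 2.5e-6, m$Kd)
  expect_equal(a_pkg, a_ora, tolerance = 1e-6)
  # and for the three-step calcium constants
  m3 <- calcium_truth()
  a_pkg3 <- free_ligand(2e-3, 1.25e-3, m3)
  a_ora3 <- grid_scan_free_ligand(2e-3, 1.25e-3, m3$Kd)
  expect_equal(a_pkg3, a_ora3, tolerance = 1e-6)
})

test_that("species: limits, Kd definition, and conservation", {
  m1 <- binding_model("sequential", Kd = 2e-6, dH = -50)
  # no free ligand, no complexes
  expect_equal(unname(species(0, 1e-6, m1)), c(1e-6, 0))
  # at A_free = Kd, [MA] = [M] by definition
  sp <- species(2e-6, 1e-6, m1)
  expect_equal(sp[["MA"]], sp[["M"]], tolerance = 1e-12)
  # conservation for random draws across 1-3 step models
  set.seed(42)
  for (k in 1:3) {
    mk <- binding_model("sequential", Kd = 10^stats::runif(k, -9, -3),
                        dH = stats::rnorm(k, -100, 50))
    for (r in 1:10) {
      a <- 10^stats::runif(1, -9, -2)
      M <- 10^stats::runif(1, -7, -3)
      expect_equal(sum(species(a, M, mk)), M, tolerance = 1e-12)
    }
  }
})

test_that("ligand mass is conserved across a full titration", {
  sch <- assembly_scheme()
  m <- assembly_truth()
  V0 <- sch$cell_volume_uL
  A_tot <- 0; M_tot <- sch$cell_conc_M
  for (v in sch$injection_volumes_uL) {
    d <- 1 - v / V0
    M_tot <- M_tot * d
    A_tot <- A_tot * d + sch$syringe_conc_M * v / V0
    a <- free_ligand(A_tot, M_tot, m)
    sp <- species(a, M_tot, m)
    bound <- sp[["MA"]] + 2 * sp[["MA2"]]
    expect_equal(a + bound, A_tot, tolerance = 1e-9 * A_tot)
  }
})

test_that("simulate_isotherm: zero-enthalpy model gives identically zero heats", {
  sch <- assembly_scheme()
  m0 <- binding_model("sequential", Kd = c(1e-9, 1e-6), dH = c(0, 0))
  expect_true(all(simulate_isotherm(sch, m0)$q_norm == 0))
})

test_that("tight-binding limit: cumulative heat equals V0 M0 sum(dH)", {
  # saturating schedule (molar ratio reaches ~3.8 for a 2-site scheme)
  sch <- titration_scheme(cell_conc_M = 2.5e-6, syringe_conc_M = 50e-6,
                          temperature_K = 298.15)
  m <- binding_model("sequential", Kd = c(1e-15, 1e-15),
                     dH = c(-100, -150))
  # no-displacement mode makes the closed-form limit exact
  iso <- simulate_isotherm(sch, m, dilution = "none")
  q_raw <- iso$q_norm * sch$syringe_conc_M * iso$volume_uL * 1e-6  # kJ
  expected <- sch$cell_volume_uL * 1e-6 * sch$cell_conc_M * sum(m$dH)
  expect_equal(sum(q_raw), expected, tolerance = 0.01 * abs(expected))
})

test_that("Wiseman midpoint: one-set c = 10 has q ~ dH/2 at molar ratio 1", {
  M0 <- 10e-6
  m <- binding_model("one_set", Kd = M0 / 10, dH = -80, n_sites = 1)
  # fine schedule so the discrete heat at ratio 1 is sharp
  sch <- titration_scheme(cell_conc_M = M0, syringe_conc_M = 200e-6,
                          injection_volumes_uL = rep(0.5, 50),
                          temperature_K = 298.15)
  iso <- simulate_isotherm(sch, m, dilution = "none")
  at1 <- which.min(abs(iso$molar_ratio - 1))
  expect_equal(iso$q_norm[at1], m$dH / 2, tolerance = 0.05 * abs(m$dH / 2))
})

test_that("one-step sequential and one-set(n = 1) produce identical isotherms", {
  sch <- assembly_scheme()
  seq1 <- binding_model("sequential", Kd = 5e-7, dH = -120)
  one <- binding_model("one_set", Kd = 5e-7, dH = -120, n_sites = 1)
  expect_equal(simulate_isotherm(sch, seq1)$q_norm,
               simulate_isotherm(sch, one)$q_norm, tolerance = 1e-12)
})

test_that("simulate_isotherm is deterministic and ratios increase", {
  sch <- calcium_scheme()
  m <- calcium_truth()
  i1 <- simulate_isotherm(sch, m)
  i2 <- simulate_isotherm(sch, m)
  expect_identical(i1$q_norm, i2$q_norm)
  expect_true(all(diff(i1$molar_ratio) > 0))
})

test_that("weaker binding releases less total heat (exothermic steps)", {
  sch <- assembly_scheme()
  base <- c(1e-8, 1e-6)
  total_heat <- function(Kd) {
    m <- binding_model("sequential", Kd = Kd, dH = c(-100, -200))
    sum(simulate_isotherm(sch, m)$q_norm)
  }
  for (step in 1:2) {
    for (factor in c(10, 100)) {
      weak <- base; weak[step] <- base[step] * factor
      # exothermic: heats negative; weaker binding gives less negative total
      expect_gte(total_heat(weak), total_heat(base))
    }
  }
})

test_that("thermo_decompose: sign conventions and closed-form values", {
  # Kd = 1 M is the standard state: dG = 0
  expect_equal(thermo_decompose(1, -10, 298.15)$dG, 0)
  # one-set assembly constant at 30 C: dG = RT ln Kd ~ -41.6 kJ/mol
  td <- thermo_decompose(66.7e-9, -100, 303.15)
  expect_equal(td$dG, 8.314 * 303.15 * log(66.7e-9) / 1000,
               tolerance = 1e-12)
  expect_equal(round(td$dG, 1), -41.6)
  # dH = dG gives zero entropic term; identity dG = dH + mTdS holds
  dG <- thermo_decompose(1e-6, 0, 298.15)$dG
  expect_equal(thermo_decompose(1e-6, dG, 298.15)$mTdS, 0, tolerance = 1e-9)
  td2 <- thermo_decompose(c(1e-4, 1e-3, 1.94e-6), c(4.78, 150.7, -154.42),
                          303.15)
  expect_equal(td2$dG, td2$dH + td2$mTdS, tolerance = 1e-9)
})

test_that("isotherm CSV round trip", {
  iso <- simulate_isotherm(assembly_scheme(), assembly_truth())
  f <- tempfile(fileext = ".csv")
  write_isotherm(iso, f)
  back <- read_isotherm(f)
  expect_equal(back$q_norm, iso$q_norm, tolerance = 1e-9)
  expect_equal(back$molar_ratio, iso$molar_ratio, tolerance = 1e-9)
})
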