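# Chelator speciation: apparent affinities, the coupled Ca/Mg/EGTA/fura-2
# solve, and its conservation properties.

test_that("apparent EGTA affinity is in the physiological range and falls with pH", {
  kd72 <- apparent_kd("EGTA", pH = 7.2, temperature_C = 22, ionic_strength = 0.15)
  expect_gt(kd72, 0.1)
  expect_lt(kd72, 0.3)
  # regression value pinned from the full speciation solve with the shipped
  # constants table
  expect_equal(kd72, 0.1632, tolerance = 1e-3)

  kd85 <- apparent_kd("EGTA", pH = 8.5, temperature_C = 22, ionic_strength = 0.15)
  expect_lt(kd85, kd72)
  # strictly decreasing across a pH grid
  grid <- vapply(seq(6, 9, by = 0.25), function(ph) {
    apparent_kd("EGTA", ph, 22, 0.15)
  }, numeric(1))
  expect_true(all(diff(grid) < 0))

  kdf <- apparent_kd("fura-2", pH = 7.2, temperature_C = 22, ionic_strength = 0.15)
  expect_true(is.finite(kdf) && kdf > 0)
  expect_lt(kdf, 1) # near its absolute sub-micromolar affinity, weak protonation
  expect_error(apparent_kd("BAPTA", 7.2), class = "cabuffer_unsupported_ligand")
})

test_that("the defined-Ca2+ recipe yields ~0.35 uM free Ca2+", {
  sp <- solve_free_ca(r_def_recipe())
  expect_equal(sp$free_ca_uM, 0.35, tolerance = 0.05 / 0.35)
  expect_lt(sp$residual_rel, 1e-9)
})

test_that("chelator-free and calcium-free limits behave", {
  r_min <- solution_composition(
    c(KCl = 129.5, KOH = 13, NaCl = 15, MgCl2 = 1, HEPES = 5,
      EGTA = 4, "fura-2" = 0.05), pH = 7.2)
  expect_lt(solve_free_ca(r_min)$free_ca_uM, 1e-3) # < 1 nM: no Ca source

  r_max <- solution_composition(
    c(KCl = 140, KOH = 2.5, NaCl = 15, MgCl2 = 1, HEPES = 5,
      CaCl2 = 10, "fura-2" = 0.05), pH = 7.2)
  sp <- solve_free_ca(r_max)
  expect_gt(sp$free_ca_uM, 10000 - 50) # 10 mM minus at most the dye
  expect_lte(sp$free_ca_uM, 10000)
})

test_that("mass balance and monotonicity hold across a recipe grid", {
  for (ca_mM in c(0.5, 2, 3.5)) {
    for (egta_mM in c(1, 4)) {
      sol <- solution_composition(
        c(KCl = 130, MgCl2 = 1, HEPES = 5, EGTA = egta_mM, CaCl2 = ca_mM),
        pH = 7.2)
      sp <- solve_free_ca(sol)
      expect_lt(sp$residual_rel, 1e-9)
      expect_true(all(unlist(sp$species[c("free_mM", "protonated_mM",
                                          "ca_bound_mM", "mg_bound_mM")]) >= 0))
    }
  }
  free_over_ca <- vapply(c(0.5, 1.5, 2.5, 3.5), function(ca) {
    solve_free_ca(solution_composition(
      c(KCl = 130, HEPES = 5, EGTA = 4, CaCl2 = ca), pH = 7.2))$free_ca_uM
  }, numeric(1))
  expect_true(all(diff(free_over_ca) > 0))
  free_over_egta <- vapply(c(3, 4, 6, 8), function(eg) {
    solve_free_ca(solution_composition(
      c(KCl = 130, HEPES = 5, EGTA = eg, CaCl2 = 2.7), pH = 7.2))$free_ca_uM
  }, numeric(1))
  expect_true(all(diff(free_over_egta) < 0))
})

test_that("single-chelator solve matches the closed-form quadratic", {
  # one-site binding with the apparent constant: Ca_f solves
  # Ca_f^2 + (L - Ca_T + Kd) Ca_f - Kd Ca_T = 0
  sol <- solution_composition(c(KCl = 130, HEPES = 5, EGTA = 4, CaCl2 = 2.7),
                              pH = 7.2)
  sp <- solve_free_ca(sol)
  kd <- sp$species$kd_app_uM * 1e-6
  L <- 4e-3; caT <- 2.7e-3
  b <- L - caT + kd
  ca_quad <- (-b + sqrt(b^2 + 4 * kd * caT)) / 2
  expect_equal(sp$free_ca_uM, ca_quad * 1e6, tolerance = 1e-6)
})

test_that("EGTA purity scales the chelator total", {
  sol <- solution_composition(c(KCl = 130, HEPES = 5, EGTA = 4, CaCl2 = 2.7),
                              pH = 7.2)
  full <- solve_free_ca(sol, purity = 1.0)
  short <- solve_free_ca(sol, purity = 0.95)
  expect_gt(short$free_ca_uM, full$free_ca_uM) # less chelator -> more free Ca
  expect_error(solve_free_ca(sol, purity = 1.2), class = "cabuffer_validation_error")
})

test_that("recipes load from YAML and negative totals are rejected", {
  path <- system.file("extdata", "r_def.yaml", package = "cabuffer")
  sol <- read_solution_recipe(path)
  expect_s3_class(sol, "solution_composition")
  expect_equal(solve_free_ca(sol)$free_ca_uM, solve_free_ca(r_def_recipe())$free_ca_uM)
  expect_error(solution_composition(c(KCl = -1), pH = 7.2),
               class = "cabuffer_validation_error")
})
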