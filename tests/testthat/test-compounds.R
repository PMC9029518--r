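test_that("mean logP matches the tabulated one-decimal values for all compounds", {
  lp <- logp_average(compounds_tbl)
  expect_equal(round_half_up(lp$logp_av, 1)[match(names(printed_logp_av), lp$name)],
               unname(printed_logp_av), ignore_attr = TRUE)
  # full-precision spot checks
  expect_equal(logp_average(c(5.84, 4.97, 4.54, 4.86, 4.7)), 4.982)
  expect_equal(logp_average(c(3.20, 3.15, 1.47, 4.04, 2.5)), 2.872)
  expect_equal(logp_average(3.7), 3.7)
  expect_error(logp_average(numeric(0)), class = "nanoprecip_input_error")
})

test_that("ionized percentage follows Henderson-Hasselbalch for every acid/base class", {
  expect_equal(alpha_percent(9.4, 9.4), 50)
  expect_equal(alpha_percent(10.9788, 9.4), 2.569, tolerance = 1e-3)
  expect_equal(alpha_percent(10.9788, 7.66), 0.0480, tolerance = 1e-2)
  # weak acid mirrors the base; neutral is zero by convention
  expect_equal(alpha_percent(7.2, 2.98, "weak_acid"),
               100 / (1 + 10^(2.98 - 7.2)))
  expect_equal(alpha_percent(7, 8, "neutral"), 0)
})

test_that("ionized and neutral fractions are complementary and monotone in pH", {
  ph <- seq(0, 14, by = 0.25)
  a <- alpha_percent(ph, 9.4)
  expect_equal(a + (100 - a), rep(100, length(ph)))
  expect_true(all(diff(a) < 0))           # weak base: strictly decreasing
  expect_true(all(a > 0 & a < 100))
  ac <- alpha_percent(ph, 2.98, "weak_acid")
  expect_true(all(diff(ac) > 0))
})

test_that("pH-dependent solubility reproduces the weak-base relation and its limits", {
  expect_equal(solubility_at_ph(11, 3.5e-5, 9.4), 3.5e-5 * (1 + 10^(-1.6)))
  expect_equal(signif_half_up(solubility_at_ph(11, 3.5e-5, 9.4), 2), 3.6e-5)
  expect_equal(solubility_at_ph(9.4, 3.5e-5, 9.4), 7e-5)   # pH = pKa doubles
  expect_equal(solubility_at_ph(1e6, 3.5e-5, 9.4), 3.5e-5) # free-base limit
  # monotone decreasing in pH, never below the intrinsic value
  ph <- seq(2, 13, by = 0.5)
  cs <- solubility_at_ph(ph, 3.5e-5, 9.4)
  expect_true(all(diff(cs) < 0))
  expect_true(all(cs >= 3.5e-5))
})

test_that("zeta-potential stability classification uses the 30 mV magnitude rule", {
  expect_equal(as.character(classify_colloidal_stability(c(45.3, -44.1, 0, 1.0, 15.6, -22.8))),
               c("stable", "stable", "unstable", "unstable", "unstable", "unstable"))
  expect_equal(as.character(classify_colloidal_stability(c(-30.001, 30.001))),
               c("stable", "stable"))
})

test_that("effective interfacial tension drops linearly to the CMC plateau", {
  expect_equal(effective_interfacial_tension(0, 0.02, 0.1, 0.036), 0.02)
  expect_equal(effective_interfacial_tension(0.01, 0.02, 0.1, 0.036), 0.019)
  # at and above CMC the plateau value holds
  plateau <- 0.02 - 0.1 * 0.036
  expect_equal(effective_interfacial_tension(0.036, 0.02, 0.1, 0.036), plateau)
  expect_equal(effective_interfacial_tension(5, 0.02, 0.1, 0.036), plateau)
  # clamped at the floor, never non-positive
  expect_equal(effective_interfacial_tension(0.03, 0.02, 1, 0.036, floor = 1e-4), 1e-4)
  expect_error(effective_interfacial_tension(-1, 0.02, 0.1, 0.036),
               class = "nanoprecip_input_error")
})

test_that("compound table validation enforces the physical invariants", {
  expect_error(compound_table("X", "weak_base", 9, list(numeric(0)), 1e-5,
                              molecular_volume = 1e-28),
               class = "nanoprecip_input_error")
  expect_error(compound_table("X", "weak_base", 9, list(1), -1e-5,
                              molecular_volume = 1e-28),
               class = "nanoprecip_input_error")
  expect_error(compound_table("X", "weak_base", 15, list(1), 1e-5,
                              molecular_volume = 1e-28),
               class = "nanoprecip_input_error")
  expect_error(compound_table("X", "weak_base", 9, list(1), 1e-5,
                              molecular_volume = 1e-28, surface_active = TRUE),
               class = "nanoprecip_input_error")
})

test_that("compound CSV round-trips through read/write", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_compounds(compounds_tbl, path)
  back <- read_compounds(path)
  expect_equal(back$logp_values, compounds_tbl$logp_values)
  expect_equal(back$free_base_solubility, compounds_tbl$free_base_solubility)
  expect_equal(back$name, compounds_tbl$name)
})
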