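test_that("a fixed seed makes runs identical and zero portions yield no records", {
  r1 <- simulate_protocol(fast_config(seed = 11))
  r2 <- simulate_protocol(fast_config(seed = 11))
  expect_identical(r1, r2)
  r3 <- simulate_protocol(fast_config(seed = 12))
  expect_false(identical(r1$dh_nm, r3$dh_nm))
  empty <- simulate_protocol(fast_config(solvent_volume_ml = 0))
  expect_equal(nrow(empty), 0)
})

test_that("records carry one row per portion with positive sizes", {
  r <- simulate_protocol(fast_config(seed = 3))
  expect_equal(r$portion, 1:10)
  expect_true(all(is.finite(r$dh_nm) & r$dh_nm > 0))
  expect_true(all(diff(r$c0_mM) > 0))
})

test_that("solute mass is conserved at every step of every run", {
  recs <- simulate_study(study_sim_configs(seed = 17))
  rel_err <- with(recs, abs(dissolved_mol + particulate_mol - added_mol) /
                          added_mol)
  expect_lt(max(rel_err), 1e-9)
})

test_that("aggregation conserves particulate volume and reduces particle count", {
  set.seed(42)
  for (i in 1:25) {
    nb <- sample(1:12, 1)
    d <- sort(10^stats::runif(nb, -9, -7))
    N <- 10^stats::runif(nb, 8, 16)
    events <- stats::runif(1, 0, 0.45 * sum(N))
    out <- nanoprecip:::.aggregate_step(d, N, events)
    expect_equal(sum(out$N * out$d^3), sum(N * d^3), tolerance = 1e-12)
    if (events > 0) expect_lt(sum(out$N), sum(N))
    expect_true(all(out$N > 0))
  }
})

test_that("bin consolidation preserves count and volume while capping bin number", {
  set.seed(7)
  d <- 10^stats::runif(100, -9, -6)
  N <- 10^stats::runif(100, 5, 15)
  out <- nanoprecip:::.consolidate_bins(d, N, 40)
  expect_lte(length(out$d), 40)
  expect_equal(sum(out$N), sum(N), tolerance = 1e-12)
  expect_equal(sum(out$N * out$d^3), sum(N * d^3), tolerance = 1e-12)
})

test_that("the DLS report is the d^6-weighted mean diameter", {
  d <- c(1e-7, 3e-7)
  N <- c(1e10, 1e4)
  expect_equal(nanoprecip:::.intensity_mean_d(d, N),
               sum(N * d^6) / sum(N * d^5))
  # equal counts: intensity mean sits above the arithmetic mean
  expect_gt(nanoprecip:::.intensity_mean_d(c(1e-7, 3e-7), c(1, 1)), 2e-7)
})

test_that("mechanistic monotonicities hold with noise disabled", {
  # higher interfacial tension (via the logP mapping) -> larger final size
  base <- simulate_protocol(fast_config(noise_sigma = 0, seed = 5))
  hi <- simulate_protocol(fast_config(noise_sigma = 0, seed = 5,
                                      gamma_logp_intercept = 0.0175))
  expect_gt(hi$dh_nm[10], base$dh_nm[10])
  # higher solvent concentration -> higher pre-nucleation supersaturation
  tr_lo <- c0_trajectory(ami_row, 39.85, 200, naoh_mM = 1)
  tr_hi <- c0_trajectory(ami_row, 79.7, 200, naoh_mM = 1)
  expect_true(all(tr_hi$beta > tr_lo$beta))
  # larger antisolvent excess (1:10 -> 1:20) lowers the cosolvent boost of C*
  tr_1to10 <- c0_trajectory(ami_row, 79.7, 100, naoh_mM = 1)
  tr_1to20 <- c0_trajectory(ami_row, 79.7, 200, naoh_mM = 1)
  expect_lt(max(tr_1to20$phi), max(tr_1to10$phi))
  expect_lt(tr_1to20$c_star_M[10] / solubility_at_ph(tr_1to20$ph[10], 3.5e-5, 9.4),
            tr_1to10$c_star_M[10] / solubility_at_ph(tr_1to10$ph[10], 3.5e-5, 9.4))
})

test_that("simulated sizes rise with concentration in the way DLS series do", {
  # noise off: every series ends above where it starts and the trend is
  # strongly increasing; transient dips can occur while a freshly
  # nucleated small mode grows into intensity dominance, as in real
  # bimodal DLS records
  recs <- simulate_study(study_sim_configs(seed = 23, noise_sigma = 0))
  trend <- recs |>
    dplyr::group_by(variant, protocol) |>
    dplyr::summarise(
      rises = dh_nm[dplyr::n()] > dh_nm[1],
      rho = suppressWarnings(stats::cor(portion, dh_nm, method = "spearman")),
      .groups = "drop"
    )
  expect_true(all(trend$rises))
  expect_gt(stats::median(trend$rho), 0.9)
})

test_that("study-level simulation rejects bad inputs and keeps run identity", {
  expect_error(simulate_study(list()), class = "nanoprecip_input_error")
  cfg <- fast_config()
  expect_error(simulate_study(list(cfg, cfg)), class = "nanoprecip_input_error")
  one <- simulate_study(list(cfg))
  expect_identical(one, simulate_protocol(cfg))
})

test_that("the gamma(logP) mapping must stay positive", {
  expect_error(fast_config(gamma_logp_intercept = -1),
               class = "nanoprecip_config_error")
})
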