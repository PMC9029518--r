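series_fixture <- tibble::tibble(
  compound = "AMI", variant = "AMIa", protocol = "No. 1", replicate = 1L,
  c0_mM = c(0.4, 0.8, 1.2, 1.6, 2.0),
  dh_nm = c(216, 250, 270, 301, 313)
)

test_that("final size is the diameter at maximal concentration, order-invariant", {
  expect_equal(extract_dhf(series_fixture)$dhf_nm, 313)
  shuffled <- series_fixture[c(3, 5, 1, 4, 2), ]
  expect_equal(extract_dhf(shuffled)$dhf_nm, 313)
  one <- series_fixture[3, ]
  expect_equal(extract_dhf(one)$dhf_nm, 270)
  # ties on c0 break toward the later record
  tied <- series_fixture
  tied$c0_mM[5] <- tied$c0_mM[4]
  expect_equal(extract_dhf(tied)$dhf_nm, 313)
  expect_error(extract_dhf(series_fixture[0, ]), class = "nanoprecip_input_error")
  expect_error(extract_dhf(dplyr::select(series_fixture, -dh_nm)),
               class = "nanoprecip_schema_error")
})

test_that("per-compound averages pool variants of the same drug", {
  expect_equal(dhf_average(c(100, 200)), 150)
  expect_error(dhf_average(numeric(0)), class = "nanoprecip_input_error")
  # CUR upper bounds of the measured ranges, used as a DHf proxy
  expect_equal(dhf_average(c(152, 159, 168, 157, 168)), 160.8)
  tbl <- tibble::tibble(
    compound = c(rep("AMI", 10), rep("CUR", 5)),
    variant = c(rep("AMIa", 5), rep("AMIb", 5), rep("CUR", 5)),
    protocol = rep(paste("No.", 1:5), 3),
    dhf_nm = c(1:10 * 10, rep(100, 5))
  )
  pooled <- dhf_average(tbl, combine_variants = TRUE)
  expect_equal(nrow(pooled), 2)
  expect_equal(pooled$dhf_av_nm[pooled$compound == "AMI"], mean(1:10 * 10))
  expect_equal(pooled$n[pooled$compound == "AMI"], 10)
  unpooled <- dhf_average(tbl, combine_variants = FALSE)
  expect_equal(nrow(unpooled), 3)
})

test_that("the size-logP fit agrees with the normal-equations oracle", {
  set.seed(99)
  for (i in 1:10) {
    x <- stats::runif(6, 2, 6)
    y <- 50 + 80 * x + stats::rnorm(6, 0, 30)
    f <- fit_size_vs_logp(tibble::tibble(logp_av = x, dhf_av_nm = y))
    o <- ols_oracle(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-10)
  }
})

test_that("R-squared is invariant under affine rescaling and exact for collinear data", {
  pts <- tibble::tibble(logp_av = c(2, 3, 4.5, 5), dhf_av_nm = c(150, 260, 310, 470))
  f1 <- fit_size_vs_logp(pts)
  f2 <- fit_size_vs_logp(dplyr::mutate(pts, logp_av = 3 * logp_av - 1,
                                       dhf_av_nm = 0.1 * dhf_av_nm + 7))
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  col <- tibble::tibble(logp_av = 1:4, dhf_av_nm = 10 + 5 * (1:4))
  expect_equal(fit_size_vs_logp(col)$r_squared, 1)
  expect_error(fit_size_vs_logp(tibble::tibble(logp_av = rep(3, 4),
                                               dhf_av_nm = 1:4)),
               class = "nanoprecip_degenerate_error")
  expect_error(fit_size_vs_logp(pts[1:2, ]), class = "nanoprecip_input_error")
})

test_that("tidy and glance expose the fit in broom form", {
  pts <- tibble::tibble(logp_av = c(2, 3, 4.5, 5), dhf_av_nm = c(150, 260, 310, 470))
  f <- fit_size_vs_logp(pts)
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "logp_av"))
  expect_equal(td$estimate[2], f$slope)
  gl <- glance(f)
  expect_equal(gl$r.squared, f$r_squared)
  expect_equal(gl$nobs, 4)
})

test_that("proxy final sizes from the measured upper bounds give a positive logP slope", {
  ranges <- measured_dh_ranges()
  ranges$compound <- sub("[ab]$", "", ranges$variant)
  proxy <- ranges |>
    dplyr::group_by(compound) |>
    dplyr::summarise(dhf_av_nm = mean(dh_max_nm), .groups = "drop")
  lp <- logp_average(compounds_tbl) |>
    dplyr::select(compound = name, logp_av)
  pts <- dplyr::inner_join(proxy, lp, by = "compound")
  f <- fit_size_vs_logp(pts)
  expect_gt(f$slope, 0)
  o <- ols_oracle(pts$logp_av, pts$dhf_av_nm)
  expect_equal(f$r_squared, o$r_squared, tolerance = 1e-10)
  expect_equal(o$r_squared, 0.916703, tolerance = 1e-5)
})

test_that("the trend report assembles sizes, averages, contrasts and the fit", {
  recs <- simulate_study(study_sim_configs(seed = 31))
  rep <- trend_report(recs)
  expect_equal(nrow(rep$dhf_wide), 6)      # six variant rows
  expect_equal(nrow(rep$dhf), 30)
  expect_equal(nrow(rep$dhf_av), 5)
  expect_s3_class(rep$fit, "size_logp_fit")
  # design-matrix contrasts: one flow, two concentration, two ratio pairs
  expect_equal(sort(unique(rep$contrasts$factor)),
               c("c0_solvent", "flow_rate", "sas_ratio"))
  expect_equal(nrow(rep$contrasts), 6 * 5)
  expect_true(all(is.finite(rep$contrasts$delta_nm)))
  # pH contrast table compares the two amitriptyline variants per protocol
  expect_equal(nrow(rep$ph_contrasts), 5)
  # single-compound input: report without a global fit
  solo <- trend_report(dplyr::filter(recs, variant == "CUR"))
  expect_null(solo$fit)
  expect_equal(nrow(solo$dhf), 5)
  # missing protocols give NA contrasts, not errors
  partial <- trend_report(dplyr::filter(recs, protocol %in% c("No. 1", "No. 3")))
  expect_true(any(is.na(partial$contrasts$delta_nm)))
})
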