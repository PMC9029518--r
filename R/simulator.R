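#' Configuration for one simulated precipitation run
#'
#' Bundles everything one staged-addition simulation needs: the
#' compound constants, the protocol numbers, the classical-nucleation
#' parameters, and the generator's own knobs (gamma-from-logP mapping,
#' mixing spread, growth coefficient, measurement noise, seed).
#'
#' The interfacial tension of each compound is produced from its mean
#' logP: gamma = `gamma_logp_intercept` + `gamma_logp_slope` * (logP)av,
#' encoding the mechanism that more lipophilic solids present a higher
#' solid-solution interfacial tension and therefore nucleate more
#' slowly and end up larger. For charged surface-active compounds the
#' tension is further reduced via [effective_interfacial_tension()].
#'
#' @param compound One-row compound tibble (see
#'   [psychotropic_compounds()]).
#' @param protocol_id Protocol label, e.g. `"No. 1"`.
#' @param flow_rate_ml_min Solvent addition rate, mL/min.
#' @param c0_solvent_mM Compound concentration in the solvent solution,
#'   mM.
#' @param antisolvent_ml Antisolvent volume, mL.
#' @param naoh_mM Antisolvent NaOH concentration, mM.
#' @param variant Compound-variant label tagged onto the records
#'   (defaults to the compound name).
#' @param replicate Integer replicate id.
#' @param seed Integer seed fixing all randomness of the run.
#' @param solvent_volume_ml,portion_ml Staging volumes, mL.
#' @param temperature Temperature, K.
#' @param viscosity Medium dynamic viscosity, Pa s.
#' @param prefactor Nucleation prefactor An, 1/(m^3 s).
#' @param cosolvency_slope Decades of solubility per unit solvent
#'   fraction (see [mixture_solubility()]).
#' @param growth_coefficient Linear (diffusion-limited) growth
#'   coefficient: radial growth speed per unit dissolved excess,
#'   m/s per (mol/L).
#' @param mixing_uniformity In \[0, 1\]: 1 means perfectly uniform local
#'   supersaturation; lower values widen the lognormal spread of local
#'   beta. Higher flow rate also narrows the spread (better mixing).
#' @param beta_spread Base sigma of the local log-beta spread at
#'   `mixing_uniformity = 0` and 1 mL/min.
#' @param n_parcels Number of local-supersaturation parcels sampled per
#'   portion (their nucleation rates are averaged).
#' @param gamma_logp_intercept,gamma_logp_slope The gamma(logP) mapping,
#'   N/m and N/m per logP unit.
#' @param surfactant_gamma_slope Tension decrease per unit ionized
#'   concentration for charged surface-active compounds, N/m per mol/L.
#' @param charged_threshold alpha% above which a surface-active
#'   compound counts as charged.
#' @param noise_sigma Lognormal sigma of the multiplicative
#'   measurement noise on the reported diameter (0 disables noise).
#' @param n_substeps Growth substeps per portion.
#' @param max_bins Cap on the number of diameter bins carried.
#' @param ostwald_ripening Optional qualitative post-step coarsening
#'   flag: when `TRUE`, each portion ends by redistributing the
#'   smallest bin's mass onto the largest bin.
#' @param pkw Water ionic-product exponent.
#' @return List of class `sim_config`.
#' @examples
#' ami <- dplyr::filter(psychotropic_compounds(), name == "AMI")
#' cfg <- sim_config(ami, "No. 1", flow_rate_ml_min = 1,
#'                   c0_solvent_mM = 79.7, antisolvent_ml = 200,
#'                   naoh_mM = 1, seed = 42)
#' @export
sim_config <- function(compound, protocol_id, flow_rate_ml_min,
                       c0_solvent_mM, antisolvent_ml, naoh_mM = 0,
                       variant = compound$name[[1]], replicate = 1L,
                       seed = 1L,
                       solvent_volume_ml = 10, portion_ml = 1,
                       temperature = nanoprecip_constants()$temperature,
                       viscosity = nanoprecip_constants()$viscosity,
                       prefactor = nanoprecip_constants()$prefactor,
                       cosolvency_slope = 10,
                       growth_coefficient = 1e-6,
                       mixing_uniformity = 0.5,
                       beta_spread = 0.6,
                       n_parcels = 12L,
                       gamma_logp_intercept = 0.0159,
                       gamma_logp_slope = 0.00138,
                       surfactant_gamma_slope = 5,
                       charged_threshold = 5,
                       noise_sigma = 0.05,
                       n_substeps = 5L,
                       max_bins = 40L,
                       ostwald_ripening = FALSE,
                       pkw = nanoprecip_constants()$pKw) {
  logp_av <- logp_average(compound$logp_values[[1]])
  gamma0 <- gamma_logp_intercept + gamma_logp_slope * logp_av
  if (!is.finite(gamma0) || gamma0 <= 0) {
    .np_abort("gamma(logP) mapping produced a non-positive interfacial tension.",
              class = "nanoprecip_config_error")
  }
  if (mixing_uniformity < 0 || mixing_uniformity > 1) {
    .np_abort("`mixing_uniformity` must lie in [0, 1].",
              class = "nanoprecip_config_error")
  }
  if (noise_sigma < 0) {
    .np_abort("`noise_sigma` must be >= 0.", class = "nanoprecip_config_error")
  }
  structure(list(
    compound = compound, protocol_id = protocol_id,
    flow_rate_ml_min = flow_rate_ml_min, c0_solvent_mM = c0_solvent_mM,
    antisolvent_ml = antisolvent_ml, naoh_mM = naoh_mM,
    variant = variant, replicate = as.integer(replicate),
    seed = as.integer(seed),
    solvent_volume_ml = solvent_volume_ml, portion_ml = portion_ml,
    temperature = temperature, viscosity = viscosity,
    prefactor = prefactor, cosolvency_slope = cosolvency_slope,
    growth_coefficient = growth_coefficient,
    mixing_uniformity = mixing_uniformity, beta_spread = beta_spread,
    n_parcels = as.integer(n_parcels),
    gamma_logp_intercept = gamma_logp_intercept,
    gamma_logp_slope = gamma_logp_slope,
    gamma0 = gamma0, logp_av = logp_av,
    surfactant_gamma_slope = surfactant_gamma_slope,
    charged_threshold = charged_threshold,
    noise_sigma = noise_sigma, n_substeps = as.integer(n_substeps),
    max_bins = as.integer(max_bins), ostwald_ripening = ostwald_ripening,
    pkw = pkw
  ), class = "sim_config")
}

# moles of solute locked in particles (d in m, N absolute counts)
.particulate_mol <- function(d, N, omega) {
  if (length(d) == 0L) return(0)
  sum(N * (pi / 6) * d^3) / omega / .N_A
}

# intensity-weighted (d^6-weighted) mean diameter, m
.intensity_mean_d <- function(d, N) {
  if (length(d) == 0L || sum(N) <= 0) return(NA_real_)
  sum(N * d^6) / sum(N * d^5)
}

# one Smoluchowski coagulation step: a single deterministic sweep in
# which bins, sorted by decreasing diameter, merge pairwise with their
# size neighbour (largest with largest). The event budget is split
# across pairs in proportion to their particle counts, so no pair can
# consume more than its population share. Conserves total particle
# volume exactly and strictly decreases the count when events > 0.
.aggregate_step <- function(d, N, events) {
  keep <- N > 0
  d <- d[keep]; N <- N[keep]
  if (length(d) == 0L || events <= 0) return(list(d = d, N = N))
  total <- sum(N)
  ord <- order(d, decreasing = TRUE)
  d <- d[ord]; N <- N[ord]
  if (length(d) == 1L) {
    m <- min(events, N[1] / 2)
    N[1] <- N[1] - 2 * m
    d <- c(d, 2^(1 / 3) * d[1])
    N <- c(N, m)
  } else {
    new_d <- numeric(0); new_N <- numeric(0)
    i <- 1L
    while (i < length(d)) {
      e_pair <- events * (N[i] + N[i + 1]) / total
      m <- min(e_pair, N[i], N[i + 1])
      if (m > 0) {
        new_d <- c(new_d, (d[i]^3 + d[i + 1]^3)^(1 / 3))
        new_N <- c(new_N, m)
        N[i] <- N[i] - m
        N[i + 1] <- N[i + 1] - m
      }
      i <- i + 2L
    }
    d <- c(d, new_d); N <- c(N, new_N)
  }
  keep <- N > 0
  list(d = d[keep], N = N[keep])
}

# merge closest (in log diameter) bins until at most max_bins remain;
# conserves count and particle volume
.consolidate_bins <- function(d, N, max_bins) {
  while (length(d) > max_bins) {
    ord <- order(d)
    d <- d[ord]; N <- N[ord]
    i <- which.min(diff(log(d)))
    Nm <- N[i] + N[i + 1]
    dm <- ((N[i] * d[i]^3 + N[i + 1] * d[i + 1]^3) / Nm)^(1 / 3)
    d <- c(d[-c(i, i + 1)], dm)
    N <- c(N[-c(i, i + 1)], Nm)
  }
  list(d = d, N = N)
}

#' Simulate one staged-addition precipitation run
#'
#' Generates a DLS-like size series for one (compound, protocol) pair.
#' Per 1-mL portion the model:
#' \enumerate{
#'   \item updates the mixture state (volume, solvent fraction, NaOH
#'     dilution pH, dissolved concentration, solubility, beta);
#'   \item samples local supersaturation parcels (lognormal spread,
#'     narrowed by mixing uniformity and flow rate) and averages their
#'     classical nucleation rates;
#'   \item nucleates J V dt particles of diameter 2 r*, capped by the
#'     dissolved excess;
#'   \item grows all bins linearly in (C0 - C*) until the dissolved
#'     concentration relaxes to solubility, conserving mass;
#'   \item applies one volume-conserving Smoluchowski aggregation step
#'     (pairwise merges, largest bins first);
#'   \item records the intensity-weighted (d^6-weighted) mean diameter
#'     with multiplicative lognormal noise.
#' }
#' Solute bookkeeping is exact: dissolved + particulate always equals
#' the cumulative added amount.
#'
#' @param config A [sim_config()].
#' @param audit If `TRUE` (default) the returned records carry the
#'   internal state columns (moles dissolved/particulate/added,
#'   particle count, beta, solubility, effective tension) used by the
#'   conservation checks.
#' @return Tibble with one row per portion: `compound`, `variant`,
#'   `protocol`, `replicate`, `portion`, `c0_mM`, `dh_nm` (+ audit
#'   columns).
#' @examples
#' ami <- dplyr::filter(psychotropic_compounds(), name == "AMI")
#' cfg <- sim_config(ami, "No. 1", 1, 79.7, 200, naoh_mM = 1, seed = 7)
#' simulate_protocol(cfg)
#' @export
simulate_protocol <- function(config, audit = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cmp <- config$compound
  omega <- cmp$molecular_volume[[1]]
  n_portions <- as.integer(round(config$solvent_volume_ml / config$portion_ml))
  if (n_portions == 0L) {
    return(tibble::tibble(compound = character(), variant = character(),
                          protocol = character(), replicate = integer(),
                          portion = integer(), c0_mM = numeric(),
                          dh_nm = numeric()))
  }
  dt <- config$portion_ml / config$flow_rate_ml_min * 60   # s per portion
  ks <- smoluchowski_rate_constant(config$temperature, config$viscosity)
  sigma_loc <- config$beta_spread * (1 - config$mixing_uniformity) /
    config$flow_rate_ml_min

  vol_L <- config$antisolvent_ml / 1000
  dissolved <- 0    # mol
  added <- 0        # mol
  d <- numeric(0)   # bin diameters, m
  N <- numeric(0)   # bin counts (whole dispersion)

  rows <- vector("list", n_portions)
  for (k in seq_len(n_portions)) {
    # (1) add one portion of solvent solution
    portion_mol <- (config$c0_solvent_mM / 1000) * (config$portion_ml / 1000)
    vol_L <- vol_L + config$portion_ml / 1000
    dissolved <- dissolved + portion_mol
    added <- added + portion_mol
    vol_m3 <- vol_L / 1000
    added_ml <- k * config$portion_ml
    phi <- added_ml / (config$antisolvent_ml + added_ml)
    ph <- naoh_dilution_ph(config$naoh_mM, config$antisolvent_ml, added_ml,
                           pkw = config$pkw)
    c_star <- mixture_solubility(cmp, ph, phi, config$cosolvency_slope)
    c0 <- dissolved / vol_L
    beta <- supersaturation(c0, c_star)

    # effective interfacial tension (surfactant action of the ionized form)
    alpha <- alpha_percent(ph, cmp$pka[[1]], cmp$acid_base[[1]])
    gamma <- config$gamma0
    if (isTRUE(cmp$surface_active[[1]]) && alpha >= config$charged_threshold) {
      gamma <- effective_interfacial_tension(
        alpha / 100 * c0, config$gamma0,
        config$surfactant_gamma_slope, cmp$cmc[[1]]
      )
    }
    cnt <- cnt_params(gamma, omega, config$temperature, config$prefactor)

    # (2) diffusion-limited growth toward equilibrium: condensation onto
    # the existing surface relaxes the supersaturation before any fresh
    # nucleation is drawn, as in seeded precipitation
    if (length(d) > 0L) {
      dt_sub <- dt / config$n_substeps
      for (s in seq_len(config$n_substeps)) {
        excess <- dissolved / vol_L - c_star
        if (excess <= 0) break
        dr <- config$growth_coefficient * excess * dt_sub
        dV <- pi * d^2 * dr              # per-particle volume increment
        dep_mol <- sum(N * dV) / omega / .N_A
        avail <- excess * vol_L
        if (dep_mol > avail && dep_mol > 0) {
          dV <- dV * avail / dep_mol
          dep_mol <- avail
        }
        d <- (d^3 + 6 * dV / pi)^(1 / 3)
        dissolved <- dissolved - dep_mol
      }
    }

    # (3)+(4) parcel-averaged nucleation from the relaxed residual beta
    beta_res <- supersaturation(dissolved / vol_L, c_star)
    if (beta_res > 1) {
      beta_loc <- beta_res * exp(stats::rnorm(config$n_parcels, 0, sigma_loc))
      J <- mean(nucleation_rate(cnt, pmax(beta_loc, 1e-12)))
      if (J > 0) {
        n_new <- J * vol_m3 * dt
        b_eff <- max(mean(beta_loc[beta_loc > 1]), 1 + 1e-9)
        d_new <- 2 * critical_radius(cnt, b_eff)
        new_mol <- n_new * (pi / 6) * d_new^3 / omega / .N_A
        avail <- max(0, (dissolved / vol_L - c_star) * vol_L)
        if (new_mol > avail && new_mol > 0) {
          n_new <- n_new * avail / new_mol
          new_mol <- avail
        }
        if (n_new > 0) {
          d <- c(d, d_new)
          N <- c(N, n_new)
          dissolved <- dissolved - new_mol
        }
      }
    }

    # (5) Smoluchowski aggregation
    if (length(d) > 0L) {
      np <- sum(N) / vol_m3
      events <- min(collision_rate(ks, np) * vol_m3 * dt, 0.45 * sum(N))
      agg <- .aggregate_step(d, N, events)
      d <- agg$d; N <- agg$N
    }

    # optional qualitative coarsening
    if (isTRUE(config$ostwald_ripening) && length(d) > 1L) {
      ord <- order(d)
      d <- d[ord]; N <- N[ord]
      nb <- length(d)
      vol_small <- N[1] * d[1]^3
      d[nb] <- ((N[nb] * d[nb]^3 + vol_small) / N[nb])^(1 / 3)
      d <- d[-1]; N <- N[-1]
    }

    cb <- .consolidate_bins(d, N, config$max_bins)
    d <- cb$d; N <- cb$N

    # (6) report
    dh <- .intensity_mean_d(d, N)
    noise <- if (config$noise_sigma > 0) {
      exp(stats::rnorm(1, 0, config$noise_sigma))
    } else 1
    rows[[k]] <- tibble::tibble(
      compound = cmp$name[[1]], variant = config$variant,
      protocol = config$protocol_id, replicate = config$replicate,
      portion = k,
      c0_mM = added / vol_L * 1000,   # cumulative solute concentration
      dh_nm = dh * 1e9 * noise,
      ph = ph, phi = phi, beta = beta, c_star_M = c_star,
      gamma_eff = gamma, n_particles = sum(N),
      dissolved_mol = dissolved,
      particulate_mol = .particulate_mol(d, N, omega),
      added_mol = added
    )
  }
  out <- dplyr::bind_rows(rows)
  if (!audit) {
    out <- dplyr::select(out, "compound", "variant", "protocol",
                         "replicate", "portion", "c0_mM", "dh_nm")
  }
  out
}

#' Simulate a whole study grid
#'
#' Runs [simulate_protocol()] over a list of configurations and binds
#' the records. Duplicate (variant, protocol, replicate) keys are an
#' error, since the analysis treats them as the series identity.
#'
#' @param configs List of [sim_config()] objects.
#' @param audit Passed through to [simulate_protocol()].
#' @return Tibble of concatenated records.
#' @examples
#' cfgs <- study_sim_configs(seed = 1)
#' records <- simulate_study(cfgs[1:2])
#' @export
simulate_study <- function(configs, audit = TRUE) {
  if (length(configs) == 0L) {
    .np_abort("`configs` must be non-empty.", class = "nanoprecip_input_error")
  }
  keys <- vapply(configs, function(cf)
    paste(cf$variant, cf$protocol_id, cf$replicate, sep = "\r"), "")
  if (anyDuplicated(keys)) {
    .np_abort("duplicate (variant, protocol, replicate) keys in `configs`.",
              class = "nanoprecip_input_error")
  }
  dplyr::bind_rows(lapply(configs, simulate_protocol, audit = audit))
}

#' Build the 30 simulation configurations of the study grid
#'
#' Crosses the six compound variants with the five preparation
#' protocols (see [study_grid()]) and instantiates one [sim_config()]
#' per cell, with per-run seeds derived deterministically from `seed`.
#'
#' @param conditions,protocols,compounds Study tables; defaults are the
#'   packaged ones.
#' @param seed Base integer seed.
#' @param replicate Replicate id tagged onto every run.
#' @param ... Overrides passed to every [sim_config()] (e.g.
#'   `noise_sigma = 0`).
#' @return List of `sim_config` objects.
#' @examples
#' length(study_sim_configs(seed = 1))   # 30
#' @export
study_sim_configs <- function(conditions = study_conditions(),
                              protocols = study_protocols(),
                              compounds = psychotropic_compounds(),
                              seed = 1L, replicate = 1L, ...) {
  grid <- study_grid(conditions, protocols)
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cmp <- dplyr::filter(compounds, .data$name == g$compound)
    sim_config(
      compound = cmp, protocol_id = g$protocol,
      flow_rate_ml_min = g$flow_rate_ml_min,
      c0_solvent_mM = g$c0_solvent_mM,
      antisolvent_ml = g$antisolvent_ml,
      naoh_mM = g$antisolvent_naoh_mM,
      variant = g$variant, replicate = replicate,
      seed = (seed * 1009L + i * 9973L) %% 2147483647L,
      ...
    )
  })
}
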