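#' Study preparation protocols and conditions
#'
#' `study_protocols()` returns the five preparation protocols of the
#' precipitation study (flow rate, solvent-concentration mode, solvent:
#' antisolvent ratio). `study_conditions()` returns the per-compound
#' chemistry: the saturation concentration of the solvent solution and
#' the NaOH antisolvent for each compound variant (AMIa and AMIb are
#' the same drug precipitated into 0.25 mM and 1.0 mM NaOH).
#' `measured_dh_ranges()` returns the measured hydrodynamic-diameter
#' ranges per (variant, protocol) — wet-lab fixture data used only as
#' proxies in the size-versus-logP analysis, never as model targets.
#'
#' @return Tibbles read from the packaged CSV fixtures.
#' @examples
#' study_protocols()
#' study_conditions()
#' @export
study_protocols <- function() {
  read_protocols(system.file("extdata", "protocols.csv",
                             package = "nanoprecip", mustWork = TRUE))
}

#' @rdname study_protocols
#' @export
study_conditions <- function() {
  readr::read_csv(system.file("extdata", "study_conditions.csv",
                              package = "nanoprecip", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' @rdname study_protocols
#' @export
measured_dh_ranges <- function() {
  readr::read_csv(system.file("extdata", "dh_ranges.csv",
                              package = "nanoprecip", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' Read a protocol table
#'
#' @param path CSV with columns `protocol, flow_rate_ml_min, c0_mode,
#'   sas_ratio` (`c0_mode` is `Cs` or `half_Cs`; `sas_ratio` is a string
#'   such as `"1:20"`).
#' @return Validated tibble.
#' @export
read_protocols <- function(path) {
  # sas_ratio must stay character: readr would guess "1:20" to be a time
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(sas_ratio = "c",
                                                 .default = readr::col_guess()))
  required <- c("protocol", "flow_rate_ml_min", "c0_mode", "sas_ratio")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    .np_abort(paste0("protocol table is missing column(s): ",
                     paste(missing, collapse = ", ")),
              class = "nanoprecip_schema_error")
  }
  if (!all(tbl$c0_mode %in% c("Cs", "half_Cs"))) {
    .np_abort("`c0_mode` must be 'Cs' or 'half_Cs'.",
              class = "nanoprecip_schema_error")
  }
  sas_to_volume_ml(tbl$sas_ratio) # validates the ratio strings
  tibble::as_tibble(tbl)
}

#' Antisolvent volume implied by a solvent:antisolvent ratio
#'
#' With the standard 10 mL solvent charge, a 1:20 ratio means 200 mL of
#' antisolvent and 1:10 means 100 mL.
#'
#' @param sas_ratio Character ratio like `"1:20"` (vectorized).
#' @param solvent_volume_ml Total solvent volume, mL (default 10).
#' @return Antisolvent volume, mL.
#' @examples
#' sas_to_volume_ml(c("1:20", "1:10"))
#' @export
sas_to_volume_ml <- function(sas_ratio, solvent_volume_ml = 10) {
  parts <- strsplit(as.character(sas_ratio), ":", fixed = TRUE)
  num <- vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p))
    if (length(v) != 2L || any(!is.finite(v)) || any(v <= 0)) {
      c(NA_real_, NA_real_)
    } else v
  }, numeric(2))
  if (anyNA(num)) {
    .np_abort("`sas_ratio` must look like '1:20'.",
              class = "nanoprecip_input_error")
  }
  solvent_volume_ml * num[2, ] / num[1, ]
}

#' pH of a diluted NaOH antisolvent
#'
#' The antisolvent is a dilute strong base; adding solvent portions
#' contributes volume but no acid or base, so the hydroxide
#' concentration is diluted in proportion:
#' \[OH-\] = c_NaOH * V_antisolvent / (V_antisolvent + V_added),
#' and pH = pKw + log10\[OH-\]. Full dissociation is assumed, and the
#' organic solvent is treated as acid-base inert. A zero NaOH
#' concentration returns neutral pH 7.
#'
#' @param naoh_mM NaOH concentration of the undiluted antisolvent, mM.
#' @param antisolvent_ml Antisolvent volume, mL.
#' @param added_ml Cumulative solvent volume added, mL (default 0).
#' @param pkw Water ionic-product exponent (default 14.0, 25 degC).
#' @return pH (vectorized over any argument).
#' @examples
#' naoh_dilution_ph(0.25, 200)        # 10.398 -- nominal "pH 10.4"
#' naoh_dilution_ph(1.0, 200)         # 11.0
#' naoh_dilution_ph(1.0, 200, 10)     # 10.9788 -- end-of-addition pH
#' @export
naoh_dilution_ph <- function(naoh_mM, antisolvent_ml, added_ml = 0,
                             pkw = nanoprecip_constants()$pKw) {
  if (any(antisolvent_ml <= 0) || any(added_ml < 0)) {
    .np_abort("volumes must be positive.", class = "nanoprecip_input_error")
  }
  oh <- (naoh_mM / 1000) * antisolvent_ml / (antisolvent_ml + added_ml)
  ifelse(oh > 0, pkw + log10(oh), 7.0)
}

#' Mixture solubility with log-linear cosolvency
#'
#' Solubility of the compound in the solvent + antisolvent mixture:
#' the aqueous pH-dependent solubility, raised log-linearly with the
#' solvent volume fraction phi (the standard log-linear cosolvency
#' model): log10 C* = log10 C*_w(pH) + slope * phi. A slope of zero
#' disables the cosolvent effect.
#'
#' @param compound One-row compound tibble (or a list with
#'   `free_base_solubility`, `pka`, `acid_base`).
#' @param ph Mixture pH.
#' @param phi Solvent volume fraction, in \[0, 1\].
#' @param cosolvency_slope Decades of solubility gained per unit phi
#'   (>= 0). Default 10.
#' @return Solubility C*, mol/L.
#' @examples
#' ami <- dplyr::filter(psychotropic_compounds(), name == "AMI")
#' mixture_solubility(ami, ph = 11, phi = 0.04762, cosolvency_slope = 20)
#' @export
mixture_solubility <- function(compound, ph, phi, cosolvency_slope = 10) {
  if (any(cosolvency_slope < 0)) {
    .np_abort("`cosolvency_slope` must be >= 0.",
              class = "nanoprecip_input_error")
  }
  cw <- solubility_at_ph(ph, compound$free_base_solubility[[1]],
                         compound$pka[[1]], compound$acid_base[[1]])
  cw * 10^(cosolvency_slope * phi)
}

#' Supersaturation ratio
#'
#' beta = C0 / C*: the dissolved concentration over the solubility at
#' the current mixture condition. beta = 1 at equilibrium; beta < 1
#' means the solution is undersaturated and nothing precipitates.
#'
#' @param c0 Dissolved compound concentration, mol/L (>= 0).
#' @param c_star Solubility at the same condition, mol/L (> 0).
#' @return beta (vectorized).
#' @examples
#' supersaturation(3.795e-3, 3.6e-5)   # about 105
#' @export
supersaturation <- function(c0, c_star) {
  if (any(c_star <= 0)) {
    .np_abort("`c_star` must be > 0.", class = "nanoprecip_input_error")
  }
  if (any(c0 < 0)) {
    .np_abort("`c0` must be >= 0.", class = "nanoprecip_input_error")
  }
  c0 / c_star
}

#' Staged-addition concentration trajectory
#'
#' Tracks the mixture through the portionwise addition of the solvent
#' solution into the antisolvent: after k portions of `portion_ml`,
#' the (pre-precipitation) dissolved concentration is
#' C0 = C0solvent * k v / (V_as + k v), the solvent fraction is
#' phi = k v / (V_as + k v), the pH follows NaOH dilution, and
#' beta = C0 / C*(pH, phi).
#'
#' @param compound One-row compound tibble.
#' @param c0_solvent_mM Compound concentration in the solvent solution,
#'   mM.
#' @param antisolvent_ml Antisolvent volume, mL.
#' @param naoh_mM Antisolvent NaOH concentration, mM (0 for water).
#' @param solvent_volume_ml Total solvent volume to add, mL (default 10).
#' @param portion_ml Portion size, mL (default 1; must divide the total).
#' @param cosolvency_slope See [mixture_solubility()].
#' @param pkw Water ionic product exponent.
#' @return Tibble with one row per portion: `portion`, `added_ml`,
#'   `total_ml`, `phi`, `ph`, `c0_M`, `c_star_M`, `beta`.
#' @examples
#' ami <- dplyr::filter(psychotropic_compounds(), name == "AMI")
#' c0_trajectory(ami, c0_solvent_mM = 79.7, antisolvent_ml = 200,
#'               naoh_mM = 1.0)
#' @export
c0_trajectory <- function(compound, c0_solvent_mM, antisolvent_ml,
                          naoh_mM = 0, solvent_volume_ml = 10,
                          portion_ml = 1, cosolvency_slope = 10,
                          pkw = nanoprecip_constants()$pKw) {
  .assert_scalar_num(c0_solvent_mM, "c0_solvent_mM", positive = TRUE)
  .assert_scalar_num(antisolvent_ml, "antisolvent_ml", positive = TRUE)
  n <- solvent_volume_ml / portion_ml
  if (abs(n - round(n)) > 1e-9) {
    .np_abort("`portion_ml` must divide `solvent_volume_ml`.",
              class = "nanoprecip_input_error")
  }
  n <- as.integer(round(n))
  k <- seq_len(n)
  added <- k * portion_ml
  total <- antisolvent_ml + added
  phi <- added / total
  ph <- naoh_dilution_ph(naoh_mM, antisolvent_ml, added, pkw = pkw)
  c0 <- (c0_solvent_mM / 1000) * added / total
  c_star <- mixture_solubility(compound, ph, phi, cosolvency_slope)
  tibble::tibble(
    portion = k, added_ml = added, total_ml = total, phi = phi, ph = ph,
    c0_M = c0, c_star_M = c_star, beta = supersaturation(c0, c_star)
  )
}

#' Mean ionized percentage over the preparation protocols
#'
#' Reproduces the study's charge estimates: for each compound variant
#' the end-of-addition pH of its antisolvent is computed per protocol
#' (NaOH diluted by the full 10 mL of added solvent; 200 mL antisolvent
#' for a 1:20 ratio, 100 mL for 1:10), the ionized percentage follows
#' from the Henderson-Hasselbalch relation, and the five protocol
#' values are averaged.
#'
#' @param conditions Tibble as [study_conditions()].
#' @param protocols Tibble as [study_protocols()].
#' @param compounds Compound tibble as [psychotropic_compounds()].
#' @param solvent_volume_ml Added solvent volume, mL (default 10).
#' @param charged_threshold Surface-activity alpha% threshold
#'   (default 5).
#' @return Tibble with one row per variant: `variant`, `compound`,
#'   `alpha_mean`, `alpha_sd`, `charged`, plus a `by_protocol`
#'   list-column of per-protocol values.
#' @examples
#' alpha_study()
#' @export
alpha_study <- function(conditions = study_conditions(),
                        protocols = study_protocols(),
                        compounds = psychotropic_compounds(),
                        solvent_volume_ml = 10,
                        charged_threshold = 5) {
  purrr::pmap_dfr(conditions, function(variant, compound,
                                       antisolvent_naoh_mM, ...) {
    row <- dplyr::filter(compounds, .data$name == compound)
    naoh <- antisolvent_naoh_mM
    per <- purrr::pmap_dbl(protocols, function(protocol, flow_rate_ml_min,
                                               c0_mode, sas_ratio) {
      vas <- sas_to_volume_ml(sas_ratio, solvent_volume_ml)
      ph_end <- naoh_dilution_ph(naoh, vas, solvent_volume_ml)
      alpha_percent(ph_end, row$pka, row$acid_base)
    })
    tibble::tibble(
      variant = variant,
      compound = compound,
      alpha_mean = mean(per),
      alpha_sd = stats::sd(per),
      charged = row$surface_active && mean(per) >= charged_threshold,
      by_protocol = list(stats::setNames(per, protocols$protocol))
    )
  })
}

#' Per-(variant, protocol) preparation grid
#'
#' Crosses the study conditions with the protocol table and resolves
#' the concrete numbers each run needs: the actual solvent
#' concentration (saturation Cs or half of it) and the antisolvent
#' volume implied by the solvent:antisolvent ratio.
#'
#' @inheritParams alpha_study
#' @return Tibble with one row per (variant, protocol).
#' @examples
#' study_grid()
#' @export
study_grid <- function(conditions = study_conditions(),
                       protocols = study_protocols(),
                       solvent_volume_ml = 10) {
  grid <- tidyr::crossing(conditions, protocols)
  dplyr::mutate(
    grid,
    c0_solvent_mM = ifelse(.data$c0_mode == "Cs",
                           .data$c0_saturation_mM,
                           .data$c0_saturation_mM / 2),
    antisolvent_ml = sas_to_volume_ml(.data$sas_ratio, solvent_volume_ml),
    solvent_volume_ml = solvent_volume_ml
  )
}
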