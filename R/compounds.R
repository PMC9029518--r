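#' Build a compound constants table
#'
#' Assembles one row of immutable physical-chemistry constants per drug
#' compound. Most verbs in the package take this table (or a filtered
#' one-row slice of it) as their first argument.
#'
#' @param name Character, short compound identifier (e.g. `"AMI"`).
#' @param acid_base One of `"weak_base"`, `"weak_acid"`, `"neutral"`:
#'   which Henderson-Hasselbalch branch applies.
#' @param pka Acid dissociation exponent, in (0, 14).
#' @param logp_values List of numeric vectors: the literature octanol-water
#'   partition coefficients for each compound. Must be non-empty.
#' @param free_base_solubility Intrinsic (un-ionized form) water solubility,
#'   mol/L. Must be > 0.
#' @param cmc Critical micelle concentration, mol/L, or `NA` when the
#'   compound is not surface active.
#' @param molecular_volume Volume of one molecule in the solid nucleus,
#'   m^3.
#' @param surface_active Logical: does the ionized form act as a
#'   surfactant? Requires a finite `cmc`.
#' @param aggregation_number Micelle aggregation number (metadata only,
#'   unused by any computation). Default `NA`.
#' @return A tibble with one row per compound and a `logp_values`
#'   list-column.
#' @examples
#' compound_table(
#'   name = "AMI", acid_base = "weak_base", pka = 9.4,
#'   logp_values = list(c(5.84, 4.97, 4.54, 4.86, 4.7)),
#'   free_base_solubility = 3.5e-5, cmc = 3.6e-2,
#'   molecular_volume = 4.2e-28, surface_active = TRUE
#' )
#' @export
compound_table <- function(name, acid_base, pka, logp_values,
                           free_base_solubility, cmc = NA_real_,
                           molecular_volume, surface_active = FALSE,
                           aggregation_number = NA_real_) {
  acid_base <- match.arg(acid_base, c("weak_base", "weak_acid", "neutral"),
                         several.ok = TRUE)
  tbl <- tibble::tibble(
    name = as.character(name),
    acid_base = acid_base,
    pka = as.numeric(pka),
    logp_values = logp_values,
    free_base_solubility = as.numeric(free_base_solubility),
    cmc = as.numeric(cmc),
    molecular_volume = as.numeric(molecular_volume),
    surface_active = as.logical(surface_active),
    aggregation_number = as.numeric(aggregation_number)
  )
  validate_compounds(tbl)
}

validate_compounds <- function(tbl) {
  if (any(lengths(tbl$logp_values) == 0L)) {
    .np_abort("`logp_values` must be non-empty for every compound.",
              class = "nanoprecip_input_error")
  }
  if (any(!is.finite(tbl$free_base_solubility) | tbl$free_base_solubility <= 0)) {
    .np_abort("`free_base_solubility` must be > 0 (mol/L).",
              class = "nanoprecip_input_error")
  }
  if (any(tbl$pka <= 0 | tbl$pka >= 14)) {
    .np_abort("`pka` must lie strictly between 0 and 14.",
              class = "nanoprecip_input_error")
  }
  if (any(tbl$surface_active & !is.finite(tbl$cmc))) {
    .np_abort("surface-active compounds need a finite `cmc` (mol/L).",
              class = "nanoprecip_input_error")
  }
  if (any(!is.finite(tbl$molecular_volume) | tbl$molecular_volume <= 0)) {
    .np_abort("`molecular_volume` must be > 0 (m^3).",
              class = "nanoprecip_input_error")
  }
  tbl
}

#' The five psychotropic study compounds
#'
#' Constants table for amitriptyline hydrochloride (AMI), coumarin 6
#' (COU), curcumin (CUR), nortriptyline hydrochloride (NOR) and
#' prochlorperazine dimaleate (PRO): pKa, the literature logP lists,
#' intrinsic solubility, CMC and molecular volume, plus the measured
#' zeta potential and redispersion pH of each end dispersion
#' (wet-lab metadata carried along for stability classification).
#'
#' Only amitriptyline's intrinsic solubility (3.5e-5 M), CMC (3.6e-2 M)
#' and aggregation number (7) are experimentally constrained; the
#' intrinsic solubilities and molecular volumes of the other compounds
#' are representative literature-order values used as simulator
#' conditions, not measurements.
#'
#' @return Tibble as from [compound_table()], plus `zp_mV` and
#'   `ph_measured` columns.
#' @examples
#' psychotropic_compounds()
#' @export
psychotropic_compounds <- function() {
  path <- system.file("extdata", "compounds.csv", package = "nanoprecip",
                      mustWork = TRUE)
  read_compounds(path)
}

#' Read / write a compound constants table
#'
#' CSV interchange for [compound_table()]s. The `logp_values` list-column
#' is serialized as a semicolon-separated string.
#'
#' @param path File path of a CSV with columns `name, acid_base, pka,
#'   logp_values, free_base_solubility, cmc, molecular_volume,
#'   surface_active, aggregation_number` (extra columns are kept).
#' @return `read_compounds()`: a validated compound tibble.
#' @export
read_compounds <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("name", "acid_base", "pka", "logp_values",
                "free_base_solubility", "molecular_volume")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    .np_abort(paste0("compound table is missing column(s): ",
                     paste(missing, collapse = ", ")),
              class = "nanoprecip_schema_error")
  }
  raw$logp_values <- lapply(strsplit(as.character(raw$logp_values), ";"),
                            function(x) as.numeric(trimws(x)))
  if (!"cmc" %in% names(raw)) raw$cmc <- NA_real_
  if (!"surface_active" %in% names(raw)) raw$surface_active <- FALSE
  if (!"aggregation_number" %in% names(raw)) raw$aggregation_number <- NA_real_
  validate_compounds(tibble::as_tibble(raw))
}

#' @rdname read_compounds
#' @param compounds A compound tibble.
#' @export
write_compounds <- function(compounds, path) {
  out <- compounds
  out$logp_values <- vapply(out$logp_values, paste, "", collapse = ";")
  readr::write_csv(out, path)
  invisible(path)
}

#' Average literature logP
#'
#' The per-compound partition-coefficient summary used throughout the
#' size analysis: the arithmetic mean of the literature logP values,
#' written (logP)av. Reported tables round it to one decimal; the
#' computation keeps full precision.
#'
#' @param x A compound tibble (gains a `logp_av` column) or a bare
#'   numeric vector of logP values (returns the scalar mean).
#' @param ... Unused.
#' @return Tibble with `logp_av` appended, or a scalar.
#' @examples
#' logp_average(c(5.84, 4.97, 4.54, 4.86, 4.7))   # 4.982, reported 5.0
#' logp_average(psychotropic_compounds())
#' @export
logp_average <- function(x, ...) UseMethod("logp_average")

#' @export
logp_average.numeric <- function(x, ...) {
  if (length(x) == 0L) {
    .np_abort("logP list must be non-empty.", class = "nanoprecip_input_error")
  }
  mean(x)
}

#' @export
logp_average.data.frame <- function(x, ...) {
  dplyr::mutate(x, logp_av = vapply(.data$logp_values, logp_average, 0))
}

#' Ionized percentage from the Henderson-Hasselbalch relation
#'
#' Fraction (in percent) of molecules carrying charge at a given pH:
#' for a weak base alpha% = 100 / (1 + 10^(pH - pKa)); for a weak acid
#' the sign of the exponent flips; a neutral compound returns 0 by
#' convention.
#'
#' @param ph Solution pH (vectorized).
#' @param pka Acid dissociation exponent.
#' @param acid_base `"weak_base"` (default), `"weak_acid"` or `"neutral"`.
#' @return Ionized percentage in \[0, 100\].
#' @examples
#' alpha_percent(9.4, 9.4)            # 50: pH at pKa
#' alpha_percent(10.9788, 9.4)        # 2.569: end-dispersion pH, 1 mM NaOH
#' @export
alpha_percent <- function(ph, pka, acid_base = "weak_base") {
  acid_base <- match.arg(acid_base, c("weak_base", "weak_acid", "neutral"))
  switch(acid_base,
    weak_base = 100 / (1 + 10^(ph - pka)),
    weak_acid = 100 / (1 + 10^(pka - ph)),
    neutral   = rep(0, length(ph))
  )
}

#' Ionization state of each compound at a given pH
#'
#' Data-frame verb over [alpha_percent()]: appends the ionized
#' percentage and a surface-activity flag (`charged`) for every
#' compound row at the supplied pH. A compound counts as charged enough
#' to act as a surfactant when it is flagged `surface_active` and its
#' alpha% reaches `charged_threshold`.
#'
#' @param compounds Compound tibble.
#' @param ph Solution pH (scalar, or one value per row).
#' @param charged_threshold Minimum alpha% (default 5) at which a
#'   surface-active compound is treated as charged.
#' @return Input tibble plus `ph`, `alpha_percent`, `charged`.
#' @examples
#' ionized_fraction(psychotropic_compounds(), ph = 11)
#' @export
ionized_fraction <- function(compounds, ph, charged_threshold = 5) {
  dplyr::mutate(
    compounds,
    ph = ph,
    alpha_percent = alpha_percent_vec(.data$pka, ph, .data$acid_base),
    charged = .data$surface_active & .data$alpha_percent >= charged_threshold
  )
}

# row-wise alpha% for mixed acid/base tables
alpha_percent_vec <- function(pka, ph, acid_base) {
  mapply(function(k, p, ab) alpha_percent(p, k, ab), pka, ph, acid_base)
}

#' pH-dependent water solubility of an ionizable compound
#'
#' For a weak base B much less soluble than its salt, total solubility
#' follows CB*,w = Cf.b.*,w (1 + \[H+\]/Ka) = Cf.b.*,w (1 + 10^(pKa - pH)):
#' it never falls below the intrinsic (free-base) solubility and
#' decreases strictly with pH. The weak-acid branch mirrors it
#' (exponent pH - pKa); a neutral compound keeps its intrinsic value.
#'
#' @param ph Solution pH (vectorized).
#' @param free_base_solubility Intrinsic solubility of the un-ionized
#'   form, mol/L.
#' @inheritParams alpha_percent
#' @return Total solubility, mol/L.
#' @examples
#' solubility_at_ph(11, 3.5e-5, 9.4)    # 3.588e-5 M
#' solubility_at_ph(10.4, 3.5e-5, 9.4)  # 3.85e-5 M
#' @export
solubility_at_ph <- function(ph, free_base_solubility, pka,
                             acid_base = "weak_base") {
  acid_base <- match.arg(acid_base, c("weak_base", "weak_acid", "neutral"))
  switch(acid_base,
    weak_base = free_base_solubility * (1 + 10^(pka - ph)),
    weak_acid = free_base_solubility * (1 + 10^(ph - pka)),
    neutral   = rep(free_base_solubility, length(ph))
  )
}

#' @rdname solubility_at_ph
#' @param compounds Compound tibble; gains a `solubility` column (mol/L).
#' @export
ph_dependent_solubility <- function(compounds, ph) {
  dplyr::mutate(
    compounds,
    ph = ph,
    solubility = mapply(solubility_at_ph, ph, .data$free_base_solubility,
                        .data$pka, .data$acid_base)
  )
}

#' Colloidal stability class from zeta potential
#'
#' A dispersion is conventionally considered colloidally stable when
#' the magnitude of the particle zeta potential exceeds 30 mV, i.e.
#' electrostatic repulsion is strong enough to keep particles apart.
#'
#' @param zeta_potential_mV Zeta potential(s), mV.
#' @param threshold_mV Magnitude threshold, default 30 mV.
#' @return Factor with levels `stable`, `unstable`.
#' @examples
#' classify_colloidal_stability(c(45.3, 1.0, -44.1))
#' @export
classify_colloidal_stability <- function(zeta_potential_mV,
                                         threshold_mV = 30) {
  factor(ifelse(abs(zeta_potential_mV) > threshold_mV, "stable", "unstable"),
         levels = c("stable", "unstable"))
}

#' Effective interfacial tension of a surfactant-laden interface
#'
#' Truncated-Szyszkowski simplification of surfactant action: the
#' tension drops linearly with the ionized-surfactant concentration up
#' to the critical micelle concentration and plateaus beyond it, with a
#' positive floor so downstream nucleation formulas stay defined.
#'
#' @param ionized_concentration Concentration of the ionized
#'   (surface-active) form, mol/L. Must be >= 0.
#' @param gamma0 Bare solid-solution interfacial tension, N/m.
#' @param slope Tension decrease per unit concentration,
#'   N/m per mol/L. Must be >= 0.
#' @param cmc Critical micelle concentration, mol/L (plateau onset).
#' @param floor Lower clamp, N/m.
#' @return Effective tension, N/m.
#' @examples
#' effective_interfacial_tension(0.01, gamma0 = 0.02, slope = 0.1, cmc = 0.036)
#' @export
effective_interfacial_tension <- function(ionized_concentration, gamma0,
                                          slope, cmc,
                                          floor = nanoprecip_constants()$gamma_floor) {
  if (any(ionized_concentration < 0)) {
    .np_abort("`ionized_concentration` must be >= 0.",
              class = "nanoprecip_input_error")
  }
  .assert_scalar_num(gamma0, "gamma0", positive = TRUE)
  if (slope < 0) {
    .np_abort("`slope` must be >= 0.", class = "nanoprecip_input_error")
  }
  pmax(gamma0 - slope * pmin(ionized_concentration, cmc), floor)
}
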