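#' Read / write tidy DLS record tables
#'
#' CSV interchange for the simulator output and for user-supplied size
#' series. Concentrations are mM and diameters nm, matching how
#' preparation tables are usually reported; writing keeps only the
#' core record columns so a write-read round trip is the identity on
#' them.
#'
#' @param records Record tibble with at least `compound`, `protocol`,
#'   `c0_mM`, `dh_nm` (plus `variant`, `replicate`, `portion` when
#'   present).
#' @param path CSV file path.
#' @return `read_dls_records()`: validated tibble.
#'   `write_dls_records()`: the path, invisibly.
#' @export
write_dls_records <- function(records, path) {
  keep <- intersect(c("compound", "variant", "protocol", "replicate",
                      "portion", "c0_mM", "dh_nm"), names(records))
  readr::write_csv(dplyr::select(records, dplyr::all_of(keep)), path)
  invisible(path)
}

#' @rdname write_dls_records
#' @export
read_dls_records <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("compound", "protocol", "c0_mM", "dh_nm")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    .np_abort(paste0("record CSV is missing column(s): ",
                     paste(missing, collapse = ", ")),
              class = "nanoprecip_schema_error")
  }
  tibble::as_tibble(tbl)
}

#' Read a study configuration file
#'
#' YAML description of a simulation campaign: paths to the compound
#' and protocol tables (defaulting to the packaged ones), a seed, and
#' any [sim_config()] overrides under `simulator:`.
#'
#' @param path YAML file. Recognized top-level keys: `compounds`,
#'   `protocols`, `conditions` (CSV paths), `seed` (integer),
#'   `replicates` (integer), `simulator` (named overrides).
#' @return Named list with resolved tables and settings.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) {
    .np_abort(sprintf("config file '%s' does not exist.", path),
              class = "nanoprecip_input_error")
  }
  cfg <- yaml::read_yaml(path)
  list(
    compounds = if (!is.null(cfg$compounds)) read_compounds(cfg$compounds)
                else psychotropic_compounds(),
    protocols = if (!is.null(cfg$protocols)) read_protocols(cfg$protocols)
                else study_protocols(),
    conditions = if (!is.null(cfg$conditions)) {
      readr::read_csv(cfg$conditions, show_col_types = FALSE)
    } else study_conditions(),
    seed = if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L,
    replicates = if (!is.null(cfg$replicates)) as.integer(cfg$replicates)
                 else 1L,
    simulator = if (!is.null(cfg$simulator)) cfg$simulator else list()
  )
}

#' Property report for one compound
#'
#' Prints (and returns) the derived physicochemical properties of one
#' packaged compound: mean logP, ionized percentage and pH-dependent
#' solubility at a chosen pH, and the colloidal-stability class of its
#' measured zeta potential.
#'
#' @param name Compound identifier (e.g. `"AMI"`).
#' @param ph pH at which to evaluate ionization and solubility.
#' @param zeta_potential_mV Zeta potential to classify; defaults to the
#'   measured value carried in the compound table.
#' @param compounds Compound table.
#' @return Character vector of report lines, invisibly; the lines are
#'   also printed.
#' @examples
#' run_props("CUR", ph = 7)
#' @export
run_props <- function(name, ph = 7,
                      zeta_potential_mV = NULL,
                      compounds = psychotropic_compounds()) {
  row <- dplyr::filter(compounds, .data$name == !!name)
  if (nrow(row) != 1L) {
    .np_abort(sprintf("unknown compound '%s'; available: %s", name,
                      paste(compounds$name, collapse = ", ")),
              class = "nanoprecip_input_error")
  }
  zp <- if (is.null(zeta_potential_mV)) row$zp_mV[[1]] else zeta_potential_mV
  lp <- logp_average(row$logp_values[[1]])
  al <- alpha_percent(ph, row$pka[[1]], row$acid_base[[1]])
  cs <- solubility_at_ph(ph, row$free_base_solubility[[1]], row$pka[[1]],
                         row$acid_base[[1]])
  lines <- c(
    sprintf("Compound %s (%s, pKa %.2f)", row$name, row$acid_base, row$pka),
    sprintf("  (logP)av           : %.1f  (mean of %d literature values, %.3f)",
            round_half_up(lp, 1), length(row$logp_values[[1]]), lp),
    sprintf("  alpha%% at pH %.2f  : %.4g %%", ph, al),
    sprintf("  C* at pH %.2f      : %.3g mol/L", ph, cs),
    if (is.finite(zp)) {
      sprintf("  zeta potential      : %.1f mV -> %s", zp,
              as.character(classify_colloidal_stability(zp)))
    }
  )
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' Run a simulation campaign from a config file
#'
#' Reads a YAML study configuration, simulates the full grid, and
#' writes the tidy record CSV plus a JSON run manifest (seed, config
#' digest, package version) so outputs are reproducible bit-for-bit
#' from (config, seed).
#'
#' @param config_path YAML study configuration (see
#'   [read_study_config()]).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the record tibble.
#' @export
run_simulate <- function(config_path, out_dir) {
  cfg <- read_study_config(config_path)
  if (nrow(cfg$protocols) == 0L) {
    .np_abort("protocol table is empty.", class = "nanoprecip_input_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  configs <- do.call(study_sim_configs, c(
    list(conditions = cfg$conditions, protocols = cfg$protocols,
         compounds = cfg$compounds, seed = cfg$seed),
    cfg$simulator
  ))
  records <- simulate_study(configs)
  write_dls_records(records, file.path(out_dir, "dls_records.csv"))
  manifest <- list(
    seed = cfg$seed,
    n_series = length(configs),
    config_digest = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("nanoprecip"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(records)
}

#' Run the size analysis on a record CSV
#'
#' Reads a tidy record CSV, computes the [trend_report()], and writes
#' the per-protocol final sizes, the per-compound averages with the
#' fitted line, and a plain-text report.
#'
#' @param records_path CSV of records (see [read_dls_records()]).
#' @param out_dir Output directory (created if absent).
#' @param compounds Compound table supplying (logP)av.
#' @return Invisibly, the `trend_report` object.
#' @export
run_analyze <- function(records_path, out_dir,
                        compounds = psychotropic_compounds()) {
  records <- read_dls_records(records_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- trend_report(records, compounds)
  readr::write_csv(report$dhf, file.path(out_dir, "dhf_by_protocol.csv"))
  readr::write_csv(report$dhf_av, file.path(out_dir, "dhf_average.csv"))
  if (!is.null(report$fit)) {
    readr::write_csv(glance(report$fit), file.path(out_dir, "size_logp_fit.csv"))
  }
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(report)
}
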