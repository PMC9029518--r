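#' Final hydrodynamic diameter of a size series
#'
#' The "final size" DHf of a protocol run is the hydrodynamic diameter
#' recorded at the largest cumulative concentration C0 — i.e. at the
#' end of solvent addition. Record order does not matter; exact C0 ties
#' are broken by the last record.
#'
#' @param records Tidy record tibble (columns `c0_mM`, `dh_nm`, and the
#'   grouping keys `variant`/`compound`/`protocol` if present). With a
#'   single series, returns one row; with several, one row per
#'   (variant, protocol, replicate) group.
#' @return Tibble with columns `dhf_nm` plus the grouping keys.
#' @examples
#' cfg <- study_sim_configs(seed = 1)[[1]]
#' extract_dhf(simulate_protocol(cfg))
#' @export
extract_dhf <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    .np_abort("`records` must be a non-empty data frame.",
              class = "nanoprecip_input_error")
  }
  required <- c("c0_mM", "dh_nm")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    .np_abort(paste0("records are missing column(s): ",
                     paste(missing, collapse = ", ")),
              class = "nanoprecip_schema_error")
  }
  keys <- intersect(c("compound", "variant", "protocol", "replicate"),
                    names(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      dhf_nm = .data$dh_nm[max(which(.data$c0_mM == max(.data$c0_mM)))],
      .groups = "drop"
    )
}

#' Per-compound average final size
#'
#' (DHf)av: the arithmetic mean of the per-protocol final sizes of one
#' compound. When `combine_variants` is `TRUE` (the default), variants
#' of the same drug (e.g. the two antisolvent-pH variants of
#' amitriptyline) pool into a single mean over all their protocol
#' values.
#'
#' @param dhf Either a numeric vector of DHf values (returns their
#'   mean) or the tibble from [extract_dhf()] (returns one row per
#'   compound).
#' @param combine_variants Pool variants of the same compound.
#' @param ... Unused.
#' @return Scalar mean, or tibble with `compound`, `dhf_av_nm`, `n`.
#' @examples
#' dhf_average(c(100, 200))   # 150
#' @export
dhf_average <- function(dhf, combine_variants = TRUE, ...) {
  if (is.numeric(dhf)) {
    if (length(dhf) == 0L) {
      .np_abort("`dhf` must be non-empty.", class = "nanoprecip_input_error")
    }
    return(mean(dhf))
  }
  key <- if (combine_variants && "compound" %in% names(dhf)) {
    "compound"
  } else if ("variant" %in% names(dhf)) "variant" else "compound"
  dhf |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(dhf_av_nm = mean(.data$dhf_nm), n = dplyr::n(),
                     .groups = "drop")
}

#' Linear fit of average final size against average logP
#'
#' Ordinary least squares of (DHf)av on (logP)av across compounds: the
#' headline empirical trend that more lipophilic compounds precipitate
#' into larger nanoparticles. The reported R^2 is the squared Pearson
#' correlation of observed and fitted values, identical to the OLS
#' coefficient of determination for a simple linear regression.
#'
#' @param points Data frame with columns `logp_av` and `dhf_av_nm`
#'   (extra columns such as `compound` are kept for plotting), at
#'   least 3 rows.
#' @return Object of class `size_logp_fit`: a list with `slope`
#'   (nm per logP unit), `intercept` (nm), `r_squared`, the underlying
#'   `lm` fit and the input `points`. Has [tidy()][generics::tidy],
#'   [glance()][generics::glance], `autoplot()` and `print()` methods.
#' @examples
#' pts <- tibble::tibble(logp_av = c(2.9, 3.0, 4.5, 4.7, 5.0),
#'                       dhf_av_nm = c(161, 203, 298, 358, 399))
#' fit <- fit_size_vs_logp(pts)
#' glance(fit)
#' @export
fit_size_vs_logp <- function(points) {
  required <- c("logp_av", "dhf_av_nm")
  missing <- setdiff(required, names(points))
  if (length(missing)) {
    .np_abort(paste0("`points` is missing column(s): ",
                     paste(missing, collapse = ", ")),
              class = "nanoprecip_schema_error")
  }
  if (nrow(points) < 3L) {
    .np_abort("need at least 3 points for the size-logP regression.",
              class = "nanoprecip_input_error")
  }
  if (stats::sd(points$logp_av) == 0) {
    .np_abort("all logP values identical: regression is degenerate.",
              class = "nanoprecip_degenerate_error")
  }
  fit <- stats::lm(dhf_av_nm ~ logp_av, data = points)
  structure(list(
    slope = unname(stats::coef(fit)[["logp_av"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = stats::cor(points$dhf_av_nm, stats::fitted(fit))^2,
    lm = fit,
    points = tibble::as_tibble(points)
  ), class = "size_logp_fit")
}

#' @export
print.size_logp_fit <- function(x, ...) {
  cat("Size-vs-logP linear fit (", nrow(x$points), " compounds)\n", sep = "")
  cat(sprintf("  (DHf)av = %.1f + %.1f * (logP)av  [nm]\n",
              x$intercept, x$slope))
  cat(sprintf("  R^2 = %.3f; trend: %s with lipophilicity\n",
              x$r_squared,
              if (x$slope > 0) "size increases" else "size decreases"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Broom-style accessors for a size-logP fit
#'
#' @param x A `size_logp_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient (term, estimate,
#'   std.error, statistic, p.value). `glance()`: one row with
#'   `slope`, `intercept`, `r.squared`, `nobs`.
#' @examples
#' pts <- tibble::tibble(logp_av = c(2.9, 3.0, 4.5, 4.7, 5.0),
#'                       dhf_av_nm = c(161, 203, 298, 358, 399))
#' tidy(fit_size_vs_logp(pts))
#' @export
tidy.size_logp_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname tidy.size_logp_fit
#' @export
glance.size_logp_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, nobs = nrow(x$points))
}

# protocol-pair contrasts isolated by the study design matrix
.contrast_pairs <- tibble::tribble(
  ~factor,       ~high,   ~low,
  "flow_rate",   "No. 3", "No. 1",
  "c0_solvent",  "No. 1", "No. 4",
  "c0_solvent",  "No. 5", "No. 2",
  "sas_ratio",   "No. 4", "No. 2",
  "sas_ratio",   "No. 1", "No. 5"
)

#' Full size-analysis report of a study table
#'
#' Runs the whole size analysis on a tidy record table: per-(variant,
#' protocol) final sizes, per-compound (DHf)av (variants pooled), the
#' global (DHf)av-vs-(logP)av regression (when at least three compounds
#' are present), and the single-factor protocol contrasts the study
#' design isolates — flow rate (No. 1 vs No. 3), solvent concentration
#' (No. 4 vs No. 1 and No. 2 vs No. 5), solvent:antisolvent ratio
#' (No. 2 vs No. 4 and No. 5 vs No. 1) and antisolvent pH (AMIa vs
#' AMIb within each protocol). Missing protocol pairs yield `NA`
#' contrasts, not errors.
#'
#' @param records Tidy record tibble (simulator output or user data
#'   with columns `compound`, `protocol`, `c0_mM`, `dh_nm`, optionally
#'   `variant`).
#' @param compounds Compound table supplying (logP)av; default the
#'   packaged one.
#' @return Object of class `trend_report`: list with `dhf` (long
#'   per-variant/protocol table), `dhf_wide` (variants as rows,
#'   protocols as columns), `dhf_av`, `fit` (a
#'   [fit_size_vs_logp()] object or `NULL`), `contrasts` and
#'   `ph_contrasts`.
#' @examples
#' rec <- simulate_study(study_sim_configs(seed = 1)[1:5])
#' trend_report(rec)
#' @export
trend_report <- function(records, compounds = psychotropic_compounds()) {
  if (!"variant" %in% names(records)) records$variant <- records$compound
  dhf <- extract_dhf(records)
  dhf_av <- dhf_average(dhf, combine_variants = TRUE)
  lp <- logp_average(compounds) |>
    dplyr::select(compound = "name", "logp_av")
  pts <- dplyr::inner_join(dhf_av, lp, by = "compound")
  fit <- if (nrow(pts) >= 3L && stats::sd(pts$logp_av) > 0) {
    fit_size_vs_logp(pts)
  } else NULL

  wide <- tidyr::pivot_wider(
    dplyr::select(dhf, dplyr::any_of(c("compound", "variant", "protocol",
                                       "dhf_nm"))),
    names_from = "protocol", values_from = "dhf_nm"
  )

  get_dhf <- function(v, p) {
    hit <- dhf$dhf_nm[dhf$variant == v & dhf$protocol == p]
    if (length(hit) == 1L) hit else NA_real_
  }
  variants <- unique(dhf$variant)
  contrasts <- tidyr::crossing(variant = variants, .contrast_pairs) |>
    dplyr::mutate(
      dhf_high = mapply(get_dhf, .data$variant, .data$high),
      dhf_low = mapply(get_dhf, .data$variant, .data$low),
      delta_nm = .data$dhf_high - .data$dhf_low
    )

  ph_contrasts <- NULL
  if (all(c("AMIa", "AMIb") %in% variants)) {
    prots <- sort(unique(dhf$protocol))
    ph_contrasts <- tibble::tibble(
      protocol = prots,
      dhf_low_ph = vapply(prots, function(p) get_dhf("AMIa", p), 0),
      dhf_high_ph = vapply(prots, function(p) get_dhf("AMIb", p), 0)
    ) |>
      dplyr::mutate(delta_nm = .data$dhf_high_ph - .data$dhf_low_ph)
  }

  structure(list(dhf = dhf, dhf_wide = wide, dhf_av = dhf_av,
                 fit = fit, contrasts = contrasts,
                 ph_contrasts = ph_contrasts),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat("Antisolvent-precipitation size analysis\n")
  cat("\nFinal sizes DHf (nm) per variant and protocol:\n")
  print(x$dhf_wide, n = Inf)
  cat("\nPer-compound average final size (DHf)av:\n")
  print(x$dhf_av, n = Inf)
  if (!is.null(x$fit)) {
    cat("\n")
    print(x$fit)
  }
  invisible(x)
}
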