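#' Plot hydrodynamic-diameter series against concentration
#'
#' One panel per compound variant, one curve per protocol: the
#' DLS-style view of how particle size evolves as solvent solution is
#' added and the mixture concentration C0 rises.
#'
#' @param records Tidy record tibble (simulator output or measured
#'   data) with `c0_mM`, `dh_nm`, `protocol` and `variant`/`compound`.
#' @return A ggplot object.
#' @examples
#' rec <- simulate_study(study_sim_configs(seed = 1)[1:5])
#' plot_dh_series(rec)
#' @export
plot_dh_series <- function(records) {
  if (!"variant" %in% names(records)) records$variant <- records$compound
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$c0_mM, y = .data$dh_nm,
                               colour = .data$protocol)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$variant), scales = "free") +
    ggplot2::labs(x = expression(C[0] ~ "(mM)"),
                  y = expression(D[H] ~ "(nm)"),
                  colour = "Protocol") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a size-vs-logP fit
#'
#' Scatter of per-compound average final size against mean logP with
#' the fitted least-squares line.
#'
#' @param object A [fit_size_vs_logp()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.size_logp_fit <- function(object, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$logp_av,
                                         y = .data$dhf_av_nm)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression((logP)[av]),
      y = expression((D[Hf])[av] ~ "(nm)"),
      subtitle = sprintf("slope = %.1f nm per logP unit, R² = %.2f",
                         object$slope, object$r_squared)
    ) +
    ggplot2::theme_bw()
  if ("compound" %in% names(pts)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$compound),
                                vjust = -0.8, size = 3)
  }
  p
}
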