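#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat map of mean asymmetry magnitude over the template
#'
#' Renders the per-vertex mean displacement norm (mm) of a set of asymmetry
#' fields as a frontal (x-y) scatter of the template vertices coloured by
#' magnitude — the standard asymmetry heat map.
#'
#' @param fields List of [asymmetry_field()] objects.
#' @param template The [template_mesh()] the fields live on.
#' @return A ggplot object.
#' @export
plot_asymmetry_heatmap <- function(fields, template) {
  channel <- heatmap_field(fields)
  V <- template$mesh$vertices
  df <- tibble::tibble(x = V[, 1], y = V[, 2], mm = channel)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$mm)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = "asymmetry (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = "Mean asymmetry magnitude") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fa_sample <- function(object, which = c("fa", "total"), ...) {
  which <- match.arg(which)
  fields <- if (which == "fa") object$fa else object$total
  plot_asymmetry_heatmap(fields, object$template) +
    ggplot2::labs(title = sprintf("Mean %s asymmetry magnitude",
                                  if (which == "fa") "fluctuating" else "total"))
}

#' @export
autoplot.fa_equivalence <- function(object, conf_level = 0.90, ...) {
  se <- 1 / sqrt(object$n - 3)
  zr <- atanh(object$r)
  ci <- tanh(zr + stats::qnorm(c((1 - conf_level) / 2,
                                 1 - (1 - conf_level) / 2)) * se)
  df <- tibble::tibble(r = object$r, lo = ci[1], hi = ci[2])
  ggplot2::ggplot(df, ggplot2::aes(x = "observed", y = .data$r)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::geom_hline(yintercept = object$bound, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::annotate("text", x = 1, y = object$bound,
                      label = sprintf("%s bound %.2f", object$bound_kind,
                                      object$bound),
                      vjust = -0.6, colour = "firebrick") +
    ggplot2::labs(y = "correlation", x = NULL,
                  title = sprintf("Equivalence: r = %.2f (n = %d), one-sided p = %.3g",
                                  object$r, object$n, object$p)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.study_report <- function(object, conf_level = 0.90, ...) {
  df <- purrr::map_dfr(object$groups, function(g) {
    se <- 1 / sqrt(g$main_cor$n - 3)
    zr <- atanh(g$main_cor$r)
    ci <- tanh(zr + stats::qnorm(c((1 - conf_level) / 2,
                                   1 - (1 - conf_level) / 2)) * se)
    bounds <- purrr::map_dbl(g$equivalence, "bound")
    tibble::tibble(group = g$name, r = g$main_cor$r, lo = ci[1], hi = ci[2],
                   bound_regular = bounds[["regular"]],
                   bound_conservative = bounds[["conservative"]])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$r)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$bound_regular),
                        shape = 4, colour = "firebrick", size = 3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$bound_conservative),
                        shape = 4, colour = "darkorange", size = 3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(y = "FA x vocal attractiveness (r)", x = NULL,
                  title = "Observed correlations vs equivalence bounds",
                  subtitle = sprintf("point ranges: %.0f%% CI; crosses: regular (red) and conservative (orange) bounds",
                                     100 * conf_level)) +
    ggplot2::theme_minimal()
}
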