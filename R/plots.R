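#' Ramachandran scatter plot
#'
#' Region polygons (favored/allowed) are drawn under the per-residue
#' (phi, psi) points.
#'
#' @param torsions tibble from [backbone_torsions()].
#' @param regions polygons as in [rama_default_regions()].
#' @return a ggplot object.
#' @export
plot_ramachandran <- function(torsions, regions = rama_default_regions()) {
  poly_df <- bind_rows(lapply(names(regions), function(lvl) {
    bind_rows(lapply(names(regions[[lvl]]), function(nm) {
      p <- regions[[lvl]][[nm]]
      tibble(phi = p[, 1], psi = p[, 2], level = lvl,
             poly = paste(lvl, nm))
    }))
  }))
  pts <- torsions[!is.na(torsions$phi) & !is.na(torsions$psi), ]
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = poly_df[poly_df$level == "allowed", ],
      ggplot2::aes(x = phi, y = psi, group = poly), fill = "grey85") +
    ggplot2::geom_polygon(
      data = poly_df[poly_df$level == "favored", ],
      ggplot2::aes(x = phi, y = psi, group = poly), fill = "grey65") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = phi, y = psi, colour = region),
                        size = 1) +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::labs(x = expression(phi~"(degrees)"),
                  y = expression(psi~"(degrees)")) +
    ggplot2::theme_minimal()
}

#' Plot a trajectory metric summary
#'
#' Per-frame series with the trajectory mean; `type = "box"` draws the
#' five-number box plot instead.
#'
#' @param object a `traj_summary`.
#' @param type `"series"` or `"box"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.traj_summary <- function(object, type = c("series", "box"), ...) {
  type <- match.arg(type)
  ylab <- switch(object$metric, sg_c = "SG-C distance (Å)",
                 rmsd = "RMSD (Å)", hbond = "hydrogen bonds")
  if (type == "series") {
    ggplot2::ggplot(object$per_frame, ggplot2::aes(x = frame, y = value)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
      ggplot2::labs(x = "frame", y = ylab) +
      ggplot2::theme_minimal()
  } else {
    f <- object$five_num
    ggplot2::ggplot() +
      ggplot2::geom_boxplot(ggplot2::aes(x = object$metric,
                                         ymin = f$min, lower = f$q1,
                                         middle = f$median, upper = f$q3,
                                         ymax = f$max),
                            stat = "identity", width = 0.4,
                            fill = "steelblue", alpha = 0.6) +
      ggplot2::labs(x = NULL, y = ylab) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar plot of clot degradation by group
#'
#' Group means with standard-error bars, in the style of a clot-lysis
#' dose-response figure.
#'
#' @param records output of [clot_degradation()].
#' @return a ggplot object.
#' @export
plot_clot_degradation <- function(records) {
  sm <- summarise(group_by(records, group),
                  mean = mean(degradation_pct),
                  se = stats::sd(degradation_pct) / sqrt(n()),
                  .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(x = group, y = mean)) +
    ggplot2::geom_col(fill = "firebrick", alpha = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - se, ymax = mean + se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "clot degradation (%)") +
    ggplot2::theme_minimal()
}
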