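#' Tidy and glance methods for markerprobe result objects
#'
#' Broom-style accessors: `tidy()` returns per-component rows, `glance()` a
#' one-row model summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name markerprobe-tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname markerprobe-tidiers
#' @export
glance.mantel_result <- function(x, ...) {
  tibble(r = x$r, p_value = x$p, n = x$n, n_perm = x$n_perm, seed = x$seed)
}

#' @rdname markerprobe-tidiers
#' @export
tidy.mantel_result <- function(x, ...) glance.mantel_result(x)

#' @rdname markerprobe-tidiers
#' @export
glance.anosim_result <- function(x, ...) {
  tibble(R = x$R, p_value = x$p, n_perm = x$n_perm, seed = x$seed)
}

#' @rdname markerprobe-tidiers
#' @export
tidy.anosim_result <- function(x, ...) glance.anosim_result(x)

#' @rdname markerprobe-tidiers
#' @export
tidy.pcoa_result <- function(x, ...) x$points

#' @rdname markerprobe-tidiers
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble(n = nrow(x$points),
         percent_axis1 = x$percent[1],
         percent_axis2 = if (length(x$percent) > 1) x$percent[2] else NA_real_,
         n_negative_eigenvalues = sum(x$eigenvalues < 0))
}

#' @rdname markerprobe-tidiers
#' @export
tidy.cca_result <- function(x, ...) {
  tibble(axis = paste0("CCA", seq_along(x$eigenvalues)),
         eigenvalue = x$eigenvalues,
         percent_total = x$percent_total,
         percent_constrained = x$percent_constrained)
}

#' @rdname markerprobe-tidiers
#' @export
glance.cca_result <- function(x, ...) {
  tibble(total_inertia = x$total_inertia,
         constrained_inertia = x$constrained_inertia,
         percent_constrained = 100 * x$constrained_inertia / x$total_inertia,
         pseudo_f = x$pseudo_f, p_value = x$p, n_perm = x$n_perm)
}

#' @rdname markerprobe-tidiers
#' @export
tidy.indval_result <- function(x, ...) x$summary

#' @rdname markerprobe-tidiers
#' @export
glance.indval_result <- function(x, ...) {
  tibble(n_otus = nrow(x$summary),
         n_significant = sum(x$summary$significant),
         alpha = x$alpha, n_perm = x$n_perm)
}

#' @rdname markerprobe-tidiers
#' @export
tidy.calibration_curve <- function(x, ...) as_tibble(x)

#' @rdname markerprobe-tidiers
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(recommended_threshold = attr(x, "recommended_threshold"),
         tolerance_met = attr(x, "tolerance_met"),
         tolerance = attr(x, "tolerance"))
}

#' Ordination and calibration plots
#'
#' `autoplot()` methods give quick-look ggplot figures: PCoA and CCA sample
#' maps and the clustering-threshold calibration curve.
#'
#' @param object A result object.
#' @param colour Optional named vector mapping sample to a grouping.
#' @param ... Unused.
#' @return A ggplot object.
#' @name markerprobe-autoplot
NULL

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   labs theme_minimal scale_y_log10
#' @export
ggplot2::autoplot

#' @rdname markerprobe-autoplot
#' @export
autoplot.pcoa_result <- function(object, colour = NULL, ...) {
  pts <- object$points
  if (!is.null(colour)) pts$group <- colour[pts$sample]
  p <- ggplot(pts, aes(x = .data$Axis1, y = .data$Axis2)) +
    labs(x = sprintf("PCoA 1 (%.1f%%)", object$percent[1]),
         y = sprintf("PCoA 2 (%.1f%%)", object$percent[2])) +
    theme_minimal()
  if (is.null(colour)) p + geom_point()
  else p + geom_point(aes(colour = .data$group))
}

#' @rdname markerprobe-autoplot
#' @export
autoplot.cca_result <- function(object, colour = NULL, ...) {
  pts <- object$site_scores
  if (!is.null(colour)) pts$group <- colour[pts$sample]
  p <- ggplot(pts, aes(x = .data$CCA1,
                       y = if (ncol(pts) > 2) .data$CCA2 else 0)) +
    labs(x = sprintf("CCA1 (%.1f%% of community variation)",
                     object$percent_total[1]),
         y = "CCA2") +
    theme_minimal()
  if (is.null(colour)) p + geom_point()
  else p + geom_point(aes(colour = .data$group))
}

#' @rdname markerprobe-autoplot
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$identity_level, y = .data$within_cluster_variance)) +
    geom_line() + geom_point() +
    geom_hline(yintercept = attr(object, "tolerance"), linetype = 2) +
    labs(x = "amplicon clustering identity",
         y = "pooled within-cluster variance of full-length distances") +
    theme_minimal()
}
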