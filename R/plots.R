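#' Membership bar plot for an admixture fit
#'
#' The classic stacked-bar ancestry plot: one thin bar per genotype, split
#' into K colored segments.
#'
#' @param object A `pvp_admixture` object.
#' @param group Optional per-sample labels used to order and facet bars
#'   (e.g. ecotype or accession).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pvp_admixture <- function(object, group = NULL, ...) {
  df <- tidy(object)
  ord <- tibble(sample_id = rownames(object$Q),
                top = apply(object$Q, 1, which.max),
                maxq = apply(object$Q, 1, max))
  if (!is.null(group)) ord$grp <- group
  ord <- arrange(ord, .data$top, dplyr::desc(.data$maxq))
  df$sample_id <- factor(df$sample_id, levels = ord$sample_id)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$q,
                                        fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "membership (Q)", fill = "cluster") +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  p
}

#' Scatter plot of the first two PCoA axes
#'
#' @param object A `pvp_pcoa` object.
#' @param colour Optional per-sample labels for coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pvp_pcoa <- function(object, colour = NULL, ...) {
  df <- as_tibble(object$coordinates[, 1:2, drop = FALSE])
  names(df) <- c("Axis1", "Axis2")
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%%)", object$pct_variance[1]),
      y = sprintf("Axis 2 (%.1f%%)", object$pct_variance[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
}

#' Windowed SNP profile plot (100-bp bins)
#'
#' @param windows Output of [window_variant_profile()] (optionally several
#'   contigs bound together with a `contig_id` column).
#' @return A ggplot object.
#' @export
plot_window_profile <- function(windows) {
  p <- ggplot2::ggplot(windows,
                       ggplot2::aes(x = .data$window_start,
                                    y = .data$snp_count)) +
    ggplot2::geom_col(width = diff(windows$window_start[1:2] %||% c(0, 100))) +
    ggplot2::labs(x = "position (bp)", y = "SNPs per bin") +
    ggplot2::theme_minimal()
  if ("contig_id" %in% names(windows)) {
    p <- p + ggplot2::facet_wrap(~contig_id, scales = "free_x")
  }
  p
}

#' Map-style plot of sample ancestry by location
#'
#' @param samples Sample tibble with latitude/longitude.
#' @param assigned Per-sample subpopulation labels (e.g. from
#'   [classify_membership()]).
#' @return A ggplot object.
#' @export
plot_sample_map <- function(samples, assigned) {
  df <- samples |> mutate(assigned = assigned)
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude,
                                   colour = .data$assigned)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude", colour = NULL) +
    ggplot2::theme_minimal()
}
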