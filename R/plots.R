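#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_line geom_ribbon
#'   geom_tile geom_smooth labs scale_fill_manual scale_fill_gradient
#'   facet_wrap position_dodge theme_minimal
NULL

#' Plot a distance-decay relationship
#'
#' @param object A `trflp_decay` from [distance_decay()].
#' @param ... Unused.
#' @return A ggplot: community dissimilarity against geographic distance
#'   with a linear trend.
#' @export
autoplot.trflp_decay <- function(object, ...) {
  ggplot(object$pairs, aes(.data$distance_km, .data$dissimilarity)) +
    geom_point(alpha = 0.4) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "black") +
    labs(
      x = "Geographic distance (km)", y = "Community dissimilarity",
      subtitle = sprintf("r = %.3f, permutation p = %.3g", object$r, object$p)
    ) +
    theme_minimal()
}

#' Plot an occupancy-frequency distribution
#'
#' ERM bars in black and NEM bars in white, per occupancy bin.
#'
#' @param object A `trflp_occupancy`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trflp_occupancy <- function(object, ...) {
  ggplot(object$table,
         aes(.data$bin, .data$proportion, fill = .data$guild)) +
    geom_col(position = position_dodge(), colour = "black") +
    scale_fill_manual(values = c(ERM = "black", NEM = "white")) +
    labs(
      x = if (object$mode == "individuals") "Host individuals occupied"
          else "Regions occupied",
      y = "Proportion of TRFs", fill = NULL
    ) +
    theme_minimal()
}

#' Plot a TRF accumulation curve
#'
#' @param object A `trflp_accumulation`.
#' @param ... Unused.
#' @return A ggplot with mean +/- SD ribbon.
#' @export
autoplot.trflp_accumulation <- function(object, ...) {
  ggplot(object$table, aes(.data$n_hosts, .data$mean_pct)) +
    geom_ribbon(aes(ymin = .data$mean_pct - .data$sd_pct,
                    ymax = .data$mean_pct + .data$sd_pct), alpha = 0.2) +
    geom_line() +
    labs(x = "Host individuals sampled", y = "% of TRFs detected") +
    theme_minimal()
}

#' Plot host individuals on the genetic PCA axes
#'
#' @param object A `trflp_pca`.
#' @param groups Optional tibble from [host_groups()] to colour by.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2.
#' @export
autoplot.trflp_pca <- function(object, groups = NULL, ...) {
  dat <- tidy(object)
  if (!is.null(groups)) {
    dat <- dplyr::left_join(dat, groups, by = "id") |>
      dplyr::mutate(host_group = factor(.data$host_group))
  }
  p <- ggplot(dat, aes(.data$PC1, .data$PC2))
  p <- if (is.null(groups)) p + geom_point() else
    p + geom_point(aes(colour = .data$host_group))
  p + labs(x = "HSTPC1", y = "HSTPC2", colour = "Host group") + theme_minimal()
}

#' Plot an ordination score map
#'
#' @param object A `trflp_ordination`.
#' @param ... Unused.
#' @return A ggplot of the first two axes.
#' @export
autoplot.trflp_ordination <- function(object, ...) {
  ggplot(tidy(object), aes(.data$PC1, .data$PC2)) +
    geom_point() +
    labs(x = "Axis 1", y = "Axis 2") +
    theme_minimal()
}

#' Plot a clustered OTU distribution heatmap
#'
#' Rows (OTUs) follow the Bray-Curtis single-linkage leaf order.
#'
#' @param object A `trflp_heatmap` from [cluster_heatmap()].
#' @param ... Unused.
#' @return A ggplot tile map.
#' @export
autoplot.trflp_heatmap <- function(object, ...) {
  ggplot(tidy(object), aes(.data$group, .data$otu_id, fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "black") +
    labs(x = NULL, y = NULL, fill = "Relative\nabundance") +
    theme_minimal()
}
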