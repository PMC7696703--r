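#' Model-position plot of a scan
#'
#' Scatter of subset-model mean positions over the scan plane: yellow
#' squares for significant models, black dots for non-significant ones.
#'
#' @param scan a `scan_result`.
#' @return a ggplot object.
#' @export
plot_smart_models <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  df <- scan$subsets
  df$status <- factor(ifelse(df$significant, "significant",
                             "non-significant"),
                      levels = c("non-significant", "significant"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_ttd, y = .data$pos_tbs,
                                   colour = .data$status,
                                   shape = .data$status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c("non-significant" = "black",
                                            "significant" = "gold2")) +
    ggplot2::scale_shape_manual(values = c("non-significant" = 16,
                                           "significant" = 15)) +
    ggplot2::labs(x = "Time to diagnosis (years)",
                  y = "Time between repeated samples (years)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

density_map_df <- function(map) {
  data.frame(ttd = rep(map$ttd, times = length(map$tbs)),
             tbs = rep(map$tbs, each = length(map$ttd)),
             value = as.vector(map$counts))
}

#' Heatmap of an observation-density map
#'
#' Observed case-control coordinates can be overlaid via `coords`.
#'
#' @param map a `density_map`.
#' @param coords optional data frame with `ttd`, `tbs` columns.
#' @return a ggplot object.
#' @export
plot_density_map <- function(map, coords = NULL) {
  stopifnot(inherits(map, "density_map"))
  df <- density_map_df(map)
  signed <- any(df$value < 0)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ttd, y = .data$tbs,
                                        fill = .data$value)) +
    ggplot2::geom_raster()
  g <- if (signed) {
    g + ggplot2::scale_fill_gradient2(low = "blue3", mid = "white",
                                      high = "red3", midpoint = 0)
  } else {
    g + ggplot2::scale_fill_gradient(low = "white", high = "blue3")
  }
  if (!is.null(coords)) {
    g <- g + ggplot2::geom_point(data = coords,
                                 ggplot2::aes(x = .data$ttd, y = .data$tbs),
                                 inherit.aes = FALSE, size = 1)
  }
  g + ggplot2::labs(x = "Time to diagnosis (years)",
                    y = "Time between repeated samples (years)",
                    fill = "overlaid\nsubsets") +
    ggplot2::theme_minimal()
}

#' Colour-banded probability map
#'
#' @param map a `probability_map`.
#' @return a ggplot object.
#' @export
plot_probability_map <- function(map) {
  stopifnot(inherits(map, "probability_map"))
  df <- data.frame(ttd = rep(map$ttd, times = length(map$tbs)),
                   tbs = rep(map$tbs, each = length(map$ttd)),
                   level = as.vector(map$level))
  pal <- c("<0.001" = "#67000d", "<0.01" = "#cb181d", "<0.05" = "#fb6a4a",
           "<0.10" = "#fcae91", "<0.20" = "#fee5d9", ">0.20" = "white")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ttd, y = .data$tbs,
                                   fill = .data$level)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::labs(x = "Time to diagnosis (years)",
                  y = "Time between repeated samples (years)",
                  fill = "null\nprobability") +
    ggplot2::theme_minimal()
}

#' ROC curve of a validation result
#'
#' @param result a `validation_result`.
#' @return a ggplot object.
#' @export
plot_roc <- function(result) {
  stopifnot(inherits(result, "validation_result"))
  df <- data.frame(fpr = 1 - result$roc$specificity,
                   tpr = result$roc$sensitivity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.2f (p = %.2g)", result$auc,
                                  result$p_rank)) +
    ggplot2::theme_minimal()
}

#' Dendrogram of clustered model loadings
#'
#' Base-graphics dendrogram with the simulated cut threshold drawn as a
#' dashed line.
#'
#' @param clusters a `cluster_result`.
#' @export
plot_model_dendrogram <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_result"))
  if (is.null(clusters$hclust)) stop("no tree: fewer than 2 models")
  plot(clusters$hclust, labels = FALSE, hang = -1,
       xlab = "significant models", sub = "",
       main = sprintf("%d cluster(s)", clusters$n_clusters))
  graphics::abline(h = clusters$threshold, lty = 2, col = "red")
  invisible(clusters)
}
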