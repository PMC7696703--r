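#' Cosine distance between two loading vectors
#'
#' `1 - cos(w_i, w_j)`: 0 for identical directions, 1 for orthogonal, 2
#' for opposite directions.
#'
#' @param w_i,w_j numeric vectors of equal length, nonzero norm.
#' @return the distance in `[0, 2]`.
#' @export
loading_distance <- function(w_i, w_j) {
  ni <- sqrt(sum(w_i^2)); nj <- sqrt(sum(w_j^2))
  if (ni == 0 || nj == 0) stop("zero loading vector")
  1 - sum(w_i * w_j) / (ni * nj)
}

cosine_dist_matrix <- function(W) {
  nrm <- sqrt(rowSums(W^2))
  if (any(nrm == 0)) stop("zero loading vector")
  U <- W / nrm
  d <- 1 - tcrossprod(U)
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  stats::as.dist(d)
}

#' Cluster significant-model loadings
#'
#' Hierarchical clustering (average linkage) of the predictive loading
#' vectors of significant subset models under the 1 - cosine distance. The
#' number of clusters is decided against a simulated null: loading sets of
#' matched size and dimension are drawn with independent standard-normal
#' entries, the maximum merge height of each replicate's average-linkage
#' tree is recorded, and observed merges above the `level` quantile of
#' those maxima split clusters. Directionless noise loadings are nearly
#' mutually orthogonal in high dimension, so a tree whose merges all stay
#' below the null threshold is read as a single shared pattern.
#'
#' @param W matrix of loading vectors, one row per significant model (or a
#'   `scan_result`, from which significant-model loadings are taken).
#' @param n_null null replicates for the cluster-count threshold.
#' @param level quantile of the null maximum merge heights.
#' @param seed seed for the null draws.
#' @return an object of class `cluster_result`: `dist`, `hclust`,
#'   `threshold`, `n_clusters`, `labels`, `null_max_heights`.
#' @export
cluster_models <- function(W, n_null = 1000L, level = 0.95, seed = 1L) {
  if (inherits(W, "scan_result")) {
    keep <- W$subsets$significant & !is.na(W$W[, 1L])
    W <- W$W[keep, , drop = FALSE]
  }
  W <- as.matrix(W)
  m <- nrow(W)
  if (m < 2L) {
    return(structure(list(dist = NULL, hclust = NULL, threshold = NA_real_,
                          n_clusters = as.integer(m),
                          labels = rep(1L, m),
                          null_max_heights = numeric(0)),
                     class = "cluster_result"))
  }
  d <- cosine_dist_matrix(W)
  hc <- stats::hclust(d, method = "average")

  p <- ncol(W)
  null_max <- with_private_seed(seed, {
    vapply(seq_len(n_null), function(r) {
      Wr <- matrix(stats::rnorm(m * p), m, p)
      max(stats::hclust(cosine_dist_matrix(Wr), method = "average")$height)
    }, numeric(1))
  })
  thr <- stats::quantile(null_max, level, names = FALSE)
  labels <- if (max(hc$height) <= thr) {
    rep(1L, m)
  } else {
    stats::cutree(hc, h = thr)
  }
  structure(list(dist = d, hclust = hc, threshold = thr,
                 n_clusters = length(unique(labels)),
                 labels = labels, null_max_heights = null_max),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: ", length(x$labels), " models, ",
      x$n_clusters, " cluster(s) at threshold ",
      format(x$threshold, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Serialize a model dendrogram to Newick
#'
#' @param clusters a `cluster_result` with a fitted tree.
#' @param path output path.
#' @export
write_dendrogram_newick <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_result"))
  if (is.null(clusters$hclust)) stop("no tree: fewer than 2 models")
  phy <- ape::as.phylo(clusters$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
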