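#' Scan settings
#'
#' Bundles the tunable parameters of the subset scan. The seven distance
#' weights for the time-to-diagnosis axis default to the doubling sequence
#' 1/8, 1/4, 1/2, 1, 2, 4, 8 (the time-between-samples axis always has
#' weight 1); the grid step is 0.25 years; each subset holds the 20 nearest
#' case-control observations.
#'
#' @param step grid increment in years.
#' @param k subset size (nearest observations per anchor).
#' @param weights time-to-diagnosis distance weights.
#' @param k_folds cross-validation folds per subset model.
#' @param n_ortho orthogonal components per subset model (0 keeps the
#'   models to a single predictive component).
#' @param alpha model/variable significance level.
#' @param select_vars per-round w/p variable selection inside the CV.
#' @param fold_seed seed for the cross-validation fold partition.
#' @param ellipse_level coverage level of the Hotelling T2 ellipses.
#' @return a list of settings with class `scan_settings`.
#' @export
scan_settings <- function(step = 0.25, k = 20L, weights = 2^(-3:3),
                          k_folds = 7L, n_ortho = 0L, alpha = 0.05,
                          select_vars = TRUE, fold_seed = 1L,
                          ellipse_level = 0.95) {
  stopifnot(step > 0, k >= 3L, all(weights > 0), k_folds >= 2L,
            n_ortho >= 0L, alpha > 0, alpha < 1)
  structure(list(step = step, k = as.integer(k), weights = weights,
                 k_folds = as.integer(k_folds),
                 n_ortho = as.integer(n_ortho), alpha = alpha,
                 select_vars = select_vars,
                 fold_seed = as.integer(fold_seed),
                 ellipse_level = ellipse_level),
            class = "scan_settings")
}

#' Build the scan grid
#'
#' Lattice of anchor points aligned to multiples of `step` covering the
#' observed (time to diagnosis) x (time between samples) bounding box,
#' inclusive.
#'
#' @param cohort a `paired_cohort` with `ttd` and `tbs` coordinates.
#' @param step grid increment in years.
#' @return list with `ttd` and `tbs` axis values and a two-column matrix
#'   `points` of all grid anchors.
#' @export
build_grid <- function(cohort, step = 0.25) {
  stopifnot(inherits(cohort, "paired_cohort"), step > 0)
  if (nrow(cohort$d) == 0L) stop("empty cohort")
  ttd_axis <- grid_axis(cohort$ttd, step)
  tbs_axis <- grid_axis(cohort$tbs, step)
  pts <- as.matrix(expand.grid(ttd = ttd_axis, tbs = tbs_axis,
                               KEEP.OUT.ATTRS = FALSE))
  list(ttd = ttd_axis, tbs = tbs_axis, points = pts, step = step)
}

grid_axis <- function(x, step) {
  x <- x[!is.na(x)]
  lo <- floor(min(x) / step + 1e-9) * step
  hi <- ceiling(max(x) / step - 1e-9) * step
  seq(lo, hi, by = step)
}

#' Select the subset nearest a scan anchor
#'
#' Returns the `k` observations minimizing the weighted distance
#' `sqrt((w * dttd)^2 + dtbs^2)` from the anchor. Ties are broken
#' deterministically by pair id so subsets are reproducible.
#'
#' @param anchor numeric `(ttd, tbs)` anchor point.
#' @param weight distance weight for the time-to-diagnosis axis.
#' @param cohort a `paired_cohort`.
#' @param k subset size.
#' @return integer vector of member row indices, sorted.
#' @export
select_subset <- function(anchor, weight, cohort, k = 20L) {
  n <- length(cohort$ttd)
  if (k > n) stop("k must not exceed the number of observations")
  d2 <- (weight * (cohort$ttd - anchor[1L]))^2 + (cohort$tbs - anchor[2L])^2
  ord <- order(d2, cohort$pair_ids)
  sort(ord[seq_len(k)])
}

#' Hotelling T2 confidence ellipse of a point set
#'
#' Center is the sample mean, axes come from the eigen-decomposition of the
#' sample covariance scaled by the small-sample Hotelling T2 quantile
#' `2 (n - 1) / (n - 2) * qf(level, 2, n - 2)` (which tends to the
#' chi-square radius `sqrt(qchisq(level, 2))` as `n` grows).
#'
#' @param points two-column matrix of `(ttd, tbs)` coordinates (`n >= 3`).
#' @param level coverage level.
#' @return list with `center`, `radii` (major, minor), `angle` (radians of
#'   the major axis), `cov`, `t2crit`, `n`, and `degenerate` (`TRUE` when
#'   the points are collinear, giving a zero minor axis).
#' @export
hotelling_ellipse <- function(points, level = 0.95) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points for a Hotelling ellipse")
  ctr <- colMeans(points)
  S <- stats::cov(points)
  eg <- eigen(S, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  t2crit <- 2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
  degenerate <- vals[2L] <= max(vals[1L], .Machine$double.eps) * 1e-10
  radii <- sqrt(vals * t2crit)
  if (degenerate) radii[2L] <- 0
  list(center = ctr, radii = radii,
       angle = atan2(eg$vectors[2L, 1L], eg$vectors[1L, 1L]),
       cov = S, t2crit = t2crit, n = n, degenerate = degenerate)
}

# logical vector: which rows of pts (m x 2) fall inside the ellipse;
# a degenerate ellipse has zero area and covers nothing
ellipse_covers <- function(ellipse, pts) {
  if (ellipse$degenerate) return(rep(FALSE, nrow(pts)))
  md <- stats::mahalanobis(pts, ellipse$center, ellipse$cov)
  md <= ellipse$t2crit
}

#' Run the subset scan
#'
#' For every grid anchor and every time-to-diagnosis weight, selects the
#' nearest-`k` subset, deduplicates identical member sets, and fits a
#' cross-validated effect-projection model per unique subset. Each record
#' keeps the model's CV-ANOVA significance, its position (unweighted mean
#' coordinates of the members), its Hotelling ellipse, the predictive
#' loading vector of a full-subset fit, and the per-variable loading
#' statistics used by the variable-level density maps. Non-computable
#' models (a CV round without selected variables) are retained as
#' non-significant sentinels, never dropped.
#'
#' The scan is deterministic: the same cohort and settings always produce
#' the same result.
#'
#' @param cohort a `paired_cohort` from [disease_progress()].
#' @param settings a [scan_settings()] list.
#' @param keep_var_stats store per-subset per-variable statistics (needed
#'   by [variable_density()]).
#' @return an object of class `scan_result`.
#' @export
run_scan <- function(cohort, settings = scan_settings(),
                     keep_var_stats = TRUE) {
  stopifnot(inherits(cohort, "paired_cohort"))
  n <- nrow(cohort$d)
  p <- ncol(cohort$d)
  if (settings$k > n) stop("subset size k exceeds the number of pairs")
  grid <- build_grid(cohort, settings$step)

  # enumerate unique member sets over grid x weights
  seen <- new.env(hash = TRUE, parent = emptyenv())
  members <- list()
  anchors <- list()
  n_pts <- nrow(grid$points)
  for (w in settings$weights) {
    d2_ttd <- (w * outer(grid$points[, 1L], cohort$ttd, "-"))^2
    d2 <- d2_ttd + outer(grid$points[, 2L], cohort$tbs, "-")^2
    for (g in seq_len(n_pts)) {
      ord <- order(d2[g, ], cohort$pair_ids)
      mem <- sort(ord[seq_len(settings$k)])
      key <- paste(mem, collapse = ",")
      if (is.null(seen[[key]])) {
        idx <- length(members) + 1L
        seen[[key]] <- idx
        members[[idx]] <- mem
        anchors[[idx]] <- c(grid$points[g, ], weight = w)
      }
    }
  }

  n_sub <- length(members)
  folds_by_size <- list()
  q2 <- p_cv <- pos_ttd <- pos_tbs <- rep(NA_real_, n_sub)
  computable <- rep(TRUE, n_sub)
  ellipses <- vector("list", n_sub)
  W <- matrix(NA_real_, n_sub, p, dimnames = list(NULL, cohort$variable_ids))
  if (keep_var_stats) {
    T_w <- P_w <- P_p <- matrix(NA_real_, n_sub, p,
                                dimnames = list(NULL, cohort$variable_ids))
  }

  for (i in seq_len(n_sub)) {
    mem <- members[[i]]
    m <- length(mem)
    key <- as.character(m)
    if (is.null(folds_by_size[[key]])) {
      folds_by_size[[key]] <- cv_folds(m, min(settings$k_folds, m),
                                       settings$fold_seed)
    }
    Dm <- cohort$d[mem, , drop = FALSE]
    pos_ttd[i] <- mean(cohort$ttd[mem])
    pos_tbs[i] <- mean(cohort$tbs[mem])
    ellipses[[i]] <- hotelling_ellipse(cbind(cohort$ttd[mem],
                                             cohort$tbs[mem]),
                                       settings$ellipse_level)

    cv <- cross_validate(Dm, kind = "ep", n_ortho = settings$n_ortho,
                         select_vars = settings$select_vars,
                         alpha = settings$alpha,
                         folds = folds_by_size[[key]])
    q2[i] <- cv$Q2
    p_cv[i] <- cv$p_cvanova
    computable[i] <- cv$computable

    # full-subset fit for loadings and per-variable statistics
    s <- col_sds(Dm)
    valid <- which(s > 0)
    if (length(valid) > 0L) {
      Xs <- sweep(Dm[, valid, drop = FALSE], 2L, s[valid], "/")
      core <- ep_core_fit(Xs, rep(1, m), settings$n_ortho)
      if (!is.null(core)) {
        wfull <- numeric(p)
        wfull[valid] <- core$w
        W[i, ] <- wfull
        if (keep_var_stats) {
          mu <- colMeans(Dm[, valid, drop = FALSE])
          t_w <- mu / (s[valid] / sqrt(m))
          p_w <- 2 * stats::pt(abs(t_w), df = m - 1L, lower.tail = FALSE)
          yhat <- core$fitted
          denom <- sqrt(colSums(Xs^2)) * sqrt(sum(yhat^2))
          cs <- pmax(-1, pmin(1, drop(crossprod(Xs, yhat)) / denom))
          t_p <- ifelse(abs(cs) < 1,
                        cs * sqrt(m - 1) / sqrt(1 - cs^2), Inf)
          p_p <- ifelse(is.finite(t_p),
                        2 * stats::pt(abs(t_p), df = m - 2L,
                                      lower.tail = FALSE), 0)
          T_w[i, valid] <- t_w
          P_w[i, valid] <- p_w
          P_p[i, valid] <- p_p
        }
      }
    }
  }

  subsets <- data.frame(
    subset_id = seq_len(n_sub),
    anchor_ttd = vapply(anchors, `[[`, numeric(1), 1L),
    anchor_tbs = vapply(anchors, `[[`, numeric(1), 2L),
    weight = vapply(anchors, `[[`, numeric(1), 3L),
    n_members = lengths(members),
    pos_ttd = pos_ttd, pos_tbs = pos_tbs,
    Q2 = q2, p_cvanova = p_cv,
    computable = computable,
    significant = !is.na(p_cv) & p_cv < settings$alpha,
    stringsAsFactors = FALSE)

  out <- list(subsets = subsets, members = members, ellipses = ellipses,
              W = W, grid = grid, settings = settings,
              coords = data.frame(pair_id = cohort$pair_ids,
                                  ttd = cohort$ttd, tbs = cohort$tbs,
                                  stringsAsFactors = FALSE),
              variable_ids = cohort$variable_ids)
  if (keep_var_stats) {
    out$var_stats <- list(t_w = T_w, p_w = P_w, p_p = P_p)
  }
  structure(out, class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result: ", nrow(x$subsets), " unique subsets (",
      sum(x$subsets$significant), " significant at alpha = ",
      x$settings$alpha, ")\n", sep = "")
  invisible(x)
}

# raster of cell centers shared by the observation-density machinery
density_raster <- function(scan, raster_step = scan$settings$step) {
  ttd <- grid_axis(scan$coords$ttd, raster_step)
  tbs <- grid_axis(scan$coords$tbs, raster_step)
  list(ttd = ttd, tbs = tbs, step = raster_step,
       cells = as.matrix(expand.grid(ttd = ttd, tbs = tbs,
                                     KEEP.OUT.ATTRS = FALSE)))
}

# n_subsets x n_cells logical coverage of ellipse interiors over the raster
coverage_matrix <- function(scan, raster) {
  vapply(scan$ellipses, ellipse_covers, logical(nrow(raster$cells)),
         pts = raster$cells)
}

#' Observation-density map of significant subsets
#'
#' Overlays the Hotelling ellipses of all subsets with significant models
#' on a raster over the scan plane; each cell counts the ellipses covering
#' its center. This is the density shown by the SMART-observation plot.
#'
#' @param scan a `scan_result`.
#' @param raster_step cell size in years (defaults to the scan step).
#' @param subset_flags optional logical vector overriding which subsets are
#'   counted (defaults to the significant ones).
#' @return an object of class `density_map` with `ttd`, `tbs` axis centers
#'   and a `counts` matrix (`length(ttd)` x `length(tbs)`).
#' @export
observation_density <- function(scan, raster_step = scan$settings$step,
                                subset_flags = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  raster <- density_raster(scan, raster_step)
  if (is.null(subset_flags)) subset_flags <- scan$subsets$significant
  cov <- coverage_matrix(scan, raster)
  counts <- if (any(subset_flags)) {
    rowSums(cov[, subset_flags, drop = FALSE])
  } else {
    rep(0L, nrow(raster$cells))
  }
  new_density_map(raster, counts)
}

new_density_map <- function(raster, counts) {
  structure(list(ttd = raster$ttd, tbs = raster$tbs,
                 counts = matrix(counts, nrow = length(raster$ttd),
                                 ncol = length(raster$tbs)),
                 step = raster$step),
            class = "density_map")
}

#' Signed density map for one variable
#'
#' Density over the subsets in which the given variable passes a
#' significance criterion, signed by the direction of change (+1 where the
#' variable is elevated in cases, -1 where reduced). The `multivariate`
#' criterion additionally requires a significant subset model, so its map
#' is always a cellwise subset (in absolute count) of the `ttest` map.
#'
#' @param scan a `scan_result` run with `keep_var_stats = TRUE`.
#' @param variable_id variable name (or column index).
#' @param criterion `"ttest"` (univariate p < alpha), `"fdr"` (univariate
#'   with Benjamini-Hochberg FDR < `fdr_q` across variables within each
#'   subset) or `"multivariate"` (significant model + w + p criteria).
#' @param raster_step cell size in years.
#' @param fdr_q FDR level for the `fdr` criterion.
#' @return a `density_map` whose counts carry the sign of the change.
#' @export
variable_density <- function(scan, variable_id,
                             criterion = c("ttest", "fdr", "multivariate"),
                             raster_step = scan$settings$step,
                             fdr_q = 0.2) {
  stopifnot(inherits(scan, "scan_result"))
  criterion <- match.arg(criterion)
  if (is.null(scan$var_stats)) {
    stop("scan was run without keep_var_stats = TRUE")
  }
  j <- if (is.character(variable_id)) {
    match(variable_id, scan$variable_ids)
  } else {
    as.integer(variable_id)
  }
  if (is.na(j) || j < 1L || j > length(scan$variable_ids)) {
    stop("unknown variable: ", variable_id)
  }
  alpha <- scan$settings$alpha
  p_w <- scan$var_stats$p_w[, j]
  uni <- !is.na(p_w) & p_w < alpha
  passes <- switch(criterion,
    ttest = uni,
    fdr = {
      adj <- t(apply(scan$var_stats$p_w, 1L, stats::p.adjust,
                     method = "BH"))
      uni & !is.na(adj[, j]) & adj[, j] <= fdr_q
    },
    multivariate = {
      p_p <- scan$var_stats$p_p[, j]
      scan$subsets$significant & uni & !is.na(p_p) & p_p < alpha
    })
  sgn <- sign(scan$var_stats$t_w[, j])
  raster <- density_raster(scan, raster_step)
  cov <- coverage_matrix(scan, raster)
  counts <- if (any(passes)) {
    drop(cov[, passes, drop = FALSE] %*% sgn[passes])
  } else {
    rep(0, nrow(raster$cells))
  }
  new_density_map(raster, counts)
}

#' Cross-validated model for a declared region of interest
#'
#' Fits a one-predictive-component effect-projection model (no orthogonal
#' components, to limit overfitting) on the variable panel, restricted to
#' the pairs inside the user-declared rectangle `ttd < roi[1]` and
#' `tbs < roi[2]` (the `tbs` condition is ignored for single-time-point
#' difference cohorts). The region is declared by the analyst after
#' inspecting the scan output; no automatic rectangle estimation is done.
#'
#' @param cohort a `paired_cohort`.
#' @param roi numeric `(ttd_max, tbs_max)` in years.
#' @param variables panel of variable ids (default: all).
#' @param k_folds,fold_seed cross-validation controls.
#' @param select_vars per-round variable selection (off by default: the
#'   panel is already fixed).
#' @return a `cv_result` with Q2 and CV-ANOVA p for the region model.
#' @export
roi_model <- function(cohort, roi, variables = NULL, k_folds = 7L,
                      fold_seed = 1L, select_vars = FALSE) {
  stopifnot(inherits(cohort, "paired_cohort"), length(roi) == 2L)
  inside <- cohort$ttd < roi[1L] &
    (is.na(cohort$tbs) | cohort$tbs < roi[2L])
  if (sum(inside) < 3L) {
    stop("region of interest contains fewer than 3 observations")
  }
  sub <- subset_cohort(cohort, pairs = which(inside), variables = variables)
  cross_validate(sub, kind = "ep", n_ortho = 0L,
                 k_folds = min(k_folds, nrow(sub$d)),
                 select_vars = select_vars, fold_seed = fold_seed)
}
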