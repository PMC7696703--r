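#' Recompute the observation density under random data
#'
#' Re-runs the scan's subset models `n_reps` times with the metabolite data
#' replaced by independent standard-normal draws of the same pairs x
#' variables shape, keeping the time coordinates — and therefore the subset
#' memberships, positions and ellipses — fixed. Each replicate records the
#' significant-subset density over the raster, yielding the per-cell null
#' distribution that calibrates the observed SMART-observation plot.
#'
#' Replicates are seeded independently (`seed + replicate index`), so the
#' result does not depend on execution order, and an interrupted run can be
#' resumed from a checkpoint.
#'
#' @param scan a `scan_result` from the real data; its settings, member
#'   sets and ellipses are reused unchanged.
#' @param n_reps number of random-data replicates.
#' @param seed base seed.
#' @param raster_step density raster cell size (defaults to the scan step).
#' @param checkpoint_path optional `.rds` path; partial results are saved
#'   every `checkpoint_every` replicates and reloaded on restart.
#' @param checkpoint_every checkpoint interval in replicates.
#' @param verbose print progress.
#' @return an object of class `null_densities`: integer matrix `densities`
#'   (cells x replicates), the raster, `n_reps` and `seed`.
#' @export
simulate_null <- function(scan, n_reps = 10000L, seed = 1L,
                          raster_step = scan$settings$step,
                          checkpoint_path = NULL,
                          checkpoint_every = 200L, verbose = FALSE) {
  stopifnot(inherits(scan, "scan_result"))
  raster <- density_raster(scan, raster_step)
  cov <- coverage_matrix(scan, raster)
  n <- nrow(scan$coords)
  p <- length(scan$variable_ids)
  st <- scan$settings
  members <- scan$members
  n_sub <- length(members)
  folds_by_size <- list()
  for (m in unique(lengths(members))) {
    folds_by_size[[as.character(m)]] <-
      cv_folds(m, min(st$k_folds, m), st$fold_seed)
  }

  dens <- matrix(NA_integer_, nrow(raster$cells), n_reps)
  start_rep <- 1L
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    ck <- readRDS(checkpoint_path)
    if (ck$seed == seed && ck$n_reps == n_reps &&
        nrow(ck$densities) == nrow(dens)) {
      dens[, seq_len(ck$done)] <- ck$densities[, seq_len(ck$done)]
      start_rep <- ck$done + 1L
    }
  }

  for (r in seq(from = start_rep, length.out = max(0L, n_reps - start_rep + 1L))) {
    D <- with_private_seed(seed + r, matrix(stats::rnorm(n * p), n, p))
    sig <- logical(n_sub)
    for (i in seq_len(n_sub)) {
      mem <- members[[i]]
      cv <- cross_validate(D[mem, , drop = FALSE], kind = "ep",
                           n_ortho = st$n_ortho,
                           select_vars = st$select_vars, alpha = st$alpha,
                           folds = folds_by_size[[as.character(length(mem))]])
      sig[i] <- !is.na(cv$p_cvanova) && cv$p_cvanova < st$alpha
    }
    dens[, r] <- if (any(sig)) {
      as.integer(rowSums(cov[, sig, drop = FALSE]))
    } else {
      0L
    }
    if (!is.null(checkpoint_path) &&
        (r %% checkpoint_every == 0L || r == n_reps)) {
      saveRDS(list(seed = seed, n_reps = n_reps, done = r,
                   densities = dens), checkpoint_path)
    }
    if (verbose && r %% 50L == 0L) {
      message("null replicate ", r, "/", n_reps)
    }
  }

  structure(list(densities = dens, ttd = raster$ttd, tbs = raster$tbs,
                 step = raster$step, n_reps = n_reps, seed = seed),
            class = "null_densities")
}

prob_levels <- c("<0.001", "<0.01", "<0.05", "<0.10", "<0.20", ">0.20")

#' Null-calibrated probability map
#'
#' Converts an observed significant-subset density map into per-cell
#' probabilities of seeing the same or higher density under the random-data
#' null, using the add-one estimator
#' `p = (1 + #\{replicates >= observed\}) / (1 + n_reps)` (never exactly
#' zero), and discretizes them into the six display levels `"<0.001"`,
#' `"<0.01"`, `"<0.05"`, `"<0.10"`, `"<0.20"`, `">0.20"`. Cells with zero
#' observed density are reported as `">0.20"`.
#'
#' @param observed a `density_map` of the real data.
#' @param nulls a `null_densities` object on the same raster.
#' @return an object of class `probability_map` with matrices `p` and
#'   `level`.
#' @export
probability_map <- function(observed, nulls) {
  stopifnot(inherits(observed, "density_map"),
            inherits(nulls, "null_densities"))
  if (!isTRUE(all.equal(observed$ttd, nulls$ttd)) ||
      !isTRUE(all.equal(observed$tbs, nulls$tbs))) {
    stop("raster mismatch between observed map and null densities")
  }
  obs <- as.vector(observed$counts)
  exceed <- rowSums(nulls$densities >= obs)
  p_hat <- (1 + exceed) / (1 + nulls$n_reps)
  p_hat[obs <= 0] <- 1
  lev <- ifelse(p_hat < 0.001, "<0.001",
         ifelse(p_hat < 0.01, "<0.01",
         ifelse(p_hat < 0.05, "<0.05",
         ifelse(p_hat < 0.10, "<0.10",
         ifelse(p_hat < 0.20, "<0.20", ">0.20")))))
  structure(list(ttd = observed$ttd, tbs = observed$tbs,
                 p = matrix(p_hat, length(observed$ttd)),
                 level = matrix(factor(lev, levels = prob_levels),
                                length(observed$ttd)),
                 n_reps = nulls$n_reps, step = observed$step),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat("probability_map: ", length(x$ttd), " x ", length(x$tbs),
      " cells, ", x$n_reps, " null replicates\n", sep = "")
  print(table(x$level))
  invisible(x)
}
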