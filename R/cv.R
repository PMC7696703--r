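#' Deterministic cross-validation folds
#'
#' Assigns observations to `k` balanced folds through a seeded permutation,
#' so the same `(n, k, seed)` always yields the same partition. The
#' assignment is computed with a private RNG stream; the global RNG state is
#' left untouched.
#'
#' @param n number of observations.
#' @param k number of folds (`k <= n`).
#' @param seed integer fold seed.
#' @return integer vector of fold labels in `1:k`.
#' @export
cv_folds <- function(n, k, seed = 1L) {
  if (k > n) stop("k_folds must not exceed the number of observations")
  perm <- with_private_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(k), n)
  fold
}

# run code under a temporary RNG state; restores the caller's stream
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Cross-validate an OPLS model with per-fold variable selection
#'
#' In every cross-validation round a model is fitted on the training part
#' only; when `select_vars` is `TRUE`, the variables reaching both loading
#' significance criteria in that round (paired-t "w" and cosine-similarity
#' "p", two-sided p < `alpha`, computed on the training fold) are kept, the
#' model is refitted on them, and the held-out responses are predicted.
#' Predictive ability is `Q2 = 1 - PRESS / SS(y)` over the pooled held-out
#' predictions; for uncentered effect-projection data `SS(y)` is the
#' uncorrected sum of squares of the unit response.
#'
#' If some round selects no variable the model is declared non-computable
#' and a sentinel result (`computable = FALSE`, `Q2 = NA`,
#' `p_cvanova = NA`) is returned rather than an error.
#'
#' @param D paired-difference matrix (EP) or predictor matrix (DA); a
#'   `paired_cohort` is accepted.
#' @param kind `"ep"` (constant unit response, uncentered sd scaling) or
#'   `"da"` (two-class response, centered pooled-sd scaling).
#' @param y response vector, required for `kind = "da"`.
#' @param n_ortho orthogonal components per fitted model.
#' @param k_folds number of folds (default 7, the chemometrics convention).
#' @param select_vars apply the per-round w/p variable selection.
#' @param alpha per-round selection level.
#' @param fold_seed seed for the fold partition.
#' @param folds optional explicit fold assignment (overrides `fold_seed`).
#' @return an object of class `cv_result` with elements `y`, `y_pred`,
#'   `Q2`, `press`, `p_cvanova`, `F_stat`, `selected_vars_per_fold`,
#'   `computable`, `n_components` and `settings`.
#' @export
cross_validate <- function(D, kind = c("ep", "da"), y = NULL, n_ortho = 0L,
                           k_folds = 7L, select_vars = TRUE, alpha = 0.05,
                           fold_seed = 1L, folds = NULL) {
  kind <- match.arg(kind)
  if (inherits(D, "paired_cohort")) D <- D$d
  D <- as.matrix(D)
  n <- nrow(D)
  if (kind == "ep") {
    y <- rep(1, n)
  } else {
    if (is.null(y)) stop("kind = 'da' requires a response vector y")
    y <- as.numeric(y)
  }
  if (is.null(folds)) folds <- cv_folds(n, k_folds, fold_seed)
  k_eff <- length(unique(folds))

  y_pred <- rep(NA_real_, n)
  selected <- vector("list", k_eff)
  computable <- TRUE
  fold_levels <- sort(unique(folds))

  for (fi in seq_along(fold_levels)) {
    test <- which(folds == fold_levels[fi])
    train <- which(folds != fold_levels[fi])
    fit <- cv_fit_fold(D[train, , drop = FALSE], y[train], kind, n_ortho,
                       select_vars, alpha)
    if (is.null(fit)) {
      computable <- FALSE
      selected[[fi]] <- integer(0)
      next
    }
    selected[[fi]] <- fit$selected
    y_pred[test] <- cv_predict_fold(fit, D[test, , drop = FALSE])
  }

  n_components <- 1L + n_ortho
  if (computable) {
    press <- sum((y - y_pred)^2)
    ss <- if (kind == "ep") sum(y^2) else sum((y - mean(y))^2)
    q2 <- 1 - press / ss
    an <- cv_anova_stat(y, y_pred, n_components, kind)
  } else {
    press <- NA_real_
    q2 <- NA_real_
    an <- list(p = NA_real_, F_stat = NA_real_, df1 = NA_integer_,
               df2 = NA_integer_, perfect_fit = FALSE)
  }

  structure(list(y = y, y_pred = y_pred, Q2 = q2, press = press,
                 p_cvanova = an$p, F_stat = an$F_stat,
                 df = c(an$df1, an$df2), perfect_fit = an$perfect_fit,
                 selected_vars_per_fold = selected,
                 computable = computable,
                 n_components = n_components,
                 settings = list(kind = kind, n_ortho = n_ortho,
                                 k_folds = k_eff,
                                 select_vars = select_vars, alpha = alpha,
                                 fold_seed = fold_seed)),
            class = "cv_result")
}

# Fit one cross-validation round; returns NULL when selection leaves no
# variable (the non-computable sentinel bubbles up from here).
cv_fit_fold <- function(Dtr, ytr, kind, n_ortho, select_vars, alpha) {
  n_tr <- nrow(Dtr)
  if (kind == "ep") {
    ctr <- NULL
    s <- col_sds(Dtr)
  } else {
    ctr <- colMeans(Dtr)
    s <- pooled_or_plain_sd(Dtr, ytr)
    y_ctr <- mean(ytr)
    ytr <- ytr - y_ctr
  }
  valid <- which(s > 0)
  if (length(valid) == 0L) return(NULL)
  Xs <- Dtr[, valid, drop = FALSE]
  if (!is.null(ctr)) Xs <- sweep(Xs, 2L, ctr[valid])
  Xs <- sweep(Xs, 2L, s[valid], "/")

  fit1 <- ep_core_fit(Xs, ytr, n_ortho)
  if (is.null(fit1)) return(NULL)

  if (select_vars) {
    if (kind == "ep") {
      m <- colMeans(Dtr[, valid, drop = FALSE])
      sv <- s[valid]
      t_w <- m / (sv / sqrt(n_tr))
      p_w <- 2 * stats::pt(abs(t_w), df = n_tr - 1L, lower.tail = FALSE)
      yhat <- fit1$fitted
      denom <- sqrt(colSums(Xs^2)) * sqrt(sum(yhat^2))
      cs <- drop(crossprod(Xs, yhat)) / denom
    } else {
      # DA analogue: two-sample t on the raw column and centered cosine
      # (Pearson) against the fitted response
      t_w <- two_sample_t(Dtr[, valid, drop = FALSE], ytr)
      p_w <- 2 * stats::pt(abs(t_w), df = n_tr - 2L, lower.tail = FALSE)
      yhat <- fit1$fitted
      Xc <- sweep(Xs, 2L, colMeans(Xs))
      yc <- yhat - mean(yhat)
      denom <- sqrt(colSums(Xc^2)) * sqrt(sum(yc^2))
      cs <- drop(crossprod(Xc, yc)) / denom
    }
    cs <- pmax(-1, pmin(1, cs))
    t_p <- ifelse(abs(cs) < 1, cs * sqrt(n_tr - 1) / sqrt(1 - cs^2), Inf)
    p_p <- ifelse(is.finite(t_p),
                  2 * stats::pt(abs(t_p), df = n_tr - 2L,
                                lower.tail = FALSE), 0)
    keep <- which(!is.na(p_w) & p_w < alpha & !is.na(p_p) & p_p < alpha)
    if (length(keep) == 0L) return(NULL)
    Xs <- Xs[, keep, drop = FALSE]
    fit1 <- ep_core_fit(Xs, ytr, n_ortho)
    if (is.null(fit1)) return(NULL)
    selected <- valid[keep]
  } else {
    selected <- valid
  }

  list(core = fit1, selected = selected, center = ctr, scale = s,
       kind = kind,
       y_center = if (kind == "da") y_ctr else 0)
}

cv_predict_fold <- function(fit, Dte) {
  Xs <- Dte[, fit$selected, drop = FALSE]
  if (!is.null(fit$center)) Xs <- sweep(Xs, 2L, fit$center[fit$selected])
  Xs <- sweep(Xs, 2L, fit$scale[fit$selected], "/")
  core <- fit$core
  for (i in seq_len(ncol(core$W_o))) {
    t_o <- Xs %*% core$W_o[, i]
    Xs <- Xs - tcrossprod(t_o, core$P_o[, i])
  }
  drop(Xs %*% core$w) * core$b + fit$y_center
}

# minimal OPLS fit used inside the CV loop (no class construction overhead)
ep_core_fit <- function(Xs, y, n_ortho) {
  W_o <- P_o <- matrix(0, ncol(Xs), 0L)
  Xd <- Xs
  for (i in seq_len(n_ortho)) {
    w <- crossprod(Xd, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) return(NULL)
    w <- w / nw
    t_p <- Xd %*% w
    p_l <- crossprod(Xd, t_p) / sum(t_p^2)
    w_o <- p_l - drop(crossprod(w, p_l)) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-10) return(NULL)
    w_o <- w_o / nwo
    t_o <- Xd %*% w_o
    p_o <- crossprod(Xd, t_o) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
  }
  w <- crossprod(Xd, y)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) return(NULL)
  w <- w / nw
  t_p <- drop(Xd %*% w)
  sst <- sum(t_p^2)
  b <- sum(t_p * y) / sst
  list(w = drop(w), b = b, W_o = W_o, P_o = P_o, fitted = b * t_p)
}

pooled_or_plain_sd <- function(X, y) {
  cls <- unique(y)
  if (length(cls) == 2L) {
    X1 <- X[y == cls[1L], , drop = FALSE]
    X2 <- X[y == cls[2L], , drop = FALSE]
    ss1 <- colSums(sweep(X1, 2L, colMeans(X1))^2)
    ss2 <- colSums(sweep(X2, 2L, colMeans(X2))^2)
    sqrt((ss1 + ss2) / (nrow(X) - 2L))
  } else {
    col_sds(X)
  }
}

two_sample_t <- function(X, y) {
  cls <- sort(unique(y))
  X1 <- X[y == cls[1L], , drop = FALSE]
  X2 <- X[y == cls[2L], , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  sp2 <- (colSums(sweep(X1, 2L, colMeans(X1))^2) +
            colSums(sweep(X2, 2L, colMeans(X2))^2)) / (n1 + n2 - 2L)
  (colMeans(X2) - colMeans(X1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' CV-ANOVA significance of a cross-validated model
#'
#' Analysis of variance of the cross-validated residuals: the total
#' variation of the response is decomposed into the part explained by the
#' cross-validated predictions and the predictive residual sum of squares
#' (PRESS), and compared with an F test.
#'
#' Degrees of freedom follow the CV-ANOVA scheme for projection models:
#' with `A` model components and `n` observations, the regression is
#' charged `A` degrees of freedom and the residuals keep the rest. For a
#' centered response the total carries `n - 1` degrees of freedom; for the
#' uncentered unit response of effect projections it carries `n`, so the
#' residual degrees of freedom are `n - 1 - A` and `n - A` respectively.
#' `F = (SS_reg / A) / (PRESS / df_res)` is referred to the upper tail of
#' `F(A, df_res)`. A PRESS of zero returns `p = 0` with a perfect-fit flag;
#' a PRESS exceeding the total variation gives `F = 0`, `p = 1`.
#'
#' @param cv a `cv_result` from [cross_validate()].
#' @param n_components number of model components `A` (defaults to the
#'   fitted `1 + n_ortho`).
#' @return the CV-ANOVA p-value, with attributes `F_stat`, `df` and
#'   `perfect_fit`.
#' @export
cv_anova <- function(cv, n_components = cv$n_components) {
  stopifnot(inherits(cv, "cv_result"))
  if (!cv$computable) {
    out <- NA_real_
    attr(out, "perfect_fit") <- FALSE
    return(out)
  }
  an <- cv_anova_stat(cv$y, cv$y_pred, n_components, cv$settings$kind)
  out <- an$p
  attr(out, "F_stat") <- an$F_stat
  attr(out, "df") <- c(an$df1, an$df2)
  attr(out, "perfect_fit") <- an$perfect_fit
  out
}

cv_anova_stat <- function(y, y_pred, n_components, kind) {
  n <- length(y)
  centered <- kind != "ep"
  ss_tot <- if (centered) sum((y - mean(y))^2) else sum(y^2)
  df_res <- if (centered) n - 1L - n_components else n - n_components
  press <- sum((y - y_pred)^2)
  if (df_res <= 0) stop("rank error: too many components for n")
  if (press == 0) {
    return(list(p = 0, F_stat = Inf, df1 = n_components, df2 = df_res,
                perfect_fit = TRUE))
  }
  ss_reg <- ss_tot - press
  if (ss_reg <= 0) {
    return(list(p = 1, F_stat = 0, df1 = n_components, df2 = df_res,
                perfect_fit = FALSE))
  }
  f_stat <- (ss_reg / n_components) / (press / df_res)
  list(p = stats::pf(f_stat, n_components, df_res, lower.tail = FALSE),
       F_stat = f_stat, df1 = n_components, df2 = df_res,
       perfect_fit = FALSE)
}

#' @export
print.cv_result <- function(x, ...) {
  if (x$computable) {
    cat(sprintf("cv_result: Q2 = %.3f, CV-ANOVA p = %.3g (%d folds)\n",
                x$Q2, x$p_cvanova, x$settings$k_folds))
  } else {
    cat("cv_result: non-computable (a round selected no variables)\n")
  }
  invisible(x)
}
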