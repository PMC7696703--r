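#' Effect-projection scaling
#'
#' Scales each column by its sample standard deviation (n - 1 denominator)
#' without centering. Paired-difference data keep their natural origin at
#' zero ("no change"), so centering would discard the effect of interest.
#'
#' @param D numeric matrix of paired differences.
#' @return list with `X` (scaled matrix) and `scaling` (record with
#'   `center = NULL` and per-variable `scale` divisors).
#' @export
scale_ep <- function(D) {
  D <- as.matrix(D)
  s <- col_sds(D)
  if (any(s == 0)) {
    bad <- colnames(D)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop("degenerate variable(s) with zero standard deviation: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(X = sweep(D, 2L, s, "/"),
       scaling = list(center = NULL, scale = s))
}

#' Unit-variance scaling for discriminant models
#'
#' Centers each column at its mean and divides by the class-pooled sample
#' standard deviation (the square root of the within-class variance pooled
#' over the two groups). With `y = NULL` the ordinary sample standard
#' deviation is used.
#'
#' @param X numeric matrix.
#' @param y optional two-level class vector used to pool the variance.
#' @return list with `X` (scaled matrix) and `scaling` record.
#' @export
scale_uv <- function(X, y = NULL) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  if (is.null(y)) {
    s <- col_sds(X)
  } else {
    cls <- unique(y)
    if (length(cls) != 2L) stop("pooled scaling needs exactly two classes")
    X1 <- X[y == cls[1L], , drop = FALSE]
    X2 <- X[y == cls[2L], , drop = FALSE]
    n1 <- nrow(X1); n2 <- nrow(X2)
    ss1 <- colSums(sweep(X1, 2L, colMeans(X1))^2)
    ss2 <- colSums(sweep(X2, 2L, colMeans(X2))^2)
    s <- sqrt((ss1 + ss2) / (n1 + n2 - 2L))
  }
  if (any(s == 0)) {
    bad <- colnames(X)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop("degenerate variable(s) with zero standard deviation: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2L, ctr), 2L, s, "/")
  list(X = Xs, scaling = list(center = ctr, scale = s))
}

col_sds <- function(X) {
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows to estimate standard deviations")
  m <- colMeans(X)
  sqrt(colSums(sweep(X, 2L, m)^2) / (n - 1L))
}

#' Fit a single-response OPLS model
#'
#' NIPALS-style orthogonal projections to latent structures for one
#' response. Variation in `X` orthogonal to `y` is removed as `n_ortho`
#' sequential components before the final predictive component is fitted:
#' the predictive weight vector `w` is proportional to `X'y` (unit norm),
#' scores are `t = Xw`, loadings `p = X't/t't`, and the inner relation
#' coefficient `b = t'y/t't` maps scores to the response.
#'
#' `X` is used as supplied; apply [scale_ep()] or [scale_uv()] first (the
#' scaling record may be attached via `scaling` so [predict.opls_model()]
#' can reproduce it on new data).
#'
#' @param X numeric matrix, already scaled.
#' @param y numeric response vector.
#' @param n_ortho number of orthogonal components to remove (>= 0).
#' @param scaling optional scaling record from [scale_ep()]/[scale_uv()].
#' @return an object of class `opls_model`.
#' @export
fit_opls <- function(X, y, n_ortho = 0L, scaling = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (nrow(X) < 3L) stop("sample-size error: need at least 3 observations")
  tol <- 1e-12

  p_dim <- ncol(X)
  W_o <- matrix(0, p_dim, 0L)
  P_o <- matrix(0, p_dim, 0L)
  T_o <- matrix(0, nrow(X), 0L)
  Xd <- X
  for (i in seq_len(n_ortho)) {
    w <- crossprod(Xd, y)
    nw <- sqrt(sum(w^2))
    if (nw < tol) stop("rank error: response orthogonal to X")
    w <- w / nw
    t_p <- Xd %*% w
    p_l <- crossprod(Xd, t_p) / sum(t_p^2)
    w_o <- p_l - drop(crossprod(w, p_l)) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-10) {
      stop("rank error: no orthogonal variation left for component ", i,
           call. = FALSE)
    }
    w_o <- w_o / nwo
    t_o <- Xd %*% w_o
    p_o <- crossprod(Xd, t_o) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
  }

  w <- crossprod(Xd, y)
  nw <- sqrt(sum(w^2))
  if (nw < tol) stop("rank error: response orthogonal to X")
  w <- w / nw
  t_p <- drop(Xd %*% w)
  sst <- sum(t_p^2)
  p_l <- drop(crossprod(Xd, t_p)) / sst
  b <- sum(t_p * y) / sst

  structure(list(w = drop(w), p = p_l, t = t_p, b = b,
                 W_o = W_o, P_o = P_o, T_o = T_o,
                 n_ortho = n_ortho,
                 fitted = b * t_p, y = y,
                 scaling = scaling,
                 variable_ids = colnames(X)),
            class = "opls_model")
}

#' Fit an OPLS effect-projection (EP) model
#'
#' Effect projections treat each matched pair's difference vector as one
#' dependent observation and regress the constant unit response on the
#' sd-scaled, uncentered differences. A systematic effect shared by the
#' pairs then surfaces as a predictive component whose single-variable
#' t-statistic is exactly the paired two-tailed t-test.
#'
#' @param D a `paired_cohort` or a numeric paired-difference matrix.
#' @param n_ortho orthogonal components beyond the predictive one.
#' @return an `opls_model` fitted on `scale_ep(D)` with response `rep(1, n)`.
#' @export
fit_opls_ep <- function(D, n_ortho = 0L) {
  if (inherits(D, "paired_cohort")) D <- D$d
  D <- as.matrix(D)
  if (nrow(D) < 3L) {
    stop("sample-size error: effect-projection fit needs >= 3 pairs",
         call. = FALSE)
  }
  sc <- scale_ep(D)
  fit_opls(sc$X, rep(1, nrow(D)), n_ortho = n_ortho, scaling = sc$scaling)
}

#' Predict responses for new observations
#'
#' Applies the model's scaling record to `newdata`, removes the fitted
#' orthogonal components, and returns predictive scores and predicted
#' responses.
#'
#' @param object an `opls_model`.
#' @param newdata matrix (or `paired_cohort`) with the model's variables.
#' @param ... unused.
#' @return list with `t` (predictive scores) and `y_pred` (`b * t`).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "paired_cohort")) newdata <- newdata$d
  newdata <- as.matrix(newdata)
  vid <- object$variable_ids
  if (!is.null(vid)) {
    if (!is.null(colnames(newdata))) {
      if (!all(vid %in% colnames(newdata))) {
        stop("schema error: newdata lacks model variable(s): ",
             paste(setdiff(vid, colnames(newdata)), collapse = ", "),
             call. = FALSE)
      }
      newdata <- newdata[, vid, drop = FALSE]
    } else if (ncol(newdata) != length(vid)) {
      stop("schema error: newdata has ", ncol(newdata),
           " variables, model expects ", length(vid), call. = FALSE)
    }
  }
  if (!is.null(object$scaling)) {
    if (!is.null(object$scaling$center)) {
      newdata <- sweep(newdata, 2L, object$scaling$center)
    }
    newdata <- sweep(newdata, 2L, object$scaling$scale, "/")
  }
  Xd <- newdata
  for (i in seq_len(object$n_ortho)) {
    t_o <- Xd %*% object$W_o[, i]
    Xd <- Xd - tcrossprod(t_o, object$P_o[, i])
  }
  t_p <- drop(Xd %*% object$w)
  list(t = t_p, y_pred = object$b * t_p)
}

#' @export
print.opls_model <- function(x, ...) {
  cat("opls_model: ", length(x$w), " variables, 1 predictive + ",
      x$n_ortho, " orthogonal component(s)\n", sep = "")
  invisible(x)
}
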