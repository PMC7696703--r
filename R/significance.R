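#' Paired t-statistic for one difference variable (the "w" criterion)
#'
#' The per-variable significance attached to the predictive weights of an
#' effect-projection model is the paired two-tailed Student t-test on the
#' difference data: `t = mean / (sd / sqrt(n))` with `n - 1` degrees of
#' freedom. The statistic is invariant to the sd-scaling used for the fit,
#' so it can be computed on raw or scaled columns alike.
#'
#' @param d_col numeric vector of paired differences for one variable.
#' @return list with `t`, `p` and `df`; a zero-sd column yields `t = NA`
#'   (undefined-statistic sentinel) with `p = NA`.
#' @export
w_statistic <- function(d_col) {
  n <- length(d_col)
  if (n < 2L) stop("need at least 2 observations")
  s <- stats::sd(d_col)
  if (s == 0) return(list(t = NA_real_, p = NA_real_, df = n - 1L))
  t_stat <- mean(d_col) / (s / sqrt(n))
  list(t = t_stat,
       p = 2 * stats::pt(abs(t_stat), df = n - 1L, lower.tail = FALSE),
       df = n - 1L)
}

#' t-statistic for a cosine similarity (the "p" criterion)
#'
#' Converts the cosine similarity `cs` between a variable column and the
#' model-estimated response into a t-statistic,
#' `t = cs * sqrt(n - 1) / sqrt(1 - cs^2)`, tested two-tailed with `n - 2`
#' degrees of freedom.
#'
#' @param cs cosine similarity in `[-1, 1]`.
#' @param n number of observations (>= 3).
#' @return list with `t`, `p` and `df`; `|cs| = 1` yields an infinite-t
#'   sentinel with `p = 0`.
#' @export
cosine_t <- function(cs, n) {
  if (n < 3L) stop("need at least 3 observations")
  if (abs(cs) > 1 + 1e-12) stop("cosine similarity outside [-1, 1]")
  cs <- max(-1, min(1, cs))
  if (abs(cs) == 1) {
    return(list(t = sign(cs) * Inf, p = 0, df = n - 2L))
  }
  t_stat <- cs * sqrt(n - 1) / sqrt(1 - cs^2)
  list(t = t_stat,
       p = 2 * stats::pt(abs(t_stat), df = n - 2L, lower.tail = FALSE),
       df = n - 2L)
}

#' Per-variable loading statistics for an effect-projection model
#'
#' Computes, for every variable of a paired-difference matrix, the two
#' loading-based criteria: the paired t on the raw difference column (the
#' "w" statistic) and the cosine-similarity t between the sd-scaled,
#' uncentered column and the model-estimated response (the "p" statistic).
#' Cosines are uncentered because effect-projection data are uncentered.
#'
#' @param D paired-difference matrix (raw, unscaled) or `paired_cohort`.
#' @param model an `opls_model` fitted on `scale_ep(D)`; if `NULL`, a
#'   one-component EP model is fitted internally.
#' @return data frame with one row per variable: `variable`, `t_w`, `p_w`,
#'   `cs`, `t_p`, `p_p`, `direction` (sign of the mean difference).
#' @export
variable_stats <- function(D, model = NULL) {
  if (inherits(D, "paired_cohort")) D <- D$d
  D <- as.matrix(D)
  if (is.null(model)) model <- fit_opls_ep(D)
  n <- nrow(D)
  m <- colMeans(D)
  s <- col_sds(D)
  t_w <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
  p_w <- 2 * stats::pt(abs(t_w), df = n - 1L, lower.tail = FALSE)

  Xs <- sweep(D, 2L, ifelse(s > 0, s, 1), "/")
  yhat <- model$fitted
  denom <- sqrt(colSums(Xs^2)) * sqrt(sum(yhat^2))
  cs <- ifelse(denom > 0, drop(crossprod(Xs, yhat)) / denom, NA_real_)
  cs <- pmax(-1, pmin(1, cs))
  t_p <- ifelse(abs(cs) < 1, cs * sqrt(n - 1) / sqrt(1 - cs^2),
                sign(cs) * Inf)
  p_p <- ifelse(is.finite(t_p),
                2 * stats::pt(abs(t_p), df = n - 2L, lower.tail = FALSE), 0)
  p_p[is.na(cs)] <- NA_real_

  vars <- colnames(D)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(D)))
  data.frame(variable = vars, t_w = t_w, p_w = p_w, cs = cs,
             t_p = t_p, p_p = p_p,
             direction = sign(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multivariate-significance flags for a variable-statistics table
#'
#' A variable is multivariate significant only inside a significant model:
#' the model's CV-ANOVA p-value must be below `alpha`, and both per-variable
#' criteria (`p_w`, `p_p`) must be below `alpha`.
#'
#' @param p_cvanova model-level CV-ANOVA p-value (`NA` for non-computable
#'   models; treated as non-significant).
#' @param stats data frame from [variable_stats()].
#' @param alpha significance level for model and variables.
#' @param fdr_q false-discovery-rate level for the `fdr` flag on `p_w`.
#' @return `stats` with added logical columns `univariate`, `fdr`,
#'   `multivariate`.
#' @export
multivariate_flags <- function(p_cvanova, stats, alpha = 0.05, fdr_q = 0.2) {
  model_sig <- !is.na(p_cvanova) && p_cvanova < alpha
  stats$univariate <- !is.na(stats$p_w) & stats$p_w < alpha
  stats$fdr <- stats$univariate & bh_fdr(stats$p_w, q = fdr_q)
  stats$multivariate <- model_sig & stats$univariate &
    !is.na(stats$p_p) & stats$p_p < alpha
  stats
}

#' Benjamini-Hochberg false-discovery-rate selection
#'
#' Standard step-up procedure: variables whose BH-adjusted p-value is at
#' most `q` are selected.
#'
#' @param pvals numeric p-values (`NA` allowed, never selected).
#' @param q FDR level.
#' @return logical vector of selections.
#' @export
bh_fdr <- function(pvals, q = 0.2) {
  adj <- stats::p.adjust(pvals, method = "BH")
  !is.na(adj) & adj <= q
}

#' Write a variable-statistics table as TSV
#'
#' @param stats data frame from [variable_stats()] /
#'   [multivariate_flags()].
#' @param path output path.
#' @export
write_variable_stats <- function(stats, path) {
  write_tsv(stats, path)
  invisible(path)
}
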