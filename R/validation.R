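#' Train a latent biomarker on the discovery region of interest
#'
#' The latent biomarker is the panel of variables selected by the scan plus
#' the one-component effect-projection model that scores new paired
#' differences with it. The model is trained on the discovery cohort's
#' pairs inside the region of interest, restricted to the panel.
#'
#' @param cohort discovery `paired_cohort` (from [disease_progress()]).
#' @param panel character vector of panel variable ids.
#' @param roi numeric `(ttd_max, tbs_max)` region of interest in years.
#' @param window positive-condition threshold in years of time to
#'   diagnosis, used by downstream evaluation.
#' @return an object of class `latent_biomarker` holding the panel, the
#'   trained `opls_model`, the region and the window.
#' @export
latent_biomarker <- function(cohort, panel, roi, window = 8) {
  stopifnot(inherits(cohort, "paired_cohort"))
  inside <- cohort$ttd < roi[1L] &
    (is.na(cohort$tbs) | cohort$tbs < roi[2L])
  if (sum(inside) < 3L) {
    stop("region of interest contains fewer than 3 observations")
  }
  sub <- subset_cohort(cohort, pairs = which(inside), variables = panel)
  model <- fit_opls_ep(sub, n_ortho = 0L)
  structure(list(panel = sub$variable_ids, model = model, roi = roi,
                 window = window),
            class = "latent_biomarker")
}

#' Score a validation cohort with a latent biomarker
#'
#' Projects the paired case-control differences of an independent cohort
#' onto the trained effect-projection model, restricted to the panel, and
#' returns one predicted response per pair. Effect-projection models are
#' uncentered, so a pair with identical case and control values scores
#' exactly zero and scores are linear in the difference vector.
#'
#' @param biomarker a `latent_biomarker`.
#' @param cohort validation `paired_cohort` (typically from
#'   [case_control_difference()]).
#' @return numeric vector of per-pair scores (names = pair ids).
#' @export
score_validation <- function(biomarker, cohort) {
  stopifnot(inherits(biomarker, "latent_biomarker"),
            inherits(cohort, "paired_cohort"))
  missing_vars <- setdiff(biomarker$panel, cohort$variable_ids)
  if (length(missing_vars) > 0L) {
    stop("validation cohort lacks panel variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  sub <- subset_cohort(cohort, variables = biomarker$panel)
  scores <- predict(biomarker$model, sub$d)$y_pred
  names(scores) <- cohort$pair_ids
  scores
}

#' Dependent t-test of biomarker scores inside a time window
#'
#' One-sample t-test of the scores of pairs with time to diagnosis below
#' `window` years. Because each score is already a case-minus-control
#' paired contrast, the one-sample test on scores is the dependent t-test
#' between matched cases and controls in the window.
#'
#' @param scores per-pair scores from [score_validation()].
#' @param ttd per-pair time to diagnosis in years.
#' @param window window width in years.
#' @return list with `t`, `p`, `df` and `n_pairs`; all-constant scores
#'   return an undefined-statistic sentinel (`t = NA`).
#' @export
window_ttest <- function(scores, ttd, window = 8) {
  stopifnot(length(scores) == length(ttd))
  s <- scores[ttd < window]
  if (length(s) < 2L) stop("fewer than 2 pairs inside the window")
  if (stats::sd(s) == 0) {
    return(list(t = NA_real_, p = NA_real_, df = length(s) - 1L,
                n_pairs = length(s)))
  }
  tt <- stats::t.test(s)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n_pairs = length(s))
}

#' ROC evaluation of biomarker scores
#'
#' Empirical ROC over score thresholds with pairs closer than `window`
#' years to diagnosis as the positive condition; AUC by the trapezoid rule
#' (ties handled by midranks, so AUC equals the Mann-Whitney
#' `U / (n1 * n2)` statistic). Significance of the separation is assessed
#' by a rank test between the two groups: by default the rank-sum
#' (Mann-Whitney) test, which matches the two independent groups being
#' compared; a one-sample signed-rank test of the positive-group scores
#' against zero is available as an alternative.
#'
#' @param scores per-pair scores.
#' @param positive logical vector of positive-condition membership (e.g.
#'   `ttd < 8`).
#' @param rank_test `"rank_sum"` or `"signed_rank"`.
#' @return an object of class `validation_result`: `auc`, `roc` (data
#'   frame of specificity/sensitivity points), `p_rank`, `rank_test`,
#'   `n_pos`, `n_neg`, plus the inputs.
#' @export
roc_auc <- function(scores, positive,
                    rank_test = c("rank_sum", "signed_rank")) {
  rank_test <- match.arg(rank_test)
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  if (!any(positive) || all(positive)) {
    stop("both classes must be non-empty for ROC analysis")
  }
  r <- pROC::roc(response = positive, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  roc_df <- data.frame(specificity = r$specificities,
                       sensitivity = r$sensitivities)
  roc_df <- roc_df[order(1 - roc_df$specificity, roc_df$sensitivity), ]
  p_rank <- if (rank_test == "rank_sum") {
    stats::wilcox.test(scores[positive], scores[!positive],
                       exact = FALSE)$p.value
  } else {
    stats::wilcox.test(scores[positive], mu = 0, exact = FALSE)$p.value
  }
  structure(list(auc = as.numeric(r$auc), roc = roc_df, p_rank = p_rank,
                 rank_test = rank_test,
                 n_pos = sum(positive), n_neg = sum(!positive),
                 scores = as.numeric(scores), positive = positive),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(
    "validation_result: AUC = %.3f (%s p = %.3g; %d positive / %d negative)\n",
    x$auc, x$rank_test, x$p_rank, x$n_pos, x$n_neg))
  invisible(x)
}
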