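#' Within-subject progression
#'
#' For every subject with a baseline and a repeated sample, the elementwise
#' progression is the repeated intensities minus the baseline intensities.
#' Subtracting the baseline normalizes stable individual differences and
#' emphasizes change over time.
#'
#' @param table a [sample_table()] from a repeated-time-point design.
#' @return numeric matrix, one row per subject (rownames = subject ids),
#'   one column per variable.
#' @export
progression <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  meta <- table$meta
  subjects <- unique(meta$subject_id)
  out <- matrix(NA_real_, nrow = length(subjects),
                ncol = ncol(table$values),
                dimnames = list(subjects, table$variable_ids))
  for (s in subjects) {
    i_base <- which(meta$subject_id == s & meta$timepoint == "baseline")
    i_rep <- which(meta$subject_id == s & meta$timepoint == "repeated")
    if (length(i_base) != 1L || length(i_rep) != 1L) {
      stop("pairing error: subject ", s,
           " must have exactly one baseline and one repeated sample",
           call. = FALSE)
    }
    out[s, ] <- table$values[i_rep, ] - table$values[i_base, ]
  }
  out
}

#' Case-control difference of progression patterns
#'
#' Builds the paired-difference cohort that all downstream effect-projection
#' models are fitted on. Per matched pair, the disease-progress vector is
#' the case subject's progression minus the control subject's progression;
#' subtracting the matched control's progression removes variation shared by
#' the pair (passage of time, storage, assay drift), leaving case-specific
#' change.
#'
#' Each pair also carries its two scan coordinates: `ttd`, the time to
#' diagnosis of the case's repeated (later) sample, and `tbs`, the time
#' between the case's baseline and repeated samples, both in years.
#'
#' @param table a [sample_table()] with baseline + repeated samples for
#'   every subject and a diagnosis time for every case.
#' @return a `paired_cohort`: list with `d` (pairs x variables matrix),
#'   `ttd`, `tbs`, `pair_ids`, `variable_ids`, `kind = "progress"`.
#' @export
disease_progress <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  prog <- progression(table)
  meta <- table$meta
  pair_ids <- sort(unique(meta$pair_id))
  p <- ncol(table$values)
  d <- matrix(NA_real_, length(pair_ids), p,
              dimnames = list(pair_ids, table$variable_ids))
  ttd <- tbs <- numeric(length(pair_ids))
  for (i in seq_along(pair_ids)) {
    m <- meta[meta$pair_id == pair_ids[i], ]
    case_subj <- unique(m$subject_id[m$group == "case"])
    ctrl_subj <- unique(m$subject_id[m$group == "control"])
    d[i, ] <- prog[case_subj, ] - prog[ctrl_subj, ]
    case_rep <- m[m$subject_id == case_subj & m$timepoint == "repeated", ]
    case_base <- m[m$subject_id == case_subj & m$timepoint == "baseline", ]
    if (is.na(case_rep$diagnosis_time)) {
      stop("metadata error: case subject ", case_subj,
           " in pair ", pair_ids[i], " lacks a diagnosis time", call. = FALSE)
    }
    ttd[i] <- case_rep$diagnosis_time - case_rep$sampling_time
    tbs[i] <- case_rep$sampling_time - case_base$sampling_time
  }
  new_paired_cohort(d, ttd, tbs, pair_ids, table$variable_ids,
                    kind = "progress")
}

#' Case-control difference for a single-time-point cohort
#'
#' For designs with one sample per subject, the paired difference is simply
#' case intensities minus matched-control intensities. The time between
#' repeated samples is undefined for this design and stored as `NA`.
#'
#' @param table a [sample_table()] whose samples all have
#'   `timepoint == "single"`.
#' @return a `paired_cohort` with `kind = "difference"` and `tbs = NA`.
#' @export
case_control_difference <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  meta <- table$meta
  if (!all(meta$timepoint == "single")) {
    stop("case_control_difference expects a single-time-point cohort",
         call. = FALSE)
  }
  pair_ids <- sort(unique(meta$pair_id))
  p <- ncol(table$values)
  d <- matrix(NA_real_, length(pair_ids), p,
              dimnames = list(pair_ids, table$variable_ids))
  ttd <- numeric(length(pair_ids))
  for (i in seq_along(pair_ids)) {
    m <- meta[meta$pair_id == pair_ids[i], ]
    i_case <- which(m$group == "case")
    i_ctrl <- which(m$group == "control")
    if (length(i_case) != 1L || length(i_ctrl) != 1L) {
      stop("pairing error: pair ", pair_ids[i],
           " must have one case and one control sample", call. = FALSE)
    }
    rows <- match(m$sample_id, meta$sample_id)
    d[i, ] <- table$values[rows[i_case], ] - table$values[rows[i_ctrl], ]
    if (is.na(m$diagnosis_time[i_case])) {
      stop("metadata error: case in pair ", pair_ids[i],
           " lacks a diagnosis time", call. = FALSE)
    }
    ttd[i] <- m$diagnosis_time[i_case] - m$sampling_time[i_case]
  }
  new_paired_cohort(d, ttd, rep(NA_real_, length(pair_ids)), pair_ids,
                    table$variable_ids, kind = "difference")
}

new_paired_cohort <- function(d, ttd, tbs, pair_ids, variable_ids, kind) {
  if (any(ttd <= 0)) {
    stop("metadata error: non-positive time to diagnosis for pair(s) ",
         paste(pair_ids[ttd <= 0], collapse = ", "), call. = FALSE)
  }
  if (kind == "progress" && any(tbs <= 0)) {
    stop("metadata error: non-positive time between samples for pair(s) ",
         paste(pair_ids[!is.na(tbs) & tbs <= 0], collapse = ", "),
         call. = FALSE)
  }
  structure(list(d = d, ttd = ttd, tbs = tbs, pair_ids = pair_ids,
                 variable_ids = variable_ids, kind = kind),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat("paired_cohort (", x$kind, "): ", nrow(x$d), " pairs x ",
      ncol(x$d), " variables\n", sep = "")
  cat("  time to diagnosis: ", sprintf("%.2f-%.2f", min(x$ttd), max(x$ttd)),
      " years\n", sep = "")
  if (!all(is.na(x$tbs))) {
    cat("  time between samples: ",
        sprintf("%.2f-%.2f", min(x$tbs), max(x$tbs)), " years\n", sep = "")
  }
  invisible(x)
}

# restrict a paired cohort to selected pairs and/or variables
subset_cohort <- function(cohort, pairs = NULL, variables = NULL) {
  stopifnot(inherits(cohort, "paired_cohort"))
  i <- if (is.null(pairs)) seq_len(nrow(cohort$d)) else pairs
  j <- if (is.null(variables)) seq_len(ncol(cohort$d)) else variables
  if (is.character(j)) {
    miss <- setdiff(j, cohort$variable_ids)
    if (length(miss) > 0L) {
      stop("unknown variable(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    j <- match(j, cohort$variable_ids)
  }
  new_paired_cohort(cohort$d[i, j, drop = FALSE], cohort$ttd[i],
                    cohort$tbs[i], cohort$pair_ids[i],
                    cohort$variable_ids[j], cohort$kind)
}
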