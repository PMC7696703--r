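#' Configuration for the synthetic matched-cohort generator
#'
#' The defaults emulate the discovery design that the scan was developed
#' on: 64 matched case-control pairs, each sampled at a baseline and a
#' repeated pre-diagnostic time point, 142 quantified variables, and a
#' case-specific increase in a 15-variable panel confined to the
#' rectangular region of the scan plane closer than 8 years to diagnosis
#' with less than 7 years between the repeated samples.
#'
#' @param n_pairs number of matched case-control pairs.
#' @param n_variables number of measured variables.
#' @param panel_size number of planted effect variables.
#' @param effect_size planted shift in units of the per-variable total
#'   (subject + noise) standard deviation.
#' @param roi_ttd,roi_tbs planted-effect rectangle bounds in years.
#' @param ttd_range,tbs_range uniform sampling ranges of the per-pair time
#'   coordinates, years.
#' @param taper_margin linear ramp width (years) over which the effect
#'   fades to zero at the rectangle boundary; 0 gives a hard edge.
#' @param subject_sd between-subject random-effect standard deviation.
#' @param noise_sd per-sample measurement noise standard deviation.
#' @param var_scale_range per-variable scale multipliers are drawn
#'   uniformly from this range, giving variables heterogeneous variances.
#' @param baseline_level_range per-variable mean intensities are drawn
#'   uniformly from this range (arbitrary positive units).
#' @param panel optional explicit panel: variable ids (`"var007"` style) or
#'   indices. `NULL` draws a random panel of `panel_size` variables. Pass
#'   the discovery truth panel when generating a matching validation
#'   cohort.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 64L, n_variables = 142L, panel_size = 15L,
                       effect_size = 1.5, roi_ttd = 8, roi_tbs = 7,
                       ttd_range = c(0.5, 12), tbs_range = c(0.5, 9),
                       taper_margin = 1, subject_sd = 1, noise_sd = 1,
                       var_scale_range = c(0.5, 2),
                       baseline_level_range = c(50, 150), panel = NULL,
                       seed = NULL) {
  stopifnot(n_pairs >= 3L, n_variables >= 1L,
            panel_size >= 0L, panel_size <= n_variables,
            effect_size >= 0, subject_sd >= 0, noise_sd >= 0,
            taper_margin >= 0,
            ttd_range[1L] > 0, ttd_range[2L] > ttd_range[1L],
            tbs_range[1L] > 0, tbs_range[2L] > tbs_range[1L],
            roi_ttd <= ttd_range[2L], roi_tbs <= tbs_range[2L])
  structure(list(n_pairs = as.integer(n_pairs),
                 n_variables = as.integer(n_variables),
                 panel_size = as.integer(panel_size),
                 effect_size = effect_size, roi_ttd = roi_ttd,
                 roi_tbs = roi_tbs, ttd_range = ttd_range,
                 tbs_range = tbs_range, taper_margin = taper_margin,
                 subject_sd = subject_sd, noise_sd = noise_sd,
                 var_scale_range = var_scale_range,
                 baseline_level_range = baseline_level_range,
                 panel = panel, seed = seed),
            class = "sim_config")
}

# linear ramp: 1 well inside the boundary, 0 at and beyond it
taper_factor <- function(x, x_max, margin) {
  if (margin == 0) return(as.numeric(x < x_max))
  pmin(1, pmax(0, (x_max - x) / margin))
}

#' Generate a synthetic repeated-time-point cohort
#'
#' Draws per-pair time coordinates uniformly over the configured ranges;
#' every sample value is a variable-level mean plus a subject random effect
#' plus measurement noise. Cases additionally receive the planted shift on
#' the panel variables in their repeated sample only — so the within-pair
#' progression differences concentrate the effect — if and only if the
#' pair falls inside the planted rectangle, with a linear taper to zero at
#' its boundary. Controls never receive the effect.
#'
#' @param config a [sim_config()].
#' @return a [sample_table()] with attribute `truth`: list with the panel
#'   ids, the rectangle, and the per-pair effect magnitude actually
#'   applied (in total-sd units).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  gen <- function() generate_cohort_impl(config)
  if (is.null(config$seed)) gen() else with_private_seed(config$seed, gen())
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_pairs
  p <- cfg$n_variables
  vars <- sprintf("var%03d", seq_len(p))
  panel <- resolve_panel(cfg, vars)
  mu <- stats::runif(p, cfg$baseline_level_range[1L],
                     cfg$baseline_level_range[2L])
  sj <- stats::runif(p, cfg$var_scale_range[1L], cfg$var_scale_range[2L])
  total_sd <- sj * sqrt(cfg$subject_sd^2 + cfg$noise_sd^2)

  ttd <- stats::runif(n, cfg$ttd_range[1L], cfg$ttd_range[2L])
  tbs <- stats::runif(n, cfg$tbs_range[1L], cfg$tbs_range[2L])
  t0 <- stats::runif(n, 1990, 2000)
  magnitude <- cfg$effect_size *
    taper_factor(ttd, cfg$roi_ttd, cfg$taper_margin) *
    taper_factor(tbs, cfg$roi_tbs, cfg$taper_margin)

  n_samples <- 4L * n
  values <- matrix(NA_real_, n_samples, p)
  meta <- data.frame(sample_id = character(n_samples),
                     subject_id = character(n_samples),
                     pair_id = character(n_samples),
                     group = character(n_samples),
                     timepoint = character(n_samples),
                     sampling_time = numeric(n_samples),
                     diagnosis_time = numeric(n_samples),
                     stringsAsFactors = FALSE)
  row <- 0L
  for (i in seq_len(n)) {
    pair <- sprintf("pair%02d", i)
    for (role in c("case", "control")) {
      subj <- paste0(pair, "_", role)
      a <- stats::rnorm(p, 0, cfg$subject_sd * sj)
      for (tp in c("baseline", "repeated")) {
        row <- row + 1L
        v <- mu + a + stats::rnorm(p, 0, cfg$noise_sd * sj)
        if (role == "case" && tp == "repeated" && magnitude[i] > 0) {
          v[panel] <- v[panel] + magnitude[i] * total_sd[panel]
        }
        values[row, ] <- v
        meta$sample_id[row] <- paste0(subj, "_", tp)
        meta$subject_id[row] <- subj
        meta$pair_id[row] <- pair
        meta$group[row] <- role
        meta$timepoint[row] <- tp
        meta$sampling_time[row] <-
          if (tp == "baseline") t0[i] else t0[i] + tbs[i]
        meta$diagnosis_time[row] <-
          if (role == "case") t0[i] + tbs[i] + ttd[i] else NA_real_
      }
    }
  }
  colnames(values) <- vars
  rownames(values) <- meta$sample_id
  tab <- sample_table(values, meta)
  attr(tab, "truth") <- list(panel = vars[panel],
                             roi = c(ttd_max = cfg$roi_ttd,
                                     tbs_max = cfg$roi_tbs),
                             ttd = ttd, tbs = tbs,
                             effect_magnitude = magnitude)
  tab
}

#' Generate a synthetic single-time-point validation cohort
#'
#' Like [generate_cohort()] but with one sample per subject
#' (`timepoint = "single"`). The planted shift applies to the case sample
#' when the pair's time to diagnosis is below the configured bound, with
#' the same linear taper (the between-sample time plays no role in this
#' design).
#'
#' @param config a [sim_config()]; set `n_pairs` to the validation size.
#' @return a [sample_table()] with a `truth` attribute.
#' @export
generate_validation <- function(config = sim_config(n_pairs = 68L)) {
  stopifnot(inherits(config, "sim_config"))
  gen <- function() generate_validation_impl(config)
  if (is.null(config$seed)) gen() else with_private_seed(config$seed, gen())
}

generate_validation_impl <- function(cfg) {
  n <- cfg$n_pairs
  p <- cfg$n_variables
  vars <- sprintf("var%03d", seq_len(p))
  panel <- resolve_panel(cfg, vars)
  mu <- stats::runif(p, cfg$baseline_level_range[1L],
                     cfg$baseline_level_range[2L])
  sj <- stats::runif(p, cfg$var_scale_range[1L], cfg$var_scale_range[2L])
  total_sd <- sj * sqrt(cfg$subject_sd^2 + cfg$noise_sd^2)

  ttd <- stats::runif(n, cfg$ttd_range[1L], cfg$ttd_range[2L])
  t0 <- stats::runif(n, 1990, 2000)
  magnitude <- cfg$effect_size *
    taper_factor(ttd, cfg$roi_ttd, cfg$taper_margin)

  n_samples <- 2L * n
  values <- matrix(NA_real_, n_samples, p)
  meta <- data.frame(sample_id = character(n_samples),
                     subject_id = character(n_samples),
                     pair_id = character(n_samples),
                     group = character(n_samples),
                     timepoint = "single",
                     sampling_time = numeric(n_samples),
                     diagnosis_time = numeric(n_samples),
                     stringsAsFactors = FALSE)
  row <- 0L
  for (i in seq_len(n)) {
    pair <- sprintf("vpair%02d", i)
    for (role in c("case", "control")) {
      row <- row + 1L
      subj <- paste0(pair, "_", role)
      a <- stats::rnorm(p, 0, cfg$subject_sd * sj)
      v <- mu + a + stats::rnorm(p, 0, cfg$noise_sd * sj)
      if (role == "case" && magnitude[i] > 0) {
        v[panel] <- v[panel] + magnitude[i] * total_sd[panel]
      }
      values[row, ] <- v
      meta$sample_id[row] <- subj
      meta$subject_id[row] <- subj
      meta$pair_id[row] <- pair
      meta$group[row] <- role
      meta$sampling_time[row] <- t0[i]
      meta$diagnosis_time[row] <-
        if (role == "case") t0[i] + ttd[i] else NA_real_
    }
  }
  colnames(values) <- vars
  rownames(values) <- meta$sample_id
  tab <- sample_table(values, meta)
  attr(tab, "truth") <- list(panel = vars[panel],
                             roi = c(ttd_max = cfg$roi_ttd,
                                     tbs_max = cfg$roi_tbs),
                             ttd = ttd,
                             effect_magnitude = magnitude)
  tab
}

resolve_panel <- function(cfg, vars) {
  if (is.null(cfg$panel)) {
    return(sort(sample.int(length(vars), cfg$panel_size)))
  }
  if (is.character(cfg$panel)) {
    idx <- match(cfg$panel, vars)
    if (anyNA(idx)) {
      stop("unknown panel variable(s): ",
           paste(cfg$panel[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    return(sort(idx))
  }
  sort(as.integer(cfg$panel))
}

#' Write the generator truth record as JSON
#'
#' @param table a generated [sample_table()] with a `truth` attribute.
#' @param path output path.
#' @export
write_truth_json <- function(table, path) {
  truth <- attr(table, "truth")
  if (is.null(truth)) stop("table carries no truth record")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
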