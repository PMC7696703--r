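# fixtures are built in code: tiny hand-written tables plus seeded
# generator cohorts

# one matched pair, baseline + repeated, fully hand-specified values
toy_pair_table <- function(case_base = c(10, 1), case_rep = c(13, 1),
                           ctrl_base = c(5, 2), ctrl_rep = c(6, 3),
                           t0 = 2000, tbs = 2, ttd = 5) {
  values <- rbind(case_base, case_rep, ctrl_base, ctrl_rep)
  colnames(values) <- paste0("m", seq_len(ncol(values)))
  rownames(values) <- c("s1", "s2", "s3", "s4")
  meta <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    subject_id = c("caseA", "caseA", "ctrlA", "ctrlA"),
    pair_id = "p1",
    group = c("case", "case", "control", "control"),
    timepoint = c("baseline", "repeated", "baseline", "repeated"),
    sampling_time = c(t0, t0 + tbs, t0, t0 + tbs),
    diagnosis_time = c(t0 + tbs + ttd, t0 + tbs + ttd, NA, NA),
    stringsAsFactors = FALSE)
  sample_table(values, meta)
}

# n-pair repeated-time-point table with explicit value matrices per role
multi_pair_table <- function(case_base, case_rep, ctrl_base, ctrl_rep,
                             ttd = NULL, tbs = NULL) {
  n <- nrow(case_base)
  p <- ncol(case_base)
  if (is.null(ttd)) ttd <- seq(1, 2, length.out = n)
  if (is.null(tbs)) tbs <- seq(1, 1.5, length.out = n)
  rows <- list(); metas <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("p%02d", i)
    ids <- paste0(pid, c("_cb", "_cr", "_kb", "_kr"))
    rows[[i]] <- rbind(case_base[i, ], case_rep[i, ],
                       ctrl_base[i, ], ctrl_rep[i, ])
    metas[[i]] <- data.frame(
      sample_id = ids,
      subject_id = rep(paste0(pid, c("_case", "_ctrl")), each = 2),
      pair_id = pid,
      group = rep(c("case", "control"), each = 2),
      timepoint = rep(c("baseline", "repeated"), 2),
      sampling_time = c(0, tbs[i], 0, tbs[i]),
      diagnosis_time = c(tbs[i] + ttd[i], tbs[i] + ttd[i], NA, NA),
      stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, rows)
  colnames(values) <- paste0("m", seq_len(p))
  meta <- do.call(rbind, metas)
  rownames(values) <- meta$sample_id
  sample_table(values, meta)
}

# single-time-point table from explicit case/control matrices
single_tp_table <- function(case_vals, ctrl_vals, ttd = NULL) {
  n <- nrow(case_vals)
  if (is.null(ttd)) ttd <- seq(1, 3, length.out = n)
  rows <- list(); metas <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("v%02d", i)
    rows[[i]] <- rbind(case_vals[i, ], ctrl_vals[i, ])
    metas[[i]] <- data.frame(
      sample_id = paste0(pid, c("_case", "_ctrl")),
      subject_id = paste0(pid, c("_case", "_ctrl")),
      pair_id = pid,
      group = c("case", "control"),
      timepoint = "single",
      sampling_time = 0,
      diagnosis_time = c(ttd[i], NA),
      stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, rows)
  colnames(values) <- paste0("m", seq_len(ncol(case_vals)))
  meta <- do.call(rbind, metas)
  rownames(values) <- meta$sample_id
  sample_table(values, meta)
}

# small generator cohort for scan-level tests
small_sim_cohort <- function(seed = 11, n_pairs = 24, n_variables = 30,
                             panel_size = 5, effect_size = 1.5, ...) {
  cfg <- sim_config(n_pairs = n_pairs, n_variables = n_variables,
                    panel_size = panel_size, effect_size = effect_size,
                    seed = seed, ...)
  tab <- generate_cohort(cfg)
  list(table = tab, cohort = disease_progress(tab),
       truth = attr(tab, "truth"), config = cfg)
}
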