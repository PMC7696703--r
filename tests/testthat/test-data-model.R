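test_that("a minimal one-pair table validates and reconstructs its pair", {
  tab <- toy_pair_table()
  expect_s3_class(tab, "sample_table")
  expect_equal(nrow(tab$values), 4L)
  coh <- disease_progress(tab)
  expect_equal(nrow(coh$d), 1L)
  expect_equal(coh$ttd, 5)
  expect_equal(coh$tbs, 2)
})

test_that("schema violations are rejected with informative errors", {
  tab <- toy_pair_table()
  v <- tab$values
  colnames(v) <- c("m1", "m1")
  expect_error(sample_table(v, tab$meta), "duplicated variable")

  meta_bad <- tab$meta
  meta_bad$pair_id <- NULL
  expect_error(sample_table(tab$values, meta_bad), "pair_id")

  v2 <- tab$values
  v2[1, 1] <- NA
  expect_error(sample_table(v2, tab$meta), "missing")

  # a pair with two case subjects
  meta2 <- tab$meta
  meta2$group <- c("case", "case", "case", "case")
  expect_error(sample_table(tab$values, meta2), "pairing error.*p1")
})

test_that("progression is the elementwise repeated-minus-baseline oracle", {
  tab <- toy_pair_table(case_base = c(10, 1), case_rep = c(13, 1))
  prog <- progression(tab)
  expect_equal(unname(prog["caseA", ]), c(3, 0))

  # identical time points give an all-zero row
  tab0 <- toy_pair_table(ctrl_base = c(4, 4), ctrl_rep = c(4, 4))
  expect_equal(unname(progression(tab0)["ctrlA", ]), c(0, 0))

  # random 5-pair, 4-variable table against per-cell subtraction
  set.seed(101)
  mats <- replicate(4, matrix(rnorm(20), 5, 4), simplify = FALSE)
  tab_r <- multi_pair_table(mats[[1]], mats[[2]], mats[[3]], mats[[4]])
  prog_r <- progression(tab_r)
  for (i in 1:5) {
    pid <- sprintf("p%02d", i)
    expect_equal(unname(prog_r[paste0(pid, "_case"), ]),
                 mats[[2]][i, ] - mats[[1]][i, ])
    expect_equal(unname(prog_r[paste0(pid, "_ctrl"), ]),
                 mats[[4]][i, ] - mats[[3]][i, ])
  }
})

test_that("disease progress subtracts control progression from case progression", {
  # case progression (2, 0), control progression (1, 1) -> d = (1, -1)
  tab <- toy_pair_table(case_base = c(0, 0), case_rep = c(2, 0),
                        ctrl_base = c(0, 0), ctrl_rep = c(1, 1))
  coh <- disease_progress(tab)
  expect_equal(unname(coh$d[1, ]), c(1, -1))

  # equal progressions give the perfect-matching null
  tab0 <- toy_pair_table(case_base = c(1, 2), case_rep = c(3, 5),
                         ctrl_base = c(7, 1), ctrl_rep = c(9, 4))
  expect_equal(unname(disease_progress(tab0)$d[1, ]), c(0, 0))
})

test_that("swapping case/control labels negates every disease-progress vector", {
  sim <- small_sim_cohort(seed = 5, n_pairs = 8, n_variables = 6)
  tab <- sim$table
  meta_sw <- tab$meta
  meta_sw$group <- ifelse(meta_sw$group == "case", "control", "case")
  # diagnosis time must follow the case label for ttd to stay defined
  diag_by_pair <- tapply(tab$meta$diagnosis_time, tab$meta$pair_id,
                         function(x) x[!is.na(x)][1])
  meta_sw$diagnosis_time <- ifelse(meta_sw$group == "case",
                                   diag_by_pair[meta_sw$pair_id], NA)
  tab_sw <- sample_table(tab$values, meta_sw)
  expect_equal(disease_progress(tab_sw)$d, -disease_progress(tab)$d,
               ignore_attr = TRUE)
})

test_that("progression and disease progress are linear in the data", {
  set.seed(77)
  mats_a <- replicate(4, matrix(rnorm(12), 3, 4), simplify = FALSE)
  mats_b <- replicate(4, matrix(rnorm(12), 3, 4), simplify = FALSE)
  tab_a <- do.call(multi_pair_table, mats_a)
  tab_b <- do.call(multi_pair_table, mats_b)
  tab_ab <- do.call(multi_pair_table, Map(`+`, mats_a, mats_b))
  expect_equal(progression(tab_ab), progression(tab_a) + progression(tab_b))
  expect_equal(disease_progress(tab_ab)$d,
               disease_progress(tab_a)$d + disease_progress(tab_b)$d)
})

test_that("single-time-point differences match the per-cell oracle", {
  set.seed(33)
  cvals <- matrix(rnorm(9), 3, 3)
  kvals <- matrix(rnorm(9), 3, 3)
  tab <- single_tp_table(cvals, kvals)
  coh <- case_control_difference(tab)
  expect_equal(unname(coh$d), cvals - kvals)
  expect_true(all(is.na(coh$tbs)))

  # identical case/control rows give the zero vector
  tab0 <- single_tp_table(cvals, cvals)
  expect_true(all(case_control_difference(tab0)$d == 0))
})

test_that("a case lacking a diagnosis time is a metadata error", {
  tab <- toy_pair_table()
  meta <- tab$meta
  meta$diagnosis_time <- NA_real_
  tab2 <- sample_table(tab$values, meta)
  expect_error(disease_progress(tab2), "diagnosis time")
})

test_that("write/read round trip preserves the values matrix exactly", {
  sim <- small_sim_cohort(seed = 19, n_pairs = 6, n_variables = 8)
  vp <- tempfile(fileext = ".tsv")
  mp <- tempfile(fileext = ".tsv")
  write_cohort(sim$table, vp, mp)
  back <- read_cohort(vp, mp)
  expect_equal(back$values, sim$table$values, tolerance = 0)
  expect_equal(back$meta$sampling_time, sim$table$meta$sampling_time,
               tolerance = 0)
  unlink(c(vp, mp))
})

test_that("ISO-8601 dates convert to year spans", {
  tab <- toy_pair_table()
  meta <- tab$meta
  meta$sampling_time <- c("2000-01-01", "2002-01-01",
                          "2000-01-01", "2002-01-01")
  meta$diagnosis_time <- c("2007-01-01", "2007-01-01", NA, NA)
  tab2 <- sample_table(tab$values, meta)
  coh <- disease_progress(tab2)
  expect_equal(coh$tbs, 2, tolerance = 0.01)
  expect_equal(coh$ttd, 5, tolerance = 0.01)
})
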