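test_that("generated cohorts satisfy the matched-design invariants", {
  cfg <- sim_config(n_pairs = 10, n_variables = 12, panel_size = 4,
                    seed = 36)
  tab <- generate_cohort(cfg)
  expect_s3_class(tab, "sample_table")          # validation ran
  expect_equal(nrow(tab$values), 40L)
  expect_equal(length(unique(tab$meta$pair_id)), 10L)
  coh <- disease_progress(tab)
  expect_true(all(coh$ttd > 0))
  expect_true(all(coh$tbs > 0))
  truth <- attr(tab, "truth")
  expect_length(truth$panel, 4L)
  expect_true(all(truth$panel %in% tab$variable_ids))

  val <- generate_validation(sim_config(n_pairs = 8, n_variables = 12,
                                        panel_size = 4, seed = 37))
  expect_true(all(val$meta$timepoint == "single"))
  expect_equal(nrow(val$values), 16L)
  expect_s3_class(case_control_difference(val), "paired_cohort")
})

test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- sim_config(n_pairs = 6, n_variables = 8, panel_size = 3, seed = 38)
  t1 <- generate_cohort(cfg)
  t2 <- generate_cohort(cfg)
  expect_identical(t1$values, t2$values)
  expect_identical(t1$meta, t2$meta)
  t3 <- generate_cohort(sim_config(n_pairs = 6, n_variables = 8,
                                   panel_size = 3, seed = 39))
  expect_false(identical(t1$values, t3$values))
})

test_that("the planted effect lands only on case repeated samples in the region", {
  cfg <- sim_config(n_pairs = 20, n_variables = 10, panel_size = 3,
                    effect_size = 3, taper_margin = 0, seed = 40)
  tab <- generate_cohort(cfg)
  truth <- attr(tab, "truth")
  inside <- truth$ttd < 8 & truth$tbs < 7
  expect_equal(truth$effect_magnitude > 0, inside)
  expect_equal(unique(truth$effect_magnitude[inside]), 3)

  coh <- disease_progress(tab)
  panel_idx <- match(truth$panel, coh$variable_ids)
  m_in <- mean(coh$d[inside, panel_idx])
  m_out <- mean(coh$d[!inside, panel_idx])
  expect_gt(m_in, m_out + 1)
})

test_that("the taper ramps the effect linearly to zero at the boundary", {
  tf <- smartscan:::taper_factor
  expect_equal(tf(c(6, 7.5, 8, 9), 8, 1), c(1, 0.5, 0, 0))
  expect_equal(tf(c(7.999, 8), 8, 0), c(1, 0))
})

test_that("a zero effect size leaves cases and controls exchangeable", {
  p_vals <- vapply(1:20, function(r) {
    cfg <- sim_config(n_pairs = 20, n_variables = 5, panel_size = 2,
                      effect_size = 0, seed = 400 + r)
    coh <- disease_progress(generate_cohort(cfg))
    t.test(rowMeans(coh$d))$p.value
  }, numeric(1))
  # roughly uniform p-values: no systematic case-control difference
  expect_gt(mean(p_vals), 0.25)
  expect_lt(mean(p_vals), 0.75)
  expect_lte(sum(p_vals < 0.05), 4)
})

test_that("the realized effect in the differences matches the configured size", {
  # d = (case repeated - case baseline) - (control repeated - control
  # baseline): the planted shift enters once, so E[d_panel] =
  # magnitude * total_sd
  devs <- vapply(1:30, function(r) {
    cfg <- sim_config(n_pairs = 16, n_variables = 8, panel_size = 3,
                      effect_size = 1.5, taper_margin = 0, seed = 500 + r)
    tab <- generate_cohort(cfg)
    truth <- attr(tab, "truth")
    coh <- disease_progress(tab)
    inside <- truth$effect_magnitude > 0
    if (sum(inside) < 2) return(NA_real_)
    panel_idx <- match(truth$panel, coh$variable_ids)
    sds <- apply(tab$values[, truth$panel, drop = FALSE], 2, sd)
    mean(sweep(coh$d[inside, panel_idx, drop = FALSE], 2,
               sds, "/")) / 1.5
  }, numeric(1))
  # ratio of realized to configured effect concentrates near 1 (the
  # baseline sd estimate inflates slightly through the planted shift)
  expect_equal(mean(devs, na.rm = TRUE), 1, tolerance = 0.25)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_pairs = 2), "n_pairs")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(roi_ttd = 30), "roi_ttd")
})
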