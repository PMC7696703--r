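make_coord_cohort <- function(ttd, tbs, p = 3, seed = 1) {
  n <- length(ttd)
  d <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  colnames(d) <- paste0("m", seq_len(p))
  smartscan:::new_paired_cohort(d, ttd, tbs,
                                sprintf("p%03d", seq_len(n)),
                                colnames(d), "progress")
}

test_that("the grid covers the bounding box aligned to the step", {
  coh <- make_coord_cohort(ttd = c(1, 2), tbs = c(1, 1.5))
  g <- build_grid(coh, step = 0.25)
  expect_equal(g$ttd, seq(1, 2, by = 0.25))
  expect_equal(g$tbs, seq(1, 1.5, by = 0.25))
  expect_equal(nrow(g$points), 15L)

  # single observation on the lattice: one grid point per axis
  coh1 <- make_coord_cohort(ttd = 1.5, tbs = 2)
  g1 <- build_grid(coh1, step = 0.25)
  expect_equal(nrow(g1$points), 1L)

  # a step larger than the range leaves only enclosing corner points
  g2 <- build_grid(coh, step = 4)
  expect_equal(g2$ttd, c(0, 4))
  expect_equal(g2$tbs, c(0, 4))
})

test_that("subset selection matches the exhaustive weighted-distance sort", {
  set.seed(12)
  coh <- make_coord_cohort(ttd = runif(30, 1, 10), tbs = runif(30, 1, 8))
  for (r in 1:50) {
    anchor <- c(runif(1, 0, 11), runif(1, 0, 9))
    w <- sample(2^(-3:3), 1)
    k <- sample(c(5, 10, 20), 1)
    got <- select_subset(anchor, w, coh, k = k)
    d <- sqrt((w * (coh$ttd - anchor[1]))^2 + (coh$tbs - anchor[2])^2)
    want <- sort(order(d, coh$pair_ids)[seq_len(k)])
    expect_identical(got, want)
  }
  # k = n returns everyone regardless of anchor
  expect_identical(select_subset(c(0, 0), 1, coh, k = 30), 1:30)
})

test_that("the weight stretches the time-to-diagnosis axis as intended", {
  # cross of points: arms along ttd and along tbs at distance 2 from center
  coh <- make_coord_cohort(ttd = c(5, 3, 7, 5, 5), tbs = c(5, 5, 5, 3, 7))
  up <- select_subset(c(5, 5), 8, coh, k = 3)    # ttd deviations punished
  expect_true(all(c(4, 5) %in% up))              # picks the tbs arm
  flat <- select_subset(c(5, 5), 1 / 8, coh, k = 3)
  expect_true(all(c(2, 3) %in% flat))            # picks the ttd arm
})

test_that("Hotelling ellipse matches its asymptotic and equivariance properties", {
  set.seed(13)
  pts <- matrix(rnorm(20000), ncol = 2)
  e <- hotelling_ellipse(pts)
  expect_equal(e$t2crit, qchisq(0.95, 2), tolerance = 0.01)
  expect_equal(unname(e$radii), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 0.05)

  # rotation equivariance
  pts2 <- matrix(rnorm(100), ncol = 2) %*% diag(c(3, 1))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  e1 <- hotelling_ellipse(pts2)
  e2 <- hotelling_ellipse(pts2 %*% t(R))
  expect_equal(e2$radii, e1$radii, tolerance = 1e-8)
  ang_diff <- (e2$angle - e1$angle - th) %% pi
  expect_true(min(ang_diff, pi - ang_diff) < 1e-6)

  # collinear points degrade to a zero-width sentinel
  line <- cbind(1:5, 2 * (1:5) + 1)
  el <- hotelling_ellipse(line)
  expect_true(el$degenerate)
  expect_equal(unname(el$radii[2]), 0)
  expect_false(any(smartscan:::ellipse_covers(el, cbind(3, 7))))
})

test_that("the scan deduplicates subsets and is deterministic", {
  sim <- small_sim_cohort(seed = 14, n_pairs = 16, n_variables = 10,
                          panel_size = 3)
  st <- scan_settings(step = 1, k = 8, k_folds = 4)
  scan <- run_scan(sim$cohort, st)
  keys <- vapply(scan$members, paste, character(1), collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
  g <- build_grid(sim$cohort, 1)
  expect_lte(nrow(scan$subsets), nrow(g$points) * 7)
  expect_true(all(scan$subsets$n_members == 8))

  scan2 <- run_scan(sim$cohort, st)
  expect_identical(scan$subsets, scan2$subsets)
  expect_identical(scan$members, scan2$members)

  # positions lie inside the members' bounding box
  for (i in seq_len(nrow(scan$subsets))) {
    mem <- scan$members[[i]]
    expect_gte(scan$subsets$pos_ttd[i], min(sim$cohort$ttd[mem]))
    expect_lte(scan$subsets$pos_ttd[i], max(sim$cohort$ttd[mem]))
  }
})

test_that("observation density counts overlaid ellipse indicators", {
  sim <- small_sim_cohort(seed = 15, n_pairs = 12, n_variables = 8,
                          panel_size = 3)
  scan <- run_scan(sim$cohort, scan_settings(step = 1.5, k = 6, k_folds = 3))
  n_sub <- nrow(scan$subsets)
  raster <- smartscan:::density_raster(scan, 1.5)

  # no significant subsets: all-zero map
  none <- rep(FALSE, n_sub)
  dm0 <- observation_density(scan, 1.5, subset_flags = none)
  expect_true(all(dm0$counts == 0))

  # a single subset: map equals its ellipse indicator
  one <- none; one[1] <- TRUE
  dm1 <- observation_density(scan, 1.5, subset_flags = one)
  ind <- smartscan:::ellipse_covers(scan$ellipses[[1]], raster$cells)
  expect_equal(as.vector(dm1$counts), as.integer(ind))

  # two subsets: counts add cellwise
  two <- none; two[c(1, n_sub)] <- TRUE
  dm2 <- observation_density(scan, 1.5, subset_flags = two)
  ind2 <- smartscan:::ellipse_covers(scan$ellipses[[n_sub]], raster$cells)
  expect_equal(as.vector(dm2$counts), as.integer(ind) + as.integer(ind2))
  expect_lte(max(dm2$counts), 2)
})

test_that("variable density respects criterion nesting and the planted sign", {
  sim <- small_sim_cohort(seed = 16, n_pairs = 20, n_variables = 12,
                          panel_size = 4, effect_size = 2)
  scan <- run_scan(sim$cohort, scan_settings(step = 1, k = 10, k_folds = 5))
  pv <- sim$truth$panel[1]
  vm_t <- variable_density(scan, pv, "ttest")
  vm_f <- variable_density(scan, pv, "fdr")
  vm_m <- variable_density(scan, pv, "multivariate")
  expect_true(all(abs(vm_m$counts) <= abs(vm_t$counts)))
  expect_true(all(abs(vm_f$counts) <= abs(vm_t$counts)))
  # planted increase: map never negative
  expect_true(all(vm_m$counts >= 0))

  # a variable that is never significant gives a zero map
  null_scan <- scan
  jnull <- setdiff(scan$variable_ids, sim$truth$panel)[1]
  null_scan$var_stats$p_w[, jnull] <- 1
  vm0 <- variable_density(null_scan, jnull, "ttest")
  expect_true(all(vm0$counts == 0))

  expect_error(variable_density(scan, "nope", "ttest"), "unknown variable")
})

test_that("the region-of-interest model is predictive only for planted panels", {
  sim <- small_sim_cohort(seed = 17, n_pairs = 30, n_variables = 20,
                          panel_size = 5, effect_size = 2)
  rm_panel <- roi_model(sim$cohort, c(8, 7), variables = sim$truth$panel)
  expect_gt(rm_panel$Q2, 0.3)
  expect_lt(rm_panel$p_cvanova, 0.05)

  # null cohort: non-positive Q2 in the median
  q2 <- vapply(1:15, function(r) {
    simn <- small_sim_cohort(seed = 100 + r, n_pairs = 30,
                             n_variables = 20, panel_size = 5,
                             effect_size = 0)
    roi_model(simn$cohort, c(8, 7))$Q2
  }, numeric(1))
  expect_lte(median(q2), 0)

  expect_error(roi_model(sim$cohort, c(0.1, 0.1)), "fewer than 3")
})
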