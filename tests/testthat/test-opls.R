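test_that("effect-projection scaling divides by the sample sd without centering", {
  D <- cbind(a = c(1, 3, 5), b = c(2, 2.5, 6))
  sc <- scale_ep(D)
  expect_null(sc$scaling$center)
  expect_equal(sc$X[, "a"], c(1, 3, 5) / sd(c(1, 3, 5)), ignore_attr = TRUE)
  # output columns all have unit sample sd
  set.seed(2)
  sc2 <- scale_ep(matrix(rnorm(100), 20, 5))
  expect_equal(apply(sc2$X, 2, sd), rep(1, 5), tolerance = 1e-12)
  expect_error(scale_ep(cbind(ok = 1:3, flat = c(2, 2, 2))), "flat")
})

test_that("unit-variance scaling centers and pools the class variance", {
  set.seed(4)
  X <- matrix(rnorm(30), 10, 3)
  y <- rep(c(0, 1), each = 5)
  sc <- scale_uv(X, y)
  expect_equal(colMeans(sc$X), rep(0, 3), tolerance = 1e-12)
  # pooled sd by hand
  sp <- sqrt((colSums(sweep(X[1:5, ], 2, colMeans(X[1:5, ]))^2) +
                colSums(sweep(X[6:10, ], 2, colMeans(X[6:10, ]))^2)) / 8)
  expect_equal(sc$scaling$scale, sp)
  # equal class variances: pooled sd close to the common sd
  expect_error(scale_uv(cbind(1:4, rep(1, 4))), "degenerate")
})

test_that("one-variable fit recovers the least-squares regression through the origin", {
  set.seed(9)
  x <- rnorm(10) + 2
  y <- rep(1, 10)
  m <- fit_opls(cbind(x), y, n_ortho = 0)
  ls <- sum(x * y) / sum(x^2)
  expect_equal(m$fitted, x * ls, tolerance = 1e-12)
  expect_equal(unname(abs(m$w)), 1)
})

test_that("identical columns receive identical weights", {
  set.seed(10)
  x <- rnorm(8)
  m <- fit_opls(cbind(x, x, rnorm(8)), rep(1, 8))
  expect_equal(m$w[1], m$w[2], tolerance = 1e-12)
})

test_that("orthogonal components are orthogonal to the predictive scores", {
  set.seed(12)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  for (no in 1:3) {
    m <- fit_opls(X, y, n_ortho = no)
    for (i in seq_len(no)) {
      expect_lt(abs(sum(m$t * m$T_o[, i])), 1e-8)
    }
    # orthogonal score vectors mutually orthogonal
    if (no > 1) {
      g <- crossprod(m$T_o)
      expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
    }
  }
})

test_that("a response orthogonal to X is a rank error; near-orthogonal explains ~0", {
  X <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  y <- rep(1, 4)  # exactly orthogonal to both columns
  expect_error(fit_opls(X, y), "rank error")
  y2 <- y + c(1e-8, 0, 0, 0)
  m <- fit_opls(X, y2)
  expect_lt(sum(m$fitted^2) / sum(y2^2), 1e-6)
})

test_that("EP fit puts its weight on a dominant shifted variable", {
  set.seed(21)
  D <- matrix(rnorm(60, 0, 0.05), 12, 5)
  D[, 1] <- 50 + rnorm(12, 0, 0.01)
  m <- fit_opls_ep(D)
  expect_gt(abs(m$w[1]), 0.999)
})

test_that("single-variable EP statistic equals the paired t-test", {
  # hand case: D = (1, 2, 3) -> t = 2 / (1 / sqrt(3)) = 2 sqrt(3)
  st <- variable_stats(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(st$t_w, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(st$t_w, 3.464, tolerance = 1e-3)

  set.seed(31)
  for (r in 1:25) {
    n <- sample(3:30, 1)
    x <- rnorm(n, mean = runif(1, -1, 1))
    st <- variable_stats(matrix(x, ncol = 1))
    tt <- t.test(x)
    expect_equal(st$t_w, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(st$p_w, tt$p.value, tolerance = 1e-10)
  }
})

test_that("negating the difference data flips loadings and preserves Q2", {
  set.seed(41)
  D <- matrix(rnorm(80), 16, 5) + 0.8
  m1 <- fit_opls_ep(D)
  m2 <- fit_opls_ep(-D)
  # the weight direction flips with the data; the scores t = Xw and the
  # fitted response are invariant under a constant unit response
  expect_equal(m2$w, -m1$w, tolerance = 1e-10)
  expect_equal(m2$t, m1$t, tolerance = 1e-10)
  cv1 <- cross_validate(D, kind = "ep", select_vars = FALSE)
  cv2 <- cross_validate(-D, kind = "ep", select_vars = FALSE)
  expect_equal(cv2$Q2, cv1$Q2, tolerance = 1e-10)
})

test_that("EP statistics are invariant to positive rescaling of any variable", {
  set.seed(51)
  D <- matrix(rnorm(60), 12, 5) + 0.5
  D2 <- D
  D2[, 3] <- D2[, 3] * 37.5
  m1 <- fit_opls_ep(D); m2 <- fit_opls_ep(D2)
  expect_equal(m2$w, m1$w, tolerance = 1e-10)
  expect_equal(m2$t, m1$t, tolerance = 1e-10)
  s1 <- variable_stats(D, m1); s2 <- variable_stats(D2, m2)
  expect_equal(s2$t_w, s1$t_w, tolerance = 1e-10)
  expect_equal(s2$t_p, s1$t_p, tolerance = 1e-10)
  cv1 <- cross_validate(D, kind = "ep")
  cv2 <- cross_validate(D2, kind = "ep")
  expect_equal(cv2$Q2, cv1$Q2, tolerance = 1e-10)
})

test_that("prediction reproduces training scores and is zero on zero rows", {
  set.seed(61)
  D <- matrix(rnorm(60), 12, 5) + 1
  m <- fit_opls_ep(D)
  pr <- predict(m, D)
  expect_equal(pr$t, m$t, tolerance = 1e-10)
  expect_equal(predict(m, matrix(0, 1, 5))$y_pred, 0)

  # one-variable model: prediction is the scaled value times w * b
  D1 <- matrix(c(2, 3, 4), ncol = 1, dimnames = list(NULL, "v"))
  m1 <- fit_opls_ep(D1)
  x_new <- matrix(5, 1, 1, dimnames = list(NULL, "v"))
  expect_equal(predict(m1, x_new)$y_pred,
               (5 / m1$scaling$scale) * m1$w * m1$b, ignore_attr = TRUE)
})

test_that("prediction demands the model's variables", {
  set.seed(71)
  D <- matrix(rnorm(30), 6, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  m <- fit_opls_ep(D)
  bad <- D[, 1:3]
  expect_error(predict(m, bad), "schema error")
})
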