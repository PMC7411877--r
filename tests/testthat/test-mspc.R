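test_that("fitting recovers a known principal subspace", {
  p <- 8; r <- 6
  sig <- withr::with_seed(31, {
    b <- qr.Q(qr(matrix(rnorm(p * r), p, r))) %*% diag(sqrt(c(8, 7, 6, 5, 4, 3)))
    b %*% t(b) + 0.01 * diag(p)
  })
  d <- sqrt(diag(sig))
  corr_true <- sig / outer(d, d)
  v_true <- eigen(corr_true, symmetric = TRUE)$vectors[, 1:r]
  x <- withr::with_seed(32, MASS::mvrnorm(5000, mu = rep(0, p), Sigma = sig))
  m <- fit_mspc(x, n_components = r)
  # principal angles between estimated and true 6-D subspaces
  sv <- svd(t(v_true) %*% m$loadings)$d
  max_angle <- acos(min(pmin(sv, 1))) * 180 / pi
  expect_lt(max_angle, 5)
  # loadings are orthonormal, score SDs positive non-increasing
  expect_equal(t(m$loadings) %*% m$loadings, diag(r), tolerance = 1e-8)
  expect_true(all(diff(m$sigma) <= 1e-12) && all(m$sigma > 0))
})

test_that("the center is the sample mean and full rank kills Q", {
  x <- withr::with_seed(33, matrix(rnorm(200 * 8), 200, 8))
  mirrored <- rbind(x, sweep(-sweep(x, 2, colMeans(x)), 2, -colMeans(x)))
  m <- fit_mspc(mirrored, n_components = 6)
  expect_equal(unname(m$center), unname(colMeans(x)), tolerance = 1e-12)

  m8 <- fit_mspc(x, n_components = 8)
  q <- q_statistic(m8, x)
  expect_lt(max(abs(q)), 1e-16)
})

test_that("zero-variance training columns are rejected by name", {
  x <- withr::with_seed(34, matrix(rnorm(100 * 8), 100, 8))
  colnames(x) <- paste0("idx", 1:8)
  x[, "idx3"] <- 7
  expect_error(fit_mspc(x, n_components = 6), "idx3")
})

test_that("Q and T2 satisfy their defining identities", {
  m <- rand_orthonormal_model(seed = 35)
  v <- m$loadings
  # a scaled point inside the model subspace has zero residual
  x_in <- m$center + m$scale * as.vector(v %*% rnorm(6))
  expect_lt(q_statistic(m, x_in), 1e-16)
  # a scaled point orthogonal to the subspace with norm 2 gives Q = 4
  perp <- qr.Q(qr(cbind(v, rnorm(8))))[, 7]
  x_perp <- m$center + m$scale * (2 * perp)
  expect_equal(q_statistic(m, x_perp), 4, tolerance = 1e-10)
  # one unit-scaled score gives T2 = 1; the origin gives 0
  x_t2 <- m$center + m$scale * (m$sigma[1] * v[, 1])
  expect_equal(t2_statistic(m, x_t2), 1, tolerance = 1e-10)
  expect_equal(t2_statistic(m, m$center), 0)
  # Pythagoras: Q + |V'x|^2 = |x|^2
  withr::with_seed(36, {
    for (i in 1:20) {
      x <- rnorm(8, m$center, 50)
      xs <- (x - m$center) / m$scale
      expect_equal(q_statistic(m, x) + sum((t(v) %*% xs)^2), sum(xs^2),
                   tolerance = 1e-8)
    }
  })
})

test_that("statistics match brute-force matrix evaluation", {
  m <- rand_orthonormal_model(seed = 37)
  # unit-scale deviations in model coordinates
  xs <- withr::with_seed(38, {
    z <- matrix(rnorm(200 * 8), 200, 8)
    sweep(sweep(z, 2, m$scale, "*"), 2, m$center, "+")
  })
  q <- q_statistic(m, xs)
  t2 <- t2_statistic(m, xs)
  for (i in 1:200) {
    expect_lt(abs(q[i] - brute_q(m, xs[i, ])), 1e-10)
    expect_lt(abs(t2[i] - brute_t2(m, xs[i, ])), 1e-10)
  }
})

test_that("column permutation and sign flips leave Q and T2 unchanged", {
  m <- rand_orthonormal_model(seed = 39)
  perm <- c(3, 1, 2, 6, 5, 4)
  flip <- c(1, -1, 1, -1, -1, 1)
  m2 <- m
  m2$loadings <- sweep(m$loadings[, perm], 2, flip, "*")
  m2$sigma <- m$sigma[perm]
  xs <- withr::with_seed(40, matrix(rnorm(50 * 8, 1000, 80), 50, 8))
  expect_equal(q_statistic(m2, xs), q_statistic(m, xs), tolerance = 1e-10)
  expect_equal(t2_statistic(m2, xs), t2_statistic(m, xs), tolerance = 1e-10)
})

test_that("control limits are interpolated percentiles of the tuning sample", {
  m <- rand_orthonormal_model(seed = 41)
  m <- tune_control_limits(m, q_values = 1:1000, t2_values = 1:1000,
                           alpha = 99)
  # type-7 linear interpolation: 1 + 0.99 * 999 = 990.01
  expect_equal(m$cl_Q, 990.01)
  expect_equal(m$alpha, 99)
  m2 <- tune_control_limits(m, rep(3.5, 200), rep(3.5, 200))
  expect_equal(m2$cl_Q, 3.5)
  expect_equal(m2$cl_T2, 3.5)
  # at most 1% of the tuning sample exceeds the limit
  qs <- withr::with_seed(42, rchisq(5000, 3))
  m3 <- tune_control_limits(m, qs, qs, alpha = 99)
  expect_lte(mean(qs > m3$cl_Q), 0.01)
  expect_error(tune_control_limits(m, 1:50, 1:50), "at least 100")
})

test_that("held-out exceedance sits near the nominal 1%", {
  x <- simulate_hrv_vectors(30000, seed = 43)
  m <- fit_mspc(x[1:5000, ], n_components = 6)
  tune <- monitoring_statistics(m, x[5001:15000, ])
  m <- tune_control_limits(m, tune$Q, tune$T2, alpha = 99)
  held <- monitoring_statistics(m, x[15001:30000, ])
  expect_gt(mean(held$Q > m$cl_Q), 0.005)
  expect_lt(mean(held$Q > m$cl_Q), 0.015)
  expect_gt(mean(held$T2 > m$cl_T2), 0.005)
  expect_lt(mean(held$T2 > m$cl_T2), 0.015)
})

test_that("model files round-trip bit-exactly through JSON", {
  x <- simulate_hrv_vectors(2000, seed = 44)
  m <- fit_mspc(x, n_components = 6)
  s <- monitoring_statistics(m, x)
  m <- tune_control_limits(m, s$Q, s$T2, alpha = 99)
  path <- withr::local_tempfile(fileext = ".json")
  write_mspc_model(m, path, metadata = list(note = "fixture"))
  back <- read_mspc_model(path)
  expect_identical(unname(back$center), unname(m$center))
  expect_identical(unname(back$scale), unname(m$scale))
  expect_identical(back$loadings, unname(m$loadings))
  expect_identical(back$sigma, m$sigma)
  expect_identical(back$cl_Q, m$cl_Q)
  expect_identical(back$cl_T2, m$cl_T2)
  expect_identical(back$index_names, m$index_names)
  # statistics computed from the file agree exactly
  expect_identical(q_statistic(back, x[1:5, ]), q_statistic(m, x[1:5, ]))
  # an untuned model round-trips its NA limits
  m0 <- fit_mspc(x, n_components = 4)
  write_mspc_model(m0, path)
  expect_true(is.na(read_mspc_model(path)$cl_Q))
})
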