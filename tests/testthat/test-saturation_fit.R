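test_that("noise-free isotherm points are recovered exactly", {
  x <- c(1, 2.5, 5, 10, 15, 30, 40)
  y <- 100 * x / (5 + x)
  fit <- fit_one_site(x, y)
  expect_true(fit$converged)
  expect_equal(fit$kd_app, 5, tolerance = 1e-6)
  expect_equal(fit$bmax_app, 100, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-6)
  # half-saturation identity: curve at x = Kd is Bmax / 2
  expect_equal(predict(fit, fit$kd_app), fit$bmax_app / 2)
})

test_that("degenerate all-zero data is flagged, not raised", {
  x <- c(1, 5, 10, 20); y <- rep(0, 4)
  fit <- fit_one_site(x, y)
  expect_false(fit$converged && fit$bmax_app > 1e-6)
  expect_error(fit_one_site(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("scale equivariance: x -> c*x scales Kd, leaves Bmax", {
  x <- c(0.5, 2, 4, 8, 20, 35)
  y <- 80 * x / (12 + x)
  f1 <- fit_one_site(x, y)
  f2 <- fit_one_site(3 * x, y)
  expect_equal(f2$kd_app, 3 * f1$kd_app, tolerance = 1e-6)
  expect_equal(f2$bmax_app, f1$bmax_app, tolerance = 1e-6)
})

test_that("replicate_sem matches the textbook formula", {
  expect_equal(replicate_sem(c(1, 1, 1)), 0)
  expect_equal(replicate_sem(c(0.6, 1.0)), 0.2)
  v <- rep(c(0.8, 0.2), 5)
  expect_equal(replicate_sem(v), sd(v) / sqrt(length(v)))
  expect_error(replicate_sem(1), ">= 2")
})

test_that("delta_delta_g evaluates RT ln(KdA/KdB) and is antisymmetric", {
  # reported P-gp site Kds: 0.8% vs 16.0% at 310 K
  expect_equal(delta_delta_g(0.8, 16.0, 310), 8.314e-3 * 310 * log(0.05),
               tolerance = 1e-9)
  expect_equal(delta_delta_g(0.8, 16.0, 310), -7.72, tolerance = 1e-3)
  # reported PC2 site Kds: 11% vs 49%
  expect_equal(delta_delta_g(11, 49, 310), -3.85, tolerance = 1e-3)
  expect_equal(delta_delta_g(7, 7, 310), 0)
  set.seed(5)
  for (rep in 1:20) {
    ka <- runif(1, 0.1, 50); kb <- runif(1, 0.1, 50); tt <- runif(1, 280, 330)
    expect_equal(delta_delta_g(ka, kb, tt), -delta_delta_g(kb, ka, tt))
  }
  expect_error(delta_delta_g(-1, 5), "positive")
})

test_that("delta_g_app uses the mole-fraction reference, stronger = lower", {
  expect_equal(delta_g_app(100, 310), 0)
  expect_equal(delta_g_app(0.8, 310) - delta_g_app(16, 310),
               delta_delta_g(0.8, 16, 310))
  expect_lt(delta_g_app(0.8, 310), delta_g_app(16, 310))
})

test_that("fit_saturation reports pooled fit plus per-replicate SEM", {
  m <- kinetic_site_model(0.01, 0.1)
  ds <- generate_saturation_dataset(m, replicates = 3L, frames = 4000L,
                                    base_seed = 8L)
  f <- fit_saturation(ds$points)
  expect_true(f$pooled$converged)
  expect_length(f$per_replicate, 3L)
  expect_gte(f$kd_sem, 0)
  expect_equal(f$kd_app, f$pooled$kd_app)
})

test_that("convergence_scan: full subset is the identity, truncation caps", {
  m <- kinetic_site_model(0.01, 0.1)
  ds <- generate_saturation_dataset(m, concentrations = c(2, 10, 30),
                                    replicates = 3L, frames = 2000L,
                                    base_seed = 4L, keep_series = TRUE)
  scan <- convergence_scan(ds, replicate_subsets = list(1:3),
                           frame_truncations = c(1000L, 5000L))
  full <- attr(scan, "full_fit")
  expect_equal(scan$kd_app[is.na(scan$frames)], full$kd_app)
  expect_equal(scan$kd_drift_rel[is.na(scan$frames)], 0)
  # truncation beyond the trajectory is the identity
  long <- which(!is.na(scan$frames) & scan$frames == 5000L)
  expect_equal(scan$kd_app[long], full$kd_app)
  # shorter series genuinely changes the points
  short <- which(!is.na(scan$frames) & scan$frames == 1000L)
  expect_false(isTRUE(all.equal(scan$kd_app[short], full$kd_app)))
  expect_error(convergence_scan(ds, replicate_subsets = list()), "empty")
})
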