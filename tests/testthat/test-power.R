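test_that("covariates realize their specifications", {
  expect_equal(covariate_from_spec(covariate_spec("equispaced"), 4),
               c(0.25, 0.5, 0.75, 1))
  expect_equal(covariate_from_spec(covariate_spec("uniform"), 4),
               c(0.125, 0.375, 0.625, 0.875))
  z <- covariate_from_spec(covariate_spec("normal", mean = 5, sd = 1.5), 20)
  expect_equal(z, sort(qnorm(((1:20) - 0.5) / 20, 5, 1.5)),
               tolerance = 1e-10)
  expect_error(covariate_spec("normal", sd = -1), "positive")
  expect_error(covariate_spec("uniform", min = 2, max = 1), "exceed")
  expect_error(covariate_spec("normal", rate = 1), "unknown parameter")
  expect_error(covariate_from_spec(covariate_spec("explicit",
                                                  values = 1:5), 7),
               "length")
})

test_that("alternative mean is linear in delta with matching sign", {
  sp <- function(d) power_spec(psi = 0.6, delta = d, sigma = 0.1, n = 100)
  expect_equal(expected_s0_h1(sp(0)), 0)
  e1 <- expected_s0_h1(sp(1))
  expect_equal(expected_s0_h1(sp(-2)), -2 * e1, tolerance = 1e-12)
  expect_gt(e1, 0)
  expect_error(expected_s0_h1(power_spec(psi = 2, delta = 1, sigma = 1,
                                         n = 50)),
               "strictly inside")
})

test_that("alternative mean agrees with a Monte-Carlo simulation", {
  spec <- power_spec(psi = 0.6, delta = 0.5, sigma = 0.1, n = 100)
  e1 <- expected_s0_h1(spec)
  n <- 100
  z <- covariate_from_spec(spec$covariate, n)
  grid <- default_psi_grid(z, 10)
  set.seed(61)
  reps <- 2000
  s0 <- replicate(reps, {
    y <- 1 + 0.3 * z + 0.5 * pmax(z - 0.6, 0) + rnorm(n, sd = 0.1)
    s <- cp_series(y, z, X = cbind(z = z))
    pscore_statistic(s, phi_spec("segmented", grid),
                     sigma2_source = "known", sigma2 = 0.01)$statistic
  })
  expect_lt(abs(mean(s0) - e1), 3 / sqrt(reps))   # unit-variance statistic
})

test_that("analytic power reproduces its null, symmetry and monotonicity", {
  base <- power_spec(psi = 0.6, delta = 0.5, sigma = 0.1, n = 100)
  expect_equal(seg_power(base), 0.749, tolerance = 5e-4)
  # null limit: power equals the level exactly at delta = 0
  null <- power_spec(psi = 0.6, delta = 0, sigma = 0.1, n = 100,
                     alpha = 0.01)
  expect_equal(seg_power(null), 0.01)
  # two-sided power is even in delta
  neg <- power_spec(psi = 0.6, delta = -0.5, sigma = 0.1, n = 100)
  expect_equal(seg_power(neg), seg_power(base), tolerance = 1e-12)
  # increasing in |delta| and in n
  p_small <- seg_power(power_spec(0.6, 0.25, 0.1, 100))
  expect_gt(seg_power(base), p_small)
  expect_gt(seg_power(base, n = 150), seg_power(base))
  # decreasing towards the covariate boundaries
  p_mid <- seg_power(power_spec(0.5, 0.5, 0.1, 100))
  p_edge <- seg_power(power_spec(0.93, 0.5, 0.1, 100))
  expect_gt(p_mid, p_edge)
})

test_that("analytic power matches Monte-Carlo rejection rates", {
  # five scenario points on the segmented alternative
  cases <- list(
    list(psi = 0.6, delta = 0.5, n = 100),
    list(psi = 0.5, delta = 0.3, n = 80),
    list(psi = 0.4, delta = 0.6, n = 60),
    list(psi = 0.6, delta = 0.2, n = 120),
    list(psi = 0.7, delta = 0.8, n = 50))
  reps <- 1000
  set.seed(71)
  for (cs in cases) {
    spec <- power_spec(psi = cs$psi, delta = cs$delta, sigma = 0.1,
                       n = cs$n, alpha = 0.01)
    pw <- seg_power(spec)
    z <- covariate_from_spec(spec$covariate, cs$n)
    grid <- default_psi_grid(z, 10)
    rej <- mean(replicate(reps, {
      y <- 0.5 + z + cs$delta * pmax(z - cs$psi, 0) + rnorm(cs$n, sd = 0.1)
      s <- cp_series(y, z, X = cbind(z = z))
      r <- pscore_statistic(s, phi_spec("segmented", grid),
                            sigma2_source = "known", sigma2 = 0.01)
      r$p_value < 0.01
    }))
    se <- sqrt(pw * (1 - pw) / reps)
    expect_lt(abs(rej - pw), 3 * max(se, 1e-3))
  }
})

test_that("sample-size inversion is minimal and monotone", {
  spec <- power_spec(psi = 0.6, delta = 0.5, sigma = 0.1, alpha = 0.01)
  for (target in c(0.5, 0.8, 0.9)) {
    nn <- seg_sample_size(spec, target)
    expect_gte(seg_power(spec, nn), target)
    expect_lt(seg_power(spec, nn - 1), target)
  }
  expect_gt(seg_sample_size(spec, 0.9), seg_sample_size(spec, 0.8))
  # inverting the forward example lands near its sample size
  n749 <- seg_sample_size(spec, 0.749)
  expect_lte(abs(n749 - 100), 2)
  # distribution-based covariate regenerates with n
  spn <- power_spec(psi = 5, delta = 0.5, sigma = 1,
                    covariate = covariate_spec("normal", mean = 5, sd = 1.5))
  nn <- seg_sample_size(spn, 0.85)
  expect_gte(seg_power(spn, nn), 0.85)
  expect_lt(seg_power(spn, nn - 1), 0.85)
  expect_error(seg_sample_size(power_spec(0.5, 0.5, 1,
                  covariate = covariate_spec("explicit", values = (1:10) / 10)),
                  0.8), "explicit")
  expect_error(seg_sample_size(spec, 0.005), "target_power")
})

test_that("broken-line profile fit recovers noiseless parameters", {
  z <- (1:40) / 40
  y <- 1 + 2 * z + 3 * pmax(z - 0.5, 0)        # exact broken line
  f <- fit_segmented(cp_series(y, z))
  expect_equal(f$delta_hat, 3, tolerance = 1e-6)
  expect_equal(f$psi_hat, 0.5, tolerance = 1e-10)
  expect_lt(f$sigma_hat, 1e-6)
})

test_that("flat-profile data trigger the wide-uncertainty path", {
  set.seed(81)
  z <- (1:60) / 60
  y <- 1 + 0.5 * z + rnorm(60, sd = 0.1)       # no breakpoint
  f <- suppressWarnings(fit_segmented(cp_series(y, z)))
  expect_lt(abs(f$delta_hat), 1)
  expect_true(all(is.finite(f$cov)))
})

test_that("profile fit covers the truth across replications", {
  reps <- 100
  ok <- 0L
  for (r in seq_len(reps)) {
    set.seed(9000 + r)
    z <- sort(runif(200))
    y <- 1 + z + 2 * pmax(z - 0.5, 0) + rnorm(200, sd = 0.05)
    f <- fit_segmented(cp_series(y, z))
    se_d <- sqrt(f$cov["delta", "delta"]); se_p <- sqrt(f$cov["psi", "psi"])
    if (abs(f$delta_hat - 2) <= 3 * se_d &&
        abs(f$psi_hat - 0.5) <= 3 * se_p) ok <- ok + 1L
  }
  expect_gte(ok / reps, 0.90)
})

test_that("post-experimental power degenerates and bounds correctly", {
  set.seed(91)
  z <- sort(runif(100))
  y <- 1 + z + 1.5 * pmax(z - 0.5, 0) + rnorm(100, sd = 0.2)
  f <- fit_segmented(cp_series(y, z))
  # zero covariance collapses the interval onto the point power
  f0 <- f; f0$cov <- matrix(0, 2, 2, dimnames = dimnames(f$cov))
  r0 <- postexp_power(f0, ci = TRUE, ci_reps = 50, seed = 1)
  expect_equal(r0$ci[1], r0$power, tolerance = 1e-10)
  expect_equal(r0$ci[2], r0$power, tolerance = 1e-10)
  # interval endpoints always within [alpha, 1]
  r <- postexp_power(f, ci = TRUE, ci_reps = 200, seed = 2, alpha = 0.01)
  expect_gte(r$ci[1], 0.01 - 1e-12)
  expect_lte(r$ci[2], 1)
  # reproducible under a fixed seed
  r2 <- postexp_power(f, ci = TRUE, ci_reps = 200, seed = 2, alpha = 0.01)
  expect_identical(r$ci, r2$ci)
  # non-PSD covariance is refused
  fbad <- f; fbad$cov <- matrix(c(1, 2, 2, 1), 2,
                                dimnames = dimnames(f$cov))
  expect_error(postexp_power(fbad), "positive semi-definite")
})
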