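test_that("an exact exponential gives its rate back with R^2 = 1", {
  t <- 0:10
  ser <- inactivation_series(100, t, exp(-0.1 * t))
  fit <- fit_pseudo_first_order(ser)
  expect_equal(fit$k_prime, 0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("constant activity is flagged as no inactivation", {
  ser <- inactivation_series(100, 0:5, rep(1, 6))
  fit <- fit_pseudo_first_order(ser)
  expect_equal(fit$k_prime, 0)
  expect_true("no_inactivation" %in% fit$flags)
  expect_error(fit_pseudo_first_order(
    inactivation_series(100, 0:4, c(1, 0.5, 0.2, 0.1, 0))), "non-positive")
})

test_that("noiseless simulation reproduces the rate law per concentration", {
  Ki <- 0.28; k2 <- 0.27
  sim <- simulate_inactivation(Ki, k2, concentrations_uM = 100)
  fit <- fit_pseudo_first_order(sim[[1]])
  expect_equal(fit$k_prime, k2 * 100 / (Ki * 1000 + 100), tolerance = 1e-6)
  # saturation and half-saturation limits of the planted k'
  big <- simulate_inactivation(Ki, k2, concentrations_uM = 1e9)
  expect_equal(attr(big, "truth")$k_prime, k2, tolerance = 1e-6)
  half <- simulate_inactivation(Ki, k2, concentrations_uM = Ki * 1000)
  expect_equal(attr(half, "truth")$k_prime, k2 / 2, tolerance = 1e-12)
})

test_that("the double-reciprocal fit inverts exact data to machine precision", {
  Ki <- 0.28; k2 <- 0.27
  conc <- c(50, 100, 150, 200, 260)
  kp <- k2 * conc / (Ki * 1000 + conc)
  fit <- fit_kitz_wilson(data.frame(conc_uM = conc, k_prime = kp))
  expect_equal(fit$Ki_mM, Ki, tolerance = 1e-9)
  expect_equal(fit$k2_per_min, k2, tolerance = 1e-9)
  # nonlinear cross-check agrees
  expect_equal(fit$nls_Ki_mM, Ki, tolerance = 1e-6)
  expect_equal(fit$nls_k2_per_min, k2, tolerance = 1e-6)
})

test_that("round-trip identity holds for arbitrary positive parameters", {
  set.seed(77)
  for (i in 1:5) {
    Ki <- runif(1, 0.05, 2); k2 <- runif(1, 0.05, 2)
    sim <- simulate_inactivation(Ki, k2)
    fit <- fit_inactivation(sim)
    expect_equal(fit$Ki_mM, Ki, tolerance = 1e-8)
    expect_equal(fit$k2_per_min, k2, tolerance = 1e-8)
    # fitted k' increase with [I] and stay below k2
    expect_true(all(diff(fit$per_series$k_prime) > 0))
    expect_true(all(fit$per_series$k_prime < fit$k2_per_min))
  }
})

test_that("degenerate reciprocal fits are flagged or rejected", {
  flat <- data.frame(conc_uM = c(50, 100, 200), k_prime = 0.2)
  fit <- fit_kitz_wilson(flat)
  expect_true("degenerate_slope" %in% fit$flags)
  expect_equal(fit$Ki_mM, 0)
  expect_error(fit_kitz_wilson(data.frame(conc_uM = c(50, 100),
                                          k_prime = c(0.1, 0.2))), "3")
  # superlinear k' growth drives the reciprocal intercept negative
  superlinear <- data.frame(conc_uM = c(50, 100, 200),
                            k_prime = c(0.1, 0.3, 1.2))
  expect_error(fit_kitz_wilson(superlinear), "saturation")
  # k' decreasing with [I]: negative slope, Ki clamped at 0 and flagged
  decreasing <- data.frame(conc_uM = c(10, 100, 1000),
                           k_prime = c(0.3, 0.2, 0.1))
  fit2 <- fit_kitz_wilson(decreasing)
  expect_true("degenerate_slope" %in% fit2$flags)
  expect_equal(fit2$Ki_mM, 0)
})

test_that("noisy estimates have small median bias over many seeds", {
  Ki <- 0.28; k2 <- 0.27
  est <- t(vapply(1:60, function(s) {
    sim <- simulate_inactivation(Ki, k2, noise_sd = 0.05, seed = s)
    fit <- fit_inactivation(sim)
    c(fit$Ki_mM, fit$k2_per_min)
  }, numeric(2)))
  expect_lt(abs(median(est[, 1]) - Ki) / Ki, 0.10)
  expect_lt(abs(median(est[, 2]) - k2) / k2, 0.10)
})

test_that("series validation enforces the physical domain", {
  expect_error(inactivation_series(-5, 0:3, exp(-0.1 * 0:3)), "positive")
  expect_error(inactivation_series(50, c(0, 2, 1), c(1, 0.9, 0.8)),
               "increasing")
  expect_error(inactivation_series(50, 0:2, c(1, 1.2, 0.9)), "fraction")
})
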