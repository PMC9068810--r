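test_that("empirical CDF is the right-continuous step function", {
  F1 <- empirical_cdf(c(1, 2, 3))
  expect_equal(F1(2), 2 / 3)
  expect_equal(F1(3), 1)
  F2 <- empirical_cdf(5)
  expect_equal(F2(4.999), 0)
  expect_equal(F2(5), 1)
  expect_error(empirical_cdf(numeric(0)), "no uncensored")
  expect_equal(empirical_cdf(c(1, 2), censored = c(FALSE, TRUE))(1.5), 1)
})

test_that("CDF least-squares fit recovers a single exponential", {
  set.seed(401)
  tt <- rexp(5000, 1 / 5)
  fit <- fit_cdf_exponentials(tt, k = 1, rng_seed = 1)
  expect_lt(abs(fit$lifetimes_raw - 5), 5 * 3 / sqrt(5000))

  # nesting: k = 2 on single-exponential data degenerates gracefully
  fit2 <- fit_cdf_exponentials(tt, k = 2, rng_seed = 1)
  degenerate <- min(fit2$fractions) < 0.05 ||
    max(fit2$lifetimes_raw) / min(fit2$lifetimes_raw) < 1.5
  expect_true(degenerate || fit$loss / fit2$loss < 1.1)
  expect_lte(fit2$loss, fit$loss * (1 + 1e-6))

  expect_error(fit_cdf_exponentials(rep(2, 50), k = 1), "degenerate")
  expect_error(fit_cdf_exponentials(rexp(5), k = 1), ">= 10")
})

test_that("censored mixture MLE matches the closed form for k = 1", {
  set.seed(402)
  tt <- rexp(500, 1 / 20) + 1   # keep everything above resolution
  fit <- fit_mle_mixture(tt, k = 1, resolution = 0.2)
  expect_equal(fit$lifetimes_raw, mean(tt))
  # censoring included through the survival term
  cens <- tt > 30
  tt2 <- pmin(tt, 30)
  fit2 <- fit_mle_mixture(tt2, cens, k = 1, resolution = 0.2)
  expect_equal(fit2$lifetimes_raw, sum(tt2) / sum(!cens))
  expect_equal(fit2$n_censored, sum(cens))
})

test_that("ignoring right-censoring underestimates the lifetime", {
  set.seed(403)
  tt <- rexp(3000, 1 / 133)
  cens <- tt > 300
  obs <- pmin(tt, 300)
  fit_ok <- fit_mle_mixture(obs, cens, k = 1, resolution = 0.2)
  fit_bad <- fit_mle_mixture(obs, rep(FALSE, 3000), k = 1, resolution = 0.2)
  expect_lt(abs(fit_ok$lifetimes_raw - 133) / 133, 0.1)
  # naive estimate converges to E[min(T, 300)] = 133*(1 - exp(-300/133))
  expect_lt(fit_bad$lifetimes_raw, fit_ok$lifetimes_raw * 0.95)
  expect_lt(abs(fit_bad$lifetimes_raw - 133 * (1 - exp(-300 / 133))) / 133,
            0.1)
})

test_that("sub-resolution dwells yield a zero-lifetime component", {
  set.seed(404)
  n <- 4000
  comp <- sample(1:2, n, TRUE, prob = c(0.4, 0.6))
  tt <- rexp(n, 1 / c(0.02, 13)[comp])
  fit <- fit_mle_mixture(tt, k = 2, resolution = 0.2, rng_seed = 2)
  expect_equal(fit$lifetimes[1], 0)
  se <- sqrt(0.4 * 0.6 / n)
  expect_lt(abs(fit$fractions[1] - 0.4), 3 * se)
  expect_lt(abs(fit$lifetimes[2] - 13) / 13, 0.1)
})

test_that("three-component mixtures are recovered and nested logLik grows", {
  set.seed(405)
  n <- 6000
  comp <- sample(1:3, n, TRUE, prob = c(0.4, 0.4, 0.2))
  tt <- rexp(n, 1 / c(0.5, 13, 133)[comp])
  fits <- lapply(1:3, function(k)
    fit_mle_mixture(tt, k = k, resolution = 0.2, rng_seed = 3))
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  expect_true(all(diff(lls) > -1e-6))
  f3 <- fits[[3]]
  expect_lt(abs(f3$lifetimes_raw[1] - 0.5), 0.15)
  expect_lt(abs(f3$lifetimes_raw[2] - 13) / 13, 0.15)
  expect_lt(abs(f3$lifetimes_raw[3] - 133) / 133, 0.25)
  expect_lt(max(abs(f3$fractions - c(0.4, 0.4, 0.2))), 0.05)
  expect_equal(sum(f3$fractions), 1, tolerance = 1e-6)
})

test_that("CDF and MLE estimators agree on large uncensored samples", {
  set.seed(406)
  tt <- rexp(5000, 1 / 40) + 0.5
  f_cdf <- fit_cdf_exponentials(tt, k = 1, rng_seed = 4)
  f_mle <- fit_mle_mixture(tt, k = 1, resolution = 0.2)
  expect_lt(abs(f_cdf$lifetimes_raw - f_mle$lifetimes_raw) /
              f_mle$lifetimes_raw, 0.02)
})

test_that("model selection chooses the parsimonious component count", {
  set.seed(407)
  one <- rexp(2000, 1 / 10) + 0.5
  fits1 <- lapply(1:2, function(k)
    fit_mle_mixture(one, k = k, resolution = 0.2, rng_seed = 5))
  sel1 <- select_model(fits1)
  expect_equal(sel1$k, 1L)
  expect_named(sel1$bic, c("k1", "k2"))

  comp <- sample(1:3, 10000, TRUE, prob = c(0.4, 0.4, 0.2))
  three <- rexp(10000, 1 / c(0.5, 13, 133)[comp]) + 0.25
  fits3 <- lapply(1:3, function(k)
    fit_mle_mixture(three, k = k, resolution = 0.2, rng_seed = 6))
  expect_equal(select_model(fits3)$k, 3L)

  # low power: n = 30 with lifetimes 10 vs 15 is indistinguishable
  comp2 <- sample(1:2, 30, TRUE)
  small <- rexp(30, 1 / c(10, 15)[comp2]) + 0.5
  fits_s <- lapply(1:2, function(k)
    fit_mle_mixture(small, k = k, resolution = 0.2, rng_seed = 7))
  expect_equal(select_model(fits_s)$k, 1L)

  expect_error(select_model(list(fits3[[1]], fits3[[3]])), "nested")
})

test_that("bootstrap intervals are deterministic and sane", {
  set.seed(408)
  tt <- rexp(800, 1 / 13) + 0.3
  fit <- fit_mle_mixture(tt, k = 1, resolution = 0.2)
  b1 <- bootstrap_errors(tt, NULL, fit, n_boot = 200, rng_seed = 11)
  b2 <- bootstrap_errors(tt, NULL, fit, n_boot = 200, rng_seed = 11)
  expect_identical(b1$ci_lower, b2$ci_lower)
  expect_identical(b1$ci_upper, b2$ci_upper)
  expect_true(b1$ci_lower[1] <= fit$lifetimes_raw &&
                fit$lifetimes_raw <= b1$ci_upper[1])
  expect_error(bootstrap_errors(tt, NULL, fit, n_boot = 0), "positive")
})

test_that("density histogram uses binomial errors and normalizes", {
  set.seed(409)
  tt <- c(runif(50, 0, 1), runif(50, 1, 4))
  h <- density_histogram(tt, c(0, 1, 2, 3, 4))
  expect_equal(h$density[1], 0.5)
  expect_equal(h$error[1], sqrt(0.5 * 0.5 / 100) / 1)
  expect_equal(sum(h$density * (h$bin_hi - h$bin_lo)), 1)
  # empty bin: density and error both zero
  h2 <- density_histogram(c(0.5, 2.5), c(0, 1, 2, 3))
  expect_equal(h2$density[2], 0)
  expect_equal(h2$error[2], 0)
  expect_error(density_histogram(tt, c(0, 2, 1)), "increasing")
})

test_that("two-sample KS statistic matches brute-force ECDF enumeration", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)

  x <- c(1, 2, 3); y <- c(1, 2, 3, 4)
  grid <- sort(unique(c(x, y)))
  d_brute <- max(vapply(grid, function(t)
    abs(mean(x <= t) - mean(y <= t)), numeric(1)))
  expect_equal(ks_two_sample(x, y)$D, d_brute)

  set.seed(410)
  a <- rexp(40, 1); b <- rexp(60, 1 / 2)
  grid2 <- sort(unique(c(a, b)))
  d2 <- max(vapply(grid2, function(t)
    abs(mean(a <= t) - mean(b <= t)), numeric(1)))
  expect_equal(ks_two_sample(a, b)$D, d2)
})

test_that("cellular access-time bound reproduces the analytic ranges", {
  ab <- access_time_bound(copies = c(10, 60), volume_um3 = 0.5, k_on = 2e5)
  expect_equal(signif(ab$concentration_nM[1], 1), 30)
  expect_equal(signif(ab$concentration_nM[2], 1), 200)
  expect_equal(signif(ab$access_time_s[ab$copies == 60], 2), 25)
  expect_equal(signif(ab$access_time_s[ab$copies == 10], 2), 150)
  # doubling k_on halves the access time, concentration unchanged
  ab2 <- access_time_bound(copies = c(10, 60), volume_um3 = 0.5, k_on = 4e5)
  expect_equal(ab2$access_time_s, ab$access_time_s / 2)
  expect_equal(ab2$concentration_nM, ab$concentration_nM)
})

test_that("simulate method draws from the fitted mixture", {
  fit <- fit_mle_mixture(rexp(500, 1 / 10) + 0.5, k = 1, resolution = 0.2)
  s1 <- simulate(fit, nsim = 1000, seed = 20)
  s2 <- simulate(fit, nsim = 1000, seed = 20)
  expect_identical(s1, s2)
  expect_lt(abs(mean(s1) - fit$lifetimes_raw) / fit$lifetimes_raw, 0.15)
})
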