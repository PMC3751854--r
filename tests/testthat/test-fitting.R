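test_that("point selection drops the first echo and trailing low-SNR run", {
  s <- make_series(500, 50, noise_sd = 0)
  # all 8 echoes well above the floor: 7 survive
  expect_identical(nrow(select_points(s, noise_sd = 1)), 7L)
  # last two echoes pushed under 2 * noise_sd: 5 survive
  s2 <- s
  s2$si[7:8] <- c(1.9, 1.5) * 10
  expect_identical(nrow(select_points(s2, noise_sd = 10)), 5L)
  # an interior dip is kept
  s3 <- s
  s3$si[4] <- 0.5 * 10
  kept <- select_points(s3, noise_sd = 10)
  expect_identical(nrow(kept), 7L)
  expect_true(any(kept$si == 5))
  # everything below the floor: nothing survives
  s4 <- s
  s4$si <- rep(1, 8)
  expect_identical(nrow(select_points(s4, noise_sd = 10)), 0L)
  # noise_sd = 0 disables the SNR rule
  expect_identical(nrow(select_points(s4, noise_sd = 0)), 7L)
})

test_that("robust log-linear fit recovers exact data and resists outliers", {
  te <- TE8[-1]
  clean <- tibble::tibble(te_ms = te, si = 500 * exp(-te / 50))
  rob <- robust_loglinear_fit(clean)
  expect_true(rob$ok)
  expect_lt(abs(rob$t2_ms0 - 50) / 50, 1e-9)
  expect_lt(abs(rob$beta0 - 500) / 500, 1e-9)
  expect_lt(rob$p_t2, 1e-6)
  expect_lt(rob$p_beta, 1e-6)
  # a 10x outlier: bisquare downweights it, plain log-LS does not
  dirty <- clean
  dirty$si[5] <- dirty$si[5] * 10
  rob2 <- robust_loglinear_fit(dirty)
  expect_lt(abs(rob2$t2_ms0 - 50) / 50, 0.02)
  ols <- stats::lm(log(si) ~ te_ms, data = dirty)
  expect_gt(abs(-1 / coef(ols)[2] - 50) / 50, 0.10)
})

test_that("robust IRLS matches MASS::rlm bisquare on noisy data", {
  skip_if_not_installed("MASS")
  set.seed(3)
  te <- TE8[-1]
  for (i in 1:5) {
    si <- rician(500 * exp(-te / 50), 15)
    mine <- robust_loglinear_fit(tibble::tibble(te_ms = te, si = si))
    ref <- MASS::rlm(log(si) ~ te, psi = MASS::psi.bisquare, maxit = 100)
    expect_equal(mine$slope, unname(coef(ref)[2]), tolerance = 1e-4)
    expect_equal(mine$intercept, unname(coef(ref)[1]), tolerance = 1e-4)
  }
})

test_that("non-decaying or degenerate series take the failure path", {
  te <- TE8[-1]
  flat <- tibble::tibble(te_ms = te, si = rep(100, 7))
  r <- robust_loglinear_fit(flat)
  expect_false(r$ok)
  expect_identical(r$reason, "non_decaying")
  expect_identical(r$p_t2, 1)
  rising <- tibble::tibble(te_ms = te, si = 100 * exp(te / 80))
  expect_identical(robust_loglinear_fit(rising)$reason, "non_decaying")
  few <- tibble::tibble(te_ms = te[1:2], si = c(100, 50))
  expect_identical(robust_loglinear_fit(few)$reason, "too_few_points")
})

test_that("noise-free series is fitted exactly and accepted", {
  fit <- fit_monoexponential(make_series(500, 50, noise_sd = 0,
                                         first_echo_scale = 0.85),
                             noise_sd = 0)
  expect_true(fit$accepted)
  expect_identical(fit$n_points_used, 7L)
  expect_identical(fit$init_source, "robust_linear")
  expect_lt(abs(fit$t2_ms - 50) / 50, 1e-6)
  expect_lt(abs(fit$beta - 500) / 500, 1e-6)
  expect_lt(fit$p_t2, 1e-10)
  td <- tidy(fit)
  expect_identical(td$term, c("beta", "t2_ms"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
})

test_that("perturbing the first echo changes nothing", {
  s <- make_series(500, 50, noise_sd = 0)
  f1 <- fit_monoexponential(s, noise_sd = 5)
  s$si[1] <- 9999
  f2 <- fit_monoexponential(s, noise_sd = 5)
  expect_identical(f1$t2_ms, f2$t2_ms)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$p_t2, f2$p_t2)
  expect_identical(f1$accepted, f2$accepted)
})

test_that("common rescaling leaves T2 and p-values invariant, scales beta", {
  set.seed(8)
  s <- make_series(500, 60, noise_sd = 12)
  f1 <- fit_monoexponential(s, noise_sd = 12)
  s2 <- s
  s2$si <- s$si * 7
  f2 <- fit_monoexponential(s2, noise_sd = 7 * 12)
  expect_equal(f2$t2_ms, f1$t2_ms, tolerance = 1e-7)
  expect_equal(f2$p_t2, f1$p_t2, tolerance = 1e-6)
  expect_equal(f2$p_beta, f1$p_beta, tolerance = 1e-6)
  expect_equal(f2$beta, 7 * f1$beta, tolerance = 1e-7)
  expect_equal(f2$se_beta, 7 * f1$se_beta, tolerance = 1e-6)
})

test_that("all-noise series is never accepted and gate holds its level", {
  set.seed(21)
  accepted <- replicate(400, {
    s <- tibble::tibble(te_ms = TE8, si = rician(rep(0, 8), 10))
    fit_monoexponential(s, noise_sd = 10)$accepted
  })
  expect_lte(mean(accepted), 0.05)
})

test_that("too few surviving points reject with the right reason", {
  # short series: insufficient points even before the SNR rule
  s <- tibble::tibble(te_ms = TE8[1:3], si = c(400, 300, 200))
  f <- fit_monoexponential(s, noise_sd = 1)
  expect_false(f$accepted)
  expect_identical(f$reject_reason, "insufficient_points")
  # full series drowned by noise: below_noise
  s2 <- tibble::tibble(te_ms = TE8, si = rep(5, 8))
  f2 <- fit_monoexponential(s2, noise_sd = 10)
  expect_false(f2$accepted)
  expect_identical(f2$reject_reason, "below_noise")
})

test_that("default initial values are used when the linear gate fails", {
  # monotonically rising signal: robust fit flags non-decaying
  s <- tibble::tibble(te_ms = TE8, si = 100 * exp(TE8 / 300))
  f <- fit_monoexponential(s, noise_sd = 1)
  expect_identical(f$init_source, "default")
  expect_false(f$accepted)
})

test_that("T2 estimator precision improves as noise falls", {
  set.seed(31)
  spread <- vapply(c(15, 5), function(sdn) {
    est <- replicate(150, {
      f <- fit_monoexponential(make_series(500, 50, noise_sd = sdn,
                                           first_echo_scale = 0.85), sdn)
      f$t2_ms
    })
    sd(est, na.rm = TRUE)
  }, numeric(1))
  expect_lt(spread[2], spread[1])
})

test_that("half-life arithmetic matches the TE-design numbers", {
  expect_equal(round(halflife_ms(50)), 35)
  expect_equal(round(halflife_ms(35)), 24)
  x <- c(0.5, 10, 50, 107, 333)
  expect_equal(halflife_ms(x) / x, rep(log(2), 5))
  expect_error(halflife_ms(0), "positive")
  expect_equal(pixel_size_mm(160, 640), 0.25)
  expect_error(pixel_size_mm(-1, 10), "positive")
})

test_that("noise SD estimators invert the Rayleigh moments", {
  set.seed(17)
  n <- 120
  stack <- array(rician(rep(0, n * n * 2), 10), c(n, n, 2))
  series <- list(stack = stack, te_ms = c(10, 20))
  bg <- matrix(TRUE, n, n)
  est_mean <- estimate_noise_sd(series, bg, method = "mean")
  est_sd <- estimate_noise_sd(series, bg, method = "sd")
  expect_lt(abs(est_mean - 10) / 10, 0.02)
  expect_lt(abs(est_mean - est_sd) / est_mean, 0.05)
  zero <- list(stack = array(0, c(4, 4, 2)), te_ms = c(10, 20))
  expect_warning(z <- estimate_noise_sd(zero, matrix(TRUE, 4, 4)), "zero")
  expect_identical(z, 0)
  expect_error(estimate_noise_sd(series, matrix(FALSE, n, n)), "empty")
})

test_that("LM never loses to the dense grid-search oracle", {
  set.seed(4)
  cfg <- fit_config()
  for (i in 1:20) {
    beta <- runif(1, 100, 1000)
    t2 <- runif(1, 20, 150)
    sdn <- runif(1, 2, 20)
    s <- make_series(beta, t2, noise_sd = sdn, first_echo_scale = 0.85)
    f <- fit_monoexponential(s, sdn, cfg)
    if (!is.finite(f$rss)) next
    sel <- select_points(s, sdn, cfg)
    g <- grid_search_rss(sel$te_ms, sel$si)
    expect_lte(f$rss, g * (1 + 1e-9))
  }
})
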