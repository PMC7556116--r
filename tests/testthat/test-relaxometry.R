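test_that("noiseless exponentials are recovered to machine-level accuracy", {
  tgrid <- seq(0, 8e-3, length.out = 8)
  curve <- decay_curve(tgrid, 3.2 * exp(-500 * tgrid), "s1", "echo")
  fit <- fit_monoexponential(curve)
  expect_equal(fit$rate, 500, tolerance = 1e-6)
  expect_equal(fit$amplitude, 3.2, tolerance = 1e-6)
  expect_equal(fit$delta_homo, 500 / pi, tolerance = 1e-6)
  # constant curve
  flat <- fit_monoexponential(decay_curve(tgrid, rep(2, 8), "s2", "echo"))
  expect_equal(flat$rate, 0)
  expect_equal(flat$delta_homo, 0)
  # spin-lock fits carry no linewidth
  sl <- fit_monoexponential(decay_curve(tgrid, exp(-100 * tgrid), "s3",
                                        "spinlock"))
  expect_true(is.na(sl$delta_homo))
})

test_that("a 160 Hz homogeneous linewidth corresponds to T2' of 2 ms", {
  tgrid <- seq(0, 6e-3, length.out = 8)
  fit <- fit_monoexponential(
    decay_curve(tgrid, exp(-160 * pi * tgrid), "x", "echo")
  )
  expect_equal(fit$delta_homo, 160, tolerance = 1e-6)
  expect_equal(fit$T_decay, 2e-3, tolerance = 0.01)
  expect_equal(t2prime_from_delta_homo(160) * 1e3, 2, tolerance = 0.05)
  expect_equal(delta_homo_from_rate(0), 0)
  # round trip
  expect_equal(delta_homo_from_rate(rate_from_delta_homo(123.4)), 123.4,
               tolerance = 1e-12)
  expect_equal(1 / (pi * t2prime_from_delta_homo(37)), 37, tolerance = 1e-12)
})

test_that("fits are scale invariant and nearly unbiased across rates", {
  # sampling adapted to the rate, as a measurement would be: ~2.5 decay
  # constants covered by 9 points
  for (R in c(10, 50, 160 * pi, 1000)) {
    tg <- seq(0, 2.5 / R, length.out = 9)
    bias <- vapply(1:60, function(s) {
      curve <- make_decay(R, tg, noise_fraction = 0.05, seed = s)
      fit_monoexponential(curve)$rate / R - 1
    }, numeric(1))
    expect_lt(abs(stats::median(bias)), 0.03)
  }
  tgrid <- seq(0.2e-3, 12e-3, length.out = 9)
  c1 <- make_decay(300, tgrid, 0.05, seed = 11)
  c2 <- decay_curve(c1$times, 1e4 * c1$intensities, "scaled", "echo")
  f1 <- fit_monoexponential(c1)
  f2 <- fit_monoexponential(c2)
  expect_equal(f2$rate, f1$rate, tolerance = 1e-8)
  expect_equal(f2$amplitude, 1e4 * f1$amplitude, tolerance = 1e-6)
})

test_that("bootstrap errors are seed-deterministic and vanish without noise", {
  tgrid <- seq(0, 10e-3, length.out = 8)
  curve <- make_decay(400, tgrid, noise_fraction = 0.05, seed = 3)
  f1 <- bootstrap_ci(curve, n_iter = 200, seed = 42)
  f2 <- bootstrap_ci(curve, n_iter = 200, seed = 42)
  expect_identical(f1$ci_2sigma, f2$ci_2sigma)
  expect_gt(f1$ci_2sigma, 0)
  expect_equal(f1$n_bootstrap, 200L)
  clean <- decay_curve(tgrid, exp(-400 * tgrid), "clean", "echo")
  expect_equal(bootstrap_ci(clean, n_iter = 150, seed = 1)$ci_2sigma, 0)
  expect_error(bootstrap_ci(curve, n_iter = 50, seed = 1), "n_iter")
})

test_that("bootstrap 2-sigma intervals cover the true rate at ~95%", {
  # coverage oracle: repeated synthetic experiments at 5% noise
  tgrid <- seq(0.3e-3, 12e-3, length.out = 8)
  R <- 300
  hits <- vapply(1:120, function(s) {
    curve <- make_decay(R, tgrid, noise_fraction = 0.05, seed = 1000 + s)
    fit <- bootstrap_ci(curve, n_iter = 200, seed = s)
    abs(fit$rate - R) <= fit$ci_2sigma
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("decay tables round-trip through CSV fitting", {
  tgrid <- seq(0, 10e-3, length.out = 8)
  tab <- do.call(rbind, lapply(c(a = 150, b = 600), function(R) NULL))
  rows <- list()
  for (site in c("a", "b")) {
    R <- c(a = 150, b = 600)[[site]]
    cv <- make_decay(R, tgrid, 0.03, seed = match(site, c("a", "b")),
                     site_label = site)
    rows[[site]] <- data.frame(site = site, time_s = cv$times,
                               intensity = cv$intensities)
  }
  path <- tempfile(fileext = ".csv")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  fits <- fit_decay_table(path, experiment_kind = "echo", n_bootstrap = 150,
                          seed = 2)
  expect_equal(nrow(fits), 2)
  expect_equal(fits$rate_s[fits$site == "a"], 150, tolerance = 0.1)
  expect_equal(fits$rate_s[fits$site == "b"], 600, tolerance = 0.1)
  expect_true(all(fits$ci_2sigma > 0))
})
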