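test_that("editing efficiency reproduces the NH/NH2 editing delays", {
  J <- 92
  # NH2 null at 1/(4J): 2.7 ms at J = 92 Hz, found by root-finding
  supp <- suppression_delay(J)
  expect_equal(supp, 1 / (4 * J), tolerance = 1e-9)
  expect_equal(signif(supp * 1e3, 2), 2.7)
  expect_equal(editing_efficiency(inept_params(J = J, tau_N = supp)), 0,
               tolerance = 1e-9)
  # NH efficiency is maximal at the same delay
  nh <- function(tn) editing_efficiency(inept_params(J = J, tau_N = tn,
                                                     n_protons = 1))
  expect_equal(stats::optimize(nh, c(0, 1 / (2 * J)),
                               maximum = TRUE)$maximum, supp,
               tolerance = 1e-5)
  # NH2 maximum near 1.4 ms (= 1/(8J))
  mx <- nh2_max_delay(J)
  expect_equal(mx, 1 / (8 * J), tolerance = 1e-6)
  expect_equal(signif(mx * 1e3, 2), 1.4)
  # 1/J scaling of the null
  expect_equal(suppression_delay(184), supp / 2, tolerance = 1e-9)
  # no finite null for NH before its maximum
  expect_error(suppression_delay(J, n_protons = 1), "NH2")
  # zero delay transfers nothing
  expect_equal(editing_efficiency(inept_params(tau_N = 0)), 0)
})

test_that("editing factor is periodic in tau_N and odd about its nulls", {
  J <- 92
  eps2 <- function(tn) editing_efficiency(inept_params(J = J, tau_N = tn))
  period <- 1 / (2 * J)
  null <- 1 / (4 * J)
  for (tn in c(0.3e-3, 1.1e-3, 2.4e-3)) {
    expect_equal(eps2(tn + period), eps2(tn), tolerance = 1e-12)
    expect_equal(eps2(null + tn), -eps2(null - tn), tolerance = 1e-12)
  }
  curve <- editing_curve(J = J)
  expect_true(all(abs(curve$epsilon_NH) <= 1))
  expect_true(all(abs(curve$epsilon_NH2) <= 1))
  expect_equal(curve$epsilon_NH2[1], 0)
})

test_that("density-matrix INEPT matches the analytic formula to 1e-6", {
  J <- 92
  grid <- seq(0.2e-3, 5.2e-3, length.out = 11)
  for (n in 1:3) {
    for (tn in grid) {
      p <- inept_params(J = J, tau_H = 2e-3, tau_N = tn, n_protons = n)
      expect_equal(simulate_inept_numeric(p), editing_efficiency(p),
                   tolerance = 1e-6)
    }
  }
  # full transfer for NH at matched quarter-J delays
  p1 <- inept_params(J = J, tau_H = 1 / (4 * J), tau_N = 1 / (4 * J),
                     n_protons = 1)
  expect_equal(simulate_inept_numeric(p1), 1, tolerance = 1e-9)
})

test_that("relaxation attenuation follows the proton-echo convention", {
  p <- inept_params(J = 92, tau_H = 2e-3, tau_N = 1.2e-3, n_protons = 2,
                    T2prime_H = 2e-3)
  att <- relaxation_attenuation(p)
  # T2' = 2 ms, tau_H = 2 ms: 1 - exp(-2) ~ 86.5%, the ~88% regime
  expect_equal(att, 1 - exp(-2), tolerance = 1e-12)
  expect_gt(att, 0.85)
  expect_lt(att, 0.91)
  # no relaxation, no attenuation
  expect_equal(relaxation_attenuation(inept_params(T2prime_H = Inf)), 0)
  # strictly increasing in tau_H
  atts <- vapply(seq(0.5e-3, 4e-3, length.out = 8), function(th) {
    relaxation_attenuation(inept_params(tau_H = th, T2prime_H = 2e-3))
  }, numeric(1))
  expect_true(all(diff(atts) > 0))
  # alternative conventions are larger (more proton transverse time)
  expect_gt(relaxation_attenuation(p, convention = "2tauH+2tauN"), att)
  expect_gt(relaxation_attenuation(p, convention = "4tauH"), att)
})

test_that("numeric damping reproduces the analytic attenuation", {
  p <- inept_params(J = 92, tau_H = 2e-3, tau_N = 1.2e-3, n_protons = 2,
                    T2prime_H = 2e-3)
  p0 <- p
  p0$T2prime_H <- Inf
  ratio <- simulate_inept_numeric(p) / simulate_inept_numeric(p0)
  expect_equal(1 - ratio, relaxation_attenuation(p, convention = "2tauH"),
               tolerance = 1e-6)
})
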