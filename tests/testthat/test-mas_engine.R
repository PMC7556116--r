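test_that("rotor-modulated coupling has no net evolution at the magic angle", {
  cond <- mas_conditions(spinning_rate = 110e3, n_crystallites = 5)
  sys <- two_proton_system()
  # rotor-period average of the pair coefficient vanishes for any orientation
  Tr <- 1 / cond$spinning_rate
  tt <- (seq_len(2000) - 0.5) * Tr / 2000
  for (orient in list(c(0.3, 1.1), c(2.0, 0.4), c(5.1, 2.8))) {
    Hbar <- Reduce(`+`, lapply(tt, function(t1) {
      hamiltonian_at(sys, cond, orient, t1)
    })) / length(tt)
    expect_lt(max(Mod(Hbar)), 1e-6 * 2 * pi * 15015)
  }
})

test_that("single-spin Hamiltonian with an offset is diagonal", {
  sys <- build_spin_system(list(spin_site("a", "1H", c(0, 0, 0),
                                          isotropic_shift = 2)))
  cond <- mas_conditions()
  H <- hamiltonian_at(sys, cond, c(0.5, 0.5), 1e-6)
  expect_equal(H[1, 2], 0 + 0i)
  expect_equal(H[2, 1], 0 + 0i)
  off <- 2 * pi * 2e-6 * larmor_frequency("1H", 20)
  expect_equal(Re(H[1, 1]), off / 2, tolerance = 1e-9)
})

test_that("rotor propagator is unitary, converged, and exact for one spin", {
  sys <- three_proton_cluster()
  cond <- mas_conditions(n_crystallites = 1)
  U <- rotor_propagator(sys, cond, c(0.7, 1.2))
  expect_lt(max(Mod(U %*% Conj(t(U)) - diag(8))), 1e-10)
  # doubling the time discretization barely changes echo amplitudes
  sch <- rotor_synchronized_grid(mas_conditions(n_crystallites = 8), 2e-3,
                                 n_points = 4)
  a50 <- simulate_echo_decay(sys, mas_conditions(n_crystallites = 8), sch)
  a100 <- simulate_echo_decay(
    sys, mas_conditions(steps_per_rotor_period = 100, n_crystallites = 8), sch
  )
  expect_lt(max(abs(a50$amplitudes - a100$amplitudes)), 1e-4)
  # commuting (single-spin) case equals the closed-form exponential
  sys1 <- build_spin_system(list(spin_site("a", "1H", c(0, 0, 0),
                                           isotropic_shift = 1)))
  U1 <- rotor_propagator(sys1, cond, c(0.1, 0.2))
  w <- 2 * pi * 1e-6 * larmor_frequency("1H", 20)
  Tr <- 1 / cond$spinning_rate
  expect_equal(U1, diag(exp(-1i * w * c(0.5, -0.5) * Tr)), tolerance = 1e-9)
})

test_that("static two-spin powder pattern shows Pake horns at 3/4 of the anisotropy", {
  sys <- two_proton_system(2.0)
  cond <- mas_conditions(static = TRUE, n_crystallites = 2584)
  spec <- simulate_spectrum(sys, cond, lb_hz = 300, df_hz = 30,
                            freq_range = c(-30000, 30000))
  df <- spec$spectrum
  horn_pos <- df$freq_hz[df$freq_hz > 2000][
    which.max(df$intensity[df$freq_hz > 2000])]
  horn_neg <- df$freq_hz[df$freq_hz < -2000][
    which.max(df$intensity[df$freq_hz < -2000])]
  expect_equal(horn_pos, 0.75 * 15015, tolerance = 0.03)
  expect_equal(horn_neg, -0.75 * 15015, tolerance = 0.03)
})

test_that("echoes of one- and two-spin systems refocus exactly", {
  cond <- mas_conditions(n_crystallites = 12)
  sch <- rotor_synchronized_grid(cond, 5e-3, n_points = 6)
  sys1 <- build_spin_system(list(spin_site("a", "1H", c(0, 0, 0),
                                           isotropic_shift = 3)))
  d1 <- simulate_echo_decay(sys1, cond, sch, detection = "total")
  expect_equal(d1$amplitudes, rep(1, 6), tolerance = 1e-8)
  sys2 <- two_proton_system(2.0)
  for (det in c("total", "peak")) {
    d2 <- simulate_echo_decay(sys2, cond, sch, detection = det)
    expect_equal(d2$amplitudes, rep(1, 6), tolerance = 1e-8)
  }
  expect_lt(fit_decay_linewidth(simulate_echo_decay(sys2, cond, sch))$delta_homo,
            1e-6)
})

test_that("engine echo evolution matches brute-force fine-step propagation", {
  # oracle: direct product of 500 piecewise exponentials per rotor period
  # over the whole echo, in plain R
  sys <- three_proton_cluster()
  cond <- mas_conditions(spinning_rate = 110e3, steps_per_rotor_period = 50,
                         n_crystallites = 1)
  orient <- c(0.8, 1.1)
  k <- 55 # half-echo periods (0.5 ms)
  U <- rotor_propagator(sys, cond, orient)
  n <- 3
  ids <- vapply(sys$sites, function(s) s$site_id, character(1))
  Ix <- Reduce(`+`, lapply(1:n, function(j) ladderNMR:::single_spin_op(n, j, "x")))
  P <- ladderNMR:::pulse_operator(n, 1:n, pi, "x")
  Uk <- diag(8) + 0i
  for (q in seq_len(k)) Uk <- U %*% Uk
  E <- Uk %*% P %*% Uk
  amp_engine <- Re(sum(diag(Ix %*% E %*% Ix %*% Conj(t(E))))) /
    Re(sum(diag(Ix %*% Ix)))

  S <- 500
  Tr <- 1 / cond$spinning_rate
  dt <- Tr / S
  prop_over <- function(t0, t1) {
    nst <- round((t1 - t0) / dt)
    tmid <- t0 + (seq_len(nst) - 0.5) * dt
    Uacc <- diag(8) + 0i
    for (s in seq_len(nst)) {
      H <- hamiltonian_at(sys, cond, orient, tmid[s])
      ed <- eigen(H, symmetric = TRUE)
      Uacc <- (ed$vectors %*% diag(exp(-1i * ed$values * dt)) %*%
                 Conj(t(ed$vectors))) %*% Uacc
    }
    Uacc
  }
  Eb <- prop_over(k * Tr, 2 * k * Tr) %*% P %*% prop_over(0, k * Tr)
  amp_brute <- Re(sum(diag(Ix %*% Eb %*% Ix %*% Conj(t(Eb))))) /
    Re(sum(diag(Ix %*% Ix)))
  expect_lt(abs(amp_engine - amp_brute), 1e-4)
})

test_that("powder-averaged decay is invariant under global coordinate rotation", {
  th <- 1.1
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  sites <- list(
    spin_site("a", "1H", c(0, 0, 0)),
    spin_site("b", "1H", c(0.8747, 0, -0.505)),
    spin_site("c", "1H", c(0.8747, 0, 3.285))
  )
  rot <- lapply(sites, function(s) {
    spin_site(s$site_id, "1H", as.numeric(R %*% s$position))
  })
  cond <- mas_conditions(n_crystallites = 144)
  sch <- rotor_synchronized_grid(cond, 8e-3, n_points = 5)
  d0 <- simulate_echo_decay(build_spin_system(sites), cond, sch)
  d1 <- simulate_echo_decay(build_spin_system(rot), cond, sch)
  expect_lt(max(abs(d0$amplitudes - d1$amplitudes)), 0.01)
})

test_that("spectra place single lines correctly and conserve intensity", {
  sys <- build_spin_system(list(spin_site("a", "1H", c(0, 0, 0),
                                          isotropic_shift = 0.002)))
  cond <- mas_conditions(n_crystallites = 3)
  spec <- simulate_spectrum(sys, cond, lb_hz = 2)
  off <- 0.002e-6 * larmor_frequency("1H", 20)
  peak <- spec$spectrum$freq_hz[which.max(spec$spectrum$intensity)]
  df_grid <- diff(spec$spectrum$freq_hz[1:2])
  expect_lt(abs(peak - off), df_grid)
  # spectrum integral equals the first FID point (unit-area line shapes)
  expect_equal(sum(spec$spectrum$intensity) * df_grid, Re(spec$fid[1]),
               tolerance = 0.02)
  expect_equal(Re(spec$fid[1]), 1, tolerance = 1e-9)
})

test_that("spectator-sector averaging agrees with full-space propagation", {
  sites <- list(
    spin_site("H1", "1H", c(0, 0, 1.01)),
    spin_site("H2", "1H", c(0.87, 0, -0.5)),
    spin_site("N1", "15N", c(0, 0, 0))
  )
  sys <- build_spin_system(sites, scalar_couplings = list(
    list(pair = c("N1", "H1"), J = 92), list(pair = c("N1", "H2"), J = 92)
  ))
  cond <- mas_conditions(n_crystallites = 13)
  sch <- rotor_synchronized_grid(cond, 4e-3, n_points = 5)
  for (det in c("total", "peak")) {
    ds <- simulate_echo_decay(sys, cond, sch, engine = "sector", detection = det)
    df <- simulate_echo_decay(sys, cond, sch, engine = "full", detection = det)
    expect_lt(max(abs(ds$amplitudes - df$amplitudes)), 1e-9)
  }
})

test_that("echo schedules enforce rotor synchronization and monotonicity", {
  cond <- mas_conditions(spinning_rate = 110e3)
  expect_error(echo_schedule(c(1e-3, 2e-3)), "first echo time")
  expect_error(echo_schedule(c(0, 2e-3, 1e-3)), "increasing")
  bad <- echo_schedule(c(0, 1.00001e-3))
  expect_error(simulate_echo_decay(two_proton_system(), cond, bad),
               "rotor")
  grid <- rotor_synchronized_grid(cond, 1e-2, n_points = 6)
  k <- grid$echo_times * cond$spinning_rate / 2
  expect_equal(k, round(k))
  expect_equal(grid$echo_times[1], 0)
})

test_that("cross-term probe validates toggles and reduces correctly", {
  sys_h <- two_proton_system()
  cond <- mas_conditions(n_crystallites = 8)
  sch <- rotor_synchronized_grid(cond, 2e-3, n_points = 4)
  expect_error(
    cross_term_probe(sys_h, cond, sch,
                     toggles = list(heteronuclear_dipolar = TRUE,
                                    scalar_J = FALSE)),
    "single isotope"
  )
  sys_small <- build_spin_system(list(
    spin_site("H1", "1H", c(0, 0, 1.01)),
    spin_site("H2", "1H", c(0.87, 0, -0.5)),
    spin_site("N1", "15N", c(0, 0, 0))
  ))
  expect_error(
    cross_term_probe(sys_small, cond, sch,
                     toggles = list(heteronuclear_dipolar = TRUE,
                                    scalar_J = TRUE)),
    "scalar"
  )
  # all toggles off: the two runs are identical
  ct <- cross_term_probe(sys_small, cond, sch,
                         toggles = list(heteronuclear_dipolar = FALSE,
                                        scalar_J = FALSE))
  expect_equal(ct$included$amplitudes, ct$excluded$amplitudes,
               tolerance = 1e-12)
  expect_equal(ct$delta_homo_difference_hz, 0, tolerance = 1e-8)
})
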