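#' Magic-angle spinning conditions
#'
#' Everything that turns a [build_spin_system()] into a time-dependent
#' Hamiltonian: spinning rate, rotor angle, time discretization and the
#' deterministic powder scheme.
#'
#' @param spinning_rate rotor frequency in Hz (the fibril linewidth
#'   simulations use 110 kHz). Ignored when `static = TRUE`.
#' @param rotor_angle angle of the rotor axis to the static field in rad;
#'   default the magic angle `atan(sqrt(2))`.
#' @param steps_per_rotor_period number of piecewise-constant Hamiltonian
#'   steps per rotor period (>= 20; default 50).
#' @param n_crystallites number of powder orientations (default 233).
#' @param powder_scheme name of the deterministic orientation set; only
#'   `"spiral"` (a ZCW-type equal-weight golden-spiral set) is provided.
#' @param carrier_offsets named numeric vector of carrier positions in ppm
#'   per isotope (defaults to 0; simulations are run on-resonance).
#' @param static logical; `TRUE` selects the non-spinning limit (used for the
#'   two-spin Pake-pattern convention check).
#' @return A `mas_conditions` list.
#' @export
mas_conditions <- function(spinning_rate = 110e3,
                           rotor_angle = atan(sqrt(2)),
                           steps_per_rotor_period = 50,
                           n_crystallites = 233,
                           powder_scheme = "spiral",
                           carrier_offsets = c("1H" = 0, "15N" = 0),
                           static = FALSE) {
  if (!static && spinning_rate <= 0) stop("spinning_rate must be > 0")
  if (steps_per_rotor_period < 20) {
    stop("steps_per_rotor_period must be >= 20")
  }
  structure(
    list(
      spinning_rate = spinning_rate,
      rotor_angle = rotor_angle,
      steps_per_rotor_period = as.integer(steps_per_rotor_period),
      n_crystallites = as.integer(n_crystallites),
      powder_scheme = powder_scheme,
      carrier_offsets = carrier_offsets,
      static = static
    ),
    class = "mas_conditions"
  )
}

rotor_period <- function(conditions) 1 / conditions$spinning_rate

#' Deterministic powder orientations
#'
#' Equal-weight ZCW-type golden-spiral set over the full sphere: reproducible
#' (no random orientations) and convergent under doubling of the count.
#'
#' @param n number of crystallites.
#' @return A matrix with columns `alpha`, `beta` (rad) and `weight`
#'   (weights sum to 1).
#' @export
powder_orientations <- function(n) {
  j <- seq_len(n) - 1
  z <- (2 * j + 1) / n - 1
  golden <- (1 + sqrt(5)) / 2
  alpha <- (2 * pi * j / golden^2) %% (2 * pi)
  cbind(alpha = alpha, beta = acos(z), weight = rep(1 / n, n))
}

rotation_matrix <- function(alpha, beta, gamma = 0) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(gamma) %*% ry(beta) %*% rz(alpha)
}

# Second-rank spatial modulation (3 cos^2 theta(t) - 1)/2 of one coupling
# axis for one crystallite, evaluated at times t (s). Under MAS theta(t) is
# the instantaneous angle between the (rotating) internuclear vector and B0;
# at the magic angle its rotor-period average vanishes.
spatial_modulation <- function(axis, orientation, conditions, t) {
  R <- rotation_matrix(orientation[1], orientation[2],
                       if (length(orientation) >= 3) orientation[3] else 0)
  n_r <- as.numeric(R %*% axis)
  if (conditions$static) {
    cth <- n_r[3]
    rep((3 * cth^2 - 1) / 2, length(t))
  } else {
    thm <- conditions$rotor_angle
    wr <- 2 * pi * conditions$spinning_rate
    cth <- sin(thm) * (n_r[1] * cos(wr * t) + n_r[2] * sin(wr * t)) +
      cos(thm) * n_r[3]
    (3 * cth^2 - 1) / 2
  }
}

site_offsets_rad <- function(system, conditions) {
  vapply(system$sites, function(s) {
    iso <- s$isotope$isotope_label
    carrier <- conditions$carrier_offsets[iso]
    if (is.na(carrier)) carrier <- 0
    2 * pi * (s$isotropic_shift - carrier) * 1e-6 *
      larmor_frequency(iso, system$field)
  }, numeric(1))
}

# Static part of the Hamiltonian (offsets + weak-coupling J) plus the list
# of dipolar pair operators and per-pair anisotropies, on the full space.
full_space_terms <- function(system, include_heteronuclear = TRUE,
                             include_scalar_J = TRUE, conditions) {
  n <- length(system$sites)
  ids <- site_ids(system)
  isos <- site_isotopes(system)
  dim <- 2^n
  off <- site_offsets_rad(system, conditions)
  H0 <- matrix(0i, dim, dim)
  for (k in seq_len(n)) {
    if (off[k] != 0) H0 <- H0 + off[k] * single_spin_op(n, k, "z")
  }
  if (include_scalar_J) {
    for (sc in system$scalar_couplings) {
      i <- match(sc$pair[1], ids)
      j <- match(sc$pair[2], ids)
      # weak-coupling scalar term 2*pi*J IzSz (splitting J)
      H0 <- H0 + 2 * pi * sc$J *
        single_spin_op(n, i, "z") %*% single_spin_op(n, j, "z")
    }
  }
  ops <- list()
  aniso <- numeric(0)
  axes <- list()
  for (d in system$dipolar) {
    i <- match(d$pair[1], ids)
    j <- match(d$pair[2], ids)
    hetero <- isos[i] != isos[j]
    if (hetero && !include_heteronuclear) next
    A <- if (hetero) heteronuclear_pair_op(n, i, j) else homonuclear_pair_op(n, i, j)
    ops[[length(ops) + 1]] <- A
    aniso <- c(aniso, d$anisotropy_over_2pi)
    axes[[length(axes) + 1]] <- d$axis
  }
  list(H0 = H0, ops = ops, aniso = aniso, axes = axes, n = n)
}

#' Secular MAS Hamiltonian at a time point
#'
#' Sum of offset terms, secular homonuclear dipolar terms
#' `w_ij(t) (3 IizIjz - Ii.Ij)`, truncated heteronuclear terms
#' `w_ij(t) 2 IizSjz`, and weak-coupling scalar terms `2 pi J IizSjz`,
#' where `w_ij(t) = 2 pi delta_ij (3 cos^2 theta_ij(t) - 1)/2` is the
#' rotor-modulated dipolar anisotropy (no static term at the magic angle).
#'
#' @param system a [build_spin_system()] result.
#' @param conditions a [mas_conditions()].
#' @param orientation crystallite Euler angles `c(alpha, beta)` (optionally a
#'   third rotor-phase angle), rad.
#' @param t time in seconds (>= 0).
#' @return Complex Hermitian matrix (rad/s) on the `2^N` space.
#' @export
hamiltonian_at <- function(system, conditions, orientation, t) {
  stopifnot(t >= 0)
  terms <- full_space_terms(system, conditions = conditions)
  H <- terms$H0
  for (k in seq_along(terms$ops)) {
    w <- 2 * pi * terms$aniso[k] *
      spatial_modulation(terms$axes[[k]], orientation, conditions, t)
    H <- H + w * terms$ops[[k]]
  }
  H
}

# Coefficient time series (n_steps x n_pairs, rad/s) at step midpoints of one
# rotor period.
coeff_series <- function(axes, aniso, orientation, conditions) {
  Tr <- rotor_period(conditions)
  S <- conditions$steps_per_rotor_period
  tmid <- (seq_len(S) - 0.5) * Tr / S
  if (length(axes) == 0) {
    return(matrix(0, S, 0))
  }
  vapply(seq_along(axes), function(k) {
    2 * pi * aniso[k] * spatial_modulation(axes[[k]], orientation, conditions, tmid)
  }, numeric(S))
}

#' One-rotor-period propagator
#'
#' Product of piecewise-constant exponentials over one rotor period, on the
#' full `2^N` space. Multi-period evolution reuses powers of this unitary.
#'
#' @inheritParams hamiltonian_at
#' @return Complex unitary matrix.
#' @export
rotor_propagator <- function(system, conditions, orientation) {
  if (conditions$static) stop("rotor_propagator requires spinning conditions")
  terms <- full_space_terms(system, conditions = conditions)
  C <- coeff_series(terms$axes, terms$aniso, orientation, conditions)
  dt <- rotor_period(conditions) / conditions$steps_per_rotor_period
  if (length(terms$ops) == 0) {
    ed <- eigen(terms$H0, symmetric = TRUE)
    return(ed$vectors %*% diag(exp(-1i * ed$values * rotor_period(conditions)), nrow = nrow(terms$H0)) %*%
             Conj(t(ed$vectors)))
  }
  propagate_piecewise_cpp(terms$H0, terms$ops, C, dt)
}

#' Rotor-synchronized echo schedule
#'
#' @param echo_times total echo durations in seconds; must start at 0, be
#'   strictly increasing, and each be an even multiple of the rotor period
#'   (checked against the conditions at simulation time).
#' @param detected_isotope isotope whose total transverse magnetization is
#'   excited, refocused by the ideal pi pulse, and detected.
#' @return An `echo_schedule` list.
#' @export
echo_schedule <- function(echo_times, detected_isotope = "1H") {
  echo_times <- as.numeric(echo_times)
  if (echo_times[1] != 0) stop("first echo time must be 0")
  if (any(diff(echo_times) <= 0)) stop("echo times must be strictly increasing")
  structure(
    list(echo_times = echo_times, detected_isotope = detected_isotope,
         pulse_model = "ideal_pi"),
    class = "echo_schedule"
  )
}

#' Convenience constructor for a rotor-synchronized echo grid
#'
#' @param conditions a [mas_conditions()].
#' @param max_time approximate longest total echo time in seconds.
#' @param n_points number of echo points including time zero.
#' @param detected_isotope passed to [echo_schedule()].
#' @return An [echo_schedule()] whose times are exact even multiples of the
#'   rotor period.
#' @export
rotor_synchronized_grid <- function(conditions, max_time, n_points = 12,
                                    detected_isotope = "1H") {
  Tr <- rotor_period(conditions)
  kmax <- max(1, round(max_time / (2 * Tr)))
  k <- unique(round(seq(0, kmax, length.out = n_points)))
  echo_schedule(2 * Tr * k, detected_isotope = detected_isotope)
}

schedule_half_periods <- function(schedule, conditions) {
  Tr <- rotor_period(conditions)
  k <- schedule$echo_times / (2 * Tr)
  if (any(abs(k - round(k)) > 1e-6)) {
    stop("echo times must be even multiples of the rotor period ",
         "(rotor-synchronized schedule)", call. = FALSE)
  }
  as.integer(round(k))
}

# Split a system into detected spins and z-spectator configurations.
# Spins of a non-detected isotope never acquire transverse coherence under
# ideal detected-isotope pulses, so each z-projection is conserved exactly
# and the evolution block-diagonalizes into 2^m detected-spin problems.
# Requires that spectators have no retained couplings among themselves.
spectator_split <- function(system, detected_isotope) {
  isos <- site_isotopes(system)
  det <- which(isos == detected_isotope)
  spec <- which(isos != detected_isotope)
  if (length(det) == 0) stop("no sites of detected isotope ", detected_isotope)
  ids <- site_ids(system)
  for (d in system$dipolar) {
    i <- match(d$pair[1], ids)
    j <- match(d$pair[2], ids)
    if (i %in% spec && j %in% spec) {
      return(NULL) # spectator-spectator coupling: sector picture inapplicable
    }
  }
  list(detected = det, spectators = spec)
}

# Assemble the per-sector propagation problems for one crystallite.
# Returns list(H0 = ..., ops = shared op list, C = coeff matrix) per sector.
sector_problems <- function(system, conditions, detected_isotope,
                            include_heteronuclear = TRUE,
                            include_scalar_J = TRUE) {
  split <- spectator_split(system, detected_isotope)
  stopifnot(!is.null(split))
  det <- split$detected
  spec <- split$spectators
  nd <- length(det)
  ids <- site_ids(system)
  isos <- site_isotopes(system)
  off <- site_offsets_rad(system, conditions)

  homo_ops <- list(); homo_axes <- list(); homo_aniso <- numeric(0)
  het <- list() # each: det index (local), spec index (global), aniso, axis
  for (d in system$dipolar) {
    i <- match(d$pair[1], ids)
    j <- match(d$pair[2], ids)
    if (i %in% det && j %in% det) {
      li <- match(i, det); lj <- match(j, det)
      homo_ops[[length(homo_ops) + 1]] <- homonuclear_pair_op(nd, li, lj)
      homo_axes[[length(homo_axes) + 1]] <- d$axis
      homo_aniso <- c(homo_aniso, d$anisotropy_over_2pi)
    } else if (include_heteronuclear) {
      di <- if (i %in% det) i else j
      sj <- if (i %in% det) j else i
      het[[length(het) + 1]] <- list(det_local = match(di, det), spec = sj,
                                     aniso = d$anisotropy_over_2pi,
                                     axis = d$axis)
    }
  }
  iz_ops <- lapply(seq_len(nd), function(k) single_spin_op(nd, k, "z"))

  H0_base <- matrix(0i, 2^nd, 2^nd)
  for (k in seq_len(nd)) {
    if (off[det[k]] != 0) H0_base <- H0_base + off[det[k]] * iz_ops[[k]]
  }

  jterms <- list() # per scalar coupling: det_local, spec, J
  if (include_scalar_J) {
    for (sc in system$scalar_couplings) {
      i <- match(sc$pair[1], ids)
      j <- match(sc$pair[2], ids)
      if (i %in% det && j %in% det) {
        H0_base <- H0_base + 2 * pi * sc$J *
          iz_ops[[match(i, det)]] %*% iz_ops[[match(j, det)]]
      } else if (xor(i %in% det, j %in% det)) {
        di <- if (i %in% det) i else j
        sj <- if (i %in% det) j else i
        jterms[[length(jterms) + 1]] <- list(det_local = match(di, det),
                                             spec = sj, J = sc$J)
      }
    }
  }

  m <- length(spec)
  sector_signs <- if (m == 0) matrix(0, 1, 0) else {
    as.matrix(expand.grid(rep(list(c(-0.5, 0.5)), m)))
  }
  list(
    nd = nd, det = det, spec = spec,
    homo_ops = homo_ops, homo_axes = homo_axes, homo_aniso = homo_aniso,
    het = het, jterms = jterms, iz_ops = iz_ops, H0_base = H0_base,
    sector_signs = sector_signs
  )
}

# Sector Hamiltonian pieces for one crystallite: returns list of
# list(H0, ops, C) over sectors. Homonuclear coefficient columns are shared;
# heteronuclear couplings appear as Iz terms scaled by the spectator sign.
sector_crystallite <- function(sp, orientation, conditions) {
  C_homo <- coeff_series(sp$homo_axes, sp$homo_aniso, orientation, conditions)
  het_series <- lapply(sp$het, function(h) {
    2 * pi * h$aniso * spatial_modulation(h$axis, orientation, conditions,
      (seq_len(conditions$steps_per_rotor_period) - 0.5) *
        rotor_period(conditions) / conditions$steps_per_rotor_period)
  })
  lapply(seq_len(nrow(sp$sector_signs)), function(s) {
    signs <- sp$sector_signs[s, ]
    H0 <- sp$H0_base
    for (jt in sp$jterms) {
      ms <- signs[match(jt$spec, sp$spec)]
      H0 <- H0 + 2 * pi * jt$J * ms * sp$iz_ops[[jt$det_local]]
    }
    ops <- sp$homo_ops
    C <- C_homo
    for (k in seq_along(sp$het)) {
      h <- sp$het[[k]]
      ms <- signs[match(h$spec, sp$spec)]
      ops <- c(ops, sp$iz_ops[h$det_local])
      C <- cbind(C, 2 * ms * het_series[[k]])
    }
    list(H0 = H0, ops = ops, C = C)
  })
}

#' Simulate a rotor-synchronized spin-echo decay
#'
#' For each total echo time `2 tau`, the transverse magnetization of the
#' detected isotope is evolved for `tau`, an ideal pi pulse is applied to
#' all detected spins, and evolution continues for `tau`. Decays are
#' powder-averaged and normalized to echo time zero; fitting the result with
#' [fit_monoexponential()] yields the coherent homogeneous linewidth.
#'
#' Two detection conventions are offered. `"peak"` (default) records the
#' spectral peak intensity of the detected resonance — the Lorentzian-
#' weighted (width `lb_hz`) sum of transition amplitudes around the line
#' position — which is what site-specific relaxation measurements follow
#' when peak intensities are read from spectra; magnetization dephased by
#' coherent multi-spin terms into broad spectral wings no longer contributes.
#' `"total"` records the expectation value of the total transverse
#' magnetization, which additionally exposes that fast coherent
#' redistribution (in strongly coupled geometries it decays much faster than
#' any resolved line).
#'
#' Spins of other isotopes (e.g. 15N next to detected protons) are treated
#' by exact conserved-sector averaging over their z-projections (they carry
#' no transverse coherence under ideal detected-isotope pulses); set
#' `engine = "full"` to propagate in the full Hilbert space instead.
#'
#' @param system a [build_spin_system()] result.
#' @param conditions a [mas_conditions()] (spinning; not static).
#' @param schedule an [echo_schedule()]; echo times must be even multiples of
#'   the rotor period.
#' @param engine `"auto"` (sector averaging when applicable), `"sector"`, or
#'   `"full"`.
#' @param detection `"peak"` (site-resolved peak intensity) or `"total"`
#'   (total transverse magnetization).
#' @param lb_hz Lorentzian detection width for `detection = "peak"`, Hz.
#' @param include_heteronuclear,include_scalar_J include heteronuclear
#'   dipolar / scalar-J interactions (used by [cross_term_probe()]).
#' @return A `simulated_decay` with `times` (s), `amplitudes` (normalized to
#'   1 at time 0) and `crystallite_count`.
#' @export
simulate_echo_decay <- function(system, conditions, schedule,
                                engine = c("auto", "sector", "full"),
                                detection = c("peak", "total"),
                                lb_hz = 2,
                                include_heteronuclear = TRUE,
                                include_scalar_J = TRUE) {
  engine <- match.arg(engine)
  detection <- match.arg(detection)
  if (conditions$static) stop("echo simulation requires spinning conditions")
  k_half <- schedule_half_periods(schedule, conditions)
  det_iso <- schedule$detected_isotope
  isos <- site_isotopes(system)
  use_sector <- switch(engine,
    full = FALSE,
    sector = TRUE,
    auto = !is.null(spectator_split(system, det_iso)) && any(isos != det_iso)
  )
  orients <- powder_orientations(conditions$n_crystallites)
  dt <- rotor_period(conditions) / conditions$steps_per_rotor_period
  acc <- numeric(length(k_half))
  amp_fun <- function(U, Pp, rho0, Dtot, Dplus) {
    if (detection == "total") {
      echo_amplitudes_cpp(U, Pp, rho0, Dtot, k_half)
    } else {
      echo_peak_amplitudes_cpp(U, Pp, rho0, Dplus, k_half,
                               rotor_period(conditions), lb_hz, 0)
    }
  }

  if (use_sector) {
    sp <- sector_problems(system, conditions, det_iso,
                          include_heteronuclear = include_heteronuclear,
                          include_scalar_J = include_scalar_J)
    nd <- sp$nd
    rho0 <- total_spin_op(nd, seq_len(nd), "x")
    Dtot <- rho0
    Dplus <- rho0 + 1i * total_spin_op(nd, seq_len(nd), "y")
    Pp <- pulse_operator(nd, seq_len(nd), pi, "x")
    for (r in seq_len(nrow(orients))) {
      orientation <- orients[r, 1:2]
      probs <- sector_crystallite(sp, orientation, conditions)
      amps <- rowMeans(vapply(probs, function(pb) {
        U <- if (length(pb$ops) == 0) {
          ed <- eigen(pb$H0, symmetric = TRUE)
          ed$vectors %*% diag(exp(-1i * ed$values * rotor_period(conditions)),
                              nrow = 2^nd) %*% Conj(t(ed$vectors))
        } else {
          propagate_piecewise_cpp(pb$H0, pb$ops, pb$C, dt)
        }
        amp_fun(U, Pp, rho0, Dtot, Dplus)
      }, numeric(length(k_half))))
      acc <- acc + orients[r, "weight"] * amps
    }
  } else {
    n <- length(system$sites)
    det_idx <- which(isos == det_iso)
    if (length(det_idx) == 0) stop("no sites of detected isotope ", det_iso)
    terms <- full_space_terms(system,
                              include_heteronuclear = include_heteronuclear,
                              include_scalar_J = include_scalar_J,
                              conditions = conditions)
    rho0 <- total_spin_op(n, det_idx, "x")
    Dtot <- rho0
    Dplus <- rho0 + 1i * total_spin_op(n, det_idx, "y")
    Pp <- pulse_operator(n, det_idx, pi, "x")
    for (r in seq_len(nrow(orients))) {
      orientation <- orients[r, 1:2]
      C <- coeff_series(terms$axes, terms$aniso, orientation, conditions)
      U <- if (length(terms$ops) == 0) {
        ed <- eigen(terms$H0, symmetric = TRUE)
        ed$vectors %*% diag(exp(-1i * ed$values * rotor_period(conditions)),
                            nrow = 2^n) %*% Conj(t(ed$vectors))
      } else {
        propagate_piecewise_cpp(terms$H0, terms$ops, C, dt)
      }
      amps <- amp_fun(U, Pp, rho0, Dtot, Dplus)
      acc <- acc + orients[r, "weight"] * amps
    }
  }

  acc <- as.numeric(acc)
  structure(
    list(times = schedule$echo_times, amplitudes = acc / acc[1],
         crystallite_count = conditions$n_crystallites,
         detected_isotope = det_iso),
    class = "simulated_decay"
  )
}

#' @export
print.simulated_decay <- function(x, ...) {
  cat(sprintf(
    "<simulated_decay> %d echo points to %.3g ms, %d crystallites, detect %s\n",
    length(x$times), max(x$times) * 1e3, x$crystallite_count,
    x$detected_isotope
  ))
  invisible(x)
}

#' Fit the homogeneous linewidth of a simulated decay
#'
#' Mono-exponential fit of a [simulate_echo_decay()] result; returns the
#' full [fit_monoexponential()] object whose `delta_homo` is the coherent
#' homogeneous linewidth in Hz.
#'
#' @param decay a `simulated_decay`.
#' @return A `fit_result`.
#' @export
fit_decay_linewidth <- function(decay) {
  curve <- decay_curve(decay$times, decay$amplitudes,
                       site_label = "simulated", experiment_kind = "echo")
  fit_monoexponential(curve)
}

#' Simulate a 1D spectrum
#'
#' Powder-averaged spectrum of the total transverse magnetization after an
#' ideal 90-degree pulse on the detected isotope. Under MAS, detection is
#' rotor-synchronized (stroboscopic; dwell an integer multiple of the rotor
#' period), which folds all spinning sidebands onto the centerbands; in the
#' static limit detection is continuous. The spectrum is assembled from the
#' exact transition sticks of each crystallite and convolved with a
#' Lorentzian apodization of width `lb_hz` (FWHM).
#'
#' @param system a [build_spin_system()] result.
#' @param conditions a [mas_conditions()].
#' @param npoints number of synthesized complex FID points.
#' @param dwell_s FID dwell time in seconds; under MAS it must be an integer
#'   multiple of the rotor period (default one rotor period).
#' @param lb_hz Lorentzian apodization FWHM in Hz (default 1).
#' @param detected_isotope isotope excited and detected.
#' @param freq_range spectral window `c(min, max)` in Hz; default chosen to
#'   cover all significant transitions.
#' @param df_hz frequency grid spacing; default `lb_hz / 10`.
#' @return A `simulated_spectrum` with elements `fid` (complex, normalized so
#'   the first point is 1), `times`, `spectrum` (tibble with `freq_hz`,
#'   `intensity`; unit-area Lorentzians so the spectrum integrates to the
#'   first FID point), and `sticks`.
#' @export
simulate_spectrum <- function(system, conditions, npoints = 512,
                              dwell_s = NULL, lb_hz = 1,
                              detected_isotope = "1H",
                              freq_range = NULL, df_hz = NULL) {
  isos <- site_isotopes(system)
  use_sector <- !is.null(spectator_split(system, detected_isotope)) &&
    any(isos != detected_isotope)
  orients <- powder_orientations(conditions$n_crystallites)
  if (is.null(dwell_s)) {
    dwell_s <- if (conditions$static) 1e-5 else rotor_period(conditions)
  }
  if (!conditions$static) {
    p <- dwell_s / rotor_period(conditions)
    if (abs(p - round(p)) > 1e-6 || round(p) < 1) {
      stop("under MAS the dwell must be an integer multiple of the rotor period")
    }
  }

  all_freq <- numeric(0)
  all_w <- complex(0)
  collect <- function(st, wt) {
    all_freq <<- c(all_freq, st$freq)
    all_w <<- c(all_w, wt * complex(real = st$w_re, imaginary = st$w_im))
  }

  sticks_for <- function(H0, ops, C, orientation) {
    # returns sticks for one (sector x crystallite) problem
    dim <- nrow(H0)
    tol <- 1e-10 * dim
    if (conditions$static) {
      H <- H0
      if (length(ops) > 0) {
        for (k in seq_along(ops)) H <- H + C[1, k] * ops[[k]]
      }
      static_sticks_cpp(H, rho0, Dop, tol)
    } else {
      dt <- rotor_period(conditions) / conditions$steps_per_rotor_period
      U <- if (length(ops) == 0) {
        ed <- eigen(H0, symmetric = TRUE)
        ed$vectors %*% diag(exp(-1i * ed$values * rotor_period(conditions)),
                            nrow = dim) %*% Conj(t(ed$vectors))
      } else {
        propagate_piecewise_cpp(H0, ops, C, dt)
      }
      p <- round(dwell_s / rotor_period(conditions))
      if (p > 1) {
        Up <- U
        for (q in seq_len(p - 1)) Up <- Up %*% U
        U <- Up
      }
      strobe_sticks_cpp(U, rho0, Dop, dwell_s, tol)
    }
  }

  if (use_sector) {
    sp <- sector_problems(system, conditions, detected_isotope)
    nd <- sp$nd
    rho0 <- total_spin_op(nd, seq_len(nd), "x")
    Dop <- total_spin_op(nd, seq_len(nd), "x") +
      1i * total_spin_op(nd, seq_len(nd), "y")
    n_sector <- nrow(sp$sector_signs)
    for (r in seq_len(nrow(orients))) {
      probs <- sector_crystallite(sp, orients[r, 1:2], conditions)
      for (pb in probs) {
        st <- sticks_for(pb$H0, pb$ops, pb$C, orients[r, 1:2])
        collect(st, orients[r, "weight"] / n_sector)
      }
    }
  } else {
    n <- length(system$sites)
    det_idx <- which(isos == detected_isotope)
    if (length(det_idx) == 0) stop("no sites of detected isotope ", detected_isotope)
    terms <- full_space_terms(system, conditions = conditions)
    rho0 <- total_spin_op(n, det_idx, "x")
    Dop <- total_spin_op(n, det_idx, "x") + 1i * total_spin_op(n, det_idx, "y")
    for (r in seq_len(nrow(orients))) {
      C <- if (conditions$static) {
        if (length(terms$axes) == 0) matrix(0, 1, 0) else
          matrix(vapply(seq_along(terms$axes), function(k) {
            2 * pi * terms$aniso[k] *
              spatial_modulation(terms$axes[[k]], orients[r, 1:2], conditions, 0)
          }, numeric(1)), nrow = 1)
      } else {
        coeff_series(terms$axes, terms$aniso, orients[r, 1:2], conditions)
      }
      st <- sticks_for(terms$H0, terms$ops, C, orients[r, 1:2])
      collect(st, orients[r, "weight"])
    }
  }

  # normalize so the zero-time FID point (= sum of stick weights) is 1
  norm <- sum(Re(all_w))
  all_w <- all_w / norm

  if (is.null(freq_range)) {
    big <- abs(all_freq[Mod(all_w) > 1e-6])
    span <- if (length(big) == 0) 10 * lb_hz else max(big) + 20 * lb_hz
    freq_range <- c(-span, span)
  }
  if (is.null(df_hz)) df_hz <- lb_hz / 10
  grid <- seq(freq_range[1], freq_range[2], by = df_hz)
  inside <- all_freq >= freq_range[1] & all_freq <= freq_range[2]
  bins <- numeric(length(grid))
  if (any(inside)) {
    # linear split between neighboring bins preserves the first moment
    pos <- (all_freq[inside] - freq_range[1]) / df_hz
    lo <- pmin(floor(pos), length(grid) - 2)
    frac <- pos - lo
    wre <- Re(all_w[inside])
    for (b in seq_along(lo)) {
      bins[lo[b] + 1] <- bins[lo[b] + 1] + wre[b] * (1 - frac[b])
      bins[lo[b] + 2] <- bins[lo[b] + 2] + wre[b] * frac[b]
    }
  }
  half <- lb_hz / 2
  kern_f <- seq(-length(grid), length(grid)) * df_hz
  kern <- (half / pi) / (kern_f^2 + half^2)
  intensity <- stats::convolve(bins, rev(kern), type = "open")
  offset <- length(grid)
  intensity <- intensity[(offset + 1):(offset + length(grid))] # align centers

  tt <- (seq_len(npoints) - 1) * dwell_s
  damp <- exp(-pi * lb_hz * tt)
  fid <- vapply(tt, function(t1) sum(all_w * exp(2i * pi * all_freq * t1)),
                complex(1)) * damp

  structure(
    list(
      fid = fid, times = tt,
      spectrum = tibble::tibble(freq_hz = grid, intensity = intensity),
      sticks = tibble::tibble(freq_hz = all_freq, weight = all_w),
      lb_hz = lb_hz, dwell_s = dwell_s
    ),
    class = "simulated_spectrum"
  )
}

#' @export
print.simulated_spectrum <- function(x, ...) {
  cat(sprintf(
    "<simulated_spectrum> %d FID points (dwell %.3g us), grid %.4g..%.4g Hz, lb %.3g Hz\n",
    length(x$fid), x$dwell_s * 1e6, min(x$spectrum$freq_hz),
    max(x$spectrum$freq_hz), x$lb_hz
  ))
  invisible(x)
}

#' Full width at half maximum of the tallest spectral line
#'
#' Measured by linear interpolation of the half-maximum crossings around the
#' global maximum of the spectrum. Subtract the apodization width `lb_hz` to
#' get the width beyond apodization.
#'
#' @param spec a [simulate_spectrum()] result (or a tibble with `freq_hz`,
#'   `intensity`).
#' @return FWHM in Hz.
#' @export
spectrum_fwhm <- function(spec) {
  df <- if (inherits(spec, "simulated_spectrum")) spec$spectrum else spec
  y <- df$intensity
  x <- df$freq_hz
  imax <- which.max(y)
  hm <- y[imax] / 2
  il <- imax
  while (il > 1 && y[il] > hm) il <- il - 1
  ir <- imax
  while (ir < length(y) && y[ir] > hm) ir <- ir + 1
  if (il == 1 || ir == length(y)) {
    stop("half-maximum crossing outside the spectral window; widen freq_range")
  }
  xl <- x[il] + (hm - y[il]) / (y[il + 1] - y[il]) * (x[il + 1] - x[il])
  xr <- x[ir - 1] + (hm - y[ir - 1]) / (y[ir] - y[ir - 1]) * (x[ir] - x[ir - 1])
  xr - xl
}

#' Probe dipolar/J cross-term contributions to the homogeneous linewidth
#'
#' Simulates the detected-isotope spin-echo decay with the toggled
#' interactions (heteronuclear dipolar couplings and/or scalar J couplings to
#' the other isotope) included versus excluded, fits both, and reports the
#' difference in homogeneous linewidth.
#'
#' @inheritParams simulate_echo_decay
#' @param toggles named logical list with elements `heteronuclear_dipolar`
#'   and `scalar_J`; toggled interactions are present in the "included" run
#'   and absent in the "excluded" run.
#' @return List with `included`, `excluded` (both `simulated_decay`),
#'   `fit_included`, `fit_excluded`, and `delta_homo_difference_hz`.
#' @export
cross_term_probe <- function(system, conditions, schedule,
                             toggles = list(heteronuclear_dipolar = TRUE,
                                            scalar_J = TRUE),
                             detection = "peak", lb_hz = 2) {
  isos <- site_isotopes(system)
  het_present <- any(isos != schedule$detected_isotope)
  if (isTRUE(toggles$heteronuclear_dipolar) && !het_present) {
    stop("heteronuclear toggle requested but the system has a single isotope")
  }
  if (isTRUE(toggles$scalar_J) && length(system$scalar_couplings) == 0) {
    stop("scalar_J toggle requested but the system carries no scalar couplings")
  }
  inc <- simulate_echo_decay(
    system, conditions, schedule, detection = detection, lb_hz = lb_hz,
    include_heteronuclear = isTRUE(toggles$heteronuclear_dipolar),
    include_scalar_J = isTRUE(toggles$scalar_J)
  )
  exc <- simulate_echo_decay(
    system, conditions, schedule, detection = detection, lb_hz = lb_hz,
    include_heteronuclear = FALSE, include_scalar_J = FALSE
  )
  f_inc <- fit_decay_linewidth(inc)
  f_exc <- fit_decay_linewidth(exc)
  list(
    included = inc, excluded = exc,
    fit_included = f_inc, fit_excluded = f_exc,
    delta_homo_difference_hz = f_inc$delta_homo - f_exc$delta_homo
  )
}
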