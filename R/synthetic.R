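# Synthetic fixtures: idealized ladder geometries, noisy decay curves and
# observables tables. Everything is seed-deterministic and regenerated at
# run time; no binary fixtures are shipped.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Idealized amide-ladder geometry specification
#'
#' A stack of primary-amide NH2 fragments along the fibril axis with the
#' canonical cross-beta rise, standing in for a ladder pulled from a fibril
#' structure. Standard amide geometry is used (N-H 1.01 angstrom, H-N-H 120
#' degrees); only relative distances matter for the dipolar couplings.
#'
#' @param n_layers number of stacked NH2 fragments (>= 2).
#' @param layer_rise inter-layer rise in angstrom (default 4.8, the
#'   cross-beta stacking distance; must exceed 2).
#' @param nh_bond N-H bond length in angstrom.
#' @param hnh_angle_deg H-N-H angle in degrees.
#' @param lateral_jitter standard deviation of Gaussian in-plane displacement
#'   per layer, angstrom (0 = perfectly regular ladder).
#' @param seed RNG seed for the jitter.
#' @return A `ladder_geometry_spec` list.
#' @export
ladder_geometry_spec <- function(n_layers = 3, layer_rise = 4.8,
                                 nh_bond = 1.01, hnh_angle_deg = 120,
                                 lateral_jitter = 0, seed = 1) {
  stopifnot(n_layers >= 2, layer_rise > 2, nh_bond > 0, lateral_jitter >= 0)
  structure(
    list(n_layers = as.integer(n_layers), layer_rise = layer_rise,
         nh_bond = nh_bond, hnh_angle_deg = hnh_angle_deg,
         lateral_jitter = lateral_jitter, seed = seed),
    class = "ladder_geometry_spec"
  )
}

# Closed-form coordinates of the ladder. Each layer is a planar primary
# amide (C-N 1.33, C-O 1.23 angstrom, sp2 angles) in the xz-plane, and the
# whole fragment is rotated so that the internal HD21 -> O vector lies along
# the stacking axis: under pure translation by the layer rise, the carbonyl
# oxygen of layer l+1 then sits directly above the cis (donor) proton of
# layer l, giving the most linear N-H...O hydrogen bond a translationally
# symmetric ladder allows. Only the N and the two protons enter the spin
# system, but the hydrogen-bonding construction fixes their orientation and
# keeps the inter-layer H...H contacts at ladder-like (>= rise - O offset)
# distances.
amide_fragment <- function(nh_bond, hnh_angle_deg) {
  half <- hnh_angle_deg / 2 * pi / 180
  N <- c(0, 0, 0)
  C <- c(1.33, 0, 0)
  # H bisector opposite the C-N bond; HZ on the same side as the carbonyl O
  HZ <- N + nh_bond * c(-cos(half), 0, sin(half))
  HE <- N + nh_bond * c(-cos(half), 0, -sin(half))
  O <- C + 1.23 * c(cos(58 * pi / 180), 0, sin(58 * pi / 180)) # O-C-N 122 deg
  v <- O - HZ
  a <- pi - atan2(v[1], v[3]) # rotate about y so v points along -z
  rot <- function(p) c(p[1] * cos(a) + p[3] * sin(a), p[2],
                       -p[1] * sin(a) + p[3] * cos(a))
  list(N = rot(N), HZ = rot(HZ), HE = rot(HE), O = rot(O))
}

ladder_coordinates <- function(spec) {
  fr <- amide_fragment(spec$nh_bond, spec$hnh_angle_deg)
  jit <- with_seed(spec$seed, {
    matrix(stats::rnorm(2 * spec$n_layers, sd = spec$lateral_jitter),
           ncol = 2)
  })
  rows <- list()
  for (l in seq_len(spec$n_layers)) {
    shift <- c(jit[l, 1], jit[l, 2], (l - 1) * spec$layer_rise)
    N <- fr$N + shift
    H1 <- fr$HZ + shift
    H2 <- fr$HE + shift
    rows[[length(rows) + 1]] <- data.frame(
      resno = l, atom = c("ND2", "HD21", "HD22"), element = c("N", "H", "H"),
      x = c(N[1], H1[1], H2[1]), y = c(N[2], H1[2], H2[2]),
      z = c(N[3], H1[3], H2[3])
    )
  }
  do.call(rbind, rows)
}

#' Write an idealized ladder geometry as a multi-model PDB
#'
#' Writes stacked synthetic NH2 fragments (N, HD21, HD22 per layer, residue
#' type ASN) with `MODEL`/`ENDMDL` records and returns the exact coordinates
#' used, so that [read_pdb_sites()] round-trips them.
#'
#' @param spec a [ladder_geometry_spec()].
#' @param path output PDB path.
#' @param n_models number of models to write; models beyond the first redraw
#'   the lateral jitter (seed offset by the model index).
#' @return Invisibly, a list with `path` and `sites` (data frame of the
#'   model-1 ground-truth coordinates, one row per atom).
#' @export
make_ladder_pdb <- function(spec, path, n_models = 1) {
  con <- tryCatch(file(path, open = "wt"), error = function(e) {
    stop("cannot open ", path, " for writing", call. = FALSE)
  })
  on.exit(close(con))
  truth <- NULL
  serial <- 0L
  for (m in seq_len(n_models)) {
    spec_m <- spec
    spec_m$seed <- spec$seed + (m - 1L)
    coords <- ladder_coordinates(spec_m)
    if (m == 1) truth <- coords
    writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(coords))) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, coords$atom[i], "ASN", "A", coords$resno[i], coords$x[i],
        coords$y[i], coords$z[i], 1.00, 0.00, coords$element[i]
      ), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(list(path = path, sites = truth))
}

#' Selectors for the ladder protons of a synthetic ladder PDB
#'
#' @param n_layers number of layers written by [make_ladder_pdb()].
#' @return Selector list for [read_pdb_sites()] covering HD21/HD22 of every
#'   layer.
#' @export
ladder_proton_selectors <- function(n_layers) {
  out <- list()
  for (l in seq_len(n_layers)) {
    out[[length(out) + 1]] <- list(resno = l, atom = "HD21")
    out[[length(out) + 1]] <- list(resno = l, atom = "HD22")
  }
  out
}

#' @rdname ladder_proton_selectors
#' @export
ladder_nitrogen_selectors <- function(n_layers) {
  lapply(seq_len(n_layers), function(l) list(resno = l, atom = "ND2"))
}

#' Synthetic decay-curve specification and generator
#'
#' `make_decay` draws `A * exp(-R t) * (1 + eps_t)` with Gaussian
#' multiplicative noise of the stated fraction, deterministically for a
#' given seed.
#'
#' @param true_rate decay rate in 1/s.
#' @param time_grid sampling times in seconds.
#' @param noise_fraction multiplicative Gaussian noise sd (>= 0; the
#'   relaxation series here carry about 5% noise).
#' @param seed RNG seed.
#' @param amplitude signal amplitude at time zero.
#' @param site_label,experiment_kind passed to [decay_curve()].
#' @return A [decay_curve()].
#' @export
make_decay <- function(true_rate, time_grid = seq(0, 10e-3, length.out = 8),
                       noise_fraction = 0.05, seed = 1, amplitude = 1,
                       site_label = "synthetic",
                       experiment_kind = "echo") {
  stopifnot(noise_fraction >= 0)
  eps <- with_seed(seed, stats::rnorm(length(time_grid), sd = noise_fraction))
  y <- amplitude * exp(-true_rate * time_grid) * (1 + eps)
  decay_curve(time_grid, y, site_label = site_label,
              experiment_kind = experiment_kind)
}

table1_observables <- function() {
  tibble::tibble(
    residue = c("N226", "N262", "N243", "N279", "Q240", "Q259"),
    cp_visible = TRUE,
    inept_visible = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    n15_shift = c(114.9, 112.8, 118.9, 116.5, 104.0, 110.2),
    c13_shift = c(177.6, 173.9, 176.1, 176.4, 175.5, 180.3),
    shift_h1 = c(8.4, 7.6, 7.4, 7.0, 7.8, 7.3),
    shift_h2 = c(6.5, 6.8, NA, NA, 4.9, 6.7),
    delta_homo_1 = c(157, 138, 128, 543, 41, 43),
    delta_homo_2 = c(82, 160, NA, NA, 38, NA),
    delta_homo_err_1 = c(18, 20, 50, 140, 20, 10),
    delta_homo_err_2 = c(18, 40, NA, NA, 18, NA),
    r1rho_15N = c(2.6, 3.8, 25, 50, 2.5, 40),
    r1rho_15N_err = c(0.7, 1.6, 10, 30, 0.5, 30),
    r1rho_1H = c(120, 196, 190, 302, 29, 132),
    r1rho_1H_err = c(9, 9, 17, 52, 4, 7),
    hncoh_correlation = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

#' Generate a per-residue observables table
#'
#' Two profiles: `"hets_table1"` reproduces the measured spectral and
#' relaxation summary of the six fibril N/Q side-chains exactly (shifts in
#' ppm, homogeneous linewidths in Hz, rotating-frame rates in 1/s);
#' `"random"` draws rigid-ladder and flexible archetypes around those two
#' regimes for property-style testing.
#'
#' @param profile `"hets_table1"` or `"random"`.
#' @param seed RNG seed (random profile).
#' @param n number of rows (random profile).
#' @param path optional CSV path to write the table to.
#' @return Tibble; random-profile rows carry an extra `archetype` column.
#' @export
make_observables_table <- function(profile = c("hets_table1", "random"),
                                   seed = 1, n = 12, path = NULL) {
  profile <- match.arg(profile)
  tab <- if (profile == "hets_table1") {
    table1_observables()
  } else {
    with_seed(seed, {
      arch <- rep(c("rigid", "flexible"), length.out = n)
      rows <- lapply(seq_len(n), function(i) {
        if (arch[i] == "rigid") {
          hi <- stats::runif(1, 7.8, 8.6)
          lo <- stats::runif(1, 6.3, 6.9)
          r1 <- min(8, max(0.5, stats::rnorm(1, 3, 1)))
          dh <- max(60, stats::rnorm(1, 150, 30))
          r1h <- max(50, stats::rnorm(1, 150, 40))
          iv <- FALSE
          hn <- TRUE
        } else {
          hi <- stats::runif(1, 7.0, 7.5)
          lo <- stats::runif(1, 6.6, 7.2)
          r1 <- max(15, stats::rnorm(1, 35, 10))
          dh <- max(100, stats::rnorm(1, 350, 120))
          r1h <- max(100, stats::rnorm(1, 250, 60))
          iv <- FALSE
          hn <- FALSE
        }
        tibble::tibble(
          residue = sprintf("SYN%02d", i), cp_visible = TRUE,
          inept_visible = iv, n15_shift = stats::rnorm(1, 113, 3),
          c13_shift = stats::rnorm(1, 176.5, 1.5),
          shift_h1 = hi, shift_h2 = lo,
          delta_homo_1 = dh, delta_homo_2 = NA_real_,
          delta_homo_err_1 = 0.15 * dh, delta_homo_err_2 = NA_real_,
          r1rho_15N = r1, r1rho_15N_err = 0.25 * r1,
          r1rho_1H = r1h, r1rho_1H_err = 0.1 * r1h,
          hncoh_correlation = hn, archetype = arch[i]
        )
      })
      do.call(rbind, rows)
    })
  }
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  tab
}
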