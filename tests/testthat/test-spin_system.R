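test_that("dipolar anisotropy matches hand evaluation and r^-3 scaling", {
  gH <- nmr_constants$gamma[["1H"]]
  sys2 <- two_proton_system(2.0)
  expect_length(sys2$dipolar, 1)
  d <- sys2$dipolar[[1]]
  # two protons at 2.0 angstrom: about -15.0 kHz
  expect_equal(d$anisotropy_over_2pi, oracle_dipolar_hz(gH, gH, 2.0),
               tolerance = 1e-10)
  expect_equal(d$anisotropy_over_2pi, -15015, tolerance = 1e-4)
  expect_equal(d$distance, 2.0)
  expect_equal(sum(d$axis^2), 1)
  # exact r^-3: the 4.0 angstrom coupling is 1/8 of the 2.0 angstrom one
  sys4 <- two_proton_system(4.0)
  expect_equal(sys4$dipolar[[1]]$anisotropy_over_2pi,
               d$anisotropy_over_2pi / 8)
})

test_that("coupling cutoff filters pairs and pair count is complete at 0", {
  sites <- list(
    spin_site("a", "1H", c(0, 0, 0)),
    spin_site("b", "1H", c(0, 0, 3)),
    spin_site("c", "1H", c(0, 4, 0)),
    spin_site("d", "1H", c(5, 0, 0))
  )
  sys0 <- build_spin_system(sites, coupling_cutoff = 0)
  expect_length(sys0$dipolar, 4 * 3 / 2)
  sys_hi <- build_spin_system(sites, coupling_cutoff = 1e6)
  expect_length(sys_hi$dipolar, 0)
  # every retained pair exceeds the cutoff, none below it is retained
  sys_mid <- build_spin_system(sites, coupling_cutoff = 500)
  retained <- vapply(sys_mid$dipolar, function(d) abs(d$anisotropy_over_2pi),
                     numeric(1))
  expect_true(all(retained > 500))
  all0 <- vapply(sys0$dipolar, function(d) abs(d$anisotropy_over_2pi),
                 numeric(1))
  expect_equal(sum(all0 > 500), length(retained))
})

test_that("anisotropies are invariant under global rotation and translation", {
  sites <- list(
    spin_site("a", "1H", c(0.2, 1.1, 0)),
    spin_site("b", "1H", c(1.9, 0, 0.5)),
    spin_site("c", "1H", c(0, 2.5, 2.2))
  )
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- lapply(sites, function(s) {
    spin_site(s$site_id, "1H", as.numeric(R %*% s$position) + c(3, -1, 7))
  })
  a <- build_spin_system(sites)
  b <- build_spin_system(moved)
  for (k in seq_along(a$dipolar)) {
    expect_equal(b$dipolar[[k]]$anisotropy_over_2pi,
                 a$dipolar[[k]]$anisotropy_over_2pi, tolerance = 1e-12)
    # axis rotates with the coordinates
    expect_equal(b$dipolar[[k]]$axis, as.numeric(R %*% a$dipolar[[k]]$axis),
                 tolerance = 1e-12)
  }
})

test_that("build_spin_system is deterministic and rejects coincident sites", {
  sys_a <- two_proton_system()
  sys_b <- two_proton_system()
  expect_identical(sys_a, sys_b)
  expect_error(
    build_spin_system(list(
      spin_site("a", "1H", c(0, 0, 0)),
      spin_site("b", "1H", c(0, 0, 0.05))
    )),
    "coincident"
  )
})

test_that("PDB reading selects models and atoms, with descriptive errors", {
  pdb <- tempfile(fileext = ".pdb")
  truth <- make_ladder_pdb(ladder_geometry_spec(n_layers = 2, seed = 7),
                           pdb, n_models = 3)
  sites <- read_pdb_sites(pdb, 1, ladder_proton_selectors(2))
  expect_length(sites, 4)
  expect_true(all(vapply(sites, function(s) s$isotope$isotope_label,
                         character(1)) == "1H"))
  # coordinates round-trip the generator's values (PDB precision 1e-3)
  hrows <- truth$sites[truth$sites$atom != "ND2", ]
  for (k in seq_along(sites)) {
    expect_equal(sites[[k]]$position,
                 as.numeric(hrows[k, c("x", "y", "z")]), tolerance = 1e-3)
  }
  # nitrogen selector infers 15N
  nsite <- read_pdb_sites(pdb, 1, list(list(resno = 1, atom = "ND2")))
  expect_equal(nsite[[1]]$isotope$isotope_label, "15N")
  expect_true(nsite[[1]]$isotope$gyromagnetic_ratio < 0)
  # missing model / missing selector fail descriptively
  expect_error(read_pdb_sites(pdb, 9, ladder_proton_selectors(2)), "model 9")
  expect_error(read_pdb_sites(pdb, 1, list(list(resno = 99, atom = "HZ9"))),
               "resno 99")
  # other models differ (fresh jitter draw) only if jitter > 0; with the
  # default zero jitter they coincide
  s2 <- read_pdb_sites(pdb, 2, ladder_proton_selectors(2))
  expect_equal(s2[[1]]$position, sites[[1]]$position, tolerance = 1e-3)
})

test_that("spin systems serialize to JSON and back", {
  sys <- ladder_full_system(2)
  path <- tempfile(fileext = ".json")
  write_spin_system(sys, path)
  back <- read_spin_system(path)
  expect_equal(length(back$sites), length(sys$sites))
  expect_equal(length(back$dipolar), length(sys$dipolar))
  expect_equal(back$field, sys$field)
  expect_equal(back$dipolar[[1]]$anisotropy_over_2pi,
               sys$dipolar[[1]]$anisotropy_over_2pi, tolerance = 1e-12)
  expect_equal(length(back$scalar_couplings), length(sys$scalar_couplings))
})
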