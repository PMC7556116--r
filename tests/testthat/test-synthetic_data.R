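test_that("ladder geometry reproduces its closed-form distances", {
  spec <- ladder_geometry_spec(n_layers = 3, layer_rise = 4.8)
  pdb <- tempfile(fileext = ".pdb")
  truth <- make_ladder_pdb(spec, pdb)$sites
  h <- truth[truth$atom != "ND2", c("x", "y", "z")]
  d <- as.matrix(dist(h))
  # intra-pair H-H distance: 2 * 1.01 * sin(60 deg)
  intra <- 2 * 1.01 * sin(60 * pi / 180)
  expect_equal(d[1, 2], intra, tolerance = 1e-6)
  expect_equal(d[3, 4], intra, tolerance = 1e-6)
  # translational symmetry: layer 2 -> 3 repeats layer 1 -> 2 exactly
  expect_equal(d[3, 5], d[1, 3], tolerance = 1e-6)
  expect_equal(d[4, 6], d[2, 4], tolerance = 1e-6)
  # like-for-like inter-layer distance equals the rise
  expect_equal(d[1, 3], 4.8, tolerance = 1e-6)
  # the ladder is sparse: no inter-layer contact below the rise
  inter <- d[1:2, 3:4]
  expect_true(all(inter >= 4.8 - 1e-9))
  # geometry invariants
  expect_error(ladder_geometry_spec(n_layers = 1), "n_layers")
  expect_error(ladder_geometry_spec(layer_rise = 1.5), "rise")
})

test_that("written PDB round-trips through the reader", {
  spec <- ladder_geometry_spec(n_layers = 2, lateral_jitter = 0.3, seed = 5)
  pdb <- tempfile(fileext = ".pdb")
  truth <- make_ladder_pdb(spec, pdb)$sites
  sel <- c(ladder_proton_selectors(2), ladder_nitrogen_selectors(2))
  sites <- read_pdb_sites(pdb, 1, sel)
  got <- t(vapply(sites, function(s) s$position, numeric(3)))
  want <- rbind(
    as.matrix(truth[truth$atom != "ND2", c("x", "y", "z")]),
    as.matrix(truth[truth$atom == "ND2", c("x", "y", "z")])
  )
  expect_equal(got, want, tolerance = 1e-3, ignore_attr = TRUE)
  # jitter is seed-deterministic
  pdb2 <- tempfile(fileext = ".pdb")
  truth2 <- make_ladder_pdb(spec, pdb2)$sites
  expect_identical(truth, truth2)
})

test_that("synthetic decays are exact without noise and seed-deterministic", {
  tgrid <- seq(0, 8e-3, length.out = 8)
  clean <- make_decay(250, tgrid, noise_fraction = 0, seed = 1)
  expect_equal(clean$intensities, exp(-250 * tgrid), tolerance = 1e-12)
  a <- make_decay(250, tgrid, 0.05, seed = 9)
  b <- make_decay(250, tgrid, 0.05, seed = 9)
  expect_identical(a$intensities, b$intensities)
  c2 <- make_decay(250, tgrid, 0.05, seed = 10)
  expect_false(identical(a$intensities, c2$intensities))
})

test_that("fitted rates fall inside bootstrap 2-sigma for most seeds", {
  tgrid <- seq(0.3e-3, 12e-3, length.out = 8)
  R <- 400
  hits <- vapply(1:60, function(s) {
    curve <- make_decay(R, tgrid, noise_fraction = 0.05, seed = s)
    fit <- bootstrap_ci(curve, n_iter = 150, seed = s)
    abs(fit$rate - R) <= fit$ci_2sigma
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("observables tables carry the measured values and archetypes behave", {
  tab <- make_observables_table("hets_table1")
  expect_equal(nrow(tab), 6)
  expect_equal(tab$r1rho_15N[tab$residue == "N226"], 2.6)
  expect_equal(tab$shift_h1[tab$residue == "Q240"], 7.8)
  expect_equal(tab$shift_h2[tab$residue == "Q240"], 4.9)
  expect_equal(tab$delta_homo_1[tab$residue == "N279"], 543)
  # CSV round trip
  path <- tempfile(fileext = ".csv")
  make_observables_table("hets_table1", path = path)
  back <- utils::read.csv(path)
  expect_equal(back$r1rho_15N, tab$r1rho_15N)
  # random profile: reproducible, and rigid archetypes classify as ladders
  r1 <- make_observables_table("random", seed = 4, n = 40)
  r2 <- make_observables_table("random", seed = 4, n = 40)
  expect_identical(r1, r2)
  calls <- classify_table(r1)
  rigid_rows <- which(r1$archetype == "rigid")
  expect_gte(mean(calls$call[rigid_rows] == "rigid_ladder"), 0.95)
  flex_rows <- which(r1$archetype == "flexible")
  expect_gte(mean(calls$call[flex_rows] == "flexible"), 0.95)
})
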