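# Shared builders for test spin systems; everything is generated in code.

two_proton_system <- function(r = 2.0) {
  build_spin_system(list(
    spin_site("a", "1H", c(0, 0, 0)),
    spin_site("b", "1H", c(0, 0, r))
  ))
}

# NH2-like three-proton cluster: one strong pair plus a moderately coupled
# third proton with a non-parallel axis (gives genuine multi-spin dynamics).
three_proton_cluster <- function() {
  build_spin_system(list(
    spin_site("a", "1H", c(0, 0, 0)),
    spin_site("b", "1H", c(0.8747, 0, -0.505)),
    spin_site("c", "1H", c(0.8747, 0, 3.285))
  ))
}

# Dense four-proton cluster (~2.2-2.6 angstrom contacts, non-coplanar).
dense_proton_cluster <- function() {
  build_spin_system(list(
    spin_site("a", "1H", c(0, 0, 0)),
    spin_site("b", "1H", c(2.2, 0, 0)),
    spin_site("c", "1H", c(1.0, 2.0, 0.3)),
    spin_site("d", "1H", c(0.9, 0.8, 2.1))
  ))
}

# Synthetic ladder spin systems read back through the PDB round trip.
ladder_proton_system <- function(n_layers = 3, ...) {
  pdb <- tempfile(fileext = ".pdb")
  make_ladder_pdb(ladder_geometry_spec(n_layers = n_layers, ...), pdb)
  build_spin_system(
    read_pdb_sites(pdb, 1, ladder_proton_selectors(n_layers))
  )
}

ladder_full_system <- function(n_layers = 3, J = 92) {
  pdb <- tempfile(fileext = ".pdb")
  make_ladder_pdb(ladder_geometry_spec(n_layers = n_layers), pdb)
  sites <- read_pdb_sites(
    pdb, 1,
    c(ladder_proton_selectors(n_layers), ladder_nitrogen_selectors(n_layers))
  )
  sc <- list()
  for (l in seq_len(n_layers)) {
    sc[[length(sc) + 1]] <- list(
      pair = c(sprintf("ASN%d.ND2", l), sprintf("ASN%d.HD21", l)), J = J
    )
    sc[[length(sc) + 1]] <- list(
      pair = c(sprintf("ASN%d.ND2", l), sprintf("ASN%d.HD22", l)), J = J
    )
  }
  build_spin_system(sites, scalar_couplings = sc)
}

# Independent hand evaluation of the dipolar anisotropy (CODATA constants),
# kept separate from the package's own constants table.
oracle_dipolar_hz <- function(gamma_i, gamma_j, r_angstrom) {
  mu0_over_4pi <- 1e-7
  hbar <- 1.0545718e-34
  -mu0_over_4pi * gamma_i * gamma_j * hbar / (2 * pi * (r_angstrom * 1e-10)^3)
}
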