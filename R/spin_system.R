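#' Construct a spin site
#'
#' A site is one NMR-active nucleus with a position in a common (crystal)
#' frame. Positions are in angstrom.
#'
#' @param site_id unique identifier, e.g. `"N226.HD21"`.
#' @param isotope isotope label (`"1H"`, `"15N"`) or a [nucleus_spec()].
#' @param position numeric length-3 position in angstrom.
#' @param isotropic_shift isotropic chemical shift in ppm (default 0; the
#'   linewidth simulations are run on-resonance).
#' @param label free-text provenance (residue/atom).
#' @return A `spin_site` list.
#' @export
spin_site <- function(site_id, isotope, position, isotropic_shift = 0,
                      label = site_id) {
  if (!inherits(isotope, "nucleus_spec")) isotope <- nucleus_spec(isotope)
  position <- as.numeric(position)
  stopifnot(length(position) == 3, all(is.finite(position)))
  structure(
    list(
      site_id = as.character(site_id),
      isotope = isotope,
      position = position,
      isotropic_shift = isotropic_shift,
      label = label
    ),
    class = "spin_site"
  )
}

infer_isotope_from_atom <- function(elety, elesy = NULL) {
  elem <- NULL
  if (!is.null(elesy) && !is.na(elesy) && nzchar(trimws(elesy))) {
    elem <- toupper(trimws(elesy))
  } else {
    chars <- strsplit(gsub("[^A-Za-z]", "", elety), "")[[1]]
    if (length(chars) == 0) stop("cannot infer element from atom name: ", elety)
    elem <- toupper(chars[1])
  }
  switch(elem,
    "H" = "1H",
    "N" = "15N",
    stop("unsupported element '", elem, "' for atom ", elety, call. = FALSE)
  )
}

#' Read spin sites from a multi-model PDB file
#'
#' Extracts selected atoms of one model of a (possibly multi-model) PDB file
#' as [spin_site()]s, inferring the isotope from the element (H becomes 1H,
#' N becomes 15N). This is how the six NH2 ladder protons are pulled out of a
#' fibril structure.
#'
#' @param path PDB file path.
#' @param model_index 1-based model number (PDB `MODEL` record).
#' @param selectors list of selectors; each is a list/vector with elements
#'   `resno` (residue number) and `atom` (atom name, e.g. `"HD21"`).
#'   Optionally `chain`. Each selector must match exactly one atom.
#' @return List of [spin_site()] in selector order; coordinates in angstrom.
#' @export
read_pdb_sites <- function(path, model_index = 1, selectors) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  n_models <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > n_models) {
    stop(sprintf("model %d not present (file has %d model(s))",
                 model_index, n_models), call. = FALSE)
  }
  xyz <- pdb$xyz[model_index, ]
  atoms <- pdb$atom
  out <- vector("list", length(selectors))
  for (s in seq_along(selectors)) {
    sel <- selectors[[s]]
    resno <- as.integer(sel[["resno"]])
    atom <- as.character(sel[["atom"]])
    hit <- which(atoms$resno == resno & trimws(atoms$elety) == atom)
    if (!is.null(sel[["chain"]]) && !is.na(sel[["chain"]])) {
      hit <- hit[atoms$chain[hit] == sel[["chain"]]]
    }
    if (length(hit) == 0) {
      stop(sprintf("selector (resno %d, atom %s) matches no atom", resno, atom),
           call. = FALSE)
    }
    if (length(hit) > 1) {
      stop(sprintf("selector (resno %d, atom %s) is ambiguous (%d matches); add a chain",
                   resno, atom, length(hit)), call. = FALSE)
    }
    idx <- 3 * (hit - 1) + 1:3
    elesy <- if ("elesy" %in% names(atoms)) atoms$elesy[hit] else NULL
    iso <- infer_isotope_from_atom(atoms$elety[hit], elesy)
    out[[s]] <- spin_site(
      site_id = sprintf("%s%d.%s", atoms$resid[hit], resno, atom),
      isotope = iso,
      position = xyz[idx],
      label = sprintf("%s %d %s (model %d)", atoms$resid[hit], resno, atom,
                      model_index)
    )
  }
  ids <- vapply(out, function(x) x$site_id, character(1))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    ids[duplicated(ids)] <- paste0(ids[duplicated(ids)], ".",
                                   seq_len(sum(duplicated(ids))))
    for (k in seq_along(out)) out[[k]]$site_id <- ids[k]
  }
  out
}

#' Dipolar anisotropy from an internuclear vector
#'
#' The through-space dipolar coupling anisotropy (delta/2pi, signed, in Hz)
#' for two nuclei separated by `r` angstrom:
#' `-(mu0/4pi) * gamma_i * gamma_j * hbar / (2pi r^3)`.
#'
#' @param gamma_i,gamma_j gyromagnetic ratios (rad s^-1 T^-1).
#' @param r_angstrom internuclear distance in angstrom.
#' @return Anisotropy over 2pi in Hz (e.g. about -15.0 kHz for two protons at
#'   2.0 angstrom).
#' @export
dipolar_anisotropy_hz <- function(gamma_i, gamma_j, r_angstrom) {
  r <- r_angstrom * 1e-10
  -(nmr_constants$mu0 / (4 * pi)) * gamma_i * gamma_j * nmr_constants$hbar /
    (2 * pi * r^3)
}

#' Build a spin system from sites
#'
#' Computes all pairwise dipolar couplings from the coordinates and retains
#' every pair whose absolute anisotropy exceeds `coupling_cutoff` (and no
#' others). Axes are normalized internuclear vectors in the crystal frame.
#'
#' @param sites list of [spin_site()].
#' @param field static field in tesla (default 20.0).
#' @param coupling_cutoff retain pairs with |anisotropy/2pi| > cutoff, in Hz.
#'   Default 50 Hz: weaker couplings have negligible effect at the linewidths
#'   studied here.
#' @param scalar_couplings list of scalar couplings, each a list with
#'   `pair = c(id_i, id_j)` and `J` in Hz (one-bond N-H is ~92 Hz).
#' @return A `spin_system` with elements `sites`, `dipolar` (list of pair
#'   couplings with `pair`, `anisotropy_over_2pi` in Hz, unit `axis`,
#'   `distance` in angstrom), `scalar_couplings`, `field`.
#' @export
build_spin_system <- function(sites, field = 20.0, coupling_cutoff = 50,
                              scalar_couplings = list()) {
  stopifnot(length(sites) >= 1, coupling_cutoff >= 0)
  ids <- vapply(sites, function(x) x$site_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate site_id: ", ids[duplicated(ids)][1])
  n <- length(sites)
  dip <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        dvec <- sites[[j]]$position - sites[[i]]$position
        r <- sqrt(sum(dvec^2))
        if (r < 0.1) {
          stop(sprintf("sites %s and %s are coincident (r = %.3g angstrom)",
                       ids[i], ids[j], r), call. = FALSE)
        }
        aniso <- dipolar_anisotropy_hz(
          sites[[i]]$isotope$gyromagnetic_ratio,
          sites[[j]]$isotope$gyromagnetic_ratio, r
        )
        if (abs(aniso) > coupling_cutoff) {
          dip[[length(dip) + 1]] <- list(
            pair = c(ids[i], ids[j]),
            anisotropy_over_2pi = aniso,
            axis = dvec / r,
            distance = r
          )
        }
      }
    }
  }
  for (sc in scalar_couplings) {
    if (!all(sc$pair %in% ids)) {
      stop("scalar coupling refers to unknown site: ",
           paste(setdiff(sc$pair, ids), collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(
      sites = sites,
      dipolar = dip,
      scalar_couplings = scalar_couplings,
      field = field,
      coupling_cutoff = coupling_cutoff
    ),
    class = "spin_system"
  )
}

#' @export
print.spin_system <- function(x, ...) {
  iso <- table(vapply(x$sites, function(s) s$isotope$isotope_label, character(1)))
  cat(sprintf(
    "<spin_system> %d sites (%s), %d dipolar pair(s) above %.3g Hz, %d scalar J, B0 = %.3g T\n",
    length(x$sites),
    paste(sprintf("%d x %s", as.integer(iso), names(iso)), collapse = ", "),
    length(x$dipolar), x$coupling_cutoff, length(x$scalar_couplings), x$field
  ))
  invisible(x)
}

site_isotopes <- function(system) {
  vapply(system$sites, function(s) s$isotope$isotope_label, character(1))
}

site_ids <- function(system) {
  vapply(system$sites, function(s) s$site_id, character(1))
}

#' Serialize / restore a spin system
#'
#' Writes the system (sites, couplings, field) to a JSON file for reuse by
#' downstream analysis scripts, and reads it back.
#'
#' @param system a [build_spin_system()] result.
#' @param path file path.
#' @return `write_spin_system` returns `path` invisibly;
#'   `read_spin_system` returns a `spin_system`.
#' @export
write_spin_system <- function(system, path) {
  obj <- list(
    field = system$field,
    coupling_cutoff = system$coupling_cutoff,
    sites = lapply(system$sites, function(s) {
      list(site_id = s$site_id, isotope = s$isotope$isotope_label,
           position = s$position, isotropic_shift = s$isotropic_shift,
           label = s$label)
    }),
    scalar_couplings = system$scalar_couplings
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spin_system
#' @export
read_spin_system <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  sites <- lapply(obj$sites, function(s) {
    spin_site(s$site_id, s$isotope, unlist(s$position),
              isotropic_shift = s$isotropic_shift, label = s$label)
  })
  sc <- lapply(obj$scalar_couplings, function(x) {
    list(pair = unlist(x$pair), J = x$J)
  })
  build_spin_system(sites, field = obj$field,
                    coupling_cutoff = obj$coupling_cutoff,
                    scalar_couplings = sc)
}
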