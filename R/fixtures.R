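#' Parameters for the synthetic ring fixture
#'
#' Describes a synthetic membrane-oriented "protein": carbon
#' pseudo-atoms arranged on stacked circles of known radius so that the
#' belt pipeline's answer is known analytically. An optional second,
#' smaller shell emulates grooves/decoy surfaces inside the main shell.
#'
#' @param ring_radius radius of the main atom shell (Angstrom).
#' @param n_rings number of stacked rings.
#' @param atoms_per_ring atoms per ring (>= 3).
#' @param z_span total z extent covered by the rings (Angstrom).
#' @param radial_jitter_sd Gaussian jitter applied to the radius only
#'   (Angstrom, >= 0), so the target radial density stays
#'   one-dimensional.
#' @param half_thickness membrane half-thickness written as a REMARK.
#' @param seed RNG seed for the jitter.
#' @param decoy_inner_radius optional radius of a second, inner shell.
#' @return A `fixture_params` list.
#' @export
fixture_params <- function(ring_radius = 20, n_rings = 5L, atoms_per_ring = 36L,
                           z_span = 24, radial_jitter_sd = 0,
                           half_thickness = 15, seed = 1L,
                           decoy_inner_radius = NULL) {
  stopifnot(ring_radius > 0, n_rings >= 1, atoms_per_ring >= 3,
            z_span >= 0, radial_jitter_sd >= 0, half_thickness > 0)
  if (!is.null(decoy_inner_radius)) {
    stopifnot(decoy_inner_radius > 0, decoy_inner_radius < ring_radius)
  }
  structure(
    list(ring_radius = ring_radius, n_rings = as.integer(n_rings),
         atoms_per_ring = as.integer(atoms_per_ring), z_span = z_span,
         radial_jitter_sd = radial_jitter_sd, half_thickness = half_thickness,
         seed = as.integer(seed), decoy_inner_radius = decoy_inner_radius),
    class = "fixture_params"
  )
}

ring_atom_coords <- function(radius, n_rings, atoms_per_ring, z_span, jitter_sd) {
  zs <- if (n_rings == 1L) 0 else seq(-z_span / 2, z_span / 2, length.out = n_rings)
  ang <- seq(0, 2 * pi, length.out = atoms_per_ring + 1L)[-(atoms_per_ring + 1L)]
  grid <- expand.grid(ang = ang, z = zs)
  rad <- radius + if (jitter_sd > 0) stats::rnorm(nrow(grid), 0, jitter_sd) else 0
  data.frame(x = rad * cos(grid$ang), y = rad * sin(grid$ang), z = grid$z)
}

#' Generate a synthetic membrane-oriented ring structure
#'
#' Carbon pseudo-atoms (residue `ALA`, one chain) on `n_rings` circles
#' of radius `ring_radius` evenly spaced over
#' `z in [-z_span/2, +z_span/2]`, with optional seeded Gaussian radial
#' jitter and an optional inner decoy shell, plus a half-thickness
#' REMARK. Spacing is checked so atoms sit >= 2.5 Angstrom apart (at 3
#' jitter standard deviations), which keeps every shell atom's SASA
#' far above the exposure cutoff. The returned structure is re-parsed
#' from the serialized text, so its coordinates carry the PDB format's
#' 3-decimal precision.
#'
#' @param params a `fixture_params` list.
#' @return List with `structure` (an `oriented_structure`), `pdb_text`
#'   and `params`.
#' @examples
#' fx <- make_ring_fixture(fixture_params(ring_radius = 20))
#' range(radial_distances(fx$structure$atoms))
#' @export
make_ring_fixture <- function(params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  p <- params
  check_ring_spacing(p$ring_radius, p$n_rings, p$atoms_per_ring, p$z_span,
                     p$radial_jitter_sd)

  coords <- with_seed(p$seed, {
    main <- ring_atom_coords(p$ring_radius, p$n_rings, p$atoms_per_ring,
                             p$z_span, p$radial_jitter_sd)
    if (!is.null(p$decoy_inner_radius)) {
      # Fewer atoms on the smaller shell so arc spacing stays >= 2.5 A.
      n_decoy <- max(3L, floor(p$atoms_per_ring * p$decoy_inner_radius / p$ring_radius))
      check_ring_spacing(p$decoy_inner_radius, p$n_rings, n_decoy, p$z_span,
                         p$radial_jitter_sd)
      decoy <- ring_atom_coords(p$decoy_inner_radius, p$n_rings, n_decoy,
                                p$z_span, p$radial_jitter_sd)
      rbind(main, decoy)
    } else {
      main
    }
  })

  n <- nrow(coords)
  atoms <- data.frame(
    serial = seq_len(n), atom_name = "CA", element = "C",
    residue_name = "ALA", chain_id = "A", residue_number = seq_len(n),
    x = coords$x, y = coords$y, z = coords$z,
    record_kind = "ATOM", is_dummy = FALSE, is_hydrogen = FALSE,
    stringsAsFactors = FALSE
  )
  skeleton <- structure(
    list(atoms = atoms, half_thickness = p$half_thickness,
         source_label = "ring-fixture", solvent_residues = c("HOH", "WAT"),
         n_skipped = 0L),
    class = "oriented_structure"
  )
  pdb_text <- write_oriented_pdb(skeleton)
  list(structure = parse_pdb(pdb_text, source_label = "ring-fixture"),
       pdb_text = pdb_text,
       params = params)
}

check_ring_spacing <- function(radius, n_rings, atoms_per_ring, z_span, jitter_sd) {
  arc <- 2 * pi * max(0, radius - 3 * jitter_sd) / atoms_per_ring
  zsp <- if (n_rings > 1L) z_span / (n_rings - 1L) else Inf
  if (min(arc, zsp) < 2.5) {
    detbelt_stop("bad_fixture",
                 "atoms would be closer than 2.5 Angstrom (arc %.2f, ring spacing %.2f); use fewer atoms_per_ring or rings",
                 arc, zsp)
  }
  invisible(TRUE)
}
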