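#' Bondi van der Waals radii
#'
#' The standard Bondi set for the elements that occur in proteins,
#' lipids and detergents. Unlisted elements fall back to the default
#' carbon-like radius in [assign_vdw_radii()].
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
bondi_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
}

#' Assign van der Waals radii to heavy atoms
#'
#' @param atoms data frame of atom records (see [parse_pdb()]); all
#'   atoms must be heavy (no hydrogens, no dummies).
#' @param radii named element -> radius (Angstrom) table.
#' @param default_radius radius for elements absent from `radii`; a
#'   warning lists the unknown elements once.
#' @return A `sphere_set`: list with `centers` (n x 3 matrix), `radii`
#'   (length n) and `atom_index` (row indices into `atoms`).
#' @export
assign_vdw_radii <- function(atoms, radii = bondi_radii(), default_radius = 1.70) {
  if (is.null(atoms) || nrow(atoms) == 0L) {
    detbelt_stop("empty_structure", "cannot assign radii: no atoms")
  }
  el <- toupper(atoms$element)
  names(radii) <- toupper(names(radii))
  r <- unname(radii[el])
  unknown <- unique(el[is.na(r)])
  if (length(unknown)) {
    detbelt_warn("unknown element(s) %s assigned default radius %.2f Angstrom",
                 paste(unknown, collapse = ", "), default_radius)
    r[is.na(r)] <- default_radius
  }
  structure(
    list(centers = cbind(x = atoms$x, y = atoms$y, z = atoms$z),
         radii = r,
         atom_index = seq_len(nrow(atoms))),
    class = "sphere_set"
  )
}

#' Deterministic Fibonacci sphere lattice
#'
#' Near-uniform point set on the unit sphere by the golden-angle spiral;
#' fully deterministic for a given `n`, which makes the Shrake-Rupley
#' areas reproducible.
#'
#' @param n number of points (>= 1).
#' @return An `n` x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

# All pairs of spheres closer than the sum of their expanded radii,
# found through a uniform grid (cell list) with cell size equal to the
# largest possible interaction distance. Returns a list mapping each
# sphere to the indices of its potential occluders. Results are
# identical to the quadratic all-pairs scan (asserted in the tests).
neighbor_lists <- function(centers, rho) {
  n <- nrow(centers)
  cutoff <- 2 * max(rho)
  cell <- floor(centers / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  buckets <- split(seq_len(n), key)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (k in seq_len(27)) {
      kk <- paste(cell[i, 1] + offsets[k, 1],
                  cell[i, 2] + offsets[k, 2],
                  cell[i, 3] + offsets[k, 3], sep = ",")
      b <- buckets[[kk]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != i]
    if (length(cand)) {
      d2 <- (centers[cand, 1] - centers[i, 1])^2 +
            (centers[cand, 2] - centers[i, 2])^2 +
            (centers[cand, 3] - centers[i, 3])^2
      cand <- cand[d2 < (rho[cand] + rho[i])^2]
    }
    out[[i]] <- cand
  }
  out
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by test-point counting: each atom is expanded by the
#' probe radius, covered with a deterministic Fibonacci lattice of
#' `n_points` points, and the fraction of points not buried inside any
#' neighbouring expanded sphere gives the exposed area
#' `(exposed / n_points) * 4 * pi * (r + probe)^2`.
#'
#' @param spheres a `sphere_set` from [assign_vdw_radii()].
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points test points per sphere; the default 960 keeps areas
#'   within a fraction of a square Angstrom of convergence.
#' @return A `sasa_result`: list with `area` (Angstrom^2, aligned with
#'   the sphere set), `probe_radius` and `n_points`.
#' @examples
#' atoms <- data.frame(element = "C", x = 0, y = 0, z = 0)
#' s <- shrake_rupley_sasa(assign_vdw_radii(atoms))
#' s$area  # isolated carbon: 4 * pi * 3.1^2
#' @export
shrake_rupley_sasa <- function(spheres, probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(spheres, "sphere_set"), probe_radius >= 0, n_points >= 1)
  centers <- spheres$centers
  rho <- spheres$radii + probe_radius
  n <- nrow(centers)
  lattice <- fibonacci_sphere(n_points)
  nb <- neighbor_lists(centers, rho)
  area <- numeric(n)
  for (i in seq_len(n)) {
    pts <- lattice * rho[i]
    pts[, 1] <- pts[, 1] + centers[i, 1]
    pts[, 2] <- pts[, 2] + centers[i, 2]
    pts[, 3] <- pts[, 3] + centers[i, 3]
    exposed <- rep(TRUE, n_points)
    for (j in nb[[i]]) {
      if (!any(exposed)) break
      d2 <- (pts[, 1] - centers[j, 1])^2 +
            (pts[, 2] - centers[j, 2])^2 +
            (pts[, 3] - centers[j, 3])^2
      exposed <- exposed & d2 >= rho[j]^2
    }
    area[i] <- sum(exposed) / n_points * 4 * pi * rho[i]^2
  }
  structure(
    list(area = area, probe_radius = probe_radius, n_points = as.integer(n_points)),
    class = "sasa_result"
  )
}

#' Dump per-atom SASA as a tab-separated table
#'
#' @param atoms heavy-atom records aligned with `sasa`.
#' @param sasa a `sasa_result`.
#' @param path optional output file.
#' @return Data frame with serial, atom name, residue and area
#'   (invisibly when written to `path`).
#' @export
dump_sasa <- function(atoms, sasa, path = NULL) {
  stopifnot(inherits(sasa, "sasa_result"), nrow(atoms) == length(sasa$area))
  tab <- data.frame(serial = atoms$serial,
                    atom_name = atoms$atom_name,
                    residue = sprintf("%s %s%d", atoms$residue_name,
                                      atoms$chain_id, atoms$residue_number),
                    area_A2 = round(sasa$area, 3))
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
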