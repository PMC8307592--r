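#' Options controlling the belt computation
#'
#' Collects the tunable parameters of the belt pipeline with their
#' defaults. The accessible-surface-area cutoff (3 Angstrom^2, strict
#' inequality) selects solvent-exposed atoms; the van der Waals offset
#' (1.66 Angstrom, the average heavy-atom van der Waals radius) is added
#' to the detected radial density peak to give the inner radius.
#'
#' @param asa_cutoff SASA threshold in Angstrom^2; atoms with area
#'   strictly greater than this count as exposed.
#' @param vdw_offset offset added to the rightmost density peak
#'   (Angstrom).
#' @param probe_radius solvent probe radius for SASA (Angstrom).
#' @param n_points Shrake-Rupley test points per atom.
#' @param inner_radius_override optional inner radius (Angstrom)
#'   replacing the density-derived value; all other metrics are
#'   recomputed around it, the total detergent volume is unchanged.
#' @param half_thickness_override optional membrane half-thickness
#'   (Angstrom) replacing the value read from the structure.
#' @param kde_bandwidth `"silverman"` or an explicit bandwidth
#'   (Angstrom) for the radial kernel density estimate.
#' @param peak_min_fraction local maxima whose density is below this
#'   fraction of the global maximum are ignored when picking the
#'   rightmost peak, so isolated outermost atoms cannot define the belt.
#' @param volume_overrides optional named vector, detergent id ->
#'   monomer volume (Angstrom^3), overriding database volumes per run.
#' @param seed seed for any stochastic rendering sampling; the belt
#'   computation itself is deterministic.
#' @return A `belt_options` list.
#' @export
belt_options <- function(asa_cutoff = 3,
                         vdw_offset = 1.66,
                         probe_radius = 1.4,
                         n_points = 960L,
                         inner_radius_override = NULL,
                         half_thickness_override = NULL,
                         kde_bandwidth = "silverman",
                         peak_min_fraction = 0.10,
                         volume_overrides = NULL,
                         seed = 1L) {
  stopifnot(asa_cutoff >= 0, vdw_offset >= 0, probe_radius >= 0,
            n_points >= 1, peak_min_fraction >= 0, peak_min_fraction <= 1)
  if (!is.null(inner_radius_override)) stopifnot(inner_radius_override > 0)
  if (!is.null(half_thickness_override)) stopifnot(half_thickness_override > 0)
  if (is.numeric(kde_bandwidth)) stopifnot(kde_bandwidth > 0)
  structure(
    list(asa_cutoff = asa_cutoff, vdw_offset = vdw_offset,
         probe_radius = probe_radius, n_points = as.integer(n_points),
         inner_radius_override = inner_radius_override,
         half_thickness_override = half_thickness_override,
         kde_bandwidth = kde_bandwidth,
         peak_min_fraction = peak_min_fraction,
         volume_overrides = volume_overrides,
         seed = as.integer(seed)),
    class = "belt_options"
  )
}

#' Belt height from the membrane half-thickness
#'
#' The belt spans the full membrane: twice the half-thickness recorded
#' in the oriented structure.
#'
#' @param half_thickness membrane half-thickness (Angstrom).
#' @return Belt height h (Angstrom).
#' @export
belt_height <- function(half_thickness) {
  if (is.null(half_thickness) || !is.finite(half_thickness)) {
    detbelt_stop("no_thickness",
                 "thickness unavailable: no half-thickness REMARK, no dummy atoms, no override")
  }
  if (half_thickness <= 0) {
    detbelt_stop("no_thickness", "half-thickness must be > 0 (got %g)", half_thickness)
  }
  2 * half_thickness
}

#' Select solvent-exposed transmembrane atoms
#'
#' Heavy atoms inside the transmembrane slab (|z| <= half-thickness,
#' atom centres, inclusive) whose solvent-accessible surface area is
#' strictly greater than the cutoff.
#'
#' @param structure an `oriented_structure`.
#' @param sasa a `sasa_result` aligned with
#'   `protein_heavy_atoms(structure)`.
#' @param options a `belt_options` list.
#' @return Data frame of retained atom records.
#' @export
select_exposed_tm_atoms <- function(structure, sasa, options = belt_options()) {
  stopifnot(inherits(sasa, "sasa_result"))
  heavy <- protein_heavy_atoms(structure)
  if (nrow(heavy) != length(sasa$area)) {
    detbelt_stop("misaligned_sasa",
                 "SASA result (%d areas) does not align with heavy atoms (%d)",
                 length(sasa$area), nrow(heavy))
  }
  half <- options$half_thickness_override
  if (is.null(half)) half <- structure$half_thickness
  if (is.null(half) || !is.finite(half)) {
    detbelt_stop("no_thickness", "thickness unavailable for transmembrane atom selection")
  }
  keep <- abs(heavy$z) <= half & sasa$area > options$asa_cutoff
  if (!any(keep)) {
    detbelt_stop("no_tm_atoms",
                 "no exposed transmembrane atoms (slab |z| <= %.2f, SASA > %.2f): the protein may not span the membrane or the cutoff is too high",
                 half, options$asa_cutoff)
  }
  heavy[keep, , drop = FALSE]
}

#' Radial distances to the membrane normal
#'
#' @param atoms data frame with `x` and `y` columns.
#' @return sqrt(x^2 + y^2) per atom (Angstrom), order preserved.
#' @export
radial_distances <- function(atoms) {
  if (is.null(atoms) || nrow(atoms) == 0L) {
    detbelt_stop("no_tm_atoms", "no atoms to compute radial distances for")
  }
  sqrt(atoms$x^2 + atoms$y^2)
}

#' Kernel density estimate of the radial distance distribution
#'
#' Gaussian kernel, Silverman's rule-of-thumb bandwidth (or an explicit
#' bandwidth), evaluated on a uniform 512-point grid covering
#' `[max(0, min - 3 bw), max + 3 bw]`. When all distances coincide the
#' density is a point mass; the profile is then flagged degenerate and
#' [rightmost_peak()] short-circuits to that value.
#'
#' @param distances radial distances (Angstrom), at least 2 values.
#' @param options a `belt_options` list.
#' @return A `radial_profile`: list with `grid`, `density`, `bandwidth`,
#'   `n_samples`, `degenerate` and (if degenerate) `value`.
#' @export
density_estimate <- function(distances, options = belt_options()) {
  stopifnot(length(distances) >= 2, all(is.finite(distances)))
  if (diff(range(distances)) < .Machine$double.eps^0.5) {
    return(structure(
      list(grid = distances[1L], density = Inf, bandwidth = 0,
           n_samples = length(distances), degenerate = TRUE,
           value = distances[1L]),
      class = "radial_profile"
    ))
  }
  bw <- if (is.numeric(options$kde_bandwidth)) {
    options$kde_bandwidth
  } else {
    stats::bw.nrd0(distances)  # Silverman's rule of thumb
  }
  d <- stats::density(distances, bw = bw, kernel = "gaussian", n = 512,
                      from = max(0, min(distances) - 3 * bw),
                      to = max(distances) + 3 * bw)
  structure(
    list(grid = d$x, density = d$y, bandwidth = bw,
         n_samples = length(distances), degenerate = FALSE),
    class = "radial_profile"
  )
}

#' Rightmost peak of a radial density profile
#'
#' Returns the grid position of the largest-radius local maximum whose
#' density reaches at least `peak_min_fraction` of the global maximum.
#' The fraction guard keeps a handful of stray outermost atoms from
#' defining the belt. Degenerate (point-mass) profiles return their
#' value directly.
#'
#' @param profile a `radial_profile`.
#' @param options a `belt_options` list.
#' @return Peak radial position (Angstrom).
#' @export
rightmost_peak <- function(profile, options = belt_options()) {
  stopifnot(inherits(profile, "radial_profile"))
  if (isTRUE(profile$degenerate)) return(profile$value)
  y <- profile$density
  n <- length(y)
  left <- c(-Inf, y[-n])
  right <- c(y[-1L], -Inf)
  is_max <- y > left & y >= right
  qualifying <- is_max & y >= options$peak_min_fraction * max(y)
  if (!any(qualifying)) {
    detbelt_warn("no qualifying local maximum in radial density; using global maximum")
    return(profile$grid[which.max(y)])
  }
  profile$grid[max(which(qualifying))]
}

#' Inner belt radius from the density peak
#'
#' The peak radial distance plus the average heavy-atom van der Waals
#' radius (default 1.66 Angstrom), so the belt starts at the outside of
#' the exposed atom shell. An explicit override replaces the computed
#' value (the metrics downstream are recomputed around it).
#'
#' @param peak peak radial distance (Angstrom).
#' @param options a `belt_options` list.
#' @return List with `r` (Angstrom) and `r_source` (`"computed"` or
#'   `"override"`).
#' @export
inner_radius <- function(peak, options = belt_options()) {
  if (!is.null(options$inner_radius_override)) {
    return(list(r = options$inner_radius_override, r_source = "override"))
  }
  stopifnot(peak >= 0)
  list(r = peak + options$vdw_offset, r_source = "computed")
}

#' Outer belt radius from volume conservation
#'
#' The outer radius R of a hollow cylinder of height h and inner radius
#' r whose volume equals the total detergent volume V:
#' `R = sqrt(V / (pi h) + r^2)`, so that `pi h (R^2 - r^2) = V` exactly.
#'
#' @param V total detergent volume (Angstrom^3, >= 0).
#' @param h belt height (Angstrom, > 0).
#' @param r inner radius (Angstrom, >= 0).
#' @return Outer radius R (Angstrom).
#' @export
outer_radius <- function(V, h, r) {
  stopifnot(V >= 0, h > 0, r >= 0)
  sqrt(V / (pi * h) + r^2)
}

#' Stack a detergent mixture into the belt
#'
#' Mixtures are drawn as coaxial cylinder slabs stacked bottom-to-top in
#' user input order, each slab's height proportional to its detergent's
#' share of the total volume, so that every slab's hollow-cylinder
#' volume equals the volume of that detergent exactly. The stacking
#' order is a display convention, not a physical arrangement.
#'
#' @param h belt height (Angstrom).
#' @param r inner radius (Angstrom).
#' @param R outer radius (Angstrom).
#' @param volumes data frame with columns `detergent_id`, `n_monomers`,
#'   `volume` (Angstrom^3) in stacking order; optional `color`.
#' @return Data frame of stacks with `z_lo`/`z_hi` tiling
#'   `[-h/2, +h/2]`.
#' @export
stack_mixture <- function(h, r, R, volumes) {
  stopifnot(h > 0, R >= r, r >= 0, nrow(volumes) >= 1, all(volumes$volume >= 0))
  V <- sum(volumes$volume)
  if (V <= 0) {
    detbelt_stop("empty_belt", "all stack volumes are zero")
  }
  heights <- h * volumes$volume / V
  z_hi <- -h / 2 + cumsum(heights)
  z_hi[length(z_hi)] <- h / 2  # absorb floating-point drift at the top
  z_lo <- c(-h / 2, z_hi[-length(z_hi)])
  out <- data.frame(detergent_id = volumes$detergent_id,
                    n_monomers = volumes$n_monomers,
                    volume = volumes$volume,
                    z_lo = z_lo, z_hi = z_hi,
                    stringsAsFactors = FALSE)
  if (!is.null(volumes$color)) out$color <- volumes$color
  out
}

with_stage <- function(stage, expr) {
  tryCatch(expr, detbelt_error = function(e) {
    if (!grepl("^\\[", conditionMessage(e))) {
      e$message <- sprintf("[%s] %s", stage, conditionMessage(e))
    }
    stop(e)
  })
}

#' Compute the detergent belt around an oriented structure
#'
#' End-to-end pipeline: belt height from the membrane half-thickness;
#' Shrake-Rupley SASA over all heavy atoms; selection of exposed
#' transmembrane atoms; kernel density of their radial distances;
#' rightmost density peak plus the van der Waals offset as inner radius
#' (unless overridden); total detergent volume from monomer counts and
#' the database; outer radius by volume conservation; mixture stacks.
#'
#' @param structure an `oriented_structure`.
#' @param spec a `belt_spec` (see [belt_spec()]).
#' @param db a `detergent_db` (default: the built-in database).
#' @param options a `belt_options` list.
#' @return A `belt_geometry`: list with `h`, `r`, `R`, `V_total`
#'   (Angstrom / Angstrom^3), `stacks`, `r_source`, `peak_radius`,
#'   `n_tm_atoms` and `half_thickness`.
#' @examples
#' fx <- make_ring_fixture(fixture_params(ring_radius = 20, seed = 1))
#' geom <- build_belt(fx$structure, belt_spec("DDM", 400))
#' geom$r  # ~ 21.66: atom shell at 20 plus the 1.66 vdW offset
#' @export
build_belt <- function(structure, spec, db = load_detergent_db(),
                       options = belt_options()) {
  stopifnot(inherits(structure, "oriented_structure"), inherits(spec, "belt_spec"))
  half <- options$half_thickness_override
  if (is.null(half)) half <- structure$half_thickness
  h <- with_stage("height", belt_height(half))

  heavy <- with_stage("atoms", protein_heavy_atoms(structure))
  spheres <- with_stage("sasa", assign_vdw_radii(heavy))
  sasa <- with_stage("sasa",
                     shrake_rupley_sasa(spheres, options$probe_radius, options$n_points))
  tm <- with_stage("tm-selection", select_exposed_tm_atoms(structure, sasa, options))
  dists <- with_stage("radial", radial_distances(tm))
  profile <- with_stage("density", density_estimate(dists, options))
  peak <- with_stage("peak", rightmost_peak(profile, options))
  ir <- inner_radius(peak, options)

  vol <- with_stage("volume", total_volume(spec, db, options$volume_overrides))
  R <- with_stage("geometry", outer_radius(vol$V_total, h, ir$r))
  stacks <- with_stage("geometry", stack_mixture(h, ir$r, R, vol$per_entry))

  structure(
    list(h = h, r = ir$r, R = R, V_total = vol$V_total,
         stacks = stacks, r_source = ir$r_source, peak_radius = peak,
         n_tm_atoms = nrow(tm), half_thickness = half),
    class = "belt_geometry"
  )
}

#' @export
print.belt_geometry <- function(x, ...) {
  cat("Detergent belt (hollow cylinder)\n")
  cat(sprintf("  height h        : %8.2f Angstrom\n", x$h))
  cat(sprintf("  inner radius r  : %8.2f Angstrom (%s)\n", x$r, x$r_source))
  cat(sprintf("  outer radius R  : %8.2f Angstrom\n", x$R))
  cat(sprintf("  total volume V  : %10.0f Angstrom^3\n", x$V_total))
  for (i in seq_len(nrow(x$stacks))) {
    s <- x$stacks[i, ]
    cat(sprintf("  stack %d: %s x %d, %.0f Angstrom^3, z in [%.2f, %.2f]\n",
                i, s$detergent_id, s$n_monomers, s$volume, s$z_lo, s$z_hi))
  }
  invisible(x)
}
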