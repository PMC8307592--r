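# Shared oracles and fixture builders for the test suite.

# Monte-Carlo SASA oracle: for each sphere, sample points uniformly on
# its probe-expanded surface and count the fraction not buried inside
# any other expanded sphere. Independent of the Shrake-Rupley path
# (random directions, no lattice, no neighbour lists).
mc_sasa <- function(centers, radii, probe = 1.4, n_mc = 1e5, seed = 42) {
  set.seed(seed)
  rho <- radii + probe
  n <- nrow(centers)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    dirs <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- dirs * rho[i]
    pts <- sweep(pts, 2, centers[i, ], "+")
    exposed <- rep(TRUE, n_mc)
    for (j in seq_len(n)[-i]) {
      d2 <- (pts[, 1] - centers[j, 1])^2 + (pts[, 2] - centers[j, 2])^2 +
        (pts[, 3] - centers[j, 3])^2
      exposed <- exposed & d2 >= rho[j]^2
    }
    areas[i] <- mean(exposed) * 4 * pi * rho[i]^2
  }
  areas
}

# Closed-form SASA of sphere A (vdW radius ra) occluded by one sphere
# (vdW radius rb) at centre distance d, probe-expanded on both sides.
two_sphere_sasa <- function(ra, rb, d, probe = 1.4) {
  rhoa <- ra + probe
  rhob <- rb + probe
  if (d >= rhoa + rhob) return(4 * pi * rhoa^2)      # no overlap
  if (d + rhoa <= rhob) return(0)                    # fully engulfed
  ccut <- (d^2 + rhoa^2 - rhob^2) / (2 * d)          # intersection plane
  2 * pi * rhoa * (rhoa + ccut)
}

# Occluder distance that gives sphere A a target analytic SASA, by
# inverting the closed form above (big occluder radius rb).
occluder_distance_for_sasa <- function(target, ra, rb, probe = 1.4) {
  rhoa <- ra + probe
  rhob <- rb + probe
  ccut <- target / (2 * pi * rhoa) - rhoa
  # ccut = (d^2 + rhoa^2 - rhob^2) / (2 d)  ->  d^2 - 2 ccut d + (rhoa^2 - rhob^2) = 0
  d <- ccut + sqrt(ccut^2 - rhoa^2 + rhob^2)
  stopifnot(is.finite(d), d > 0, d + rhoa > rhob, d < rhoa + rhob)
  d
}

# Random atom cluster with a minimum pairwise separation, so spheres
# overlap partially (as bonded/packed heavy atoms do) without burying
# any atom almost completely — per-atom relative area comparisons stay
# statistically meaningful.
random_cluster <- function(n, seed, box = 8, min_dist = 2.8) {
  set.seed(seed)
  pts <- matrix(stats::runif(3, 0, box), ncol = 3)
  while (nrow(pts) < n) {
    cand <- stats::runif(3, 0, box)
    d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 + (pts[, 3] - cand[3])^2
    if (min(d2) >= min_dist^2) pts <- rbind(pts, cand)
  }
  pts
}

# Minimal atom-record data frame for synthetic sphere clusters.
carbon_atoms <- function(xyz) {
  n <- nrow(xyz)
  data.frame(serial = seq_len(n), atom_name = "C", element = "C",
             residue_name = "LIG", chain_id = "A", residue_number = seq_len(n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             record_kind = "HETATM", is_dummy = FALSE, is_hydrogen = FALSE,
             stringsAsFactors = FALSE)
}

# One fully-formed PDB line for ad-hoc parsing tests.
pdb_atom_line <- function(serial = 1, name = "CA", resn = "ALA", chain = "A",
                          resno = 1, x = 0, y = 0, z = 0, kind = "ATOM",
                          element = " C") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          kind, serial, nm, resn, chain, resno, x, y, z, 1, 0, element)
}

builtin_db <- function() load_detergent_db()
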