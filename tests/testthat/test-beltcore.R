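test_that("belt height doubles the half-thickness and rejects bad input", {
  expect_equal(belt_height(15.2), 30.4)
  expect_equal(belt_height(14.0), 28.0)
  expect_error(belt_height(0), class = "detbelt_no_thickness")
  expect_error(belt_height(NA_real_), class = "detbelt_no_thickness")
})

test_that("transmembrane selection applies the z-slab and the strict SASA cutoff", {
  atoms <- carbon_atoms(rbind(c(10, 0, 0),   # in slab, exposed
                              c(10, 0, 20),  # outside slab
                              c(11, 0, 0),   # in slab, SASA exactly at cutoff
                              c(12, 0, 1)))  # in slab, below cutoff
  s <- structure(list(atoms = atoms, half_thickness = 15,
                      source_label = "", solvent_residues = c("HOH", "WAT"),
                      n_skipped = 0L),
                 class = "oriented_structure")
  sasa <- structure(list(area = c(10, 10, 3.0, 2.9), probe_radius = 1.4,
                         n_points = 960L), class = "sasa_result")
  kept <- select_exposed_tm_atoms(s, sasa, belt_options())
  expect_equal(kept$serial, 1L)  # 3.0 excluded: strictly greater than 3 required

  sasa_none <- structure(list(area = rep(0, 4), probe_radius = 1.4,
                              n_points = 960L), class = "sasa_result")
  expect_error(select_exposed_tm_atoms(s, sasa_none, belt_options()),
               class = "detbelt_no_tm_atoms")
})

test_that("radial distances are the xy-plane norm", {
  atoms <- carbon_atoms(rbind(c(3, 4, 7), c(0, 0, -2), c(-20, 0, 3)))
  expect_equal(radial_distances(atoms), c(5, 0, 20))
})

test_that("identical distances give a degenerate point-mass profile", {
  prof <- density_estimate(rep(20, 500))
  expect_true(prof$degenerate)
  expect_equal(rightmost_peak(prof), 20.0)
})

test_that("the KDE integrates to one and finds a unimodal mode", {
  set.seed(1)
  x <- stats::rnorm(1000, 15, 1)
  prof <- density_estimate(x)
  integral <- sum(diff(prof$grid) * (head(prof$density, -1) + tail(prof$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 0.01)
  expect_true(all(diff(prof$grid) > 0))
  # dense-grid oracle on the same sample
  dense <- stats::density(x, bw = prof$bandwidth, n = 8192,
                          from = min(prof$grid), to = max(prof$grid))
  expect_equal(rightmost_peak(prof), dense$x[which.max(dense$y)], tolerance = 0.3)
  expect_equal(rightmost_peak(prof), 15, tolerance = 0.3)
})

test_that("the rightmost peak beats a taller left mode but respects the fraction guard", {
  set.seed(1)
  x <- c(stats::rnorm(300, 10, 0.5), stats::rnorm(200, 22, 0.5))
  prof <- density_estimate(x)
  # oracle: rightmost grid local maximum above 10% of the global max
  y <- prof$density
  lm <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf) & y >= 0.1 * max(y))
  expect_equal(rightmost_peak(prof), prof$grid[max(lm)])
  expect_equal(rightmost_peak(prof), 22, tolerance = 0.3)

  # right mode carrying ~2% of the samples falls below the 10% guard
  set.seed(2)
  x2 <- c(stats::rnorm(1000, 10, 0.5), stats::rnorm(8, 22, 0.3))
  prof2 <- density_estimate(x2, belt_options(kde_bandwidth = 0.5))
  expect_equal(rightmost_peak(prof2), 10, tolerance = 0.5)
  # with the guard disabled the stray mode wins: the guard is what protects us
  expect_equal(rightmost_peak(prof2, belt_options(kde_bandwidth = 0.5,
                                                  peak_min_fraction = 0)),
               22, tolerance = 0.5)
})

test_that("inner radius adds the vdW offset unless overridden", {
  expect_equal(inner_radius(20)$r, 21.66)
  expect_equal(inner_radius(0)$r, 1.66)
  expect_equal(inner_radius(20)$r_source, "computed")
  ov <- inner_radius(20, belt_options(inner_radius_override = 25))
  expect_equal(ov$r, 25)
  expect_equal(ov$r_source, "override")
})

test_that("outer radius conserves the hollow-cylinder volume", {
  expect_equal(outer_radius(0, 30, 10), 10)
  expect_equal(outer_radius(pi * 30 * 100, 30, 0), 10)
  R <- outer_radius(172000, 30, 20)
  expect_equal(R, sqrt(172000 / (pi * 30) + 400), tolerance = 1e-12)
  expect_equal(pi * 30 * (R^2 - 20^2), 172000, tolerance = 1e-9)
})

test_that("volume conservation holds over random geometry triples", {
  set.seed(3)
  for (k in 1:200) {
    h <- stats::runif(1, 10, 60)
    r <- stats::runif(1, 0, 50)
    V <- stats::runif(1, 0, 5e5)
    R <- outer_radius(V, h, r)
    expect_true(R >= r)
    expect_equal(pi * h * (R^2 - r^2), V, tolerance = 1e-6)
  }
})

test_that("mixture stacks tile the belt and conserve per-stack volumes", {
  vols <- data.frame(detergent_id = c("A", "B"), n_monomers = c(2L, 1L),
                     volume = c(2e5, 1e5))
  R <- outer_radius(3e5, 30, 20)
  s <- stack_mixture(30, 20, R, vols)
  expect_equal(s$z_lo, c(-15, 5))
  expect_equal(s$z_hi, c(5, 15))
  # per-stack hollow-cylinder volume equals its detergent's volume
  expect_equal(pi * (s$z_hi - s$z_lo) * (R^2 - 20^2), s$volume, tolerance = 1e-9)

  vols3 <- data.frame(detergent_id = c("A", "B", "C"), n_monomers = c(1L, 1L, 1L),
                      volume = rep(1e5, 3))
  R3 <- outer_radius(3e5, 30, 20)
  s3 <- stack_mixture(30, 20, R3, vols3)
  expect_equal(s3$z_hi - s3$z_lo, rep(10, 3))
  expect_equal(s3$z_lo[-1], s3$z_hi[-3])  # no gaps, no overlap
  expect_equal(range(c(s3$z_lo, s3$z_hi)), c(-15, 15))

  expect_error(stack_mixture(30, 20, 20, data.frame(detergent_id = "A",
                                                    n_monomers = 1L, volume = 0)),
               class = "detbelt_empty_belt")
})

test_that("build_belt recovers the ring geometry end to end", {
  db <- builtin_db()
  fx <- make_ring_fixture(fixture_params(ring_radius = 20, half_thickness = 15))
  opts <- belt_options(n_points = 480L)
  geom <- build_belt(fx$structure, belt_spec("DDM", 400), db, opts)
  vol_ddm <- detergent_lookup(db, "DDM")$monomer_volume_A3
  expect_equal(geom$h, 30)
  expect_equal(geom$r, geom$peak_radius + 1.66)
  expect_equal(geom$r, 21.66, tolerance = 0.05)
  expect_equal(geom$V_total, 400 * vol_ddm)
  expect_equal(geom$R, sqrt(geom$V_total / (pi * 30) + geom$r^2), tolerance = 1e-12)
  expect_equal(pi * geom$h * (geom$R^2 - geom$r^2), geom$V_total, tolerance = 1e-6)
})

test_that("the inner-radius override recomputes R but never the volume", {
  db <- builtin_db()
  fx <- make_ring_fixture(fixture_params())
  base <- build_belt(fx$structure, belt_spec("DDM", 400), db,
                     belt_options(n_points = 480L))
  over <- build_belt(fx$structure, belt_spec("DDM", 400), db,
                     belt_options(n_points = 480L, inner_radius_override = 25))
  expect_equal(over$r, 25)
  expect_equal(over$r_source, "override")
  expect_equal(over$V_total, base$V_total)
  expect_equal(pi * over$h * (over$R^2 - over$r^2),
               pi * base$h * (base$R^2 - base$r^2), tolerance = 1e-9)
  expect_gt(over$R, 25)
})

test_that("R grows strictly with monomer count and equals r at zero volume", {
  db <- builtin_db()
  fx <- make_ring_fixture(fixture_params())
  counts <- c(50, 200, 400, 800)
  Rs <- vapply(counts, function(n) {
    build_belt(fx$structure, belt_spec("DDM", n), db,
               belt_options(n_points = 480L))$R
  }, numeric(1))
  expect_true(all(diff(Rs) > 0))
  geom <- build_belt(fx$structure, belt_spec("DDM", 400), db,
                     belt_options(n_points = 480L))
  expect_equal(outer_radius(0, geom$h, geom$r), geom$r)
})

test_that("permuting mixture entries permutes stacks but not the metrics", {
  db <- builtin_db()
  fx <- make_ring_fixture(fixture_params())
  a <- build_belt(fx$structure, belt_spec(c("DDM", "CHOLATE"), c(300, 150)), db,
                  belt_options(n_points = 480L))
  b <- build_belt(fx$structure, belt_spec(c("CHOLATE", "DDM"), c(150, 300)), db,
                  belt_options(n_points = 480L))
  expect_equal(a$h, b$h)
  expect_equal(a$r, b$r)
  expect_equal(a$R, b$R)
  expect_equal(a$V_total, b$V_total)
  expect_equal(a$stacks$detergent_id, rev(b$stacks$detergent_id))
  expect_equal(sort(a$stacks$volume), sort(b$stacks$volume))
})

test_that("spec validation rejects zero and fractional monomer counts", {
  expect_error(belt_spec("DDM", 0), class = "detbelt_bad_spec")
  expect_error(belt_spec("DDM", 10.5), class = "detbelt_bad_spec")
  expect_error(belt_spec(character(0), integer(0)), class = "detbelt_bad_spec")
})

test_that("errors propagate with stage labels", {
  fx <- make_ring_fixture(fixture_params())
  s <- fx$structure
  s$half_thickness <- NA_real_
  err <- tryCatch(build_belt(s, belt_spec("DDM", 400), builtin_db()),
                  error = identity)
  expect_s3_class(err, "detbelt_no_thickness")
  expect_match(conditionMessage(err), "^\\[height\\]")
})
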