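# small helper frames ---------------------------------------------------------

one_sphere_frame <- function() polylobe:::sites_frame(5, 5, 5, diameter = 2,
                                                      box = 10)

test_that("dense sub-box extraction: filled box, corner cluster, two clusters", {
  # uniformly filled box -> the full box
  g <- expand.grid(x = seq(0.5, 7.5, 1), y = seq(0.5, 7.5, 1),
                   z = seq(0.5, 7.5, 1))
  full <- polylobe:::sites_frame(g$x, g$y, g$z, diameter = 1, box = 8)
  reg <- extract_dense_subbox(full, min_density = 0.05, coarse = 2)
  expect_equal(reg$origin, c(0, 0, 0))
  expect_equal(reg$extent, c(8, 8, 8))

  # one compact cluster in a corner -> region inside its (coarse-padded) bbox
  # (min_density near the cluster's own packing keeps growth local)
  cl <- expand.grid(x = seq(0.5, 3.5, 0.6), y = seq(0.5, 3.5, 0.6),
                    z = seq(0.5, 3.5, 0.6))
  corner <- polylobe:::sites_frame(cl$x, cl$y, cl$z, diameter = 1, box = 20)
  regc <- extract_dense_subbox(corner, min_density = 1, coarse = 2)
  expect_true(all(regc$origin + regc$extent <= 4 + 2 + 1e-9))

  # two equally dense clusters, one twice the extent: the region overlaps
  # the larger one (volume tie-break across equally dense seeds)
  big <- expand.grid(x = seq(10.5, 17.3, 0.6), y = seq(10.5, 17.3, 0.6),
                     z = seq(10.5, 17.3, 0.6))
  two <- polylobe:::sites_frame(c(cl$x, big$x), c(cl$y, big$y),
                                c(cl$z, big$z), diameter = 1, box = 20)
  regt <- extract_dense_subbox(two, min_density = 1, coarse = 2)
  lo <- pmax(regt$origin, 10)
  hi <- pmin(regt$origin + regt$extent, 18)
  expect_true(all(hi > lo))  # nonempty intersection with the larger cluster

  # nothing dense enough -> explicit failure
  sparse <- make_fixture("ideal_gas", n_particles = 3, box = 30, seed = 2)
  expect_error(extract_dense_subbox(sparse, min_density = 0.5),
               "empty selection")
})

test_that("distance field: arithmetic, brute-force oracle, empty region", {
  fr <- one_sphere_frame()
  reg <- polylobe:::box_region(c(1.25, 4.75, 4.75), c(8, 0.5, 0.5), 10)
  vg <- distance_field(reg, fr, spacing = 0.5)
  # voxel on the x-axis at distance 3 from the sphere centre -> 3 - 1 = 2
  xs <- reg$origin[1] + (seq_len(vg$dims[1]) - 0.5) * vg$spacing
  i <- which(abs(xs - 2) < 1e-9)
  expect_equal(vg$D[i, 1, 1], 2, tolerance = 1e-12)
  # inside the sphere -> clamped to zero
  j <- which(abs(xs - 4.5) < 1e-9)
  expect_identical(vg$D[j, 1, 1], 0)

  # random 20-sphere fixture vs direct minimum over spheres (minimum image)
  set.seed(31)
  fr20 <- polylobe:::sites_frame(runif(20, 0, 12), runif(20, 0, 12),
                                 runif(20, 0, 12),
                                 diameter = runif(20, 0.5, 2), box = 12)
  reg2 <- polylobe:::box_region(c(2, 3, 1), c(4, 3, 5), 12)
  vg2 <- distance_field(reg2, fr20, spacing = 0.5)
  s <- fr20$sites
  for (probe in list(c(1, 1, 1), c(3, 2, 5), c(8, 6, 10))) {
    v <- reg2$origin + (probe - 0.5) * 0.5
    dx <- polylobe:::min_image(s$x - v[1], 12)
    dy <- polylobe:::min_image(s$y - v[2], 12)
    dz <- polylobe:::min_image(s$z - v[3], 12)
    want <- max(0, min(sqrt(dx^2 + dy^2 + dz^2) - s$diameter / 2))
    expect_equal(vg2$D[probe[1], probe[2], probe[3]], want, tolerance = 1e-12)
  }

  empty <- polylobe:::new_frame(fr$sites[0, ], 10)
  vge <- distance_field(reg, empty)
  expect_true(vge$unbounded)
  expect_true(all(is.infinite(vge$D)))

  expect_error(distance_field(polylobe:::box_region(c(5, 5, 5), c(8, 1, 1),
                                                    10), fr),
               "within the frame")
})

test_that("spherical cavity yields a narrow PSD peak at its diameter", {
  cav <- make_fixture("cavity_box", cavity_diameter = 4)
  box <- cav$box_edge
  reg <- polylobe:::box_region(rep(box / 2 - 3.05, 3), rep(6.1, 3), box)
  psd <- pore_size_distribution(reg, cav, probe_radius = 0.5, spacing = 0.1)
  expect_equal(psd$mode, 4, tolerance = 0.1 / 4 + 1e-9)  # within one bin
  # narrow: at least 90% of accessible voxels within 2 bins of the mode
  near <- abs(psd$data$diameter - psd$mode) <= 0.2
  expect_gt(sum(psd$data$count[near]) / sum(psd$data$count), 0.9)
  # density integrates to one
  expect_equal(sum(psd$data$density) * 0.1, 1, tolerance = 1e-9)
})

test_that("slab void has modal pore diameter near its thickness", {
  slab <- make_fixture("slab_box", t = 2)
  reg <- polylobe:::box_region(c(1, 1, 1.6), c(6, 6, 2.8), slab$box_edge)
  psd <- pore_size_distribution(reg, slab, probe_radius = 0.5, spacing = 0.1)
  expect_equal(psd$mode, 2, tolerance = 0.1)  # 10%: walls are sphere-bumpy
})

test_that("probe larger than every void produces an empty distribution", {
  cav <- make_fixture("cavity_box", cavity_diameter = 4)
  reg <- polylobe:::box_region(rep(1, 3), rep(6, 3), cav$box_edge)
  psd <- pore_size_distribution(reg, cav, probe_radius = 3, spacing = 1)
  expect_identical(nrow(psd$data), 0L)
  expect_error(pore_size_distribution(reg, cav, probe_radius = 0.5,
                                      spacing = 0.4),
               "not resolved")
  expect_error(pore_size_distribution(polylobe:::box_region(rep(1, 3),
                                                            rep(0.5, 3),
                                                            cav$box_edge),
                                      cav, probe_radius = 0.5, spacing = 0.1),
               "degenerate")
})

test_that("accessible void volume is non-increasing in probe radius and PSD support is bounded", {
  cav <- make_fixture("cavity_box", cavity_diameter = 4)
  reg <- polylobe:::box_region(rep(cav$box_edge / 2 - 3.05, 3), rep(6.1, 3),
                               cav$box_edge)
  vg <- distance_field(reg, cav, spacing = 0.1)
  acc <- vapply(seq(0.2, 2.2, 0.2), function(p) mean(vg$D >= p), 0)
  expect_true(all(diff(acc) <= 0))

  psd <- pore_size_distribution(reg, cav)
  expect_true(all(psd$data$diameter[psd$data$count > 0] >= 2 * 0.5 - 0.05))
  expect_true(all(psd$data$diameter[psd$data$count > 0] <=
                    2 * max(vg$D) + 0.05))
})

test_that("halving the grid spacing moves the cavity mode by less than 5%", {
  cav <- make_fixture("cavity_box", cavity_diameter = 6)
  reg <- polylobe:::box_region(rep(cav$box_edge / 2 - 4.05, 3), rep(8.1, 3),
                               cav$box_edge)
  m1 <- pore_size_distribution(reg, cav, spacing = 0.2)$mode
  m2 <- pore_size_distribution(reg, cav, spacing = 0.1)$mode
  expect_lt(abs(m1 - m2) / m2, 0.05)
})

test_that("largest included sphere equals exhaustive brute force on a toy grid", {
  set.seed(41)
  fr <- polylobe:::sites_frame(runif(6, 0, 4), runif(6, 0, 4),
                               runif(6, 0, 4), diameter = runif(6, 0.8, 1.6),
                               box = 4)
  reg <- polylobe:::box_region(c(0, 0, 0), c(4, 4, 4), 4)
  vg <- distance_field(reg, fr, spacing = 0.25)   # 16^3 voxels
  probe <- 0.25
  exact_radii <- sort(unique(as.vector(vg$D)[as.vector(vg$D) >= probe]))
  prf <- polylobe:::pore_radius_field(vg, probe, radii = exact_radii)

  # oracle: pore_radius(v) = max{ D(c) : |v - c| <= D(c) } over all voxels c
  dims <- vg$dims
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]),
                                  y = seq_len(dims[2]),
                                  z = seq_len(dims[3]))) * 0.25
  D <- as.vector(vg$D)
  cand <- which(D >= probe)
  want <- numeric(length(D))
  for (ci in cand) {
    d2 <- rowSums(sweep(coords, 2, coords[ci, ])^2)
    inside <- d2 <= D[ci]^2 + 1e-12
    want[inside] <- pmax(want[inside], D[ci])
  }
  want[D < probe] <- 0  # inaccessible voxels excluded
  expect_equal(as.vector(prf$pore_radius), want, tolerance = 1e-12)
})
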