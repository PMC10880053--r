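test_that("RDF of a Poisson gas is flat within sampling bands", {
  frames <- lapply(1:10, function(s)
    make_fixture("ideal_gas", n_particles = 500, box = 20, seed = s))
  g <- rdf(frames, dr = 0.1)
  # bins with adequate sampling: observed counts within 3 sd (Poisson) of the
  # ideal-gas expectation, i.e. g within 1 +/- 3/sqrt(expected)
  expected <- g$data$count / pmax(g$data$g, 1e-300)
  ok <- expected >= 10
  expect_gt(sum(ok), 50)
  expect_true(all(abs(g$data$g[ok] - 1) <= 3 / sqrt(expected[ok])))
})

test_that("two fixed particles give a single RDF bin at their separation", {
  fr <- polylobe:::sites_frame(c(10, 15), c(10, 10), c(10, 10), diameter = 2,
                               box = 30)
  g <- rdf(fr, dr = 0.05)
  nz <- g$data[g$data$count > 0, ]
  expect_identical(nrow(nz), 1L)
  expect_true(nz$r - 0.025 <= 5 && 5 < nz$r + 0.025)
})

test_that("simple-cubic lattice RDF has its first peak at the spacing with coordination 6", {
  fr <- make_fixture("sc_lattice", n_side = 5, a = 3)
  g <- rdf(fr, dr = 0.05)
  first <- which(g$data$count > 0)[1]
  expect_lt(abs(g$data$r[first] - 3), 0.03)  # within half a bin of the spacing
  # coordination number = 2 * (pairs in first shell) / N
  shell <- g$data$count[g$data$r > 2.9 & g$data$r < 3.1]
  expect_identical(2 * sum(shell) / 125, 6)
})

test_that("RDF input validation", {
  expect_error(rdf(list()), "no frames")
  fr <- make_fixture("ideal_gas", n_particles = 10, box = 20, seed = 1)
  expect_error(rdf(fr, r_max = 15), "half the box")
})

test_that("lobe bonds follow the 3 sigma_ij cutoff and match brute force", {
  mk2 <- function(gap) polylobe:::new_frame(data.frame(
    particle = 1:2, site = 1L, kind = "L", diameter = 1,
    x = c(10, 10 + gap), y = 10, z = 10), 40)
  expect_identical(nrow(bonded_lobe_pairs(mk2(2.9))), 1L)
  expect_identical(nrow(bonded_lobe_pairs(mk2(3.1))), 0L)

  # random 100-lobe frame vs O(N^2) double loop
  fr <- with_seed_local(8, polylobe:::new_frame(data.frame(
    particle = rep(1:50, each = 2), site = rep(1:2, 50), kind = "L",
    diameter = runif(100, 0.5, 1.5),
    x = runif(100, 0, 12), y = runif(100, 0, 12), z = runif(100, 0, 12)),
    12))
  got <- bonded_lobe_pairs(fr)
  want <- brute_bonds(fr)
  expect_identical(nrow(got), nrow(want))
  got_m <- unname(as.matrix(got[order(got$lobe_a, got$lobe_b),
                                c("lobe_a", "lobe_b")]))
  want_m <- unname(want[order(want[, 1], want[, 2]), , drop = FALSE])
  expect_equal(got_m, want_m, ignore_attr = TRUE)
})

test_that("bond statistics: degrees, handshake, ring fixture and joint marginals", {
  # isolated bonded dimer: the two bonded lobes have degree 1, others 0
  fr <- make_fixture("dimer")
  bs <- bonds_per_lobe(fr)
  expect_identical(sort(bs$per_lobe$n_bonds), c(0L, 0L, 1L, 1L))

  # 5-ring: every lobe has exactly one partner
  r5 <- make_fixture("ring5")
  bs5 <- bonds_per_lobe(r5)
  expect_true(all(bs5$per_lobe$n_bonds == 1L))
  expect_identical(bs5$mean_bonds_per_lobe, 1)

  # handshake: degree sum = 2 x bonds
  st <- lattice_state(20, "TP", sigma_G = 0.4, seed = 13)
  frp <- as_frame(st)
  bsp <- bonds_per_lobe(frp)
  expect_identical(sum(bsp$per_lobe$n_bonds), 2L * bsp$n_bonds_total)

  # joint histogram marginals equal the univariate distributions
  joint <- bsp$joint
  expect_equal(as.numeric(colSums(joint)) / sum(joint), bsp$p_bonds)
  size_marginal <- as.numeric(rowSums(joint))
  size_hist <- as.numeric(table(cut(bsp$per_lobe$diameter, bsp$size_breaks,
                                    include.lowest = TRUE)))
  expect_identical(size_marginal, size_hist)

  # monodisperse: joint collapses to a single size bin
  bm <- bonds_per_lobe(as_frame(lattice_state(8, "DB", seed = 1)))
  expect_identical(sum(rowSums(bm$joint) > 0), 1L)
})

test_that("neighbor sets under bond and distance criteria", {
  fr <- make_fixture("dimer")
  nb <- neighbor_sets(fr)
  expect_identical(lengths(nb), c(`1` = 1L, `2` = 1L))

  gas <- make_fixture("ideal_gas", n_particles = 50, box = 30, seed = 4)
  expect_true(all(lengths(neighbor_sets(gas)) == 0))

  hex <- make_fixture("hex_sheet", nx = 6, ny = 6, a = 3)
  nbh <- neighbor_sets(hex, "distance", r_n = 1.1 * 3)
  expect_identical(max(lengths(nbh)), 6L)      # interior coordination
  expect_gt(sum(lengths(nbh) == 6), 0)
  expect_error(neighbor_sets(hex, "distance"), "r_n")
})

test_that("relative neighbor orientation on exact geometries", {
  tri <- make_fixture("collinear_trimer", a = 3)
  nb <- neighbor_sets(tri, "distance", r_n = 3.5)
  ang <- relative_neighbor_orientation(tri, nb)
  nz <- ang$data[ang$data$count > 0, ]
  expect_identical(nrow(nz), 1L)
  expect_gt(nz$theta, 178)
  expect_equal(sum(ang$data$p), 1, tolerance = 1e-12)

  eq <- make_fixture("triangle", a = 3)
  nbe <- neighbor_sets(eq, "distance", r_n = 3.5)
  ange <- relative_neighbor_orientation(eq, nbe)
  nze <- ange$data[ange$data$count > 0, ]
  expect_true(all(abs(nze$theta - 60) <= 2))
  expect_identical(sum(nze$count), 3L)

  hex <- make_fixture("hex_sheet", nx = 6, ny = 6, a = 3)
  nbh <- neighbor_sets(hex, "distance", r_n = 3.3)
  angh <- relative_neighbor_orientation(hex, nbh)
  nzh <- angh$data[angh$data$count > 0, ]
  expect_true(all(vapply(nzh$theta, function(th)
    any(abs(th - c(60, 120, 180)) <= 2), TRUE)))
  expect_true(all(angh$data$theta >= 0 & angh$data$theta <= 180))
  expect_equal(sum(angh$data$p), 1, tolerance = 1e-12)

  # two-nearest-only mode restricts each particle to one angle
  ang2 <- relative_neighbor_orientation(hex, nbh, two_nearest_only = TRUE)
  expect_identical(ang2$n_angles,
                   sum(lengths(nbh) >= 2))
})

test_that("cluster labels: singletons, chain, and union-find oracle", {
  gas <- make_fixture("ideal_gas", n_particles = 40, box = 30, seed = 6)
  cg <- cluster_labels(gas)
  expect_identical(cg$labels, 1:40)
  expect_true(all(cg$sizes == 1L))

  # bonded chain of 10 dumbbells along x
  L <- 3.2
  chain <- polylobe:::new_frame(do.call(rbind, lapply(1:10, function(i)
    data.frame(particle = i, site = 1:3, kind = c("S", "L", "L"),
               diameter = c(2, 1, 1),
               x = 5 + (i - 1) * L + c(0, 1, -1), y = 20, z = 20))), 60)
  cc <- cluster_labels(chain)
  expect_identical(cc$n_clusters, 1L)
  expect_identical(cc$sizes, 10L)

  # random bond graph on 50 particles vs brute-force union-find
  fr <- with_seed_local(17, polylobe:::new_frame(data.frame(
    particle = rep(1:50, each = 2), site = rep(1:2, 50), kind = "L",
    diameter = 1,
    x = runif(100, 0, 25), y = runif(100, 0, 25), z = runif(100, 0, 25)),
    25))
  got <- cluster_labels(fr)
  b <- bonded_lobe_pairs(fr)
  want <- union_find_labels(50, cbind(b$particle_a, b$particle_b))
  expect_identical(got$labels, want)
})

test_that("pairwise metrics are invariant under rigid periodic translation", {
  st <- lattice_state(27, "DB", sigma_G = 0.3, seed = 21)
  fr <- as_frame(st)
  fr2 <- translate_frame(fr, c(7.3, -2.1, 11.8))
  expect_equal(rdf(fr)$data$g, rdf(fr2)$data$g)
  expect_identical(bonds_per_lobe(fr)$per_lobe$n_bonds,
                   bonds_per_lobe(fr2)$per_lobe$n_bonds)
  a1 <- relative_neighbor_orientation(fr)
  a2 <- relative_neighbor_orientation(fr2)
  expect_equal(a1$data$p, a2$data$p)
  expect_identical(cluster_labels(fr)$labels, cluster_labels(fr2)$labels)
})

test_that("metric CSV export carries the JSON convention header", {
  g <- rdf(make_fixture("sc_lattice"))
  f <- tempfile(fileext = ".csv")
  write_metric_csv(g, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# \\{")
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  expect_equal(meta$dr, 0.05)
  tab <- read.csv(f, comment.char = "#")
  expect_equal(tab$g, g$data$g)
})
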