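# coerce trajectory / state / single frame into a list of frames
as_frame_list <- function(frames) {
  if (inherits(frames, "md_trajectory")) return(frames$frames)
  if (inherits(frames, "system_state")) return(list(as_frame(frames)))
  if (inherits(frames, "md_frame")) return(list(frames))
  stopifnot(is.list(frames), all(vapply(frames, inherits, TRUE, "md_frame")))
  frames
}

# minimum-image pair distances among rows of an n x 3 matrix (n small enough
# for the dense O(n^2) formulation used at analysis scale)
pair_distances <- function(xyz, box) {
  n <- nrow(xyz)
  if (n < 2) return(numeric(0))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- min_image(xyz[idx[, 1], 1] - xyz[idx[, 2], 1], box)
  dy <- min_image(xyz[idx[, 1], 2] - xyz[idx[, 2], 2], box)
  dz <- min_image(xyz[idx[, 1], 3] - xyz[idx[, 2], 3], box)
  sqrt(dx^2 + dy^2 + dz^2)
}

seed_centers <- function(frame) {
  s <- frame$sites[frame$sites$kind == "S", ]
  s <- s[order(s$particle), ]
  as.matrix(s[, c("x", "y", "z")])
}

#' Radial distribution function of particle centres
#'
#' Histograms the minimum-image distances between seed (particle) centres
#' and normalizes each bin by the ideal-gas expectation
#' \eqn{\frac{N}{2}\,\rho\,\frac{4\pi}{3}[(r+\Delta r)^3 - r^3]},
#' averaged over frames.
#'
#' @param frames A frame, list of frames, `system_state` or
#'   `md_trajectory`.
#' @param dr Bin width; default 0.05 (reduced length).
#' @param r_max Histogram range; default (and maximum) half the box edge.
#' @return Object of class `rdf_result`: data frame `data` with columns
#'   `r` (bin centres) and `g`, plus normalization metadata.
#' @export
rdf <- function(frames, dr = 0.05, r_max = NULL) {
  frames <- as_frame_list(frames)
  if (length(frames) == 0) stop("no frames: cannot compute an RDF")
  box <- frames[[1]]$box_edge
  r_max <- r_max %||% (box / 2)
  if (r_max > box / 2 + 1e-9)
    stop("r_max must not exceed half the box edge (minimum image)")
  breaks <- seq(0, r_max, by = dr)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  counts <- numeric(length(breaks) - 1)
  N <- nrow(seed_centers(frames[[1]]))
  for (f in frames) {
    d <- pair_distances(seed_centers(f), f$box_edge)
    counts <- counts + tabulate(findInterval(d[d < r_max], breaks),
                                nbins = length(breaks) - 1)
  }
  rho <- N / box^3
  shell <- (4 * pi / 3) * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  expected <- (N / 2) * rho * shell * length(frames)
  g <- counts / expected
  structure(list(data = data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                                   g = g, count = counts),
                 dr = dr, r_max = r_max, n_frames = length(frames),
                 rho = rho, n_particles = N),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  pk <- x$data[which.max(x$data$g), ]
  cat(sprintf("g(r): %d bins (dr = %g) over %d frame(s); max g = %.3g at r = %.3g\n",
              nrow(x$data), x$dr, x$n_frames, pk$g, pk$r))
  invisible(x)
}

#' Inter-particle lobe-lobe bonds
#'
#' Two lobes on different particles are bonded when their separation is
#' below that pair's attractive-LJ cutoff \eqn{3\sigma_{ij}}.  The
#' relation is symmetric and excludes intra-particle pairs.
#'
#' @param frame An `md_frame` (or `system_state`).
#' @param table Optional interaction table; only its cutoff convention
#'   (always \eqn{3\sigma_{ij}}) is relevant, so it may be omitted.
#' @param rcut_factor Cutoff multiple of \eqn{\sigma_{ij}}; default 3.
#' @return Data frame of bonds with site row indices (`site_a`, `site_b`
#'   into `frame$sites`), particles, lobe diameters and separations.
#' @export
bonded_lobe_pairs <- function(frame, table = NULL, rcut_factor = 3) {
  frame <- as_frame_list(frame)[[1]]
  lob <- frame$sites[frame$sites$kind == "L", ]
  rownames(lob) <- NULL
  n <- nrow(lob)
  empty <- data.frame(lobe_a = integer(0), lobe_b = integer(0),
                      particle_a = integer(0), particle_b = integer(0),
                      diameter_a = numeric(0), diameter_b = numeric(0),
                      r = numeric(0))
  if (n < 2) return(empty)
  box <- frame$box_edge
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- lob$particle[idx[, 1]] != lob$particle[idx[, 2]]
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0) return(empty)
  dx <- min_image(lob$x[idx[, 1]] - lob$x[idx[, 2]], box)
  dy <- min_image(lob$y[idx[, 1]] - lob$y[idx[, 2]], box)
  dz <- min_image(lob$z[idx[, 1]] - lob$z[idx[, 2]], box)
  r <- sqrt(dx^2 + dy^2 + dz^2)
  sij <- (lob$diameter[idx[, 1]] + lob$diameter[idx[, 2]]) / 2
  b <- which(r < rcut_factor * sij)
  data.frame(lobe_a = idx[b, 1], lobe_b = idx[b, 2],
             particle_a = lob$particle[idx[b, 1]],
             particle_b = lob$particle[idx[b, 2]],
             diameter_a = lob$diameter[idx[b, 1]],
             diameter_b = lob$diameter[idx[b, 2]],
             r = r[b])
}

#' Per-lobe bond statistics
#'
#' Degree of every lobe in the bond network of [bonded_lobe_pairs()],
#' their average, the bond-count distribution P(n), and the joint
#' histogram over (lobe-diameter bin, bond count).
#'
#' @param frame An `md_frame` (or `system_state`).
#' @param table Optional interaction table, see [bonded_lobe_pairs()].
#' @param size_breaks Lobe-diameter bin edges; default width 0.1 covering
#'   the realized diameter range.
#' @param rcut_factor Bond cutoff multiple, default 3.
#' @return Object of class `bond_stats`: `per_lobe` data frame (one row
#'   per lobe: particle, diameter, n_bonds), `mean_bonds_per_lobe`,
#'   `p_bonds` (P(n) summing to 1) and `joint` (size bin x bond count
#'   matrix of lobe counts).
#' @export
bonds_per_lobe <- function(frame, table = NULL, size_breaks = NULL,
                           rcut_factor = 3) {
  frame <- as_frame_list(frame)[[1]]
  lob <- frame$sites[frame$sites$kind == "L", ]
  rownames(lob) <- NULL
  bonds <- bonded_lobe_pairs(frame, table, rcut_factor)
  deg <- integer(nrow(lob))
  if (nrow(bonds) > 0) {
    t1 <- tabulate(bonds$lobe_a, nbins = nrow(lob))
    t2 <- tabulate(bonds$lobe_b, nbins = nrow(lob))
    deg <- as.integer(t1 + t2)
  }
  per_lobe <- data.frame(particle = lob$particle, diameter = lob$diameter,
                         n_bonds = as.integer(deg))
  if (is.null(size_breaks)) {
    lo <- floor(min(lob$diameter) * 10) / 10
    hi <- ceiling(max(lob$diameter) * 10) / 10
    if (hi <= lo) hi <- lo + 0.1
    size_breaks <- seq(lo, hi, by = 0.1)
  }
  sbin <- cut(per_lobe$diameter, size_breaks, include.lowest = TRUE)
  joint <- table(size_bin = sbin,
                 n_bonds = factor(per_lobe$n_bonds,
                                  levels = 0:max(per_lobe$n_bonds)))
  pn <- table(factor(per_lobe$n_bonds, levels = 0:max(per_lobe$n_bonds)))
  structure(list(per_lobe = per_lobe,
                 mean_bonds_per_lobe = mean(per_lobe$n_bonds),
                 p_bonds = as.numeric(pn) / sum(pn),
                 n_bonds_levels = as.integer(names(pn)),
                 joint = joint, size_breaks = size_breaks,
                 n_bonds_total = nrow(bonds)),
            class = "bond_stats")
}

#' @export
print.bond_stats <- function(x, ...) {
  cat(sprintf("bond stats: %d lobes, %d bonds, mean bonds per lobe = %.3f\n",
              nrow(x$per_lobe), x$n_bonds_total, x$mean_bonds_per_lobe))
  invisible(x)
}

#' Per-particle neighbor sets
#'
#' Default criterion: particles i and j are neighbors when they share at
#' least one lobe-lobe bond.  The alternative distance criterion uses a
#' centre-centre cutoff `r_n` (useful in gas phases with no bonds).
#'
#' @param frame An `md_frame` (or `system_state`).
#' @param criterion `"bond"` (default) or `"distance"`.
#' @param r_n Centre distance cutoff for `criterion = "distance"`.
#' @param table Optional interaction table for the bond criterion.
#' @return List (length = number of particles) of integer neighbor
#'   vectors.
#' @export
neighbor_sets <- function(frame, criterion = c("bond", "distance"),
                          r_n = NULL, table = NULL) {
  criterion <- match.arg(criterion)
  frame <- as_frame_list(frame)[[1]]
  parts <- sort(unique(frame$sites$particle))
  nb <- setNames(vector("list", length(parts)), parts)
  for (i in seq_along(nb)) nb[[i]] <- integer(0)
  if (criterion == "bond") {
    bonds <- bonded_lobe_pairs(frame, table)
    for (k in seq_len(nrow(bonds))) {
      a <- as.character(bonds$particle_a[k]); b <- as.character(bonds$particle_b[k])
      nb[[a]] <- union(nb[[a]], bonds$particle_b[k])
      nb[[b]] <- union(nb[[b]], bonds$particle_a[k])
    }
  } else {
    if (is.null(r_n)) stop("distance criterion needs r_n")
    ctr <- seed_centers(frame)
    box <- frame$box_edge
    for (i in seq_along(parts)) {
      dx <- min_image(ctr[, 1] - ctr[i, 1], box)
      dy <- min_image(ctr[, 2] - ctr[i, 2], box)
      dz <- min_image(ctr[, 3] - ctr[i, 3], box)
      r <- sqrt(dx^2 + dy^2 + dz^2)
      nb[[i]] <- parts[r < r_n & parts != parts[i]]
    }
  }
  nb
}

#' Relative neighbor orientation distribution P(theta_jik)
#'
#' For every particle i and every unordered pair \{j, k\} of its
#' neighbors, the angle between the minimum-image displacement vectors
#' \eqn{r_{ij}} and \eqn{r_{ik}} enters the histogram.  Angles are in
#' degrees on \eqn{[0, 180]}; the probabilities sum to 1 (discrete
#' convention, recorded in the metadata).  With `two_nearest_only = TRUE`
#' only each particle's two nearest neighbors contribute a single angle.
#' Particles with fewer than two neighbors contribute nothing.
#'
#' @param frame An `md_frame` (or `system_state`).
#' @param neighbors Optional precomputed [neighbor_sets()]; default
#'   bond-criterion sets.
#' @param bin_width Histogram bin width in degrees, default 2.
#' @param two_nearest_only Restrict each particle to its two nearest
#'   neighbors (by centre distance)?
#' @return Object of class `angle_distribution`: data frame `data`
#'   (`theta` bin centres, `p`, `count`) plus metadata.
#' @export
relative_neighbor_orientation <- function(frame, neighbors = NULL,
                                          bin_width = 2,
                                          two_nearest_only = FALSE) {
  frame <- as_frame_list(frame)[[1]]
  neighbors <- neighbors %||% neighbor_sets(frame)
  ctr <- seed_centers(frame)
  parts <- sort(unique(frame$sites$particle))
  box <- frame$box_edge
  angles <- numeric(0)
  for (ii in seq_along(parts)) {
    nbs <- match(neighbors[[ii]], parts)
    if (length(nbs) < 2) next
    disp <- cbind(min_image(ctr[nbs, 1] - ctr[ii, 1], box),
                  min_image(ctr[nbs, 2] - ctr[ii, 2], box),
                  min_image(ctr[nbs, 3] - ctr[ii, 3], box))
    if (two_nearest_only) {
      ord <- order(sqrt(rowSums(disp^2)))[1:2]
      disp <- disp[ord, , drop = FALSE]
    }
    u <- disp / sqrt(rowSums(disp^2))
    np <- nrow(u)
    for (a in seq_len(np - 1)) for (b in (a + 1):np) {
      cth <- sum(u[a, ] * u[b, ])
      angles <- c(angles, acos(pmin(1, pmax(-1, cth))) * 180 / pi)
    }
  }
  breaks <- seq(0, 180, by = bin_width)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  counts <- tabulate(findInterval(angles, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  p <- if (sum(counts) > 0) counts / sum(counts) else counts * 0
  structure(list(data = data.frame(theta = (breaks[-1] + breaks[-length(breaks)]) / 2,
                                   p = p, count = counts),
                 bin_width = bin_width, n_angles = length(angles),
                 normalization = "sum(P) = 1 (discrete)",
                 criterion = if (two_nearest_only) "two nearest" else
                   "all neighbor pairs"),
            class = "angle_distribution")
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat(sprintf("P(theta_jik): %d angles in %g-degree bins (%s)\n",
              x$n_angles, x$bin_width, x$criterion))
  invisible(x)
}

#' Bond-network cluster labels
#'
#' Connected components of the particle graph whose edges are lobe-lobe
#' bonds.  Labels are deterministic: each component is labelled by its
#' smallest member particle index, and label ids are renumbered 1, 2, ...
#' in order of that smallest member.
#'
#' @param frame An `md_frame` (or `system_state`).
#' @param table Optional interaction table.
#' @return Object of class `cluster_result`: integer vector `labels`
#'   (per particle), `sizes` (per cluster, ordered by label) and
#'   `largest_fraction` (largest cluster size / N).
#' @export
cluster_labels <- function(frame, table = NULL) {
  frame <- as_frame_list(frame)[[1]]
  parts <- sort(unique(frame$sites$particle))
  N <- length(parts)
  bonds <- bonded_lobe_pairs(frame, table)
  g <- igraph::make_empty_graph(n = N, directed = FALSE)
  if (nrow(bonds) > 0) {
    e <- rbind(match(bonds$particle_a, parts), match(bonds$particle_b, parts))
    g <- igraph::add_edges(g, as.vector(e))
  }
  comp <- igraph::components(g)
  memb <- comp$membership
  # deterministic relabeling by smallest member index
  first <- vapply(seq_len(comp$no), function(c) min(which(memb == c)), 0L)
  new_id <- integer(comp$no)
  new_id[order(first)] <- seq_len(comp$no)
  labels <- new_id[memb]
  sizes <- as.integer(table(factor(labels, levels = seq_len(comp$no))))
  structure(list(labels = as.integer(labels), sizes = sizes,
                 largest_fraction = max(sizes) / N,
                 n_clusters = as.integer(comp$no)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("%d clusters; largest holds %.1f%% of particles\n",
              x$n_clusters, 100 * x$largest_fraction))
  invisible(x)
}

#' Write a binned metric to CSV with a JSON metadata header
#'
#' The conventions (bin widths, normalization, frame counts) are written
#' as a `# `-prefixed JSON line followed by a regular CSV table.
#'
#' @param x An `rdf_result`, `angle_distribution` or `psd_result`.
#' @param path Output file.
#' @export
write_metric_csv <- function(x, path) {
  meta <- x[setdiff(names(x), "data")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA)), con)
  write.csv(x$data, con, row.names = FALSE)
  invisible(path)
}
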