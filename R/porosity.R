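#' Extract the densest axis-aligned sub-box of a frame
#'
#' Lays a coarse density grid over the box, seeds at the densest cell and
#' greedily grows one face at a time, always taking the expansion that
#' keeps the local site volume fraction highest; growth stops when no
#' expansion keeps the density at or above `min_density`.  Ties are broken
#' toward larger volume, then lexicographically smaller origin.  The
#' density is the physical packing fraction (sphere volumes
#' \eqn{(\pi/6) d^3} over region volume, no overlap correction).
#'
#' @param frame An `md_frame` (or `system_state`).
#' @param min_density Minimum site volume fraction of the region,
#'   default 0.05.
#' @param coarse Coarse cell edge, default 2 (one seed diameter).
#' @return Object of class `box_region`: `origin`, `extent` (lengths),
#'   `box_edge`, `density`.
#' @export
extract_dense_subbox <- function(frame, min_density = 0.05, coarse = 2) {
  frame <- as_frame_list(frame)[[1]]
  box <- frame$box_edge
  nc <- max(1L, floor(box / coarse))
  h <- box / nc
  s <- frame$sites
  # physical sphere volumes (pi/6) d^3: the density here is a real local
  # packing fraction, unlike the box-sizing rule's (4 pi/3) s^3 convention
  vol <- (pi / 6) * s$diameter^3

  cell_of <- function(x) pmin(floor((x %% box) / h), nc - 1)
  ci <- cell_of(s$x); cj <- cell_of(s$y); ck <- cell_of(s$z)

  region_density <- function(o, e) {
    # o: origin cell indices (0-based), e: extent in cells; non-wrapping
    inside <- ci >= o[1] & ci < o[1] + e[1] &
              cj >= o[2] & cj < o[2] + e[2] &
              ck >= o[3] & ck < o[3] + e[3]
    sum(vol[inside]) / (prod(e) * h^3)
  }

  dens <- array(0, c(nc, nc, nc))
  key <- cbind(ci + 1, cj + 1, ck + 1)
  for (r in seq_len(nrow(key)))
    dens[key[r, 1], key[r, 2], key[r, 3]] <-
      dens[key[r, 1], key[r, 2], key[r, 3]] + vol[r]
  dens <- dens / h^3
  if (max(dens) < min_density)
    stop("empty selection: no coarse cell reaches min_density = ", min_density)

  grow_from <- function(seed_cell) {
    o <- seed_cell
    e <- c(1, 1, 1)
    repeat {
      cand <- list()
      for (axis in 1:3) {
        if (o[axis] + e[axis] < nc) { # grow high face
          e2 <- e; e2[axis] <- e[axis] + 1
          cand[[length(cand) + 1]] <- list(o = o, e = e2)
        }
        if (o[axis] > 0) {            # grow low face
          o2 <- o; o2[axis] <- o[axis] - 1
          e2 <- e; e2[axis] <- e[axis] + 1
          cand[[length(cand) + 1]] <- list(o = o2, e = e2)
        }
      }
      if (length(cand) == 0) break
      d <- vapply(cand, function(cd) region_density(cd$o, cd$e), 0)
      ok <- d >= min_density
      if (!any(ok)) break
      score <- order(-ok, -d,
                     vapply(cand, function(cd) cd$o[1], 0),
                     vapply(cand, function(cd) cd$o[2], 0),
                     vapply(cand, function(cd) cd$o[3], 0))[1]
      o <- cand[[score]]$o
      e <- cand[[score]]$e
    }
    list(o = o, e = e, vol = prod(e))
  }

  # grow from every cell tied for the maximum density (bounded count);
  # keep the largest region, ties broken by lexicographically smaller origin
  seeds <- which(dens >= max(dens) - 1e-9, arr.ind = TRUE)
  seeds <- seeds[order(seeds[, 1], seeds[, 2], seeds[, 3]), , drop = FALSE]
  seeds <- seeds[seq_len(min(nrow(seeds), 64L)), , drop = FALSE]
  regions <- lapply(seq_len(nrow(seeds)), function(k)
    grow_from(as.numeric(seeds[k, ]) - 1))
  vols <- vapply(regions, `[[`, 0, "vol")
  origins <- t(vapply(regions, `[[`, numeric(3), "o"))
  pick <- order(-vols, origins[, 1], origins[, 2], origins[, 3])[1]
  o <- regions[[pick]]$o
  e <- regions[[pick]]$e

  structure(list(origin = o * h, extent = e * h, box_edge = box,
                 density = region_density(o, e)),
            class = "box_region")
}

#' @export
print.box_region <- function(x, ...) {
  cat(sprintf("region: origin (%s), extent (%s), site density %.3f\n",
              paste(signif(x$origin, 4), collapse = ", "),
              paste(signif(x$extent, 4), collapse = ", "), x$density))
  invisible(x)
}

# explicit region constructor (used by fixtures/tests)
box_region <- function(origin, extent, box_edge) {
  structure(list(origin = origin, extent = extent, box_edge = box_edge,
                 density = NA_real_), class = "box_region")
}

#' Distance-to-nearest-site-surface field on a voxel grid
#'
#' For every voxel centre in the region, the Euclidean distance to the
#' nearest site surface (site radius = diameter / 2), under the full box's
#' cubic minimum image; clamped at 0 inside any site.  An empty frame
#' yields an unbounded field (all `Inf`) flagged in the result.
#'
#' @param region A `box_region`.
#' @param frame The `md_frame` providing the sites.
#' @param spacing Voxel edge, default 0.1 (reduced length).
#' @return Object of class `voxel_grid`: 3-D array `D`, `spacing`,
#'   `origin`, `dims`, logical `unbounded`.
#' @export
distance_field <- function(region, frame, spacing = 0.1) {
  frame <- as_frame_list(frame)[[1]]
  if (any(region$origin < 0 | region$origin + region$extent >
          region$box_edge + 1e-9))
    stop("region must lie within the frame's box")
  dims <- pmax(1L, as.integer(round(region$extent / spacing)))
  gx <- region$origin[1] + (seq_len(dims[1]) - 0.5) * spacing
  gy <- region$origin[2] + (seq_len(dims[2]) - 0.5) * spacing
  gz <- region$origin[3] + (seq_len(dims[3]) - 0.5) * spacing
  gg <- expand.grid(x = gx, y = gy, z = gz)
  s <- frame$sites
  if (nrow(s) == 0) {
    D <- array(Inf, dims)
    return(structure(list(D = D, spacing = spacing, origin = region$origin,
                          dims = dims, unbounded = TRUE),
                     class = "voxel_grid"))
  }
  Dv <- cpp_site_distance_field(gg$x, gg$y, gg$z,
                                as.matrix(s[, c("x", "y", "z")]),
                                s$diameter / 2, frame$box_edge, TRUE)
  structure(list(D = array(Dv, dims), spacing = spacing,
                 origin = region$origin, dims = dims, unbounded = FALSE),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel grid %s at spacing %g; void fraction %.3f\n",
              paste(x$dims, collapse = " x "), x$spacing,
              mean(x$D > 0)))
  invisible(x)
}

# largest-covering-sphere radius per voxel via per-radius morphological
# opening: erosion is a threshold of the surface-distance field, dilation a
# Euclidean distance transform of the eroded set.
pore_radius_field <- function(grid, probe_radius, radii = NULL) {
  D <- grid$D
  h <- grid$spacing
  dmax <- max(D)
  if (is.null(radii)) {
    cand <- sort(unique(as.vector(D[D >= probe_radius])))
    radii <- if (length(cand) <= 512) cand else
      unique(c(seq(probe_radius, dmax, by = h / 2), dmax))
  }
  radii <- sort(radii[radii >= probe_radius & radii <= dmax + 1e-12])
  pr <- array(0, dim(D))
  accessible <- D >= probe_radius
  for (r in radii) {
    centers <- D >= r
    if (!any(centers)) next
    Tsq <- cpp_edt_sq(as.vector(centers), as.integer(dim(D)))
    covered <- sqrt(Tsq) * h <= r + 1e-9
    upd <- covered & accessible
    pr[upd] <- pmax(pr[upd], r)
  }
  list(pore_radius = pr, accessible = accessible, radii = radii)
}

#' Pore size distribution (largest included sphere)
#'
#' For every void voxel accessible to a probe of radius `probe_radius`
#' (surface distance at least the probe radius), finds the diameter of the
#' largest sphere that fits entirely in void space and contains that
#' voxel, and histograms these diameters over voxels into a probability
#' density.  Implemented as per-radius morphological openings of the void
#' space (erosion = threshold of the surface-distance field; dilation = a
#' Euclidean distance transform), which evaluates the covering-sphere
#' criterion exactly on the voxel grid.
#'
#' @param region A `box_region` (e.g. from [extract_dense_subbox()]).
#' @param frame The `md_frame` with the sites.
#' @param probe_radius Probe radius; the standard convention is half the mean
#'   lobe diameter, 0.5.
#' @param spacing Voxel edge; must be at most `probe_radius / 2`
#'   (default 0.1).
#' @param radii Optional explicit set of candidate sphere radii; default
#'   the exact set of distinct field values when small, else a grid at
#'   `spacing / 2` resolution.
#' @param bin_width Diameter histogram bin width, default `spacing`.
#' @return Object of class `psd_result`: data frame `data` with
#'   `diameter` (bin centres, units of the mean lobe diameter), `density`
#'   (integrating to 1) and `count`; zero rows when no voxel is
#'   accessible.  Metadata: probe radius, spacing, region, modal
#'   diameter.
#' @export
pore_size_distribution <- function(region, frame, probe_radius = 0.5,
                                   spacing = 0.1, radii = NULL,
                                   bin_width = spacing) {
  stopifnot(probe_radius > 0)
  if (spacing > probe_radius / 2 + 1e-12)
    stop("grid not resolved: spacing must be at most probe_radius / 2")
  if (any(region$extent < 2 * probe_radius))
    stop("degenerate region: smaller than one probe diameter along an axis")
  grid <- distance_field(region, frame, spacing)
  prf <- pore_radius_field(grid, probe_radius, radii)
  dia <- 2 * prf$pore_radius[prf$accessible]
  dia <- dia[dia > 0]
  if (length(dia) == 0) {
    dat <- data.frame(diameter = numeric(0), density = numeric(0),
                      count = integer(0))
    return(structure(list(data = dat, probe_radius = probe_radius,
                          spacing = spacing, region = unclass(region),
                          mode = NA_real_, n_voxels = 0),
                     class = "psd_result"))
  }
  breaks <- seq(2 * probe_radius - bin_width / 2, max(dia) + bin_width,
                by = bin_width)
  counts <- tabulate(findInterval(dia, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  dens <- counts / (sum(counts) * bin_width)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  structure(list(data = data.frame(diameter = centers, density = dens,
                                   count = counts),
                 probe_radius = probe_radius, spacing = spacing,
                 region = unclass(region),
                 mode = centers[which.max(counts)], n_voxels = length(dia)),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  if (nrow(x$data) == 0)
    cat("pore size distribution: empty (no voxel accessible to the probe)\n")
  else
    cat(sprintf("pore size distribution over %d voxels; modal diameter %.3g (probe radius %g)\n",
                x$n_voxels, x$mode, x$probe_radius))
  invisible(x)
}
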