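# sphere "volume" convention used by the box-sizing rule: (4*pi/3) s^3 with s
# the stated size parameter.  Only this convention reproduces the reference
# box edges 75/78/80 for N = 1000 at phi = 0.1.
size_volume <- function(s) (4 * pi / 3) * s^3

#' Cubic box edge from the volume-fraction rule
#'
#' The simulation domain is the cube of volume
#' \eqn{V_0 = N (V_S + N_L V_L) / \phi}, with \eqn{V_S} and \eqn{V_L} the
#' sphere volumes of the seed and the *nominal* (mean-diameter) lobe, so
#' that all systems at the same \eqn{\phi} have comparable domains
#' regardless of polydispersity.  With `snap = TRUE` the edge is rounded up
#' to an integer, the rule that reproduces the reference edges 75 (DB),
#' 78 (TP) and 80 (TH) for N = 1000, \eqn{\phi} = 0.1, \eqn{\sigma_S} = 2,
#' \eqn{\sigma_L} = 1.
#'
#' @param n_particles Number of particles.
#' @param shape `"DB"`, `"TP"` or `"TH"`.
#' @param phi Target volume fraction, in (0, 1).
#' @param sigma_S,sigma_L Seed and nominal lobe size parameters.
#' @param snap Round the edge up to an integer? Default `TRUE`.
#' @return Box edge length (reduced units).
#' @examples
#' compute_box_edge(1000, "DB", 0.1)  # 75
#' @export
compute_box_edge <- function(n_particles, shape, phi, sigma_S = 2,
                             sigma_L = 1, snap = TRUE) {
  stopifnot(n_particles >= 1)
  if (!is.numeric(phi) || phi <= 0 || phi >= 1)
    stop("volume fraction phi must lie in (0, 1), got ", phi)
  nl <- n_lobes(shape)
  V0 <- n_particles * (size_volume(sigma_S) + nl * size_volume(sigma_L)) / phi
  edge <- V0^(1 / 3)
  if (snap) ceiling(edge) else edge
}

#' Full system specification
#'
#' @param n_particles Number of lobed particles.
#' @param shape `"DB"`, `"TP"` or `"TH"`.
#' @param phi Volume fraction; default 0.1.
#' @param T_star Reduced temperature.
#' @param poly A [poly_spec()].
#' @param rng_seed Integer seed controlling blueprint sampling and initial
#'   placement.
#' @param sigma_S Seed diameter, default 2.
#' @param box_edge Optional override of the box edge; by default computed
#'   from [compute_box_edge()] with integer snapping.
#' @param snap Passed to [compute_box_edge()] when `box_edge` is `NULL`.
#' @return Object of class `system_spec`.
#' @export
system_spec <- function(n_particles, shape, phi = 0.1, T_star = 1,
                        poly = poly_spec(), rng_seed = 1, sigma_S = 2,
                        box_edge = NULL, snap = TRUE) {
  shape <- match.arg(shape, c("DB", "TP", "TH"))
  stopifnot(n_particles >= 1, T_star > 0)
  if (is.null(box_edge))
    box_edge <- compute_box_edge(n_particles, shape, phi, sigma_S,
                                 poly$mu_G, snap = snap)
  if (box_edge < 2 * max(sigma_S, poly$upper))
    stop("box edge ", box_edge, " smaller than twice the largest site diameter")
  structure(list(n_particles = n_particles, shape = shape, phi = phi,
                 T_star = T_star, poly = poly, rng_seed = rng_seed,
                 sigma_S = sigma_S, box_edge = box_edge),
            class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf("%d %s particles, phi = %g, T* = %g, sigma_G = %g, box %g\n",
              x$n_particles, x$shape, x$phi, x$T_star, x$poly$sigma_G,
              x$box_edge))
  invisible(x)
}

# --- quaternion helpers (scalar-first) --------------------------------------

quat_rotate <- function(q, v) {
  # rotate rows of v (n x 3) by unit quaternion q
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  v %*% t(R)
}

random_quaternion <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

# --- system state ------------------------------------------------------------

new_system_state <- function(centers, quats, vels, angmom, blueprints,
                             box_edge, spec = NULL) {
  stopifnot(nrow(centers) == length(blueprints),
            all(abs(sqrt(rowSums(quats^2)) - 1) < 1e-9),
            all(centers >= 0 & centers < box_edge))
  structure(list(centers = centers, quats = quats, vels = vels,
                 angmom = angmom, blueprints = blueprints,
                 box_edge = box_edge, spec = spec),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("system_state: %d %s particles in a box of edge %g\n",
              nrow(x$centers), x$blueprints[[1]]$shape, x$box_edge))
  invisible(x)
}

# per-particle site diameter matrix (N x n_sites) and shared anchors
state_diameters <- function(state)
  do.call(rbind, lapply(state$blueprints, site_diameters))

state_anchors <- function(state) site_anchors(state$blueprints[[1]])

state_kinds <- function(state) site_kinds(state$blueprints[[1]])

#' Site positions of every particle in a state
#'
#' @param state A `system_state`.
#' @return Data frame with columns `particle`, `site`, `kind` (`"S"`/`"L"`),
#'   `diameter`, `x`, `y`, `z` (space-frame, unwrapped relative to each
#'   particle centre which is wrapped into the box).
#' @export
site_positions <- function(state) {
  anchors <- state_anchors(state)
  kinds <- state_kinds(state)
  N <- nrow(state$centers)
  ns <- nrow(anchors)
  out <- vector("list", N)
  for (i in seq_len(N)) {
    rot <- quat_rotate(state$quats[i, ], anchors)
    out[[i]] <- data.frame(
      particle = i, site = seq_len(ns),
      kind = ifelse(kinds == 0L, "S", "L"),
      diameter = site_diameters(state$blueprints[[i]]),
      x = state$centers[i, 1] + rot[, 1],
      y = state$centers[i, 2] + rot[, 2],
      z = state$centers[i, 3] + rot[, 3])
  }
  do.call(rbind, out)
}

#' Convert a system state to an analysis frame
#'
#' A *frame* is the unit all analysis functions consume: a list with a
#' `sites` data frame (columns `particle`, `kind`, `diameter`, `x`, `y`,
#' `z`) and the `box_edge`.
#'
#' @param state A `system_state`.
#' @return Object of class `md_frame`.
#' @export
as_frame <- function(state) {
  new_frame(site_positions(state), state$box_edge)
}

new_frame <- function(sites, box_edge, step = NA_integer_) {
  structure(list(sites = sites, box_edge = box_edge, step = step),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("frame: %d sites (%d particles), box %g\n",
              nrow(x$sites), length(unique(x$sites$particle)), x$box_edge))
  invisible(x)
}

#' Volume fraction from the realized site diameters
#'
#' Sums \eqn{(4\pi/3) s^3} over every seed and every *realized* lobe
#' diameter and divides by the box volume; the same additive, size-parameter
#' volume convention as the box-sizing rule (no overlap correction).
#'
#' @param state A `system_state`.
#' @return The realized volume fraction (0 for an empty system).
#' @export
actual_volume_fraction <- function(state) {
  if (length(state$blueprints) == 0) return(0)
  v <- sum(vapply(state$blueprints,
                  function(bp) sum(size_volume(site_diameters(bp))), 0))
  v / state$box_edge^3
}

#' Build a valid initial configuration
#'
#' Particles are placed by random sequential insertion: each trial particle
#' gets a uniform random centre and orientation and is rejected if any of
#' its sites comes closer (minimum image) than the repulsive contact
#' distance to an already placed site (\eqn{\sigma_{ij} + \Delta} for
#' seed-involving pairs, \eqn{\sigma_{ij}} for lobe-lobe).  Velocities and
#' body-frame angular momenta are drawn from the Maxwell-Boltzmann
#' distribution at `T_star`.  Deterministic given `spec$rng_seed`.
#' `method = "lattice"` instead places particles on a simple-cubic lattice
#' (random orientations).
#'
#' @param spec A [system_spec()].
#' @param method `"random"` (default) or `"lattice"`.
#' @param max_attempts Insertion attempts per particle before giving up.
#' @param mass,inertia Body mass and principal inertia used for the
#'   Maxwell-Boltzmann draw; default those of [body_inertia()].
#' @return A `system_state`.
#' @export
initialize_configuration <- function(spec, method = c("random", "lattice"),
                                     max_attempts = 2000, mass = 1,
                                     inertia = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "system_spec"))
  inertia <- inertia %||% body_inertia(spec$shape, sigma_S = spec$sigma_S,
                                       sigma_L = spec$poly$mu_G, mass = mass)
  with_seed(spec$rng_seed, {
    N <- spec$n_particles
    box <- spec$box_edge
    blueprints <- lapply(seq_len(N), function(i)
      build_blueprint(spec$shape, spec$poly, sigma_S = spec$sigma_S))
    anchors <- site_anchors(blueprints[[1]])
    kinds <- site_kinds(blueprints[[1]])

    centers <- matrix(0, N, 3)
    quats <- matrix(0, N, 4)

    # accepted site positions / diameters / kinds so far
    sx <- NULL; sdiam <- NULL; skind <- NULL

    contact_ok <- function(pos, diam) {
      if (is.null(sx)) return(TRUE)
      for (s in seq_len(nrow(pos))) {
        dx <- min_image(sx[, 1] - pos[s, 1], box)
        dy <- min_image(sx[, 2] - pos[s, 2], box)
        dz <- min_image(sx[, 3] - pos[s, 3], box)
        r <- sqrt(dx^2 + dy^2 + dz^2)
        sij <- (sdiam + diam[s]) / 2
        contact <- ifelse(skind == 1L & kinds[s] == 1L, sij, sij + (sij - 1))
        if (any(r < contact)) return(FALSE)
      }
      TRUE
    }

    if (method == "lattice") {
      n_side <- ceiling(N^(1 / 3))
      a <- box / n_side
      idx <- 0L
      for (ix in 0:(n_side - 1)) for (iy in 0:(n_side - 1))
        for (iz in 0:(n_side - 1)) {
          if (idx >= N) break
          idx <- idx + 1L
          centers[idx, ] <- (c(ix, iy, iz) + 0.5) * a
          quats[idx, ] <- random_quaternion()
        }
    } else {
      for (i in seq_len(N)) {
        placed <- FALSE
        for (attempt in seq_len(max_attempts)) {
          ctr <- runif(3, 0, box)
          q <- random_quaternion()
          pos <- sweep(quat_rotate(q, anchors), 2, ctr, `+`)
          diam <- site_diameters(blueprints[[i]])
          if (contact_ok(pos, diam)) {
            centers[i, ] <- ctr
            quats[i, ] <- q
            sx <- rbind(sx, pos)
            sdiam <- c(sdiam, diam)
            skind <- c(skind, kinds)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("packing infeasible: could not insert particle ", i, " after ",
               max_attempts, " attempts (phi too high?)")
      }
    }

    vels <- matrix(rnorm(3 * N, 0, sqrt(spec$T_star / mass)), N, 3)
    angmom <- matrix(rnorm(3 * N), N, 3) %*% diag(sqrt(inertia * spec$T_star))
    new_system_state(centers, quats, vels, angmom, blueprints,
                     box_edge = box, spec = spec)
  })
}
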