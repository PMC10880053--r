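# helper: build a monodisperse DB state from explicit centers/quats
db_state <- function(centers, quats, box) {
  N <- nrow(centers)
  bps <- replicate(N, build_blueprint("DB", poly_spec()), simplify = FALSE)
  new_system_state(centers %% box, quats,
                   matrix(0, N, 3), matrix(0, N, 3), bps, box)
}

sites_frame <- function(x, y, z, kind = "S", diameter = 1, particle = NULL,
                        box) {
  n <- length(x)
  new_frame(data.frame(particle = particle %||% seq_len(n), site = 1L,
                       kind = kind, diameter = diameter,
                       x = x %% box, y = y %% box, z = z %% box), box)
}

# net axial force magnitude on body 2 of a collinear DB dimer with lobe gap g
dimer_axial_force <- function(g, box = 40) {
  L <- 2 + g
  st <- db_state(rbind(c(20, 20, 18), c(20, 20, 18 + L)),
                 rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)), box)
  compute_forces_torques(st)$force[2, 3]
}

#' Deterministic ground-truth configurations
#'
#' Constructs named reference configurations with known geometry, used to
#' validate every analysis operation:
#' \describe{
#'   \item{`dimer`}{Two collinear dumbbells bonded through one lobe pair at
#'     the numerically solved zero-force separation; the built
#'     `system_state` is attached as `attr(frame, "state")`.}
#'   \item{`collinear_trimer`}{Three centres on a line, spacing `a` = 3.}
#'   \item{`triangle`}{Equilateral triangle of side `a` = 3.}
#'   \item{`hex_sheet`}{`nx` by `ny` triangular (hexagonal-packing) sheet of
#'     spacing `a` = 3 in the xy-plane; interior particles have 6 neighbors
#'     at `1.1 a`.}
#'   \item{`sc_lattice`}{Simple-cubic lattice, `n_side`^3 particles at
#'     spacing `a` = 3 in a fully periodic box of edge `n_side * a`.}
#'   \item{`ring5`}{Five dumbbells on a pentagon, each lobe bonded to
#'     exactly one lobe of the adjacent particle (gap solved numerically).}
#'   \item{`ideal_gas`}{`n` uniform random centres (Poisson configuration)
#'     in a box of edge `box`; reproducible from `seed`.}
#'   \item{`cavity_box`}{A sphere-packed matrix with a spherical cavity of
#'     diameter `cavity_diameter` (default 4) carved at the centre; the
#'     cavity wall is a dense spherical shell so the largest included
#'     sphere has exactly that diameter.}
#'   \item{`slab_box`}{A void slab of thickness `t` (default 2) between two
#'     dense sphere walls spanning the periodic box.}
#' }
#'
#' @param name Fixture name, see above.
#' @param ... Fixture-specific overrides (`a`, `nx`, `ny`, `n_side`, `n`,
#'   `box`, `seed`, `cavity_diameter`, `t`, `gap`).
#' @return An `md_frame`; `dimer` and `ring5` carry a `"state"` /
#'   construction attribute where noted.
#' @examples
#' make_fixture("triangle")
#' @export
make_fixture <- function(name = c("dimer", "collinear_trimer", "triangle",
                                  "hex_sheet", "sc_lattice", "ring5",
                                  "ideal_gas", "cavity_box", "slab_box"),
                         ...) {
  name <- match.arg(name)
  args <- list(...)
  switch(name,
    dimer = {
      box <- args$box %||% 40
      gap <- args$gap %||%
        uniroot(dimer_axial_force, c(2^(1 / 6), 2), box = box,
                tol = 1e-12)$root
      L <- 2 + gap
      st <- db_state(rbind(c(20, 20, 18), c(20, 20, 18 + L)),
                     rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)), box)
      fr <- as_frame(st)
      attr(fr, "state") <- st
      attr(fr, "gap") <- gap
      fr
    },
    collinear_trimer = {
      a <- args$a %||% 3; box <- args$box %||% 20
      sites_frame(10 + a * (-1:1), rep(10, 3), rep(10, 3), diameter = 2,
                  box = box)
    },
    triangle = {
      a <- args$a %||% 3; box <- args$box %||% 20
      v <- rbind(c(0, 0), c(a, 0), c(a / 2, a * sqrt(3) / 2))
      sites_frame(8 + v[, 1], 8 + v[, 2], rep(10, 3), diameter = 2, box = box)
    },
    hex_sheet = {
      a <- args$a %||% 3
      nx <- args$nx %||% 6; ny <- args$ny %||% 6
      ij <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
      x <- (ij$i + 0.5 * (ij$j %% 2)) * a
      y <- ij$j * a * sqrt(3) / 2
      box <- args$box %||% (max(c(x, y)) + 4 * a)
      sites_frame(2 + x, 2 + y, rep(box / 2, length(x)), diameter = 2,
                  box = box)
    },
    sc_lattice = {
      a <- args$a %||% 3
      n_side <- args$n_side %||% 5
      box <- n_side * a
      g <- expand.grid(i = 0:(n_side - 1), j = 0:(n_side - 1),
                       k = 0:(n_side - 1))
      sites_frame((g$i + 0.5) * a, (g$j + 0.5) * a, (g$k + 0.5) * a,
                  diameter = 2, box = box)
    },
    ring5 = {
      gap <- args$gap %||% 1.5
      d <- 1
      lobe_gap <- function(R) {
        th <- 2 * pi * (0:1) / 5
        p <- R * cbind(cos(th), sin(th))
        tv <- cbind(-sin(th), cos(th))
        a1 <- p[1, ] + d * tv[1, ]
        b2 <- p[2, ] - d * tv[2, ]
        sqrt(sum((a1 - b2)^2)) - gap
      }
      R <- uniroot(lobe_gap, c(2, 60), tol = 1e-12)$root
      th <- 2 * pi * (0:4) / 5
      box <- args$box %||% (2 * R + 12)
      ctr <- box / 2
      px <- ctr + R * cos(th); py <- ctr + R * sin(th)
      tx <- -sin(th); ty <- cos(th)
      sites <- do.call(rbind, lapply(1:5, function(i) data.frame(
        particle = i, site = 1:3, kind = c("S", "L", "L"),
        diameter = c(2, 1, 1),
        x = c(px[i], px[i] + d * tx[i], px[i] - d * tx[i]),
        y = c(py[i], py[i] + d * ty[i], py[i] - d * ty[i]),
        z = ctr)))
      fr <- new_frame(sites, box)
      attr(fr, "circumradius") <- R
      fr
    },
    ideal_gas = {
      n <- args$n_particles %||% 500; box <- args$box %||% 20
      seed <- args$seed %||% 1
      with_seed(seed,
        sites_frame(runif(n, 0, box), runif(n, 0, box), runif(n, 0, box),
                    diameter = 1, box = box))
    },
    cavity_box = {
      cd <- args$cavity_diameter %||% 4
      box <- args$box %||% (cd + 4)
      ctr <- box / 2
      g <- expand.grid(x = seq(0.5, box - 0.5, by = 1),
                       y = seq(0.5, box - 0.5, by = 1),
                       z = seq(0.5, box - 0.5, by = 1))
      rad <- cd / 2 + 0.5
      keep <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2) > rad + 0.25
      g <- g[keep, ]
      # dense Fibonacci shell at exactly the cavity-wall radius
      ns <- args$n_shell %||% 600
      k <- seq_len(ns) - 0.5
      phi <- acos(1 - 2 * k / ns)
      theta <- pi * (1 + sqrt(5)) * k
      sx <- ctr + rad * sin(phi) * cos(theta)
      sy <- ctr + rad * sin(phi) * sin(theta)
      sz <- ctr + rad * cos(phi)
      sites_frame(c(g$x, sx), c(g$y, sy), c(g$z, sz), diameter = 1,
                  box = box)
    },
    slab_box = {
      t <- args$t %||% 2
      box <- args$box %||% 8
      wall <- expand.grid(x = seq(0.25, box - 0.25, by = 0.5),
                          y = seq(0.25, box - 0.25, by = 0.5))
      z1 <- 1
      z2 <- z1 + t + 1  # surfaces t apart (sphere radius 0.5 each side)
      fr <- sites_frame(rep(wall$x, 2), rep(wall$y, 2),
                        c(rep(z1, nrow(wall)), rep(z2, nrow(wall))),
                        diameter = 1, box = box)
      attr(fr, "gap_z") <- c(z1 + 0.5, z2 - 0.5)
      fr
    })
}
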