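#' Canonical lobe directions for a particle shape
#'
#' Unit vectors from the seed centre toward each lobe, in the body frame:
#' antipodal for dumbbells (`"DB"`), coplanar at 120 degrees for trigonal
#' planar (`"TP"`), tetrahedral vertices (pairwise angle
#' \eqn{\arccos(-1/3) \approx 109.47^\circ}) for tetrahedral (`"TH"`).
#'
#' @param shape One of `"DB"`, `"TP"`, `"TH"`.
#' @return An `N_L x 3` matrix of unit vectors.
#' @export
shape_directions <- function(shape) {
  shape <- match.arg(shape, c("DB", "TP", "TH"))
  switch(shape,
    DB = rbind(c(0, 0, 1), c(0, 0, -1)),
    TP = {
      ang <- pi / 2 + 2 * pi * (0:2) / 3
      cbind(cos(ang), sin(ang), 0)
    },
    TH = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3))
}

#' Number of lobes for a shape
#' @param shape One of `"DB"`, `"TP"`, `"TH"`.
#' @return 2, 3 or 4.
#' @export
n_lobes <- function(shape) nrow(shape_directions(shape))

#' Build a (possibly polydisperse) lobed-particle blueprint
#'
#' A lobed particle is a rigid composite of one seed sphere (diameter
#' `sigma_S`, at the body origin) and `N_L` lobe spheres anchored at
#' distance `d` from the seed centre along the shape's canonical
#' directions.  Each lobe diameter is drawn independently from the
#' truncated Gaussian in `poly`; the anchor distance does not vary with
#' the sampled diameter.
#'
#' @param shape `"DB"` (2 lobes), `"TP"` (3) or `"TH"` (4).
#' @param poly A [poly_spec()]; defaults to the monodisperse case.
#' @param sigma_S Seed diameter; default 2 (twice the mean lobe diameter).
#' @param d Anchor distance from seed centre to lobe centre; default
#'   `sigma_S / 2`, i.e. lobe centres on the seed surface.
#' @return Object of class `particle_blueprint` with fields `shape`,
#'   `sigma_S`, `d`, `lobe_diameters`, `lobe_anchors` (anchor vectors,
#'   `N_L x 3`).
#' @examples
#' set.seed(7)
#' build_blueprint("TP", poly_spec(sigma_G = 0.3))
#' @export
build_blueprint <- function(shape, poly = poly_spec(), sigma_S = 2,
                            d = sigma_S / 2) {
  shape <- match.arg(shape, c("DB", "TP", "TH"))
  dirs <- shape_directions(shape)
  diam <- sample_lobe_diameter(poly, nrow(dirs))
  structure(list(shape = shape, sigma_S = sigma_S, d = d,
                 lobe_diameters = diam, lobe_anchors = dirs * d),
            class = "particle_blueprint")
}

#' @export
print.particle_blueprint <- function(x, ...) {
  cat(sprintf("%s particle: seed diameter %g, %d lobes (diameters %s) at anchor distance %g\n",
              x$shape, x$sigma_S, length(x$lobe_diameters),
              paste(signif(x$lobe_diameters, 4), collapse = ", "), x$d))
  invisible(x)
}

# site diameters of a blueprint, seed first
site_diameters <- function(bp) c(bp$sigma_S, bp$lobe_diameters)

# site anchors (seed at origin), (N_L + 1) x 3
site_anchors <- function(bp) rbind(c(0, 0, 0), bp$lobe_anchors)

# site kinds: 0 = seed, 1 = lobe
site_kinds <- function(bp) c(0L, rep(1L, length(bp$lobe_diameters)))
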