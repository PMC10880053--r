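SSLJ_CUT_FACTOR <- 2^(1 / 6)
LJ_CUT_FACTOR <- 3

#' Pair interaction parameters for two sites
#'
#' The combined size is the arithmetic mean \eqn{\sigma_{ij} = (\sigma_i +
#' \sigma_j)/2}.  Lobe-lobe pairs attract through a truncated-and-shifted
#' Lennard-Jones potential with \eqn{r_{cut} = 3\sigma_{ij}}; every pair
#' involving a seed repels through the surface-shifted Lennard-Jones
#' (SSLJ) with surface shift \eqn{\Delta = \sigma_{ij} - 1} and cutoff
#' \eqn{r_{cut} = 2^{1/6}\sigma_{ij}} (effective range \eqn{r_{cut} +
#' \Delta}).
#'
#' @param d_i,d_j Site diameters.
#' @param kind_i,kind_j Site kinds, `"S"` or `"L"`.
#' @param eps_sl Well depth of the repulsive SSLJ pairs (default 1).
#' @param eps_ll Well depth of the attractive lobe-lobe LJ (default 3).
#' @return Object of class `pair_params` with fields `sigma_ij`, `epsilon`,
#'   `delta`, `r_cut`, `kind` (`"SSLJ"` or `"LJ"`).
#' @examples
#' pair_params(0.8, 1.2, "L", "L")  # sigma_ij = 1, r_cut = 3
#' @export
pair_params <- function(d_i, d_j, kind_i, kind_j, eps_sl = 1, eps_ll = 3) {
  kind_i <- match.arg(kind_i, c("S", "L"))
  kind_j <- match.arg(kind_j, c("S", "L"))
  sigma <- (d_i + d_j) / 2
  if (kind_i == "L" && kind_j == "L") {
    p <- list(sigma_ij = sigma, epsilon = eps_ll, delta = 0,
              r_cut = LJ_CUT_FACTOR * sigma, kind = "LJ")
  } else {
    p <- list(sigma_ij = sigma, epsilon = eps_sl, delta = sigma - 1,
              r_cut = SSLJ_CUT_FACTOR * sigma, kind = "SSLJ")
  }
  structure(p, class = "pair_params")
}

#' @export
print.pair_params <- function(x, ...) {
  cat(sprintf("%s pair: sigma_ij = %g, epsilon = %g, delta = %g, r_cut = %g\n",
              x$kind, x$sigma_ij, x$epsilon, x$delta, x$r_cut))
  invisible(x)
}

#' Surface-shifted Lennard-Jones (repulsive) energy
#'
#' \deqn{U(r) = 4\epsilon[(\sigma_{ij}/(r-\Delta))^{12} -
#'   (\sigma_{ij}/(r-\Delta))^6] + \epsilon}
#' for \eqn{r - \Delta < 2^{1/6}\sigma_{ij}} and 0 beyond; the
#' \eqn{+\epsilon} offset (`wca_shift = TRUE`, the default) makes the
#' potential continuous at the cutoff so it is purely repulsive.
#'
#' @param r Site separation(s); must exceed `p$delta` (non-penetration).
#' @param p A `pair_params` of kind `"SSLJ"`.
#' @param wca_shift Apply the \eqn{+\epsilon} continuity offset?
#' @return Energy value(s).
#' @export
sslj_energy <- function(r, p, wca_shift = TRUE) {
  stopifnot(p$kind == "SSLJ")
  if (any(r <= p$delta))
    stop("hard-core violation: r must exceed the surface shift delta = ",
         p$delta)
  u <- r - p$delta
  s6 <- (p$sigma_ij / u)^6
  e <- 4 * p$epsilon * (s6^2 - s6) + if (wca_shift) p$epsilon else 0
  ifelse(u < SSLJ_CUT_FACTOR * p$sigma_ij, e, 0)
}

#' Truncated-and-shifted Lennard-Jones (attractive) energy
#'
#' \deqn{U(r) = 4\epsilon[(\sigma_{ij}/r)^{12} - (\sigma_{ij}/r)^6] -
#'   U_{LJ}(3\sigma_{ij})}
#' for \eqn{r < 3\sigma_{ij}} and 0 beyond.  The shift
#' (\eqn{\approx 0.0055\epsilon}) keeps the energy continuous at the
#' cutoff; `shifted = FALSE` gives the bare truncated potential.
#'
#' @param r Site separation(s), positive.
#' @param p A `pair_params` of kind `"LJ"`.
#' @param shifted Apply the cutoff energy shift? Default `TRUE`.
#' @return Energy value(s).
#' @export
lj_energy <- function(r, p, shifted = TRUE) {
  stopifnot(p$kind == "LJ", all(r > 0))
  s6 <- (p$sigma_ij / r)^6
  sc6 <- (1 / LJ_CUT_FACTOR)^6
  shift <- if (shifted) 4 * p$epsilon * (sc6^2 - sc6) else 0
  ifelse(r < LJ_CUT_FACTOR * p$sigma_ij,
         4 * p$epsilon * (s6^2 - s6) - shift, 0)
}

#' Pair force vector
#'
#' Analytic \eqn{-\nabla U} of [sslj_energy()] / [lj_energy()] acting on
#' the site at `+r_vec` (the partner feels the opposite force).  Zero
#' beyond the cutoff.
#'
#' @param r_vec Displacement vector (length 3) from site j to site i.
#' @param p A `pair_params`.
#' @param wca_shift Passed through for SSLJ (does not affect the force).
#' @return Force vector of length 3.
#' @export
pair_force <- function(r_vec, p, wca_shift = TRUE) {
  r <- sqrt(sum(r_vec^2))
  if (p$kind == "LJ") {
    if (r >= LJ_CUT_FACTOR * p$sigma_ij) return(c(0, 0, 0))
    s6 <- (p$sigma_ij / r)^6
    fmag_over_r <- 24 * p$epsilon * (2 * s6^2 - s6) / r^2
    return(fmag_over_r * r_vec)
  }
  if (r <= p$delta)
    stop("hard-core violation: |r_vec| must exceed delta = ", p$delta)
  u <- r - p$delta
  if (u >= SSLJ_CUT_FACTOR * p$sigma_ij) return(c(0, 0, 0))
  s6 <- (p$sigma_ij / u)^6
  fmag_over_r <- 24 * p$epsilon * (2 * s6^2 - s6) / (u * r)
  fmag_over_r * r_vec
}

#' Interaction table for a set of blueprints
#'
#' Enumerates the unique realized site types (kind, diameter) and maps
#' every unordered type pair to its [pair_params()].  Intra-particle pairs
#' are never looked up by the engine (rigid body).  For very polydisperse
#' systems with more than `max_materialize` site types the table is kept
#' lazy (pairs resolved on demand); it is always resolvable for every pair.
#'
#' @param blueprints List of `particle_blueprint`s (or a `system_state`).
#' @param eps_sl,eps_ll Well depths, defaults 1 and 3.
#' @param max_materialize Materialize the full pair data frame when the
#'   number of site types is at most this.
#' @return Object of class `interaction_table`.
#' @export
build_interaction_table <- function(blueprints, eps_sl = 1, eps_ll = 3,
                                    max_materialize = 400) {
  if (inherits(blueprints, "system_state")) blueprints <- blueprints$blueprints
  stopifnot(length(blueprints) > 0)
  kinds <- unlist(lapply(blueprints, function(bp)
    ifelse(site_kinds(bp) == 0L, "S", "L")))
  diams <- unlist(lapply(blueprints, site_diameters))
  types <- unique(data.frame(kind = kinds, diameter = diams))
  rownames(types) <- NULL
  types <- types[order(types$kind, types$diameter), ]
  pairs <- NULL
  if (nrow(types) <= max_materialize) {
    idx <- which(upper.tri(matrix(0, nrow(types), nrow(types)), diag = TRUE),
                 arr.ind = TRUE)
    pairs <- data.frame(i = idx[, 1], j = idx[, 2])
    pp <- mapply(function(i, j)
      unclass(pair_params(types$diameter[i], types$diameter[j],
                          types$kind[i], types$kind[j], eps_sl, eps_ll)),
      pairs$i, pairs$j, SIMPLIFY = FALSE)
    pairs$sigma_ij <- vapply(pp, `[[`, 0, "sigma_ij")
    pairs$epsilon <- vapply(pp, `[[`, 0, "epsilon")
    pairs$delta <- vapply(pp, `[[`, 0, "delta")
    pairs$r_cut <- vapply(pp, `[[`, 0, "r_cut")
    pairs$kind <- vapply(pp, `[[`, "", "kind")
  }
  structure(list(types = types, pairs = pairs, eps_sl = eps_sl,
                 eps_ll = eps_ll), class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  np <- if (is.null(x$pairs)) nrow(x$types) * (nrow(x$types) + 1) / 2
        else nrow(x$pairs)
  cat(sprintf("interaction table: %d site types, %d pair entries (eps_SL = %g, eps_LL = %g)\n",
              nrow(x$types), np, x$eps_sl, x$eps_ll))
  invisible(x)
}

#' Resolve the pair parameters of two sites from a table
#'
#' @param table An `interaction_table`.
#' @param d_i,d_j Site diameters.
#' @param kind_i,kind_j Site kinds `"S"`/`"L"`.
#' @return A `pair_params`; errors if the site types are not in the table.
#' @export
resolve_pair <- function(table, d_i, d_j, kind_i, kind_j) {
  for (d in c(d_i, d_j)) {
    k <- if (d == d_i) kind_i else kind_j
    if (!any(table$types$kind == k & abs(table$types$diameter - d) < 1e-12))
      stop("site type (", k, ", ", d, ") not covered by this table")
  }
  pair_params(d_i, d_j, kind_i, kind_j, table$eps_sl, table$eps_ll)
}

#' Dump / load an interaction table as JSON
#'
#' @param table An `interaction_table`.
#' @param path File path.
#' @return `read_interaction_table` returns the reconstructed table.
#' @export
write_interaction_table <- function(table, path) {
  jsonlite::write_json(list(types = table$types, pairs = table$pairs,
                            eps_sl = table$eps_sl, eps_ll = table$eps_ll),
                       path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_interaction_table
#' @export
read_interaction_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(types = as.data.frame(x$types),
                 pairs = if (is.null(x$pairs)) NULL else as.data.frame(x$pairs),
                 eps_sl = x$eps_sl, eps_ll = x$eps_ll),
            class = "interaction_table")
}
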