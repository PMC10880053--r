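#' Write frames as extended XYZ
#'
#' One block per frame: the site count, a comment line carrying the cubic
#' `Lattice`, the column `Properties`
#' (`species:S:1:pos:R:3:particle:I:1:diameter:R:1`) and the step, then
#' one row per site: kind (`S`/`L`), position, parent particle index and
#' site diameter.
#'
#' @param frames A frame, list of frames, `system_state` or
#'   `md_trajectory`.
#' @param path Output file.
#' @export
write_xyz <- function(frames, path) {
  frames <- as_frame_list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    s <- f$sites
    writeLines(as.character(nrow(s)), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:particle:I:1:diameter:R:1 Step=%d',
      f$box_edge, f$box_edge, f$box_edge,
      if (is.na(f$step)) 0L else as.integer(f$step)), con)
    writeLines(sprintf("%s %.10g %.10g %.10g %d %.10g",
                       s$kind, s$x, s$y, s$z, s$particle, s$diameter), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' @param path File written by [write_xyz()] (or compatible).
#' @return List of `md_frame`s.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    lat <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    box <- as.numeric(strsplit(sub('Lattice="', "", sub('"$', "", lat)),
                               " ")[[1]][1])
    step <- suppressWarnings(as.integer(
      sub(".*Step=([0-9]+).*", "\\1", comment)))
    rows <- strsplit(lines[(i + 2):(i + 1 + n)], " +")
    sites <- data.frame(
      particle = as.integer(vapply(rows, `[`, "", 5)),
      site = NA_integer_,
      kind = vapply(rows, `[`, "", 1),
      diameter = as.numeric(vapply(rows, `[`, "", 6)),
      x = as.numeric(vapply(rows, `[`, "", 2)),
      y = as.numeric(vapply(rows, `[`, "", 3)),
      z = as.numeric(vapply(rows, `[`, "", 4)))
    frames[[length(frames) + 1]] <- new_frame(sites, box,
                                              step %||% NA_integer_)
    i <- i + 2 + n
  }
  frames
}

#' Serialize blueprints or a system spec to JSON
#'
#' @param blueprints List of `particle_blueprint`s.
#' @param path File path.
#' @export
write_blueprints <- function(blueprints, path) {
  jsonlite::write_json(lapply(blueprints, function(bp)
    list(shape = bp$shape, sigma_S = bp$sigma_S, d = bp$d,
         lobe_diameters = bp$lobe_diameters)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_blueprints
#' @export
read_blueprints <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE), function(b) {
    dirs <- shape_directions(b$shape)
    structure(list(shape = b$shape, sigma_S = b$sigma_S, d = b$d,
                   lobe_diameters = unlist(b$lobe_diameters),
                   lobe_anchors = dirs * b$d),
              class = "particle_blueprint")
  })
}

#' @rdname write_blueprints
#' @param spec A [system_spec()].
#' @export
write_system_spec <- function(spec, path) {
  jsonlite::write_json(unclass(lapply(unclass(spec), unclass)), path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_blueprints
#' @export
read_system_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  system_spec(n_particles = x$n_particles, shape = x$shape, phi = x$phi,
              T_star = x$T_star,
              poly = poly_spec(x$poly$mu_G, x$poly$sigma_G),
              rng_seed = x$rng_seed, sigma_S = x$sigma_S,
              box_edge = x$box_edge)
}
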