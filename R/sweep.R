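#' Plan a (temperature x polydispersity) state-diagram sweep
#'
#' Builds the grid of conditions for the reduced-scale state diagram.
#' The full state-diagram grid is \eqn{T^* \in \{0.2, 0.4, 0.6, 0.8, 1.0\}} and
#' \eqn{\sigma_G \in \{0.1, ..., 0.5\}}; the monodisperse baseline
#' \eqn{\sigma_G = 0} is included by default for reference.  Per-condition
#' seeds are derived deterministically from the global seed and the
#' condition index.
#'
#' @param shapes Character vector of shapes, default `"DB"`.
#' @param T_star Reduced temperatures.
#' @param sigma_G Polydispersity values.
#' @param n_particles Particles per condition (desk-scale default 64; the
#'   full-scale protocol uses 1000).
#' @param n_equil,n_prod Step counts (desk-scale defaults 1e5 each; the
#'   full-scale protocol uses 5e7 each).
#' @param phi Volume fraction, default 0.1.
#' @param global_seed Master seed.
#' @param write_every,log_every Recording intervals.
#' @param output_root Optional directory for per-condition outputs.
#' @return Object of class `sweep_plan`: data frame `conditions` plus run
#'   parameters.
#' @export
sweep_plan <- function(shapes = "DB", T_star = c(0.2, 0.4, 0.6, 0.8, 1.0),
                       sigma_G = seq(0, 0.5, by = 0.1), n_particles = 64,
                       n_equil = 1e5, n_prod = 1e5, phi = 0.1,
                       global_seed = 1, write_every = 5000,
                       log_every = 5000, output_root = NULL) {
  cond <- expand.grid(shape = shapes, T_star = T_star, sigma_G = sigma_G,
                      stringsAsFactors = FALSE)
  cond <- unique(cond)
  cond$index <- seq_len(nrow(cond))
  cond$seed <- (global_seed * 1000003 + cond$index * 7919) %% 2147483647
  structure(list(conditions = cond, n_particles = n_particles,
                 n_equil = n_equil, n_prod = n_prod, phi = phi,
                 global_seed = global_seed, write_every = write_every,
                 log_every = log_every, output_root = output_root),
            class = "sweep_plan")
}

#' @export
print.sweep_plan <- function(x, ...) {
  cat(sprintf("sweep plan: %d conditions, N = %d, %g + %g steps each\n",
              nrow(x$conditions), x$n_particles, x$n_equil, x$n_prod))
  invisible(x)
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run a state-diagram sweep
#'
#' For every condition of the plan: build the system, simulate
#' (equilibration + production), and compute the summary metrics used to
#' label the state diagram — mean bonds per lobe, largest-cluster
#' fraction, first-RDF-peak height, and the modal pore diameter of the
#' densest sub-box (NA where no dense region or no accessible pore
#' exists).  Failures are isolated per condition and recorded in the
#' manifest.
#'
#' @param plan A [sweep_plan()].
#' @param params_fn Optional `function(T_star, seed)` returning the
#'   [integrator_params()] for a condition (default dt = 0.005, unit
#'   frictions).
#' @return Object of class `run_manifest`: `summary` data frame (one row
#'   per condition), `config_hash`, `package_version`, `outputs` (paths,
#'   when `output_root` is set) and `status` per condition.
#' @export
run_sweep <- function(plan, params_fn = NULL) {
  stopifnot(inherits(plan, "sweep_plan"))
  cond <- plan$conditions
  params_fn <- params_fn %||% function(T_star, seed)
    integrator_params(T_star = T_star, rng_seed = seed)
  rows <- vector("list", nrow(cond))
  status <- character(nrow(cond))
  outputs <- list()
  for (k in seq_len(nrow(cond))) {
    rows[[k]] <- data.frame(
      mean_bonds_per_lobe = NA_real_, largest_cluster_fraction = NA_real_,
      rdf_first_peak = NA_real_, psd_mode = NA_real_)
    status[k] <- "failed"
    try({
      spec <- system_spec(plan$n_particles, cond$shape[k], phi = plan$phi,
                          T_star = cond$T_star[k],
                          poly = poly_spec(sigma_G = cond$sigma_G[k]),
                          rng_seed = cond$seed[k])
      out_dir <- if (!is.null(plan$output_root))
        file.path(plan$output_root, sprintf("cond_%03d", k)) else NULL
      traj <- run_simulation(spec, params_fn(cond$T_star[k], cond$seed[k]),
                             n_equil = plan$n_equil, n_prod = plan$n_prod,
                             write_every = plan$write_every,
                             log_every = plan$log_every,
                             output_dir = out_dir)
      if (!is.null(out_dir)) outputs[[sprintf("cond_%03d", k)]] <- out_dir
      fr <- if (length(traj$frames) > 0) traj$frames[[length(traj$frames)]]
            else as_frame(traj$final_state)
      bs <- bonds_per_lobe(fr)
      cl <- cluster_labels(fr)
      gr <- rdf(if (length(traj$frames) > 0) traj$frames else list(fr))
      peak <- max(gr$data$g)
      psd_mode <- tryCatch({
        reg <- extract_dense_subbox(fr)
        # cap the voxel problem per condition; very diffuse regions carry no
        # meaningful pore statistics anyway
        if (prod(reg$extent) > 1000) NA_real_ else
          pore_size_distribution(reg, fr)$mode
      }, error = function(e) NA_real_)
      rows[[k]]$mean_bonds_per_lobe <- bs$mean_bonds_per_lobe
      rows[[k]]$largest_cluster_fraction <- cl$largest_fraction
      rows[[k]]$rdf_first_peak <- peak
      rows[[k]]$psd_mode <- psd_mode
      status[k] <- "ok"
    }, silent = TRUE)
  }
  metrics <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(mean_bonds_per_lobe = numeric(0),
               largest_cluster_fraction = numeric(0),
               rdf_first_peak = numeric(0), psd_mode = numeric(0))
  summary <- cbind(cond[, c("index", "shape", "T_star", "sigma_G", "seed"),
                        drop = FALSE], metrics)
  manifest <- structure(list(summary = summary,
                             config_hash = config_hash(unclass(plan)),
                             package_version =
                               as.character(utils::packageVersion("polylobe")),
                             outputs = outputs, status = status),
                        class = "run_manifest")
  if (!is.null(plan$output_root)) {
    dir.create(plan$output_root, recursive = TRUE, showWarnings = FALSE)
    write.csv(summary, file.path(plan$output_root, "state_diagram.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(config_hash = manifest$config_hash,
                              package_version = manifest$package_version,
                              status = manifest$status,
                              outputs = outputs),
                         file.path(plan$output_root, "manifest.json"),
                         auto_unbox = TRUE)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("sweep manifest: %d conditions (%d ok), config %s\n",
              length(x$status), sum(x$status == "ok"), x$config_hash))
  invisible(x)
}
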