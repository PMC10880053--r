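# Independent oracles used across the suite.

# moments of the +/- 1 SD truncated standard normal by numeric quadrature
tn_moment <- function(k) {
  z <- integrate(dnorm, -1, 1)$value
  integrate(function(x) x^k * dnorm(x) / z, -1, 1)$value
}

# central-difference gradient of a scalar energy function of r
central_diff <- function(f, r, h = 1e-6 * r) (f(r + h) - f(r - h)) / (2 * h)

# plain union-find over an edge list; returns component labels renumbered by
# smallest member
union_find_labels <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges) > 0)
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, sort(unique(roots)))
}

# brute-force O(n^2) bonded lobe pairs on a frame
brute_bonds <- function(frame, rcut_factor = 3) {
  lob <- frame$sites[frame$sites$kind == "L", ]
  rownames(lob) <- NULL
  box <- frame$box_edge
  out <- NULL
  n <- nrow(lob)
  for (a in seq_len(max(0, n - 1))) for (b in (a + 1):n) {
    if (lob$particle[a] == lob$particle[b]) next
    d <- c(lob$x[a] - lob$x[b], lob$y[a] - lob$y[b], lob$z[a] - lob$z[b])
    d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    if (r < rcut_factor * (lob$diameter[a] + lob$diameter[b]) / 2)
      out <- rbind(out, c(a, b))
  }
  out
}

# random polydisperse DB state, placed on a lattice (no dynamics involved)
lattice_state <- function(n = 27, shape = "DB", sigma_G = 0, seed = 1,
                          T_star = 1) {
  spec <- system_spec(n, shape, T_star = T_star,
                      poly = poly_spec(sigma_G = sigma_G), rng_seed = seed)
  initialize_configuration(spec, method = "lattice")
}

# translate every site of a frame by a fixed vector (periodic wrap)
translate_frame <- function(frame, v) {
  s <- frame$sites
  s$x <- (s$x + v[1]) %% frame$box_edge
  s$y <- (s$y + v[2]) %% frame$box_edge
  s$z <- (s$z + v[3]) %% frame$box_edge
  polylobe:::new_frame(s, frame$box_edge, frame$step)
}

# seed-scoped evaluation without touching the suite's RNG state
with_seed_local <- function(seed, expr) polylobe:::with_seed(seed, expr)
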