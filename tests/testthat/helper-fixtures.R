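# Shared fixtures: small geometries and parameter sets used across tests.

tiny_config <- function(...) {
  geometry_config(Lx = 6.4, Ly = 4, dx = 0.1, dy = 0.1, seed = 7, ...)
}

tiny_geometry <- function(...) build_geometry(tiny_config(...))

# Parameters with all stochastic channels silenced and membrane/pump terms
# off: the deterministic reaction-diffusion backbone.
quiet_params <- function(...) {
  sim_params(ryr_ka = 0, ryr_ki = 0, ryr_ki_ca = 0, g_cal = 0, k_ncx = 0,
             v_up = 0, g_leak = 0, ...)
}

# A geometry stripped of all channels (no RyR/LCC nodes).
channel_free <- function(geom) {
  geom$ryr_count[] <- 0L
  geom$lcc_count[] <- 0L
  geom
}

# Random RyR occupancy map on a small grid (for clustering oracles).
random_ryr_geometry <- function(nx = 30, ny = 20, p_occ = 0.06, seed = 1) {
  g <- build_geometry(geometry_config(Lx = nx / 10, Ly = ny / 10,
                                      dx = 0.1, dy = 0.1, seed = 1))
  set.seed(seed)
  g$ryr_count <- matrix(ifelse(runif(nx * ny) < p_occ, 9L, 0L), nx, ny)
  g$lcc_count[] <- 0L
  g
}

# O(n^2) brute-force transitive-closure clustering of RyR-bearing nodes,
# independent of the package's union-find implementation.
brute_force_carus <- function(geom, merge_distance = geom$config$merge_distance) {
  occ <- which(geom$ryr_count > 0L, arr.ind = TRUE)
  n <- nrow(occ)
  if (n == 0) return(list())
  gap <- function(a, b) {
    gx <- max(0, (abs(occ[a, 1] - occ[b, 1]) - 1) * geom$dx)
    gy <- max(0, (abs(occ[a, 2] - occ[b, 2]) - 1) * geom$dy)
    sqrt(gx^2 + gy^2)
  }
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n))
    adj[a, b] <- gap(a, b) <= merge_distance + 1e-12
  grp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (grp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      a <- queue[[1]]; queue <- queue[-1]
      if (grp[a] > 0L) next
      grp[a] <- cur
      queue <- c(queue, which(adj[a, ] & grp == 0L))
    }
  }
  idx <- occ[, 1] + (occ[, 2] - 1L) * geom$nx
  unname(split(sort(idx)[order(order(idx))], grp)) |>
    lapply(sort) |>
    (\(x) x[order(vapply(x, min, numeric(1)))])()
}

# Canonical form of a CaRU partition for comparison.
canonical_partition <- function(members) {
  members <- lapply(members, function(x) as.integer(unname(sort(x))))
  unname(members[order(vapply(members, min, numeric(1)))])
}
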