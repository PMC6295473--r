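#' Geometry configuration
#'
#' Parameters describing the discretized cell microstructure: cell size and
#' grid spacing, z-line period and width, calcium-release-unit (CaRU)
#' placement, per-domain sarcoplasmic-reticulum (SR) volume fractions and
#' reference diffusion coefficients.
#'
#' The standard cell is 100 x 15 um at dx = dy = 0.1 um with z-lines (0.3 um
#' wide strips) every 1.6 um.  Interior CaRUs sit along each z-line at 0.5 um
#' transversal spacing with their longitudinal coordinate drawn from a
#' Gaussian of standard deviation `sigma` centred on the z-line; perimeter
#' CaRUs (each carrying an L-type channel site) are exactly periodic at
#' 0.5 um along the membrane.  A CaRU is realized as `nodes_per_caru`
#' contiguous grid nodes each holding `ryrs_per_node` ryanodine receptors
#' (at most 10 per node).
#'
#' @param Lx,Ly Cell dimensions (um).
#' @param dx,dy Grid spacing (um); `Lx/dx` and `Ly/dy` must be integers.
#' @param zline_period Longitudinal z-line period Tx (um).
#' @param zline_width Width of a z-line strip (um).
#' @param interior_caru_period_y Transversal CaRU spacing Ty along a z-line (um).
#' @param perimeter_caru_period Spacing of perimeter CaRUs along the membrane (um).
#' @param sigma Gaussian longitudinal dispersion of interior CaRU centres (um).
#' @param ryrs_per_node RyRs per RyR-bearing node (<= 10).
#' @param nodes_per_caru Nodes forming one CaRU (4 = 2x2 block, 6 = 2x3 block).
#' @param lccs_per_site L-type channels per perimeter site.
#' @param merge_distance Edge-to-edge merge distance defining functional CaRUs (um).
#' @param v_sr_zline,v_sr_sarc SR volume fraction in the z-line/membrane and
#'   sarcomere domains (dimensionless, in (0, 1)).
#' @param D_i_ref,D_sr_ref Reference diffusion coefficients between z-lines
#'   (um^2/ms).
#' @param total_ryr_target Optional total-RyR budget; when set, interior CaRU
#'   placements are subsampled uniformly at random to match it (used to
#'   compare cluster-size variants at fixed total RyR count).
#' @param seed RNG seed for stochastic placement (interior CaRU centres).
#' @return A validated `geometry_config` list.
#' @export
geometry_config <- function(Lx = 100, Ly = 15, dx = 0.1, dy = 0.1,
                            zline_period = 1.6, zline_width = 0.3,
                            interior_caru_period_y = 0.5,
                            perimeter_caru_period = 0.5,
                            sigma = 0.4, ryrs_per_node = 9L,
                            nodes_per_caru = 4L, lccs_per_site = 5L,
                            merge_distance = 0.15,
                            v_sr_zline = 0.06, v_sr_sarc = 0.02,
                            D_i_ref = 0.25, D_sr_ref = 0.09,
                            total_ryr_target = NULL, seed = 1L) {
  cfg <- list(Lx = Lx, Ly = Ly, dx = dx, dy = dy,
              zline_period = zline_period, zline_width = zline_width,
              interior_caru_period_y = interior_caru_period_y,
              perimeter_caru_period = perimeter_caru_period,
              sigma = sigma, ryrs_per_node = as.integer(ryrs_per_node),
              nodes_per_caru = as.integer(nodes_per_caru),
              lccs_per_site = as.integer(lccs_per_site),
              merge_distance = merge_distance,
              v_sr_zline = v_sr_zline, v_sr_sarc = v_sr_sarc,
              D_i_ref = D_i_ref, D_sr_ref = D_sr_ref,
              total_ryr_target = total_ryr_target,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_geometry_config(cfg)
  class(cfg) <- "geometry_config"
  cfg
}

validate_geometry_config <- function(cfg) {
  stopifnot(cfg$Lx > 0, cfg$Ly > 0, cfg$dx > 0, cfg$dy > 0)
  for (fld in c("Lx", "Ly")) {
    d <- if (fld == "Lx") cfg$dx else cfg$dy
    r <- cfg[[fld]] / d
    if (abs(r - round(r)) > 1e-8)
      stop(sprintf("grid not commensurate: %s = %g is not an integer multiple of spacing %g",
                   fld, cfg[[fld]], d), call. = FALSE)
  }
  if (cfg$v_sr_zline <= 0 || cfg$v_sr_zline >= 1 ||
      cfg$v_sr_sarc <= 0 || cfg$v_sr_sarc >= 1)
    stop("SR volume fractions must lie strictly between 0 and 1", call. = FALSE)
  if (cfg$ryrs_per_node > 10L)
    stop("ryrs_per_node must be <= 10 (at most 10 RyRs fit on one grid node)",
         call. = FALSE)
  if (cfg$ryrs_per_node < 1L) stop("ryrs_per_node must be >= 1", call. = FALSE)
  if (cfg$sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (cfg$merge_distance < 0) stop("merge_distance must be >= 0", call. = FALSE)
  if (!cfg$nodes_per_caru %in% c(4L, 6L))
    stop("nodes_per_caru must be 4 (2x2 block) or 6 (2x3 block)", call. = FALSE)
  if (cfg$D_i_ref <= 0 || cfg$D_sr_ref <= 0)
    stop("reference diffusion coefficients must be positive", call. = FALSE)
  invisible(cfg)
}

# Block footprint (node offsets) for a CaRU anchored at (j0, k0):
# 2x2 for 4 nodes, 2x3 (2 longitudinal x 3 transversal) for 6 nodes.
caru_block_offsets <- function(nodes_per_caru) {
  if (nodes_per_caru == 4L) expand.grid(dj = 0:1, dk = 0:1)
  else expand.grid(dj = 0:1, dk = 0:2)
}

#' Build the discretized cell microstructure
#'
#' Constructs per-node structural fields: domain label (sarcomere / z-line /
#' membrane), cytosolic and SR volume fractions, diffusion coefficients
#' (linear in the local volume fraction, normalized to the reference values
#' between z-lines), RyR counts and L-type channel counts.  The membrane is
#' the outermost one-node ring and belongs to the SR-rich domain, as do the
#' z-line strips.
#'
#' Interior CaRU centres are placed along each z-line at the transversal
#' period, with longitudinal coordinate `z-line centre + N(0, sigma^2)`
#' clipped to the cell; colliding blocks are re-sampled up to 20 times and
#' then shifted to the nearest free slot (all occurrences are counted in the
#' returned `log`).  Perimeter CaRUs are exactly periodic along the boundary
#' and each carries one L-type channel site on its membrane node.
#'
#' @param config A [geometry_config()].
#' @param zline_centers Optional explicit z-line centre coordinates (um);
#'   by default z-lines recur at `zline_period`.
#' @return A `cell_geometry` list: `nx`, `ny`, `dx`, `dy`, matrices `domain`,
#'   `v_i`, `v_sr`, `D_i`, `D_sr`, `ryr_count`, `lcc_count`, the `config`,
#'   and a placement `log`.
#' @export
build_geometry <- function(config, zline_centers = NULL) {
  validate_geometry_config(config)
  seed <- if (is.null(config$seed)) NULL else stream_seed(config$seed, "geometry")
  with_stream(seed, build_geometry_impl(config, zline_centers))
}

build_geometry_impl <- function(config, zline_centers = NULL) {
  nx <- as.integer(round(config$Lx / config$dx))
  ny <- as.integer(round(config$Ly / config$dy))
  dx <- config$dx; dy <- config$dy

  if (is.null(zline_centers)) {
    n_z <- floor((config$Lx - config$zline_period / 2) / config$zline_period)
    zline_centers <- config$zline_period * seq_len(n_z)
  }
  if (length(zline_centers) == 0)
    stop("no z-lines fit in the domain", call. = FALSE)

  domain <- matrix(SARCOMERE, nx, ny)
  half_w_nodes <- floor(config$zline_width / dx / 2)
  zline_cols <- integer(0)
  for (xc in zline_centers) {
    jc <- as.integer(floor(xc / dx + 0.5 + 1e-9))
    cols <- (jc - half_w_nodes):(jc + half_w_nodes)
    cols <- cols[cols >= 2 & cols <= nx - 1]
    zline_cols <- c(zline_cols, cols)
    domain[cols, 2:(ny - 1)] <- ZLINE
  }
  domain[1, ] <- MEMBRANE; domain[nx, ] <- MEMBRANE
  domain[, 1] <- MEMBRANE; domain[, ny] <- MEMBRANE

  v_sr <- matrix(config$v_sr_sarc, nx, ny)
  v_sr[domain != SARCOMERE] <- config$v_sr_zline
  v_i <- 1 - v_sr
  # diffusion linear in local volume fraction, normalized so values between
  # z-lines equal the reference coefficients
  D_i <- config$D_i_ref * v_i / (1 - config$v_sr_sarc)
  D_sr <- config$D_sr_ref * v_sr / config$v_sr_sarc

  ryr_count <- matrix(0L, nx, ny)
  lcc_count <- matrix(0L, nx, ny)
  offs <- caru_block_offsets(config$nodes_per_caru)
  log <- list(retries = 0L, shifts = 0L, dropped = 0L, clipped = 0L)

  place_block <- function(j0, k0) {
    js <- j0 + offs$dj; ks <- k0 + offs$dk
    if (any(js < 1 | js > nx | ks < 1 | ks > ny)) return(FALSE)
    if (any(ryr_count[cbind(js, ks)] > 0L)) return(FALSE)
    ryr_count[cbind(js, ks)] <<- config$ryrs_per_node
    TRUE
  }

  # --- perimeter CaRUs: exact period along the boundary path ---------------
  ring <- boundary_path(nx, ny)
  step_nodes <- max(1L, as.integer(round(config$perimeter_caru_period / dx)))
  sel <- seq(1L, nrow(ring), by = step_nodes)
  n_perim <- 0L
  for (q in sel) {
    j <- ring$j[q]; k <- ring$k[q]
    # block extends inward from the membrane node and forward along the path
    if (k == 1L) { j0 <- min(j, nx - 1L); k0 <- 1L }
    else if (k == ny) { j0 <- min(j, nx - 1L); k0 <- ny - 1L }
    else if (j == 1L) { j0 <- 1L; k0 <- min(k, ny - 1L) }
    else { j0 <- nx - 1L; k0 <- min(k, ny - 1L) }
    blk <- expand.grid(dj = 0:1, dk = 0:1)  # perimeter CaRUs use 2x2 blocks
    js <- j0 + blk$dj; ks <- k0 + blk$dk
    if (any(ryr_count[cbind(js, ks)] > 0L)) { log$dropped <- log$dropped + 1L; next }
    ryr_count[cbind(js, ks)] <- config$ryrs_per_node
    lcc_count[j, k] <- config$lccs_per_site
    n_perim <- n_perim + 1L
  }

  # --- interior CaRUs ------------------------------------------------------
  Ty <- config$interior_caru_period_y
  ky_margin <- 2 * dy + (if (config$nodes_per_caru == 6L) dy else 0)
  y_centers <- seq(Ty, config$Ly - Ty, by = Ty)
  y_centers <- y_centers[y_centers > ky_margin & y_centers < config$Ly - ky_margin]

  cand <- expand.grid(zc = zline_centers, yc = y_centers)
  keep <- seq_len(nrow(cand))
  if (!is.null(config$total_ryr_target)) {
    per_caru <- config$nodes_per_caru * config$ryrs_per_node
    n_keep <- min(nrow(cand), round(config$total_ryr_target / per_caru))
    keep <- sort(sample.int(nrow(cand), n_keep))
    log$dropped <- log$dropped + (nrow(cand) - n_keep)
  }

  n_interior <- 0L
  x_lo <- 2 * dx; x_hi <- config$Lx - 2 * dx
  for (q in keep) {
    zc <- cand$zc[q]; yc <- cand$yc[q]
    placed <- FALSE
    for (try in seq_len(20L)) {
      xc <- zc + if (config$sigma > 0) rnorm(1, 0, config$sigma) else 0
      if (xc < x_lo) { xc <- x_lo; log$clipped <- log$clipped + 1L }
      if (xc > x_hi) { xc <- x_hi; log$clipped <- log$clipped + 1L }
      j0 <- max(2L, min(nx - 2L, as.integer(floor(xc / dx + 0.5))))
      k0 <- max(2L, min(ny - 1L - max(offs$dk), anchor_k(yc, dy, config)))
      if (place_block(j0, k0)) { placed <- TRUE; break }
      log$retries <- log$retries + 1L
      if (config$sigma == 0) break  # degenerate Gaussian: nothing to re-sample
    }
    if (!placed) {
      # deterministic shift to the nearest free slot along x
      j0c <- max(2L, min(nx - 2L, as.integer(floor(zc / dx + 0.5))))
      k0 <- max(2L, min(ny - 1L - max(offs$dk), anchor_k(yc, dy, config)))
      for (shift in seq_len(nx)) {
        for (sgn in c(1L, -1L)) {
          j0 <- j0c + sgn * shift
          if (j0 < 2L || j0 > nx - 2L) next
          if (place_block(j0, k0)) { placed <- TRUE; break }
        }
        if (placed) break
      }
      if (placed) log$shifts <- log$shifts + 1L else log$dropped <- log$dropped + 1L
    }
    if (placed) n_interior <- n_interior + 1L
  }

  log$n_perimeter_carus <- n_perim
  log$n_interior_carus <- n_interior

  geom <- list(nx = nx, ny = ny, dx = dx, dy = dy,
               zline_centers = zline_centers,
               domain = domain, v_i = v_i, v_sr = v_sr,
               D_i = D_i, D_sr = D_sr,
               ryr_count = ryr_count, lcc_count = lcc_count,
               config = config, log = log)
  class(geom) <- "cell_geometry"
  geom
}

# Transversal anchor row for a CaRU block centred at yc: middle of the 2 (or
# 3, for 2x3 blocks) transversal rows.
anchor_k <- function(yc, dy, config) {
  if (config$nodes_per_caru == 6L) as.integer(floor(yc / dy))
  else as.integer(floor(yc / dy + 0.5))
}

# Ordered node path along the one-node-thick boundary ring.
boundary_path <- function(nx, ny) {
  j <- c(1:nx, rep(nx, ny - 2), nx:1, rep(1, ny - 2))
  k <- c(rep(1, nx), 2:(ny - 1), rep(ny, nx), (ny - 1):2)
  data.frame(j = as.integer(j), k = as.integer(k))
}

#' Build the 10-z-line wave-assay geometry
#'
#' A geometry with exactly 10 equidistant z-lines spaced 1.5 um apart
#' (centred in the domain), used by [run_wave_assay()] to measure
#' longitudinal wave-front speed.
#'
#' @param config A [geometry_config()]; `Lx` must accommodate the 13.5 um
#'   span of the 10 z-lines plus a margin.
#' @param n_zlines Number of z-lines (default 10).
#' @param spacing Z-line spacing (um, default 1.5).
#' @return A `cell_geometry`.
#' @export
build_wave_assay_geometry <- function(config, n_zlines = 10L, spacing = 1.5) {
  span <- (n_zlines - 1) * spacing
  if (config$Lx < span + 2 * spacing / 2)
    stop(sprintf("domain too short: need Lx >= %g um for %d z-lines at %g um spacing",
                 span + spacing, n_zlines, spacing), call. = FALSE)
  x0 <- (config$Lx - span) / 2
  centers <- x0 + spacing * (seq_len(n_zlines) - 1)
  build_geometry(config, zline_centers = centers)
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("cell_geometry: %g x %g um grid (%d x %d nodes, dx = %g um)\n",
              x$nx * x$dx, x$ny * x$dy, x$nx, x$ny, x$dx))
  cat(sprintf("  z-lines: %d; RyR-bearing nodes: %d (total %d RyRs); LCC sites: %d\n",
              length(x$zline_centers), sum(x$ryr_count > 0), sum(x$ryr_count),
              sum(x$lcc_count > 0)))
  invisible(x)
}

#' Partition RyR-bearing nodes into functional CaRUs
#'
#' Two RyR-bearing nodes belong to the same functional calcium release unit
#' if they are separated by at most `merge_distance` edge to edge (squares of
#' side `dx`), taking the transitive closure of that relation.  Centres are
#' RyR-count-weighted centroids; areas are member-node counts times
#' `dx * dy`.
#'
#' @param geom A `cell_geometry`.
#' @param merge_distance Edge-to-edge merge distance (um); defaults to the
#'   geometry config value (0.15 um).
#' @return A data.frame with one row per CaRU (`caru_id`, `center_x_um`,
#'   `center_y_um`, `n_ryr`, `n_nodes`, `area_um2`) with the node membership
#'   in `attr(, "members")` (list of linear node indices).
#' @export
identify_carus <- function(geom, merge_distance = NULL) {
  if (is.null(merge_distance)) merge_distance <- geom$config$merge_distance
  occ <- which(geom$ryr_count > 0L, arr.ind = TRUE)
  n <- nrow(occ)
  empty <- data.frame(caru_id = integer(0), center_x_um = numeric(0),
                      center_y_um = numeric(0), n_ryr = integer(0),
                      n_nodes = integer(0), area_um2 = numeric(0))
  if (n == 0) { attr(empty, "members") <- list(); return(empty) }

  dx <- geom$dx; dy <- geom$dy
  # neighbor offsets whose edge-to-edge gap is within the merge distance
  rj <- floor(merge_distance / dx) + 1L
  rk <- floor(merge_distance / dy) + 1L
  offs <- expand.grid(dj = -rj:rj, dk = -rk:rk)
  gapx <- pmax(0, (abs(offs$dj) - 1) * dx)
  gapy <- pmax(0, (abs(offs$dk) - 1) * dy)
  offs <- offs[sqrt(gapx^2 + gapy^2) <= merge_distance + 1e-12 &
                 !(offs$dj == 0 & offs$dk == 0), ]

  id_of <- matrix(0L, geom$nx, geom$ny)
  id_of[occ] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (q in seq_len(nrow(offs))) {
    js <- occ[, 1] + offs$dj[q]; ks <- occ[, 2] + offs$dk[q]
    ok <- js >= 1 & js <= geom$nx & ks >= 1 & ks <= geom$ny
    if (!any(ok)) next
    nb <- rep(0L, n); nb[ok] <- id_of[cbind(js[ok], ks[ok])]
    for (a in which(nb > 0L)) {
      ra <- find(a); rb <- find(nb[a])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  grp <- match(root, unique(root))

  w <- geom$ryr_count[occ]
  xs <- (occ[, 1] - 0.5) * dx; ys <- (occ[, 2] - 0.5) * dy
  res <- do.call(rbind, lapply(seq_len(max(grp)), function(g) {
    m <- grp == g
    data.frame(caru_id = g,
               center_x_um = sum(w[m] * xs[m]) / sum(w[m]),
               center_y_um = sum(w[m] * ys[m]) / sum(w[m]),
               n_ryr = sum(w[m]), n_nodes = sum(m),
               area_um2 = sum(m) * dx * dy)
  }))
  members <- split(as.integer(occ[, 1] + (occ[, 2] - 1L) * geom$nx), grp)
  attr(res, "members") <- members
  res
}

#' Cluster-level structural statistics
#'
#' Mean CaRU area, mean nearest-neighbour centre-to-centre distance and mean
#' longitudinal dispersion (distance of RyR-bearing nodes to the nearest
#' z-line centreline), averaged across a list of geometries (configurations).
#'
#' @param geoms A `cell_geometry` or list of them.
#' @param interior_only Restrict the dispersion measure to interior (non
#'   membrane-adjacent) RyR nodes (default TRUE; perimeter CaRUs have no
#'   associated z-line).
#' @return A `structure_stats` list: `mean_caru_area`,
#'   `mean_nn_center_distance`, `mean_longitudinal_dispersion`,
#'   `n_configurations`, plus per-configuration values.
#' @export
structure_statistics <- function(geoms, interior_only = TRUE) {
  if (inherits(geoms, "cell_geometry")) geoms <- list(geoms)
  stopifnot(length(geoms) >= 1)
  per <- lapply(geoms, function(g) {
    carus <- identify_carus(g)
    nn <- NA_real_
    if (nrow(carus) >= 2) {
      d <- as.matrix(stats::dist(carus[, c("center_x_um", "center_y_um")]))
      diag(d) <- Inf
      nn <- mean(apply(d, 1, min))
    } else warning("geometry with < 2 CaRUs: nearest-neighbour distance undefined")
    occ <- which(g$ryr_count > 0L, arr.ind = TRUE)
    if (interior_only) {
      edge <- occ[, 1] <= 2 | occ[, 1] >= g$nx - 1 | occ[, 2] <= 2 | occ[, 2] >= g$ny - 1
      occ <- occ[!edge, , drop = FALSE]
    }
    disp <- NA_real_
    if (nrow(occ) > 0) {
      xs <- (occ[, 1] - 0.5) * g$dx
      w <- g$ryr_count[occ]
      dmin <- vapply(xs, function(x) min(abs(x - g$zline_centers)), numeric(1))
      disp <- sum(w * dmin) / sum(w)
    }
    c(area = mean(carus$area_um2), nn = nn, disp = disp, n_caru = nrow(carus))
  })
  per <- do.call(rbind, per)
  out <- list(mean_caru_area = mean(per[, "area"]),
              mean_nn_center_distance = mean(per[, "nn"]),
              mean_longitudinal_dispersion = mean(per[, "disp"]),
              mean_n_carus = mean(per[, "n_caru"]),
              n_configurations = nrow(per),
              per_configuration = as.data.frame(per))
  class(out) <- "structure_stats"
  out
}

#' @export
print.structure_stats <- function(x, ...) {
  cat(sprintf("structure_stats over %d configuration(s):\n", x$n_configurations))
  cat(sprintf("  mean CaRU area:            %.4f um^2\n", x$mean_caru_area))
  cat(sprintf("  mean NN centre distance:   %.3f um\n", x$mean_nn_center_distance))
  cat(sprintf("  mean longitudinal spread:  %.3f um\n", x$mean_longitudinal_dispersion))
  invisible(x)
}
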