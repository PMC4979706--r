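#' Distance-decay regression and residuals at pair midpoints
#'
#' Ordinary least squares of pairwise genetic distance on Euclidean
#' distance over the n(n-1)/2 site pairs; each pair contributes its
#' residual (observed - predicted) at the arithmetic midpoint of the two
#' site centroids. Infinite genetic distances (e.g. capped linearized
#' F_ST) are excluded with a logged count.
#'
#' @param d_gen [dist_matrix()] of genetic distances.
#' @param sites a [site_map()] covering the same labels.
#' @param log_euclidean regress on log-transformed Euclidean distance.
#' @return list of class `residual_surface`: `slope`, `intercept`,
#'   `residuals` (per pair), `midpoints` (x, y per pair), `pairs`,
#'   `n_excluded_infinite`, `r_squared`.
#' @export
distance_decay_residuals <- function(d_gen, sites, log_euclidean = FALSE) {
  stopifnot(inherits(d_gen, "dist_matrix"), inherits(sites, "site_map"))
  d_eu <- euclidean_distances(sites)
  check_matched_labels(d_gen, d_eu)
  k <- length(d_gen$labels)
  if (k < 3) {
    if (k == 2) warning("2 sites: regression is a perfect fit, residuals 0")
    else stop("need >= 2 sites")
  }
  ut <- which(upper.tri(d_gen$values), arr.ind = TRUE)
  g <- d_gen$values[upper.tri(d_gen$values)]
  e <- d_eu$values[upper.tri(d_eu$values)]
  if (log_euclidean) e <- log(e)
  fin <- is.finite(g) & is.finite(e)
  n_exc <- sum(!fin)
  if (n_exc > 0)
    message(n_exc, " pair(s) with non-finite distance excluded from the regression")
  fit <- stats::lm.fit(cbind(1, e[fin]), g[fin])
  coefs <- fit$coefficients
  resid <- g[fin] - (coefs[1] + coefs[2] * e[fin])
  si <- ut[fin, 1]; sj <- ut[fin, 2]
  mx <- (sites$x[si] + sites$x[sj]) / 2
  my <- (sites$y[si] + sites$y[sj]) / 2
  ss_tot <- sum((g[fin] - mean(g[fin]))^2)
  structure(list(slope = unname(coefs[2]), intercept = unname(coefs[1]),
                 residuals = resid,
                 midpoints = data.frame(x = mx, y = my),
                 pairs = data.frame(from = d_gen$labels[si],
                                    to = d_gen$labels[sj]),
                 n_excluded_infinite = n_exc,
                 r_squared = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_),
            class = "residual_surface")
}

#' @export
print.residual_surface <- function(x, ...) {
  cat(sprintf("residual_surface: %d pairs, slope %.4g, intercept %.4g, R^2 %.3f\n",
              nrow(x$midpoints), x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Inverse-distance-weighted interpolation of pair residuals
#'
#' Cell value = sum(w_k e_k) / sum(w_k) with w_k = 1/dist^power from the
#' cell center to each pair midpoint; a cell coincident with a midpoint
#' takes that midpoint's residual exactly. Cells with no midpoint within
#' `search_radius` become nodata.
#'
#' @param rs a `residual_surface`.
#' @param grid_spec either a [raster_grid()] supplying geometry, or NULL to
#'   use `n_cells` x `n_cells` over the midpoint bounding box + 10% margin.
#' @param idw_power inverse-distance exponent (default 2).
#' @param search_radius km; midpoints farther than this do not contribute.
#' @param n_cells default grid resolution (default 100).
#' @return a `raster_grid` of interpolated residuals. Residuals can be
#'   negative, so this grid does not carry the strict-positivity constraint
#'   of resistance rasters; treat it as a surface, not a resistance input.
#' @export
idw_residual_surface <- function(rs, grid_spec = NULL, idw_power = 2,
                                 search_radius = Inf, n_cells = 100) {
  stopifnot(inherits(rs, "residual_surface"))
  if (!nrow(rs$midpoints)) stop("no midpoints to interpolate")
  geom <- idw_grid_geometry(rs$midpoints, grid_spec, n_cells)
  ctr <- geom$centers
  vals <- matrix(NA_real_, geom$n_rows, geom$n_cols)
  e <- rs$residuals
  for (i in seq_len(geom$n_rows)) {
    dy2 <- (ctr$y[i] - rs$midpoints$y)^2
    for (j in seq_len(geom$n_cols)) {
      d <- sqrt((ctr$x[j] - rs$midpoints$x)^2 + dy2)
      hit <- which(d < 1e-9)
      if (length(hit)) { vals[i, j] <- e[hit[1]]; next }
      use <- d <= search_radius
      if (!any(use)) next
      w <- 1 / d[use]^idw_power
      vals[i, j] <- sum(w * e[use]) / sum(w)
    }
  }
  surface_grid(vals, geom$cell_size, geom$origin)
}

# raster_grid without the positivity constraint (residual surfaces can be
# negative); same structure and class, constructed directly
surface_grid <- function(values, cell_size, origin) {
  structure(list(values = values, n_rows = nrow(values),
                 n_cols = ncol(values), cell_size = cell_size,
                 origin = as.numeric(origin), nodata = is.na(values)),
            class = "raster_grid")
}

idw_grid_geometry <- function(midpoints, grid_spec, n_cells) {
  if (inherits(grid_spec, "raster_grid")) {
    g <- grid_spec
    return(list(n_rows = g$n_rows, n_cols = g$n_cols,
                cell_size = g$cell_size, origin = g$origin,
                centers = raster_cell_centers(g)))
  }
  xr <- range(midpoints$x); yr <- range(midpoints$y)
  margin <- 0.1 * max(diff(xr), diff(yr), 1)
  xr <- xr + c(-margin, margin); yr <- yr + c(-margin, margin)
  cell <- max(diff(xr), diff(yr)) / n_cells
  nc <- max(2L, ceiling(diff(xr) / cell)); nr <- max(2L, ceiling(diff(yr) / cell))
  g <- list(n_rows = nr, n_cols = nc, cell_size = cell,
            origin = c(xr[1], yr[1]))
  g$centers <- raster_cell_centers(structure(g, class = "raster_grid"))
  g
}

#' Permutation null for the residual surface
#'
#' Randomizes the genetic matrix with respect to geography by permuting
#' its rows and columns by a single random site relabeling per replicate,
#' recomputing regression residuals and the IDW surface each time. Returns
#' per-cell null quantiles and the observed surface's exceedance map.
#'
#' @param d_gen,sites as [distance_decay_residuals()].
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param grid_spec,idw_power,search_radius,n_cells as
#'   [idw_residual_surface()].
#' @param probs null quantiles to return (default 2.5%, 50%, 97.5%).
#' @return list: `observed` (raster_grid), `null_quantiles` (list of
#'   raster_grid per prob), `exceedance` (raster_grid: fraction of null
#'   surfaces the observed cell exceeds), `n_perm`.
#' @export
surface_permutation_null <- function(d_gen, sites, n_perm = 99, seed = 1,
                                     grid_spec = NULL, idw_power = 2,
                                     search_radius = Inf, n_cells = 25,
                                     probs = c(0.025, 0.5, 0.975)) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  obs_rs <- distance_decay_residuals(d_gen, sites)
  obs <- idw_residual_surface(obs_rs, grid_spec, idw_power, search_radius, n_cells)
  k <- length(d_gen$labels)
  null_vals <- array(NA_real_, c(obs$n_rows, obs$n_cols, n_perm))
  for (b in seq_len(n_perm)) {
    # permutation 1 is the identity: the observed surface is a member of
    # its own null set
    perm <- if (b == 1) seq_len(k) else sample.int(k)
    dv <- d_gen$values[perm, perm]
    dimnames(dv) <- list(d_gen$labels, d_gen$labels)
    dp <- structure(list(labels = d_gen$labels, values = dv,
                         method = d_gen$method,
                         has_infinite = d_gen$has_infinite),
                    class = "dist_matrix")
    rs <- distance_decay_residuals(dp, sites)
    null_vals[, , b] <- idw_residual_surface(rs, obs, idw_power,
                                             search_radius)$values
  }
  qs <- lapply(probs, function(p)
    surface_grid(apply(null_vals, c(1, 2), stats::quantile, probs = p,
                       na.rm = TRUE),
                 obs$cell_size, obs$origin))
  names(qs) <- paste0("q", probs)
  exceed <- surface_grid(
    apply(sweep(null_vals, c(1, 2), obs$values, "<"), c(1, 2), mean, na.rm = TRUE),
    obs$cell_size, obs$origin)
  list(observed = obs, null_quantiles = qs, exceedance = exceed,
       n_perm = n_perm)
}
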