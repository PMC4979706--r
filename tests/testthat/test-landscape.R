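test_that("distance-decay regression: exact linear and constant cases", {
  sm <- site_map(paste0("s", 1:4), c(0, 10, 20, 40), c(0, 0, 0, 0))
  d_eu <- euclidean_distances(sm)
  # genetic distance exactly linear in Euclidean -> all residuals 0
  gv <- 0.02 * d_eu$values; dimnames(gv) <- dimnames(d_eu$values)
  rs <- distance_decay_residuals(dist_matrix(gv), sm)
  expect_equal(rs$residuals, rep(0, 6), tolerance = 1e-12)
  expect_equal(rs$slope, 0.02, tolerance = 1e-12)
  # constant genetic distance -> slope 0, residuals 0
  cv <- matrix(0.5, 4, 4, dimnames = dimnames(d_eu$values)); diag(cv) <- 0
  rs2 <- distance_decay_residuals(dist_matrix(cv), sm)
  expect_equal(rs2$slope, 0, tolerance = 1e-12)
  expect_equal(rs2$residuals, rep(0, 6), tolerance = 1e-12)
})

test_that("5-site residuals equal the closed-form OLS oracle", {
  set.seed(19)
  sm <- site_map(paste0("s", 1:5), runif(5, 0, 100), runif(5, 0, 100))
  d_eu <- euclidean_distances(sm)
  gv <- 0.3 + 0.01 * d_eu$values + matrix(rnorm(25, 0, 0.05), 5)
  gv <- (gv + t(gv)) / 2; diag(gv) <- 0
  dimnames(gv) <- dimnames(d_eu$values)
  rs <- distance_decay_residuals(dist_matrix(gv), sm)
  oracle <- oracle_ols_residuals(upper_vec(d_eu), upper_vec(dist_matrix(gv)))
  expect_equal(rs$residuals, oracle, tolerance = 1e-10)
})

test_that("infinite linearized distances are excluded with a count", {
  sm <- site_map(paste0("s", 1:4), c(0, 10, 20, 40), rep(0, 4))
  gv <- euclidean_distances(sm)$values * 0.01
  gv[1, 2] <- gv[2, 1] <- Inf
  dimnames(gv) <- list(sm$site, sm$site)
  expect_message(rs <- distance_decay_residuals(dist_matrix(gv), sm),
                 "1 pair")
  expect_equal(length(rs$residuals), 5)
  expect_equal(rs$n_excluded_infinite, 1)
})

test_that("IDW surface: constant, exact hit, and hand-computed weights", {
  sm <- site_map(paste0("s", 1:3), c(0, 10, 20), c(0, 0, 10))
  gv <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
               dimnames = list(sm$site, sm$site))
  rs <- distance_decay_residuals(dist_matrix(gv), sm)
  # constant residuals c -> constant surface c
  rs_const <- rs; rs_const$residuals <- rep(0.25, 3)
  g <- idw_residual_surface(rs_const, n_cells = 10)
  expect_true(all(abs(g$values[!g$nodata] - 0.25) < 1e-9))
  # exact hit: cell center on a midpoint takes that residual exactly
  rs_hit <- rs; rs_hit$residuals <- c(0.7, -0.2, 0.1)
  base <- raster_grid(matrix(1, 1, 1), cell_size = 2,
                      origin = c(rs_hit$midpoints$x[1] - 1,
                                 rs_hit$midpoints$y[1] - 1))
  ghit <- idw_residual_surface(rs_hit, base)
  expect_equal(ghit$values[1, 1], 0.7)
  # two midpoints at known distances: hand-computed weighted mean
  rs2 <- rs
  rs2$midpoints <- data.frame(x = c(0, 4), y = c(0, 0))
  rs2$residuals <- c(1, -1)
  cellg <- raster_grid(matrix(1, 1, 1), cell_size = 2, origin = c(0, -1))
  # cell center at (1, 0): distances 1 and 3, weights 1 and 1/9
  g2 <- idw_residual_surface(rs2, cellg, idw_power = 2)
  expect_equal(g2$values[1, 1], (1 * 1 + (1 / 9) * -1) / (1 + 1 / 9),
               tolerance = 1e-12)
  # surface bounded by the residual range
  gb <- idw_residual_surface(rs_hit, n_cells = 12)
  expect_true(all(gb$values[!gb$nodata] <= max(rs_hit$residuals) + 1e-12))
  expect_true(all(gb$values[!gb$nodata] >= min(rs_hit$residuals) - 1e-12))
})

test_that("surface permutation null contains the observed surface", {
  set.seed(3)
  sm <- site_map(paste0("s", 1:5), runif(5, 0, 50), runif(5, 0, 50))
  gv <- euclidean_distances(sm)$values * 0.01 + 0.2
  diag(gv) <- 0
  gv <- gv + matrix(rnorm(25, 0, 0.02), 5); gv <- (gv + t(gv)) / 2; diag(gv) <- 0
  gv <- pmax(gv, 0); dimnames(gv) <- list(sm$site, sm$site)
  pn <- surface_permutation_null(dist_matrix(gv), sm, n_perm = 19, seed = 5,
                                 n_cells = 8)
  # permutation 1 is the identity, so per-cell exceedance is < 1 everywhere
  ex <- pn$exceedance$values[!pn$exceedance$nodata]
  expect_true(all(ex < 1))
  expect_true(all(ex >= 0))
  expect_equal(pn$n_perm, 19)
  expect_error(surface_permutation_null(dist_matrix(gv), sm, n_perm = 0),
               "n_perm")
})

test_that("effective resistance reproduces series and parallel circuits", {
  r <- raster_grid(matrix(1, 1, 3), cell_size = 1, origin = c(0, 0))
  sm <- site_map(c("a", "b"), c(0.5, 2.5), c(0.5, 0.5))
  expect_equal(resistance_distance(r, sm)$values["a", "b"], 2)
  # two disjoint identical paths -> half the single-path resistance
  v <- matrix(1, 3, 3); v[2, 2] <- NA
  r2 <- raster_grid(v, 1, c(0, 0))
  sm2 <- site_map(c("a", "b"), c(0.5, 2.5), c(1.5, 1.5))
  expect_equal(resistance_distance(r2, sm2)$values["a", "b"], 2)
  # doubling per-cell resistance doubles the effective resistance
  r3 <- raster_grid(matrix(2, 1, 3), 1, c(0, 0))
  expect_equal(resistance_distance(r3, sm)$values["a", "b"], 4)
})

test_that("random 6x6 rasters match the dense pseudoinverse oracle to 1e-8", {
  set.seed(23)
  for (rep in 1:5) {
    vals <- matrix(exp(rnorm(36, 0, 1)), 6, 6)
    r <- raster_grid(vals, 1, c(0, 0))
    sm <- site_map(c("a", "b", "c", "d"),
                   c(0.5, 5.5, 2.5, 4.5), c(0.5, 5.5, 3.5, 1.5))
    d <- resistance_distance(r, sm)
    # dense Laplacian pseudoinverse oracle
    cell_id <- matrix(seq_len(36), 6, 6)
    g <- foxscape:::resistance_graph(r, cell_id)
    L <- matrix(0, 36, 36)
    for (e in seq_along(g$from)) {
      L[g$from[e], g$to[e]] <- L[g$from[e], g$to[e]] - g$cond[e]
      L[g$to[e], g$from[e]] <- L[g$to[e], g$from[e]] - g$cond[e]
    }
    diag(L) <- -rowSums(L)
    Lp <- MASS::ginv(L)
    nd <- cell_id[foxscape:::raster_locate(r, sm$x, sm$y)]
    oracle <- outer(seq_len(4), seq_len(4), Vectorize(function(i, j)
      Lp[nd[i], nd[i]] + Lp[nd[j], nd[j]] - 2 * Lp[nd[i], nd[j]]))
    expect_lt(max(abs(d$values - oracle)), 1e-8)
    # metric properties: symmetry and triangle inequality
    expect_equal(d$values, t(d$values))
    for (i in 1:4) for (j in 1:4) for (k in 1:4)
      expect_lte(d$values[i, j], d$values[i, k] + d$values[k, j] + 1e-10)
  }
})

test_that("disconnected components yield flagged infinite resistance", {
  v <- matrix(1, 3, 3); v[, 2] <- NA
  r <- raster_grid(v, 1, c(0, 0))
  sm <- site_map(c("a", "b"), c(0.5, 2.5), c(1.5, 1.5))
  expect_warning(d <- resistance_distance(r, sm), "disconnected")
  expect_true(is.infinite(d$values["a", "b"]))
  expect_true(d$has_infinite)
  # site off non-nodata cells errors with the site named
  smbad <- site_map("a", 1.5, 1.5)
  expect_error(suppressWarnings(resistance_distance(r, smbad)), "a")
})

test_that("uniform-raster resistance is monotone in collinear distance", {
  r <- raster_grid(matrix(1, 3, 12), 1, c(0, 0))
  sm <- site_map(paste0("s", 1:4), c(0.5, 1.5, 4.5, 10.5), rep(1.5, 4))
  d <- resistance_distance(r, sm)
  eu <- euclidean_distances(sm)
  expect_equal(cor(upper_vec(d), upper_vec(eu), method = "spearman"), 1)
})

test_that("suitability inversion floors near-zero suitabilities", {
  s <- raster_grid(matrix(c(1, 0.5, 0.001, 0.2), 2, 2), 1, c(0, 0))
  r <- suitability_to_resistance(s, floor = 0.01)
  expect_equal(r$values[1, 1], 1)
  expect_equal(r$values[2, 1], 2)
  expect_equal(r$values[1, 2], 100)  # floored at 1/0.01
})

test_that("Mantel r matches vegan and self-correlation attains min p", {
  set.seed(3)
  k <- 7
  xy <- matrix(runif(2 * k), k)
  dx <- as.matrix(dist(xy)); dimnames(dx) <- list(letters[1:k], letters[1:k])
  dy <- dx + matrix(abs(rnorm(k * k, 0, 0.1)), k)
  dy <- (dy + t(dy)) / 2; diag(dy) <- 0; dimnames(dy) <- dimnames(dx)
  mx <- dist_matrix(dx); my <- dist_matrix(dy)
  ours <- mantel_test(mx, my, n_perm = 499, seed = 9)
  ref <- vegan::mantel(stats::as.dist(dx), stats::as.dist(dy),
                       permutations = 499)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.02)
  self <- mantel_test(mx, mx, n_perm = 99, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 100)
})

test_that("exact enumeration p on 4x4 matrices matches the oracle", {
  set.seed(44)
  m1 <- matrix(runif(16), 4); m1 <- (m1 + t(m1)) / 2; diag(m1) <- 0
  m2 <- matrix(runif(16), 4); m2 <- (m2 + t(m2)) / 2; diag(m2) <- 0
  dimnames(m1) <- dimnames(m2) <- list(letters[1:4], letters[1:4])
  d1 <- dist_matrix(m1); d2 <- dist_matrix(m2)
  res <- mantel_test(d1, d2, all_perms = TRUE)
  expect_equal(res$n_perm, 24)
  # brute-force oracle: recompute r over all 24 relabelings directly
  perms <- foxscape:::all_permutations(4)
  x <- m1[upper.tri(m1)]
  rs <- vapply(perms, function(p) {
    mm <- m2[p, p]; stats::cor(x, mm[upper.tri(mm)])
  }, numeric(1))
  p_oracle <- (1 + sum(rs >= res$r - 1e-12)) / 25
  expect_equal(res$p, p_oracle)
})

test_that("log transforms are applied and guarded", {
  m <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  mz <- matrix(c(0, 0, 0, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(mantel_test(dist_matrix(mz), dist_matrix(m), 99, log_x = TRUE),
               "strictly positive")
  expect_error(mantel_test(dist_matrix(mz), dist_matrix(mz), 99),
               "zero-variance")
})

test_that("partial Mantel: constant z reduces to simple, y = z kills x|z", {
  set.seed(12)
  k <- 6
  mk <- function() {
    m <- matrix(runif(k * k, 1, 2), k); m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:k], letters[1:k])
    dist_matrix(m)
  }
  x <- mk(); y <- mk()
  zc <- dist_matrix(matrix(1, k, k, dimnames = list(letters[1:k], letters[1:k])) -
                      diag(1, k))
  simple <- mantel_test(x, y, n_perm = 199, seed = 7)
  partial <- partial_mantel_test(x, y, zc, n_perm = 199, seed = 7)
  expect_equal(partial$r, simple$r, tolerance = 1e-10)
  # y regressed on itself leaves no signal
  p2 <- partial_mantel_test(x, y, y, n_perm = 199, seed = 8)
  expect_lt(abs(p2$r), 0.35)
  expect_gt(p2$p, 0.05)
})

test_that("partial Mantel separates true resistance from Euclidean proxy", {
  set.seed(29)
  k <- 8
  xy <- matrix(runif(2 * k, 0, 100), k)
  eu <- as.matrix(dist(xy))
  res <- eu * matrix(runif(k * k, 0.5, 3), k)  # resistance distorts distance
  res <- (res + t(res)) / 2; diag(res) <- 0
  gen <- 0.01 * res + matrix(rnorm(k * k, 0, 0.02), k)
  gen <- (gen + t(gen)) / 2; diag(gen) <- 0; gen <- pmax(gen, 0)
  lab <- letters[1:k]
  dimnames(eu) <- dimnames(res) <- dimnames(gen) <- list(lab, lab)
  dg <- dist_matrix(gen); dr <- dist_matrix(res); de <- dist_matrix(eu)
  p_res <- partial_mantel_test(dg, dr, de, n_perm = 499, seed = 2)
  p_eu <- partial_mantel_test(dg, de, dr, n_perm = 499, seed = 2)
  expect_lt(p_res$p, 0.05)   # resistance explains genetics beyond distance
  expect_gt(p_eu$p, p_res$p) # the reciprocal control is weaker
})
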