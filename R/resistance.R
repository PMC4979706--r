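#' Circuit-theory effective resistance between sites on a raster
#'
#' The raster is turned into an electrical network: nodes are non-nodata
#' cells, edges join 4-neighbors with conductance equal to the mean of the
#' two cells' conductances (1/resistance). Pairwise effective resistance is
#' obtained by solving the graph Laplacian system with one node grounded
#' (sparse Cholesky, factored once per connected component). Site pairs in
#' different components get +Inf, flagged.
#'
#' @param r a [raster_grid()] of per-cell resistances.
#' @param sites a [site_map()]; every site must fall on a non-nodata cell.
#' @return a [dist_matrix()] of effective resistances.
#' @export
resistance_distance <- function(r, sites) {
  stopifnot(inherits(r, "raster_grid"), inherits(sites, "site_map"))
  if (any(r$values[!r$nodata] <= 0))
    stop("resistance values must be strictly positive where not nodata")
  loc <- raster_locate(r, sites$x, sites$y)
  cell_id <- matrix(NA_integer_, r$n_rows, r$n_cols)
  keep <- !r$nodata
  cell_id[keep] <- seq_len(sum(keep))
  site_node <- cell_id[loc]
  if (anyNA(site_node)) {
    bad <- which(is.na(site_node))
    stop("site(s) on nodata cells: ", paste(sites$site[bad], collapse = ", "))
  }
  g <- resistance_graph(r, cell_id)
  n_nodes <- sum(keep)
  # connected components via label propagation on the sparse adjacency
  comp <- graph_components(g$from, g$to, n_nodes)
  k <- nrow(sites)
  out <- matrix(Inf, k, k, dimnames = list(sites$site, sites$site))
  diag(out) <- 0
  for (cp in unique(comp[site_node])) {
    in_comp <- which(comp == cp)
    s_here <- which(comp[site_node] == cp)
    if (length(s_here) < 2) next
    remap <- integer(n_nodes); remap[in_comp] <- seq_along(in_comp)
    e_in <- comp[g$from] == cp
    L <- Matrix::sparseMatrix(
      i = c(remap[g$from[e_in]], remap[g$to[e_in]]),
      j = c(remap[g$to[e_in]], remap[g$from[e_in]]),
      x = -c(g$cond[e_in], g$cond[e_in]),
      dims = c(length(in_comp), length(in_comp)))
    diag(L) <- -Matrix::rowSums(L)
    ground <- remap[site_node[s_here[1]]]
    idx <- setdiff(seq_along(in_comp), ground)
    Lr <- L[idx, idx]
    fac <- Matrix::Cholesky(Lr, LDL = FALSE, perm = TRUE)
    # potentials for unit current injected at each non-ground site node
    pos <- match(remap[site_node[s_here]], idx)  # NA for the ground site
    v <- matrix(0, length(in_comp), length(s_here))
    for (a in seq_along(s_here)) {
      if (is.na(pos[a])) next
      b <- rep(0, length(idx)); b[pos[a]] <- 1
      v[idx, a] <- as.numeric(Matrix::solve(fac, b))
    }
    nd <- remap[site_node[s_here]]
    for (a in seq_len(length(s_here) - 1)) for (b2 in seq((a + 1), length(s_here))) {
      # R_eff(a,b) = v_a(a) + v_b(b) - v_a(b) - v_b(a) with ground fixed
      reff <- v[nd[a], a] + v[nd[b2], b2] - v[nd[b2], a] - v[nd[a], b2]
      ia <- s_here[a]; ib <- s_here[b2]
      out[ia, ib] <- out[ib, ia] <- reff
    }
  }
  if (any(is.infinite(out[upper.tri(out)])))
    warning("site pair(s) in disconnected raster components: resistance +Inf")
  dist_matrix(out, method = "effective-resistance")
}

# 4-neighbor edge list with mean-conductance edge weights
resistance_graph <- function(r, cell_id) {
  cond <- 1 / r$values
  cond[r$nodata] <- NA
  from <- integer(0); to <- integer(0); cw <- numeric(0)
  # horizontal neighbors
  a <- cell_id[, -r$n_cols, drop = FALSE]; b <- cell_id[, -1, drop = FALSE]
  ca <- cond[, -r$n_cols, drop = FALSE]; cb <- cond[, -1, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  from <- c(from, a[ok]); to <- c(to, b[ok]); cw <- c(cw, (ca[ok] + cb[ok]) / 2)
  # vertical neighbors
  a <- cell_id[-r$n_rows, , drop = FALSE]; b <- cell_id[-1, , drop = FALSE]
  ca <- cond[-r$n_rows, , drop = FALSE]; cb <- cond[-1, , drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  from <- c(from, a[ok]); to <- c(to, b[ok]); cw <- c(cw, (ca[ok] + cb[ok]) / 2)
  list(from = from, to = to, cond = cw)
}

# connected components of an undirected edge list (union-find)
graph_components <- function(from, to, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(from)) {
    ra <- find(from[e]); rb <- find(to[e])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}
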