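#' Mantel test of matrix correlation
#'
#' r is the Pearson correlation of the off-diagonal upper triangles; the
#' permutation null simultaneously permutes rows and columns of the second
#' matrix by a random site relabeling. The default alternative is
#' one-tailed positive (association hypotheses are directional here):
#' p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1).
#'
#' @param x,y [dist_matrix()] objects with matched labels.
#' @param n_perm number of permutations (default 9999).
#' @param seed RNG seed.
#' @param log_x,log_y log-transform a (strictly positive) matrix first.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param all_perms enumerate all label permutations instead of sampling
#'   (exact test; only sensible for few labels).
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `partial`
#'   (FALSE), `alternative`.
#' @export
mantel_test <- function(x, y, n_perm = 9999, seed = 1,
                        log_x = FALSE, log_y = FALSE,
                        alternative = c("greater", "two.sided"),
                        all_perms = FALSE) {
  alternative <- match.arg(alternative)
  check_matched_labels(x, y)
  xv <- mantel_prepare(x, log_x, "x")
  yv <- mantel_prepare(y, log_y, "y")
  fin <- is.finite(xv$tri) & is.finite(yv$tri)
  if (any(!fin))
    message(sum(!fin), " pair(s) with non-finite distance excluded")
  sdx <- stats::sd(xv$tri[fin]); sdy <- stats::sd(yv$tri[fin])
  if (is.na(sdx) || is.na(sdy) || sdx == 0 || sdy == 0)
    stop("zero-variance distance triangle: r undefined")
  k <- nrow(xv$m)
  tri_cor <- function(ym) {
    yt <- ym[upper.tri(ym)]
    stats::cor(xv$tri[fin], yt[fin])
  }
  r_obs <- tri_cor(yv$m)
  set.seed(seed)
  perms <- if (all_perms) all_permutations(k) else
    replicate(n_perm, sample.int(k), simplify = FALSE)
  n_perm <- length(perms)
  r_perm <- vapply(perms, function(p) tri_cor(yv$m[p, p]), numeric(1))
  p <- mantel_pvalue(r_obs, r_perm, alternative)
  structure(list(r = r_obs, p = p, n_perm = n_perm, partial = FALSE,
                 conditioning = NULL, alternative = alternative),
            class = "mantel_result")
}

#' Partial Mantel test (correlation of x and y controlling z)
#'
#' Each of x and y is regressed element-wise on z over the triangle; the
#' residual matrices are correlated, and significance comes from permuting
#' the rows/columns of the y residual matrix (residual-permutation method).
#'
#' @param x,y,z [dist_matrix()] objects with matched labels.
#' @inheritParams mantel_test
#' @param log_z log-transform z.
#' @return a `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel_test <- function(x, y, z, n_perm = 9999, seed = 1,
                                log_x = FALSE, log_y = FALSE, log_z = FALSE,
                                alternative = c("greater", "two.sided"),
                                all_perms = FALSE) {
  alternative <- match.arg(alternative)
  check_matched_labels(x, y, z)
  xv <- mantel_prepare(x, log_x, "x")
  yv <- mantel_prepare(y, log_y, "y")
  zv <- mantel_prepare(z, log_z, "z")
  fin <- is.finite(xv$tri) & is.finite(yv$tri) & is.finite(zv$tri)
  if (any(!fin))
    message(sum(!fin), " pair(s) with non-finite distance excluded")
  sdx <- stats::sd(xv$tri[fin]); sdy <- stats::sd(yv$tri[fin])
  if (is.na(sdx) || is.na(sdy) || sdx == 0 || sdy == 0)
    stop("zero-variance distance triangle: r undefined")
  resid_mat <- function(v, m) {
    # residuals of triangle on z triangle, refilled into matrix form
    zt <- zv$tri
    if (stats::sd(zt[fin]) == 0) {
      rm <- m; rm[] <- 0
      rm[upper.tri(rm)] <- v - mean(v[fin])
    } else {
      fit <- stats::lm.fit(cbind(1, zt[fin]), v[fin])
      res <- rep(NA_real_, length(v))
      res[fin] <- fit$residuals
      rm <- m; rm[] <- 0
      rm[upper.tri(rm)] <- res
    }
    rm[lower.tri(rm)] <- t(rm)[lower.tri(rm)]
    rm
  }
  rx <- resid_mat(xv$tri, xv$m)
  ry <- resid_mat(yv$tri, yv$m)
  k <- nrow(rx)
  tri_cor <- function(ym) {
    a <- rx[upper.tri(rx)]; b <- ym[upper.tri(ym)]
    ok <- !is.na(a) & !is.na(b)
    stats::cor(a[ok], b[ok])
  }
  r_obs <- tri_cor(ry)
  set.seed(seed)
  perms <- if (all_perms) all_permutations(k) else
    replicate(n_perm, sample.int(k), simplify = FALSE)
  n_perm <- length(perms)
  r_perm <- vapply(perms, function(p) tri_cor(ry[p, p]), numeric(1))
  p <- mantel_pvalue(r_obs, r_perm, alternative)
  structure(list(r = r_obs, p = p, n_perm = n_perm, partial = TRUE,
                 conditioning = z$method, alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%sMantel: r = %.4f, p = %.5g (%s, %d permutations%s)\n",
              if (x$partial) "partial " else "", x$r, x$p, x$alternative,
              x$n_perm,
              if (x$partial) paste0(", controlling ",
                                    x$conditioning %||% "z") else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mantel_prepare <- function(d, do_log, nm) {
  stopifnot(inherits(d, "dist_matrix"))
  m <- d$values
  if (do_log) {
    tri <- m[upper.tri(m)]
    if (any(tri[is.finite(tri)] <= 0))
      stop("log transform requested for '", nm,
           "' but its off-diagonal entries are not strictly positive")
    m[upper.tri(m) | lower.tri(m)] <- log(m[upper.tri(m) | lower.tri(m)])
  }
  list(m = m, tri = m[upper.tri(m)])
}

mantel_pvalue <- function(r_obs, r_perm, alternative) {
  r_perm <- r_perm[is.finite(r_perm)]
  n <- length(r_perm)
  if (alternative == "greater")
    (1 + sum(r_perm >= r_obs - 1e-12)) / (n + 1)
  else
    (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n + 1)
}

all_permutations <- function(k) {
  if (k > 8) stop("full enumeration limited to 8 labels")
  out <- list(1L)
  for (i in 2:k) {
    new <- list()
    for (p in out) for (pos in seq_len(i)) {
      new[[length(new) + 1L]] <- append(p, i, after = pos - 1L)
    }
    out <- new
  }
  out
}
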