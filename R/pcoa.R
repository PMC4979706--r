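#' Principal coordinates of individual genotypic distances
#'
#' Squared inter-individual genotypic distance by the Smouse-Peakall
#' per-locus allele-mismatch metric (0 for identical genotypes; 1 between a
#' heterozygote and a genotype sharing one allele; 2 between heterozygotes
#' sharing none; 3 between a homozygote and a heterozygote sharing none;
#' 4 between different homozygotes), summed over loci with pairwise
#' deletion. The summed matrix is Gower double-centered and
#' eigendecomposed; axes with positive eigenvalues are returned, negative
#' eigenvalues reported.
#'
#' Pairs with no typed locus in common are imputed at the mean squared
#' distance of all computable pairs, with a logged count.
#'
#' @param gt a [genotype_table()].
#' @return list of class `ordination_result`: `coordinates` (individuals x
#'   axes, centered), `eigenvalues` (all, sorted), `percent_variance` (per
#'   positive axis), `n_imputed_pairs`, `site`.
#' @export
pcoa_individuals <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  n <- length(gt$individuals)
  if (n < 3) stop("PCoA needs >= 3 individuals")
  d2 <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (l in seq_along(gt$loci)) {
    a1 <- gt$alleles[, l, 1]; a2 <- gt$alleles[, l, 2]
    ok <- which(!is.na(a1))
    if (length(ok) < 2) next
    dl <- smouse_peakall_locus(a1[ok], a2[ok])
    d2[ok, ok] <- d2[ok, ok] + dl
    cnt[ok, ok] <- cnt[ok, ok] + 1L
  }
  computable <- cnt > 0 | row(cnt) == col(cnt)
  n_imputed <- sum(!computable[upper.tri(computable)])
  if (n_imputed > 0) {
    fill <- mean(d2[upper.tri(d2)][computable[upper.tri(computable)]])
    d2[!computable] <- fill
    message(n_imputed, " pair(s) without shared typed loci imputed at the mean squared distance")
  }
  # Gower double-centering of the squared-distance matrix
  g <- -0.5 * (d2 - outer(rowMeans(d2), rep(1, n)) -
                 outer(rep(1, n), colMeans(d2)) + mean(d2))
  eg <- eigen(g, symmetric = TRUE)
  pos <- eg$values > 1e-9 * max(abs(eg$values), 1)
  coords <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), nrow = sum(pos))
  rownames(coords) <- gt$individuals
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = eg$values,
                 percent_variance = 100 * eg$values[pos] / sum(eg$values[pos]),
                 n_imputed_pairs = n_imputed,
                 site = gt$site),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("ordination_result: %d individuals, %d positive axes (axis 1: %.1f%% of inertia)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$percent_variance[1]))
  invisible(x)
}

# pairwise squared genotypic distance at one locus (Smouse & Peakall):
# with s = multiset-shared allele count between the two genotypes,
# s = 2 -> 0; s = 1 -> 1; s = 0 -> 2 (het/het), 3 (hom/het), 4 (hom/hom)
smouse_peakall_locus <- function(a1, a2) {
  n <- length(a1)
  het <- a1 != a2
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    # multiset intersection of the two allele pairs
    g1 <- c(a1[i], a2[i]); g2 <- c(a1[j], a2[j])
    s <- 0L
    for (al in unique(g1))
      s <- s + min(sum(g1 == al), sum(g2 == al))
    v <- if (s == 2L) 0
    else if (s == 1L) 1
    else if (het[i] && het[j]) 2
    else if (!het[i] && !het[j]) 4
    else 3
    d[i, j] <- d[j, i] <- v
  }
  d
}
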