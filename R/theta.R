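# Weir-Cockerham (1984) variance components for one locus.
# counts: site x allele gene-count matrix; het: site x allele matrix of
# observed heterozygote frequencies involving each allele; n: individuals
# typed per site. Returns c(a, b, c) summed over alleles.
wc84_components <- function(counts, het, n) {
  keep <- n >= 1
  counts <- counts[keep, , drop = FALSE]
  het <- het[keep, , drop = FALSE]
  n <- n[keep]
  r <- length(n)
  if (r < 2 || sum(counts) == 0) return(c(a = NA, b = NA, c = NA))
  nbar <- mean(n)
  if (nbar <= 1) return(c(a = NA, b = NA, c = NA))
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  p <- counts / (2 * n)
  a_sum <- b_sum <- c_sum <- 0
  for (al in seq_len(ncol(counts))) {
    pbar <- sum(n * p[, al]) / (r * nbar)
    s2 <- sum(n * (p[, al] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * het[, al]) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a; b_sum <- b_sum + b; c_sum <- c_sum + cc
  }
  c(a = a_sum, b = b_sum, c = c_sum)
}

# per-locus (a, b, c) for a genotype table restricted to `sites`
wc84_locus_components <- function(gt, sites) {
  counts <- allele_count_tables(gt, sites)
  typed <- typed_counts(gt, sites)
  out <- matrix(NA_real_, length(gt$loci), 3,
                dimnames = list(gt$loci, c("a", "b", "c")))
  for (l in seq_along(gt$loci)) {
    cts <- counts[[l]]
    if (ncol(cts) < 2) next  # monomorphic: no information
    het <- matrix(0, nrow(cts), ncol(cts), dimnames = dimnames(cts))
    for (si in seq_along(sites)) {
      ids <- gt$individuals[gt$site == sites[si]]
      a1 <- gt$alleles[ids, l, 1]; a2 <- gt$alleles[ids, l, 2]
      ok <- !is.na(a1)
      if (!sum(ok)) next
      for (al in colnames(cts))
        het[si, al] <- mean((a1[ok] == al) != (a2[ok] == al))
    }
    out[l, ] <- wc84_components(cts, het, typed[, l])
  }
  out
}

#' Multi-locus Weir-Cockerham theta (F_ST)
#'
#' Theta as the ratio of summed variance components, sum(a) / sum(a+b+c),
#' over loci and alleles; the pairwise matrix applies the same estimator to
#' each site pair. The 95% CI comes from bootstrap resampling of loci
#' (percentile method); negative pairwise estimates are preserved in the
#' `theta` matrix and clamped to zero only in the linearized matrix.
#'
#' @param gt a [genotype_table()].
#' @param n_boot bootstrap-over-loci replicates for the CI.
#' @param seed RNG seed for the bootstrap.
#' @param cap linearization cap as in [pairwise_haplotype_fst()].
#' @return list: `theta_global`, `ci` (length 2 or NULL if a single locus),
#'   `per_locus` (a, b, c matrix), `pairwise` (dist_matrix-like with signed
#'   entries), `linearized` ([dist_matrix()]).
#' @export
weir_cockerham_theta <- function(gt, n_boot = 1000, seed = 1, cap = 0.999) {
  stopifnot(inherits(gt, "genotype_table"))
  sites <- sort(unique(unname(gt$site)))
  if (length(sites) < 2) stop("need >= 2 sites")
  n_by_site <- vapply(sites, function(s) sum(gt$site == s), integer(1))
  if (any(n_by_site < 2)) stop("each site needs >= 2 genotyped individuals")
  comp <- wc84_locus_components(gt, sites)
  usable <- stats::complete.cases(comp)
  if (!any(usable)) stop("no polymorphic loci")
  theta_of <- function(m) sum(m[, 1]) / sum(m)
  theta <- theta_of(comp[usable, , drop = FALSE])
  ci <- NULL
  if (sum(usable) >= 2 && n_boot >= 1) {
    set.seed(seed)
    idx <- which(usable)
    boots <- vapply(seq_len(n_boot), function(b)
      theta_of(comp[sample(idx, replace = TRUE), , drop = FALSE]), numeric(1))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  } else if (sum(usable) < 2) {
    warning("single usable locus: bootstrap CI unavailable")
  }
  k <- length(sites)
  pw <- matrix(0, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    sub <- subset_genotypes(gt, gt$individuals[gt$site %in% sites[c(i, j)]])
    cij <- wc84_locus_components(sub, sites[c(i, j)])
    us <- stats::complete.cases(cij)
    pw[i, j] <- pw[j, i] <- if (any(us)) theta_of(cij[us, , drop = FALSE]) else NA
  }
  lin <- pmax(pw, 0)
  lin <- ifelse(lin >= cap & row(lin) != col(lin), Inf, lin / (1 - lin))
  diag(lin) <- 0
  list(theta_global = theta, ci = ci, per_locus = comp,
       pairwise = structure(list(labels = sites, values = pw,
                                 method = "weir-cockerham-diploid",
                                 has_infinite = FALSE), class = "dist_matrix"),
       linearized = dist_matrix(lin, method = "linearized-theta"))
}

#' Nei's D_A genetic distance between sites
#'
#' D_A = 1 - (1/L) * sum over loci of sum over alleles of sqrt(x_a * y_a).
#' A locus untyped in either member of a pair is dropped for that pair (the
#' divisor L shrinks accordingly) and the drop count is recorded.
#'
#' @param gt a [genotype_table()].
#' @return list: `da` ([dist_matrix()]), `per_locus` (list of site x site
#'   matrices), `dropped_pairs` (data.frame of pair x loci dropped counts).
#' @export
nei_da_distance <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  sites <- sort(unique(unname(gt$site)))
  if (length(sites) < 2) stop("need >= 2 sites")
  counts <- allele_count_tables(gt, sites)
  typed <- typed_counts(gt, sites)
  nei_da_from_counts(counts, typed, sites)
}

# core D_A computation given per-locus count tables (reused by the locus
# bootstrap, where loci are resampled)
nei_da_from_counts <- function(counts, typed, sites) {
  k <- length(sites)
  L <- length(counts)
  per_locus <- vector("list", L)
  share <- array(NA_real_, c(k, k, L))
  for (l in seq_len(L)) {
    cts <- counts[[l]]
    freq <- cts / pmax(2 * typed[, l], 1)
    s <- sqrt(freq) %*% t(sqrt(freq))
    s[typed[, l] == 0, ] <- NA; s[, typed[, l] == 0] <- NA
    share[, , l] <- s
    per_locus[[l]] <- 1 - s
  }
  da <- matrix(0, k, k, dimnames = list(sites, sites))
  dropped <- matrix(0L, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    v <- share[i, j, ]
    dropped[i, j] <- sum(is.na(v))
    da[i, j] <- 1 - mean(v, na.rm = TRUE)
  }
  diag(da) <- 0
  da[da < 0 & abs(da) < 1e-12] <- 0
  list(da = dist_matrix(da, method = "nei-DA"),
       per_locus = per_locus,
       dropped_pairs = dropped)
}
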