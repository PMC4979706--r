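#' Per-site diversity summaries for microsatellite data
#'
#' Observed heterozygosity (fraction of heterozygous calls), expected
#' heterozygosity (uncorrected 1 - sum p^2 by default; unbiased variant via
#' `unbiased`), allelic richness by hypergeometric rarefaction to a common
#' gene count, and the multi-locus Weir-Cockerham within-population
#' inbreeding coefficient F_IS.
#'
#' @param gt a [genotype_table()].
#' @param rarefaction_g gene count for rarefaction. Defaults to twice the
#'   smallest per-site per-locus typed sample; a larger request is lowered
#'   to that bound with a warning.
#' @param unbiased use the n/(n-1)-corrected expected heterozygosity.
#' @return data.frame, one row per site: `site`, `n`, `ho`, `he`, `ar`,
#'   `fis`, `n_loci_typed`; attribute `"per_locus"` holds the per-locus
#'   matrices and `"rarefaction_g"` the g actually used.
#' @export
site_summary_stats <- function(gt, rarefaction_g = NULL, unbiased = FALSE) {
  stopifnot(inherits(gt, "genotype_table"))
  sites <- sort(unique(unname(gt$site)))
  L <- length(gt$loci)
  counts <- allele_count_tables(gt, sites)
  typed <- typed_counts(gt, sites)
  g_max <- 2L * min(typed[typed > 0])
  if (is.null(rarefaction_g)) rarefaction_g <- g_max
  if (rarefaction_g > g_max) {
    warning(sprintf("rarefaction_g = %d exceeds 2 x smallest typed sample; lowered to %d",
                    rarefaction_g, g_max))
    rarefaction_g <- g_max
  }
  if (rarefaction_g < 2) stop("rarefaction_g must be >= 2")
  ho <- he <- ar <- matrix(NA_real_, length(sites), L,
                           dimnames = list(sites, gt$loci))
  fis <- stats::setNames(rep(NA_real_, length(sites)), sites)
  for (si in seq_along(sites)) {
    b_sum <- 0; c_sum <- 0
    for (l in seq_len(L)) {
      n <- typed[si, l]
      if (n < 1) next
      cts <- counts[[l]][si, ]
      cts <- cts[cts > 0]
      p <- cts / (2 * n)
      he[si, l] <- gene_diversity(cts, unbiased = unbiased)
      ids <- gt$individuals[gt$site == sites[si]]
      a1 <- gt$alleles[ids, l, 1]; a2 <- gt$alleles[ids, l, 2]
      ok <- !is.na(a1)
      ho[si, l] <- mean(a1[ok] != a2[ok])
      ar[si, l] <- rarefied_richness(cts, rarefaction_g)
      if (n >= 2) {
        # Weir-Cockerham within-population components per allele
        hbar <- vapply(names(cts), function(al)
          mean((a1[ok] == al) != (a2[ok] == al)), numeric(1))
        b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
        cc <- hbar / 2
        b_sum <- b_sum + sum(b); c_sum <- c_sum + sum(cc)
      }
    }
    if (b_sum + c_sum > 0) fis[si] <- 1 - c_sum / (b_sum + c_sum)
  }
  out <- data.frame(site = sites,
                    n = vapply(sites, function(s) sum(gt$site == s), integer(1)),
                    ho = rowMeans(ho, na.rm = TRUE),
                    he = rowMeans(he, na.rm = TRUE),
                    ar = rowMeans(ar, na.rm = TRUE),
                    fis = unname(fis),
                    n_loci_typed = rowSums(typed > 0),
                    row.names = NULL)
  attr(out, "per_locus") <- list(ho = ho, he = he, ar = ar)
  attr(out, "rarefaction_g") <- rarefaction_g
  out
}

# expected number of alleles in a hypergeometric subsample of g genes
rarefied_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < g) return(NA_real_)
  # P(allele a absent from the subsample) = C(N - n_a, g) / C(N, g)
  p_absent <- exp(lchoose(N - counts, g) - lchoose(N, g))
  p_absent[N - counts < g] <- 0
  sum(1 - p_absent)
}

# multilocus WC F_IS for a set of individuals (used as the HWE statistic)
multilocus_fis <- function(a1, a2) {
  # a1, a2: individuals x loci allele matrices
  b_sum <- 0; c_sum <- 0
  for (l in seq_len(ncol(a1))) {
    ok <- !is.na(a1[, l])
    n <- sum(ok)
    if (n < 2) next
    al <- c(a1[ok, l], a2[ok, l])
    cts <- table(al)
    if (length(cts) < 2) next
    p <- as.numeric(cts) / (2 * n)
    hbar <- vapply(names(cts), function(x)
      mean((a1[ok, l] == x) != (a2[ok, l] == x)), numeric(1))
    b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
    b_sum <- b_sum + sum(b); c_sum <- c_sum + sum(hbar / 2)
  }
  if (b_sum + c_sum <= 0) return(NA_real_)
  1 - c_sum / (b_sum + c_sum)
}

#' Permutation tests of Hardy-Weinberg and gametic equilibrium
#'
#' HWE: within each site, alleles are permuted among individuals at each
#' locus (breaking diploid pairing while preserving allele frequencies);
#' the statistic is the multi-locus F_IS and the p-value is two-sided,
#' p = (1 + #\{|F_perm| >= |F_obs|\}) / (n_perm + 1). Per-locus F_IS tests
#' are reported alongside. Gametic equilibrium: per locus pair within a
#' site, single-locus genotypes are permuted among individuals and the
#' statistic is the G log-likelihood-ratio of association between the two
#' genotype classifications. Monomorphic loci are skipped with NA.
#'
#' @param gt a [genotype_table()].
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list: `hwe_site` (site, fis, p), `hwe_locus` (site, locus, fis,
#'   p), `gametic` (site, locus1, locus2, g_stat, p).
#' @export
disequilibrium_tests <- function(gt, n_perm = 999, seed = 1) {
  stopifnot(inherits(gt, "genotype_table"))
  if (n_perm < 99) stop("n_perm must be >= 99")
  set.seed(seed)
  sites <- sort(unique(unname(gt$site)))
  L <- length(gt$loci)
  hwe_site <- data.frame(site = sites, fis = NA_real_, p = NA_real_)
  hwe_locus <- expand.grid(site = sites, locus = gt$loci,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hwe_locus$fis <- NA_real_; hwe_locus$p <- NA_real_
  gam <- NULL
  for (si in seq_along(sites)) {
    ids <- gt$individuals[gt$site == sites[si]]
    a1 <- matrix(gt$alleles[ids, , 1], nrow = length(ids))
    a2 <- matrix(gt$alleles[ids, , 2], nrow = length(ids))
    poly <- vapply(seq_len(L), function(l) {
      al <- c(a1[, l], a2[, l]); length(unique(al[!is.na(al)])) > 1
    }, logical(1))
    # observed statistics
    obs_site <- multilocus_fis(a1[, poly, drop = FALSE], a2[, poly, drop = FALSE])
    obs_loc <- vapply(seq_len(L), function(l)
      if (poly[l]) multilocus_fis(a1[, l, drop = FALSE], a2[, l, drop = FALSE])
      else NA_real_, numeric(1))
    perm_site <- numeric(n_perm)
    ge_loc <- rep(0, L)
    for (b in seq_len(n_perm)) {
      p1 <- a1; p2 <- a2
      for (l in which(poly)) {
        ok <- !is.na(a1[, l])
        pool <- sample(c(a1[ok, l], a2[ok, l]))
        p1[ok, l] <- pool[seq_len(sum(ok))]
        p2[ok, l] <- pool[sum(ok) + seq_len(sum(ok))]
      }
      perm_site[b] <- multilocus_fis(p1[, poly, drop = FALSE],
                                     p2[, poly, drop = FALSE])
      for (l in which(poly)) {
        fl <- multilocus_fis(p1[, l, drop = FALSE], p2[, l, drop = FALSE])
        if (!is.na(fl) && !is.na(obs_loc[l]) && abs(fl) >= abs(obs_loc[l]))
          ge_loc[l] <- ge_loc[l] + 1
      }
    }
    hwe_site$fis[si] <- obs_site
    if (!is.na(obs_site))
      hwe_site$p[si] <-
        (1 + sum(abs(perm_site[!is.na(perm_site)]) >= abs(obs_site))) / (n_perm + 1)
    for (l in seq_len(L)) {
      row <- hwe_locus$site == sites[si] & hwe_locus$locus == gt$loci[l]
      hwe_locus$fis[row] <- obs_loc[l]
      if (poly[l] && !is.na(obs_loc[l]))
        hwe_locus$p[row] <- (1 + ge_loc[l]) / (n_perm + 1)
    }
    # gametic equilibrium over locus pairs
    if (sum(poly) >= 2) {
      pp <- which(poly)
      for (ii in seq_len(length(pp) - 1)) for (jj in seq((ii + 1), length(pp))) {
        l1 <- pp[ii]; l2 <- pp[jj]
        g1 <- genotype_labels(a1[, l1], a2[, l1])
        g2 <- genotype_labels(a1[, l2], a2[, l2])
        ok <- !is.na(g1) & !is.na(g2)
        if (sum(ok) < 4) next
        g_obs <- g_stat(g1[ok], g2[ok])
        cnt <- 0
        for (b in seq_len(n_perm))
          if (g_stat(g1[ok], sample(g2[ok])) >= g_obs) cnt <- cnt + 1
        gam <- rbind(gam, data.frame(site = sites[si],
                                     locus1 = gt$loci[l1], locus2 = gt$loci[l2],
                                     g_stat = g_obs,
                                     p = (1 + cnt) / (n_perm + 1)))
      }
    }
  }
  list(hwe_site = hwe_site, hwe_locus = hwe_locus, gametic = gam)
}

genotype_labels <- function(a1, a2) {
  out <- ifelse(is.na(a1), NA_character_,
                paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
  out
}

# G log-likelihood-ratio statistic of a two-way contingency table
g_stat <- function(x, y) {
  tab <- table(x, y)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  o <- as.numeric(tab)
  e <- as.numeric(e)
  2 * sum(o[o > 0] * log(o[o > 0] / e[o > 0]))
}

#' Sequential Bonferroni (Holm) correction
#'
#' Rice's (1989) sequential Bonferroni procedure is Holm's step-down method;
#' this is a thin wrapper over [stats::p.adjust()] kept for the analysis
#' surface.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
sequential_bonferroni <- function(p) stats::p.adjust(p, method = "holm")
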