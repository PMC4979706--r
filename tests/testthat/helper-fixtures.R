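# shared builders and independent oracles for the test suite

# genotype table from a list of per-individual genotype strings:
# list(id = list(site, "a/b", "c/d", ...)) with NA for missing calls
make_gt <- function(geno, loci = NULL, sex = NULL, date = NULL,
                    repeat_loci = NULL) {
  ids <- names(geno)
  L <- length(geno[[1]]) - 1L
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  arr <- array(NA_character_, c(length(ids), L, 2))
  site <- character(length(ids))
  for (i in seq_along(ids)) {
    site[i] <- geno[[i]][[1]]
    for (l in seq_len(L)) {
      g <- geno[[i]][[l + 1L]]
      if (!is.na(g)) arr[i, l, ] <- strsplit(g, "/")[[1]]
    }
  }
  genotype_table(arr, ids, loci, site, date = date, sex = sex,
                 repeat_loci = repeat_loci)
}

# one-site genotypes drawn under Hardy-Weinberg from given allele
# frequencies (list per locus of named freq vectors)
hwe_site_gt <- function(n, freqs, site = "s1", prefix = "i") {
  L <- length(freqs)
  arr <- array(NA_character_, c(n, L, 2))
  for (l in seq_len(L)) {
    arr[, l, 1] <- sample(names(freqs[[l]]), n, TRUE, freqs[[l]])
    arr[, l, 2] <- sample(names(freqs[[l]]), n, TRUE, freqs[[l]])
  }
  genotype_table(arr, paste0(prefix, seq_len(n)),
                 paste0("L", seq_len(L)), rep(site, n))
}

# merge genotype tables from independent simulations (site labels must
# already differ); used to build hierarchical (region x deme) data
merge_gt <- function(a, b) {
  ids <- c(a$individuals, paste0("b_", b$individuals))
  loci <- a$loci
  stopifnot(identical(loci, b$loci))
  arr <- array(NA_character_, c(length(ids), length(loci), 2))
  arr[seq_along(a$individuals), , ] <- a$alleles
  arr[length(a$individuals) + seq_along(b$individuals), , ] <- b$alleles
  genotype_table(arr, ids, loci,
                 c(unname(a$site), unname(b$site)),
                 repeat_loci = a$repeat_loci)
}

# --- independent oracles ---------------------------------------------------

# Weir-Cockerham (1984) theta from first principles for a one-locus,
# multi-site sample, written directly from the published component
# definitions (independent of the package's vectorized implementation)
oracle_wc84_theta <- function(genos_by_site) {
  # genos_by_site: list per site of 2-column allele matrices
  alleles <- unique(unlist(genos_by_site))
  r <- length(genos_by_site)
  n <- vapply(genos_by_site, nrow, numeric(1))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  a_tot <- b_tot <- c_tot <- 0
  for (al in alleles) {
    p <- vapply(genos_by_site, function(g) mean(g == al), numeric(1))
    h <- vapply(genos_by_site, function(g)
      mean((g[, 1] == al) != (g[, 2] == al)), numeric(1))
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- nbar / nc *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_tot <- a_tot + a; b_tot <- b_tot + b; c_tot <- c_tot + cc
  }
  a_tot / (a_tot + b_tot + c_tot)
}

# haploid variance-components F_ST from mean squares (independent form)
oracle_haploid_fst <- function(counts) {
  n <- rowSums(counts); r <- nrow(counts)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  num <- den <- 0
  for (a in seq_len(ncol(counts))) {
    p <- counts[, a] / n
    pbar <- sum(counts[, a]) / sum(n)
    msp <- sum(n * (p - pbar)^2) / (r - 1)
    msg <- sum(n * p * (1 - p)) / (sum(n) - r)
    num <- num + msp - msg
    den <- den + msp + (nc - 1) * msg
  }
  num / den
}

# Burrows composite delta and r^2 for one allele pair, spelled out
oracle_burrows_r2 <- function(xa, xb) {
  n <- length(xa)
  pa <- mean(xa) / 2; pb <- mean(xb) / 2
  delta <- n / (n - 1) * (sum(xa * xb) / (2 * n) - 2 * pa * pb)
  delta^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# OLS residuals via the hat matrix (closed form)
oracle_ols_residuals <- function(x, y) {
  X <- cbind(1, x)
  as.numeric((diag(length(y)) - X %*% solve(t(X) %*% X) %*% t(X)) %*% y)
}

# random tree-additive distance matrix and its generating phylo tree
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.5, 2))
  m <- ape::cophenetic.phylo(tr)
  m <- m[order(rownames(m)), order(colnames(m))]
  list(tree = tr, d = dist_matrix(m))
}

# constructed cluster_run with a given Q matrix
fake_run <- function(Q, site, K = ncol(Q), ids = NULL) {
  if (is.null(ids)) ids <- paste0("i", seq_len(nrow(Q)))
  rownames(Q) <- ids
  structure(list(K = K, Q = Q, lnPD = 0,
                 site = stats::setNames(site, ids),
                 date = stats::setNames(rep(NA, nrow(Q)), ids)),
            class = "cluster_run")
}
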