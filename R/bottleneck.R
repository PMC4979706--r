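#' Heterozygote-excess bottleneck test
#'
#' Recently bottlenecked populations lose rare alleles faster than
#' heterozygosity, so observed (unbiased) heterozygosity exceeds the
#' heterozygosity expected at mutation-drift equilibrium for the observed
#' allele count. For each polymorphic locus with k alleles in a sample of n
#' genes, the equilibrium distribution of He given k (Heq) is obtained by
#' coalescent simulation under the chosen mutation model, retaining
#' replicates with exactly k alleles; the scaled mutation rate is tuned by
#' bisection on the expected allele count so conditioning is efficient.
#' Across loci, a two-tailed Wilcoxon signed-rank test is applied to the
#' standardized deviations (He - mean Heq) / sd Heq (exact distribution for
#' <= 25 loci).
#'
#' @param gt a [genotype_table()].
#' @param site site id to test.
#' @param model mutation model: `"IAM"`, `"SMM"` or `"TPM"`. Stepwise models
#'   require integer repeat-score alleles (`repeat_loci` flag or coercible).
#' @param p_smm proportion of strictly one-step mutations under TPM
#'   (default 0.7); multi-step sizes are geometric with variance ~ 30.
#' @param n_sim retained equilibrium replicates per locus.
#' @param seed RNG seed.
#' @param max_attempts_factor cap on attempts per locus, as a multiple of
#'   `n_sim`; loci that cannot reach k alleles within budget are dropped.
#' @return list of class `bottleneck_result`: `site`, `model`, `p_smm`,
#'   per-locus data.frame `loci` (k, n_genes, he_obs, heq_mean, heq_sd,
#'   std_dev), `p_wilcoxon` (two-tailed), `p_excess` (one-tailed het
#'   excess), `dropped_loci`.
#' @export
bottleneck_heterozygosity_test <- function(gt, site, model = c("TPM", "IAM", "SMM"),
                                           p_smm = 0.7, n_sim = 1000, seed = 1,
                                           max_attempts_factor = 200) {
  stopifnot(inherits(gt, "genotype_table"))
  model <- match.arg(model)
  set.seed(seed)
  ids <- gt$individuals[gt$site == site]
  if (!length(ids)) stop("no individuals at site ", site)
  res <- NULL; dropped <- character(0)
  for (l in seq_along(gt$loci)) {
    a1 <- gt$alleles[ids, l, 1]; a2 <- gt$alleles[ids, l, 2]
    ok <- !is.na(a1)
    al <- c(a1[ok], a2[ok])
    if (length(al) < 4) next
    cts <- table(al)
    k <- length(cts)
    if (k < 2) next  # monomorphic: Heq degenerate at 0
    if (model %in% c("SMM", "TPM") && !gt$repeat_loci[l] &&
        anyNA(suppressWarnings(as.integer(names(cts)))))
      stop(sprintf("locus '%s': %s needs integer repeat-score alleles",
                   gt$loci[l], model))
    n_genes <- length(al)
    he_obs <- gene_diversity(as.numeric(cts), unbiased = TRUE)
    heq <- heq_distribution(n_genes, k, model, p_smm, n_sim,
                            max_attempts = max_attempts_factor * n_sim)
    if (length(heq) < max(20, n_sim / 10)) {
      dropped <- c(dropped, gt$loci[l])
      next
    }
    res <- rbind(res, data.frame(
      locus = gt$loci[l], k = k, n_genes = n_genes, he_obs = he_obs,
      heq_mean = mean(heq), heq_sd = stats::sd(heq),
      n_kept = length(heq)))
  }
  if (is.null(res) || nrow(res) < 4)
    stop("need >= 4 polymorphic usable loci at site ", site)
  res$std_dev <- (res$he_obs - res$heq_mean) / res$heq_sd
  wt <- stats::wilcox.test(res$std_dev, alternative = "two.sided",
                           exact = nrow(res) <= 25)
  wg <- stats::wilcox.test(res$std_dev, alternative = "greater",
                           exact = nrow(res) <= 25)
  structure(list(site = site, model = model,
                 p_smm = if (model == "TPM") p_smm else NA_real_,
                 loci = res,
                 p_wilcoxon = wt$p.value, p_excess = wg$p.value,
                 dropped_loci = dropped),
            class = "bottleneck_result")
}

#' @export
print.bottleneck_result <- function(x, ...) {
  cat(sprintf("bottleneck test at '%s' (%s%s): %d loci, Wilcoxon two-tailed p = %.4g (excess p = %.4g)\n",
              x$site, x$model,
              if (x$model == "TPM") sprintf(", p_smm = %.2f", x$p_smm) else "",
              nrow(x$loci), x$p_wilcoxon, x$p_excess))
  invisible(x)
}

# distribution of unbiased He at mutation-drift equilibrium conditional on
# exactly k alleles in a sample of n genes
heq_distribution <- function(n_genes, k, model, p_smm, n_sim, max_attempts) {
  theta <- tune_theta(n_genes, k, model, p_smm)
  out <- numeric(0); attempts <- 0L
  while (length(out) < n_sim && attempts < max_attempts) {
    batch <- min(max(2L * n_sim, 100L), max_attempts - attempts)
    for (b in seq_len(batch)) {
      st <- sim_coalescent_alleles(n_genes, theta, model, p_smm)
      cts <- tabulate(match(st, unique(st)))
      if (length(cts) == k)
        out <- c(out, gene_diversity(cts, unbiased = TRUE))
      if (length(out) >= n_sim) break
    }
    attempts <- attempts + batch
  }
  out
}

.theta_cache <- new.env(parent = emptyenv())

# bisection on log(theta) targeting E[#alleles] = k; small simulation
# batches keep the budget bounded (monotonicity: more mutation, more
# alleles). Tuned rates are memoised per (n, k, model, p_smm); the tuning
# runs on its own deterministic RNG substream so that cache hits and misses
# leave the caller's random stream identical (bit-reproducibility).
tune_theta <- function(n_genes, k, model, p_smm, batch = 60, iters = 14) {
  key <- paste(n_genes, k, model,
               if (model == "TPM") format(p_smm) else "", sep = "|")
  hit <- get0(key, envir = .theta_cache)
  if (!is.null(hit)) return(hit)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed((n_genes * 131L + k * 17L + match(model, c("IAM", "SMM", "TPM"))) %%
             .Machine$integer.max)
  val <- tune_theta_search(n_genes, k, model, p_smm, batch, iters)
  assign(key, val, envir = .theta_cache)
  val
}

tune_theta_search <- function(n_genes, k, model, p_smm, batch = 60, iters = 14) {
  mean_k <- function(theta)
    mean(vapply(seq_len(batch), function(i)
      length(unique(sim_coalescent_alleles(n_genes, theta, model, p_smm))),
      numeric(1)))
  lo <- 0.01; hi <- 1
  while (mean_k(hi) < k && hi < 1e3) hi <- hi * 4
  while (mean_k(lo) > k && lo > 1e-4) lo <- lo / 4
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    if (mean_k(mid) < k) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# one coalescent sample of n genes: Kingman genealogy, Poisson(theta/2 * t)
# mutations per branch, allele states propagated root -> tips
sim_coalescent_alleles <- function(n, theta, model = c("IAM", "SMM", "TPM"),
                                   p_smm = 0.7) {
  model <- match.arg(model)
  total <- 2L * n - 1L
  parent <- integer(total); blen <- numeric(total)
  active <- seq_len(n)
  t_now <- 0; nxt <- n + 1L
  birth <- numeric(total)  # time each node was created (tips at 0)
  while (length(active) > 1L) {
    j <- length(active)
    t_now <- t_now + stats::rexp(1, j * (j - 1) / 2)
    pick <- sample.int(j, 2L)
    ch <- active[pick]
    parent[ch] <- nxt
    blen[ch] <- t_now - birth[ch]
    birth[nxt] <- t_now
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  root <- active
  state <- numeric(total)
  state[root] <- 1000  # arbitrary root repeat score
  # parents precede children when walking by decreasing creation time
  ord <- order(birth[seq_len(total)], decreasing = TRUE)
  ord <- ord[ord != root]
  m_all <- stats::rpois(length(ord), theta / 2 * blen[ord])
  if (model == "IAM") {
    fresh <- cumsum(m_all > 0) + 1000
    for (i in seq_along(ord)) {
      nd <- ord[i]
      state[nd] <- if (m_all[i] > 0) fresh[i] else state[parent[nd]]
    }
  } else {
    k_tot <- sum(m_all)
    delta <- numeric(length(ord))
    if (k_tot > 0) {
      step <- if (model == "SMM") rep(1L, k_tot)
      else ifelse(stats::runif(k_tot) < p_smm, 1L,
                  1L + stats::rgeom(k_tot, 1 / 6))  # var ~ 30 multi-step
      contrib <- sample(c(-1L, 1L), k_tot, replace = TRUE) * step
      agg <- rowsum(contrib, rep(seq_along(ord), m_all))
      delta[as.integer(rownames(agg))] <- agg[, 1]
    }
    for (i in seq_along(ord)) {
      nd <- ord[i]
      state[nd] <- state[parent[nd]] + delta[i]
    }
  }
  state[seq_len(n)]
}
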