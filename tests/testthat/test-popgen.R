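test_that("gene diversity reproduces the published per-site values", {
  # counts taken from the packaged mtDNA table
  expect_equal(round(gene_diversity(c(1, 4, 100, 10)), 3), 0.235)   # Monterey
  expect_equal(round(gene_diversity(c(48, 2, 1, 3)), 3), 0.205)     # SFB East
  expect_equal(round(gene_diversity(c(1, 18)), 3), 0.100)           # Morro Bay
  expect_equal(gene_diversity(13), 0)                               # fixed site
  expect_equal(gene_diversity(c(5, 5)), 0.5)                        # 50:50
  expect_equal(gene_diversity(c(1, 1), unbiased = TRUE), 1)
  expect_error(gene_diversity(c(0, 0)), "all-zero")
})

test_that("diversity partition F_ST behaves at the extremes", {
  # all sites identical frequency vectors -> F_ST = 0
  m <- matrix(rep(c(6L, 4L), 3), 3, 2, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), c("h1", "h2")))
  part <- global_fst_from_diversity(haplotype_counts(m))
  expect_equal(part$fst, 0, tolerance = 1e-12)
  # each site fixed for a private haplotype -> within mean 0, F_ST = 1
  m2 <- diag(10L)[1:3, 1:3] * 10L
  dimnames(m2) <- list(paste0("s", 1:3), paste0("h", 1:3))
  part2 <- global_fst_from_diversity(haplotype_counts(m2))
  expect_equal(part2$h_within_mean, 0)
  expect_equal(part2$fst, 1)
})

test_that("Wahlund direction: pooled diversity >= mean within diversity", {
  set.seed(71)
  for (rep in 1:20) {
    k <- sample(2:5, 1); nh <- sample(2:6, 1)
    m <- matrix(rpois(k * nh, 4), k, nh,
                dimnames = list(paste0("s", 1:k), paste0("h", 1:nh)))
    m[rowSums(m) == 0, 1] <- 5L
    hc <- haplotype_counts(m)
    part <- global_fst_from_diversity(hc, include = hc$sites, min_n = 1)
    expect_gte(part$h_total, part$h_within_mean - 1e-12)
    expect_gte(part$fst, -1e-12)
  }
})

test_that("pairwise haploid F_ST matches the variance-components oracle", {
  cts <- matrix(c(3L, 1L, 1L, 3L), 2, 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("x", "y")))
  hc <- haplotype_counts(cts)
  pw <- pairwise_haplotype_fst(hc)
  expect_equal(pw$fst$values["A", "B"], oracle_haploid_fst(cts),
               tolerance = 1e-12)
  # identical frequencies -> 0 (up to estimator noise exactly 0 here)
  cts2 <- matrix(c(4L, 4L, 4L, 4L), 2, 2,
                 dimnames = list(c("A", "B"), c("x", "y")))
  pw2 <- pairwise_haplotype_fst(haplotype_counts(cts2))
  expect_lte(pw2$fst$values["A", "B"], 0)  # unbiased estimator, E = 0
  # fixed for different haplotypes -> 1, linearized capped to +Inf
  cts3 <- matrix(c(10L, 0L, 0L, 10L), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("x", "y")))
  expect_message(pw3 <- pairwise_haplotype_fst(haplotype_counts(cts3)),
                 "linearization cap")
  expect_equal(pw3$fst$values["A", "B"], 1)
  expect_true(is.infinite(pw3$linearized$values["A", "B"]))
  expect_true(pw3$linearized$has_infinite)
})

test_that("random haploid tables agree with the oracle to 1e-12", {
  set.seed(42)
  for (rep in 1:15) {
    k <- sample(2:4, 1)
    cts <- matrix(rpois(k * 3, 5) + 1L, k, 3,
                  dimnames = list(paste0("s", 1:k), c("x", "y", "z")))
    expect_equal(foxscape:::wc_haploid_theta(cts), oracle_haploid_fst(cts),
                 tolerance = 1e-12)
  }
})

test_that("diploid theta equals the first-principles WC84 oracle", {
  gt <- make_gt(list(
    i1 = list("a", "1/1", "1/2"), i2 = list("a", "1/2", "2/2"),
    i3 = list("a", "1/1", "1/1"), i4 = list("b", "2/2", "1/2"),
    i5 = list("b", "1/2", "2/2"), i6 = list("b", "2/2", "2/2")))
  th <- suppressWarnings(weir_cockerham_theta(gt, n_boot = 50))
  by_site <- function(l) lapply(c("a", "b"), function(s) {
    ids <- gt$individuals[gt$site == s]
    cbind(gt$alleles[ids, l, 1], gt$alleles[ids, l, 2])
  })
  comp <- foxscape:::wc84_locus_components(gt, c("a", "b"))
  # multi-locus ratio from per-locus oracle components
  or <- vapply(1:2, function(l) {
    g <- by_site(l)
    oracle_wc84_theta(g)
  }, numeric(1))
  # oracle per locus equals package per locus
  pk <- comp[, 1] / rowSums(comp)
  expect_equal(unname(pk), or, tolerance = 1e-12)
})

test_that("theta is invariant to allele relabeling and near 0 under panmixia", {
  set.seed(9)
  freqs <- lapply(1:5, function(l) {
    f <- runif(4); stats::setNames(f / sum(f), as.character(1:4))
  })
  g1 <- hwe_site_gt(40, freqs, "s1", "a")
  g2 <- hwe_site_gt(40, freqs, "s2", "b")
  gt <- merge_gt(g1, g2)
  th <- weir_cockerham_theta(gt, n_boot = 300, seed = 3)
  expect_lt(abs(th$theta_global), 0.02)
  expect_true(th$ci[1] <= 0 && th$ci[2] >= 0)
  # relabel alleles at every locus (1->9 etc.): theta unchanged
  arr <- gt$alleles
  arr[] <- as.character(as.integer(arr) + 8L)
  gt2 <- genotype_table(arr, gt$individuals, gt$loci, gt$site)
  th2 <- weir_cockerham_theta(gt2, n_boot = 50, seed = 3)
  expect_equal(th2$theta_global, th$theta_global, tolerance = 1e-12)
})

test_that("Nei's D_A formula, bounds and locus-order invariance", {
  # one locus, x = (1, 0), y = (0.5, 0.5): D_A = 1 - sqrt(0.5)
  gt <- make_gt(list(
    i1 = list("x", "1/1"), i2 = list("x", "1/1"),
    i3 = list("y", "1/2"), i4 = list("y", "2/1")))
  da <- nei_da_distance(gt)
  expect_equal(da$da$values["x", "y"], 1 - sqrt(0.5), tolerance = 1e-12)
  # identical frequency vectors -> 0; disjoint alleles -> 1
  gt2 <- make_gt(list(
    i1 = list("x", "1/2", "3/3"), i2 = list("y", "1/2", "3/3")))
  expect_equal(nei_da_distance(gt2)$da$values["x", "y"], 0, tolerance = 1e-12)
  gt3 <- make_gt(list(
    i1 = list("x", "1/1", "3/3"), i2 = list("y", "2/2", "4/4")))
  expect_equal(nei_da_distance(gt3)$da$values["x", "y"], 1)
  # locus order invariance
  sim <- simulate_metapopulation(
    sim_config(n_sites = 3, generations = 4, N = 30, sample_size = 12), 5)
  d1 <- nei_da_distance(sim$genotypes)$da$values
  perm <- rev(sim$genotypes$loci)
  d2 <- nei_da_distance(subset_genotypes(sim$genotypes, loci = perm))$da$values
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("sex-biased gene-flow ratio honors the island-model identities", {
  # symmetric Nm = 1: F_nuc = 0.2, F_mt = 0.5 -> ratio 1
  expect_equal(sex_biased_gene_flow_ratio(0.2, 0.5)$mm_over_mf, 1)
  # boundary: no male gene flow
  expect_equal(sex_biased_gene_flow_ratio(0.2, 1 / 3)$mm_over_mf, 0)
  # inadmissible region flagged and floored
  expect_warning(r <- sex_biased_gene_flow_ratio(0.2, 0.25), "negative")
  expect_equal(r$mm_over_mf, 0)
  expect_false(r$admissible)
  expect_error(sex_biased_gene_flow_ratio(0, 0.5), "strictly")
  expect_error(sex_biased_gene_flow_ratio(0.2, 1), "strictly")
})

test_that("site summaries: fixed and fully heterozygous sites", {
  gt <- make_gt(list(
    i1 = list("fix", "1/1", "2/2"), i2 = list("fix", "1/1", "2/2"),
    i3 = list("het", "1/2", "1/2"), i4 = list("het", "1/2", "1/2")))
  s <- site_summary_stats(gt)
  fix <- s[s$site == "fix", ]
  expect_equal(fix$ho, 0); expect_equal(fix$he, 0); expect_equal(fix$ar, 1)
  expect_true(is.na(fix$fis))
  het <- s[s$site == "het", ]
  expect_equal(het$ho, 1)
  expect_equal(het$he, 0.5)
  expect_lt(het$fis, 0)
})

test_that("rarefied allelic richness matches hypergeometric expectation", {
  # counts (3, 1), g = 2: E[alleles] = 2 - C(3,2)/C(4,2) - C(1,2)/C(4,2)
  expect_equal(foxscape:::rarefied_richness(c(3, 1), 2),
               2 - choose(3, 2) / choose(4, 2), tolerance = 1e-12)
  expect_equal(foxscape:::rarefied_richness(c(5, 0), 2), 1)
  gt <- make_gt(list(i1 = list("a", "1/2"), i2 = list("a", "1/1"),
                     i3 = list("b", "1/2"), i4 = list("b", "2/2")))
  expect_warning(site_summary_stats(gt, rarefaction_g = 50), "lowered")
})

test_that("F_IS is near zero on Hardy-Weinberg simulated data", {
  set.seed(15)
  fis <- replicate(20, {
    freqs <- lapply(1:4, function(l) stats::setNames(rep(0.25, 4), 1:4))
    gt <- hwe_site_gt(200, freqs)
    site_summary_stats(gt)$fis
  })
  expect_lt(abs(mean(fis)), 2 * sd(fis) / sqrt(20) + 0.01)
})

test_that("HWE test rejects under Wahlund pooling but not within sites", {
  set.seed(33)
  fa <- lapply(1:4, function(l) stats::setNames(c(0.9, 0.1), c("1", "2")))
  fb <- lapply(1:4, function(l) stats::setNames(c(0.1, 0.9), c("1", "2")))
  ga <- hwe_site_gt(40, fa, "pooled", "a")
  gb <- hwe_site_gt(40, fb, "pooled", "b")
  pooled <- merge_gt(ga, gb)
  dq <- disequilibrium_tests(pooled, n_perm = 199, seed = 8)
  expect_lt(dq$hwe_site$p[1], 0.01)      # strong Wahlund heterozygote deficit
  expect_gt(dq$hwe_site$fis[1], 0.3)
  # within a single HWE site the test keeps its level (no tiny p)
  gh <- hwe_site_gt(40, fa, "one", "c")
  dq2 <- disequilibrium_tests(gh, n_perm = 199, seed = 9)
  expect_gt(dq2$hwe_site$p[1], 0.05)
})

test_that("gametic disequilibrium is extreme for a duplicated locus", {
  set.seed(4)
  freqs <- list(stats::setNames(rep(0.25, 4), 1:4))
  g <- hwe_site_gt(30, freqs)
  arr <- array(NA_character_, c(30, 2, 2))
  arr[, 1, ] <- g$alleles[, 1, ]
  arr[, 2, ] <- g$alleles[, 1, ]  # exact duplicate
  gt <- genotype_table(arr, g$individuals, c("L1", "L1dup"), g$site)
  dq <- disequilibrium_tests(gt, n_perm = 199, seed = 2)
  expect_equal(dq$gametic$p, 1 / 200)  # minimum attainable
  # permutation p-values bounded in [1/(n+1), 1]
  expect_true(all(dq$hwe_site$p >= 1 / 200 & dq$hwe_site$p <= 1,
                  na.rm = TRUE))
})

test_that("monomorphic loci are skipped with NA p", {
  gt <- make_gt(list(i1 = list("a", "1/1", "1/2"),
                     i2 = list("a", "1/1", "2/2"),
                     i3 = list("a", "1/1", "1/2"),
                     i4 = list("a", "1/1", "1/1")))
  dq <- disequilibrium_tests(gt, n_perm = 99, seed = 1)
  expect_true(is.na(dq$hwe_locus$p[dq$hwe_locus$locus == "L1"]))
  expect_false(is.na(dq$hwe_locus$p[dq$hwe_locus$locus == "L2"]))
})

test_that("sequential Bonferroni is Holm's step-down procedure", {
  p <- c(0.01, 0.04, 0.03, 0.005)
  expect_equal(sequential_bonferroni(p), p.adjust(p, "holm"))
})
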