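test_that("K = 1 gives all ancestry exactly 1 and finite lnPD", {
  sim <- simulate_metapopulation(
    sim_config(n_sites = 2, generations = 3, N = 20, sample_size = 8,
               n_loci = 4), seed = 2)
  r <- admixture_mcmc(sim$genotypes, K = 1, cycles = 200, burn_in = 100,
                      seed = 1)
  expect_true(all(r$Q == 1))
  expect_true(is.finite(r$lnPD))
  expect_true(all(abs(rowSums(r$Q) - 1) < 1e-9))
})

test_that("fixed-difference populations separate completely at K = 2", {
  # two populations fixed for different alleles at 13 loci
  geno <- list()
  for (i in 1:12) {
    pop <- if (i <= 6) "a" else "b"
    al <- if (i <= 6) "1/1" else "2/2"
    geno[[paste0("i", i)]] <- c(list(pop), rep(list(al), 13))
  }
  gt <- make_gt(geno)
  r <- admixture_mcmc(gt, K = 2, cycles = 600, burn_in = 300, seed = 3)
  qa <- r$Q[unname(gt$site) == "a", ]
  qb <- r$Q[unname(gt$site) == "b", ]
  # up to label swap, everyone is > 0.99 assigned to their population
  col_a <- which.max(colMeans(qa))
  expect_true(all(qa[, col_a] > 0.99))
  expect_true(all(qb[, 3 - col_a] > 0.99))
  expect_true(all(abs(rowSums(r$Q) - 1) < 1e-9))
})

test_that("lnPD separates structured from panmictic data across K", {
  set.seed(8)
  fa <- lapply(1:8, function(l) stats::setNames(c(0.9, 0.1), c("1", "2")))
  fb <- lapply(1:8, function(l) stats::setNames(c(0.1, 0.9), c("1", "2")))
  structured <- merge_gt(hwe_site_gt(20, fa, "a", "x"),
                         hwe_site_gt(20, fb, "b", "y"))
  r1 <- admixture_mcmc(structured, 1, 500, 250, seed = 4)
  r2 <- admixture_mcmc(structured, 2, 800, 400, seed = 4)
  expect_gt(r2$lnPD - r1$lnPD, 20)
  pan <- merge_gt(hwe_site_gt(20, fa, "a", "x"),
                  hwe_site_gt(20, fa, "b", "y"))
  p1 <- admixture_mcmc(pan, 1, 500, 250, seed = 5)
  p2 <- admixture_mcmc(pan, 2, 800, 400, seed = 5)
  expect_lt(p2$lnPD - p1$lnPD, 20)
})

test_that("posterior-mean Q is stable across seeds on structured data", {
  set.seed(10)
  fa <- lapply(1:10, function(l) stats::setNames(c(0.95, 0.05), c("1", "2")))
  fb <- lapply(1:10, function(l) stats::setNames(c(0.05, 0.95), c("1", "2")))
  gt <- merge_gt(hwe_site_gt(15, fa, "a", "x"), hwe_site_gt(15, fb, "b", "y"))
  ra <- admixture_mcmc(gt, 2, 600, 300, seed = 11)
  rb <- admixture_mcmc(gt, 2, 600, 300, seed = 99)
  perm <- foxscape:::greedy_match_columns(ra$Q, rb$Q)
  for (k in 1:2)
    expect_gt(stats::cor(ra$Q[, k], rb$Q[, perm][, k]), 0.95)
})

test_that("correlated-frequency model runs and matches on clean splits", {
  geno <- list()
  for (i in 1:10) {
    pop <- if (i <= 5) "a" else "b"
    al <- if (i <= 5) "1/1" else "2/2"
    geno[[paste0("i", i)]] <- c(list(pop), rep(list(al), 8))
  }
  gt <- make_gt(geno)
  r <- admixture_mcmc(gt, 2, 600, 300, seed = 6, freq_model = "correlated")
  col_a <- which.max(colMeans(r$Q[1:5, , drop = FALSE]))
  expect_true(all(r$Q[1:5, col_a] > 0.95))
  expect_true(all(r$Q[6:10, 3 - col_a] > 0.95))
})

test_that("constructed Q hierarchies choose the highest nested K", {
  # 30 individuals: clean 2-split at K=2, sub-split of cluster 1 at K=3
  n <- 30
  site <- rep(c("s1", "s2", "s3"), each = 10)
  q2 <- matrix(0, n, 2); q2[1:20, 1] <- 1; q2[21:30, 2] <- 1
  q3 <- matrix(0, n, 3)
  q3[1:10, 1] <- 1; q3[11:20, 2] <- 1; q3[21:30, 3] <- 1
  runs <- list(fake_run(matrix(1, n, 1), site),
               fake_run(q2, site), fake_run(q3, site))
  ph <- align_runs_build_profiles(runs)
  expect_true(all(ph$nesting$nested))
  expect_equal(ph$chosen_K, 3)
  expect_equal(dim(ph$profiles), c(n, 3))
  # a non-nested K=3 (splits across the K=2 boundary) stops the chain
  q3bad <- matrix(0, n, 3)
  q3bad[c(1:7, 21:25), 1] <- 1; q3bad[8:20, 2] <- 1; q3bad[26:30, 3] <- 1
  ph2 <- align_runs_build_profiles(list(fake_run(matrix(1, n, 1), site),
                                        fake_run(q2, site),
                                        fake_run(q3bad, site)))
  expect_equal(ph2$chosen_K, 2)
})

test_that("noisy replicate disagreement flags multimodality and stops the chain", {
  set.seed(31)
  n <- 40
  site <- rep(c("s1", "s2"), each = 20)
  q2a <- matrix(0.5 + rnorm(n * 2, 0, 0.05), n, 2)
  q2a <- q2a / rowSums(q2a)
  q2b <- matrix(0.5 + rnorm(n * 2, 0, 0.05), n, 2)
  q2b <- q2b / rowSums(q2b)
  runs <- list(fake_run(matrix(1, n, 1), site),
               fake_run(q2a, site), fake_run(q2b, site))
  ph <- align_runs_build_profiles(runs)
  expect_true(2 %in% ph$multimodal_K)
  expect_equal(ph$chosen_K, 1)
})

test_that("migrant classification follows the q-threshold rules", {
  Q <- rbind(c(1.0, 0.0),    # resident of s1's home cluster
             c(0.95, 0.05),  # sampled in s2 but assigns to cluster 1
             c(0.6, 0.4),    # admixed, below threshold
             c(0.05, 0.95),  # resident of s2
             c(0.1, 0.9))
  site <- c("s1", "s2", "s1", "s2", "s2")
  run <- fake_run(Q, site)
  calls <- classify_migrants(run, q_threshold = 0.75)
  expect_equal(calls$class,
               c("resident", "first-generation migrant", "admixed",
                 "resident", "resident"))
  expect_equal(calls$source_sites[2], "s1")
  # deterministic given Q and threshold
  expect_identical(calls, classify_migrants(run, q_threshold = 0.75))
  # admixed iff q_max < threshold
  expect_true(all((calls$q_max < 0.75) == (calls$class == "admixed")))
})

test_that("home-cluster ties break toward the higher mean q with a note", {
  Q <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.95, 0.05), c(0.1, 0.9))
  site <- rep("s1", 4)
  expect_message(calls <- classify_migrants(fake_run(Q, site)), "tie")
})

test_that("temporal composition tracks replacement and rejects bad periods", {
  Q <- rbind(c(1, 0), c(1, 0), c(0.1, 0.9), c(0, 1))
  run <- fake_run(Q, rep("s1", 4))
  run$date <- stats::setNames(c(1997, 1999, 2004, 2006), rownames(run$Q))
  tc <- temporal_composition(run, periods = list(early = c(1996, 2000),
                                                 late = c(2001, 2007)))
  expect_equal(unname(tc$n), c(2L, 2L))
  expect_equal(unname(tc$l1_change), sum(abs(c(0.05, 0.95) - c(1, 0))))
  # identical composition -> change 0
  runb <- fake_run(rbind(c(1, 0), c(1, 0), c(1, 0), c(1, 0)), rep("s1", 4))
  runb$date <- run$date
  tcb <- temporal_composition(runb, periods = list(early = c(1996, 2000),
                                                   late = c(2001, 2007)))
  expect_equal(unname(tcb$l1_change), 0)
  expect_error(temporal_composition(run, periods = list(a = c(1996, 2000))),
               ">= 2 periods")
  expect_error(temporal_composition(run, periods = list(a = c(1996, 2000),
                                                        b = c(2020, 2021))),
               "empty period")
})

test_that("simulated resident replacement raises the migrant fraction", {
  # early period: residents of cluster 1; late period: immigrants (cluster 2)
  n <- 40
  Q <- rbind(matrix(rep(c(0.97, 0.03), 15), ncol = 2, byrow = TRUE),
             matrix(rep(c(0.9, 0.1), 5), ncol = 2, byrow = TRUE),
             matrix(rep(c(0.08, 0.92), 12), ncol = 2, byrow = TRUE),
             matrix(rep(c(0.55, 0.45), 8), ncol = 2, byrow = TRUE))
  site <- c(rep("home", 20), rep("home", 20), rep("away", 0))
  # a second site fixes cluster 2 as its home so calls can be migrants
  Q <- rbind(Q, matrix(rep(c(0.02, 0.98), 10), ncol = 2, byrow = TRUE))
  site <- c(site, rep("away", 10))
  run <- fake_run(Q, site)
  run$date <- stats::setNames(c(rep(1998, 20), rep(2005, 20), rep(2000, 10)),
                              rownames(run$Q))
  calls <- classify_migrants(run)
  tc <- temporal_composition(run, calls = calls,
                             periods = list(early = c(1997, 2000),
                                            late = c(2001, 2007)))
  expect_gt(tc$migrant_fraction[["late"]], tc$migrant_fraction[["early"]])
  expect_gt(max(tc$l1_change), 0.5)
})
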