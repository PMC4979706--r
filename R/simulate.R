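#' Configuration for the metapopulation simulator
#'
#' Defaults emulate the study system: several independent founder events
#' from a shared source pool (small numbers of released pairs), drift over
#' tens of generations at modest census sizes, male-biased migration shaped
#' by the landscape, and maternally inherited haplotypes.
#'
#' @param n_sites number of sites (default 8 founding populations).
#' @param coords optional [site_map()]; default: sites placed uniformly at
#'   random in a 600 x 600 km study area at simulation time.
#' @param landscape optional [raster_grid()] resistance surface; migration
#'   weights are then 1/resistance-distance, otherwise 1/Euclidean.
#' @param founders_per_site breeding pairs founding each site (default 3).
#' @param generations forward generations (default 30).
#' @param N per-site census size (default 100).
#' @param m_m,m_f male and female per-generation migration rates
#'   (default 0.04 and 0.01: fourfold male-biased gene flow).
#' @param n_loci microsatellite loci (default 13).
#' @param n_alleles_source alleles per locus in the source pool (default 8).
#' @param n_haplotypes mitochondrial haplotypes in the source pool
#'   (default 10).
#' @param mutation_model `"SMM"` or `"none"`; `mutation_rate` per copy per
#'   generation (default SMM at 5e-4; set `"none"` for calibration runs).
#' @param mode `"founder"` (founder bottleneck then growth) or
#'   `"equilibrium"` (sites start as N draws from the source pool).
#' @param monogamy breed from exclusive pairs instead of random unions.
#' @param sample_size individuals genotyped per site at the end.
#' @param missing_rate fraction of genotype calls dropped at sampling.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 8, coords = NULL, landscape = NULL,
                       founders_per_site = 3, generations = 30, N = 100,
                       m_m = 0.04, m_f = 0.01, n_loci = 13,
                       n_alleles_source = 8, n_haplotypes = 10,
                       mutation_model = c("SMM", "none"),
                       mutation_rate = 5e-4,
                       mode = c("founder", "equilibrium"),
                       monogamy = FALSE, sample_size = 30,
                       missing_rate = 0) {
  stopifnot(m_m >= 0, m_m <= 1, m_f >= 0, m_f <= 1, N >= 2, generations >= 0)
  structure(list(n_sites = n_sites, coords = coords, landscape = landscape,
                 founders_per_site = founders_per_site,
                 generations = generations, N = N, m_m = m_m, m_f = m_f,
                 n_loci = n_loci, n_alleles_source = n_alleles_source,
                 n_haplotypes = n_haplotypes,
                 mutation_model = match.arg(mutation_model),
                 mutation_rate = mutation_rate,
                 mode = match.arg(mode), monogamy = monogamy,
                 sample_size = sample_size, missing_rate = missing_rate),
            class = "sim_config")
}

#' Forward-time metapopulation simulation
#'
#' Non-overlapping generations, even sex ratio, random union of gametes
#' within site (optionally monogamous pairs). Each generation, a
#' Binomial(N_sex, m_sex) number of individuals of each sex is replaced by
#' immigrants drawn from other sites with probability proportional to
#' 1/distance (resistance distance when a landscape is supplied, else
#' Euclidean). Mitochondrial haplotypes follow mothers only.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed; output is bit-reproducible given (cfg, seed).
#' @return list: `genotypes` ([genotype_table()], repeat-score alleles),
#'   `haplotypes` ([haplotype_counts()]), `sites` ([site_map()]), `truth`
#'   (realized migrant counts per generation and sex, founder states,
#'   source pool, seed).
#' @export
simulate_metapopulation <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  ns <- cfg$n_sites; L <- cfg$n_loci; N <- cfg$N
  sites <- cfg$coords
  if (is.null(sites))
    sites <- site_map(paste0("site", seq_len(ns)),
                      stats::runif(ns, 0, 600), stats::runif(ns, 0, 600))
  if (nrow(sites) != ns) stop("coords must have n_sites rows")
  # migration weights
  if (!is.null(cfg$landscape)) {
    dres <- resistance_distance(cfg$landscape, sites)
    if (dres$has_infinite && (cfg$m_m > 0 || cfg$m_f > 0))
      stop("disconnected landscape with nonzero migration")
    W <- 1 / dres$values
  } else {
    W <- 1 / euclidean_distances(sites)$values
  }
  diag(W) <- 0
  # source pool: per-locus allele ladders with broken-stick frequencies
  src_freqs <- lapply(seq_len(L), function(l) {
    k <- cfg$n_alleles_source
    f <- stats::rgamma(k, 1); f <- f / sum(f)
    stats::setNames(f, as.character(seq(100, by = 2, length.out = k)))
  })
  hap_f <- stats::rgamma(cfg$n_haplotypes, 1)
  hap_freqs <- stats::setNames(hap_f / sum(hap_f),
                               paste0("H", seq_len(cfg$n_haplotypes)))
  draw_pool <- function(n) {
    a <- array(0L, c(n, L, 2))
    for (l in seq_len(L)) {
      lbl <- as.integer(names(src_freqs[[l]]))
      a[, l, ] <- lbl[sample.int(length(lbl), 2 * n, replace = TRUE,
                                 prob = src_freqs[[l]])]
    }
    list(alleles = a,
         sex = sample(rep(c("M", "F"), length.out = n)),
         hap = sample(names(hap_freqs), n, replace = TRUE, prob = hap_freqs))
  }
  pop <- vector("list", ns)
  founders <- vector("list", ns)
  for (s in seq_len(ns)) {
    n0 <- if (cfg$mode == "founder") 2L * cfg$founders_per_site else N
    p <- draw_pool(n0)
    if (cfg$mode == "founder")  # guarantee pairs
      p$sex <- rep(c("M", "F"), cfg$founders_per_site)
    pop[[s]] <- p
    founders[[s]] <- p
  }
  mig_m <- matrix(0L, cfg$generations, ns)
  mig_f <- matrix(0L, cfg$generations, ns)
  mutate <- function(a) {
    if (cfg$mutation_model == "none" || cfg$mutation_rate <= 0) return(a)
    hit <- which(stats::runif(length(a)) < cfg$mutation_rate)
    if (length(hit))
      a[hit] <- a[hit] + sample(c(-1L, 1L), length(hit), replace = TRUE)
    a
  }
  for (g in seq_len(cfg$generations)) {
    # reproduction within each site
    newpop <- vector("list", ns)
    for (s in seq_len(ns)) {
      p <- pop[[s]]
      males <- which(p$sex == "M"); females <- which(p$sex == "F")
      if (!length(males) || !length(females))
        stop(sprintf("site %d lost one sex at generation %d", s, g))
      if (cfg$monogamy) {
        np <- min(length(males), length(females))
        pm <- sample(males)[seq_len(np)]; pf <- sample(females)[seq_len(np)]
        pair <- sample.int(np, N, replace = TRUE)
        mo <- pf[pair]; fa <- pm[pair]
      } else {
        mo <- sample(females, N, replace = TRUE)
        fa <- sample(males, N, replace = TRUE)
      }
      a <- array(0L, c(N, L, 2))
      for (l in seq_len(L)) {
        pick_m <- sample.int(2, N, replace = TRUE)
        pick_f <- sample.int(2, N, replace = TRUE)
        a[, l, 1] <- mutate(p$alleles[cbind(mo, l, pick_m)])
        a[, l, 2] <- mutate(p$alleles[cbind(fa, l, pick_f)])
      }
      newpop[[s]] <- list(alleles = a,
                          sex = sample(c("M", "F"), N, replace = TRUE),
                          hap = p$hap[mo])
    }
    # migration: replace Binomial draws of each sex with immigrants
    snapshot <- newpop
    if (ns > 1 && (cfg$m_m > 0 || cfg$m_f > 0)) {
      for (s in seq_len(ns)) {
        for (sx in c("M", "F")) {
          rate <- if (sx == "M") cfg$m_m else cfg$m_f
          here <- which(newpop[[s]]$sex == sx)
          if (!length(here) || rate <= 0) next
          nmig <- stats::rbinom(1, length(here), rate)
          if (!nmig) next
          tgt <- sample(here, nmig)
          others <- seq_len(ns)[-s]
          srcs <- others[sample.int(ns - 1L, nmig, replace = TRUE,
                                    prob = W[s, -s])]
          for (ii in seq_len(nmig)) {
            from <- srcs[ii]
            cand <- which(snapshot[[from]]$sex == sx)
            don <- cand[sample.int(length(cand), 1)]
            newpop[[s]]$alleles[tgt[ii], , ] <- snapshot[[from]]$alleles[don, , ]
            newpop[[s]]$hap[tgt[ii]] <- snapshot[[from]]$hap[don]
          }
          if (sx == "M") mig_m[g, s] <- nmig else mig_f[g, s] <- nmig
        }
      }
    }
    pop <- newpop
  }
  # final sampling
  ids <- character(0); site_lab <- character(0); sex_lab <- character(0)
  hap_lab <- character(0)
  take <- lapply(seq_len(ns), function(s) {
    n_here <- length(pop[[s]]$sex)
    sort(sample.int(n_here, min(cfg$sample_size, n_here)))
  })
  n_tot <- sum(lengths(take))
  arr <- array(NA_character_, c(n_tot, L, 2))
  row <- 0L
  for (s in seq_len(ns)) {
    for (i in take[[s]]) {
      row <- row + 1L
      arr[row, , ] <- as.character(pop[[s]]$alleles[i, , ])
      ids <- c(ids, sprintf("%s_i%03d", sites$site[s], i))
      site_lab <- c(site_lab, sites$site[s])
      sex_lab <- c(sex_lab, pop[[s]]$sex[i])
      hap_lab <- c(hap_lab, pop[[s]]$hap[i])
    }
  }
  if (cfg$missing_rate > 0) {
    drop <- which(stats::runif(n_tot * L) < cfg$missing_rate)
    for (d in drop) {
      i <- ((d - 1) %% n_tot) + 1; l <- ((d - 1) %/% n_tot) + 1
      arr[i, l, ] <- NA_character_
    }
  }
  gt <- genotype_table(arr, ids, paste0("loc", seq_len(L)), site_lab,
                       sex = sex_lab,
                       repeat_loci = rep(TRUE, L))
  haps <- sort(unique(hap_lab))
  hc_m <- t(vapply(sites$site, function(s)
    vapply(haps, function(h) sum(hap_lab == h & site_lab == s), integer(1)),
    integer(length(haps))))
  hc_m <- matrix(hc_m, nrow = ns, dimnames = list(sites$site, haps))
  list(genotypes = gt,
       haplotypes = haplotype_counts(hc_m),
       sites = sites,
       truth = list(migrants_male = mig_m, migrants_female = mig_f,
                    founders = founders, source_freqs = src_freqs,
                    hap_freqs = hap_freqs,
                    sample_haplotypes = stats::setNames(hap_lab, ids),
                    seed = seed, config = cfg))
}
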