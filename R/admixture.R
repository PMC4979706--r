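#' Bayesian admixture clustering (Structure-style Gibbs sampler)
#'
#' The classic admixture model: each allele copy of individual i at locus l
#' originates from cluster k with probability q_ik, and cluster k carries
#' allele frequencies p_kl. A Gibbs sampler alternates (1) allele-copy
#' origins Z given Q and P, (2) cluster allele frequencies P from their
#' Dirichlet full conditional, (3) ancestry vectors Q ~ Dirichlet(alpha +
#' copy counts), and (4) a Metropolis step on the symmetric Dirichlet
#' parameter alpha (uniform prior on (0, `alpha_max`)). Under the
#' correlated-frequencies model (F-model) the prior on p_kl is
#' Dirichlet(p_A,l (1 - F_k)/F_k) with the ancestral frequencies p_A and
#' per-cluster drift F_k themselves updated by Metropolis steps.
#'
#' ln P(D) is estimated as in the original method: mean minus half the
#' variance of the data log-likelihood over post-burn-in cycles. It is a
#' comparison statistic across K, not a model-choice criterion.
#'
#' @param gt a [genotype_table()].
#' @param K number of clusters (>= 1).
#' @param cycles total MCMC cycles (> burn_in).
#' @param burn_in cycles discarded before averaging.
#' @param seed RNG seed.
#' @param freq_model `"correlated"` (default, the F-model) or
#'   `"independent"`.
#' @param alpha_init,alpha_sd,alpha_max initial value, Metropolis proposal
#'   sd, and prior upper bound for alpha.
#' @param init `"kmeans"` (default) seeds the chain from a k-means
#'   clustering of the individual allele-dose matrix, which lets replicate
#'   chains find the dominant mode on strongly structured data (replicate
#'   disagreement then indicates genuine multimodality); `"random"` starts
#'   from the symmetric prior state.
#' @return list of class `cluster_run`: `K`, `Q` (posterior-mean ancestry,
#'   rows sum to 1), `lnPD`, `lnL_trace`, `alpha_trace`, `P_mean`,
#'   `cycles`, `burn_in`, `seed`, `freq_model`, `nonconverged_alpha`.
#' @export
admixture_mcmc <- function(gt, K, cycles = 2000, burn_in = 1000, seed = 1,
                           freq_model = c("correlated", "independent"),
                           alpha_init = 1, alpha_sd = 0.05, alpha_max = 10,
                           init = c("kmeans", "random")) {
  stopifnot(inherits(gt, "genotype_table"), K >= 1, cycles > burn_in)
  freq_model <- match.arg(freq_model)
  init <- match.arg(init)
  set.seed(seed)
  n <- length(gt$individuals); L <- length(gt$loci)
  # integer-coded alleles per locus
  x1 <- x2 <- matrix(NA_integer_, n, L)
  n_alleles <- integer(L); allele_names <- vector("list", L)
  for (l in seq_len(L)) {
    al <- unique(stats::na.omit(c(gt$alleles[, l, 1], gt$alleles[, l, 2])))
    allele_names[[l]] <- al
    n_alleles[l] <- length(al)
    x1[, l] <- match(gt$alleles[, l, 1], al)
    x2[, l] <- match(gt$alleles[, l, 2], al)
  }
  if (any(n_alleles == 0)) stop("locus with no typed calls")
  lambda <- 1  # flat Dirichlet base frequency prior (independent model)
  Q <- matrix(1 / K, n, K)
  P <- lapply(seq_len(L), function(l)
    matrix(1 / n_alleles[l], K, n_alleles[l]))
  if (init == "kmeans" && K > 1) {
    # allele-dose matrix, mean-imputed for missing calls
    dose <- NULL
    for (l in seq_len(L)) for (a in seq_len(n_alleles[l])) {
      v <- (x1[, l] == a) + (x2[, l] == a)
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      dose <- cbind(dose, v)
    }
    km <- tryCatch(stats::kmeans(dose, centers = K, nstart = 5),
                   error = function(e) NULL)
    if (!is.null(km)) {
      Q <- matrix(0.1 / (K - 1), n, K)
      Q[cbind(seq_len(n), km$cluster)] <- 0.9
      for (l in seq_len(L)) {
        cnt0 <- matrix(0.5, K, n_alleles[l])  # light smoothing
        for (copy in 1:2) {
          x <- if (copy == 1) x1[, l] else x2[, l]
          ok <- which(!is.na(x))
          tab <- tabulate((x[ok] - 1L) * K + km$cluster[ok],
                          K * n_alleles[l])
          cnt0 <- cnt0 + matrix(tab, K, n_alleles[l])
        }
        P[[l]] <- cnt0 / rowSums(cnt0)
      }
    }
  }
  pA <- lapply(seq_len(L), function(l) rep(1 / n_alleles[l], n_alleles[l]))
  Fk <- rep(0.01, K)
  alpha <- alpha_init
  keep <- cycles - burn_in
  Q_sum <- matrix(0, n, K)
  P_sum <- lapply(seq_len(L), function(l) matrix(0, K, n_alleles[l]))
  lnL_trace <- numeric(keep)
  alpha_trace <- numeric(cycles)
  z1 <- z2 <- matrix(1L, n, L)
  for (cy in seq_len(cycles)) {
    # -- Z given Q, P; accumulate copy counts
    m_ik <- matrix(0, n, K)
    cnt <- lapply(seq_len(L), function(l) matrix(0, K, n_alleles[l]))
    lnL <- 0
    for (l in seq_len(L)) {
      for (copy in 1:2) {
        x <- if (copy == 1) x1[, l] else x2[, l]
        ok <- which(!is.na(x))
        if (!length(ok)) next
        W <- Q[ok, , drop = FALSE] * t(P[[l]])[x[ok], , drop = FALSE]
        rs <- rowSums(W)
        lnL <- lnL + sum(log(rs))
        z <- sample_rows(W, rs)
        if (copy == 1) z1[ok, l] <- z else z2[ok, l] <- z
        m_ik[cbind(ok, z)] <- m_ik[cbind(ok, z)] + 1
        tab <- tabulate((x[ok] - 1L) * K + z, K * n_alleles[l])
        cnt[[l]] <- cnt[[l]] + matrix(tab, K, n_alleles[l])
      }
    }
    # -- P given Z
    for (l in seq_len(L)) {
      prior <- if (freq_model == "independent")
        matrix(lambda, K, n_alleles[l], byrow = TRUE)
      else outer((1 - Fk) / Fk, pA[[l]])
      P[[l]] <- rdirichlet_rows(prior + cnt[[l]])
    }
    if (freq_model == "correlated") {
      # MH on ancestral frequencies pA (per locus) and drift Fk
      for (l in seq_len(L)) {
        prop <- as.numeric(rdirichlet_rows(matrix(pA[[l]] * 200 + 0.5, 1)))
        if (all(prop > 1e-8)) {
          lr <- fmodel_loglik_pA(prop, P[[l]], Fk) -
            fmodel_loglik_pA(pA[[l]], P[[l]], Fk) +
            ddirichlet_log(pA[[l]], prop * 200 + 0.5) -
            ddirichlet_log(prop, pA[[l]] * 200 + 0.5)
          if (log(stats::runif(1)) < lr) pA[[l]] <- prop
        }
      }
      for (k in seq_len(K)) {
        prop <- Fk[k] * exp(stats::rnorm(1, 0, 0.2))
        if (prop > 1e-5 && prop < 0.9) {
          lr <- sum(vapply(seq_len(L), function(l)
            ddirichlet_log(P[[l]][k, ], pA[[l]] * (1 - prop) / prop), numeric(1))) -
            sum(vapply(seq_len(L), function(l)
              ddirichlet_log(P[[l]][k, ], pA[[l]] * (1 - Fk[k]) / Fk[k]), numeric(1))) +
            log(prop) - log(Fk[k])  # log-scale random-walk Jacobian
          if (log(stats::runif(1)) < lr) Fk[k] <- prop
        }
      }
    }
    # -- Q given Z
    if (K == 1) Q[, 1] <- 1
    else Q <- rdirichlet_rows(m_ik + alpha)
    # -- alpha Metropolis (symmetric Dirichlet prior on Q rows)
    if (K > 1) {
      prop <- alpha + stats::rnorm(1, 0, alpha_sd)
      if (prop > 0 && prop < alpha_max) {
        lq <- sum(log(Q))
        lr <- n * (lgamma(K * prop) - K * lgamma(prop)) + (prop - 1) * lq -
          (n * (lgamma(K * alpha) - K * lgamma(alpha)) + (alpha - 1) * lq)
        if (log(stats::runif(1)) < lr) alpha <- prop
      }
    }
    alpha_trace[cy] <- alpha
    if (cy > burn_in) {
      Q_sum <- Q_sum + Q
      for (l in seq_len(L)) P_sum[[l]] <- P_sum[[l]] + P[[l]]
      lnL_trace[cy - burn_in] <- lnL
    }
  }
  Q_mean <- Q_sum / keep
  Q_mean <- Q_mean / rowSums(Q_mean)
  rownames(Q_mean) <- gt$individuals
  lnPD <- mean(lnL_trace) - stats::var(lnL_trace) / 2
  post <- alpha_trace[(burn_in + 1):cycles]
  nonconv <- K > 1 && (stats::sd(post) > alpha_max / 4 ||
                         min(post) <= 1e-4 || max(post) >= alpha_max - 1e-4)
  if (nonconv)
    warning("alpha trace suggests non-convergence; inspect alpha_trace")
  P_mean <- lapply(seq_len(L), function(l) {
    m <- P_sum[[l]] / keep
    colnames(m) <- allele_names[[l]]
    m
  })
  names(P_mean) <- gt$loci
  structure(list(K = K, Q = Q_mean, lnPD = lnPD, lnL_trace = lnL_trace,
                 alpha_trace = alpha_trace, P_mean = P_mean,
                 cycles = cycles, burn_in = burn_in, seed = seed,
                 freq_model = freq_model, nonconverged_alpha = nonconv,
                 site = gt$site, date = gt$date),
            class = "cluster_run")
}

#' @export
print.cluster_run <- function(x, ...) {
  cat(sprintf("cluster_run: K = %d, %d individuals, ln P(D) = %.1f (%s frequencies, %d cycles)\n",
              x$K, nrow(x$Q), x$lnPD, x$freq_model, x$cycles))
  invisible(x)
}

# sample one category per row of an unnormalized weight matrix
sample_rows <- function(W, rs = rowSums(W)) {
  u <- stats::runif(nrow(W)) * rs
  cum <- W
  for (k in seq_len(ncol(W) - 1)) cum[, k + 1] <- cum[, k + 1] + cum[, k]
  1L + as.integer(rowSums(cum < u))
}

# one Dirichlet draw per row of a (positive) parameter matrix
rdirichlet_rows <- function(A) {
  g <- matrix(stats::rgamma(length(A), shape = pmax(A, 1e-8)), nrow(A))
  g <- g + 1e-300
  g / rowSums(g)
}

ddirichlet_log <- function(x, a) {
  x <- pmax(x, 1e-300)
  sum((a - 1) * log(x)) + lgamma(sum(a)) - sum(lgamma(a))
}

# log-likelihood of ancestral frequencies pA given cluster frequencies
fmodel_loglik_pA <- function(pA, Pl, Fk) {
  sum(vapply(seq_along(Fk), function(k)
    ddirichlet_log(Pl[k, ], pA * (1 - Fk[k]) / Fk[k]), numeric(1)))
}

#' Write ancestry fractions in Structure-like matrix form
#' @param run a `cluster_run`.
#' @param path output file.
#' @export
write_cluster_run <- function(run, path) {
  df <- data.frame(id = rownames(run$Q), site = unname(run$site),
                   round(run$Q, 5), check.names = FALSE)
  names(df)[-(1:2)] <- paste0("q", seq_len(run$K))
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
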