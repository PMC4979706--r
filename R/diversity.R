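#' Gene (haplotype) diversity
#'
#' h = 1 - sum(p_i^2), the probability that two randomly drawn copies carry
#' different haplotypes. The uncorrected form is the default; the unbiased
#' small-sample variant multiplies by n/(n-1).
#'
#' @param counts nonnegative integer haplotype counts.
#' @param unbiased apply the n/(n-1) correction.
#' @return diversity in [0, 1].
#' @export
gene_diversity <- function(counts, unbiased = FALSE) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative counts")
  n <- sum(counts)
  if (n < 1) stop("all-zero counts: diversity undefined")
  p <- counts / n
  h <- 1 - sum(p^2)
  if (unbiased) {
    if (n < 2) stop("unbiased diversity needs n >= 2")
    h <- h * n / (n - 1)
  }
  h
}

#' Global mtDNA F_ST from the diversity partition
#'
#' F_ST = 1 - mean(h_within) / h_total: total gene diversity from the pooled
#' counts over all rows, within-site mean as the unweighted average of
#' per-site diversities over the included sites.
#'
#' Inclusion into the within-site mean follows an explicit list. When the
#' table carries a declared per-site diversity column (as published tables
#' do), the default list is exactly the rows with a declared value: dash
#' rows mark small samples and unknown or mixed provenance. Without that
#' column the default is sites with n >= `min_n`. Rows named in `exclude`
#' are dropped regardless. A row whose counts fail its declared-n checksum
#' has unreliable counts; when a declared per-site diversity is available it
#' is used for that row's within-site term (with a warning), otherwise the
#' row is dropped from the within mean.
#'
#' @param hc a [haplotype_counts()].
#' @param include explicit site inclusion list for the within-site mean;
#'   NULL for the default described above (pooled totals always use every
#'   row).
#' @param min_n minimum per-site sample size, used when no declared
#'   diversity column exists.
#' @param exclude site names excluded from the within-site mean.
#' @param unbiased passed to [gene_diversity()].
#' @return list: `h_total`, `h_within` (named per-site vector),
#'   `h_within_mean`, `h_within_sd`, `fst`, `included`.
#' @export
global_fst_from_diversity <- function(hc, include = NULL, min_n = 5,
                                      exclude = NULL, unbiased = FALSE) {
  stopifnot(inherits(hc, "haplotype_counts"))
  pooled <- colSums(hc$counts)
  h_total <- gene_diversity(pooled, unbiased)
  if (h_total == 0) {
    warning("pooled diversity is zero: F_ST undefined")
    return(list(h_total = 0, h_within = numeric(0), h_within_mean = NA_real_,
                h_within_sd = NA_real_, fst = NA_real_, included = character(0)))
  }
  n_site <- rowSums(hc$counts)
  if (is.null(include)) {
    include <- if (!is.null(hc$declared_diversity))
      hc$sites[!is.na(hc$declared_diversity)]
    else hc$sites[n_site >= min_n]
  }
  keep <- hc$sites %in% include & n_site >= 2 & !(hc$sites %in% exclude)
  h_within <- numeric(0)
  for (i in which(keep)) {
    hi <- gene_diversity(hc$counts[i, ], unbiased)
    if (!is.null(hc$declared_n) && !is.na(hc$declared_n[i]) &&
        hc$declared_n[i] != n_site[i]) {
      # counts fail their checksum: fall back to the declared diversity
      if (!is.null(hc$declared_diversity) && !is.na(hc$declared_diversity[i])) {
        warning(sprintf(
          "site '%s': counts (n = %d) fail declared-n checksum (%d); using declared diversity %.3f",
          hc$sites[i], n_site[i], hc$declared_n[i], hc$declared_diversity[i]))
        hi <- hc$declared_diversity[i]
      } else {
        warning(sprintf(
          "site '%s': counts fail declared-n checksum and no declared diversity; dropped",
          hc$sites[i]))
        next
      }
    }
    h_within <- c(h_within, stats::setNames(hi, hc$sites[i]))
  }
  list(h_total = h_total,
       h_within = h_within,
       h_within_mean = mean(h_within),
       h_within_sd = stats::sd(h_within),
       fst = 1 - mean(h_within) / h_total,
       included = names(h_within))
}

# Weir-Cockerham haploid variance-components theta for one site pair (or
# more), summing components over haplotypes. Counts: sites x haplotypes.
wc_haploid_theta <- function(counts) {
  counts <- as.matrix(counts)
  n <- rowSums(counts)
  if (any(n < 2)) stop("each site needs n >= 2")
  r <- nrow(counts)
  if (r < 2) stop("need >= 2 sites")
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  p <- counts / n
  num <- 0; den <- 0
  for (a in seq_len(ncol(counts))) {
    pa <- p[, a]
    pbar <- sum(n * pa) / sum(n)
    msp <- sum(n * (pa - pbar)^2) / (r - 1)
    msg <- sum(n * pa * (1 - pa)) / sum(n - 1)
    num <- num + (msp - msg)
    den <- den + (msp + (nc - 1) * msg)
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Pairwise haploid F_ST (Weir-Cockerham variance components)
#'
#' Per site pair, the haploid analogue of theta summed over haplotypes.
#' Negative estimates are reported as computed; the linearized matrix
#' x/(1-x) clamps negatives to 0 and caps values >= `cap` to +Inf (fully
#' fixed pairs), flagged for exclusion downstream.
#'
#' @param hc a [haplotype_counts()].
#' @param min_n minimum per-site n; smaller sites are dropped.
#' @param cap F_ST at or above this linearizes to +Inf.
#' @return list of [dist_matrix()]: `fst`, `linearized`, plus `dropped`.
#' @export
pairwise_haplotype_fst <- function(hc, min_n = 2, cap = 0.999) {
  stopifnot(inherits(hc, "haplotype_counts"))
  n <- rowSums(hc$counts)
  keep <- n >= max(2, min_n)
  dropped <- hc$sites[!keep]
  cts <- hc$counts[keep, , drop = FALSE]
  sites <- hc$sites[keep]
  k <- length(sites)
  if (k < 2) stop("need >= 2 sites with n >= ", min_n)
  f <- matrix(0, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    th <- wc_haploid_theta(cts[c(i, j), , drop = FALSE])
    f[i, j] <- f[j, i] <- th
  }
  lin <- pmax(f, 0)
  lin <- ifelse(lin >= cap & row(lin) != col(lin), Inf, lin / (1 - lin))
  diag(lin) <- 0
  n_inf <- sum(is.infinite(lin[upper.tri(lin)]))
  if (n_inf > 0)
    message(n_inf, " site pair(s) at or above the linearization cap -> +Inf")
  list(fst = structure(list(labels = sites, values = f,
                            method = "weir-cockerham-haploid",
                            has_infinite = FALSE), class = "dist_matrix"),
       linearized = dist_matrix(lin, method = "linearized-haploid-fst"),
       dropped = dropped)
}

#' Male-to-female gene-flow ratio from dual-marker F_ST
#'
#' Island-model contrast of biparentally and maternally inherited markers:
#' with nuclear F_ST = 1/(1 + 4N*mbar), mbar = (m_m + m_f)/2, and
#' mitochondrial F_ST = 1/(1 + N*m_f) (N/2 females, haploid maternal
#' transmission),
#'   m_m/m_f = [ (1/F_nuc - 1)/2 - (1/F_mt - 1) ] / (1/F_mt - 1).
#' A negative implied male migration rate (F_mt too close to F_nuc for the
#' model's admissible region) is reported as ratio 0 with a flag.
#'
#' @param fst_nuclear global nuclear (microsatellite) F_ST, in (0, 1).
#' @param fst_mt global mitochondrial F_ST, in (0, 1).
#' @return list: `fst_nuclear`, `fst_mt`, `mm_over_mf`, `admissible`.
#' @export
sex_biased_gene_flow_ratio <- function(fst_nuclear, fst_mt) {
  for (v in c(fst_nuclear, fst_mt))
    if (!is.finite(v) || v <= 0 || v >= 1)
      stop("F_ST inputs must lie strictly in (0, 1)")
  nmf <- 1 / fst_mt - 1                  # N * m_f
  nmm <- (1 / fst_nuclear - 1) / 2 - nmf # N * m_m
  admissible <- nmm >= 0
  ratio <- if (admissible) nmm / nmf else 0
  if (!admissible)
    warning("implied male gene flow negative; ratio floored at 0")
  list(fst_nuclear = fst_nuclear, fst_mt = fst_mt,
       mm_over_mf = ratio, admissible = admissible)
}
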