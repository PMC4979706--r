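#' Cluster profiles across K and nested-K selection
#'
#' Integrates runs over K = 1..K_max into per-individual "cluster
#' profiles": the sequence of modal cluster memberships at each K.
#' Replicate runs within a K are aligned to the first replicate by greedy
#' maximum-correlation matching of Q columns (label-switching resolution)
#' and averaged. A K is flagged multimodal when, after alignment, the
#' replicates disagree on the modal cluster of more than a tolerance
#' fraction of individuals -- the signature of runs settling in different
#' solutions, which removes that K from the nesting chain (mirroring the
#' practice of distrusting K levels whose replicate runs diverge).
#'
#' A K -> K+1 transition is "nested" when the members of every K+1 cluster
#' (by modal assignment) derive from a single K cluster, up to the same
#' tolerance fraction of individuals, and "informative" when K+1 actually
#' occupies more modal clusters than K, counting only clusters whose modal
#' membership exceeds the tolerance fraction of individuals (a level whose
#' extra cluster attracts no one, or a lone stray, adds no structure). The
#' chosen K is the highest K
#' reachable from the lowest level through transitions that are nested and
#' informative between non-multimodal levels.
#'
#' @param runs list of `cluster_run` objects covering >= 2 values of K
#'   (replicates at the same K allowed).
#' @param nesting_tolerance fraction of individuals allowed to violate
#'   nesting (and replicate modal agreement) at a level (default 0.05).
#' @return list of class `profile_hierarchy`: `profiles` (individual x K
#'   modal-cluster matrix), `profile_table` (frequency of each distinct
#'   profile), `nesting` (per-transition data.frame), `chosen_K`,
#'   `Q_by_K` (aligned mean Q per K), `multimodal_K`.
#' @export
align_runs_build_profiles <- function(runs, nesting_tolerance = 0.05) {
  stopifnot(length(runs) >= 2)
  Ks <- vapply(runs, function(r) r$K, integer(1))
  if (length(unique(Ks)) < 2) stop("need runs at >= 2 values of K")
  ids <- rownames(runs[[1]]$Q)
  n <- length(ids)
  Q_by_K <- list(); multimodal <- integer(0)
  for (K in sort(unique(Ks))) {
    reps <- runs[Ks == K]
    ref <- reps[[1]]$Q
    acc <- ref; nrep <- 1
    bad <- FALSE
    if (length(reps) > 1) for (r in reps[-1]) {
      perm <- greedy_match_columns(ref, r$Q)
      aligned <- r$Q[, perm, drop = FALSE]
      # judge replicate agreement on confidently assigned individuals:
      # genuinely admixed ones wobble between modal clusters without
      # indicating distinct posterior modes
      conf <- apply(ref, 1, max) >= 0.6 & apply(aligned, 1, max) >= 0.6
      if (!any(conf)) conf <- rep(TRUE, n)
      disagree <- mean(max.col(ref, ties.method = "first")[conf] !=
                         max.col(aligned, ties.method = "first")[conf])
      if (disagree > nesting_tolerance) bad <- TRUE
      acc <- acc + aligned; nrep <- nrep + 1
    }
    if (bad) multimodal <- c(multimodal, K)
    Q_by_K[[as.character(K)]] <- acc / nrep
  }
  K_levels <- sort(unique(Ks))
  profiles <- sapply(K_levels, function(K)
    max.col(Q_by_K[[as.character(K)]], ties.method = "first"))
  profiles <- matrix(profiles, nrow = n,
                     dimnames = list(ids, paste0("K", K_levels)))
  prof_str <- apply(profiles, 1, paste, collapse = "-")
  profile_table <- sort(table(prof_str), decreasing = TRUE)
  # multimodal levels drop out of the chain; transitions compare
  # consecutive retained levels
  chain <- K_levels[!(K_levels %in% multimodal)]
  if (!length(chain)) chain <- K_levels[1]
  nesting <- NULL
  for (i in seq_along(chain)[-1]) {
    K_lo <- chain[i - 1]; K_hi <- chain[i]
    lo <- profiles[, match(K_lo, K_levels)]
    hi <- profiles[, match(K_hi, K_levels)]
    viol <- 0L
    for (k in sort(unique(hi))) {
      members <- which(hi == k)
      parent_tab <- table(lo[members])
      viol <- viol + sum(parent_tab) - max(parent_tab)
    }
    nested <- viol <= nesting_tolerance * n
    # clusters whose modal membership does not exceed the tolerance
    # fraction (e.g. a single stray individual) do not count as structure
    occupied <- function(z) sum(table(z) > nesting_tolerance * n)
    informative <- occupied(hi) > occupied(lo)
    nesting <- rbind(nesting, data.frame(
      from_K = K_lo, to_K = K_hi, violations = viol,
      nested = nested, informative = informative))
  }
  chosen <- chain[1]
  for (i in seq_along(chain)[-1]) {
    if (nesting$nested[i - 1] && nesting$informative[i - 1])
      chosen <- chain[i]
    else break
  }
  structure(list(profiles = profiles, profile_table = profile_table,
                 nesting = nesting, chosen_K = chosen,
                 Q_by_K = Q_by_K, multimodal_K = multimodal),
            class = "profile_hierarchy")
}

#' @export
print.profile_hierarchy <- function(x, ...) {
  cat(sprintf("profile_hierarchy: K levels %s, chosen K = %d\n",
              paste(sub("K", "", colnames(x$profiles)), collapse = ", "),
              x$chosen_K))
  if (length(x$multimodal_K))
    cat("  multimodal K excluded from nesting chain:",
        paste(x$multimodal_K, collapse = ", "), "\n")
  print(x$nesting)
  invisible(x)
}

# greedy maximum-correlation bipartite matching of Q columns: returns the
# permutation of columns of `other` best matching `ref` (approximate)
greedy_match_columns <- function(ref, other) {
  K <- ncol(ref)
  if (K == 1) return(1L)
  cm <- suppressWarnings(stats::cor(ref, other))
  cm[!is.finite(cm)] <- 0
  perm <- integer(K)
  used <- logical(K)
  for (step in seq_len(K)) {
    best <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    perm[best[1]] <- best[2]
    cm[best[1], ] <- -Inf; cm[, best[2]] <- -Inf
  }
  perm
}

#' Classify residents, first-generation migrants and admixed individuals
#'
#' The home cluster of a site is the modal cluster among its members
#' (ties broken toward the higher mean q, logged). An individual with
#' q_max >= `q_threshold` is a resident if its modal cluster is the home
#' cluster, otherwise a first-generation migrant (its source is the modal
#' cluster's home site set); q_max < threshold is admixed.
#'
#' @param run a `cluster_run` (or any list with `Q` and `site`).
#' @param site_of optional named site vector overriding `run$site`.
#' @param q_threshold assignment threshold (default 0.75).
#' @return data.frame of class `migrant_calls`: `id`, `site`,
#'   `modal_cluster`, `q_max`, `class`, `home_cluster`, `source_sites`.
#' @export
classify_migrants <- function(run, site_of = NULL, q_threshold = 0.75) {
  Q <- run$Q
  site <- if (is.null(site_of)) run$site else site_of
  site <- site[rownames(Q)]
  if (anyNA(site)) stop("site_of must cover every individual in the run")
  modal <- max.col(Q, ties.method = "first")
  q_max <- Q[cbind(seq_len(nrow(Q)), modal)]
  sites <- sort(unique(unname(site)))
  home <- stats::setNames(integer(length(sites)), sites)
  for (s in sites) {
    members <- which(site == s)
    tab <- table(modal[members])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      meanq <- vapply(top, function(k)
        mean(Q[members, as.integer(k)]), numeric(1))
      message(sprintf("site '%s': home-cluster tie between %s broken by mean q",
                      s, paste(top, collapse = "/")))
      top <- top[which.max(meanq)]
    }
    home[s] <- as.integer(top[1])
  }
  cluster_sites <- lapply(seq_len(ncol(Q)), function(k)
    names(home)[home == k])
  cls <- ifelse(q_max < q_threshold, "admixed",
                ifelse(modal == home[site], "resident",
                       "first-generation migrant"))
  out <- data.frame(id = rownames(Q), site = unname(site),
                    modal_cluster = modal, q_max = q_max, class = cls,
                    home_cluster = unname(home[site]),
                    source_sites = vapply(seq_len(nrow(Q)), function(i) {
                      if (cls[i] != "first-generation migrant") return(NA_character_)
                      ss <- cluster_sites[[modal[i]]]
                      if (length(ss)) paste(ss, collapse = ";") else "(unsampled)"
                    }, character(1)),
                    row.names = NULL)
  class(out) <- c("migrant_calls", "data.frame")
  out
}

#' Cluster composition over time periods
#'
#' Splits individuals into calendar periods, reports the per-period mean
#' ancestry (mean Q), migrant fraction (from [classify_migrants()] calls if
#' provided), and an L1 change statistic between consecutive period
#' compositions.
#'
#' @param run a `cluster_run`.
#' @param periods list of length->=2 named numeric ranges `c(from, to)`
#'   (inclusive) applied to the run's dates (years).
#' @param date_of optional named date/year vector overriding `run`'s dates.
#' @param calls optional `migrant_calls` to add migrant fractions.
#' @return list: `composition` (period x cluster mean Q), `n` per period,
#'   `migrant_fraction` (or NA), `l1_change` between consecutive periods.
#' @export
temporal_composition <- function(run, periods, date_of = NULL, calls = NULL) {
  if (length(periods) < 2) stop("need >= 2 periods")
  Q <- run$Q
  dates <- as.numeric(if (is.null(date_of)) run$date else date_of[rownames(Q)])
  if (is.null(dates) || all(is.na(dates)))
    stop("no dates available for temporal composition")
  comp <- NULL; ns <- integer(0); migfrac <- numeric(0)
  for (pn in names(periods)) {
    rng <- periods[[pn]]
    inside <- which(!is.na(dates) & dates >= rng[1] & dates <= rng[2])
    if (!length(inside)) stop("empty period: ", pn)
    comp <- rbind(comp, colMeans(Q[inside, , drop = FALSE]))
    ns <- c(ns, length(inside))
    migfrac <- c(migfrac, if (is.null(calls)) NA_real_ else
      mean(calls$class[inside] == "first-generation migrant"))
  }
  rownames(comp) <- names(periods)
  l1 <- vapply(seq_len(nrow(comp) - 1), function(i)
    sum(abs(comp[i + 1, ] - comp[i, ])), numeric(1))
  names(l1) <- paste(names(periods)[-length(periods)],
                     names(periods)[-1], sep = " -> ")
  list(composition = comp, n = stats::setNames(ns, names(periods)),
       migrant_fraction = stats::setNames(migfrac, names(periods)),
       l1_change = l1)
}
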