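#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q are
#' broken by the lexicographically smallest label pair, so the topology is
#' deterministic on equidistant inputs. Negative branch lengths are set to
#' zero with the deficit transferred to the adjacent branch of the joined
#' pair, preserving path lengths between the two joined leaves.
#'
#' @param d a [dist_matrix()] with >= 3 labels and finite entries.
#' @return list of class `tree_result`: `tree` (an [ape] `phylo`),
#'   `support` (NULL until [bootstrap_support()]), `n_boot`.
#' @export
neighbor_joining <- function(d) {
  stopifnot(inherits(d, "dist_matrix"))
  if (d$has_infinite)
    stop("infinite distances: cap or exclude them upstream before NJ")
  m <- d$values
  n <- nrow(m)
  if (n < 3) stop("NJ needs >= 3 labels")
  labels <- d$labels
  # node bookkeeping for ape's phylo edge matrix
  n_tip <- n
  next_internal <- 2L * n_tip - 2L  # internal ids count down from 2n-2
  node_id <- seq_len(n_tip)
  edges <- matrix(0L, 0, 2); elen <- numeric(0)
  active <- seq_len(n)
  names(active) <- labels
  cur <- m
  cur_labels <- labels
  cur_ids <- node_id
  while (length(cur_ids) > 3L) {
    r <- nrow(cur)
    rs <- rowSums(cur)
    q <- (r - 2) * cur - outer(rs, rs, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pairlab <- cbind(pmin(cur_labels[cand[, 1]], cur_labels[cand[, 2]]),
                     pmax(cur_labels[cand[, 1]], cur_labels[cand[, 2]]))
    pick <- order(pairlab[, 1], pairlab[, 2])[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    dij <- cur[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- dij - li
    # negative-branch adjustment: zero the negative side, transfer to the other
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    u <- next_internal; next_internal <- next_internal - 1L
    edges <- rbind(edges, c(u, cur_ids[i]), c(u, cur_ids[j]))
    elen <- c(elen, li, lj)
    dnew <- (cur[i, ] + cur[j, ] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    cur_labels <- c(cur_labels[keep], paste0("(", pairlab[pick, 1], ")"))
    cur_ids <- c(cur_ids[keep], u)
  }
  # final 3-node star: closed-form three-point branch lengths
  u <- n_tip + 1L  # ape root id
  d12 <- cur[1, 2]; d13 <- cur[1, 3]; d23 <- cur[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  lens <- c(l1, l2, l3)
  lens[lens < 0] <- 0
  edges <- rbind(edges, cbind(u, cur_ids))
  elen <- c(elen, lens)
  # internal ids are n+1 .. 2n-2 by construction (ape numbering, root n+1)
  internal <- sort(unique(edges[edges > n_tip]))
  tree <- list(edge = edges, edge.length = elen,
               tip.label = labels, Nnode = length(internal))
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  structure(list(tree = tree, support = NULL, n_boot = 0L),
            class = "tree_result")
}

#' @export
print.tree_result <- function(x, ...) {
  cat(sprintf("tree_result: %d tips%s\n", length(x$tree$tip.label),
              if (x$n_boot > 0) sprintf(", bootstrap support from %d replicates", x$n_boot)
              else ""))
  print(x$tree)
  invisible(x)
}

#' Locus-bootstrap support for the NJ tree of Nei's D_A distances
#'
#' Loci are resampled with replacement, D_A and its NJ tree recomputed per
#' replicate, and support for each internal edge of the original tree is the
#' percentage of replicates whose tree contains the same bipartition
#' (support is attached to the original-tree bipartitions, not a consensus
#' topology).
#'
#' @param gt a [genotype_table()].
#' @param n_boot bootstrap replicates (default 999).
#' @param seed RNG seed.
#' @return a `tree_result` with `support` (per internal node, percent) and
#'   the tree's `node.label` set to the support values.
#' @export
bootstrap_support <- function(gt, n_boot = 999, seed = 1) {
  stopifnot(inherits(gt, "genotype_table"))
  if (length(gt$loci) < 2)
    warning("single locus: all bootstrap replicates are identical")
  set.seed(seed)
  sites <- sort(unique(unname(gt$site)))
  counts <- allele_count_tables(gt, sites)
  typed <- typed_counts(gt, sites)
  base <- nei_da_from_counts(counts, typed, sites)
  res <- neighbor_joining(base$da)
  L <- length(gt$loci)
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(L, L, replace = TRUE)
    db <- nei_da_from_counts(counts[idx], typed[, idx, drop = FALSE], sites)
    boots[[b]] <- neighbor_joining(db$da)$tree
  }
  class(boots) <- "multiPhylo"
  cnt <- ape::prop.clades(res$tree, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  support <- 100 * cnt / n_boot
  res$tree$node.label <- round(support, 1)
  res$support <- support
  res$n_boot <- n_boot
  res
}

#' Write a tree (with support as internal node labels) to Newick
#' @param tr a `tree_result`.
#' @param path output file.
#' @export
write_tree_newick <- function(tr, path) {
  ape::write.tree(tr$tree, file = path)
  invisible(path)
}
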