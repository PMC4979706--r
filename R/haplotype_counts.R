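#' Site-by-haplotype count table
#'
#' Mitochondrial haplotype counts per sampling site. Row sums are the
#' per-site sample sizes; optional declared `n` and declared per-site gene
#' diversity columns travel along as checksums against the counts (the
#' counts stay authoritative).
#'
#' @param counts integer matrix, sites in rows, haplotypes in columns.
#' @param declared_n optional integer vector of per-site n as printed in the
#'   source table; mismatches with the row sums are kept, not fixed.
#' @param declared_diversity optional numeric vector of per-site gene
#'   diversity as printed in the source table.
#' @return an object of class `haplotype_counts`.
#' @export
haplotype_counts <- function(counts, declared_n = NULL, declared_diversity = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts needs site rownames")
  if (is.null(colnames(counts))) stop("counts needs haplotype colnames")
  if (any(counts < 0)) stop("negative haplotype count")
  if (any(counts != round(counts))) stop("non-integer haplotype count")
  storage.mode(counts) <- "integer"
  if (any(rowSums(counts) == 0)) {
    empty <- rownames(counts)[rowSums(counts) == 0]
    stop("empty haplotype count row(s): ", paste(empty, collapse = ", "))
  }
  structure(list(counts = counts,
                 sites = rownames(counts),
                 haplotypes = colnames(counts),
                 declared_n = declared_n,
                 declared_diversity = declared_diversity),
            class = "haplotype_counts")
}

#' @export
print.haplotype_counts <- function(x, ...) {
  cat(sprintf("haplotype_counts: %d sites x %d haplotypes, total N = %d\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Read haplotype counts from CSV
#'
#' Expected layout: a `site` column, optional `n` and `diversity` columns,
#' then one column per haplotype. Dashes (`-`, en dash) and blanks are zero
#' counts. Recomputed row sums are checked against a declared `n` column;
#' a mismatch warns (the row is flagged, not repaired) since published
#' tables occasionally carry internally inconsistent rows.
#'
#' @param path CSV file.
#' @return a [haplotype_counts()].
#' @export
read_haplotype_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (!"site" %in% names(df)) stop("haplotype counts CSV needs a 'site' column")
  hap_cols <- setdiff(names(df), c("site", "n", "diversity"))
  if (!length(hap_cols)) stop("no haplotype columns found")
  m <- matrix(0L, nrow(df), length(hap_cols),
              dimnames = list(df$site, hap_cols))
  for (j in seq_along(hap_cols)) {
    v <- trimws(df[[hap_cols[j]]])
    v[v %in% c("-", "–", "—", "", "NA")] <- "0"
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) stop(sprintf("non-numeric count '%s' in column '%s'",
                                 v[which(is.na(num))[1]], hap_cols[j]))
    if (any(num < 0)) stop("negative count in column ", hap_cols[j])
    if (any(num != round(num))) stop("non-integer count in column ", hap_cols[j])
    m[, j] <- as.integer(num)
  }
  declared_n <- if ("n" %in% names(df)) as.integer(df$n) else NULL
  declared_div <- if ("diversity" %in% names(df)) {
    dv <- trimws(df$diversity)
    dv[dv %in% c("-", "–", "—", "", "NA")] <- NA
    as.numeric(dv)
  } else NULL
  hc <- haplotype_counts(m, declared_n, declared_div)
  if (!is.null(declared_n)) {
    bad <- which(!is.na(declared_n) & rowSums(m) != declared_n)
    if (length(bad))
      warning("declared n disagrees with counts for site(s): ",
              paste(sprintf("%s (counts %d, declared %d)",
                            rownames(m)[bad], rowSums(m)[bad], declared_n[bad]),
                    collapse = "; "))
  }
  hc
}

#' Write haplotype counts to CSV
#' @param hc a [haplotype_counts()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_haplotype_counts <- function(hc, path) {
  df <- data.frame(site = hc$sites, n = rowSums(hc$counts),
                   check.names = FALSE)
  for (h in hc$haplotypes) df[[h]] <- hc$counts[, h]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' The packaged mitochondrial haplotype count fixture
#'
#' Site-by-haplotype counts for 392 introduced California red foxes at 10
#' mitochondrial haplotypes across 15 sampling rows, as published, including
#' the declared per-site n and gene-diversity columns used as checksums.
#'
#' @return a [haplotype_counts()].
#' @export
fox_haplotype_counts <- function() {
  read_haplotype_counts(system.file("extdata", "fox_mtdna_haplotypes.csv",
                                    package = "foxscape", mustWork = TRUE))
}
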