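#' Diploid multi-allelic genotype table
#'
#' The central container for codominant marker data: individuals by loci,
#' each call an unordered pair of allele labels, with per-individual site,
#' optional collection date and sex. Allele labels are opaque strings; loci
#' flagged in `repeat_loci` carry integer repeat scores, which stepwise
#' mutation models (SMM/TPM) require.
#'
#' @param alleles character array of dim `c(n_individuals, n_loci, 2)`;
#'   both slices `NA` for a missing call.
#' @param individuals character vector of unique individual ids.
#' @param loci character vector of unique locus ids.
#' @param site character vector (length n_individuals) of site ids.
#' @param date optional vector (length n_individuals) of dates or years.
#' @param sex optional character vector, `"M"`/`"F"`/`NA`.
#' @param repeat_loci logical vector (length n_loci): alleles are integer
#'   repeat numbers at these loci.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(alleles, individuals, loci, site,
                           date = NULL, sex = NULL, repeat_loci = NULL) {
  individuals <- as.character(individuals)
  loci <- as.character(loci)
  if (anyDuplicated(individuals))
    stop("duplicated individual ids: ",
         paste(unique(individuals[duplicated(individuals)]), collapse = ", "))
  if (anyDuplicated(loci))
    stop("duplicated locus ids: ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "))
  alleles <- as.array(alleles)
  if (length(dim(alleles)) != 3L ||
      dim(alleles)[1] != length(individuals) ||
      dim(alleles)[2] != length(loci) ||
      dim(alleles)[3] != 2L)
    stop("alleles must be a (n_individuals x n_loci x 2) array")
  storage.mode(alleles) <- "character"
  # enforce diploidy: a call is either fully present or fully missing
  half <- xor(is.na(alleles[, , 1, drop = FALSE]), is.na(alleles[, , 2, drop = FALSE]))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)
    stop(sprintf("half-missing call (1 allele of 2) for individual '%s' at locus '%s'",
                 individuals[idx[1, 1]], loci[idx[1, 2]]))
  }
  if (length(site) != length(individuals))
    stop("site must map every individual to exactly one site id")
  site <- stats::setNames(as.character(site), individuals)
  if (anyNA(site)) stop("every individual needs a site id")
  if (is.null(date)) date <- rep(NA, length(individuals))
  if (is.null(sex))  sex  <- rep(NA_character_, length(individuals))
  if (is.null(repeat_loci)) repeat_loci <- rep(FALSE, length(loci))
  dimnames(alleles) <- list(individuals, loci, NULL)
  structure(list(
    individuals = individuals, loci = loci, alleles = alleles,
    site = site,
    date = stats::setNames(date, individuals),
    sex  = stats::setNames(as.character(sex), individuals),
    repeat_loci = stats::setNames(as.logical(repeat_loci), loci)
  ), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci, %d sites\n",
              length(x$individuals), length(x$loci),
              length(unique(x$site))))
  miss <- mean(is.na(x$alleles[, , 1]))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_table <- function(object, ...) {
  sites <- sort(unique(object$site))
  data.frame(
    site = sites,
    n = vapply(sites, function(s) sum(object$site == s), integer(1)),
    row.names = NULL
  )
}

#' Subset a genotype table by individuals and/or loci
#'
#' @param gt a [genotype_table()].
#' @param individuals,loci character vectors of ids to keep (default all).
#' @return a `genotype_table`.
#' @export
subset_genotypes <- function(gt, individuals = gt$individuals, loci = gt$loci) {
  stopifnot(inherits(gt, "genotype_table"))
  bad <- setdiff(individuals, gt$individuals)
  if (length(bad)) stop("unknown individuals: ", paste(bad, collapse = ", "))
  bad <- setdiff(loci, gt$loci)
  if (length(bad)) stop("unknown loci: ", paste(bad, collapse = ", "))
  genotype_table(gt$alleles[individuals, loci, , drop = FALSE],
                 individuals, loci,
                 gt$site[individuals], gt$date[individuals],
                 gt$sex[individuals], gt$repeat_loci[loci])
}

## ---- internal tabulations used across the statistics modules ----

# per-locus allele count matrices: list over loci of (site x allele) gene counts
# pairwise deletion: an individual missing a locus contributes nothing there
allele_count_tables <- function(gt, sites = sort(unique(gt$site))) {
  lapply(seq_along(gt$loci), function(l) {
    a <- c(gt$alleles[, l, 1], gt$alleles[, l, 2])
    s <- rep(unname(gt$site), 2L)
    keep <- !is.na(a) & s %in% sites
    if (!any(keep)) {
      m <- matrix(0L, nrow = length(sites), ncol = 0,
                  dimnames = list(sites, character(0)))
      return(m)
    }
    tab <- table(factor(s[keep], levels = sites), a[keep])
    m <- matrix(as.integer(tab), nrow = length(sites),
                dimnames = list(sites, colnames(tab)))
    m
  })
}

# individuals typed per locus per site
typed_counts <- function(gt, sites = sort(unique(gt$site))) {
  sapply(seq_along(gt$loci), function(l) {
    ok <- !is.na(gt$alleles[, l, 1])
    vapply(sites, function(s) sum(ok & gt$site == s), integer(1))
  }) -> m
  m <- matrix(m, nrow = length(sites), dimnames = list(sites, gt$loci))
  m
}

## ---- I/O ----

#' Read a genotype table
#'
#' Three dialects are supported. `two_column`: CSV with columns
#' `id, site[, date][, sex]`, then two columns per locus named
#' `<locus>.1`/`<locus>.2` (empty or `NA` = missing). `genepop`: classic
#' GenePop with 2- or 3-digit allele codes, `0` codes meaning missing;
#' sites are named `pop1..popK` in file order. `structure`: a header row of
#' locus names, then one row per individual: `id site a1 a2 a1 a2 ...`,
#' `-9` = missing.
#'
#' Missing data are preserved as missing, never imputed.
#'
#' @param path file path.
#' @param dialect one of `"two_column"`, `"genepop"`, `"structure"`.
#' @param repeat_loci passed through to [genotype_table()].
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path,
                                dialect = c("two_column", "genepop", "structure"),
                                repeat_loci = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(dialect,
         two_column = read_gt_two_column(path, repeat_loci),
         genepop = read_gt_genepop(path, repeat_loci),
         structure = read_gt_structure(path, repeat_loci))
}

read_gt_two_column <- function(path, repeat_loci) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("id", "site") %in% names(df)))
    stop("two_column dialect needs 'id' and 'site' columns")
  meta <- intersect(c("id", "site", "date", "sex"), names(df))
  locus_cols <- setdiff(names(df), meta)
  base <- sub("\\.[12]$", "", locus_cols)
  loci <- unique(base)
  for (lc in loci) {
    pair <- locus_cols[base == lc]
    if (length(pair) != 2L)
      stop(sprintf("locus '%s' has %d allele columns (need 2)", lc, length(pair)))
  }
  n <- nrow(df)
  arr <- array(NA_character_, dim = c(n, length(loci), 2))
  for (j in seq_along(loci)) {
    a1 <- df[[paste0(loci[j], ".1")]]
    a2 <- df[[paste0(loci[j], ".2")]]
    a1[a1 == ""] <- NA; a2[a2 == ""] <- NA
    arr[, j, 1] <- a1; arr[, j, 2] <- a2
  }
  genotype_table(arr, df$id, loci, df$site,
                 date = if ("date" %in% names(df)) df$date else NULL,
                 sex = if ("sex" %in% names(df)) df$sex else NULL,
                 repeat_loci = repeat_loci)
}

read_gt_genepop <- function(path, repeat_loci) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("not a GenePop file (too short)")
  body <- lines[-1]  # drop title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("not a GenePop file (no POP line)")
  locus_lines <- body[seq_len(pop_idx[1] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(0); sites <- character(0); rows <- list()
  pop <- 0L
  for (i in seq(pop_idx[1], length(body))) {
    ln <- body[i]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) { pop <- pop + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L) stop("malformed GenePop genotype line: ", ln)
    id <- trimws(parts[1])
    geno <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(geno) != length(loci))
      stop(sprintf("individual '%s': %d genotype fields for %d loci",
                   id, length(geno), length(loci)))
    w <- nchar(geno)
    if (any(w %% 2L != 0L))
      stop(sprintf("individual '%s', locus '%s': odd allele-code width",
                   id, loci[which(w %% 2L != 0L)[1]]))
    half <- w %/% 2L
    a1 <- substr(geno, 1L, half)
    a2 <- substr(geno, half + 1L, w)
    zero <- as.integer(a1) == 0L | as.integer(a2) == 0L
    a1[zero] <- NA; a2[zero] <- NA
    # strip leading zeros so "003" and "03" are the same allele
    a1[!zero] <- as.character(as.integer(a1[!zero]))
    a2[!zero] <- as.character(as.integer(a2[!zero]))
    ids <- c(ids, id); sites <- c(sites, paste0("pop", pop))
    rows[[length(rows) + 1L]] <- rbind(a1, a2)
  }
  arr <- array(NA_character_, dim = c(length(ids), length(loci), 2))
  for (i in seq_along(rows)) {
    arr[i, , 1] <- rows[[i]][1, ]
    arr[i, , 2] <- rows[[i]][2, ]
  }
  genotype_table(arr, ids, loci, sites, repeat_loci = repeat_loci)
}

read_gt_structure <- function(path, repeat_loci) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  L <- length(loci)
  ids <- character(0); sites <- character(0)
  arr_rows <- list()
  for (ln in lines[-1]) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != 2L + 2L * L)
      stop(sprintf("structure row for '%s' has %d fields, expected %d",
                   f[1], length(f), 2L + 2L * L))
    g <- f[-(1:2)]
    g[g == "-9"] <- NA
    ids <- c(ids, f[1]); sites <- c(sites, f[2])
    arr_rows[[length(arr_rows) + 1L]] <- matrix(g, nrow = 2L)
  }
  arr <- array(NA_character_, dim = c(length(ids), L, 2))
  for (i in seq_along(arr_rows)) {
    arr[i, , 1] <- arr_rows[[i]][1, ]
    arr[i, , 2] <- arr_rows[[i]][2, ]
  }
  genotype_table(arr, ids, loci, sites, repeat_loci = repeat_loci)
}

#' Write a genotype table
#'
#' @param gt a [genotype_table()].
#' @param path output file.
#' @param dialect see [read_genotype_table()].
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gt, path,
                                 dialect = c("two_column", "genepop", "structure")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         two_column = {
           df <- data.frame(id = gt$individuals, site = unname(gt$site),
                            date = unname(gt$date), sex = unname(gt$sex),
                            check.names = FALSE, stringsAsFactors = FALSE)
           for (j in seq_along(gt$loci)) {
             df[[paste0(gt$loci[j], ".1")]] <- gt$alleles[, j, 1]
             df[[paste0(gt$loci[j], ".2")]] <- gt$alleles[, j, 2]
           }
           utils::write.csv(df, path, row.names = FALSE, na = "")
         },
         structure = {
           con <- file(path, "w"); on.exit(close(con))
           writeLines(paste(gt$loci, collapse = " "), con)
           for (i in seq_along(gt$individuals)) {
             g <- as.vector(rbind(gt$alleles[i, , 1], gt$alleles[i, , 2]))
             g[is.na(g)] <- "-9"
             writeLines(paste(c(gt$individuals[i], unname(gt$site[i]), g),
                              collapse = " "), con)
           }
         },
         genepop = {
           con <- file(path, "w"); on.exit(close(con))
           writeLines("foxscape genepop export", con)
           writeLines(gt$loci, con)
           width <- 3L
           for (s in unique(unname(gt$site))) {
             writeLines("POP", con)
             for (i in which(gt$site == s)) {
               a1 <- gt$alleles[i, , 1]; a2 <- gt$alleles[i, , 2]
               code <- ifelse(is.na(a1), strrep("0", 2L * width),
                              paste0(formatC(as.integer(a1), width = width, flag = "0"),
                                     formatC(as.integer(a2), width = width, flag = "0")))
               writeLines(paste0(gt$individuals[i], " , ",
                                 paste(code, collapse = " ")), con)
             }
           }
         })
  invisible(path)
}
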