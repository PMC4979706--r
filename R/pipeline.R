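#' Load and validate a pipeline configuration
#'
#' YAML with sections: `inputs` (genotypes + dialect, haplotypes, sites
#' CSV with site/x/y, optional raster), `markers` (rarefaction_g,
#' maf_cutoff, p_smm), `clustering` (k_max, replicates, cycles, burn_in),
#' `landscape` (n_cells, idw_power, n_perm), `seed`, `output_dir`. Paths
#' are resolved relative to the config file and must exist at validation
#' time.
#'
#' @param path YAML config file.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) p2 <- file.path(base, p) else p2 <- p
    if (!file.exists(p2)) stop("input path does not exist: ", p)
    normalizePath(p2)
  }
  if (is.null(cfg$inputs)) stop("config needs an 'inputs' section")
  cfg$inputs$genotypes <- resolve(cfg$inputs$genotypes)
  cfg$inputs$haplotypes <- resolve(cfg$inputs$haplotypes)
  cfg$inputs$sites <- resolve(cfg$inputs$sites)
  cfg$inputs$raster <- resolve(cfg$inputs$raster)
  defaults <- list(
    markers = list(rarefaction_g = NULL, maf_cutoff = 0.05, p_smm = 0.7,
                   n_perm = 199, bottleneck_n_sim = 200),
    clustering = list(k_max = 4, replicates = 2, cycles = 1500,
                      burn_in = 750),
    landscape = list(n_cells = 50, idw_power = 2, n_perm = 49,
                     mantel_n_perm = 999),
    seed = 1,
    output_dir = "foxscape_out")
  for (sec in names(defaults)) {
    if (is.null(cfg[[sec]])) { cfg[[sec]] <- defaults[[sec]]; next }
    if (is.list(defaults[[sec]]))
      for (kk in names(defaults[[sec]]))
        if (is.null(cfg[[sec]][[kk]])) cfg[[sec]][[kk]] <- defaults[[sec]][[kk]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full landscape-genetic pipeline
#'
#' Stages in dependency order: within-site diversity -> differentiation
#' (theta, D_A, haplotype F_ST, sex-bias ratio) -> Ne and bottleneck ->
#' tree and PCoA -> admixture clustering, profiles and migrant calls ->
#' landscape surfaces, resistance and Mantel tests. Per-stage CSV, Newick
#' and ASCII-grid outputs are written under `output_dir` with a manifest
#' (package version, seeds, parameters, warnings). A stage failure halts
#' the run with the stage name; earlier outputs are kept.
#'
#' @param cfg a `pipeline_config` (or path to one).
#' @param output_dir overrides the config's output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg, output_dir = NULL) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- output_dir %||% cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("foxscape")),
                   seed = cfg$seed, stages = list(), warnings = list(),
                   parameters = cfg[setdiff(names(cfg), "inputs")])
  log_stage <- function(name, expr) {
    res <- tryCatch(withCallingHandlers(expr, warning = function(w) {
      manifest$warnings[[name]] <<- c(manifest$warnings[[name]],
                                      conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- "complete"
    res
  }
  gt <- log_stage("load_genotypes",
                  read_genotype_table(cfg$inputs$genotypes,
                                      cfg$inputs$genotype_dialect %||% "two_column"))
  hc <- if (!is.null(cfg$inputs$haplotypes))
    log_stage("load_haplotypes", read_haplotype_counts(cfg$inputs$haplotypes))
  sm <- if (!is.null(cfg$inputs$sites)) log_stage("load_sites", {
    df <- utils::read.csv(cfg$inputs$sites)
    site_map(df$site, df$x, df$y, lonlat = isTRUE(cfg$inputs$lonlat))
  })
  # -- diversity
  summ <- log_stage("diversity", site_summary_stats(gt, cfg$markers$rarefaction_g))
  utils::write.csv(summ, file.path(out, "site_summary.csv"), row.names = FALSE)
  if (!is.null(hc)) {
    part <- log_stage("mtdna_diversity", global_fst_from_diversity(hc))
    utils::write.csv(data.frame(site = names(part$h_within),
                                diversity = part$h_within),
                     file.path(out, "mtdna_diversity.csv"), row.names = FALSE)
    manifest$parameters$mtdna_fst <- part$fst
  }
  # -- differentiation
  th <- log_stage("theta", weir_cockerham_theta(gt, seed = cfg$seed))
  write_dist_matrix(th$pairwise, file.path(out, "theta_pairwise.csv"))
  da <- log_stage("nei_da", nei_da_distance(gt))
  write_dist_matrix(da$da, file.path(out, "nei_da.csv"))
  manifest$parameters$theta_global <- th$theta_global
  if (!is.null(hc)) {
    hf <- log_stage("haplotype_fst", pairwise_haplotype_fst(hc))
    write_dist_matrix(hf$linearized, file.path(out, "mtdna_fst_linearized.csv"))
    sb <- log_stage("sex_bias",
                    sex_biased_gene_flow_ratio(th$theta_global, part$fst))
    manifest$parameters$mm_over_mf <- sb$mm_over_mf
  }
  # -- Ne and bottleneck per site
  ne_rows <- NULL
  for (s in sort(unique(unname(gt$site)))) {
    ne <- tryCatch(ld_ne(gt, s, cfg$markers$maf_cutoff), error = function(e) NULL)
    bt <- tryCatch(bottleneck_heterozygosity_test(
      gt, s, "TPM", p_smm = cfg$markers$p_smm,
      n_sim = cfg$markers$bottleneck_n_sim, seed = cfg$seed),
      error = function(e) NULL)
    ne_rows <- rbind(ne_rows, data.frame(
      site = s,
      ne = if (is.null(ne)) NA else ne$ne,
      ne_lo = if (is.null(ne)) NA else ne$ci[1],
      ne_hi = if (is.null(ne)) NA else ne$ci[2],
      bottleneck_p = if (is.null(bt)) NA else bt$p_wilcoxon,
      bottleneck_excess_p = if (is.null(bt)) NA else bt$p_excess))
  }
  manifest$stages[["ne_bottleneck"]] <- "complete"
  utils::write.csv(ne_rows, file.path(out, "ne_bottleneck.csv"), row.names = FALSE)
  # -- tree and PCoA
  tr <- log_stage("tree", bootstrap_support(gt, n_boot = 199, seed = cfg$seed))
  write_tree_newick(tr, file.path(out, "nj_tree.nwk"))
  pc <- log_stage("pcoa", pcoa_individuals(gt))
  utils::write.csv(data.frame(id = rownames(pc$coordinates),
                              site = unname(gt$site[rownames(pc$coordinates)]),
                              pc$coordinates[, seq_len(min(3, ncol(pc$coordinates))),
                                             drop = FALSE]),
                   file.path(out, "pcoa_coordinates.csv"), row.names = FALSE)
  # -- clustering, profiles, migrants
  runs <- log_stage("clustering", {
    rr <- list()
    for (K in seq_len(cfg$clustering$k_max))
      for (rep in seq_len(cfg$clustering$replicates))
        rr[[length(rr) + 1L]] <- admixture_mcmc(
          gt, K, cycles = cfg$clustering$cycles,
          burn_in = cfg$clustering$burn_in,
          seed = cfg$seed + 1000 * K + rep)
    rr
  })
  ph <- log_stage("profiles", align_runs_build_profiles(runs))
  utils::write.csv(data.frame(id = rownames(ph$profiles), ph$profiles),
                   file.path(out, "cluster_profiles.csv"), row.names = FALSE)
  chosen_runs <- runs[vapply(runs, function(r) r$K, integer(1)) == ph$chosen_K]
  calls <- log_stage("migrants", classify_migrants(chosen_runs[[1]]))
  utils::write.csv(calls, file.path(out, "migrant_calls.csv"), row.names = FALSE)
  manifest$parameters$chosen_K <- ph$chosen_K
  # -- landscape
  if (!is.null(sm)) {
    rs <- log_stage("residual_surface", {
      srf <- distance_decay_residuals(da$da, sm)
      grid <- idw_residual_surface(srf, n_cells = cfg$landscape$n_cells,
                                   idw_power = cfg$landscape$idw_power)
      write_raster_grid(grid, file.path(out, "residual_surface.asc"))
      srf
    })
    d_eu <- euclidean_distances(sm)
    if (!is.null(cfg$inputs$raster)) {
      rast <- log_stage("resistance", {
        rg <- read_raster_grid(cfg$inputs$raster)
        resistance_distance(rg, sm)
      })
      write_dist_matrix(rast, file.path(out, "resistance_distances.csv"))
      mt <- log_stage("mantel", list(
        gen_res = mantel_test(da$da, rast, cfg$landscape$mantel_n_perm,
                              seed = cfg$seed, log_y = TRUE),
        gen_eu = mantel_test(da$da, d_eu, cfg$landscape$mantel_n_perm,
                             seed = cfg$seed, log_y = TRUE),
        gen_res_given_eu = partial_mantel_test(
          da$da, rast, d_eu, cfg$landscape$mantel_n_perm,
          seed = cfg$seed, log_y = TRUE, log_z = TRUE)))
      manifest$parameters$mantel <- lapply(mt, function(m)
        list(r = m$r, p = m$p))
    }
  }
  manifest$finished <- TRUE
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}
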