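pipeline_defaults <- function() {
  list(
    mode = "simulate",            # or "files"
    vcf = NULL, site_table = NULL, collection_table = NULL,
    hyperdivergent_bed = NULL,
    simulate = list(),            # overrides for simulation_config()
    filters = list(dp_min = 5, qual_min = 30, qd_min = 20, fs_max = 100,
                   sor_max = 5, max_missing = 0.95, max_het = 0.10),
    polarize_llr = 2,
    isotype_threshold = 0.9997,
    pi_window = 10000, pi_step = 1000,
    tajima_window = 10000,
    cluster_cut = 3000,
    structure = list(window = 50, step = 10, r2_max = 0.1, maf_min = 0,
                     n_components = 50, outlier_iterations = 0, k = 7),
    gea_prune = list(window = 50, step = 1, r2_max = 0.8, maf_min = 0.1),
    min_cluster_size = 3,
    omega_subset = 5000,
    bf_cut_db = 20,
    xtx_quantile = 0.999,
    gap = 1000, flank = 150,
    seed = 1,
    outdir = NULL
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop2("unknown config key: %s%s", path, key)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop2("config key %s%s must be a list", path, key)
      if (key == "simulate") {
        defaults[[key]] <- user[[key]]  # validated by simulation_config()
      } else {
        defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                        paste0(path, key, "."))
      }
    } else {
      defaults[key] <- list(user[[key]])  # keeps explicit NULLs
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Fills the analysis defaults (variant filters, 10 kb/1 kb diversity
#' windows, 3 km clustering cut, 50/1/0.8 + MAF 0.1 GEA pruning, minimum
#' cluster size 3, BF cut 20 dB, XtX top 0.1%, 1 kb gap and 150-marker
#' flank region building, k = 7 genetic groups), checks cross-field
#' constraints, and rejects unknown keys.  Idempotent:
#' `validate_config(validate_config(x))` equals `validate_config(x)`.
#'
#' @param config A named list, a YAML file path, or NULL for defaults.
#' @return A normalized config of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config) %||% list()
  if (!is.list(config)) stop2("config must be a list or a YAML file path")
  cfg <- merge_config(pipeline_defaults(), config)
  if (!cfg$mode %in% c("simulate", "files"))
    stop2("mode must be 'simulate' or 'files'")
  if (cfg$mode == "files" && (is.null(cfg$vcf) || is.null(cfg$site_table)))
    stop2("files mode needs 'vcf' and 'site_table' paths")
  if (cfg$pi_step > cfg$pi_window)
    stop2("constraint violation: pi_step must be <= pi_window")
  if (cfg$xtx_quantile <= 0 || cfg$xtx_quantile >= 1)
    stop2("constraint violation: xtx_quantile must be in (0, 1)")
  if (cfg$gap < 0 || cfg$flank < 0)
    stop2("constraint violation: gap and flank must be non-negative")
  cfg$seed <- check_count(cfg$seed, "seed", min = 0L)
  # normalize the simulate block through its own constructor
  sim_args <- cfg$simulate
  if (!"seed" %in% names(sim_args)) sim_args$seed <- cfg$seed
  cfg$simulate <- unclass(do.call(simulation_config, sim_args))
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages end to end: simulation (or file loading), variant
#' polarization and filtering, isotype calling, windowed diversity,
#' geodesic site clustering, LD pruning + PCA + genetic groups, the dual
#' genotype-environment association scans (XtX / Bayes factors and LOCO
#' mixed-model GWA over the environmental covariates), and region
#' building with method-overlap and XtX consensus.  All outputs are
#' written under `config$outdir` (a temporary directory when NULL) and
#' hashed into a manifest; a fixed seed yields identical manifests.
#'
#' @param config A `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @return A list with every stage result plus `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  outdir <- cfg$outdir %||% file.path(tempdir(), sprintf("islegea_run_%d", cfg$seed))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv(df, p)
    files <<- c(files, p)
    p
  }

  result <- tryCatch({
    # ---- stage: inputs -------------------------------------------------
    stage <- "simulate"
    if (cfg$mode == "simulate") {
      sim <- simulate_metapopulation(do.call(simulation_config, cfg$simulate))
      gm <- sim$genotypes
      site_table <- sim$site_table
      hd_bed <- sim$truth$hyperdivergent
      vcf_path <- file.path(outdir, "simulated.vcf")
      write_vcf(gm, vcf_path)
      files <- c(files, vcf_path)
      st_path <- emit(site_table, "site_table.tsv")
      bed_path <- file.path(outdir, "hyperdivergent_truth.bed")
      writeLines(sprintf("%s\t%d\t%d", hd_bed$chrom, hd_bed$start, hd_bed$end),
                 bed_path)
      files <- c(files, bed_path)
      truth_path <- emit(sim$truth$adaptive_loci, "adaptive_truth.tsv")
    } else {
      sim <- NULL
      stage <- "load"
      gm <- load_vcf(cfg$vcf)
      site_table <- utils::read.table(cfg$site_table, header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE)
      hd_bed <- if (!is.null(cfg$hyperdivergent_bed)) read_bed(cfg$hyperdivergent_bed)
        else data.frame(chrom = character(0), start = integer(0), end = integer(0))
    }

    # ---- stage: variants ----------------------------------------------
    stage <- "variants"
    gm <- polarize_heterozygotes(gm, llr_threshold = cfg$polarize_llr)
    gm <- do.call(filter_sites, c(list(gm), cfg$filters))
    filter_log <- attr(gm, "filter_log")

    stage <- "isotypes"
    iso <- cluster_isotypes(gm, threshold = cfg$isotype_threshold)
    emit(iso, "isotypes.tsv")
    reps <- sort(unique(iso$isotype))
    gm_iso <- subset_samples(gm, reps)

    stage <- "diversity"
    pi_tab <- windowed_pi(gm_iso, window = cfg$pi_window, step = cfg$pi_step)
    taj_tab <- tajimas_d(gm_iso, window = cfg$tajima_window)
    emit(pi_tab, "windowed_pi.tsv")
    emit(taj_tab, "tajimas_d.tsv")

    # ---- stage: ecology clustering ------------------------------------
    stage <- "ecology"
    iso_sites <- site_table[match(reps, site_table$sample), , drop = FALSE]
    clusters <- cluster_sampling_sites(iso_sites, cut = cfg$cluster_cut)

    # ---- stage: structure ----------------------------------------------
    stage <- "structure"
    spr <- cfg$structure
    keep_str <- ld_prune(gm_iso, window = spr$window, step = spr$step,
                         r2_max = spr$r2_max, maf_min = spr$maf_min)
    pca <- pca_genotypes(subset_sites(gm_iso, keep_str),
                         n_components = spr$n_components,
                         outlier_iterations = spr$outlier_iterations)
    n_pcs <- max(pca$n_significant, 1L)
    k_use <- min(spr$k, nrow(pca$scores))
    groups <- assign_genetic_groups(
      pca$scores[, seq_len(min(n_pcs, ncol(pca$scores))), drop = FALSE],
      k = k_use)
    emit(groups, "genetic_groups.tsv")

    # ---- stage: gea -----------------------------------------------------
    stage <- "gea"
    gpr <- cfg$gea_prune
    keep_gea <- ld_prune(gm_iso, window = gpr$window, step = gpr$step,
                         r2_max = gpr$r2_max, maf_min = gpr$maf_min)
    gm_gea <- subset_sites(gm_iso, keep_gea)
    pf <- population_allele_frequencies(gm_gea, clusters,
                                        min_size = cfg$min_cluster_size)
    omega <- estimate_omega(pf, subset_size = cfg$omega_subset,
                            seed = cfg$seed)
    xtx <- xtx_scan(pf, omega, quantile = cfg$xtx_quantile)
    emit(xtx, "xtx_scan.tsv")

    clustered_sites <- iso_sites
    clustered_sites$population <- unname(clusters[iso_sites$sample])
    clustered_sites <- clustered_sites[!is.na(clustered_sites$population), ,
                                       drop = FALSE]
    pop_env_all <- population_covariates(clustered_sites)
    env_vars <- intersect(c("elevation", "air_temp", "surface_temp",
                            "rainfall", "soil_moisture", "lai",
                            "latitude", "longitude"),
                          colnames(pop_env_all))
    # restrict to retained clusters, ordered as the frequency table
    pop_env <- pop_env_all[colnames(pf$freq), env_vars, drop = FALSE]
    bf <- bayes_factor_scan(pf, omega, pop_env, bf_cut_db = cfg$bf_cut_db)
    emit(bf, "bayes_factor_scan.tsv")

    stage <- "gwa"
    kin <- kinship(gm_gea)
    meff <- effective_tests(gm_gea)
    gwa <- list()
    for (v in env_vars) {
      col <- switch(v, latitude = "lat", longitude = "lon", v)
      # per-isotype phenotype: median over the member strains' site values
      pheno <- vapply(reps, function(r) {
        members <- iso$strain[iso$isotype == r]
        stats::median(site_table[[col]][match(members, site_table$sample)],
                      na.rm = TRUE)
      }, numeric(1))
      g <- lmm_gwa(gm_gea, pheno, kin)
      g$covariate <- v
      gwa[[v]] <- g
    }
    gwa_all <- do.call(rbind, gwa)
    rownames(gwa_all) <- NULL
    emit(gwa_all, "gwa_scan.tsv")

    # ---- stage: regions -------------------------------------------------
    stage <- "regions"
    tested <- pf$sites
    xtx_reg <- build_regions(
      data.frame(chrom = xtx$chrom[xtx$flag], pos = xtx$pos[xtx$flag],
                 stat = xtx$xtx[xtx$flag]),
      tested, gap = cfg$gap, flank = cfg$flank, provenance = "xtx")
    overlap_list <- list(); gea_list <- list()
    bp_list <- list(); gwa_reg_list <- list()
    for (v in env_vars) {
      bfv <- bf[bf$covariate == v & bf$flag, , drop = FALSE]
      bp_reg <- build_regions(
        data.frame(chrom = bfv$chrom, pos = bfv$pos, stat = bfv$bf_db),
        tested, gap = cfg$gap, flank = cfg$flank,
        provenance = "baypass", variable = v)
      gv <- gwa[[v]]
      sig <- !is.na(gv$p) & gv$p < meff$threshold
      gwa_reg <- build_regions(
        data.frame(chrom = gv$chrom[sig], pos = gv$pos[sig],
                   stat = -log10(gv$p[sig])),
        tested, gap = cfg$gap, flank = cfg$flank,
        provenance = "gwa", variable = v)
      bp_list[[v]] <- bp_reg
      gwa_reg_list[[v]] <- gwa_reg
      if (nrow(bp_reg) && nrow(gwa_reg)) {
        ov <- intersect_regions(bp_reg, gwa_reg)
        overlap_list[[v]] <- ov
        gea_list[[v]] <- consensus_gea_regions(ov, xtx_reg)
      }
    }
    gea_reg <- do.call(rbind, gea_list) %||% region_frame()
    rownames(gea_reg) <- NULL
    distinct <- distinct_regions(gea_reg)
    hd_flagged <- if (nrow(distinct) && nrow(hd_bed))
      hyperdivergent_overlap(distinct, hd_bed) else {
        d2 <- distinct
        d2$hyperdivergent <- logical(nrow(distinct))
        attr(d2, "fraction") <- NA_real_
        d2
      }
    if (nrow(gea_reg)) {
      p <- file.path(outdir, "gea_regions.bed")
      write_regions_bed(gea_reg, p)
      files <- c(files, p)
    }
    if (nrow(distinct)) {
      p <- file.path(outdir, "distinct_regions.bed")
      write_regions_bed(distinct, p)
      files <- c(files, p)
    }

    stage <- "manifest"
    manifest <- list(
      config = unclass(cfg),
      stages = c("simulate", "variants", "isotypes", "diversity", "ecology",
                 "structure", "gea", "gwa", "regions"),
      files = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f)))
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    list(config = cfg, simulation = sim, genotypes = gm,
         isotypes = iso, genotypes_isotype = gm_iso,
         windowed_pi = pi_tab, tajimas_d = taj_tab,
         clusters = clusters, pca = pca, groups = groups,
         pop_freq = pf, omega = omega, xtx = xtx, bayes_factors = bf,
         kinship = kin, meff = meff, gwa = gwa_all,
         regions = list(xtx = xtx_reg, baypass = bp_list,
                        gwa = gwa_reg_list,
                        method_overlap = do.call(rbind, overlap_list) %||% region_frame(),
                        gea = gea_reg, distinct = hd_flagged),
         filter_log = filter_log,
         manifest = manifest, outdir = outdir)
  }, error = function(e) {
    stop2("pipeline failed at stage '%s': %s (partial outputs: %s)",
          stage, conditionMessage(e),
          if (length(files)) paste(basename(files), collapse = ", ") else "none")
  })
  result
}
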