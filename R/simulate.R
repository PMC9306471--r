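#' Default correlation targets among the six modeled environmental variables
#'
#' Elevation is strongly anti-correlated with air and surface temperature
#' (trade-wind islands place cool sites high), and the three moisture-related
#' variables (rainfall, soil moisture, leaf area index) are mutually
#' positively correlated.
#'
#' @return A 6x6 symmetric positive-definite correlation matrix with
#'   dimnames over the modeled covariates.
#' @export
default_env_correlation <- function() {
  v <- c("elevation", "air_temp", "surface_temp", "rainfall",
         "soil_moisture", "lai")
  m <- diag(6)
  dimnames(m) <- list(v, v)
  set_cor <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  set_cor("elevation", "air_temp", -0.96)
  set_cor("elevation", "surface_temp", -0.93)
  set_cor("air_temp", "surface_temp", 0.95)
  set_cor("elevation", "rainfall", 0.20)
  set_cor("elevation", "soil_moisture", 0.15)
  set_cor("elevation", "lai", -0.10)
  set_cor("air_temp", "rainfall", -0.15)
  set_cor("air_temp", "soil_moisture", -0.10)
  set_cor("air_temp", "lai", 0.15)
  set_cor("surface_temp", "rainfall", -0.20)
  set_cor("surface_temp", "soil_moisture", -0.15)
  set_cor("surface_temp", "lai", 0.10)
  set_cor("rainfall", "soil_moisture", 0.75)
  set_cor("rainfall", "lai", 0.55)
  set_cor("soil_moisture", "lai", 0.45)
  m
}

#' Configuration for the selfing-metapopulation simulator
#'
#' The defaults describe the study conditions the downstream analysis
#' assumes: 13 sampling-cluster populations of selfing nematodes, a
#' tree-structured allele-frequency covariance, six environmental
#' covariates with realistic mutual correlations, 20 environment-coupled
#' adaptive loci of standardized effect 1.5, and a handful of
#' hyper-divergent high-diversity blocks.
#'
#' @param n_populations Number of populations (sampling clusters).
#' @param samples_per_population Strains sampled per population.
#' @param n_snvs Number of biallelic SNVs before hyper-divergent
#'   densification.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Chromosome length in base pairs.
#' @param tree_depth Root-to-tip drift on the population tree; the diagonal
#'   of the drift covariance matrix Omega.
#' @param selfing_rate Probability that a genotype is emitted as a selfed
#'   homozygote; `1 - selfing_rate` of calls are drawn under random mating
#'   and can be heterozygous.
#' @param n_adaptive_loci Number of planted environment-coupled loci.
#' @param adaptive_effect Mean shift of the standardized population
#'   allele-frequency deviation per SD of the coupled covariate.
#' @param env_correlation_target Correlation targets among the six modeled
#'   environmental variables (symmetric PSD, unit diagonal).
#' @param n_hyperdivergent_blocks Number of planted hyper-divergent blocks.
#' @param block_length Length of each block in base pairs.
#' @param block_snv_fold SNV density inside blocks relative to background;
#'   needed so within-block diversity exceeds background at least 4-fold.
#' @param depth_mean Mean sequencing depth for the Poisson read-depth model.
#' @param base_error Per-read base error rate used for the genotype
#'   likelihood (PL) model.
#' @param failing_site_fraction Fraction of sites deliberately emitted with
#'   annotations that fail the variant quality filters.
#' @param seed Integer seed; fixed seed gives bit-identical outputs.
#'
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_populations = 13,
                              samples_per_population = 11,
                              n_snvs = 20000,
                              n_chromosomes = 6,
                              chromosome_length = 15e6,
                              tree_depth = 0.1,
                              selfing_rate = 0.998,
                              n_adaptive_loci = 20,
                              adaptive_effect = 1.5,
                              env_correlation_target = default_env_correlation(),
                              n_hyperdivergent_blocks = 6,
                              block_length = 5e4,
                              block_snv_fold = 6,
                              depth_mean = 27,
                              base_error = 0.01,
                              failing_site_fraction = 0.05,
                              seed = 1) {
  cfg <- list(
    n_populations = check_count(n_populations, "n_populations", min = 2L),
    samples_per_population = check_count(samples_per_population,
                                         "samples_per_population"),
    n_snvs = check_count(n_snvs, "n_snvs"),
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    chromosome_length = check_number(chromosome_length, "chromosome_length",
                                     min = 0, strict_min = TRUE),
    tree_depth = check_number(tree_depth, "tree_depth", min = 0,
                              strict_min = TRUE),
    selfing_rate = check_number(selfing_rate, "selfing_rate", 0, 1),
    n_adaptive_loci = check_count(n_adaptive_loci, "n_adaptive_loci", min = 0L),
    adaptive_effect = check_number(adaptive_effect, "adaptive_effect"),
    env_correlation_target = env_correlation_target,
    n_hyperdivergent_blocks = check_count(n_hyperdivergent_blocks,
                                          "n_hyperdivergent_blocks", min = 0L),
    block_length = check_number(block_length, "block_length", min = 0,
                                strict_min = TRUE),
    block_snv_fold = check_number(block_snv_fold, "block_snv_fold", min = 1),
    depth_mean = check_number(depth_mean, "depth_mean", min = 1),
    base_error = check_number(base_error, "base_error", 0, 0.5),
    failing_site_fraction = check_number(failing_site_fraction,
                                         "failing_site_fraction", 0, 1),
    seed = check_count(seed, "seed", min = 0L)
  )
  C <- cfg$env_correlation_target
  if (!is.matrix(C) || nrow(C) != ncol(C) ||
      max(abs(C - t(C))) > 1e-8 || any(abs(diag(C) - 1) > 1e-8))
    stop2("invalid config: env_correlation_target must be symmetric with unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop2("invalid config: env_correlation_target is not positive semi-definite")
  if (cfg$n_hyperdivergent_blocks * cfg$block_length >
      cfg$n_chromosomes * cfg$chromosome_length)
    stop2("invalid config: hyper-divergent blocks do not fit in the genome")
  structure(cfg, class = "sim_config")
}

chromosome_names <- function(n) {
  base <- c("I", "II", "III", "IV", "V", "X")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("chr", seq_len(n - 6)))
}

#' Drift covariance matrix implied by a population tree
#'
#' Entry (i, j) is the branch length shared by the root-to-tip paths of
#' tips i and j; the diagonal is each tip's root-to-tip depth.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return A symmetric positive-definite matrix with tip labels as dimnames.
#' @export
omega_from_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  om <- ape::vcv.phylo(tree)
  om[order(rownames(om)), order(colnames(om)), drop = FALSE]
}

#' Simulate a population tree and its drift covariance
#'
#' Draws a random bifurcating (coalescent-shaped) population tree, rescales
#' it so every root-to-tip path equals `tree_depth`, and returns the shared
#' branch-length covariance Omega that the allele-frequency model drifts
#' under.
#'
#' @param config A [simulation_config()].
#' @param tree Optional fixed [ape::phylo] population tree (tip count must
#'   equal `n_populations`); when supplied, its topology is used as-is,
#'   rescaled so the maximum root-to-tip depth equals `tree_depth`, and
#'   tips are relabeled `pop01..popP` in their current order.
#' @return A list with elements `omega` (P x P positive-definite matrix)
#'   and `tree` (the [ape::phylo] object).
#' @export
simulate_population_tree <- function(config, tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$tree_depth <= 0) stop2("invalid config: tree_depth must be > 0")
  P <- config$n_populations
  if (is.null(tree)) {
    set.seed(derive_seed(config$seed, 11L))
    tree <- ape::rcoal(P, tip.label = sprintf("pop%02d", seq_len(P)))
  } else {
    stopifnot(inherits(tree, "phylo"))
    if (length(tree$tip.label) != P)
      stop2("invalid config: tree has %d tips but n_populations = %d",
            length(tree$tip.label), P)
    tree$tip.label <- sprintf("pop%02d", seq_len(P))
  }
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (config$tree_depth / depth)
  omega <- omega_from_tree(tree)
  # tiny ridge so downstream Cholesky factors are stable even for
  # near-simultaneous splits
  omega <- omega + diag(1e-8 * config$tree_depth, P)
  list(omega = omega, tree = tree)
}

#' Simulate sampling sites and environmental covariates
#'
#' Populations are placed on a sphere (radius 6,371,000 m) within an
#' island-chain bounding box so that population centers are separated by
#' more than 3 km; samples scatter within ~400 m of their center.
#' Environmental covariates are drawn once per population from a
#' multivariate normal with the configured correlation targets, so they are
#' constant within a population.
#'
#' @param config A [simulation_config()].
#' @return A data frame with one row per sample: `sample`, `population`,
#'   `lat`, `lon`, and the six environmental covariates.
#' @export
simulate_site_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  P <- config$n_populations
  k <- config$samples_per_population
  set.seed(derive_seed(config$seed, 23L))

  lat_rng <- c(19.0, 22.2)
  lon_rng <- c(-159.8, -154.8)
  centers <- matrix(NA_real_, P, 2)
  n_placed <- 0L
  tries <- 0L
  while (n_placed < P) {
    tries <- tries + 1L
    if (tries > 100000L) stop2("could not place %d centers > 3 km apart", P)
    cand <- c(stats::runif(1, lat_rng[1], lat_rng[2]),
              stats::runif(1, lon_rng[1], lon_rng[2]))
    ok <- TRUE
    if (n_placed > 0L) {
      d <- geodesic_distance(rep(cand[1], n_placed), rep(cand[2], n_placed),
                             centers[seq_len(n_placed), 1],
                             centers[seq_len(n_placed), 2])
      ok <- all(d > 3500)
    }
    if (ok) {
      n_placed <- n_placed + 1L
      centers[n_placed, ] <- cand
    }
  }

  C <- config$env_correlation_target
  nv <- ncol(C)
  vars <- colnames(C) %||% paste0("env", seq_len(nv))
  Z <- matrix(stats::rnorm(P * nv), P, nv) %*% chol(C)
  colnames(Z) <- vars
  env_mean <- c(elevation = 800, air_temp = 18, surface_temp = 20,
                rainfall = 2000, soil_moisture = 0.30, lai = 3)
  env_sd <- c(elevation = 400, air_temp = 3, surface_temp = 3,
              rainfall = 800, soil_moisture = 0.10, lai = 1.5)
  for (v in vars) {
    mu <- if (v %in% names(env_mean)) env_mean[[v]] else 0
    sd <- if (v %in% names(env_sd)) env_sd[[v]] else 1
    Z[, v] <- mu + sd * Z[, v]
  }
  if ("elevation" %in% vars) Z[, "elevation"] <- pmax(Z[, "elevation"], 5)
  if ("soil_moisture" %in% vars) Z[, "soil_moisture"] <- pmax(Z[, "soil_moisture"], 0.01)
  if ("rainfall" %in% vars) Z[, "rainfall"] <- pmax(Z[, "rainfall"], 50)
  if ("lai" %in% vars) Z[, "lai"] <- pmax(Z[, "lai"], 0.05)

  pop <- rep(seq_len(P), each = k)
  # scatter within ~400 m of the center (well under the 1 km contract)
  r <- stats::runif(P * k, 0, 400)
  theta <- stats::runif(P * k, 0, 2 * pi)
  dlat <- (r * cos(theta)) / 6371000 * (180 / pi)
  dlon <- (r * sin(theta)) / (6371000 * cos(centers[pop, 1] * pi / 180)) * (180 / pi)
  out <- data.frame(
    sample = sprintf("S%04d", seq_len(P * k)),
    population = sprintf("pop%02d", pop),
    lat = centers[pop, 1] + dlat,
    lon = centers[pop, 2] + dlon,
    stringsAsFactors = FALSE
  )
  for (v in vars) out[[v]] <- Z[pop, v]
  out
}

#' Simulate population allele frequencies under drift plus local adaptation
#'
#' For each SNV an ancestral frequency is drawn uniformly on \[0.05, 0.95\]
#' and the vector of population frequencies drifts as a multivariate normal
#' with covariance `pi (1 - pi) Omega`, truncated (clipped) to
#' \[0.001, 0.999\].  Planted adaptive loci additionally shift the mean of
#' the standardized deviation by `adaptive_effect` times the standardized
#' coupled covariate.
#'
#' @param config A [simulation_config()].
#' @param omega Drift covariance matrix from [simulate_population_tree()].
#' @param site_table Site table from [simulate_site_table()]; supplies the
#'   population-level covariates that adaptive loci couple to.
#' @return A list: `sites` (chrom, pos, anc_freq, adaptive flag), `freq`
#'   (n_snvs x P matrix of population frequencies), and `adaptive_loci`
#'   (truth table: chrom, pos, snv index, covariate, effect).
#' @export
simulate_allele_frequencies <- function(config, omega, site_table) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_positive_definite(omega))
    stop2("omega must be positive definite")
  P <- config$n_populations
  n <- config$n_snvs
  set.seed(derive_seed(config$seed, 37L))

  chroms <- chromosome_names(config$n_chromosomes)
  chrom <- sort(sample(rep_len(seq_len(config$n_chromosomes), n)))
  pos <- integer(n)
  for (c_i in seq_len(config$n_chromosomes)) {
    idx <- which(chrom == c_i)
    pos[idx] <- sort(sample.int(config$chromosome_length, length(idx)))
  }

  anc <- stats::runif(n, 0.05, 0.95)
  L <- chol(omega)
  dev <- matrix(stats::rnorm(n * P), n, P) %*% L

  adaptive <- integer(0)
  truth <- data.frame(chrom = character(0), pos = integer(0),
                      snv = integer(0), covariate = character(0),
                      effect = numeric(0), stringsAsFactors = FALSE)
  if (config$n_adaptive_loci > 0 && config$adaptive_effect != 0) {
    env_vars <- intersect(colnames(config$env_correlation_target),
                          colnames(site_table))
    if (!length(env_vars)) stop2("site table carries no environmental covariates")
    adaptive <- sort(sample.int(n, config$n_adaptive_loci))
    covs <- rep_len(env_vars, config$n_adaptive_loci)
    pop_env <- population_covariates(site_table)
    for (j in seq_along(adaptive)) {
      z <- pop_env[, covs[j]]
      z <- (z - mean(z)) / stats::sd(z)
      dev[adaptive[j], ] <- dev[adaptive[j], ] + config$adaptive_effect * z
    }
    truth <- data.frame(chrom = chroms[chrom[adaptive]], pos = pos[adaptive],
                        snv = adaptive, covariate = covs,
                        effect = config$adaptive_effect,
                        stringsAsFactors = FALSE)
  }

  freq <- anc + sqrt(anc * (1 - anc)) * dev
  freq <- pmin(pmax(freq, 0.001), 0.999)
  colnames(freq) <- sort(unique(site_table$population))[seq_len(P)]

  list(
    sites = data.frame(chrom = chroms[chrom], pos = pos, anc_freq = anc,
                       adaptive = seq_len(n) %in% adaptive,
                       stringsAsFactors = FALSE),
    freq = freq,
    adaptive_loci = truth
  )
}

#' Population-level covariate table
#'
#' Collapses a per-sample site table to one row per population (covariates
#' are constant within population by construction; the mean is taken for
#' robustness, and latitude/longitude are averaged).
#'
#' @param site_table Per-sample site table.
#' @return A matrix with one row per population (sorted by label) and one
#'   column per covariate including `latitude` and `longitude`.
#' @export
population_covariates <- function(site_table) {
  pops <- sort(unique(site_table$population))
  vars <- setdiff(colnames(site_table), c("sample", "population"))
  out <- matrix(NA_real_, length(pops), length(vars),
                dimnames = list(pops, vars))
  for (i in seq_along(pops)) {
    sub <- site_table[site_table$population == pops[i], vars, drop = FALSE]
    out[i, ] <- colMeans(as.matrix(sub))
  }
  colnames(out)[colnames(out) == "lat"] <- "latitude"
  colnames(out)[colnames(out) == "lon"] <- "longitude"
  out
}

# diploid genotype likelihoods -> phred-scaled PL triple, reference-majority
# read model
pl_from_reads <- function(alt_reads, dp, base_error) {
  e <- base_error
  l0 <- stats::dbinom(alt_reads, dp, e, log = TRUE) / log(10)
  l1 <- stats::dbinom(alt_reads, dp, 0.5, log = TRUE) / log(10)
  l2 <- stats::dbinom(alt_reads, dp, 1 - e, log = TRUE) / log(10)
  pl <- -10 * cbind(l0, l1, l2)
  pl <- pl - pmin(pl[, 1], pl[, 2], pl[, 3])
  mode(pl) <- "integer"
  pmin(pl, 9999L)
}

#' Simulate genotypes for every sample
#'
#' Each sample draws a founder allele per SNV from its population frequency
#' and is emitted as a homozygous diploid genotype; a fraction
#' `1 - selfing_rate` of calls are instead drawn under random mating and can
#' be heterozygous.  Read depths are Poisson, PL genotype likelihoods follow
#' a binomial read model, and per-site QUAL/QD/FS/SOR annotations are drawn
#' to pass the quality filters except for a planted failing fraction.
#'
#' @param popfreq Output of [simulate_allele_frequencies()].
#' @param site_table Output of [simulate_site_table()].
#' @param config A [simulation_config()].
#' @return A `genotype_matrix` (see [genotype_matrix()]); the truth of which
#'   sites were planted to fail filters is in attribute `failing_truth`.
#' @export
simulate_genotypes <- function(popfreq, site_table, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 53L))
  n <- nrow(popfreq$sites)
  samples <- site_table$sample
  ns <- length(samples)
  pop_idx <- match(site_table$population, colnames(popfreq$freq))
  if (anyNA(pop_idx)) stop2("site table populations do not match frequency table")

  dosage <- matrix(0L, n, ns, dimnames = list(NULL, samples))
  for (s in seq_len(ns)) {
    p <- popfreq$freq[, pop_idx[s]]
    selfed <- stats::runif(n) < config$selfing_rate
    founder <- (stats::runif(n) < p)
    g <- ifelse(founder, 2L, 0L)
    if (any(!selfed)) {
      nh <- sum(!selfed)
      g[!selfed] <- (stats::runif(nh) < p[!selfed]) + (stats::runif(nh) < p[!selfed])
    }
    dosage[, s] <- g
  }

  dp <- matrix(stats::rpois(n * ns, config$depth_mean), n, ns)
  dp[dp < 1L] <- 1L
  p_alt <- matrix(config$base_error, n, ns)
  p_alt[dosage == 1L] <- 0.5
  p_alt[dosage == 2L] <- 1 - config$base_error
  alt_reads <- matrix(stats::rbinom(n * ns, as.vector(dp), as.vector(p_alt)), n, ns)
  pl <- pl_from_reads(as.vector(alt_reads), as.vector(dp), config$base_error)
  pl <- array(pl, dim = c(n, ns, 3))

  qual <- round(stats::runif(n, 400, 2000), 2)
  qd <- round(stats::runif(n, 22, 35), 2)
  fs <- round(stats::runif(n, 0, 20), 3)
  sor <- round(stats::runif(n, 0.5, 3), 3)
  failing <- stats::runif(n) < config$failing_site_fraction
  if (any(failing)) {
    rule <- sample(4L, sum(failing), replace = TRUE)
    w <- which(failing)
    qual[w[rule == 1L]] <- round(stats::runif(sum(rule == 1L), 2, 30), 2)
    qd[w[rule == 2L]] <- round(stats::runif(sum(rule == 2L), 2, 20), 2)
    fs[w[rule == 3L]] <- round(stats::runif(sum(rule == 3L), 101, 220), 3)
    sor[w[rule == 4L]] <- round(stats::runif(sum(rule == 4L), 5.01, 9), 3)
  }

  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4L, n, replace = TRUE)]
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

  gm <- genotype_matrix(
    sites = data.frame(chrom = popfreq$sites$chrom, pos = popfreq$sites$pos,
                       ref = ref, alt = unname(alt), qual = qual, qd = qd,
                       fs = fs, sor = sor, multiallelic = FALSE,
                       stringsAsFactors = FALSE),
    dosage = dosage, pl = pl, dp = dp,
    contigs = data.frame(chrom = chromosome_names(config$n_chromosomes),
                         length = config$chromosome_length,
                         stringsAsFactors = FALSE)
  )
  attr(gm, "failing_truth") <- failing
  gm
}

#' Plant hyper-divergent high-diversity blocks
#'
#' Within each block every sample carries one of two deeply diverged
#' haplotype classes.  Existing block SNVs become class-defining, and extra
#' class-defining SNVs are inserted so the in-block SNV density is
#' `block_snv_fold` times background, raising within-block nucleotide
#' diversity well above the neutral background.  Class membership is drawn
#' per sample with probability 1/2, independent of population, so blocks do
#' not mimic population differentiation.
#'
#' @param gm A `genotype_matrix` from [simulate_genotypes()].
#' @param config A [simulation_config()].
#' @return A list: `genotypes` (augmented matrix, positions sorted) and
#'   `truth` (0-based half-open BED data frame of planted blocks).
#' @export
plant_hyperdivergent_blocks <- function(gm, config) {
  stopifnot(inherits(config, "sim_config"))
  nb <- config$n_hyperdivergent_blocks
  truth <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (nb == 0L) return(list(genotypes = gm, truth = truth))
  set.seed(derive_seed(config$seed, 71L))
  chroms <- gm$contigs$chrom
  bl <- as.integer(config$block_length)

  placed <- list()
  tries <- 0L
  while (length(placed) < nb) {
    tries <- tries + 1L
    if (tries > 10000L)
      stop2("invalid config: could not place %d non-overlapping blocks", nb)
    ch <- sample(chroms, 1L)
    len <- gm$contigs$length[gm$contigs$chrom == ch]
    if (len <= bl) next
    start <- sample.int(as.integer(len) - bl, 1L)
    overlap <- any(vapply(placed, function(b)
      b$chrom == ch && start < b$end && (start + bl) > b$start, logical(1)))
    if (!overlap) placed[[length(placed) + 1L]] <- list(chrom = ch, start = start,
                                                       end = start + bl)
  }

  ns <- ncol(gm$dosage)
  n_bg <- nrow(gm$sites)
  background_density <- n_bg / sum(as.numeric(gm$contigs$length))
  bases <- c("A", "C", "G", "T")

  new_sites <- list()
  new_dosage <- list()
  new_dp <- list()
  new_pl <- list()
  for (b in placed) {
    class_b <- stats::runif(ns) < 0.5
    in_block <- gm$sites$chrom == b$chrom & gm$sites$pos > b$start &
      gm$sites$pos <= b$end
    if (any(in_block)) {
      blockdos <- matrix(rep(ifelse(class_b, 2L, 0L), each = sum(in_block)),
                         sum(in_block), ns)
      gm$dosage[in_block, ] <- blockdos
      if (!is.null(gm$pl)) {
        dpb <- gm$dp[in_block, , drop = FALSE]
        plb <- pl_from_reads(
          as.vector(ifelse(blockdos == 2L,
                           stats::rbinom(length(dpb), as.vector(dpb), 1 - config$base_error),
                           stats::rbinom(length(dpb), as.vector(dpb), config$base_error))),
          as.vector(dpb), config$base_error)
        gm$pl[in_block, , ] <- array(plb, c(sum(in_block), ns, 3))
      }
    }
    n_extra <- max(0L, round(bl * background_density * (config$block_snv_fold - 1)))
    if (n_extra > 0L) {
      avoid <- gm$sites$pos[in_block] - b$start
      pool <- setdiff(seq_len(bl - 1L), avoid)
      n_extra <- min(n_extra, length(pool))
      pos_new <- b$start + sort(sample(pool, n_extra))
      ref <- bases[sample.int(4L, n_extra, replace = TRUE)]
      alt <- vapply(ref, function(x) sample(setdiff(bases, x), 1L), character(1))
      new_sites[[length(new_sites) + 1L]] <- data.frame(
        chrom = b$chrom, pos = pos_new, ref = ref, alt = unname(alt),
        qual = round(stats::runif(n_extra, 400, 2000), 2),
        qd = round(stats::runif(n_extra, 22, 35), 2),
        fs = round(stats::runif(n_extra, 0, 20), 3),
        sor = round(stats::runif(n_extra, 0.5, 3), 3),
        multiallelic = FALSE, stringsAsFactors = FALSE)
      dosb <- matrix(rep(ifelse(class_b, 2L, 0L), each = n_extra), n_extra, ns)
      new_dosage[[length(new_dosage) + 1L]] <- dosb
      dpb <- matrix(stats::rpois(n_extra * ns, config$depth_mean), n_extra, ns)
      dpb[dpb < 1L] <- 1L
      new_dp[[length(new_dp) + 1L]] <- dpb
      if (!is.null(gm$pl)) {
        altr <- ifelse(dosb == 2L,
                       stats::rbinom(length(dpb), as.vector(dpb), 1 - config$base_error),
                       stats::rbinom(length(dpb), as.vector(dpb), config$base_error))
        new_pl[[length(new_pl) + 1L]] <-
          array(pl_from_reads(as.vector(altr), as.vector(dpb), config$base_error),
                c(n_extra, ns, 3))
      }
    }
  }

  if (length(new_sites)) {
    sites <- rbind(gm$sites, do.call(rbind, new_sites))
    dosage <- rbind(gm$dosage, do.call(rbind, new_dosage))
    dp <- rbind(gm$dp, do.call(rbind, new_dp))
    if (!is.null(gm$pl)) {
      pl <- array(NA_integer_, c(nrow(sites), ns, 3))
      pl[seq_len(nrow(gm$sites)), , ] <- gm$pl
      at <- nrow(gm$sites)
      for (blk in new_pl) {
        pl[at + seq_len(dim(blk)[1]), , ] <- blk
        at <- at + dim(blk)[1]
      }
    } else pl <- NULL
    ord <- order(match(sites$chrom, gm$contigs$chrom), sites$pos)
    gm <- genotype_matrix(sites = sites[ord, , drop = FALSE],
                          dosage = dosage[ord, , drop = FALSE],
                          pl = if (!is.null(pl)) pl[ord, , , drop = FALSE] else NULL,
                          dp = dp[ord, , drop = FALSE],
                          contigs = gm$contigs)
  }

  truth <- do.call(rbind, lapply(placed, function(b)
    data.frame(chrom = b$chrom, start = b$start, end = b$end,
               stringsAsFactors = FALSE)))
  truth <- truth[order(match(truth$chrom, chroms), truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genotypes = gm, truth = truth)
}

#' Simulate a complete selfing metapopulation data set
#'
#' Runs the generator end to end: population tree and drift covariance,
#' sampling sites with environmental covariates, population allele
#' frequencies with planted adaptive loci, per-sample genotypes, and
#' hyper-divergent blocks.
#'
#' @param config A [simulation_config()].
#' @param tree Optional fixed population tree (see
#'   [simulate_population_tree()]).
#' @return A list with `config`, `omega`, `tree`, `site_table`, `popfreq`,
#'   `genotypes` (a `genotype_matrix`), and `truth` (adaptive loci,
#'   hyper-divergent BED, population assignment, planted failing sites).
#' @export
simulate_metapopulation <- function(config = simulation_config(), tree = NULL) {
  tr <- simulate_population_tree(config, tree = tree)
  site_table <- simulate_site_table(config)
  popfreq <- simulate_allele_frequencies(config, tr$omega, site_table)
  gm <- simulate_genotypes(popfreq, site_table, config)
  hd <- plant_hyperdivergent_blocks(gm, config)
  list(
    config = config,
    omega = tr$omega,
    tree = tr$tree,
    site_table = site_table,
    popfreq = popfreq,
    genotypes = hd$genotypes,
    truth = list(
      adaptive_loci = popfreq$adaptive_loci,
      hyperdivergent = hd$truth,
      population_assignment = stats::setNames(site_table$population,
                                              site_table$sample),
      failing_sites = attr(gm, "failing_truth")
    )
  )
}
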