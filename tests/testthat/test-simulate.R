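test_that("drift covariance from explicit trees matches shared branch lengths", {
  star <- ape::read.tree(text = "(A:0.7,B:0.7,C:0.7,D:0.7);")
  om <- omega_from_tree(star)
  expect_equal(unname(om), diag(0.7, 4))

  two <- ape::read.tree(text = "(A:0.4,B:0.4):0.3;")
  two$root.edge <- NULL
  pair <- ape::read.tree(text = "((A:0.4,B:0.4):0.3,C:0.7);")
  omp <- omega_from_tree(pair)
  expect_equal(omp["A", "B"], 0.3)
  expect_equal(omp["A", "A"], 0.7)
  expect_equal(omp["A", "C"], 0)

  cat4 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  omc <- omega_from_tree(cat4)
  for (i in c("A", "B", "C", "D")) {
    for (j in c("A", "B", "C", "D")) {
      if (i != j)
        expect_equal(omc[i, j], oracle_shared_branch(cat4, i, j))
    }
  }
})

test_that("random population trees give positive-definite omega at the requested depth", {
  cfg <- simulation_config(n_populations = 9, tree_depth = 0.25, seed = 5)
  tr <- simulate_population_tree(cfg)
  expect_equal(dim(tr$omega), c(9, 9))
  expect_true(all(eigen(tr$omega, symmetric = TRUE)$values > 0))
  expect_equal(unname(diag(tr$omega)), rep(0.25, 9), tolerance = 1e-6)
  tr2 <- simulate_population_tree(cfg)
  expect_identical(tr$omega, tr2$omega)
  expect_error(simulation_config(tree_depth = 0), "out of range")
})

test_that("site tables respect spatial and correlation contracts", {
  id6 <- diag(6)
  dimnames(id6) <- dimnames(default_env_correlation())
  cfg <- simulation_config(n_populations = 1000, samples_per_population = 1,
                           env_correlation_target = id6, seed = 8)
  st <- simulate_site_table(cfg)
  cm <- cor(st[, c("elevation", "air_temp", "surface_temp", "rainfall",
                   "soil_moisture", "lai")])
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.1)

  cfg2 <- simulation_config(n_populations = 200, samples_per_population = 1,
                            seed = 9)
  st2 <- simulate_site_table(cfg2)
  expect_equal(cor(st2$elevation, st2$air_temp), -0.96, tolerance = 0.05)

  # population centers > 3 km apart; within-population scatter < 1 km
  cfg3 <- simulation_config(n_populations = 6, samples_per_population = 8,
                            seed = 10)
  st3 <- simulate_site_table(cfg3)
  centers <- aggregate(st3[, c("lat", "lon")], list(pop = st3$population), mean)
  d <- geosphere::distm(cbind(centers$lon, centers$lat))
  expect_true(all(d[upper.tri(d)] > 3000))
  for (p in unique(st3$population)) {
    sub <- st3[st3$population == p, ]
    expect_equal(var(sub$elevation), 0)
    dd <- geodesic_distance(sub$lat, sub$lon, centers$lat[centers$pop == p],
                            centers$lon[centers$pop == p])
    expect_true(all(dd < 1000))
  }

  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(simulation_config(env_correlation_target = bad),
               "positive semi-definite")
})

test_that("allele-frequency model recovers its own drift covariance", {
  P <- 8
  om <- diag(0.01, P)
  cfg <- simulation_config(n_populations = P, samples_per_population = 2,
                           n_snvs = 10000, n_adaptive_loci = 0, seed = 13)
  st <- simulate_site_table(cfg)
  colnames(om) <- rownames(om) <- sort(unique(st$population))
  pfq <- simulate_allele_frequencies(cfg, om, st)
  a <- (pfq$freq - pfq$sites$anc_freq) /
    sqrt(pfq$sites$anc_freq * (1 - pfq$sites$anc_freq))
  emp <- crossprod(a) / nrow(a)
  # entrywise recovery within 20%
  expect_equal(unname(diag(emp)), rep(0.01, P), tolerance = 0.2)
  expect_lt(max(abs(emp[upper.tri(emp)])), 0.002)
})

test_that("zero adaptive effect plants nothing and leaves the neutral stream intact", {
  cfg0 <- simulation_config(n_snvs = 500, n_adaptive_loci = 20,
                            adaptive_effect = 0, seed = 17)
  cfg_n <- simulation_config(n_snvs = 500, n_adaptive_loci = 0, seed = 17)
  tr <- simulate_population_tree(cfg0)
  st <- simulate_site_table(cfg0)
  f0 <- simulate_allele_frequencies(cfg0, tr$omega, st)
  fn <- simulate_allele_frequencies(cfg_n, tr$omega, st)
  expect_equal(nrow(f0$adaptive_loci), 0)
  expect_identical(f0$freq, fn$freq)
})

test_that("planted loci track their coupled covariate", {
  cfg <- simulation_config(n_snvs = 2000, n_adaptive_loci = 60,
                           adaptive_effect = 1.5, seed = 19)
  tr <- simulate_population_tree(cfg)
  st <- simulate_site_table(cfg)
  pfq <- simulate_allele_frequencies(cfg, tr$omega, st)
  pe <- population_covariates(st)
  rs <- mapply(function(snv, cv) {
    z <- pe[colnames(pfq$freq), cv]
    cor(pfq$freq[snv, ], z)
  }, pfq$adaptive_loci$snv, pfq$adaptive_loci$covariate)
  expect_gt(mean(rs), 0.5)
})

test_that("selfing rate one gives fully homozygous genotypes and deterministic VCFs", {
  cfg <- simulation_config(n_snvs = 400, selfing_rate = 1,
                           n_hyperdivergent_blocks = 0, seed = 23)
  sim <- simulate_metapopulation(cfg)
  expect_equal(sum(sim$genotypes$dosage == 1L, na.rm = TRUE), 0)

  p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, p1)
  sim2 <- simulate_metapopulation(cfg)
  write_vcf(sim2$genotypes, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("planted filter-failing sites are removed at the configured rate", {
  cfg <- simulation_config(n_snvs = 1000, failing_site_fraction = 0.1,
                           n_hyperdivergent_blocks = 0, seed = 29)
  sim <- simulate_metapopulation(cfg)
  truth <- sim$truth$failing_sites
  filtered <- filter_sites(sim$genotypes)
  kept_pos <- paste(filtered$sites$chrom, filtered$sites$pos)
  all_pos <- paste(sim$genotypes$sites$chrom, sim$genotypes$sites$pos)
  removed <- !(all_pos %in% kept_pos)
  # every planted failing site must go; a binomial count was planted
  expect_true(all(removed[truth]))
  expect_equal(sum(truth), 1000 * 0.1, tolerance = 0.35)
  expect_lt(sum(removed & !truth), 25)  # extra removals only from het/missing rules
})

test_that("hyper-divergent blocks raise windowed diversity at least four-fold", {
  cfg <- simulation_config(n_snvs = 6000, seed = 9)
  sim <- cached_sim("hd6000", cfg)
  gm <- filter_sites(sim$genotypes)
  pw <- windowed_pi(gm, 10000, 10000)
  bed <- sim$truth$hyperdivergent
  inblock <- rep(FALSE, nrow(pw))
  for (i in seq_len(nrow(bed)))
    inblock <- inblock | (pw$chrom == bed$chrom[i] & pw$start <= bed$end[i] &
                            pw$end > bed$start[i])
  expect_gt(mean(pw$pi[inblock]) / mean(pw$pi[!inblock]), 4)
  # truth intervals inside chromosome bounds
  expect_true(all(bed$start >= 0 & bed$end <= cfg$chromosome_length))

  # no blocks -> genotypes unchanged
  cfg0 <- simulation_config(n_snvs = 300, n_hyperdivergent_blocks = 0, seed = 31)
  pf <- simulate_allele_frequencies(cfg0, simulate_population_tree(cfg0)$omega,
                                    simulate_site_table(cfg0))
  gm0 <- simulate_genotypes(pf, simulate_site_table(cfg0), cfg0)
  res <- plant_hyperdivergent_blocks(gm0, cfg0)
  expect_identical(res$genotypes$dosage, gm0$dosage)
  expect_equal(nrow(res$truth), 0)
})

test_that("block haplotype classes sit near frequency one half", {
  cfg <- simulation_config(n_snvs = 2000, n_hyperdivergent_blocks = 2,
                           block_length = 1e5, seed = 37)
  sim <- simulate_metapopulation(cfg)
  bed <- sim$truth$hyperdivergent
  gm <- sim$genotypes
  for (i in seq_len(nrow(bed))) {
    inb <- gm$sites$chrom == bed$chrom[i] & gm$sites$pos > bed$start[i] &
      gm$sites$pos <= bed$end[i]
    freq <- rowMeans(gm$dosage[inb, , drop = FALSE]) / 2
    # class-defining alleles share one frequency per block, near 0.5
    expect_equal(mean(freq), 0.5, tolerance = 0.15)
    expect_lt(max(freq) - min(freq), 1e-9)
  }
})
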