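test_that("VCF round-trips through the parser", {
  cfg <- simulation_config(n_snvs = 100, n_hyperdivergent_blocks = 0, seed = 41)
  sim <- simulate_metapopulation(cfg)
  p <- tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, p)
  gm <- load_vcf(p)
  expect_equal(nrow(gm$sites), 100)
  expect_identical(unname(gm$dosage), unname(sim$genotypes$dosage))
  expect_equal(gm$sites$qual, sim$genotypes$sites$qual)
  expect_equal(gm$sites$sor, sim$genotypes$sites$sor)
  expect_identical(gm$samples, sim$genotypes$samples)

  # empty body
  pe <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=I,length=1000>",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", sep = "\t")), pe)
  gme <- load_vcf(pe)
  expect_equal(nrow(gme$sites), 0)
  expect_error(load_vcf(tempfile()), "not found")
})

test_that("multiallelic sites are flagged and dropped by the biallelic filter", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=I,length=1000>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", "S2", sep = "\t"),
               paste("I", "10", ".", "A", "T", "50", "PASS",
                     "QD=30;FS=1;SOR=1", "GT", "0/0", "1/1", sep = "\t"),
               paste("I", "20", ".", "A", "T,G", "50", "PASS",
                     "QD=30;FS=1;SOR=1", "GT", "0/0", "1/2", sep = "\t")), p)
  gm <- load_vcf(p)
  expect_identical(gm$sites$multiallelic, c(FALSE, TRUE))
  filtered <- suppressWarnings(filter_sites(gm))
  expect_equal(nrow(filtered$sites), 1)
  expect_equal(filtered$sites$pos, 10)
})

test_that("heterozygote polarization follows the likelihood ratio rule", {
  dos <- matrix(1L, 3, 1, dimnames = list(NULL, "S1"))
  pl <- array(NA_integer_, c(3, 1, 3))
  pl[1, 1, ] <- c(0L, 30L, 60L)   # LLR = +6 -> hom ref
  pl[2, 1, ] <- c(20L, 0L, 20L)   # LLR = 0 -> stays het
  pl[3, 1, ] <- c(60L, 30L, 0L)   # LLR = -6 -> hom alt
  gm <- make_gm(dos)
  gm$pl <- pl
  out <- polarize_heterozygotes(gm, llr_threshold = 2)
  expect_equal(unname(out$dosage[, 1]), c(0L, 1L, 2L))
  lg <- attr(out, "polarize_log")
  expect_equal(unname(lg[c("to_ref", "to_alt", "kept")]), c(1L, 1L, 1L))
})

test_that("polarization matches a per-call brute-force reimplementation", {
  set.seed(43)
  n <- 200; s <- 8
  dos <- matrix(sample(c(0:2, NA), n * s, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), n, s,
                dimnames = list(NULL, sprintf("S%d", 1:s)))
  pl <- array(sample(0:80, n * s * 3, replace = TRUE), c(n, s, 3))
  gm <- make_gm(dos)
  gm$pl <- pl
  out <- polarize_heterozygotes(gm, llr_threshold = 2)
  expect_identical(unname(out$dosage), unname(oracle_polarize(dos, pl, 2)))
})

test_that("site filters are boundary-exclusive and count removals", {
  dos <- matrix(rep(c(0L, 2L), each = 2), 4, 4,
                dimnames = list(NULL, sprintf("S%d", 1:4)))
  gm <- make_gm(dos,
                qual = c(31, 30, 31, 31), qd = c(21, 21, 20, 21),
                fs = c(99, 99, 99, 100), sor = c(4.9, 4.9, 4.9, 4.9))
  out <- suppressWarnings(filter_sites(gm))
  # only the site passing every strict inequality survives
  expect_equal(out$sites$pos, 1L)
  lg <- attr(out, "filter_log")
  expect_equal(unname(lg[c("qual", "qd", "fs")]), c(1L, 1L, 1L))
})

test_that("sites heterozygous in more than a tenth of samples are removed", {
  set.seed(44)
  ns <- 100
  dos <- matrix(0L, 3, ns, dimnames = list(NULL, sprintf("S%03d", 1:ns)))
  dos[1, 1:11] <- 1L   # 11% heterozygous -> removed
  dos[2, 1:10] <- 1L   # 10% -> kept (boundary-exclusive)
  out <- suppressWarnings(filter_sites(make_gm(dos)))
  expect_equal(out$sites$pos, c(2L, 3L))
})

test_that("depth masking feeds the missingness rule", {
  ns <- 20
  dos <- matrix(2L, 2, ns, dimnames = list(NULL, sprintf("S%02d", 1:ns)))
  dp <- matrix(27L, 2, ns)
  dp[1, ] <- 5L           # DP <= 5 masks every call -> 100% missing
  dp[2, 1] <- 6L          # DP = 6 survives
  gm <- make_gm(dos)
  gm$dp <- dp
  out <- filter_sites(gm)
  expect_equal(out$sites$pos, 2L)
  expect_false(is.na(out$dosage[1, 1]))
})

test_that("filtering applies its rules independently of order", {
  set.seed(45)
  sim <- cached_sim("hd6000", simulation_config(n_snvs = 6000, seed = 9))
  gm <- sim$genotypes
  full <- filter_sites(gm)
  keys <- function(g) paste(g$sites$chrom, g$sites$pos)
  # intersection of single-rule passes equals the joint filter
  pass <- Reduce(intersect, list(
    keys(filter_sites(gm, qd_min = -Inf, fs_max = Inf, sor_max = Inf)),
    keys(filter_sites(gm, qual_min = -Inf, fs_max = Inf, sor_max = Inf)),
    keys(filter_sites(gm, qual_min = -Inf, qd_min = -Inf))
  ))
  expect_setequal(keys(full), pass)
})

test_that("pairwise concordance counts identical non-missing dosages", {
  set.seed(46)
  dos <- matrix(sample(c(0L, 2L), 10000 * 2, TRUE), 10000, 2,
                dimnames = list(NULL, c("A", "B")))
  dos[, 2] <- dos[, 1]
  dos[c(5, 17), 2] <- 2L - dos[c(5, 17), 1]
  gm <- make_gm(dos)
  expect_equal(pairwise_concordance(gm, c("A", "A")), 1.0)
  expect_equal(pairwise_concordance(gm, c("A", "B")), 0.9998)

  # random pair equals the site loop
  dos2 <- matrix(sample(c(0:2, NA), 500 * 2, TRUE), 500, 2,
                 dimnames = list(NULL, c("A", "B")))
  gm2 <- make_gm(dos2)
  both <- !is.na(dos2[, 1]) & !is.na(dos2[, 2])
  expect_equal(pairwise_concordance(gm2, c("A", "B")),
               sum(dos2[both, 1] == dos2[both, 2]) / sum(both))

  dos3 <- matrix(c(1L, NA, NA, 1L), 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(pairwise_concordance(make_gm(dos3), c("A", "B")),
               "jointly genotyped")
})

test_that("isotype clustering is a transitive closure over the concordance graph", {
  # A-B and B-C concordant, A-C not: still one isotype
  base <- matrix(rep(c(0L, 2L), 5000), 10000, 1)
  A <- base; B <- base; C <- base
  B[1, 1] <- 2L - B[1, 1]                    # A-B concordance 0.9999
  C[c(1, 5, 9), 1] <- 2L - C[c(1, 5, 9), 1]  # B-C 0.9998, A-C 0.9997 (<= cut)
  dos <- cbind(A = A, B = B, C = C)
  colnames(dos) <- c("A", "B", "C")
  gm <- make_gm(dos)
  iso <- cluster_isotypes(gm, threshold = 0.9997)
  expect_equal(length(unique(iso$isotype)), 1)
  expect_true(all(iso$isotype == "A"))  # lexicographically smallest member

  # far-apart strains remain singletons
  set.seed(47)
  dos2 <- matrix(sample(c(0L, 2L), 2000 * 4, TRUE), 2000, 4,
                 dimnames = list(NULL, c("W", "X", "Y", "Z")))
  iso2 <- cluster_isotypes(make_gm(dos2), threshold = 0.9997)
  expect_equal(length(unique(iso2$isotype)), 4)
})

test_that("duplicated strains with small injected discordance fold back into isotypes", {
  sim <- cached_sim("hd6000", simulation_config(n_snvs = 6000, seed = 9))
  gm <- filter_sites(sim$genotypes)
  orig <- subset_samples(gm, 1:12)
  set.seed(48)
  dup <- orig$dosage
  colnames(dup) <- paste0(colnames(dup), "_dup")
  # inject exactly 0.01% discordant sites per duplicate
  n_flip <- max(1L, round(1e-4 * nrow(dup)))
  for (j in seq_len(ncol(dup))) {
    at <- sample.int(nrow(dup), n_flip)
    dup[at, j] <- 2L - dup[at, j]
  }
  gm2 <- make_gm(cbind(orig$dosage, dup), chrom = orig$sites$chrom,
                 pos = orig$sites$pos)
  iso <- cluster_isotypes(gm2, threshold = 0.9997)
  expect_equal(length(unique(iso$isotype)), 12)
})
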