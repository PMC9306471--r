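make_pf <- function(freq, sizes = NULL, sites = NULL) {
  # assemble a pop_freq object directly for controlled scan inputs
  P <- ncol(freq)
  sizes <- sizes %||% rep(10L, P)
  if (is.null(colnames(freq))) colnames(freq) <- sprintf("SC%02d", seq_len(P))
  pi_hat <- as.vector(freq %*% (sizes / sum(sizes)))
  structure(list(
    sites = sites %||% data.frame(chrom = "I", pos = seq_len(nrow(freq))),
    freq = freq,
    freq_var = matrix(0, nrow(freq), P, dimnames = list(NULL, colnames(freq))),
    pop_sizes = stats::setNames(sizes, colnames(freq)),
    pi_hat = pi_hat,
    usable = rep(TRUE, nrow(freq))), class = "pop_freq")
}

test_that("population frequencies are counting exercises", {
  dos <- matrix(c(2L, 2L, 2L,  0L, 2L, NA,  1L, 0L, 0L), 3, 3, byrow = TRUE,
                dimnames = list(NULL, c("A", "B", "C")))
  dos <- cbind(dos, dos, dos)  # 9 samples, 3 clusters of 3
  colnames(dos) <- sprintf("S%d", 1:9)
  gm <- make_gm(dos)
  labels <- setNames(rep(c("c1", "c2", "c3"), each = 3), sprintf("S%d", 1:9))
  pf <- population_allele_frequencies(gm, labels, min_size = 3)
  # brute-force counts
  for (cl in c("c1", "c2", "c3")) {
    cols <- names(labels)[labels == cl]
    for (i in 1:3) {
      v <- dos[i, cols]
      expect_equal(unname(pf$freq[i, cl]), unname(mean(v, na.rm = TRUE) / 2))
    }
  }
  # all-dosage-2 cluster has frequency one
  expect_equal(unname(pf$freq[1, "c1"]), 1)

  # clusters below the minimum size are dropped
  labels2 <- setNames(c(rep("a", 2), rep("b", 3), rep("c", 4)), sprintf("S%d", 1:9))
  expect_message(pf2 <- population_allele_frequencies(gm, labels2, min_size = 3),
                 "dropped")
  expect_equal(colnames(pf2$freq), c("b", "c"))
})

test_that("omega estimation recovers simple structures", {
  set.seed(81)
  # iid populations (star tree): off-diagonals vanish
  n <- 4000; P <- 6
  pi0 <- runif(n, 0.2, 0.8)
  freq <- pi0 + sqrt(pi0 * (1 - pi0)) * matrix(rnorm(n * P, sd = sqrt(0.05)), n, P)
  freq <- pmin(pmax(freq, 0.001), 0.999)
  pf <- make_pf(freq)
  om <- estimate_omega(pf, subset_size = 4000)
  expect_lt(max(abs(om$scan_cov[upper.tri(om$scan_cov)])), 0.015)
  expect_equal(om$drift_depth, 0.05, tolerance = 0.3)

  # duplicated population column: off-diagonal matches the diagonal
  freq2 <- cbind(freq, freq[, P])
  colnames(freq2) <- sprintf("SC%02d", 1:(P + 1))
  om2 <- estimate_omega(make_pf(freq2), subset_size = 4000)
  expect_equal(om2$omega[P, P + 1], om2$omega[P + 1, P + 1], tolerance = 0.01)
  expect_error(estimate_omega(make_pf(freq[1:100, ])), "500 usable")
})

test_that("XtX is a calibrated Mahalanobis scan", {
  set.seed(82)
  P <- 10; n <- 3000
  pi0 <- runif(n, 0.2, 0.8)
  om_true <- diag(0.04, P) + 0.01
  L <- chol(om_true)
  dev <- matrix(rnorm(n * P), n, P) %*% L
  freq <- pmin(pmax(pi0 + sqrt(pi0 * (1 - pi0)) * dev, 0.001), 0.999)
  pf <- make_pf(freq)
  # no differentiation at a marker: XtX = 0
  pf$freq[7, ] <- pf$pi_hat[7]
  scan <- xtx_scan(pf, om_true, quantile = 0.999)
  expect_equal(scan$xtx[7], 0, tolerance = 1e-20)
  # allele relabeling leaves XtX unchanged
  pf_flip <- pf
  pf_flip$freq[5, ] <- 1 - pf_flip$freq[5, ]
  pf_flip$pi_hat[5] <- 1 - pf_flip$pi_hat[5]
  scan_flip <- xtx_scan(pf_flip, om_true, quantile = 0.999)
  expect_equal(scan_flip$xtx[5], scan$xtx[5], tolerance = 1e-10)
  # a strongly differentiated marker is flagged above the top-0.1% cut
  pf$freq[11, ] <- rep(c(0.05, 0.95), length.out = P)
  scan2 <- xtx_scan(pf, estimate_omega(pf, subset_size = 3000), quantile = 0.999)
  expect_true(scan2$flag[11])
})

test_that("Bayes factors favor the null for orthogonal covariates and scale-invariantly", {
  set.seed(83)
  P <- 8; n <- 500
  pi0 <- runif(n, 0.3, 0.7)
  freq <- pmin(pmax(pi0 + sqrt(pi0 * (1 - pi0)) *
                      matrix(rnorm(n * P, sd = 0.2), n, P), 0.001), 0.999)
  pf <- make_pf(freq)
  om <- diag(0.04, P)
  z <- rnorm(P)
  # orthogonal construction: make a marker's deviations orthogonal to z
  zs <- (z - mean(z)) / sd(z)
  a_row <- rnorm(P)
  a_row <- a_row - zs * sum(a_row * zs) / sum(zs^2)
  pf$freq[3, ] <- pf$pi_hat[3] + sqrt(pf$pi_hat[3] * (1 - pf$pi_hat[3])) * a_row
  bf <- bayes_factor_scan(pf, om, cbind(env = z))
  expect_lt(bf$bf_db[3], 0)
  # covariate scaling cannot change the evidence
  bf2 <- bayes_factor_scan(pf, om, cbind(env = 13 * z))
  expect_equal(bf$bf_db, bf2$bf_db, tolerance = 1e-10)
  expect_warning(bayes_factor_scan(pf, om, cbind(env = z, flat = rep(1, P))),
                 "constant")
})

test_that("kinship matrices exclude the left-out chromosome", {
  set.seed(84)
  m <- 300; ns <- 25
  dos <- matrix(rbinom(m * ns, 2, runif(m, .2, .8)), m, ns)
  storage.mode(dos) <- "integer"
  colnames(dos) <- sprintf("S%02d", 1:ns)
  chrom <- rep(c("I", "II", "III"), each = 100)
  gm <- make_gm(dos, chrom = chrom, pos = rep(seq_len(100) * 5L, 3),
                contig_len = 600L)
  kin <- kinship(gm)
  expect_equal(mean(diag(kin$K)), 1, tolerance = 0.25)
  expect_equal(kin$K, t(kin$K))
  # zeroing test: the LOCO matrix equals kinship built without that chromosome
  gm_no1 <- subset_sites(gm, which(chrom != "I"))
  kin_no1 <- kinship(gm_no1)
  expect_equal(kin$loco[["I"]], kin_no1$K, tolerance = 1e-12)

  # identical samples are as related as a sample is to itself
  dos2 <- dos; dos2[, 2] <- dos2[, 1]
  gm2 <- make_gm(dos2, chrom = chrom, pos = rep(seq_len(100) * 5L, 3),
                 contig_len = 600L)
  K2 <- kinship(gm2)$K
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)
})

test_that("the mixed model reduces to least squares under identity kinship", {
  set.seed(85)
  m <- 120; ns <- 40
  dos <- matrix(rbinom(m * ns, 2, runif(m, .2, .8)), m, ns)
  storage.mode(dos) <- "integer"
  colnames(dos) <- sprintf("S%02d", 1:ns)
  gm <- make_gm(dos, chrom = rep(c("I", "II"), each = m / 2),
                pos = rep(seq_len(m / 2) * 3L, 2), contig_len = 500L)
  kin <- kinship(gm)
  for (ch in c("I", "II")) {
    kin$loco[[ch]] <- diag(ns)
    dimnames(kin$loco[[ch]]) <- list(colnames(dos), colnames(dos))
  }
  y <- setNames(rnorm(ns), colnames(dos))
  res <- lmm_gwa(gm, y, kin)
  ols_p <- sapply(seq_len(m), function(j)
    summary(lm(y ~ dos[j, ]))$coefficients[2, 4])
  ols_b <- sapply(seq_len(m), function(j)
    summary(lm(y ~ dos[j, ]))$coefficients[2, 1])
  expect_lt(max(abs(res$p - ols_p)), 1e-6)
  expect_lt(max(abs(res$beta - ols_b)), 1e-8)
})

test_that("a marker generating the phenotype attains the minimum p-value", {
  set.seed(86)
  m <- 400; ns <- 50
  dos <- matrix(rbinom(m * ns, 2, runif(m, .2, .8)), m, ns)
  storage.mode(dos) <- "integer"
  colnames(dos) <- sprintf("S%02d", 1:ns)
  chrom <- rep(c("I", "II"), each = 200)
  gm <- make_gm(dos, chrom = chrom, pos = rep(seq_len(200) * 4L, 2),
                contig_len = 1000L)
  kin <- kinship(gm)
  y <- setNames(2 * dos[57, ] + rnorm(ns, sd = 0.3), colnames(dos))
  res <- lmm_gwa(gm, y, kin)
  expect_equal(which.min(res$p), 57L)
  expect_error(lmm_gwa(gm, setNames(rep(1, ns), colnames(dos)), kin),
               "constant")
})

test_that("the effective test count tracks marker correlation blocks", {
  set.seed(87)
  ns <- 80
  # independent markers (fewer than samples): Meff close to m
  dos <- matrix(rbinom(40 * ns, 2, 0.5), 40, ns)
  storage.mode(dos) <- "integer"
  colnames(dos) <- sprintf("S%02d", 1:ns)
  gm <- make_gm(dos, pos = seq_len(40) * 5L, contig_len = 500L)
  meff <- effective_tests(gm)
  expect_gt(meff$meff, 0.75 * 40)
  expect_lte(meff$meff, 40 + 1e-9)

  # identical markers collapse to one test
  one <- dos[rep(1, 30), , drop = FALSE]
  gm1 <- make_gm(one, pos = seq_len(30) * 5L, contig_len = 500L)
  expect_equal(effective_tests(gm1)$meff, 1, tolerance = 1e-8)

  # b mutually orthogonal blocks of perfectly correlated markers: Meff = b
  b <- 4
  walsh <- rbind(rep(c(0L, 2L), length.out = ns),
                 rep(c(0L, 0L, 2L, 2L), length.out = ns),
                 rep(c(0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L), length.out = ns),
                 rep(c(rep(0L, 8), rep(2L, 8)), length.out = ns))
  blocks <- walsh[rep(1:b, each = 10), , drop = FALSE]
  colnames(blocks) <- colnames(dos)
  gmb <- make_gm(blocks, pos = seq_len(10 * b) * 5L, contig_len = 500L)
  expect_equal(effective_tests(gmb)$meff, b, tolerance = 1e-8)
  expect_equal(effective_tests(gmb)$threshold, 0.05 / b, tolerance = 1e-8)
})

test_that("variance explained is the squared correlation and regression identity", {
  set.seed(88)
  g <- rbinom(60, 2, 0.5)
  y <- 3 * g - 1
  expect_equal(variance_explained(g, y), 1)
  y2 <- rnorm(60)
  ve <- variance_explained(g, y2)
  fit <- lm(y2 ~ g)
  expect_equal(ve, 1 - sum(resid(fit)^2) / sum((y2 - mean(y2))^2))
  expect_warning(variance_explained(rep(1, 60), y2), "constant")
})
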