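#' Per-population allele frequencies
#'
#' Collapses sample dosages to per-cluster alternate-allele frequencies.
#' Clusters below `min_size` members are dropped.  The ancestral-frequency
#' estimate per SNV is the sample-size-weighted mean across retained
#' clusters.  SNVs missing in an entire cluster are flagged and excluded
#' from covariance estimation and scans.
#'
#' @param gm A `genotype_matrix`.
#' @param cluster_labels Named vector mapping sample -> cluster label
#'   (NA samples are excluded).
#' @param min_size Minimum cluster size (default 3).
#' @return An object of class `pop_freq`: `sites`, `freq` (SNV x P),
#'   `freq_var` (sampling variance of each frequency estimate),
#'   `pop_sizes`, `pi_hat`, `usable` (no missing population frequency).
#' @export
population_allele_frequencies <- function(gm, cluster_labels, min_size = 3) {
  stopifnot(inherits(gm, "genotype_matrix"))
  labels <- cluster_labels[gm$samples]
  keep <- !is.na(labels)
  sizes <- table(labels[keep])
  pops <- sort(names(sizes)[sizes >= min_size])
  if (length(pops) < 2) stop2("fewer than 2 clusters of size >= %d", min_size)
  n_dropped <- sum(!names(sizes) %in% pops)
  if (n_dropped)
    message(sprintf("%d clusters below %d members dropped", n_dropped, min_size))
  nsize <- integer(length(pops))
  freq <- matrix(NA_real_, nrow(gm$sites), length(pops),
                 dimnames = list(NULL, pops))
  freq_var <- freq
  for (j in seq_along(pops)) {
    cols <- which(!is.na(labels) & labels == pops[j])
    nsize[j] <- length(cols)
    sub <- gm$dosage[, cols, drop = FALSE]
    cnt <- rowSums(!is.na(sub))
    freq[, j] <- ifelse(cnt > 0, rowSums(sub, na.rm = TRUE) / (2 * cnt), NA_real_)
    # sampling variance of the frequency estimate: var(dosage) / (4 n)
    mu <- rowMeans(sub, na.rm = TRUE)
    ssq <- rowSums((sub - mu)^2, na.rm = TRUE) / pmax(cnt - 1, 1)
    freq_var[, j] <- ifelse(cnt > 1, ssq / (4 * cnt), NA_real_)
  }
  usable <- rowSums(is.na(freq)) == 0
  w <- nsize / sum(nsize)
  pi_hat <- as.vector(freq %*% w)
  structure(list(sites = gm$sites[, c("chrom", "pos")], freq = freq,
                 freq_var = freq_var,
                 pop_sizes = stats::setNames(nsize, pops), pi_hat = pi_hat,
                 usable = usable),
            class = "pop_freq")
}

# standardized allele-frequency deviations (SNV x P); rows with missing or
# degenerate ancestral frequency are NA
scaled_deviations <- function(pf) {
  ok <- pf$usable & pf$pi_hat > 0 & pf$pi_hat < 1
  a <- matrix(NA_real_, nrow(pf$freq), ncol(pf$freq))
  a[ok, ] <- (pf$freq[ok, , drop = FALSE] - pf$pi_hat[ok]) /
    sqrt(pf$pi_hat[ok] * (1 - pf$pi_hat[ok]))
  a
}

shrink_to_condition <- function(m, max_condition) {
  cond_of <- function(w) {
    s <- (1 - w) * m + w * diag(diag(m))
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) Inf else max(ev) / min(ev)
  }
  w <- 0
  if (cond_of(0) > max_condition) {
    if (!is.finite(cond_of(1)) || cond_of(1) > max_condition)
      stop2("covariance singular even after full diagonal shrinkage")
    lo <- 0; hi <- 1
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (cond_of(mid) > max_condition) lo <- mid else hi <- mid
    }
    w <- hi
  }
  list(m = (1 - w) * m + w * diag(diag(m)), w = w)
}

#' Estimate the population covariance matrix Omega
#'
#' Moment estimation over a subsample of SNVs.  Two related matrices are
#' produced.  `scan_cov` is the raw second-moment matrix of the
#' standardized allele-frequency deviations; because the deviations are
#' centered at an estimated ancestral frequency and carry binomial
#' sampling noise, this is the correct whitening kernel for the XtX and
#' Bayes-factor scans.  `omega` is the estimate of the underlying drift
#' covariance parameter: pairwise drift distances (which are invariant to
#' the centering) are corrected for the per-population sampling variance
#' and converted back to a covariance under the convention that the most
#' diverged pair of populations shares no drift, so the diagonal estimates
#' the root-to-tip drift depth.  Both matrices are shrunk toward their
#' diagonals just enough to keep the condition number below
#' `max_condition`.
#'
#' @param pf A `pop_freq` table.
#' @param subset_size Number of SNVs to subsample (default 5000).
#' @param seed Seed for the subsample.
#' @param max_condition Condition-number ceiling for the shrinkage target.
#' @return An object of class `omega_matrix`: `omega` (drift covariance
#'   estimate), `scan_cov` (deviation covariance used for whitening),
#'   `drift_depth`, `n_snvs`, `shrinkage`.
#' @export
estimate_omega <- function(pf, subset_size = 5000, seed = 1,
                           max_condition = 1e6) {
  stopifnot(inherits(pf, "pop_freq"))
  a <- scaled_deviations(pf)
  rows <- which(stats::complete.cases(a))
  if (length(rows) < 500) stop2("need at least 500 usable SNVs to estimate Omega")
  if (length(rows) > subset_size) {
    set.seed(derive_seed(seed, 101L))
    rows <- sort(sample(rows, subset_size))
  }
  pops <- colnames(pf$freq)
  a <- a[rows, , drop = FALSE]
  E <- crossprod(a) / nrow(a)
  dimnames(E) <- list(pops, pops)

  # per-population mean sampling variance on the standardized scale
  scale_rows <- pf$pi_hat[rows] * (1 - pf$pi_hat[rows])
  v <- colMeans(pf$freq_var[rows, , drop = FALSE] / scale_rows, na.rm = TRUE)
  Ec <- E - diag(v)
  # drift distances are invariant to ancestral-frequency centering
  d <- outer(diag(Ec), diag(Ec), "+") - 2 * Ec
  depth <- max(d) / 2
  omega <- depth - d / 2
  dimnames(omega) <- list(pops, pops)

  omega_s <- shrink_to_condition(omega, max_condition)
  scan_s <- shrink_to_condition(E, max_condition)
  structure(list(omega = omega_s$m, scan_cov = scan_s$m,
                 drift_depth = depth, n_snvs = nrow(a),
                 shrinkage = c(omega = omega_s$w, scan = scan_s$w)),
            class = "omega_matrix")
}

#' XtX differentiation scan
#'
#' The per-SNV differentiation statistic `XtX = a' Omega^-1 a`, a
#' Mahalanobis distance of the standardized population allele-frequency
#' vector under the drift covariance; under neutrality its mean is the
#' number of populations.  Markers above the empirical `quantile` cut
#' (default top 0.1%) are flagged as candidates for local adaptation.
#'
#' @param pf A `pop_freq` table.
#' @param omega An `omega_matrix` (or plain matrix).
#' @param quantile Quantile defining the genome-wide threshold.
#' @return Data frame `chrom`, `pos`, `xtx`, `flag`; skipped markers
#'   (missing population frequency) carry NA.  The threshold is in
#'   attribute `threshold`.
#' @export
xtx_scan <- function(pf, omega, quantile = 0.999) {
  stopifnot(inherits(pf, "pop_freq"))
  om <- if (inherits(omega, "omega_matrix")) omega$scan_cov else omega
  if (!is_positive_definite(om)) stop2("omega must be positive definite")
  a <- scaled_deviations(pf)
  ok <- stats::complete.cases(a)
  xtx <- rep(NA_real_, nrow(a))
  oi <- chol2inv(chol(om))
  xtx[ok] <- rowSums((a[ok, , drop = FALSE] %*% oi) * a[ok, , drop = FALSE])
  thr <- stats::quantile(xtx, quantile, na.rm = TRUE, names = FALSE)
  out <- data.frame(chrom = pf$sites$chrom, pos = pf$sites$pos, xtx = xtx,
                    flag = !is.na(xtx) & xtx > thr, stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Bayes-factor scan for genotype-environment association
#'
#' For each marker and covariate, the standardized deviation vector and
#' the population covariate are whitened by the Cholesky factor of Omega
#' and compared under a conjugate linear model with a Zellner g-prior
#' (g = number of populations) against the null of no effect.  The Bayes
#' factor is reported in deciban (10 log10 BF); the conventional decisive
#' cutoff of 20 dB corresponds to BF > 100.
#'
#' @param pf A `pop_freq` table.
#' @param omega An `omega_matrix` (or plain matrix).
#' @param covariates P x K matrix of population covariates (standardized
#'   internally to mean 0, SD 1 across populations).
#' @param g Zellner g-prior scale (default: number of populations).
#' @param bf_cut_db Flagging threshold in deciban (default 20).
#' @return Long data frame `chrom`, `pos`, `covariate`, `beta`, `bf_db`,
#'   `flag`.
#' @export
bayes_factor_scan <- function(pf, omega, covariates, g = NULL,
                              bf_cut_db = 20) {
  stopifnot(inherits(pf, "pop_freq"))
  om <- if (inherits(omega, "omega_matrix")) omega$scan_cov else omega
  P <- ncol(pf$freq)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != P)
    stop2("covariates must have one row per population (%d)", P)
  if (is.null(g)) g <- P
  a <- scaled_deviations(pf)
  ok <- stats::complete.cases(a)
  L <- t(chol(om))  # lower triangular, om = L L'
  Y <- forwardsolve(L, t(a[ok, , drop = FALSE]))  # P x n_ok, whitened
  yy <- colSums(Y^2)
  out <- list()
  for (k in seq_len(ncol(covariates))) {
    z <- covariates[, k]
    nm <- colnames(covariates)[k] %||% paste0("cov", k)
    if (stats::sd(z) == 0) {
      warning(sprintf("covariate %s is constant; skipped", nm))
      next
    }
    z <- (z - mean(z)) / stats::sd(z)
    x <- forwardsolve(L, z)
    xx <- sum(x^2)
    xy <- as.vector(crossprod(x, Y))
    r2 <- (xy^2) / (xx * yy)
    r2 <- pmin(r2, 1 - 1e-12)
    log10bf <- -0.5 * log10(1 + g) - (P / 2) * log10(1 - (g / (1 + g)) * r2)
    bf_db <- rep(NA_real_, nrow(a))
    beta <- rep(NA_real_, nrow(a))
    bf_db[ok] <- 10 * log10bf
    beta[ok] <- (g / (1 + g)) * xy / xx
    out[[nm]] <- data.frame(chrom = pf$sites$chrom, pos = pf$sites$pos,
                            covariate = nm, beta = beta, bf_db = bf_db,
                            flag = !is.na(bf_db) & bf_db > bf_cut_db,
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) stop2("no usable covariates")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "bf_cut_db") <- bf_cut_db
  res
}

#' Realized-relationship (kinship) matrices with LOCO variants
#'
#' `K = A A' / m` over normalized dosages (the PCA normalization), plus
#' one leave-one-chromosome-out matrix per chromosome that excludes that
#' chromosome's markers, avoiding proximal contamination in mixed-model
#' tests.
#'
#' @param gm A `genotype_matrix` (typically the pruned marker set).
#' @return An object of class `kinship_set`: `K`, `loco` (named list),
#'   `m` (marker count), `m_loco`.
#' @export
kinship <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  norm <- normalize_dosage(gm$dosage)
  X <- norm$X  # samples x polymorphic markers
  m <- ncol(X)
  chrom <- gm$sites$chrom[norm$polymorphic]
  G <- tcrossprod(X)
  chroms <- unique(gm$sites$chrom)
  loco <- list()
  m_loco <- integer(0)
  for (ch in chroms) {
    on_ch <- chrom == ch
    m_rest <- m - sum(on_ch)
    if (m_rest == 0)
      stop2("no markers remain when chromosome %s is left out", ch)
    G_ch <- tcrossprod(X[, on_ch, drop = FALSE])
    loco[[ch]] <- (G - G_ch) / m_rest
    m_loco[ch] <- m_rest
  }
  structure(list(K = G / m, loco = loco, m = m, m_loco = m_loco,
                 samples = gm$samples),
            class = "kinship_set")
}

# REML profile log-likelihood on the eigendecomposed model, maximized over
# log10 of the variance ratio delta = sigma_e^2 / sigma_g^2
reml_delta <- function(ytil, xtil, D, grid = seq(-5, 5, length.out = 101)) {
  n <- length(ytil)
  loglik <- function(ldelta) {
    delta <- 10^ldelta
    w <- 1 / (D + delta)
    xtwx <- sum(w * xtil^2)
    alpha <- sum(w * xtil * ytil) / xtwx
    rss <- sum(w * (ytil - xtil * alpha)^2)
    s2 <- rss / (n - 1)
    -0.5 * ((n - 1) * log(s2) + sum(log(D + delta)) + log(xtwx) + (n - 1))
  }
  ll <- vapply(grid, loglik, numeric(1))
  best <- which.max(ll)
  lo <- grid[max(best - 1, 1)]
  hi <- grid[min(best + 1, length(grid))]
  opt <- stats::optimize(loglik, c(lo, hi), maximum = TRUE, tol = 1e-6)
  list(log10_delta = opt$maximum, delta = 10^opt$maximum,
       boundary = best %in% c(1L, length(grid)))
}

#' Linear mixed-model genome-wide association
#'
#' Per-marker association of a quantitative phenotype under
#' `y = mu + g beta + u + e`, `u ~ N(0, sigma_g^2 K_LOCO)`.  The variance
#' ratio is estimated once per chromosome by REML on the eigendecomposed
#' model (coarse log-grid plus local refinement); each marker is then
#' tested by generalized least squares with a Wald t-test (df = n - 2), so
#' with an identity kinship the results coincide exactly with ordinary
#' least squares.
#'
#' @param gm A `genotype_matrix` of test markers.
#' @param phenotype Named numeric vector (names = samples); NA samples are
#'   dropped.
#' @param kin A `kinship_set` from [kinship()] (LOCO matrices used).
#' @return Data frame `chrom`, `pos`, `beta`, `se`, `p`; attributes
#'   `delta` (per chromosome) and `flagged_chromosomes` (REML at grid
#'   boundary).
#' @export
lmm_gwa <- function(gm, phenotype, kin) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(kin, "kinship_set"))
  y_all <- phenotype[gm$samples]
  use <- !is.na(y_all)
  if (sum(use) < 5) stop2("fewer than 5 phenotyped samples")
  if (stats::sd(y_all[use]) == 0) stop2("phenotype is constant")
  samples <- gm$samples[use]
  y <- as.numeric(y_all[use])
  n <- length(y)

  res <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  deltas <- c()
  flagged <- character(0)
  for (ch in unique(gm$sites$chrom)) {
    K <- kin$loco[[ch]]
    if (is.null(K)) stop2("no LOCO kinship for chromosome %s", ch)
    K <- K[samples, samples]
    eig <- eigen(K, symmetric = TRUE)
    D <- pmax(eig$values, 0)
    U <- eig$vectors
    ytil <- as.vector(crossprod(U, y))
    onetil <- as.vector(crossprod(U, rep(1, n)))
    fit <- reml_delta(ytil, onetil, D)
    deltas[ch] <- fit$delta
    if (fit$boundary) flagged <- c(flagged, ch)
    w <- 1 / (D + fit$delta)

    idx <- which(gm$sites$chrom == ch)
    # rotated dosages (missing dosages mean-imputed)
    Graw <- t(gm$dosage[idx, samples, drop = FALSE]) * 1.0
    if (anyNA(Graw)) {
      mu <- colMeans(Graw, na.rm = TRUE)
      nas <- which(is.na(Graw), arr.ind = TRUE)
      Graw[nas] <- mu[nas[, 2]]
    }
    Gt <- crossprod(U, Graw)
    W1 <- w * onetil
    S11 <- sum(onetil * W1)
    S1y <- sum(W1 * ytil)
    Syy <- sum(w * ytil^2)
    Sxx <- colSums(w * Gt^2)
    Sx1 <- colSums(Gt * W1)
    Sxy <- colSums(Gt * (w * ytil))
    denom <- S11 * Sxx - Sx1^2
    beta <- (S11 * Sxy - Sx1 * S1y) / denom
    alpha <- (S1y - Sx1 * beta) / S11
    rss <- Syy - beta * Sxy - alpha * S1y
    sigma2 <- rss / (n - 2)
    se <- sqrt(sigma2 * S11 / denom)
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    bad <- !is.finite(denom) | denom <= 0
    beta[bad] <- se[bad] <- p[bad] <- NA_real_
    res$beta[idx] <- beta
    res$se[idx] <- se
    res$p[idx] <- p
  }
  attr(res, "delta") <- deltas
  attr(res, "flagged_chromosomes") <- flagged
  res
}

#' Effective number of independent tests (Li-Ji)
#'
#' Computed from the eigenvalues of the marker correlation matrix via the
#' dual (sample-side) matrix, so it scales to marker counts far beyond the
#' sample size: `Meff = sum_i [ I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`.
#'
#' @param gm A `genotype_matrix` (the tested marker set).
#' @param alpha Family-wise error rate (default 0.05).
#' @return A list: `meff`, `threshold` (= alpha / meff), `n_markers`.
#' @export
effective_tests <- function(gm, alpha = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$sites) < 2) stop2("need at least 2 markers")
  d <- t(gm$dosage) * 1.0
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    nas <- which(is.na(d), arr.ind = TRUE)
    d[nas] <- mu[nas[, 2]]
  }
  sds <- apply(d, 2, stats::sd)
  keep <- sds > 0
  d <- scale(d[, keep, drop = FALSE])
  n <- nrow(d)
  lambda <- eigen(tcrossprod(d) / (n - 1), symmetric = TRUE,
                  only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  # snap eigenvalues that sit at an integer up to numerical noise, so the
  # fractional part of e.g. 30 - 1e-12 does not count as a full test
  near <- abs(lambda - round(lambda)) < 1e-8
  lambda[near] <- round(lambda[near])
  meff <- sum(ifelse(lambda >= 1, 1, 0) + (lambda - floor(lambda)))
  list(meff = meff, threshold = alpha / meff, n_markers = sum(keep))
}

#' Phenotypic variance explained by a marker
#'
#' Squared Pearson correlation between dosage and phenotype; equals
#' `1 - RSS/TSS` of the univariate regression.
#'
#' @param dosage Numeric dosage vector at the marker.
#' @param phenotype Numeric phenotype vector.
#' @return Fraction in \[0, 1\] (NA with a warning for constant dosage).
#' @export
variance_explained <- function(dosage, phenotype) {
  ok <- !is.na(dosage) & !is.na(phenotype)
  if (sum(ok) < 3) stop2("need at least 3 paired observations")
  if (stats::sd(dosage[ok]) == 0) {
    warning("constant dosage; variance explained undefined")
    return(NA_real_)
  }
  stats::cor(dosage[ok], phenotype[ok])^2
}
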