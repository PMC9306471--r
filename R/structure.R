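#' Prune markers in linkage disequilibrium
#'
#' plink-style `--indep-pairwise` pruning: within each `window`-marker
#' span, one member of any pair with dosage correlation `r^2 > r2_max` is
#' greedily removed (the lower minor-allele-frequency member; ties remove
#' the later position) until no pair exceeds the threshold; the window then
#' advances by `step` markers.  Windows never span chromosomes.  An
#' optional minor-allele-frequency filter is applied first.  Missing
#' dosages are mean-imputed for the correlation only.
#'
#' @param gm A `genotype_matrix`.
#' @param window Window size in markers (default 50).
#' @param step Step size in markers.
#' @param r2_max Squared-correlation threshold (default 0.8).
#' @param maf_min Minimum minor allele frequency (0 disables).
#' @return Integer vector of retained site indices into `gm$sites`.
#' @export
ld_prune <- function(gm, window = 50, step = 10, r2_max = 0.8, maf_min = 0) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (step <= 0 || window <= 0) stop2("invalid config: window and step must be positive")
  freq <- rowMeans(gm$dosage, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  candidates <- if (maf_min > 0) which(!is.na(maf) & maf >= maf_min) else which(!is.na(maf))
  retained <- integer(0)
  for (ch in unique(gm$sites$chrom)) {
    idx <- candidates[gm$sites$chrom[candidates] == ch]
    if (!length(idx)) next
    D <- t(gm$dosage[idx, , drop = FALSE]) * 1.0
    mu <- colMeans(D, na.rm = TRUE)
    for (j in seq_len(ncol(D))) {
      col <- D[, j]
      col[is.na(col)] <- mu[j]
      D[, j] <- col - mu[j]
    }
    kept <- .ld_prune_chr(D, maf[idx], as.integer(gm$sites$pos[idx]),
                          as.integer(window), as.integer(step), r2_max)
    retained <- c(retained, idx[kept])
  }
  sort(retained)
}

# marker normalization shared by PCA and kinship:
# (g - 2 p_hat) / sqrt(2 p_hat (1 - p_hat)); missing -> 0 (the mean)
normalize_dosage <- function(dosage) {
  p <- rowMeans(dosage, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  X <- (dosage[poly, , drop = FALSE] - 2 * p[poly]) / sqrt(2 * p[poly] * (1 - p[poly]))
  X[is.na(X)] <- 0
  list(X = t(X), polymorphic = which(poly), dropped = sum(!poly))
}

#' Tracy-Widom significance of leading eigenvalues
#'
#' Moment-matching recipe: at each step the remaining eigenvalues estimate
#' an effective marker count, the leading one is standardized against the
#' Tracy-Widom TW1 center and scale, and its p-value is read from the TW1
#' distribution (gamma approximation: shape 46.446, scale 0.18605, shift
#' -9.848, accurate to ~1e-2 across the testing range).
#'
#' @param eigenvalues Non-negative eigenvalues, decreasing.
#' @param n_samples Number of samples behind the covariance.
#' @param alpha Significance level for counting significant components.
#' @return Data frame `eigenvalue`, `twstat`, `p`; attribute
#'   `n_significant` counts leading eigenvalues with `p < alpha`.
#' @export
tracy_widom <- function(eigenvalues, n_samples, alpha = 0.05) {
  lambda <- eigenvalues[eigenvalues > 1e-12]
  L <- length(lambda)
  tw <- p <- rep(NA_real_, L)
  for (i in seq_len(max(L - 1, 0))) {
    lam <- lambda[i:L]
    m <- length(lam)
    S1 <- sum(lam)
    S2 <- sum(lam^2)
    # effective marker count from the spread of the remaining eigenvalues
    # (moment matching for a column-centered matrix: the implied
    # squared coefficient of variation estimates (m+1)/n_eff)
    n_eff <- ((m + 1) * S1^2) / (m * S2 - S1^2)
    if (!is.finite(n_eff) || n_eff <= 1) break
    ell <- m * lam[1] / S1
    mu <- (sqrt(n_eff - 1) + sqrt(m))^2 / n_eff
    sig <- ((sqrt(n_eff - 1) + sqrt(m)) / n_eff) *
      (1 / sqrt(n_eff - 1) + 1 / sqrt(m))^(1 / 3)
    tw[i] <- (ell - mu) / sig
    p[i] <- ptw1(tw[i], lower.tail = FALSE)
  }
  out <- data.frame(eigenvalue = lambda, twstat = tw, p = p)
  sig_run <- 0L
  for (i in seq_len(L)) {
    if (!is.na(p[i]) && p[i] < alpha) sig_run <- sig_run + 1L else break
  }
  attr(out, "n_significant") <- sig_run
  out
}

#' Tracy-Widom TW1 distribution function (gamma approximation)
#'
#' @param q Quantile.
#' @param lower.tail As in [stats::pgamma()].
#' @return Probability.
#' @export
ptw1 <- function(q, lower.tail = TRUE) {
  stats::pgamma(q + 9.848007781, shape = 46.44604884, scale = 0.18605402228,
                lower.tail = lower.tail)
}

#' Principal components analysis of a genotype matrix
#'
#' Markers are normalized by centering at twice the sample allele
#' frequency and scaling by the binomial standard deviation; monomorphic
#' markers are dropped.  The eigendecomposition of the sample covariance
#' gives sample scores (sign-canonicalized so the largest-magnitude marker
#' loading is positive), Tracy-Widom statistics per eigenvalue, and an
#' iterative outlier-removal loop: samples more than `outlier_sigma` SDs
#' from the mean along any of the top `outlier_pcs` axes are removed and
#' the decomposition recomputed.
#'
#' @param gm A `genotype_matrix` (typically LD pruned).
#' @param n_components Number of components to report.
#' @param outlier_iterations Maximum outlier-removal iterations (0 = none).
#' @param outlier_sigma Outlier threshold in SD units (default 6).
#' @param outlier_pcs Number of leading PCs scanned for outliers.
#' @return An object of class `pca_result`: `eigenvalues`, `scores`,
#'   `tw` (Tracy-Widom table), `n_significant`, `removed_outliers`,
#'   `n_markers`, `monomorphic_dropped`.
#' @export
pca_genotypes <- function(gm, n_components = 50, outlier_iterations = 0,
                          outlier_sigma = 6, outlier_pcs = 10) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(gm$samples) < 3) stop2("need at least 3 samples")
  active <- gm$samples
  removed <- data.frame(sample = character(0), iteration = integer(0),
                        stringsAsFactors = FALSE)
  dropped <- 0L
  iter <- 0L
  repeat {
    dos <- gm$dosage[, active, drop = FALSE]
    norm <- normalize_dosage(dos)
    dropped <- norm$dropped
    X <- norm$X  # samples x markers
    m <- ncol(X)
    if (m < 2) stop2("fewer than 2 polymorphic markers")
    C <- tcrossprod(X) / m
    eig <- eigen(C, symmetric = TRUE)
    lambda <- pmax(eig$values, 0)
    k <- min(n_components, length(lambda))
    U <- eig$vectors[, seq_len(k), drop = FALSE]
    # canonical sign: largest-magnitude marker loading positive
    for (j in seq_len(k)) {
      ld <- crossprod(X, U[, j])
      if (ld[which.max(abs(ld))] < 0) U[, j] <- -U[, j]
    }
    scores <- U * rep(sqrt(pmax(lambda[seq_len(k)], 0)), each = nrow(U))
    rownames(scores) <- active
    colnames(scores) <- paste0("PC", seq_len(k))

    if (iter >= outlier_iterations) break
    top <- seq_len(min(outlier_pcs, k))
    out_mask <- rep(FALSE, nrow(scores))
    for (j in top) {
      s <- scores[, j]
      sd_j <- stats::sd(s)
      if (sd_j > 0) out_mask <- out_mask | abs(s - mean(s)) / sd_j > outlier_sigma
    }
    if (!any(out_mask)) break
    iter <- iter + 1L
    removed <- rbind(removed, data.frame(sample = active[out_mask],
                                         iteration = iter,
                                         stringsAsFactors = FALSE))
    active <- active[!out_mask]
    if (length(active) < 3) stop2("outlier removal left fewer than 3 samples")
  }
  tw <- tracy_widom(lambda, n_samples = length(active))
  structure(list(eigenvalues = lambda, scores = scores, tw = tw,
                 n_significant = attr(tw, "n_significant"),
                 removed_outliers = removed, n_markers = m,
                 monomorphic_dropped = dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples x %d markers; %d significant PCs; %d outliers removed\n",
              nrow(x$scores), x$n_markers, x$n_significant,
              nrow(x$removed_outliers)))
  invisible(x)
}

#' Assign genetic groups by hierarchical clustering of PC scores
#'
#' Average-linkage hierarchical clustering on the Euclidean distance over
#' the significant principal-component scores, cut into `k` groups.
#' Group labels are canonicalized by descending size.
#'
#' @param scores Samples x PCs score matrix (rownames = samples).
#' @param k Number of groups.
#' @return Data frame `sample`, `group` (integer, 1 = largest).
#' @export
assign_genetic_groups <- function(scores, k = 7) {
  scores <- as.matrix(scores)
  if (k > nrow(scores)) stop2("invalid config: k exceeds the number of samples")
  if (k == 1) {
    return(data.frame(sample = rownames(scores), group = 1L,
                      stringsAsFactors = FALSE))
  }
  hc <- stats::hclust(stats::dist(scores), method = "average")
  raw <- stats::cutree(hc, k = k)
  sizes <- table(raw)
  remap <- stats::setNames(rank(-as.numeric(sizes), ties.method = "first"),
                           names(sizes))
  data.frame(sample = rownames(scores),
             group = as.integer(remap[as.character(raw)]),
             stringsAsFactors = FALSE)
}

#' Correlate principal components with environmental variables
#'
#' Pearson correlation and two-sided t-test p-value for every (PC,
#' variable) pair, with Bonferroni significance across the whole matrix.
#'
#' @param scores Samples x PCs score matrix.
#' @param env Data frame of per-sample variables (rows aligned to
#'   `scores`; ordinal covariates such as island age are accepted as
#'   numeric codes).
#' @param alpha Significance level before Bonferroni division.
#' @return A list of matrices: `r`, `p`, `significant`; constant variables
#'   give NA and a warning.
#' @export
pc_environment_correlation <- function(scores, env, alpha = 0.05) {
  scores <- as.matrix(scores)
  env <- as.data.frame(env)
  stopifnot(nrow(scores) == nrow(env))
  if (nrow(scores) < 3) stop2("need at least 3 paired observations")
  npc <- ncol(scores); nv <- ncol(env)
  r <- p <- matrix(NA_real_, npc, nv,
                   dimnames = list(colnames(scores), names(env)))
  for (j in seq_len(nv)) {
    x <- as.numeric(env[[j]])
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      warning(sprintf("variable %s is constant; correlation undefined",
                      names(env)[j]))
      next
    }
    for (i in seq_len(npc)) {
      ok <- !is.na(x)
      ct <- stats::cor.test(scores[ok, i], x[ok])
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  n_tests <- sum(!is.na(p))
  list(r = r, p = p,
       significant = !is.na(p) & p < alpha / max(n_tests, 1))
}
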