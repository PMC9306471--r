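#' Polarize heterozygous calls using genotype likelihood ratios
#'
#' Selfing species are expected to be homozygous nearly everywhere, so
#' heterozygous calls are usually artifacts.  Each heterozygous call whose
#' log10 likelihood ratio between homozygous-reference and
#' homozygous-alternative exceeds `llr_threshold` in magnitude is converted
#' to the more likely homozygote; calls inside the threshold band stay
#' heterozygous.  With phred-scaled PLs the ratio is
#' `(PL_homalt - PL_homref) / 10`.
#'
#' @param gm A `genotype_matrix` with PL fields.
#' @param llr_threshold Magnitude of the log10 likelihood ratio beyond
#'   which a heterozygote is polarized (default 2).
#' @return The polarized `genotype_matrix`; conversion counts are in
#'   attribute `polarize_log`.
#' @export
polarize_heterozygotes <- function(gm, llr_threshold = 2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  het <- which(!is.na(gm$dosage) & gm$dosage == 1L)
  log <- c(to_ref = 0L, to_alt = 0L, kept = 0L, no_pl = 0L)
  if (length(het)) {
    if (is.null(gm$pl)) {
      warning("no PL fields present; heterozygous calls left unchanged")
      log["no_pl"] <- length(het)
    } else {
      pl_ref <- gm$pl[, , 1][het]
      pl_alt <- gm$pl[, , 3][het]
      llr <- (pl_alt - pl_ref) / 10  # log10 L(hom-ref) - log10 L(hom-alt)
      missing_pl <- is.na(llr)
      if (any(missing_pl)) {
        warning(sprintf("%d heterozygous calls lack PL; left unchanged",
                        sum(missing_pl)))
        log["no_pl"] <- sum(missing_pl)
      }
      to_ref <- !missing_pl & llr > llr_threshold
      to_alt <- !missing_pl & llr < -llr_threshold
      gm$dosage[het[to_ref]] <- 0L
      gm$dosage[het[to_alt]] <- 2L
      log["to_ref"] <- sum(to_ref)
      log["to_alt"] <- sum(to_alt)
      log["kept"] <- sum(!missing_pl & !to_ref & !to_alt)
    }
  }
  attr(gm, "polarize_log") <- log
  gm
}

#' Apply site and genotype quality filters
#'
#' Genotype calls with read depth at or below `dp_min` are set missing;
#' sites failing QUAL/QD/FS/SOR thresholds, multiallelic sites, and sites
#' with excessive missingness or heterozygosity are removed.  All
#' thresholds are boundary-exclusive exactly as stated (e.g. `DP > 5`
#' keeps DP = 6).  An absent annotation skips that rule with a warning
#' rather than silently passing.
#'
#' @param gm A `genotype_matrix`.
#' @param dp_min Keep calls with DP strictly greater than this.
#' @param qual_min Keep sites with QUAL strictly greater than this.
#' @param qd_min Keep sites with QD strictly greater than this.
#' @param fs_max Keep sites with FS strictly less than this.
#' @param sor_max Keep sites with SOR strictly less than this.
#' @param max_missing Remove sites missing in more than this fraction of
#'   samples.
#' @param max_het Remove sites heterozygous in more than this fraction of
#'   samples.
#' @return The filtered `genotype_matrix`; per-rule removal counts are in
#'   attribute `filter_log`.
#' @export
filter_sites <- function(gm, dp_min = 5, qual_min = 30, qd_min = 20,
                         fs_max = 100, sor_max = 5, max_missing = 0.95,
                         max_het = 0.10) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$sites)
  ns <- length(gm$samples)
  masked <- 0L
  if (!is.null(gm$dp)) {
    low <- !is.na(gm$dp) & gm$dp <= dp_min
    masked <- sum(low & !is.na(gm$dosage))
    gm$dosage[low] <- NA_integer_
  } else {
    warning("no DP field present; depth masking skipped")
  }

  rule <- function(values, test, name) {
    if (all(is.na(values))) {
      warning(sprintf("annotation %s absent; rule skipped", name))
      return(rep(TRUE, n))
    }
    keep <- test(values)
    keep[is.na(keep)] <- TRUE
    keep
  }
  keep_qual <- rule(gm$sites$qual, function(x) x > qual_min, "QUAL")
  keep_qd <- rule(gm$sites$qd, function(x) x > qd_min, "QD")
  keep_fs <- rule(gm$sites$fs, function(x) x < fs_max, "FS")
  keep_sor <- rule(gm$sites$sor, function(x) x < sor_max, "SOR")
  keep_bi <- !gm$sites$multiallelic

  miss_frac <- rowMeans(is.na(gm$dosage))
  het_frac <- rowMeans(gm$dosage == 1L, na.rm = TRUE)
  het_frac[is.nan(het_frac)] <- 0
  # heterozygosity fraction uses all samples as denominator
  het_frac <- rowSums(!is.na(gm$dosage) & gm$dosage == 1L) / ns
  keep_miss <- miss_frac <= max_missing
  keep_het <- het_frac <= max_het

  keep <- keep_qual & keep_qd & keep_fs & keep_sor & keep_bi & keep_miss & keep_het
  log <- c(calls_depth_masked = masked,
           qual = sum(!keep_qual), qd = sum(!keep_qd), fs = sum(!keep_fs),
           sor = sum(!keep_sor), multiallelic = sum(!keep_bi),
           missingness = sum(!keep_miss), heterozygosity = sum(!keep_het),
           removed = sum(!keep), retained = sum(keep))
  out <- subset_sites(gm, keep)
  attr(out, "filter_log") <- log
  out
}

#' Pairwise genotype concordance between two strains
#'
#' The fraction of sites, among those genotyped in both strains, at which
#' the two carry an identical dosage.
#'
#' @param gm A `genotype_matrix`.
#' @param pair Length-2 vector of sample names or indices.
#' @return Concordance fraction in \[0, 1\].
#' @export
pairwise_concordance <- function(gm, pair) {
  stopifnot(inherits(gm, "genotype_matrix"), length(pair) == 2L)
  a <- gm$dosage[, pair[1]]
  b <- gm$dosage[, pair[2]]
  both <- !is.na(a) & !is.na(b)
  if (!any(both)) stop2("no jointly genotyped sites for this pair")
  mean(a[both] == b[both])
}

#' All-pairs concordance matrix
#'
#' @param gm A `genotype_matrix`.
#' @return A samples x samples matrix of concordances (NA when a pair has
#'   no jointly genotyped site).
#' @export
concordance_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  nonmiss <- !is.na(d)
  joint <- crossprod(nonmiss)
  matches <- matrix(0, ncol(d), ncol(d))
  for (g in 0:2) {
    m <- nonmiss & d == g
    m[is.na(d)] <- FALSE
    matches <- matches + crossprod(m)
  }
  conc <- matches / joint
  conc[joint == 0] <- NA_real_
  dimnames(conc) <- list(gm$samples, gm$samples)
  conc
}

#' Group strains into isotypes by genome-wide concordance
#'
#' Strains are grouped as connected components of the graph whose edges
#' join pairs with concordance above `threshold` (transitive closure, so a
#' chain A-B-C forms one isotype even if A and C fall below the cut).  Each
#' isotype is named after its lexicographically smallest member.
#'
#' @param gm A `genotype_matrix`.
#' @param threshold Concordance above which two strains share an isotype
#'   (default 0.9997, i.e. >99.97% shared SNVs).
#' @return A data frame `strain`, `isotype` with the concordance matrix in
#'   attribute `concordance`.
#' @export
cluster_isotypes <- function(gm, threshold = 0.9997) {
  conc <- concordance_matrix(gm)
  n <- ncol(conc)
  adj <- which(upper.tri(conc) & !is.na(conc) & conc > threshold, arr.ind = TRUE)
  comp <- union_find_components(n, adj)
  labels <- vapply(seq_len(n), function(i) {
    members <- gm$samples[comp == comp[i]]
    min(members)
  }, character(1))
  out <- data.frame(strain = gm$samples, isotype = labels,
                    stringsAsFactors = FALSE)
  attr(out, "concordance") <- conc
  out
}

# per-site pairwise-difference terms: n_alt * n_ref / choose(n_chr, 2)
site_pi_terms <- function(gm) {
  nonmiss <- rowSums(!is.na(gm$dosage))
  na <- rowSums(gm$dosage, na.rm = TRUE)
  n_chr <- 2 * nonmiss
  nr <- n_chr - na
  term <- ifelse(n_chr >= 2, na * nr / (n_chr * (n_chr - 1) / 2), 0)
  list(term = term, n_chr = n_chr)
}

window_starts <- function(len, window, step) seq(1, len, by = step)

#' Windowed nucleotide diversity
#'
#' Per-site nucleotide diversity in sliding windows:
#' `pi = sum_sites n_alt n_ref / C(n_chr, 2) / window_length`, where
#' `n_chr` counts non-missing haplotypes at the site (two per diploid
#' sample).  Windows tile each chromosome from position 1; terminal partial
#' windows use their true length as denominator.
#'
#' @param gm A filtered biallelic `genotype_matrix`.
#' @param window Window size in base pairs.
#' @param step Step size in base pairs.
#' @return Data frame `chrom`, `start`, `end` (1-based inclusive), `S`
#'   (segregating sites), `pi`.
#' @export
windowed_pi <- function(gm, window = 10000, step = 1000) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (window <= 0 || step <= 0 || window < step)
    stop2("invalid config: need window >= step > 0")
  terms <- site_pi_terms(gm)
  seg <- terms$term > 0
  out <- list()
  for (i in seq_len(nrow(gm$contigs))) {
    ch <- gm$contigs$chrom[i]
    len <- gm$contigs$length[i]
    idx <- which(gm$sites$chrom == ch)
    pos <- gm$sites$pos[idx]
    cs <- c(0, cumsum(terms$term[idx]))
    csS <- c(0, cumsum(as.numeric(seg[idx])))
    starts <- window_starts(len, window, step)
    ends <- pmin(starts + window - 1, len)
    lo <- findInterval(starts - 1, pos)   # sites with pos <= start-1
    hi <- findInterval(ends, pos)         # sites with pos <= end
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = as.integer(starts), end = as.integer(ends),
      S = as.integer(csS[hi + 1] - csS[lo + 1]),
      pi = (cs[hi + 1] - cs[lo + 1]) / (ends - starts + 1),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Non-overlapping windows; within each,
#' `D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the classical
#' constants computed from `n = 2 x samples` haplotypes.  `pi_total` is the
#' window sum of per-site pairwise-difference terms (not divided by window
#' length).  Windows without segregating sites are flagged undefined.
#'
#' @param gm A filtered biallelic `genotype_matrix`.
#' @param window Window size in base pairs.
#' @return Data frame `chrom`, `start`, `end`, `n` (haplotypes), `S`,
#'   `pi_total`, `D` (NA when undefined), `defined`.
#' @export
tajimas_d <- function(gm, window = 10000) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (window <= 0) stop2("invalid config: window must be positive")
  n_hap <- 2L * length(gm$samples)
  if (n_hap < 4L) stop2("Tajima's D undefined for fewer than 4 haplotypes")
  k <- tajima_constants(n_hap)
  terms <- site_pi_terms(gm)
  seg <- terms$term > 0
  out <- list()
  for (i in seq_len(nrow(gm$contigs))) {
    ch <- gm$contigs$chrom[i]
    len <- gm$contigs$length[i]
    idx <- which(gm$sites$chrom == ch)
    pos <- gm$sites$pos[idx]
    cs <- c(0, cumsum(terms$term[idx]))
    csS <- c(0, cumsum(as.numeric(seg[idx])))
    starts <- seq(1, len, by = window)
    ends <- pmin(starts + window - 1, len)
    lo <- findInterval(starts - 1, pos)
    hi <- findInterval(ends, pos)
    S <- as.integer(csS[hi + 1] - csS[lo + 1])
    pi_total <- cs[hi + 1] - cs[lo + 1]
    D <- rep(NA_real_, length(S))
    ok <- S > 0
    D[ok] <- (pi_total[ok] - S[ok] / k$a1) /
      sqrt(k$e1 * S[ok] + k$e2 * S[ok] * (S[ok] - 1))
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = as.integer(starts), end = as.integer(ends),
      n = n_hap, S = S, pi_total = pi_total, D = D, defined = ok,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
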