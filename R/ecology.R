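#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6,371,000 m, vectorized over
#' coordinate pairs.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in meters.
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop2("latitude outside [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 360, na.rm = TRUE))
    stop2("longitude out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

#' Cluster sampling sites into discrete locations
#'
#' Average-linkage hierarchical clustering of the haversine distance
#' matrix, cut at `cut` meters, groups samples collected within a few km
#' into discrete sampling locations.  Labels are canonical: clusters are
#' numbered by their lexicographically smallest member id, so the result
#' is invariant to input order.
#'
#' @param coords Data frame with columns `sample`, `lat`, `lon`.
#' @param cut Cut height in meters (default 3000).
#' @return Named character vector mapping sample -> cluster label
#'   (`"SC01"`, ...); samples with missing coordinates get NA and are
#'   reported in attribute `unclustered`.
#' @export
cluster_sampling_sites <- function(coords, cut = 3000) {
  stopifnot(all(c("sample", "lat", "lon") %in% names(coords)))
  ok <- !is.na(coords$lat) & !is.na(coords$lon)
  dropped <- coords$sample[!ok]
  if (length(dropped))
    message(sprintf("%d samples lack GPS positions and were not clustered",
                    length(dropped)))
  labels <- stats::setNames(rep(NA_character_, nrow(coords)), coords$sample)
  cc <- coords[ok, , drop = FALSE]
  if (nrow(cc) == 1L) {
    labels[cc$sample] <- "SC01"
  } else if (nrow(cc) > 1L) {
    d <- geosphere::distm(cbind(cc$lon, cc$lat),
                          fun = function(a, b) geosphere::distHaversine(a, b, r = 6371000))
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    raw <- stats::cutree(hc, h = cut)
    # canonicalize: order clusters by their smallest member id
    mins <- vapply(split(cc$sample, raw), min, character(1))
    new_id <- match(names(mins), names(sort(mins)))
    labels[cc$sample] <- sprintf("SC%02d", new_id[match(raw, as.integer(names(mins)))])
  }
  attr(labels, "unclustered") <- dropped
  labels
}

#' Two-sided Fisher enrichment test on a 2x2 table
#'
#' Tests whether positives are enriched in one category versus another.
#' The p-value is the exact two-sided hypergeometric probability (summing
#' all tables at most as probable as the observed one); the odds ratio is
#' the sample OR `ad/bc`, with a Haldane 0.5 correction when a zero cell
#' occurs.
#'
#' @param counts 2x2 matrix: rows are categories, columns are
#'   positive/negative counts.
#' @return A list of class `enrichment_result`: `counts`, `proportions`,
#'   `odds_ratio`, `p_value`.
#' @export
enrichment_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)))
  if (any(counts < 0) || any(counts != floor(counts)))
    stop2("counts must be non-negative integers")
  if (any(rowSums(counts) == 0)) stop2("undefined: a category has zero total")
  p <- stats::fisher.test(counts, alternative = "two.sided")$p.value
  a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
  if (any(counts == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  structure(list(counts = counts,
                 proportions = counts[, 1] / rowSums(counts),
                 odds_ratio = (a * d) / (b * c),
                 p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Fisher exact test: OR = %.3f, p = %.4g\n", x$odds_ratio,
              x$p_value))
  cat(sprintf("  proportions: %.1f%% vs %.1f%%\n", 100 * x$proportions[1],
              100 * x$proportions[2]))
  invisible(x)
}

# tie-corrected Dunn z statistics on pooled ranks
dunn_posthoc <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  grp <- split(r, groups)
  rbar <- vapply(grp, mean, numeric(1))
  ns <- lengths(grp)
  gnames <- names(grp)
  pairs <- utils::combn(length(grp), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sigma <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[i] + 1 / ns[j]))
    z[k] <- (rbar[i] - rbar[j]) / sigma
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = gnames[pairs[1, ]], group2 = gnames[pairs[2, ]],
             z = z, p = p, p_adjusted = pmin(p * ncol(pairs), 1),
             stringsAsFactors = FALSE)
}

# compact letter display by insert-absorb: groups sharing a letter are not
# significantly different at the chosen level
assign_letters <- function(gnames, diff_pairs) {
  sets <- list(gnames)
  if (nrow(diff_pairs)) {
    for (k in seq_len(nrow(diff_pairs))) {
      a <- diff_pairs$group1[k]; b <- diff_pairs$group2[k]
      new_sets <- list()
      for (s in sets) {
        if (all(c(a, b) %in% s)) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else new_sets <- c(new_sets, list(s))
      }
      # absorb sets contained in others
      keep <- rep(TRUE, length(new_sets))
      for (i in seq_along(new_sets)) {
        for (j in seq_along(new_sets)) {
          if (i != j && keep[j] && all(new_sets[[i]] %in% new_sets[[j]]) &&
              (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j))
            keep[i] <- FALSE
        }
      }
      sets <- unique(new_sets[keep])
      sets <- sets[lengths(sets) > 0]
    }
  }
  letters_out <- stats::setNames(rep("", length(gnames)), gnames)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) letters_out[g] <- paste0(letters_out[g], letters[i])
  }
  letters_out
}

#' Compare environmental niches among species
#'
#' Kruskal-Wallis test with tie correction followed by Dunn's pairwise
#' post-hoc z tests with Bonferroni adjustment, summarized as a compact
#' letter display: groups sharing a letter are not significantly different
#' at `alpha`.
#'
#' @param values Numeric vector of environmental measurements.
#' @param groups Group (species) labels, same length as `values`.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A list: `kruskal` (htest), `dunn` (pairwise table), `letters`
#'   (named vector), `excluded` (groups with < 2 observations).
#' @export
niche_compare <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  sizes <- table(groups)
  excluded <- names(sizes)[sizes < 2]
  if (length(excluded)) {
    message(sprintf("groups excluded (fewer than 2 observations): %s",
                    paste(excluded, collapse = ", ")))
    keep <- !(groups %in% excluded)
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop2("need at least 2 groups with >= 2 observations")
  kw <- stats::kruskal.test(values, factor(groups))
  dunn <- dunn_posthoc(values, groups)
  diff_pairs <- dunn[dunn$p_adjusted < alpha, , drop = FALSE]
  lett <- assign_letters(sort(unique(groups)), diff_pairs)
  list(kruskal = kw, dunn = dunn, letters = lett, excluded = excluded)
}

#' Prune mutually correlated environmental variables
#'
#' Iteratively removes, from the pair with the highest absolute Pearson
#' correlation above `r_max`, the variable with more missing values
#' (ties: the later column), until no pair exceeds the threshold.
#' Correlations use pairwise-complete observations.
#'
#' @param env Data frame or matrix of environmental variables.
#' @param r_max Correlation magnitude above which one of a pair is removed.
#' @return A list: `retained`, `removed` (with the partner that triggered
#'   removal), `correlation` (full initial matrix).
#' @export
env_correlation_prune <- function(env, r_max = 0.7) {
  env <- as.data.frame(env)
  if (ncol(env) < 2) stop2("need at least 2 variables")
  all_missing <- names(env)[vapply(env, function(x) all(is.na(x)), logical(1))]
  if (length(all_missing)) {
    message(sprintf("all-missing variables removed first: %s",
                    paste(all_missing, collapse = ", ")))
    env <- env[setdiff(names(env), all_missing)]
  }
  full_cor <- suppressWarnings(stats::cor(env, use = "pairwise.complete.obs"))
  removed <- data.frame(variable = all_missing,
                        partner = rep(NA_character_, length(all_missing)),
                        r = rep(NA_real_, length(all_missing)),
                        stringsAsFactors = FALSE)
  vars <- names(env)
  n_missing <- vapply(env, function(x) sum(is.na(x)), integer(1))
  repeat {
    if (length(vars) < 2) break
    cm <- abs(full_cor[vars, vars, drop = FALSE])
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    mx <- max(cm)
    if (mx <= r_max) break
    hit <- which(cm == mx, arr.ind = TRUE)[1, ]
    a <- vars[hit[1]]; b <- vars[hit[2]]
    drop_var <- if (n_missing[a] > n_missing[b]) a
      else if (n_missing[b] > n_missing[a]) b
      else vars[max(hit)]  # tie: later column
    partner <- setdiff(c(a, b), drop_var)
    removed <- rbind(removed, data.frame(variable = drop_var, partner = partner,
                                         r = full_cor[drop_var, partner],
                                         stringsAsFactors = FALSE))
    vars <- setdiff(vars, drop_var)
  }
  list(retained = vars, removed = removed, correlation = full_cor)
}

#' Cohabitation frequency of two species
#'
#' Fraction of collections positive for the first-named species that are
#' also positive for the second.  The species column may be a
#' list-column of species vectors or a delimiter-separated string.
#'
#' @param collections Data frame with columns `sample` and `species`.
#' @param species_a First-named species (denominator).
#' @param species_b Second species.
#' @param sep Separator when `species` is a string column.
#' @return A list: `fraction`, `n_both`, `n_denominator`.
#' @export
cohabitation_frequency <- function(collections, species_a, species_b,
                                   sep = ";") {
  sp <- collections$species
  if (!is.list(sp)) sp <- strsplit(as.character(sp), sep, fixed = TRUE)
  has_a <- vapply(sp, function(s) species_a %in% s, logical(1))
  has_b <- vapply(sp, function(s) species_b %in% s, logical(1))
  denom <- sum(has_a)
  if (denom == 0) stop2("undefined: no collection is positive for %s", species_a)
  both <- sum(has_a & has_b)
  list(fraction = both / denom, n_both = both, n_denominator = denom)
}
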