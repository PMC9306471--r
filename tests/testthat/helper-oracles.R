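# Shared fixtures and independent brute-force oracles.  Every oracle here
# is written from the definition, not by calling the package code path it
# checks.

make_gm <- function(dosage, chrom = NULL, pos = NULL, contig_len = NULL,
                    qual = 100, qd = 30, fs = 1, sor = 1) {
  n <- nrow(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("S%03d", seq_len(ncol(dosage)))
  chrom <- chrom %||% rep("I", n)
  pos <- pos %||% seq_len(n)
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = "A", alt = "T",
                      qual = rep_len(qual, n), qd = rep_len(qd, n),
                      fs = rep_len(fs, n), sor = rep_len(sor, n),
                      multiallelic = FALSE, stringsAsFactors = FALSE)
  contigs <- NULL
  if (!is.null(contig_len)) {
    contigs <- data.frame(chrom = unique(chrom), length = contig_len,
                          stringsAsFactors = FALSE)
  }
  genotype_matrix(sites = sites, dosage = dosage, contigs = contigs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# memoized small default-condition simulation shared across test files
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, config, tree = NULL) {
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_metapopulation(config, tree = tree)
  .sim_cache[[key]]
}

# shared branch length between two tips by explicit root-path enumeration
oracle_shared_branch <- function(tree, tip_a, tip_b) {
  root <- ape::Ntip(tree) + 1L
  path_edges <- function(tip) {
    node <- which(tree$tip.label == tip)
    edges <- integer(0)
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  }
  shared <- intersect(path_edges(tip_a), path_edges(tip_b))
  sum(tree$edge.length[shared])
}

# average pairwise difference per site over all haplotype pairs (diploid
# convention: each sample contributes two haplotypes, missing calls drop
# both)
oracle_pi_window <- function(dosage, window_len) {
  total <- 0
  for (i in seq_len(nrow(dosage))) {
    g <- dosage[i, ]
    g <- g[!is.na(g)]
    haps <- unlist(lapply(g, function(x) switch(as.character(x),
                                                "0" = c(0, 0),
                                                "1" = c(0, 1),
                                                "2" = c(1, 1))))
    n <- length(haps)
    if (n < 2) next
    diffs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      diffs <- diffs + (haps[a] != haps[b])
    total <- total + diffs / choose(n, 2)
  }
  unname(total / window_len)
}

# Tajima's D from the original constant definitions, coded independently
oracle_tajimas_d <- function(pi_total, S, n) {
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# heterozygote polarization by per-call loop
oracle_polarize <- function(dosage, pl, threshold) {
  out <- dosage
  for (i in seq_len(nrow(dosage))) {
    for (j in seq_len(ncol(dosage))) {
      if (!is.na(dosage[i, j]) && dosage[i, j] == 1L) {
        llr <- (pl[i, j, 3] - pl[i, j, 1]) / 10
        if (!is.na(llr)) {
          if (llr > threshold) out[i, j] <- 0L
          if (llr < -threshold) out[i, j] <- 2L
        }
      }
    }
  }
  out
}

# region building from the rules, written as a direct index walk
oracle_build_regions <- function(sig_pos, sig_stat, tested_pos, gap, flank) {
  o <- order(sig_pos)
  sig_pos <- sig_pos[o]; sig_stat <- sig_stat[o]
  tested_pos <- sort(tested_pos)
  clusters <- list()
  cur <- 1
  for (i in seq_along(sig_pos)[-1]) {
    if (sig_pos[i] - sig_pos[i - 1] > gap) {
      clusters[[length(clusters) + 1]] <- cur:(i - 1)
      cur <- i
    }
  }
  clusters[[length(clusters) + 1]] <- cur:length(sig_pos)
  spans <- lapply(clusters, function(ix) {
    li <- which(tested_pos == sig_pos[ix[1]])
    ri <- which(tested_pos == sig_pos[ix[length(ix)]])
    c(tested_pos[max(1, li - flank)], tested_pos[min(length(tested_pos), ri + flank)],
      sig_pos[ix[which.max(sig_stat[ix])]])
  })
  # merge overlaps
  merged <- list()
  for (s in spans) {
    placed <- FALSE
    for (k in seq_along(merged)) {
      if (s[1] <= merged[[k]][2] && s[2] >= merged[[k]][1]) {
        merged[[k]][1] <- min(merged[[k]][1], s[1])
        merged[[k]][2] <- max(merged[[k]][2], s[2])
        placed <- TRUE
        break
      }
    }
    if (!placed) merged[[length(merged) + 1]] <- s
  }
  # repeated merging until stable
  repeat {
    changed <- FALSE
    if (length(merged) > 1) {
      for (a in seq_len(length(merged) - 1)) {
        for (b in (a + 1):length(merged)) {
          if (merged[[a]][1] <= merged[[b]][2] && merged[[a]][2] >= merged[[b]][1]) {
            merged[[a]][1] <- min(merged[[a]][1], merged[[b]][1])
            merged[[a]][2] <- max(merged[[a]][2], merged[[b]][2])
            merged[[b]] <- NULL
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
    }
    if (!changed) break
  }
  do.call(rbind, lapply(merged, function(s)
    data.frame(start = s[1], end = s[2])))[order(sapply(merged, `[`, 1)), ,
                                           drop = FALSE]
}

# all-pairs interval overlap scan (1-based inclusive)
oracle_overlaps <- function(a, b) {
  hits <- data.frame(a = integer(0), b = integer(0))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$start[i] <= b$end[j] &&
          a$end[i] >= b$start[j])
        hits <- rbind(hits, data.frame(a = i, b = j))
    }
  }
  hits
}

# iterative correlation pruning, independent structure (scan full matrix
# copies)
oracle_env_prune <- function(df, r_max) {
  vars <- names(df)
  repeat {
    if (length(vars) < 2) break
    cm <- abs(suppressWarnings(stats::cor(df[vars],
                                          use = "pairwise.complete.obs")))
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    if (max(cm) <= r_max) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- vars[idx[1]]; b <- vars[idx[2]]
    na_a <- sum(is.na(df[[a]])); na_b <- sum(is.na(df[[b]]))
    drop <- if (na_a > na_b) a else if (na_b > na_a) b else vars[max(idx)]
    vars <- setdiff(vars, drop)
  }
  vars
}
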