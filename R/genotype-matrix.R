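#' Construct a genotype matrix container
#'
#' The central container for biallelic SNV genotypes: a per-site table
#' (chromosome, 1-based position, alleles, QUAL/QD/FS/SOR annotations), a
#' sites x samples dosage matrix (0/1/2, NA for missing), and optional PL
#' likelihood triples and read depths.
#'
#' @param sites Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `qd`, `fs`, `sor`, `multiallelic`.
#' @param dosage Integer matrix (sites x samples) with column names.
#' @param pl Optional integer array sites x samples x 3 of phred-scaled
#'   genotype likelihoods (hom-ref, het, hom-alt).
#' @param dp Optional integer matrix of per-call read depths.
#' @param contigs Data frame `chrom`, `length`; inferred from the data when
#'   absent.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, dosage, pl = NULL, dp = NULL,
                            contigs = NULL) {
  stopifnot(is.data.frame(sites), is.matrix(dosage),
            nrow(sites) == nrow(dosage))
  if (is.null(colnames(dosage))) stop2("dosage must carry sample names")
  if (nrow(sites) > 1) {
    split_pos <- split(sites$pos, sites$chrom)
    if (any(vapply(split_pos, is.unsorted, logical(1), strictly = TRUE)))
      stop2("positions must be strictly increasing within chromosome")
  }
  bad <- stats::na.omit(unique(as.vector(dosage)))
  if (length(setdiff(bad, 0:2)))
    stop2("dosages must be 0, 1, 2 or NA")
  if (is.null(contigs)) {
    contigs <- do.call(rbind, lapply(split(sites$pos, sites$chrom), max))
    contigs <- data.frame(chrom = rownames(contigs), length = contigs[, 1],
                          stringsAsFactors = FALSE)
    rownames(contigs) <- NULL
  }
  structure(list(sites = sites, dosage = dosage, pl = pl, dp = dp,
                 contigs = contigs, samples = colnames(dosage)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%d contigs)\n",
              nrow(x$sites), length(x$samples), nrow(x$contigs)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by sites or samples
#'
#' @param gm A `genotype_matrix`.
#' @param keep Indices (or logical mask; sample names for
#'   `subset_samples`) to retain.
#' @return A `genotype_matrix`.
#' @export
subset_sites <- function(gm, keep) {
  genotype_matrix(sites = gm$sites[keep, , drop = FALSE],
                  dosage = gm$dosage[keep, , drop = FALSE],
                  pl = if (!is.null(gm$pl)) gm$pl[keep, , , drop = FALSE],
                  dp = if (!is.null(gm$dp)) gm$dp[keep, , drop = FALSE],
                  contigs = gm$contigs)
}

#' @rdname subset_sites
#' @export
subset_samples <- function(gm, keep) {
  if (is.character(keep)) keep <- match(keep, gm$samples)
  genotype_matrix(sites = gm$sites,
                  dosage = gm$dosage[, keep, drop = FALSE],
                  pl = if (!is.null(gm$pl)) gm$pl[, keep, , drop = FALSE],
                  dp = if (!is.null(gm$dp)) gm$dp[, keep, drop = FALSE],
                  contigs = gm$contigs)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits GT:PL:DP genotype fields (PL/DP when present) and QD/FS/SOR INFO
#' annotations with deterministic formatting, so a fixed simulator seed
#' yields a byte-identical file.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(x) writeLines(x, con, sep = "\n", useBytes = TRUE)
  wl("##fileformat=VCFv4.2")
  wl("##source=islegea")
  for (i in seq_len(nrow(gm$contigs)))
    wl(sprintf("##contig=<ID=%s,length=%d>", gm$contigs$chrom[i],
               as.integer(gm$contigs$length[i])))
  wl('##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">')
  wl('##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">')
  wl('##INFO=<ID=SOR,Number=1,Type=Float,Description="Symmetric odds ratio strand bias">')
  wl('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  wl('##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">')
  wl('##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  wl(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT", gm$samples), collapse = "\t"))

  gt_str <- matrix("./.", nrow(gm$dosage), ncol(gm$dosage))
  gt_str[!is.na(gm$dosage) & gm$dosage == 0L] <- "0/0"
  gt_str[!is.na(gm$dosage) & gm$dosage == 1L] <- "0/1"
  gt_str[!is.na(gm$dosage) & gm$dosage == 2L] <- "1/1"
  has_pl <- !is.null(gm$pl)
  fmt <- if (has_pl) "GT:PL:DP" else "GT"
  if (has_pl) {
    pltxt <- matrix(sprintf("%d,%d,%d", gm$pl[, , 1], gm$pl[, , 2], gm$pl[, , 3]),
                    nrow(gm$dosage), ncol(gm$dosage))
    gt_str <- matrix(paste(gt_str, pltxt, as.integer(gm$dp), sep = ":"),
                     nrow(gm$dosage), ncol(gm$dosage))
  }
  info <- sprintf("QD=%.2f;FS=%.3f;SOR=%.3f", gm$sites$qd, gm$sites$fs,
                  gm$sites$sor)
  info[is.na(gm$sites$qd)] <- "."
  fixed <- paste(gm$sites$chrom, as.integer(gm$sites$pos), ".", gm$sites$ref,
                 gm$sites$alt, sprintf("%.2f", gm$sites$qual), "PASS", info,
                 fmt, sep = "\t")
  body <- paste(fixed, apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  wl(body)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses GT (and PL/DP when present) genotype fields plus QUAL and the
#' QD/FS/SOR INFO annotations.  Multiallelic sites are kept but flagged so
#' the biallelic filter can drop them.
#'
#' @param path Path to a VCF 4.x file.
#' @return A `genotype_matrix`.
#' @export
load_vcf <- function(path) {
  if (!file.exists(path)) stop2("VCF not found: %s", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop2("VCF parse error in %s: %s",
                                          path, conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  n <- nrow(fix)

  extract_info <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]+"), fix$INFO))
    out <- rep(NA_real_, n)
    hit <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    out[hit] <- as.numeric(sub(paste0("^;?", key, "="), "", m))
    out
  }

  if (n > 0) {
    gt <- vcfR::extract.gt(v, element = "GT")
    dosage <- matrix(NA_integer_, n, length(samples),
                     dimnames = list(NULL, samples))
    dosage[gt %in% c("0/0", "0|0")] <- 0L
    dosage[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    dosage[gt %in% c("1/1", "1|1")] <- 2L
    pl <- dp <- NULL
    if (any(grepl("PL", v@gt[, 1]))) {
      plc <- vcfR::extract.gt(v, element = "PL")
      spl <- strsplit(as.vector(plc), ",", fixed = TRUE)
      ok <- lengths(spl) == 3L
      plm <- matrix(NA_integer_, length(spl), 3)
      plm[ok, ] <- matrix(as.integer(unlist(spl[ok])), ncol = 3, byrow = TRUE)
      pl <- array(NA_integer_, c(n, length(samples), 3))
      for (k in 1:3) pl[, , k] <- matrix(plm[, k], n, length(samples))
    }
    if (any(grepl("DP", v@gt[, 1]))) {
      dp <- matrix(as.integer(vcfR::extract.gt(v, element = "DP")), n,
                   length(samples), dimnames = list(NULL, samples))
    }
  } else {
    dosage <- matrix(integer(0), 0, length(samples),
                     dimnames = list(NULL, samples))
    pl <- dp <- NULL
  }

  meta <- v@meta
  contig_lines <- grep("^##contig=", meta, value = TRUE)
  contigs <- NULL
  if (length(contig_lines)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", contig_lines)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1",
                                            contig_lines)))
    contigs <- data.frame(chrom = ids, length = lens, stringsAsFactors = FALSE)
  }

  sites <- data.frame(
    chrom = if (n) fix$CHROM else character(0),
    pos = if (n) as.integer(fix$POS) else integer(0),
    ref = if (n) fix$REF else character(0),
    alt = if (n) fix$ALT else character(0),
    qual = if (n) suppressWarnings(as.numeric(fix$QUAL)) else numeric(0),
    qd = if (n) extract_info("QD") else numeric(0),
    fs = if (n) extract_info("FS") else numeric(0),
    sor = if (n) extract_info("SOR") else numeric(0),
    multiallelic = if (n) grepl(",", fix$ALT, fixed = TRUE) else logical(0),
    stringsAsFactors = FALSE
  )
  if (n && any(sites$multiallelic))
    dosage[sites$multiallelic & !is.na(dosage) & dosage > 2L] <- NA_integer_
  genotype_matrix(sites = sites, dosage = dosage, pl = pl, dp = dp,
                  contigs = contigs)
}
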