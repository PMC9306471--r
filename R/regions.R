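#' Region containers
#'
#' Regions are plain data frames with columns `chrom`, `start`, `end`
#' (1-based inclusive internally), `provenance`, `variable`, `peak_pos`,
#' `peak_stat`.  [write_regions_bed()] and [read_bed()] convert to and from
#' 0-based half-open BED coordinates losslessly.
#'
#' @param chrom,start,end,provenance,variable,peak_pos,peak_stat Column
#'   values, recycled as usual.
#' @return A region data frame.
#' @export
region_frame <- function(chrom = character(0), start = integer(0),
                         end = integer(0), provenance = character(0),
                         variable = character(0), peak_pos = integer(0),
                         peak_stat = numeric(0)) {
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), provenance = provenance,
                    variable = variable, peak_pos = as.integer(peak_pos),
                    peak_stat = peak_stat, stringsAsFactors = FALSE)
  if (nrow(out) && any(out$start > out$end)) stop2("region start > end")
  out
}

#' Build regions around significant markers
#'
#' Significant markers on a chromosome are chain-merged when consecutive
#' gaps are at most `gap` base pairs; each merged cluster is then expanded
#' to span from the `flank`-th tested marker left of its leftmost member
#' to the `flank`-th tested marker right of its rightmost member (clipped
#' at chromosome ends), and overlapping expanded regions are merged.  The
#' peak marker is the most significant member.
#'
#' @param significant Data frame `chrom`, `pos`, `stat` of significant
#'   markers (`stat`: larger = more significant; pass `-log10(p)` for
#'   p-values).
#' @param tested Data frame `chrom`, `pos` of all tested markers (a
#'   superset of `significant`).
#' @param gap Chaining distance in base pairs (inclusive; default 1000).
#' @param flank Number of tested markers to extend on each side
#'   (default 150).
#' @param provenance,variable Provenance labels stored on the output.
#' @return A region data frame (possibly empty).
#' @export
build_regions <- function(significant, tested, gap = 1000, flank = 150,
                          provenance = "gwa", variable = NA_character_) {
  if (is.null(significant) || nrow(significant) == 0) return(region_frame())
  stopifnot(all(c("chrom", "pos", "stat") %in% names(significant)),
            all(c("chrom", "pos") %in% names(tested)))
  out <- list()
  for (ch in unique(significant$chrom)) {
    sig <- significant[significant$chrom == ch, , drop = FALSE]
    sig <- sig[order(sig$pos), , drop = FALSE]
    tpos <- sort(tested$pos[tested$chrom == ch])
    if (!all(sig$pos %in% tpos))
      stop2("significant markers on %s are not a subset of tested markers", ch)
    # chain-merge: new cluster when the gap to the previous marker exceeds `gap`
    brk <- c(TRUE, diff(sig$pos) > gap)
    cluster <- cumsum(brk)
    for (cl in unique(cluster)) {
      members <- sig[cluster == cl, , drop = FALSE]
      li <- match(members$pos[1], tpos)
      ri <- match(members$pos[nrow(members)], tpos)
      start <- tpos[max(1L, li - flank)]
      end <- tpos[min(length(tpos), ri + flank)]
      peak <- members[which.max(members$stat), ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = as.integer(start), end = as.integer(end),
        provenance = provenance, variable = variable,
        peak_pos = as.integer(peak$pos), peak_stat = peak$stat,
        stringsAsFactors = FALSE)
    }
  }
  regions <- do.call(rbind, out)
  merge_overlapping_regions(regions)
}

# merge overlapping/touching (shared bp) regions within chrom, keeping the
# best peak
merge_overlapping_regions <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0) return(region_frame())
  pieces <- list()
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    r <- r[order(r$start, r$end), , drop = FALSE]
    cur <- r[1, , drop = FALSE]
    for (i in seq_len(nrow(r))[-1]) {
      if (r$start[i] <= cur$end) {
        cur$end <- max(cur$end, r$end[i])
        if (r$peak_stat[i] > cur$peak_stat) {
          cur$peak_stat <- r$peak_stat[i]
          cur$peak_pos <- r$peak_pos[i]
        }
      } else {
        pieces[[length(pieces) + 1L]] <- cur
        cur <- r[i, , drop = FALSE]
      }
    }
    pieces[[length(pieces) + 1L]] <- cur
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# all overlapping pairs (>= 1 shared bp) between two 1-based inclusive
# region frames on matching chromosomes
overlap_pairs <- function(a, b) {
  hits <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    ra <- IRanges::IRanges(a$start[ia], a$end[ia])
    rb <- IRanges::IRanges(b$start[ib], b$end[ib])
    ov <- IRanges::findOverlaps(ra, rb)
    if (length(ov))
      hits[[ch]] <- data.frame(a = ia[S4Vectors::queryHits(ov)],
                               b = ib[S4Vectors::subjectHits(ov)])
  }
  if (!length(hits)) return(data.frame(a = integer(0), b = integer(0)))
  do.call(rbind, hits)
}

#' Intersect two region tracks
#'
#' bedtools-intersect semantics: every pair of regions sharing at least
#' one base pair yields the overlap interval, with provenance
#' `method_overlap` and both parents' spans and peaks carried along.  The
#' two tracks must agree on the environment variable.
#'
#' @param a,b Region data frames (e.g. the per-variable GWA and BayPass
#'   tracks).
#' @return A region data frame with extra parent columns `a_start`,
#'   `a_end`, `a_peak_pos`, `a_peak_stat`, `b_start`, `b_end`,
#'   `b_peak_pos`, `b_peak_stat`.
#' @export
intersect_regions <- function(a, b) {
  va <- unique(stats::na.omit(a$variable))
  vb <- unique(stats::na.omit(b$variable))
  if (length(va) && length(vb) && !setequal(va, vb))
    stop2("environment variable mismatch between tracks: %s vs %s",
          paste(va, collapse = ","), paste(vb, collapse = ","))
  pr <- overlap_pairs(a, b)
  if (!nrow(pr)) {
    out <- region_frame()
    out$a_start <- out$a_end <- out$b_start <- out$b_end <- integer(0)
    out$a_peak_pos <- out$b_peak_pos <- integer(0)
    out$a_peak_stat <- out$b_peak_stat <- numeric(0)
    return(out)
  }
  out <- data.frame(
    chrom = a$chrom[pr$a],
    start = pmax(a$start[pr$a], b$start[pr$b]),
    end = pmin(a$end[pr$a], b$end[pr$b]),
    provenance = "method_overlap",
    variable = ifelse(is.na(a$variable[pr$a]), b$variable[pr$b],
                      a$variable[pr$a]),
    peak_pos = a$peak_pos[pr$a],
    peak_stat = a$peak_stat[pr$a],
    a_start = a$start[pr$a], a_end = a$end[pr$a],
    a_peak_pos = a$peak_pos[pr$a], a_peak_stat = a$peak_stat[pr$a],
    b_start = b$start[pr$b], b_end = b$end[pr$b],
    b_peak_pos = b$peak_pos[pr$b], b_peak_stat = b$peak_stat[pr$b],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Consensus GEA regions
#'
#' For each method-overlap pair, the smaller of the two parent regions is
#' compared with the XtX differentiation track; if it overlaps any XtX
#' region by at least one base pair, a consensus GEA region with the
#' smaller parent's span is emitted.  Equal-sized parents resolve to the
#' first track's parent.
#'
#' @param overlaps Output of [intersect_regions()] (with parent columns).
#' @param xtx_regions Region data frame built from XtX-flagged markers.
#' @return A region data frame with provenance `gea`.
#' @export
consensus_gea_regions <- function(overlaps, xtx_regions) {
  if (is.null(overlaps) || nrow(overlaps) == 0) return(region_frame())
  len_a <- overlaps$a_end - overlaps$a_start + 1L
  len_b <- overlaps$b_end - overlaps$b_start + 1L
  use_a <- len_a <= len_b
  small <- data.frame(
    chrom = overlaps$chrom,
    start = ifelse(use_a, overlaps$a_start, overlaps$b_start),
    end = ifelse(use_a, overlaps$a_end, overlaps$b_end),
    provenance = "gea",
    variable = overlaps$variable,
    peak_pos = ifelse(use_a, overlaps$a_peak_pos, overlaps$b_peak_pos),
    peak_stat = ifelse(use_a, overlaps$a_peak_stat, overlaps$b_peak_stat),
    stringsAsFactors = FALSE)
  if (nrow(xtx_regions) == 0) return(region_frame())
  pr <- overlap_pairs(small, xtx_regions)
  keep <- sort(unique(pr$a))
  out <- small[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse consensus regions across environment variables
#'
#' Regions that overlap across environment variables are collapsed into a
#' single distinct region (union span); the contributing variables are
#' listed in the `variable` column.
#'
#' @param gea Region data frame (provenance `gea`).
#' @return A region data frame of distinct regions.
#' @export
distinct_regions <- function(gea) {
  if (is.null(gea) || nrow(gea) == 0) return(region_frame())
  out <- list()
  for (ch in unique(gea$chrom)) {
    r <- gea[gea$chrom == ch, , drop = FALSE]
    n <- nrow(r)
    pr <- overlap_pairs(r, r)
    pr <- pr[pr$a < pr$b, , drop = FALSE]
    comp <- union_find_components(n, as.matrix(pr))
    for (cl in unique(comp)) {
      members <- r[comp == cl, , drop = FALSE]
      peak <- members[which.max(members$peak_stat), ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(members$start), end = max(members$end),
        provenance = "gea_distinct",
        variable = paste(sort(unique(members$variable)), collapse = ","),
        peak_pos = peak$peak_pos, peak_stat = peak$peak_stat,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, unique(gea$chrom)), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Overlap regions with hyper-divergent intervals
#'
#' Flags each region overlapping (>= 1 bp) any hyper-divergent interval
#' and reports the flagged fraction.
#'
#' @param regions Region data frame (1-based inclusive).
#' @param bed Data frame `chrom`, `start`, `end` in 0-based half-open BED
#'   coordinates.
#' @return The regions with a logical `hyperdivergent` column; the summary
#'   fraction is in attribute `fraction`.
#' @export
hyperdivergent_overlap <- function(regions, bed) {
  if (nrow(regions) == 0) {
    out <- regions
    out$hyperdivergent <- logical(0)
    attr(out, "fraction") <- NA_real_
    return(out)
  }
  flag <- rep(FALSE, nrow(regions))
  if (nrow(bed) > 0) {
    if (!any(unique(regions$chrom) %in% unique(bed$chrom)))
      stop2("chromosome names do not match the BED: %s",
            paste(setdiff(unique(regions$chrom), unique(bed$chrom)),
                  collapse = ", "))
    bed1 <- data.frame(chrom = bed$chrom, start = bed$start + 1L,
                       end = bed$end, stringsAsFactors = FALSE)
    pr <- overlap_pairs(regions, bed1)
    flag[unique(pr$a)] <- TRUE
  }
  regions$hyperdivergent <- flag
  attr(regions, "fraction") <- mean(flag)
  regions
}

#' Write regions as a BED file
#'
#' Converts internal 1-based inclusive coordinates to 0-based half-open
#' BED; the region name column carries `provenance|variable|peak_pos`.
#'
#' @param regions Region data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s|%d", regions$chrom,
                   regions$start - 1L, regions$end,
                   regions$provenance, regions$variable, regions$peak_pos)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path Path to a BED (0-based half-open) file.
#' @return Data frame `chrom`, `start`, `end` (BED coordinates preserved).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop2("BED not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE)[, 1:3]
  names(raw) <- c("chrom", "start", "end")
  raw$start <- as.integer(raw$start)
  raw$end <- as.integer(raw$end)
  raw
}
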