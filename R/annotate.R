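# Hierarchical priority-resolved biotype annotation, length-range
# composition, TSS/TTS window profiles and tag-cluster enrichment.

#' Biotype priority order
#'
#' Annotation conflicts are resolved hierarchically; later entries win.
#'
#' @return Character vector in increasing order of priority: unknown,
#'   intron, exon, miRNA, snRNA, snoRNA, tRNA.
#' @export
biotype_priority <- function() {
  c("unknown", "intron", "exon", "miRNA", "snRNA", "snoRNA", "tRNA")
}

#' Length bins for short-RNA size ranges
#'
#' The five size ranges used to partition short RNAs by the biotypes they
#' typically contain: 0-18 nt (tiny RNAs), 19-29 nt (miRNAs), 30-50 nt
#' (TASRs/PASRs), 51-100 nt (tRNAs), 101-200 nt (snRNA/snoRNA). The
#' published "51-100" and "100-200" ranges share the value 100; bins here
#' are [51,100] and [101,200] so that every length maps to exactly one bin.
#' Lengths above 200 get their own bin and unmeasured lengths (`NA`) map to
#' `"unmeasured"`.
#'
#' @param inferred_length Integer vector of insert lengths (`NA` =
#'   unmeasured).
#' @return Factor with levels `0-18`, `19-29`, `30-50`, `51-100`, `101-200`,
#'   `>200`, `unmeasured`.
#' @examples
#' length_bin(c(10, 27, 50, 100, 150, NA))
#' @export
length_bin <- function(inferred_length) {
  lv <- c("0-18", "19-29", "30-50", "51-100", "101-200", ">200", "unmeasured")
  if (any(!is.na(inferred_length) & inferred_length < 0))
    stop("negative length")
  idx <- findInterval(inferred_length, c(0, 19, 30, 51, 101, 201))
  lab <- lv[idx]
  lab[is.na(inferred_length)] <- "unmeasured"
  factor(lab, levels = lv)
}

.as_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x))
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),  # 0-based in
    strand = if ("strand" %in% names(x)) x$strand else "*")
  extra <- setdiff(names(x), c("chrom", "start", "end", "strand"))
  if (length(extra)) S4Vectors::mcols(gr) <- x[, extra, drop = FALSE]
  gr
}

#' Resolve tag annotations by biotype priority
#'
#' Each alignment is labeled with the highest-priority biotype among the
#' features it overlaps by at least 1 nt (strand-aware by default), or
#' `"unknown"` when it overlaps none.
#'
#' @param alignments Data frame (`chrom`, `start`, `end`, `strand`; 0-based
#'   half-open) or `GRanges`.
#' @param features Data frame (`chrom`, `start`, `end`, `strand`, `biotype`)
#'   or `GRanges` with a `biotype` metadata column. Biotypes must come from
#'   [biotype_priority()] (excluding `"unknown"`).
#' @param ignore_strand Annotate across strands? Default `FALSE` (antisense
#'   tags do not inherit sense annotations).
#' @return Character vector of resolved biotypes, one per alignment.
#' @export
resolve_annotation <- function(alignments, features, ignore_strand = FALSE) {
  gr_a <- .as_granges(alignments)
  gr_f <- .as_granges(features)
  prio <- biotype_priority()
  bio <- as.character(S4Vectors::mcols(gr_f)$biotype)
  if (any(!bio %in% prio[-1]))
    stop("features carry biotypes outside the fixed vocabulary")
  ranked <- match(bio, prio)
  ov <- GenomicRanges::findOverlaps(gr_a, gr_f,
                                    ignore.strand = isTRUE(ignore_strand))
  best <- rep(1L, length(gr_a))  # 1 = unknown
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov)
    rk <- ranked[S4Vectors::subjectHits(ov)]
    agg <- tapply(rk, qh, max)
    best[as.integer(names(agg))] <- as.integer(agg)
  }
  prio[best]
}

#' Biotype composition per group
#'
#' Counts and within-group fractions of resolved biotypes, grouped by any
#' combination of columns (typically library and length bin), the tabular
#' form behind stacked composition bar plots.
#'
#' @param annotated_tags Data frame with a `biotype` column plus the
#'   grouping columns.
#' @param group_by Character vector of grouping column names (may be empty).
#' @return Data frame with the grouping columns, `biotype`, `count` and
#'   `fraction`; fractions sum to 1 within each group.
#' @export
composition_table <- function(annotated_tags,
                              group_by = c("library_id", "length_bin")) {
  stopifnot(is.data.frame(annotated_tags))
  if (nrow(annotated_tags) == 0)
    return(data.frame())
  group_by <- intersect(group_by, names(annotated_tags))
  keys <- c(group_by, "biotype")
  cnt <- stats::aggregate(list(count = rep(1L, nrow(annotated_tags))),
                          by = lapply(annotated_tags[keys], as.character),
                          FUN = sum)
  if (length(group_by)) {
    gkey <- do.call(paste, c(cnt[group_by], sep = "\r"))
    tot <- tapply(cnt$count, gkey, sum)
    cnt$fraction <- cnt$count / as.numeric(tot[gkey])
  } else {
    cnt$fraction <- cnt$count / sum(cnt$count)
  }
  cnt[do.call(order, cnt[keys]), , drop = FALSE]
}

#' Count tag 5' ends in windows around annotated sites
#'
#' For TSS/TTS profiling: counts alignments whose 5' end (strand-aware: the
#' leftmost base on `+`, the rightmost on `-`) falls within a window of
#' `window` nt centered on each site, i.e. `[site - window/2, site +
#' window/2)` in 0-based coordinates.
#'
#' @param alignments Data frame (`chrom`, `start`, `end`, `strand`) or
#'   `GRanges`, 0-based half-open.
#' @param sites Data frame with `chrom`, `position` (0-based), `strand`, and
#'   optionally `name`.
#' @param window Window width in nt (default 100; must be positive).
#' @return List: `per_site` (sites with a `count` column), `n_in_window`
#'   (alignments falling in at least one window), `fraction_in_window`.
#' @export
site_window_profile <- function(alignments, sites, window = 100L) {
  if (window <= 0) stop("window must be positive")
  if (methods::is(alignments, "GRanges")) {
    aln <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(alignments)),
      start = GenomicRanges::start(alignments) - 1L,
      end = GenomicRanges::end(alignments),
      strand = as.character(GenomicRanges::strand(alignments)),
      stringsAsFactors = FALSE)
  } else aln <- alignments
  n_aln <- nrow(aln)
  sites <- as.data.frame(sites)
  if (nrow(sites) == 0 || n_aln == 0) {
    sites$count <- integer(nrow(sites))
    return(list(per_site = sites, n_in_window = 0L, fraction_in_window =
                  if (n_aln) 0 else NA_real_))
  }
  end5 <- ifelse(aln$strand == "-", aln$end - 1L, aln$start)
  half <- window / 2
  lo <- sites$position - half
  hi <- sites$position + half
  in_any <- rep(FALSE, n_aln)
  counts <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    hit <- aln$chrom == sites$chrom[i] & end5 >= lo[i] & end5 < hi[i]
    counts[i] <- sum(hit)
    in_any <- in_any | hit
  }
  sites$count <- counts
  list(per_site = sites, n_in_window = sum(in_any),
       fraction_in_window = sum(in_any) / n_aln)
}

#' Cluster tags across libraries and compute enrichment
#'
#' Clusters are maximal single-linkage merges of overlapping tag intervals
#' pooled across all libraries (strand-aware). Per-library counts are
#' normalized to counts per million (CPM) within the library; enrichment of
#' treatment over control libraries is `log2((mean treatment CPM + p) /
#' (mean control CPM + p))` with pseudocount `p`, and `mean_expression` is
#' the mean CPM over all libraries (the dot-size scale of enrichment plots).
#'
#' @param alignments_by_library Named list of alignment data frames
#'   (`chrom`, `start`, `end`, `strand`) or `GRanges`, one per library.
#' @param treatment_ids,control_ids Names of the treatment and control
#'   libraries (each at least one).
#' @param pseudocount Added to both CPM means (default 1).
#' @param ignore_strand Merge and count across strands? Default `FALSE`.
#' @return Data frame: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, one `cpm_<library>` column per library, `fold_change_log2`,
#'   `mean_expression`.
#' @export
cluster_and_enrich <- function(alignments_by_library, treatment_ids,
                               control_ids, pseudocount = 1,
                               ignore_strand = FALSE) {
  libs <- names(alignments_by_library)
  if (length(libs) == 0) stop("empty library set")
  if (length(treatment_ids) < 1 || length(control_ids) < 1)
    stop("need at least one treatment and one control library")
  stopifnot(all(c(treatment_ids, control_ids) %in% libs))
  grl <- lapply(alignments_by_library, .as_granges)
  pooled <- do.call(c, unname(grl))
  clusters <- GenomicRanges::reduce(pooled,
                                    ignore.strand = isTRUE(ignore_strand))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(clusters)),
    start = GenomicRanges::start(clusters) - 1L,
    end = GenomicRanges::end(clusters),
    strand = as.character(GenomicRanges::strand(clusters)),
    stringsAsFactors = FALSE)
  cpm <- sapply(libs, function(lb) {
    gr <- grl[[lb]]
    n <- GenomicRanges::countOverlaps(clusters, gr,
                                      ignore.strand = isTRUE(ignore_strand))
    if (length(gr) == 0) rep(0, length(clusters))
    else n / length(gr) * 1e6
  })
  cpm <- matrix(cpm, nrow = length(clusters),
                dimnames = list(NULL, libs))
  for (lb in libs) out[[paste0("cpm_", lb)]] <- cpm[, lb]
  mt <- rowMeans(cpm[, treatment_ids, drop = FALSE])
  mc <- rowMeans(cpm[, control_ids, drop = FALSE])
  out$fold_change_log2 <- log2((mt + pseudocount) / (mc + pseudocount))
  out$mean_expression <- rowMeans(cpm)
  out
}
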