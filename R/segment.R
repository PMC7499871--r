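#' Per-target tumor-versus-normal log ratio profile
#'
#' Computes `log2((rpkm_tumor + pseudocount) / (rpkm_normal + pseudocount))`
#' per target, in panel order. Targets whose normal-sample RPKM falls below
#' a floor (a fraction of the sample median) carry too little reference
#' signal for a reliable ratio and are masked; masked targets keep their
#' position in the profile but are labelled neutral by the gene caller.
#'
#' @param tumor,normal Normalized depth tables (see [normalize_sample()])
#'   with identical `target_id` order.
#' @param panel Panel `data.frame` (supplies chrom and gene per target).
#' @param pseudocount Additive stabilizer for near-zero RPKM values.
#' @param floor_frac Normal-sample reliability floor, as a fraction of the
#'   median normal RPKM.
#' @param sample_id Identifier stored on the profile.
#' @return `data.frame` of class `log_ratio_profile` in panel order:
#'   `target_id`, `gene`, `chrom`, `log2_ratio`, `masked`; attributes
#'   `sample_id` and `pseudocount`.
#' @export
log_ratio <- function(tumor, normal, panel, pseudocount = 1e-3,
                      floor_frac = 0.1, sample_id = "tumor") {
  if (!identical(tumor$target_id, normal$target_id))
    stop("tumor and normal tables must have identical target order")
  idx <- match(tumor$target_id, panel$target_id)
  if (anyNA(idx) || !identical(idx, seq_len(nrow(panel))))
    stop("depth tables must cover the panel in panel order")
  t_rpkm <- tumor$rpkm
  n_rpkm <- normal$rpkm
  masked <- !is.finite(t_rpkm) | !is.finite(n_rpkm)
  floor <- floor_frac * stats::median(n_rpkm, na.rm = TRUE)
  masked <- masked | (!is.na(n_rpkm) & n_rpkm < floor)
  lr <- log2((ifelse(is.na(t_rpkm), 0, t_rpkm) + pseudocount) /
               (ifelse(is.na(n_rpkm), 0, n_rpkm) + pseudocount))
  lr[!is.finite(lr)] <- 0
  profile <- data.frame(
    target_id = tumor$target_id,
    gene = panel$gene,
    chrom = panel$chrom,
    log2_ratio = lr,
    masked = masked,
    stringsAsFactors = FALSE
  )
  attr(profile, "sample_id") <- sample_id
  attr(profile, "pseudocount") <- pseudocount
  class(profile) <- c("log_ratio_profile", "data.frame")
  profile
}

#' Circular binary segmentation of a log ratio profile
#'
#' Recursively partitions the ordered per-target log ratio profile into
#' segments of homogeneous mean. At each step the maximal circular arc
#' t-statistic over all candidate arc boundaries is located and the split
#' is accepted iff its permutation p-value falls below `alpha`; accepted
#' boundaries are applied and the pieces are segmented recursively.
#' Chromosome boundaries are hard segment boundaries, so each chromosome
#' is segmented independently. After recursion, adjacent segments whose
#' means differ by less than `merge_tol` are coalesced.
#'
#' @param profile A `log_ratio_profile` (see [log_ratio()]).
#' @param alpha Significance level for accepting a split.
#' @param n_perm Number of permutations for the reference distribution.
#' @param min_width Minimum number of targets in an arc and its
#'   complement.
#' @param merge_tol Adjacent segments closer than this (in log2 units) are
#'   merged.
#' @param seed Optional integer seed making the permutations reproducible.
#' @return `data.frame` with columns `chrom`, `start` (1-based index into
#'   the profile, inclusive), `end` (exclusive), `num_targets`,
#'   `segment_value` (mean log2 ratio of member targets). Segments
#'   partition the profile.
#' @export
cbs_segment <- function(profile, alpha = 0.01, n_perm = 1000L,
                        min_width = 2L, merge_tol = 0.1, seed = NULL) {
  if (!nrow(profile)) stop("profile is empty")
  if (!is.null(seed)) {
    rng <- local_rng(seed)
    on.exit(rng())
  }
  out <- list()
  offset <- 0L
  for (chr in unique(profile$chrom)) {
    x <- profile$log2_ratio[profile$chrom == chr]
    bounds <- cbs_recurse(x, alpha, n_perm, min_width)
    bounds <- cbs_merge(x, bounds, merge_tol)
    out[[chr]] <- data.frame(
      chrom = chr,
      start = offset + bounds$start,
      end = offset + bounds$end,
      num_targets = bounds$end - bounds$start,
      segment_value = bounds$mean,
      stringsAsFactors = FALSE
    )
    offset <- offset + length(x)
  }
  segs <- do.call(rbind, out)
  rownames(segs) <- NULL
  segs
}

# Recursive splitting of one chromosome's values. Returns a data.frame of
# (start, end, mean) with 1-based inclusive start, exclusive end, local to x.
cbs_recurse <- function(x, alpha, n_perm, min_width) {
  n <- length(x)
  one <- data.frame(start = 1L, end = n + 1L, mean = mean(x))
  if (n < 2L * min_width) return(one)
  scan <- cpp_cbs_scan(x, as.integer(min_width))
  if (scan$stat <= 1e-12) return(one)  # flat segment, nothing to split
  # p = (1 + exceedances) / (1 + n_perm); reject early once p >= alpha
  limit <- as.integer(ceiling(alpha * (1L + n_perm)))
  count <- cpp_cbs_perm_count(x, scan$stat, as.integer(n_perm),
                              as.integer(min_width), limit)
  p <- (1 + count) / (1 + n_perm)
  if (p >= alpha) return(one)
  cuts <- unique(c(scan$i, scan$j))     # 0-based boundary positions
  cuts <- cuts[cuts > 0L & cuts < n]
  if (!length(cuts)) return(one)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n) + 1L
  pieces <- lapply(seq_along(starts), function(k) {
    sub <- cbs_recurse(x[starts[k]:(ends[k] - 1L)], alpha, n_perm, min_width)
    sub$start <- sub$start + starts[k] - 1L
    sub$end <- sub$end + starts[k] - 1L
    sub
  })
  do.call(rbind, pieces)
}

# Iteratively merge the closest pair of adjacent segments while their mean
# difference is below tol.
cbs_merge <- function(x, bounds, tol) {
  while (nrow(bounds) > 1L) {
    d <- abs(diff(bounds$mean))
    k <- which.min(d)
    if (d[k] >= tol) break
    bounds$end[k] <- bounds$end[k + 1L]
    bounds$mean[k] <- mean(x[bounds$start[k]:(bounds$end[k] - 1L)])
    bounds <- bounds[-(k + 1L), , drop = FALSE]
  }
  rownames(bounds) <- NULL
  bounds
}

#' Export segments in SEG format
#'
#' Standard SEG columns (`ID`, `chrom`, `loc.start`, `loc.end`,
#' `num.mark`, `seg.mean`) using the panel's genomic coordinates of the
#' first and last target of each segment.
#'
#' @param segments Output of [cbs_segment()].
#' @param profile The profile that was segmented.
#' @param panel Panel `data.frame`.
#' @param sample_id Sample identifier for the `ID` column.
#' @return SEG-format `data.frame`.
#' @export
as_seg <- function(segments, profile, panel,
                   sample_id = attr(profile, "sample_id")) {
  idx <- match(profile$target_id, panel$target_id)
  data.frame(
    ID = sample_id %||% "sample",
    chrom = segments$chrom,
    loc.start = panel$start[idx[segments$start]],
    loc.end = panel$end[idx[segments$end - 1L]],
    num.mark = segments$num_targets,
    seg.mean = segments$segment_value,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
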