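#' Label each target gain / loss / neutral from its segment value
#'
#' Every target inherits the mean log2 ratio of the segment it belongs to
#' (the segment value). Targets in segments with value `>= gain_thr` are
#' labelled `gain`, `<= loss_thr` labelled `loss`, otherwise `neutral`;
#' both thresholds are inclusive. Masked targets are labelled `neutral`
#' regardless of segment value.
#'
#' @param segments Output of [cbs_segment()]; must partition the profile.
#' @param profile The segmented `log_ratio_profile`.
#' @param gain_thr Segment value at or above which targets are gains.
#' @param loss_thr Segment value at or below which targets are losses.
#' @return The profile with `segment_value` and `label` columns appended.
#' @export
classify_targets <- function(segments, profile, gain_thr = 0.35,
                             loss_thr = -0.5) {
  n <- nrow(profile)
  covered <- integer(0)
  seg_value <- numeric(n)
  for (k in seq_len(nrow(segments))) {
    idx <- segments$start[k]:(segments$end[k] - 1L)
    seg_value[idx] <- segments$segment_value[k]
    covered <- c(covered, idx)
  }
  if (!identical(sort(covered), seq_len(n)))
    stop("segments must partition the profile")
  label <- ifelse(seg_value >= gain_thr, "gain",
                  ifelse(seg_value <= loss_thr, "loss", "neutral"))
  label[profile$masked] <- "neutral"
  profile$segment_value <- seg_value
  profile$label <- label
  profile
}

#' Gene-level amplification / deletion calls
#'
#' Applies the gene-level rules to the per-target labels of one gene:
#' genes with four or fewer targets are too sparsely covered and are
#' reported `filtered`; a gene is an `amplification` when at least
#' `frac_thr` of its targets are gains, a `deletion` when at least
#' `frac_thr` are losses, and `neutral` otherwise (fractions inclusive).
#' The gene's mean log2 ratio over all of its targets gives the observed
#' average copy number against a diploid control,
#' `cn_observed = 2 * 2^mean_log2_ratio`, and [purity_adjust_cn()] converts
#' it to the tumor-cell copy number used for mutation multiplicity.
#'
#' @param labelled Output of [classify_targets()] restricted to one gene
#'   (for [call_gene()]) or covering the whole profile (for
#'   [call_genes()]).
#' @param min_targets Genes with fewer targets than this are filtered.
#' @param frac_thr Fraction of gain (loss) targets required to call an
#'   amplification (deletion).
#' @param purity Tumor purity used for the adjusted copy number.
#' @return One row (or one per gene) with columns `gene`, `n_targets`,
#'   `n_gain`, `n_loss`, `status`, `mean_log2_ratio`, `cn_observed`,
#'   `cn_tumor_adjusted`.
#' @export
call_gene <- function(labelled, min_targets = 5L, frac_thr = 0.7,
                      purity = 1) {
  if (!nrow(labelled)) stop("no targets supplied for the gene")
  if (length(unique(labelled$gene)) != 1L)
    stop("call_gene() expects targets of exactly one gene")
  n <- nrow(labelled)
  n_gain <- sum(labelled$label == "gain")
  n_loss <- sum(labelled$label == "loss")
  status <- if (n < min_targets) "filtered"
    else if (n_gain / n >= frac_thr) "amplification"
    else if (n_loss / n >= frac_thr) "deletion"
    else "neutral"
  mean_lr <- mean(labelled$log2_ratio)
  cn_obs <- 2 * 2^mean_lr
  data.frame(
    gene = labelled$gene[1L],
    n_targets = n,
    n_gain = n_gain,
    n_loss = n_loss,
    status = status,
    mean_log2_ratio = mean_lr,
    cn_observed = cn_obs,
    cn_tumor_adjusted = purity_adjust_cn(cn_obs, purity),
    stringsAsFactors = FALSE
  )
}

#' @rdname call_gene
#' @export
call_genes <- function(labelled, min_targets = 5L, frac_thr = 0.7,
                       purity = 1) {
  calls <- lapply(split(labelled, labelled$gene),
                  call_gene, min_targets = min_targets,
                  frac_thr = frac_thr, purity = purity)
  calls <- do.call(rbind, calls)
  # report in panel order of first appearance
  calls <- calls[match(unique(labelled$gene), calls$gene), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Convert an observed mixture copy number to a tumor-cell copy number
#'
#' The observed average copy number of a biopsy is a purity-weighted
#' mixture of tumor copy number and diploid normal contamination:
#' `cn_observed = purity * cn_tumor + 2 * (1 - purity)`. Inverting and
#' clamping at zero gives the tumor-cell ("locus specific") copy number:
#' `max(0, (cn_observed - 2 * (1 - purity)) / purity)`.
#'
#' @param cn_observed Observed (purity-naive) copy number, >= 0.
#' @param purity Tumor purity in (0, 1].
#' @return Purity-adjusted tumor copy number.
#' @export
purity_adjust_cn <- function(cn_observed, purity) {
  if (any(purity <= 0 | purity > 1)) stop("`purity` must lie in (0, 1]")
  if (any(cn_observed < 0)) stop("`cn_observed` must be >= 0")
  pmax(0, (cn_observed - 2 * (1 - purity)) / purity)
}
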