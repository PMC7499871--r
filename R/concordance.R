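#' Bundle a matched PT / BM sample pair
#'
#' @param patient_id Patient identifier.
#' @param pt,bm Per-sample lists with elements `variants` (somatic variant
#'   `data.frame`: `gene`, `label`, `variant_type`, `vaf`), `gene_calls`
#'   (from [call_genes()], may be empty) and `purity`.
#' @return A list of class `sample_pair`.
#' @export
sample_pair <- function(patient_id, pt, bm) {
  for (s in list(pt, bm)) {
    stopifnot(is.list(s), !is.null(s$variants))
  }
  structure(list(patient_id = patient_id, pt = pt, bm = bm),
            class = "sample_pair")
}

variant_key <- function(v) paste(v$gene, v$label, v$variant_type, sep = "|")

#' Match somatic variants between two samples
#'
#' Exact-key join on gene + label + variant type (events are compared the
#' way they are reported, not by genomic coordinate). Inputs must be
#' deduplicated call sets; duplicate keys within one sample are an error.
#'
#' @param pt_variants,bm_variants Somatic variant `data.frame`s.
#' @return A list with `matched` (`data.frame`: `gene`, `label`,
#'   `variant_type`, `pt_vaf`, `bm_vaf`), `pt_only` and `bm_only`
#'   (the unmatched singleton rows).
#' @export
match_variants <- function(pt_variants, bm_variants) {
  kp <- variant_key(pt_variants)
  kb <- variant_key(bm_variants)
  if (anyDuplicated(kp) || anyDuplicated(kb))
    stop("duplicate variant keys within one sample; inputs must be ",
         "deduplicated call sets")
  shared_keys <- intersect(kp, kb)
  ip <- match(shared_keys, kp)
  ib <- match(shared_keys, kb)
  matched <- data.frame(
    gene = pt_variants$gene[ip],
    label = pt_variants$label[ip],
    variant_type = pt_variants$variant_type[ip],
    pt_vaf = pt_variants$vaf[ip],
    bm_vaf = bm_variants$vaf[ib],
    stringsAsFactors = FALSE
  )
  list(matched = matched,
       pt_only = pt_variants[!(kp %in% shared_keys), , drop = FALSE],
       bm_only = bm_variants[!(kb %in% shared_keys), , drop = FALSE])
}

#' Score the shared somatic fingerprint of a PT / BM pair
#'
#' The scored event universe is every somatic event detected in either
#' sample: all called SNVs/indels/fusions, plus copy-number events for
#' genes whose observed copy number qualifies in at least one sample
#' (amplification at `cn >= amp_thr`, default 4; deletion at
#' `cn <= del_thr`, default 1). An SNV/indel is *shared* when it was
#' called in both samples with VAF at least `vaf_thr` (default 3%) on
#' both sides; a copy-number event is shared when both samples qualify.
#' Non-shared events are attributed to the sample that carries them (a
#' variant called in both samples but under-threshold on one side goes to
#' the higher-VAF side). The shared fraction is the number of shared
#' events over the event union (or over PT-detected events, if
#' `denominator = "pt"`), and a pair with shared fraction above 0.5 is
#' classified `shared_dominant` — the metastasis then most plausibly
#' derives from the dominant clonal line of the primary — otherwise
#' `divergent`.
#'
#' @param pair A [sample_pair()].
#' @param vaf_thr VAF presence threshold for SNVs/indels (inclusive).
#' @param amp_thr Observed copy number at or above which an amplification
#'   is present.
#' @param del_thr Observed copy number at or below which a deletion is
#'   present.
#' @param denominator `"union"` (default) or `"pt"`.
#' @return A list of class `concordance_report` with counts
#'   `n_shared_snv_indel`, `n_pt_only`, `n_bm_only`, `n_shared_amp`,
#'   `n_shared_del`, `shared_fraction`, `relatedness`, and the per-event
#'   table `events`.
#' @export
score_shared <- function(pair, vaf_thr = 0.03, amp_thr = 4, del_thr = 1,
                         denominator = c("union", "pt")) {
  stopifnot(inherits(pair, "sample_pair"))
  denominator <- match.arg(denominator)

  qual <- function(v, thr) !is.na(v) & v >= thr
  m <- match_variants(pair$pt$variants, pair$bm$variants)
  ev <- rbind(
    if (nrow(m$matched)) data.frame(
      gene = m$matched$gene, label = m$matched$label,
      type = m$matched$variant_type,
      in_pt = TRUE, in_bm = TRUE,
      qual_pt = qual(m$matched$pt_vaf, vaf_thr),
      qual_bm = qual(m$matched$bm_vaf, vaf_thr),
      pt_vaf = m$matched$pt_vaf, bm_vaf = m$matched$bm_vaf,
      stringsAsFactors = FALSE),
    if (nrow(m$pt_only)) data.frame(
      gene = m$pt_only$gene, label = m$pt_only$label,
      type = m$pt_only$variant_type,
      in_pt = TRUE, in_bm = FALSE,
      qual_pt = qual(m$pt_only$vaf, vaf_thr), qual_bm = FALSE,
      pt_vaf = m$pt_only$vaf, bm_vaf = NA_real_,
      stringsAsFactors = FALSE),
    if (nrow(m$bm_only)) data.frame(
      gene = m$bm_only$gene, label = m$bm_only$label,
      type = m$bm_only$variant_type,
      in_pt = FALSE, in_bm = TRUE,
      qual_pt = FALSE, qual_bm = qual(m$bm_only$vaf, vaf_thr),
      pt_vaf = NA_real_, bm_vaf = m$bm_only$vaf,
      stringsAsFactors = FALSE)
  )

  cnv_events <- function(kind, qualifies) {
    genes <- union(
      if (!is.null(pair$pt$gene_calls)) pair$pt$gene_calls$gene,
      if (!is.null(pair$bm$gene_calls)) pair$bm$gene_calls$gene
    )
    if (!length(genes)) return(NULL)
    cn_in <- function(calls, g) {
      if (is.null(calls) || !nrow(calls)) return(rep(NA_real_, length(g)))
      calls$cn_observed[match(g, calls$gene)]
    }
    pt_q <- qualifies(cn_in(pair$pt$gene_calls, genes))
    bm_q <- qualifies(cn_in(pair$bm$gene_calls, genes))
    pt_q[is.na(pt_q)] <- FALSE
    bm_q[is.na(bm_q)] <- FALSE
    keep <- pt_q | bm_q   # a CNV event exists only where one side qualifies
    if (!any(keep)) return(NULL)
    data.frame(gene = genes[keep], label = kind, type = kind,
               in_pt = pt_q[keep], in_bm = bm_q[keep],
               qual_pt = pt_q[keep], qual_bm = bm_q[keep],
               pt_vaf = NA_real_, bm_vaf = NA_real_,
               stringsAsFactors = FALSE)
  }
  ev <- rbind(ev,
              cnv_events("amplification", function(cn) cn >= amp_thr),
              cnv_events("deletion", function(cn) cn <= del_thr))
  if (is.null(ev))
    ev <- data.frame(gene = character(), label = character(),
                     type = character(), in_pt = logical(),
                     in_bm = logical(), qual_pt = logical(),
                     qual_bm = logical(), pt_vaf = numeric(),
                     bm_vaf = numeric())
  ev$shared <- ev$qual_pt & ev$qual_bm
  # attribute non-shared events to the carrying sample; a variant called
  # on both sides but under-threshold on one goes to the higher-VAF side
  both <- ev$in_pt & ev$in_bm & !ev$shared
  to_pt <- (ev$in_pt & !ev$in_bm) |
    (both & !is.na(ev$pt_vaf) & !is.na(ev$bm_vaf) & ev$pt_vaf >= ev$bm_vaf)
  to_bm <- !ev$shared & !to_pt

  is_var <- !(ev$type %in% c("amplification", "deletion"))
  n_shared_var <- sum(ev$shared & is_var)
  denom_n <- if (denominator == "union") nrow(ev) else sum(ev$in_pt)
  shared_fraction <- if (denom_n > 0) sum(ev$shared) / denom_n else 0

  structure(list(
    patient_id = pair$patient_id,
    n_shared_snv_indel = n_shared_var,
    n_pt_only = sum(to_pt),
    n_bm_only = sum(to_bm),
    n_shared_amp = sum(ev$shared & ev$type == "amplification"),
    n_shared_del = sum(ev$shared & ev$type == "deletion"),
    shared_fraction = shared_fraction,
    relatedness = if (shared_fraction > 0.5) "shared_dominant"
                  else "divergent",
    events = ev
  ), class = "concordance_report")
}

#' Summarize clonal relatedness over a cohort
#'
#' @param reports List of `concordance_report` objects.
#' @return A list with counts of `shared_dominant` and `divergent`
#'   patients and the patient ids in each class.
#' @export
classify_cohort <- function(reports) {
  if (!length(reports)) stop("need at least one concordance report")
  cls <- vapply(reports, function(r) r$relatedness, character(1))
  ids <- vapply(reports, function(r) as.character(r$patient_id),
                character(1))
  list(
    n_shared_dominant = sum(cls == "shared_dominant"),
    n_divergent = sum(cls == "divergent"),
    shared_dominant = ids[cls == "shared_dominant"],
    divergent = ids[cls == "divergent"]
  )
}
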