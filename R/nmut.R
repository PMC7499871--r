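#' Purity-adjusted mutation copy number
#'
#' Converts a variant allele frequency to the number of mutated copies per
#' tumor cell:
#' `n_mut = VAF * (1/p) * (p * CN_t + CN_n * (1 - p))`,
#' where `p` is the tumor purity, `CN_t` the tumor locus-specific copy
#' number and `CN_n` the normal locus copy number (2 on autosomes).
#' Fractional values indicate subclonality or low multiplicity and are
#' reported as-is, never rounded.
#'
#' @param vaf Variant allele frequency in \[0, 1\].
#' @param purity Tumor purity in (0, 1].
#' @param cn_t Tumor locus-specific copy number (>= 0).
#' @param cn_n Normal locus copy number.
#' @return Mutation copy number (real, >= 0).
#' @export
compute_nmut <- function(vaf, purity, cn_t, cn_n = 2) {
  if (any(purity <= 0 | purity > 1)) stop("`purity` must lie in (0, 1]")
  if (any(vaf < 0 | vaf > 1)) stop("`vaf` must lie in [0, 1]")
  if (any(cn_t < 0) || any(cn_n < 0)) stop("copy numbers must be >= 0")
  vaf * (1 / purity) * (purity * cn_t + cn_n * (1 - purity))
}

#' Annotate somatic variants with mutation copy numbers
#'
#' Joins each SNV/indel to its gene's purity-adjusted copy number (genes
#' without a gene call default to diploid, `cn_t = 2`) and computes
#' [compute_nmut()]. Fusion rows are passed through untouched with
#' `n_mut = NA`: a fusion's printed fraction is a detection quantity, not
#' an allele multiplicity.
#'
#' @param variants Somatic variant `data.frame` with columns `gene`,
#'   `label`, `variant_type` (`snv`, `indel` or `fusion`) and `vaf`.
#' @param gene_calls Gene-call table from [call_genes()] (may be `NULL`
#'   or empty for an all-diploid assumption).
#' @param purity Tumor purity of the sample.
#' @param cn_n Normal locus copy number.
#' @return `variants` with `purity`, `cn_t`, `cn_n` and `n_mut` columns
#'   appended.
#' @export
annotate_variants <- function(variants, gene_calls, purity, cn_n = 2) {
  if (missing(purity) || is.null(purity) || is.na(purity))
    stop("`purity` is required")
  if (purity <= 0 || purity > 1) stop("`purity` must lie in (0, 1]")
  stopifnot(all(c("gene", "label", "variant_type", "vaf") %in%
                  names(variants)))

  cn_t <- rep(2, nrow(variants))
  if (!is.null(gene_calls) && nrow(gene_calls)) {
    idx <- match(variants$gene, gene_calls$gene)
    hit <- !is.na(idx)
    cn_t[hit] <- gene_calls$cn_tumor_adjusted[idx[hit]]
  }
  is_fusion <- variants$variant_type == "fusion"
  n_mut <- rep(NA_real_, nrow(variants))
  if (any(!is_fusion))
    n_mut[!is_fusion] <- compute_nmut(variants$vaf[!is_fusion], purity,
                                      cn_t[!is_fusion], cn_n)
  variants$purity <- rep(purity, nrow(variants))
  variants$cn_t <- ifelse(is_fusion, NA_real_, cn_t)
  variants$cn_n <- ifelse(is_fusion, NA_real_, rep(cn_n, nrow(variants)))
  variants$n_mut <- n_mut
  variants
}
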