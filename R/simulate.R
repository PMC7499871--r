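#' Default GC bias curve for the simulator
#'
#' Smooth unimodal capture-efficiency multiplier peaking at GC = 0.45 with
#' range [0.6, 1.0]. Capture panels lose efficiency at both GC extremes;
#' the curve exists so the LOESS corrector has real structure to remove.
#'
#' @param peak GC fraction of maximal efficiency.
#' @param floor Minimal multiplier (at extreme GC).
#' @param width Gaussian width of the efficiency curve.
#' @return A function mapping GC fraction to a multiplier in `[floor, 1]`.
#' @export
default_gc_bias <- function(peak = 0.45, floor = 0.6, width = 0.12) {
  force(peak); force(floor); force(width)
  function(gc) floor + (1 - floor) * exp(-((gc - peak)^2) / (2 * width^2))
}

#' Expected per-target depth under a purity-diluted copy-number mixture
#'
#' A biopsy is a mixture of tumor cells (fraction `purity`, locus copy
#' number `cn_tumor`) and normal cells (diploid). Expected unique-molecule
#' depth is proportional to the average copy number of the mixture,
#' modulated by GC capture efficiency:
#' `base_depth * gc_bias(gc) * (purity*cn_tumor + 2*(1-purity)) / 2`.
#'
#' @param target One panel row (or any list with a `gc_fraction` field).
#' @param cn_tumor Integer tumor copy number at the locus (>= 0).
#' @param purity Tumor cell fraction in (0, 1].
#' @param base_depth Expected depth of a diploid locus at peak efficiency.
#' @param gc_bias Function of GC fraction; defaults to the identity
#'   (no bias).
#' @return Expected depth (positive real).
#' @export
expected_depth <- function(target, cn_tumor, purity, base_depth,
                           gc_bias = function(gc) 1) {
  if (any(purity <= 0 | purity > 1)) stop("`purity` must lie in (0, 1]")
  if (any(cn_tumor < 0)) stop("`cn_tumor` must be >= 0")
  if (any(base_depth <= 0)) stop("`base_depth` must be positive")
  gc <- if (is.list(target) || is.data.frame(target)) target$gc_fraction
        else target
  base_depth * gc_bias(gc) * (purity * cn_tumor + 2 * (1 - purity)) / 2
}

#' Expected variant allele frequency given mutation copy number
#'
#' Algebraic inverse of [compute_nmut()]: the VAF produced by a variant
#' present on `n_mut` copies per tumor cell at a locus with tumor copy
#' number `cn_tumor`, in a biopsy of the given purity:
#' `vaf = n_mut * purity / (purity*cn_tumor + cn_normal*(1 - purity))`.
#'
#' @param n_mut Mutation copy number (positive real).
#' @param purity Tumor cell fraction in (0, 1].
#' @param cn_tumor Tumor locus copy number.
#' @param cn_normal Normal locus copy number (2 for autosomes).
#' @return Expected VAF (fraction).
#' @export
expected_vaf <- function(n_mut, purity, cn_tumor, cn_normal = 2) {
  if (any(purity <= 0 | purity > 1)) stop("`purity` must lie in (0, 1]")
  denom <- purity * cn_tumor + cn_normal * (1 - purity)
  if (any(denom <= 0))
    stop("degenerate locus: purity*cn_tumor + cn_normal*(1-purity) must be > 0")
  n_mut * purity / denom
}

#' Construct a clonal truth object for a paired simulation
#'
#' Describes a two-biopsy tumor: per-sample purities, per-gene integer copy
#' numbers (default diploid for unlisted genes), and somatic variants that
#' are truncal (present in both biopsies) or private to one.
#'
#' @param purity_pt,purity_bm Tumor purities of the two biopsies, in (0, 1].
#' @param gene_cn `data.frame` with columns `gene`, `cn_pt`, `cn_bm`
#'   (integer copy numbers >= 0); may be empty.
#' @param variants `data.frame` with columns `gene`, `label`, `presence`
#'   (one of `"truncal"`, `"pt_only"`, `"bm_only"`), `n_mut` (positive
#'   real) and optionally `cn_locus` (integer; default 2).
#' @return A list of class `clonal_truth`.
#' @export
clonal_truth <- function(purity_pt, purity_bm,
                         gene_cn = data.frame(gene = character(),
                                              cn_pt = integer(),
                                              cn_bm = integer()),
                         variants = data.frame(gene = character(),
                                               label = character(),
                                               presence = character(),
                                               n_mut = numeric())) {
  if (purity_pt <= 0 || purity_pt > 1 || purity_bm <= 0 || purity_bm > 1)
    stop("purities must lie in (0, 1]")
  stopifnot(all(c("gene", "cn_pt", "cn_bm") %in% names(gene_cn)),
            all(c("gene", "label", "presence", "n_mut") %in% names(variants)))
  if (any(gene_cn$cn_pt < 0) || any(gene_cn$cn_bm < 0))
    stop("truth copy numbers must be >= 0")
  bad <- setdiff(variants$presence, c("truncal", "pt_only", "bm_only"))
  if (length(bad)) stop("unknown presence value(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(variants$cn_locus)) variants$cn_locus <- rep(2L, nrow(variants))
  structure(list(purity_pt = purity_pt, purity_bm = purity_bm,
                 gene_cn = gene_cn, variants = variants),
            class = "clonal_truth")
}

#' Randomly generate a clonal truth on a panel
#'
#' Plants copy-number events and somatic variants in randomly chosen panel
#' genes: `n_amp` genes amplified and `n_del` deleted in both biopsies,
#' and `n_variants` SNV-like variants of which a fraction
#' `truncal_fraction` is truncal and the remainder split evenly between
#' PT-private and BM-private. Variants are placed in copy-neutral genes.
#'
#' @param panel Panel `data.frame`.
#' @param purity_pt,purity_bm Biopsy purities.
#' @param n_amp,n_del Number of amplified / deleted genes.
#' @param amp_cn,del_cn Integer truth copy numbers for those genes.
#' @param n_variants Number of somatic variants.
#' @param truncal_fraction Fraction of variants present in both biopsies.
#' @param n_mut Mutation copy number given to every variant.
#' @param min_targets_cnv Restrict CNV genes to genes with at least this
#'   many targets (`NULL` for no restriction).
#' @param seed Integer seed.
#' @return A `clonal_truth` object.
#' @export
simulate_clonal_truth <- function(panel, purity_pt = 0.5, purity_bm = 0.5,
                                  n_amp = 10L, n_del = 10L,
                                  amp_cn = 8L, del_cn = 0L,
                                  n_variants = 40L, truncal_fraction = 0.7,
                                  n_mut = 1, min_targets_cnv = NULL,
                                  seed = 1L) {
  validate_panel(panel)
  rng <- local_rng(seed)
  on.exit(rng())

  genes <- unique(panel$gene)
  eligible <- genes
  if (!is.null(min_targets_cnv)) {
    cnt <- table(panel$gene)
    eligible <- names(cnt)[cnt >= min_targets_cnv]
  }
  if (n_amp + n_del > length(eligible))
    stop("not enough eligible genes for the requested CNV events")
  cnv_genes <- sample(eligible, n_amp + n_del)
  gene_cn <- data.frame(
    gene = cnv_genes,
    cn_pt = c(rep(amp_cn, n_amp), rep(del_cn, n_del)),
    cn_bm = c(rep(amp_cn, n_amp), rep(del_cn, n_del)),
    stringsAsFactors = FALSE
  )

  neutral <- setdiff(genes, cnv_genes)
  if (n_variants > length(neutral))
    stop("not enough copy-neutral genes for the requested variants")
  var_genes <- sample(neutral, n_variants)
  n_truncal <- round(n_variants * truncal_fraction)
  n_private <- n_variants - n_truncal
  presence <- c(rep("truncal", n_truncal),
                rep(c("pt_only", "bm_only"), length.out = n_private))
  variants <- data.frame(
    gene = var_genes,
    label = sprintf("M%03dX", seq_len(n_variants)),
    presence = sample(presence),
    n_mut = rep(n_mut, n_variants),
    cn_locus = rep(2L, n_variants),
    stringsAsFactors = FALSE
  )
  clonal_truth(purity_pt, purity_bm, gene_cn, variants)
}

#' Simulate a matched PT / BM / normal trio on a panel
#'
#' Draws per-target unique-molecule counts negative-binomially around
#' [expected_depth()] (the matched normal uses copy number 2 and purity 1)
#' and per-variant allele counts binomially around [expected_vaf()].
#' Overdispersion emulates FFPE library variability; `dispersion = 0`
#' falls back to Poisson counts.
#'
#' @param panel Panel `data.frame`.
#' @param truth A `clonal_truth` object; its genes must exist on the panel.
#' @param base_depth Expected diploid unique-molecule depth per target.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`).
#' @param gc_bias GC bias function applied to tumor and normal alike.
#' @param variant_depth Expected total read count at variant sites.
#' @param seed Integer seed; the only source of randomness.
#' @return A list with `pt`, `bm`, `normal` (each a list with `depth`:
#'   data.frame `target_id`, `unique_molecules`; tumors also carry
#'   `pileups`: data.frame `gene`, `label`, `alt_count`, `total_count`,
#'   and `purity`), plus the `truth` object echoed back.
#' @export
simulate_pair <- function(panel, truth,
                          base_depth = 300, dispersion = 0.05,
                          gc_bias = default_gc_bias(),
                          variant_depth = base_depth, seed = 1L) {
  validate_panel(panel)
  stopifnot(inherits(truth, "clonal_truth"))
  truth_genes <- unique(c(truth$gene_cn$gene, truth$variants$gene))
  unknown <- setdiff(truth_genes, panel$gene)
  if (length(unknown))
    stop("truth gene(s) not on panel: ", paste(unknown, collapse = ", "))

  rng <- local_rng(seed)
  on.exit(rng())

  cn_of <- function(sample) {
    cn <- rep(2L, nrow(panel))
    if (nrow(truth$gene_cn)) {
      idx <- match(panel$gene, truth$gene_cn$gene)
      hit <- !is.na(idx)
      cn[hit] <- truth$gene_cn[[paste0("cn_", sample)]][idx[hit]]
    }
    cn
  }
  draw_counts <- function(mu) {
    if (dispersion > 0) stats::rnbinom(length(mu), mu = mu,
                                       size = 1 / dispersion)
    else stats::rpois(length(mu), mu)
  }
  depth_table <- function(mu) data.frame(
    target_id = panel$target_id,
    unique_molecules = draw_counts(mu),
    stringsAsFactors = FALSE
  )

  mu_normal <- expected_depth(panel, 2L, 1, base_depth, gc_bias)
  samples <- list(
    pt = depth_table(expected_depth(panel, cn_of("pt"), truth$purity_pt,
                                    base_depth, gc_bias)),
    bm = depth_table(expected_depth(panel, cn_of("bm"), truth$purity_bm,
                                    base_depth, gc_bias)),
    normal = depth_table(mu_normal)
  )

  pileups <- function(sample, purity) {
    v <- truth$variants
    if (!nrow(v)) {
      return(data.frame(gene = character(), label = character(),
                        alt_count = integer(), total_count = integer(),
                        stringsAsFactors = FALSE))
    }
    present <- v$presence %in% c("truncal", paste0(sample, "_only"))
    cn_locus <- v$cn_locus
    vaf <- ifelse(present,
                  expected_vaf(v$n_mut, purity, cn_locus), 0)
    total <- stats::rpois(nrow(v), variant_depth)
    alt <- stats::rbinom(nrow(v), total, pmin(vaf, 1))
    data.frame(gene = v$gene, label = v$label,
               alt_count = alt, total_count = total,
               stringsAsFactors = FALSE)
  }

  list(
    pt = list(depth = samples$pt, pileups = pileups("pt", truth$purity_pt),
              purity = truth$purity_pt),
    bm = list(depth = samples$bm, pileups = pileups("bm", truth$purity_bm),
              purity = truth$purity_bm),
    normal = list(depth = samples$normal),
    truth = truth
  )
}

#' Minimal alt-fraction variant caller for simulated pileups
#'
#' Turns per-variant pileups into a somatic variant table, keeping sites
#' with enough alt evidence. This stands in for the upstream somatic
#' caller only on simulated data; real variant tables are consumed as-is.
#'
#' @param pileups `data.frame` with `gene`, `label`, `alt_count`,
#'   `total_count`.
#' @param min_alt Minimum alt read count.
#' @param min_vaf Minimum VAF.
#' @param variant_type Variant type assigned to the calls.
#' @return A somatic variant `data.frame` with columns `gene`, `label`,
#'   `variant_type`, `vaf`, `alt_count`, `total_count`.
#' @export
call_variants <- function(pileups, min_alt = 3L, min_vaf = 0.01,
                          variant_type = "snv") {
  stopifnot(all(c("gene", "label", "alt_count", "total_count") %in%
                  names(pileups)))
  vaf <- ifelse(pileups$total_count > 0,
                pileups$alt_count / pileups$total_count, 0)
  keep <- pileups$alt_count >= min_alt & vaf >= min_vaf
  data.frame(
    gene = pileups$gene[keep],
    label = pileups$label[keep],
    variant_type = rep(variant_type, sum(keep)),
    vaf = vaf[keep],
    alt_count = pileups$alt_count[keep],
    total_count = pileups$total_count[keep],
    stringsAsFactors = FALSE
  )
}
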