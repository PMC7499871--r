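#' Pipeline configuration
#'
#' Collects every named constant of the analysis in one validated list.
#' Thresholds with published values default to them: MAPQ floor 20,
#' segment-value gain/loss cutoffs 0.35 / -0.5, five-target gene floor,
#' 0.7 gain/loss target fraction, 3% shared-VAF threshold, shared
#' amplification CN >= 4 and deletion CN <= 1, and the strict CN > 5
#' therapy amplification rule. The remaining knobs (LOESS span, CBS
#' alpha / permutations / minimum width / merge tolerance, pseudocount)
#' are implementation defaults.
#'
#' @param ... Overrides of the default fields.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  config <- list(
    mapq_thr = 20L,
    loess_span = 0.3,
    pseudocount = 1e-3,
    normal_floor_frac = 0.1,
    cbs_alpha = 0.01,
    cbs_n_perm = 1000L,
    cbs_min_width = 2L,
    cbs_merge_tol = 0.1,
    gain_thr = 0.35,
    loss_thr = -0.5,
    min_targets = 5L,
    frac_thr = 0.7,
    vaf_share_thr = 0.03,
    amp_share_thr = 4,
    del_share_thr = 1,
    therapy_amp_thr = 5,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  config[names(overrides)] <- overrides
  structure(config, class = c("pipeline_config", "list"))
}

# depth input -> per-target depth table; accepts read records (columns
# barcode/chrom/start/end/mapq) or precomputed per-target counts
stage_depth <- function(input, panel, config) {
  if (all(c("barcode", "chrom", "start", "end", "mapq") %in% names(input))) {
    mols <- dedup_molecules(filter_mapq(input, config$mapq_thr))
    depth_of_coverage(mols, panel)
  } else if ("target_id" %in% names(input)) {
    input
  } else {
    stop("depth input must be read records or a per-target depth table")
  }
}

#' Run the full analysis for one matched PT / BM pair
#'
#' Executes the stages in order: molecule processing (when read records
#' are supplied), GC correction and RPKM normalization per sample,
#' tumor-versus-normal log ratios, circular binary segmentation,
#' gene-level CNV calls, purity-adjusted mutation copy numbers, PT/BM
#' concordance scoring and therapy matching. Each tumor sample is
#' normalized against the same matched normal; no stage mixes samples
#' before the log-ratio step.
#'
#' @param panel Panel `data.frame`.
#' @param pt,bm Per-tumor-sample inputs: list with `depth` (read records
#'   or per-target counts), `variants` (somatic variant table) or
#'   `pileups` (simulated pileups, called via [call_variants()]), and
#'   `purity`.
#' @param normal List with `depth` for the matched normal.
#' @param kb Knowledge table (`NULL` skips therapy matching).
#' @param initial_therapy Initially administered targeted drug.
#' @param patient_id Identifier used in the reports.
#' @param config A [pipeline_config()].
#' @return A list of class `pair_result` with per-sample `gene_calls` and
#'   `mutation_cn` tables, `segments`, the `concordance` report, the
#'   `therapy` report (or `NULL`) and the effective `config`.
#' @export
run_pair <- function(panel, pt, bm, normal, kb = NULL,
                     initial_therapy = NA, patient_id = "patient",
                     config = pipeline_config()) {
  validate_panel(panel)
  normal_norm <- normalize_sample(stage_depth(normal$depth, panel, config),
                                  panel, span = config$loess_span)

  run_tumor <- function(sample, name) {
    depth <- stage_depth(sample$depth, panel, config)
    norm <- normalize_sample(depth, panel, span = config$loess_span)
    profile <- log_ratio(norm, normal_norm, panel,
                         pseudocount = config$pseudocount,
                         floor_frac = config$normal_floor_frac,
                         sample_id = paste(patient_id, name, sep = "_"))
    segments <- cbs_segment(profile, alpha = config$cbs_alpha,
                            n_perm = config$cbs_n_perm,
                            min_width = config$cbs_min_width,
                            merge_tol = config$cbs_merge_tol,
                            seed = config$seed)
    labelled <- classify_targets(segments, profile,
                                 gain_thr = config$gain_thr,
                                 loss_thr = config$loss_thr)
    gene_calls <- call_genes(labelled, min_targets = config$min_targets,
                             frac_thr = config$frac_thr,
                             purity = sample$purity)
    variants <- if (!is.null(sample$variants)) sample$variants
      else if (!is.null(sample$pileups)) call_variants(sample$pileups)
      else data.frame(gene = character(), label = character(),
                      variant_type = character(), vaf = numeric())
    mutation_cn <- annotate_variants(variants, gene_calls, sample$purity)
    list(profile = profile, segments = segments, gene_calls = gene_calls,
         variants = variants, mutation_cn = mutation_cn,
         purity = sample$purity)
  }

  pt_res <- run_tumor(pt, "pt")
  bm_res <- run_tumor(bm, "bm")

  pair <- sample_pair(
    patient_id,
    pt = list(variants = pt_res$variants, gene_calls = pt_res$gene_calls,
              purity = pt_res$purity),
    bm = list(variants = bm_res$variants, gene_calls = bm_res$gene_calls,
              purity = bm_res$purity)
  )
  concordance <- score_shared(pair, vaf_thr = config$vaf_share_thr,
                              amp_thr = config$amp_share_thr,
                              del_thr = config$del_share_thr)
  therapy <- if (!is.null(kb))
    match_therapies(pair, kb, initial_therapy = initial_therapy,
                    therapy_amp_thr = config$therapy_amp_thr)

  structure(list(
    patient_id = patient_id,
    pt = pt_res, bm = bm_res,
    concordance = concordance,
    therapy = therapy,
    config = config
  ), class = "pair_result")
}

#' Run the analysis over a cohort of pairs
#'
#' One patient's failure is recorded and does not abort the rest.
#'
#' @param cohort Named list; each element holds the [run_pair()] arguments
#'   for one patient (`pt`, `bm`, `normal`, optionally `initial_therapy`).
#' @param panel Shared panel.
#' @param kb Knowledge table (optional).
#' @param config A [pipeline_config()].
#' @return A list with per-patient `results`, `failures` (error messages
#'   keyed by patient), the cohort `concordance` summary and
#'   `actionability` summary (when computable).
#' @export
run_cohort <- function(cohort, panel, kb = NULL,
                       config = pipeline_config()) {
  results <- list()
  failures <- list()
  for (pid in names(cohort)) {
    args <- cohort[[pid]]
    res <- tryCatch(
      run_pair(panel, pt = args$pt, bm = args$bm, normal = args$normal,
               kb = kb, initial_therapy = args$initial_therapy %||% NA,
               patient_id = pid, config = config),
      error = function(e) e
    )
    if (inherits(res, "error")) failures[[pid]] <- conditionMessage(res)
    else results[[pid]] <- res
  }
  concordance <- if (length(results))
    classify_cohort(lapply(results, function(r) r$concordance))
  actionability <- if (length(results) && !is.null(kb))
    cohort_actionability(lapply(results, function(r) r$therapy))
  list(results = results, failures = failures,
       concordance = concordance, actionability = actionability)
}
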