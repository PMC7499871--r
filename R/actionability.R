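#' Load the drug-alteration knowledge table
#'
#' Reads and validates the bundled (or a user-supplied) knowledge TSV with
#' columns `gene`, `pattern`, `pattern_kind` (`exact`, `class`,
#' `amplification`, `fusion`), `drug`, `level` (`A`-`D`), `tier` (1 for
#' levels A/B, 2 for C/D) and `note`.
#'
#' @param path Path to the knowledge TSV; defaults to the bundled table.
#' @return Validated knowledge `data.frame`.
#' @export
load_knowledge <- function(path = pp_extdata("actionability_kb.tsv")) {
  if (!file.exists(path)) stop("knowledge file not found: ", path)
  kb <- utils::read.delim(path, comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  req <- c("gene", "pattern", "pattern_kind", "drug", "level", "tier")
  missing <- setdiff(req, names(kb))
  if (length(missing))
    stop("knowledge table missing column(s): ",
         paste(missing, collapse = ", "))
  check_enum <- function(col, allowed) {
    bad <- which(!(kb[[col]] %in% allowed))
    if (length(bad))
      stop("knowledge row ", bad[1L], ": invalid ", col, " '",
           kb[[col]][bad[1L]], "'")
  }
  check_enum("level", c("A", "B", "C", "D"))
  check_enum("pattern_kind", c("exact", "class", "amplification", "fusion"))
  expected_tier <- ifelse(kb$level %in% c("A", "B"), 1L, 2L)
  bad <- which(kb$tier != expected_tier)
  if (length(bad))
    stop("knowledge row ", bad[1L], ": tier ", kb$tier[bad[1L]],
         " inconsistent with level ", kb$level[bad[1L]])
  key <- paste(kb$gene, kb$pattern, kb$pattern_kind, kb$drug)
  if (anyDuplicated(key))
    stop("knowledge row ", which(duplicated(key))[1L], ": duplicate entry")
  kb
}

#' Is a gene amplified at the clinically reportable level?
#'
#' Therapy-relevant amplification uses a strict copy-number cutoff
#' (`cn > 5` by default). This is deliberately distinct from the laxer
#' `cn >= 4` presence threshold used when scoring shared amplifications
#' between the paired biopsies.
#'
#' @param cn_observed Observed gene copy number (>= 0).
#' @param threshold Copy number that must be strictly exceeded.
#' @return Logical.
#' @export
is_amplified_for_therapy <- function(cn_observed, threshold = 5) {
  if (any(cn_observed < 0, na.rm = TRUE)) stop("copy number must be >= 0")
  !is.na(cn_observed) & cn_observed > threshold
}

# label class under the suffix grammar: trailing X (nonsense) or fs
# (frameshift) labels are "truncating"
label_class <- function(label) {
  ifelse(grepl("(X|fs)$", label), "truncating", NA_character_)
}

#' Match a sample pair's alterations to therapy options
#'
#' Collects the pair's events — somatic variants (by gene plus protein
#' label, exact match first, then label class) and therapy-level gene
#' amplifications (strict `cn > therapy_amp_thr`) — and matches them
#' against the knowledge table. When one event matches several
#' interchangeable entries (e.g. multiple first-line TKIs for the same
#' driver), the entry whose drug equals the administered initial therapy
#' is kept alone; otherwise all matches are kept. A match is an
#' *alternative* when its drug differs from the initial therapy, and
#' *BM-exclusive* when its triggering event is present in the bone
#' metastasis but absent from the primary tumor.
#'
#' @param pair A [sample_pair()].
#' @param kb Knowledge table from [load_knowledge()].
#' @param initial_therapy Drug name of the initially administered targeted
#'   therapy; `NA` or `"none"` when the initial regimen had no targeted
#'   component (all matches are then alternatives).
#' @param therapy_amp_thr Strict amplification cutoff for therapy
#'   matching.
#' @return A list of class `therapy_report` with `matches` (one row per
#'   event-drug match: `gene`, `label`, `event`, `drug`, `level`, `tier`,
#'   `present_pt`, `present_bm`, `is_alternative`, `bm_exclusive`),
#'   `alternatives` and `bm_exclusive` subsets, `patient_id` and
#'   `initial_therapy`.
#' @export
match_therapies <- function(pair, kb, initial_therapy = NA,
                            therapy_amp_thr = 5) {
  stopifnot(inherits(pair, "sample_pair"))
  no_initial <- is.na(initial_therapy) || initial_therapy %in% c("", "none")

  events <- collect_events(pair, therapy_amp_thr)
  rows <- list()
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    cand <- match_kb(kb, ev)
    if (!nrow(cand)) next
    if (!no_initial && initial_therapy %in% cand$drug)
      cand <- cand[cand$drug == initial_therapy, , drop = FALSE]
    for (m in seq_len(nrow(cand))) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = ev$gene, label = ev$label, event = ev$event,
        drug = cand$drug[m], level = cand$level[m], tier = cand$tier[m],
        present_pt = ev$present_pt, present_bm = ev$present_bm,
        stringsAsFactors = FALSE
      )
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows)
    else data.frame(gene = character(), label = character(),
                    event = character(), drug = character(),
                    level = character(), tier = integer(),
                    present_pt = logical(), present_bm = logical(),
                    stringsAsFactors = FALSE)
  if (!no_initial && nrow(matches) &&
      !(initial_therapy %in% matches$drug))
    warning("initial therapy '", initial_therapy,
            "' matches no event; counting all matches as alternatives")
  matches$is_alternative <- if (no_initial) rep(TRUE, nrow(matches))
    else matches$drug != initial_therapy
  matches$bm_exclusive <- matches$present_bm & !matches$present_pt

  structure(list(
    patient_id = pair$patient_id,
    initial_therapy = if (no_initial) NA_character_ else initial_therapy,
    matches = matches,
    alternatives = matches[matches$is_alternative, , drop = FALSE],
    bm_exclusive = matches[matches$bm_exclusive, , drop = FALSE]
  ), class = "therapy_report")
}

# one row per distinct event with per-sample presence
collect_events <- function(pair, therapy_amp_thr) {
  m <- match_variants(pair$pt$variants, pair$bm$variants)
  var_rows <- rbind(
    if (nrow(m$matched)) data.frame(
      gene = m$matched$gene, label = m$matched$label,
      event = m$matched$variant_type,
      present_pt = TRUE, present_bm = TRUE, stringsAsFactors = FALSE),
    if (nrow(m$pt_only)) data.frame(
      gene = m$pt_only$gene, label = m$pt_only$label,
      event = m$pt_only$variant_type,
      present_pt = TRUE, present_bm = FALSE, stringsAsFactors = FALSE),
    if (nrow(m$bm_only)) data.frame(
      gene = m$bm_only$gene, label = m$bm_only$label,
      event = m$bm_only$variant_type,
      present_pt = FALSE, present_bm = TRUE, stringsAsFactors = FALSE)
  )
  amp_in <- function(calls) {
    if (is.null(calls) || !nrow(calls)) return(character(0))
    calls$gene[is_amplified_for_therapy(calls$cn_observed,
                                        therapy_amp_thr)]
  }
  pt_amp <- amp_in(pair$pt$gene_calls)
  bm_amp <- amp_in(pair$bm$gene_calls)
  amp_genes <- union(pt_amp, bm_amp)
  amp_rows <- if (length(amp_genes)) data.frame(
    gene = amp_genes, label = "amplification", event = "amplification",
    present_pt = amp_genes %in% pt_amp, present_bm = amp_genes %in% bm_amp,
    stringsAsFactors = FALSE)
  out <- rbind(var_rows, amp_rows)
  if (is.null(out)) out <- data.frame(gene = character(),
                                      label = character(),
                                      event = character(),
                                      present_pt = logical(),
                                      present_bm = logical())
  out
}

# kb candidates for one event; exact label match takes precedence over
# label-class match
match_kb <- function(kb, ev) {
  gk <- kb[kb$gene == ev$gene, , drop = FALSE]
  if (!nrow(gk)) return(gk)
  if (ev$event == "amplification")
    return(gk[gk$pattern_kind == "amplification", , drop = FALSE])
  if (ev$event == "fusion")
    return(gk[gk$pattern_kind == "fusion", , drop = FALSE])
  exact <- gk[gk$pattern_kind == "exact" & gk$pattern == ev$label, ,
              drop = FALSE]
  if (nrow(exact)) return(exact)
  cls <- label_class(ev$label)
  if (is.na(cls)) return(exact)
  gk[gk$pattern_kind == "class" & gk$pattern == cls, , drop = FALSE]
}

#' Cohort-level actionability summary
#'
#' @param reports List of `therapy_report` objects.
#' @return A list with `n_patients`, `n_with_alternatives` (patients with
#'   at least one drug option beyond the initial therapy),
#'   `n_with_bm_exclusive` (patients with at least one treatable event
#'   found only in the bone metastasis), per-level match tallies, and the
#'   patient id lists behind the two counts.
#' @export
cohort_actionability <- function(reports) {
  if (!length(reports)) stop("need at least one therapy report")
  has_alt <- vapply(reports, function(r) nrow(r$alternatives) > 0L,
                    logical(1))
  has_bme <- vapply(reports, function(r) nrow(r$bm_exclusive) > 0L,
                    logical(1))
  ids <- vapply(reports, function(r) as.character(r$patient_id),
                character(1))
  levels <- unlist(lapply(reports, function(r) r$matches$level))
  list(
    n_patients = length(reports),
    n_with_alternatives = sum(has_alt),
    n_with_bm_exclusive = sum(has_bme),
    patients_with_alternatives = ids[has_alt],
    patients_with_bm_exclusive = ids[has_bme],
    matches_per_level = table(factor(levels, levels = c("A", "B", "C", "D")))
  )
}
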