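#' Bundled cohort fixtures
#'
#' The package ships machine-readable transcriptions of the 17-patient
#' cohort: per-patient clinical records (rapid hotspot-PCR results,
#' histology purities, treatments) and the per-patient treatable-variant
#' table with drug options and evidence levels. Loaders verify a pinned
#' checksum so silent edits of the bundled data are caught.
#'
#' @param path Path to the TSV; defaults to the bundled file.
#' @param check_hash Verify the bundled file's checksum (only applied to
#'   the default path).
#' @return `load_table1()`: one `data.frame` row per patient;
#'   `load_table2()`: one row per reported treatable event.
#' @name cohort_fixtures
NULL

pp_extdata <- function(file) {
  system.file("extdata", file, package = "pairedpanel", mustWork = TRUE)
}

.fixture_md5 <- c(
  table1_patients.tsv = "3afb6a3f69fa50202b6706aa3a7afa60",
  table2_variants.tsv = "c92faa19765ced05260c94a48e23ed09"
)

check_fixture_hash <- function(path) {
  want <- .fixture_md5[basename(path)]
  if (is.na(want)) return(invisible(TRUE))
  got <- unname(tools::md5sum(path))
  if (!identical(got, unname(want)))
    stop("bundled fixture ", basename(path),
         " failed its checksum; the file has been modified")
  invisible(TRUE)
}

#' @rdname cohort_fixtures
#' @export
load_table1 <- function(path = pp_extdata("table1_patients.tsv"),
                        check_hash = TRUE) {
  default <- identical(path, pp_extdata("table1_patients.tsv"))
  if (default && check_hash) check_fixture_hash(path)
  tab <- utils::read.delim(path, comment.char = "#", quote = "",
                           stringsAsFactors = FALSE)
  arms_levels <- c("E19del", "L858R", "G719X", "L861Q", "EML4-ALK",
                   "negative", "NT")
  bad <- setdiff(c(tab$arms_pt, tab$arms_bm), arms_levels)
  if (length(bad)) stop("invalid ARMS result(s): ",
                        paste(bad, collapse = ", "))
  if (any(tab$purity_pt <= 0 | tab$purity_pt > 1 |
            tab$purity_bm <= 0 | tab$purity_bm > 1))
    stop("purities must lie in (0, 1]")
  tab
}

#' @rdname cohort_fixtures
#' @export
load_table2 <- function(path = pp_extdata("table2_variants.tsv"),
                        check_hash = TRUE) {
  default <- identical(path, pp_extdata("table2_variants.tsv"))
  if (default && check_hash) check_fixture_hash(path)
  tab <- utils::read.delim(path, comment.char = "#", quote = "",
                           stringsAsFactors = FALSE)
  if (!all(tab$level %in% c("A", "B", "C", "D")))
    stop("evidence level outside A-D")
  if (!all(tab$event_kind %in% c("mutation", "amplification", "fusion")))
    stop("invalid event_kind")
  tab
}

#' Tally rapid hotspot-PCR categories over the cohort
#'
#' A patient is EGFR-positive when either biopsy carries any EGFR-class
#' result (E19del, L858R, G719X, L861Q); fusion-positive and fully
#' negative patients are tallied separately ("NT" results are ignored).
#'
#' @param records Output of [load_table1()].
#' @return Named list of counts: `egfr_positive`, `e19del`, `l858r`,
#'   `g719x`, `l861q`, `alk_fusion`, `negative`.
#' @export
count_arms_positive <- function(records) {
  egfr_classes <- c("E19del", "L858R", "G719X", "L861Q")
  per_class <- function(cls) {
    sum(records$arms_pt %in% cls | records$arms_bm %in% cls)
  }
  positive <- records$arms_pt %in% c(egfr_classes, "EML4-ALK") |
    records$arms_bm %in% c(egfr_classes, "EML4-ALK")
  list(
    egfr_positive = per_class(egfr_classes),
    e19del = per_class("E19del"),
    l858r = per_class("L858R"),
    g719x = per_class("G719X"),
    l861q = per_class("L861Q"),
    alk_fusion = per_class("EML4-ALK"),
    negative = sum(!positive)
  )
}

#' Reconstruct sample pairs from the treatable-variant fixture
#'
#' Adapter from the printed per-patient rows to the pipeline's types:
#' mutation and fusion rows become per-sample somatic variant tables
#' (sides printed "negative" are absent; printed parenthetical numbers are
#' carried along uninterpreted as `printed`), and amplification rows
#' become minimal gene-call tables carrying the observed copy number.
#' Purities are joined from the patient table.
#'
#' @param table2 Output of [load_table2()].
#' @param table1 Output of [load_table1()].
#' @return Named list of [sample_pair()] objects, one per patient, in
#'   patient order.
#' @export
table2_to_sample_pairs <- function(table2 = load_table2(),
                                   table1 = load_table1()) {
  pairs <- list()
  for (pid in unique(table1$patient_id)) {
    rows <- table2[table2$patient_id == pid, , drop = FALSE]
    side <- function(s) {
      lab <- rows[[paste0(s, "_label")]]
      printed <- rows[[paste0(s, "_printed")]]
      mut <- rows$event_kind %in% c("mutation", "fusion") &
        !is.na(lab) & lab != "negative"
      variants <- data.frame(
        gene = rows$gene[mut],
        label = lab[mut],
        variant_type = rows$variant_type[mut],
        vaf = rep(NA_real_, sum(mut)),
        printed = printed[mut],
        stringsAsFactors = FALSE
      )
      amp <- rows$event_kind == "amplification"
      gene_calls <- data.frame(
        gene = rows$gene[amp],
        status = ifelse(rows[[paste0(s, "_label")]][amp] == "amplification",
                        "amplification", "neutral"),
        cn_observed = rows[[paste0(s, "_cn")]][amp],
        stringsAsFactors = FALSE
      )
      list(variants = variants, gene_calls = gene_calls,
           purity = table1[[paste0("purity_", s)]][
             table1$patient_id == pid])
    }
    pairs[[pid]] <- sample_pair(pid, side("pt"), side("bm"))
  }
  pairs
}

#' Therapy reports for the bundled cohort
#'
#' Runs [match_therapies()] for every patient reconstructed by
#' [table2_to_sample_pairs()], using each patient's recorded initial
#' targeted therapy.
#'
#' @param kb Knowledge table.
#' @param table2,table1 Fixture tables.
#' @return Named list of `therapy_report` objects.
#' @export
fixture_therapy_reports <- function(kb = load_knowledge(),
                                    table2 = load_table2(),
                                    table1 = load_table1()) {
  pairs <- table2_to_sample_pairs(table2, table1)
  lapply(pairs, function(pair) {
    initial <- table1$initial_targeted[table1$patient_id == pair$patient_id]
    match_therapies(pair, kb, initial_therapy = initial)
  })
}
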