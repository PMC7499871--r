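#' Filter read records on mapping quality
#'
#' Removes low mapping quality records before molecule deduplication.
#' Records with `mapq >= threshold` are retained (the default drops
#' MAPQ < 20), in their input order.
#'
#' @param records `data.frame` with at least columns `barcode`, `chrom`,
#'   `start`, `end`, `mapq` (0-based half-open coordinates).
#' @param threshold Minimum mapping quality retained.
#' @return The retained records, input order preserved.
#' @export
filter_mapq <- function(records, threshold = 20L) {
  validate_records(records)
  records[records$mapq >= threshold, , drop = FALSE]
}

#' Collapse read records to unique barcoded molecules
#'
#' PCR duplicates share the molecular barcode and the exact start and stop
#' positions of the original molecule; each (barcode, chrom, start, end)
#' group is collapsed to one representative record. The representative is
#' the highest-MAPQ member, ties broken by input order, and the output
#' keeps the representatives' input order.
#'
#' @param records MAPQ-filtered read records.
#' @return One record per unique molecule.
#' @export
dedup_molecules <- function(records) {
  validate_records(records)
  if (nrow(records) == 0L) return(records)
  key <- paste(records$barcode, records$chrom, records$start, records$end,
               sep = "\r")
  # within each key pick max mapq, first occurrence on ties
  ord <- order(key, -records$mapq, seq_len(nrow(records)), method = "radix")
  first <- !duplicated(key[ord])
  keep <- sort(ord[first])
  records[keep, , drop = FALSE]
}

#' Per-target unique-molecule counts and average depth of coverage
#'
#' For every panel target, counts deduplicated molecules overlapping it by
#' at least one base and computes the average per-base depth of coverage
#' (sum of overlap lengths divided by target length). Molecules on
#' chromosomes absent from the panel are counted nowhere and reported via
#' a message.
#'
#' @param molecules Deduplicated read records.
#' @param panel Panel `data.frame`.
#' @return `data.frame` in panel order with columns `target_id`,
#'   `unique_molecules`, `doc`.
#' @export
depth_of_coverage <- function(molecules, panel) {
  validate_records(molecules)
  validate_panel(panel)

  n <- nrow(panel)
  counts <- integer(n)
  cov_bases <- numeric(n)
  off_panel <- 0L
  for (chr in unique(molecules$chrom)) {
    mi <- which(molecules$chrom == chr)
    ti <- which(panel$chrom == chr)
    if (!length(ti)) {
      off_panel <- off_panel + length(mi)
      next
    }
    mr <- IRanges::IRanges(start = molecules$start[mi] + 1L,
                           end = molecules$end[mi])
    tr <- IRanges::IRanges(start = panel$start[ti] + 1L,
                           end = panel$end[ti])
    hits <- IRanges::findOverlaps(mr, tr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(IRanges::end(mr)[qh], IRanges::end(tr)[sh]) -
      pmax(IRanges::start(mr)[qh], IRanges::start(tr)[sh]) + 1L
    tab <- tapply(ov, ti[sh], sum)
    idx <- as.integer(names(tab))
    cov_bases[idx] <- cov_bases[idx] + as.numeric(tab)
    cnt <- table(ti[sh])
    idx <- as.integer(names(cnt))
    counts[idx] <- counts[idx] + as.integer(cnt)
  }
  if (off_panel > 0L)
    message(off_panel, " molecule(s) on chromosomes absent from the panel ",
            "were ignored")
  data.frame(
    target_id = panel$target_id,
    unique_molecules = counts,
    doc = cov_bases / (panel$end - panel$start),
    stringsAsFactors = FALSE
  )
}

#' Read / write read-record TSVs
#'
#' Native flat format for read records: tab-separated with header
#' `barcode`, `chrom`, `start`, `end`, `mapq`.
#'
#' @param path File path.
#' @param records Read-record `data.frame`.
#' @return `read_records_tsv()` returns the records; `write_records_tsv()`
#'   returns `path` invisibly.
#' @export
read_records_tsv <- function(path) {
  records <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_records(records)
  records
}

#' @rdname read_records_tsv
#' @export
write_records_tsv <- function(records, path) {
  validate_records(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_records <- function(records) {
  req <- c("barcode", "chrom", "start", "end", "mapq")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("read records missing column(s): ", paste(missing, collapse = ", "))
  if (any(records$end <= records$start))
    stop("read records must satisfy end > start")
  invisible(records)
}
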