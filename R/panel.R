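#' Simulate a targeted capture panel
#'
#' Builds a gene-annotated target panel of the kind used for hybrid-capture
#' tumor sequencing: short targets (probes) grouped by gene, spread over
#' autosomes, each with a GC fraction. The panel is the coordinate backbone
#' for depth quantification, normalization and segmentation.
#'
#' @param n_genes Number of genes on the panel (the study design uses a
#'   457-gene pan-cancer panel).
#' @param targets_per_gene Either a single integer (fixed target count per
#'   gene) or an integer vector of length 2 giving an inclusive range from
#'   which per-gene target counts are drawn uniformly. The default `c(4, 8)`
#'   yields a realistic mix in which a minority of genes fall under the
#'   five-target floor used by the gene-level caller.
#' @param target_length Inclusive range of target lengths in bp.
#' @param gc_range Inclusive range of per-target GC fractions (drawn
#'   uniformly).
#' @param n_chroms Number of chromosomes genes are distributed over.
#' @param seed Integer seed; all randomness is local to this call.
#'
#' @return A `data.frame` with columns `target_id`, `gene`, `chrom`,
#'   `start`, `end` (0-based, half-open) and `gc_fraction`, sorted by
#'   (chrom, start) with each gene's targets contiguous.
#' @export
make_panel <- function(n_genes,
                       targets_per_gene = c(4L, 8L),
                       target_length = c(120L, 300L),
                       gc_range = c(0.3, 0.7),
                       n_chroms = 22L,
                       seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop("`n_genes` must be a positive integer")
  n_genes <- as.integer(n_genes)

  rng <- local_rng(seed)
  on.exit(rng())

  if (length(targets_per_gene) == 1L)
    targets_per_gene <- rep(targets_per_gene, 2L)
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  n_tgt <- sample_int_range(targets_per_gene, n_genes)
  chrom_of_gene <- sprintf("chr%d", 1L + (seq_len(n_genes) - 1L) %% n_chroms)

  rows <- vector("list", n_genes)
  pos <- integer(n_chroms)
  names(pos) <- sprintf("chr%d", seq_len(n_chroms))
  for (g in seq_len(n_genes)) {
    k <- n_tgt[g]
    len <- sample_int_range(target_length, k)
    chrom <- chrom_of_gene[g]
    # intergenic gap then intra-gene gaps between consecutive targets
    start <- pos[chrom] + 5000L + cumsum(c(0L, len[-k] + 500L))
    pos[chrom] <- start[k] + len[k]
    rows[[g]] <- data.frame(
      gene = genes[g],
      chrom = chrom,
      start = start,
      end = start + len,
      gc_fraction = round(stats::runif(k, gc_range[1L], gc_range[2L]), 4L),
      stringsAsFactors = FALSE
    )
  }
  panel <- do.call(rbind, rows)
  panel <- panel[order(chrom_rank(panel$chrom), panel$start), , drop = FALSE]
  panel <- data.frame(
    target_id = sprintf("T%05d", seq_len(nrow(panel))),
    panel,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  panel
}

#' Validate a panel data.frame
#'
#' Checks the structural invariants every downstream stage relies on:
#' required columns, positive-width 0-based half-open intervals, sorting by
#' (chrom, start), and contiguity of each gene's targets in panel order.
#'
#' @param panel A panel `data.frame` as produced by [make_panel()] or
#'   [read_panel_bed()].
#' @return The panel, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_panel <- function(panel) {
  req <- c("target_id", "gene", "chrom", "start", "end", "gc_fraction")
  missing <- setdiff(req, names(panel))
  if (length(missing))
    stop("panel is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(panel) == 0L) stop("panel has no targets")
  if (anyDuplicated(panel$target_id))
    stop("panel target_id values must be unique")
  if (any(panel$end <= panel$start))
    stop("panel targets must satisfy end > start")
  if (any(panel$gc_fraction < 0 | panel$gc_fraction > 1))
    stop("gc_fraction must lie in [0, 1]")
  ord <- order(chrom_rank(panel$chrom), panel$start)
  if (!identical(ord, seq_len(nrow(panel))))
    stop("panel targets must be sorted by (chrom, start)")
  runs <- rle(panel$gene)
  if (anyDuplicated(runs$values))
    stop("each gene's targets must be contiguous in panel order")
  invisible(panel)
}

#' Write / read a panel as BED6+2
#'
#' The on-disk format is BED6 plus two extra columns (`gene`,
#' `gc_fraction`); coordinates are 0-based half-open as in BED. `score` is
#' written as 0 and `strand` as `.`.
#'
#' @param panel A validated panel `data.frame`.
#' @param path File path.
#' @return `write_panel_bed()` returns `path` invisibly; `read_panel_bed()`
#'   returns a validated panel `data.frame`.
#' @export
write_panel_bed <- function(panel, path) {
  validate_panel(panel)
  bed <- data.frame(panel$chrom, panel$start, panel$end, panel$target_id,
                    0L, ".", panel$gene, panel$gc_fraction)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_bed
#' @export
read_panel_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 8L) stop("expected BED6+2 with gene and gc_fraction")
  panel <- data.frame(
    target_id = as.character(bed[[4L]]),
    gene = as.character(bed[[7L]]),
    chrom = as.character(bed[[1L]]),
    start = as.integer(bed[[2L]]),
    end = as.integer(bed[[3L]]),
    gc_fraction = as.numeric(bed[[8L]]),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  panel
}

# uniform integers from an inclusive range; safe when the range collapses
# to one value (sample() would otherwise treat it as 1:x)
sample_int_range <- function(range, n) {
  vals <- seq.int(range[1L], range[2L])
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

# numeric-aware chromosome ordering: chr1 < chr2 < ... < chr10 < chrX
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(core))
  num[is.na(num)] <- 1000L + as.integer(factor(core[is.na(num)]))
  num
}

# Run code under a locally-seeded RNG without touching the caller's stream.
# Returns a restore function for on.exit().
local_rng <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
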