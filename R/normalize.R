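#' GC-correct per-target depths by LOESS
#'
#' Fits a locally weighted regression of depth of coverage on target GC
#' fraction and rescales each target multiplicatively so the fitted GC
#' trend is flattened while the global mean depth is preserved:
#' `gc_corrected = doc * mean(doc) / fitted(gc)`. Tumor and matched normal
#' samples are corrected separately — this function sees exactly one
#' sample.
#'
#' Targets whose fitted value is not positive are flagged (`flagged =
#' TRUE`, `gc_corrected = NA`) and should be excluded downstream. If all
#' targets share one GC value the fit is degenerate and the correction
#' reduces to a pure global rescale to the mean (i.e. no change in
#' relative depths).
#'
#' @param rows Depth table with columns `target_id` and `doc` (or
#'   `unique_molecules`, used when `doc` is absent).
#' @param panel Panel `data.frame` supplying `gc_fraction` per target.
#' @param span LOESS span.
#' @param degree LOESS polynomial degree.
#' @param iterations Robustness iterations of the symmetric LOESS fit.
#' @param min_targets Minimum number of positive-depth targets required to
#'   attempt a fit.
#' @return `data.frame` in input order: `target_id`, `raw_doc`,
#'   `gc_corrected`, `flagged`.
#' @export
gc_correct <- function(rows, panel, span = 0.3, degree = 1L,
                       iterations = 2L, min_targets = 20L) {
  doc <- depth_column(rows)
  idx <- match(rows$target_id, panel$target_id)
  if (anyNA(idx)) stop("depth rows contain target_id values not on the panel")
  gc <- panel$gc_fraction[idx]

  if (sum(doc > 0) < min_targets)
    stop("GC correction needs at least ", min_targets,
         " targets with positive depth; got ", sum(doc > 0))

  if (stats::var(gc) == 0) {
    fitted <- rep(mean(doc), length(doc))
  } else {
    fit <- stats::loess(doc ~ gc, span = span, degree = degree,
                        family = "symmetric",
                        control = stats::loess.control(
                          surface = "direct", iterations = iterations))
    fitted <- stats::predict(fit, data.frame(gc = gc))
  }
  flagged <- !is.finite(fitted) | fitted <= 0
  corrected <- ifelse(flagged, NA_real_, doc * mean(doc) / fitted)
  data.frame(
    target_id = rows$target_id,
    raw_doc = doc,
    gc_corrected = corrected,
    flagged = flagged,
    stringsAsFactors = FALSE
  )
}

#' RPKM-normalize GC-corrected depths
#'
#' Converts per-target corrected molecule counts to reads per kilobase of
#' target per million molecules:
#' `rpkm = count * 1e9 / (target_length_bp * total_count_in_sample)`,
#' making profiles comparable across samples of different total yield.
#'
#' @param rows Output of [gc_correct()] (columns `target_id`,
#'   `gc_corrected`, `flagged`), or any depth table with a `gc_corrected`
#'   column.
#' @param panel Panel `data.frame` supplying target lengths.
#' @return `rows` with an `rpkm` column appended (NA for flagged targets).
#' @export
rpkm <- function(rows, panel) {
  if (is.null(rows$gc_corrected))
    stop("`rows` must carry a gc_corrected column (run gc_correct first)")
  idx <- match(rows$target_id, panel$target_id)
  if (anyNA(idx)) stop("depth rows contain target_id values not on the panel")
  len <- panel$end[idx] - panel$start[idx]
  total <- sum(rows$gc_corrected, na.rm = TRUE)
  if (total <= 0) stop("total molecule count is zero; cannot RPKM-normalize")
  rows$rpkm <- rows$gc_corrected * 1e9 / (len * total)
  rows
}

#' Normalize one sample end-to-end (GC correction then RPKM)
#'
#' @inheritParams gc_correct
#' @param ... Passed through to [gc_correct()].
#' @return The GC-corrected, RPKM-normalized depth table.
#' @export
normalize_sample <- function(rows, panel, ...) {
  rpkm(gc_correct(rows, panel, ...), panel)
}

depth_column <- function(rows) {
  if (!is.null(rows$doc)) return(as.numeric(rows$doc))
  if (!is.null(rows$unique_molecules))
    return(as.numeric(rows$unique_molecules))
  stop("depth table needs a `doc` or `unique_molecules` column")
}
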