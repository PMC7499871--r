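# shared in-code fixtures for the test suite

# minimal hand-built panel: 3 genes on 2 chromosomes, known coordinates
tiny_panel <- function() {
  panel <- data.frame(
    target_id = sprintf("T%02d", 1:12),
    gene = rep(c("GA", "GB", "GC"), times = c(5, 4, 3)),
    chrom = rep(c("chr1", "chr2"), times = c(9, 3)),
    start = c(seq(0, 4000, by = 1000)[1:5],
              seq(0, 3000, by = 1000)[1:4] + 10000,
              seq(0, 2000, by = 1000)[1:3]),
    end = NA,
    gc_fraction = seq(0.3, 0.7, length.out = 12),
    stringsAsFactors = FALSE
  )
  panel$end <- panel$start + 200L
  validate_panel(panel)
  panel
}

make_records <- function(barcode, chrom, start, end, mapq) {
  data.frame(barcode = barcode, chrom = chrom, start = start, end = end,
             mapq = mapq, stringsAsFactors = FALSE)
}

# variant table helper (handles zero-length gene vectors)
vt <- function(gene, label, vaf = 0.3, type = "snv") {
  n <- length(gene)
  data.frame(gene = gene, label = label,
             variant_type = rep_len(type, n), vaf = rep_len(vaf, n),
             stringsAsFactors = FALSE)
}

# exhaustive-search oracle for the maximal circular arc t-statistic:
# naive double loop over all (i, j) arc boundaries, pooled-variance
# two-sample t with the same variance floor as the scan under test
bf_max_arc <- function(x, min_width = 2L) {
  n <- length(x)
  best <- -Inf; bi <- -1L; bj <- -1L
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i
      if (k < min_width || k > n - min_width) next
      arc <- x[(i + 1):j]
      comp <- x[-((i + 1):j)]
      m1 <- mean(arc); m2 <- mean(comp)
      v <- (sum(x^2) - k * m1^2 - (n - k) * m2^2) / (n - 2)
      v <- max(v, 1e-12)
      tt <- abs(m1 - m2) / sqrt(v * (1 / k + 1 / (n - k)))
      if (tt > best + 1e-12) { best <- tt; bi <- i; bj <- j }
    }
  }
  list(i = bi, j = bj, stat = best)
}

# an arc and its complement define the same circular split; reduce (i, j)
# to the set of interior cut positions for comparisons
cut_set <- function(i, j, n) sort(setdiff(c(i, j), c(0L, n)))

# single-chromosome profile wrapper for segmentation tests
as_profile <- function(x, chrom = "chr1", gene = "G") {
  structure(data.frame(
    target_id = sprintf("T%04d", seq_along(x)),
    gene = gene, chrom = chrom, log2_ratio = x,
    masked = FALSE, stringsAsFactors = FALSE
  ), class = c("log_ratio_profile", "data.frame"))
}
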