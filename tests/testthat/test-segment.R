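norm_table <- function(panel, rpkm_values) {
  data.frame(target_id = panel$target_id, gc_corrected = rpkm_values,
             rpkm = rpkm_values, flagged = FALSE, stringsAsFactors = FALSE)
}

test_that("log ratios follow log2(tumor/normal) with masking", {
  panel <- tiny_panel()
  base <- norm_table(panel, rep(100, 12))
  # identical tables -> all zero
  expect_equal(log_ratio(base, base, panel)$log2_ratio, rep(0, 12))
  # tumor doubled everywhere -> ~1 (pseudocount is negligible at 100)
  doubled <- norm_table(panel, rep(200, 12))
  expect_equal(log_ratio(doubled, base, panel)$log2_ratio, rep(1, 12),
               tolerance = 1e-4)
  # hand-computed 4-value check, pseudocount included exactly
  pc <- 1e-3
  tum <- norm_table(panel, c(50, 100, 25, 400, rep(100, 8)))
  lr <- log_ratio(tum, base, panel, pseudocount = pc)$log2_ratio[1:4]
  expect_equal(lr, log2((c(50, 100, 25, 400) + pc) / (100 + pc)))
})

test_that("unreliable normal targets are masked, order mismatches refused", {
  panel <- tiny_panel()
  nrm <- norm_table(panel, c(rep(100, 11), 2))   # last below 10% of median
  tum <- norm_table(panel, rep(100, 12))
  prof <- log_ratio(tum, nrm, panel)
  expect_equal(prof$masked, c(rep(FALSE, 11), TRUE))
  shuffled <- tum[c(2, 1, 3:12), ]
  expect_error(log_ratio(shuffled, nrm, panel), "order")
})

test_that("constant profiles return one segment per chromosome", {
  prof <- as_profile(rep(0.2, 25))
  segs <- cbs_segment(prof, seed = 1)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$segment_value, 0.2)
  expect_equal(segs$start, 1)
  expect_equal(segs$end, 26)

  two_chrom <- as_profile(rep(0.2, 20))
  two_chrom$chrom <- rep(c("chr1", "chr2"), each = 10)
  expect_equal(nrow(cbs_segment(two_chrom, seed = 1)), 2)
})

test_that("a noise-free step splits exactly at the boundary", {
  prof <- as_profile(c(rep(0, 20), rep(1, 20)))
  segs <- cbs_segment(prof, seed = 1)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start, c(1, 21))
  expect_equal(segs$end, c(21, 41))
  expect_equal(segs$segment_value, c(0, 1))
})

test_that("the scan agrees with the exhaustive arc-search oracle", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(6:30, 1)
    x <- rnorm(n) + rep(c(0, sample(c(0, 1.5), 1)), each = ceiling(n / 2))[1:n]
    got <- pairedpanel:::cpp_cbs_scan(x, 2L)
    want <- bf_max_arc(x, 2L)
    expect_equal(got$stat, want$stat, tolerance = 1e-9)
    expect_equal(cut_set(got$i, got$j, n), cut_set(want$i, want$j, n))
  }
})

test_that("segmentation is deterministic given a seed", {
  set.seed(3)
  x <- rnorm(60) + rep(c(0, 1, 0), times = c(20, 20, 20))
  prof <- as_profile(x)
  expect_identical(cbs_segment(prof, seed = 9), cbs_segment(prof, seed = 9))
})

test_that("segment means reconstruct the profile mean exactly", {
  set.seed(5)
  x <- rnorm(80) + rep(c(-1, 0, 2, 0), each = 20)
  prof <- as_profile(x)
  segs <- cbs_segment(prof, seed = 2)
  expect_equal(sum(segs$num_targets * segs$segment_value) / length(x),
               mean(x), tolerance = 1e-12)
  # partition: starts/ends chain over the whole profile
  expect_equal(segs$start[1], 1)
  expect_equal(segs$end[nrow(segs)], length(x) + 1)
  if (nrow(segs) > 1)
    expect_equal(segs$start[-1], segs$end[-nrow(segs)])
})

test_that("tightening alpha never yields more segments", {
  set.seed(6)
  x <- rnorm(60, sd = 0.3) + rep(c(0, 1, 0), each = 20)
  prof <- as_profile(x)
  loose <- nrow(cbs_segment(prof, alpha = 0.05, seed = 4))
  tight <- nrow(cbs_segment(prof, alpha = 1e-4, seed = 4))
  expect_lte(tight, loose)
})

test_that("SEG export carries genomic coordinates", {
  panel <- make_panel(4, targets_per_gene = 10, n_chroms = 1, seed = 8)
  x <- rep(c(0, 1), each = 20)
  prof <- as_profile(x, chrom = "chr1")
  prof$target_id <- panel$target_id
  segs <- cbs_segment(prof, seed = 1)
  seg <- as_seg(segs, prof, panel, sample_id = "S1")
  expect_equal(names(seg),
               c("ID", "chrom", "loc.start", "loc.end", "num.mark",
                 "seg.mean"))
  expect_equal(seg$loc.start[1], panel$start[1])
  expect_equal(seg$loc.end[nrow(seg)], panel$end[40])
})
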