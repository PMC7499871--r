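test_that("mapping-quality filter keeps MAPQ >= 20 and preserves order", {
  rec <- make_records(c("b1", "b2", "b3"), "chr1",
                      c(0, 10, 20), c(100, 110, 120), c(19, 20, 60))
  kept <- filter_mapq(rec)
  expect_equal(kept$barcode, c("b2", "b3"))   # 19 removed, 20 retained
  expect_equal(filter_mapq(rec[0, ]), rec[0, ])
})

test_that("dedup collapses on (barcode, chrom, start, end) exactly", {
  # same barcode and coordinates: PCR duplicates -> one molecule
  dup <- make_records(c("b1", "b1"), "chr1", c(0, 0), c(150, 150), c(30, 40))
  expect_equal(nrow(dedup_molecules(dup)), 1)
  expect_equal(dedup_molecules(dup)$mapq, 40)  # highest-MAPQ representative

  # distinct barcodes at identical coordinates are distinct molecules
  two_bc <- make_records(c("b1", "b2"), "chr1", c(0, 0), c(150, 150), c(30, 30))
  expect_equal(nrow(dedup_molecules(two_bc)), 2)

  # a different stop position is a different molecule
  two_end <- make_records(c("b1", "b1"), "chr1", c(0, 0), c(150, 151), c(30, 30))
  expect_equal(nrow(dedup_molecules(two_end)), 2)
})

test_that("dedup is idempotent, ties break by input order", {
  set.seed(21)
  rec <- make_records(
    barcode = sample(c("a", "b", "c"), 40, replace = TRUE),
    chrom = "chr1",
    start = sample(c(0, 100), 40, replace = TRUE),
    end = sample(c(200, 300), 40, replace = TRUE),
    mapq = sample(c(20, 30, 30, 60), 40, replace = TRUE)
  )
  once <- dedup_molecules(rec)
  expect_identical(dedup_molecules(once), once)

  tie <- make_records(c("b1", "b1"), "chr1", c(0, 0), c(150, 150), c(30, 30))
  tie$tag <- c("first", "second")
  expect_equal(dedup_molecules(tie)$tag, "first")
})

test_that("depth of coverage matches the interval definitions", {
  panel <- tiny_panel()   # targets are 200 bp
  # one molecule exactly spanning target T01
  exact <- make_records("b1", "chr1", panel$start[1], panel$end[1], 60)
  doc <- depth_of_coverage(exact, panel)
  expect_equal(doc$unique_molecules[1], 1)
  expect_equal(doc$doc[1], 1.0)
  expect_true(all(doc$unique_molecules[-1] == 0))

  # half-covering molecule
  half <- make_records("b1", "chr1", panel$start[1], panel$start[1] + 100, 60)
  expect_equal(depth_of_coverage(half, panel)$doc[1], 0.5)

  # off-panel chromosome is ignored with a message
  off <- make_records("b1", "chrZ", 0, 100, 60)
  expect_message(res <- depth_of_coverage(off, panel), "ignored")
  expect_true(all(res$unique_molecules == 0))
})

test_that("depth of coverage equals a per-base pileup oracle", {
  panel <- tiny_panel()
  set.seed(8)
  n <- 100
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- sample(0:12000, n, replace = TRUE)
  mol <- make_records(sprintf("b%03d", 1:n), chrom, start,
                      start + sample(80:400, n, replace = TRUE), 60)
  res <- depth_of_coverage(mol, panel)

  # oracle: count molecules covering every single base of each target
  for (t in seq_len(nrow(panel))) {
    bases <- (panel$start[t] + 1):panel$end[t]   # 1-based base centers
    pile <- vapply(bases, function(b) {
      sum(mol$chrom == panel$chrom[t] & mol$start < b & mol$end >= b)
    }, numeric(1))
    expect_equal(res$doc[t], mean(pile), info = panel$target_id[t])
    overlaps <- mol$chrom == panel$chrom[t] &
      mol$start < panel$end[t] & mol$end > panel$start[t]
    expect_equal(res$unique_molecules[t], sum(overlaps))
  }

  # counts invariant to input order
  perm <- mol[sample(nrow(mol)), ]
  expect_equal(depth_of_coverage(perm, panel)$unique_molecules,
               res$unique_molecules)

  # total assigned coverage cannot exceed total molecule footprint
  expect_lte(sum(res$doc * (panel$end - panel$start)),
             sum(mol$end - mol$start))
})
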