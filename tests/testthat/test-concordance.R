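gene_call_row <- function(gene, cn) {
  data.frame(gene = gene, status = "neutral", cn_observed = cn,
             stringsAsFactors = FALSE)
}

pair_of <- function(pt_variants, bm_variants, pt_calls = NULL,
                    bm_calls = NULL) {
  sample_pair("PX",
              pt = list(variants = pt_variants, gene_calls = pt_calls,
                        purity = 0.5),
              bm = list(variants = bm_variants, gene_calls = bm_calls,
                        purity = 0.5))
}

test_that("variant matching joins on gene + label + type", {
  pt <- rbind(vt("EGFR", "E746_A750delELREA", type = "indel"),
              vt("TP53", "L858R"))
  bm <- rbind(vt("EGFR", "E746_A750delELREA", type = "indel"),
              vt("TP53", "L861Q"))
  m <- match_variants(pt, bm)
  expect_equal(nrow(m$matched), 1)
  expect_equal(m$matched$gene, "EGFR")
  expect_equal(nrow(m$pt_only), 1)
  expect_equal(nrow(m$bm_only), 1)

  empty <- vt(character(0), character(0))
  m2 <- match_variants(pt, empty)
  expect_equal(nrow(m2$matched), 0)
  expect_equal(nrow(m2$pt_only), 2)

  expect_error(match_variants(rbind(pt, pt[1, ]), bm), "duplicate")
})

test_that("sharing thresholds are applied per the fingerprint rules", {
  # both VAFs at 5%: shared
  p1 <- pair_of(vt("KRAS", "G12C", 0.05), vt("KRAS", "G12C", 0.05))
  r1 <- score_shared(p1)
  expect_equal(r1$n_shared_snv_indel, 1)
  expect_equal(r1$shared_fraction, 1)

  # one side at 2.9%: matched but not shared
  p2 <- pair_of(vt("KRAS", "G12C", 0.05), vt("KRAS", "G12C", 0.029))
  r2 <- score_shared(p2)
  expect_equal(r2$n_shared_snv_indel, 0)
  expect_equal(r2$n_pt_only, 1)

  # amplification shared at CN exactly 4 (inclusive)
  p3 <- pair_of(vt(character(0), character(0)), vt(character(0), character(0)),
                gene_call_row("CDK4", 4.0), gene_call_row("CDK4", 4.0))
  expect_equal(score_shared(p3)$n_shared_amp, 1)
  # CN 3.9 on one side: not shared
  p4 <- pair_of(vt(character(0), character(0)), vt(character(0), character(0)),
                gene_call_row("CDK4", 4.0), gene_call_row("CDK4", 3.9))
  expect_equal(score_shared(p4)$n_shared_amp, 0)

  # deletion shared at CN <= 1 both sides
  p5 <- pair_of(vt(character(0), character(0)), vt(character(0), character(0)),
                gene_call_row("CDKN2A", 0.8), gene_call_row("CDKN2A", 1.0))
  expect_equal(score_shared(p5)$n_shared_del, 1)
})

test_that("shared counts are symmetric and monotone in the thresholds", {
  pt <- rbind(vt("A", "V1", 0.05), vt("B", "V2", 0.04), vt("C", "V3", 0.2))
  bm <- rbind(vt("A", "V1", 0.06), vt("B", "V2", 0.02), vt("D", "V4", 0.1))
  fwd <- score_shared(pair_of(pt, bm))
  rev <- score_shared(pair_of(bm, pt))
  expect_equal(fwd$n_shared_snv_indel, rev$n_shared_snv_indel)
  expect_equal(fwd$shared_fraction, rev$shared_fraction)

  # raising the VAF threshold cannot increase the shared fraction
  thr <- c(0.01, 0.03, 0.05, 0.08)
  sf <- sapply(thr, function(t) score_shared(pair_of(pt, bm),
                                             vaf_thr = t)$shared_fraction)
  expect_true(all(diff(sf) <= 1e-12))

  # raising amp_thr never increases shared amplifications
  p <- pair_of(vt(character(0), character(0)), vt(character(0), character(0)),
               gene_call_row("X", 4.5), gene_call_row("X", 4.2))
  expect_equal(score_shared(p, amp_thr = 4)$n_shared_amp, 1)
  expect_equal(score_shared(p, amp_thr = 5)$n_shared_amp, 0)
})

test_that("cohort classification splits shared-dominant from divergent", {
  same <- pair_of(rbind(vt("A", "V1", 0.1), vt("B", "V2", 0.1)),
                  rbind(vt("A", "V1", 0.1), vt("B", "V2", 0.1)))
  disjoint <- pair_of(vt("A", "V1", 0.1), vt("B", "V2", 0.1))
  r_same <- score_shared(same)
  r_dis <- score_shared(disjoint)
  expect_equal(r_same$relatedness, "shared_dominant")
  expect_equal(r_dis$relatedness, "divergent")
  expect_equal(r_dis$shared_fraction, 0)

  summary <- classify_cohort(list(r_same, r_dis))
  expect_equal(summary$n_shared_dominant, 1)
  expect_equal(summary$n_divergent, 1)
})
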