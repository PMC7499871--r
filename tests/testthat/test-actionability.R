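kb_lines <- function(...) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("gene\tpattern\tpattern_kind\tdrug\tlevel\ttier\tnote", ...),
             path)
  path
}

test_that("the bundled knowledge table loads and validates", {
  kb <- load_knowledge()
  expect_true(nrow(kb) > 10)
  expect_true(all(kb$level %in% c("A", "B", "C", "D")))
  expect_true(all(kb$tier[kb$level %in% c("A", "B")] == 1))
  expect_true(all(kb$tier[kb$level %in% c("C", "D")] == 2))
  # the published pairings are present
  expect_true(any(kb$gene == "EGFR" & kb$pattern_kind == "amplification" &
                    kb$drug == "Erlotinib" & kb$level == "B"))
  expect_true(any(kb$gene == "KRAS" & kb$pattern == "G12C" &
                    kb$drug == "AMG-510" & kb$level == "B"))
})

test_that("malformed knowledge rows are rejected with their position", {
  expect_error(load_knowledge(kb_lines(
    "EGFR\tL858R\texact\tGefitinib\tE\t1\tx")), "row 1.*level")
  expect_error(load_knowledge(kb_lines(
    "EGFR\tL858R\texact\tGefitinib\tA\t2\tx")), "tier")
  expect_error(load_knowledge(kb_lines(
    "EGFR\tL858R\texact\tGefitinib\tA\t1\tx",
    "EGFR\tL858R\texact\tGefitinib\tA\t1\tdup")), "duplicate")
  expect_error(load_knowledge(kb_lines(
    "EGFR\tL858R\tfuzzy\tGefitinib\tA\t1\tx")), "pattern_kind")
})

test_that("therapy amplification is strictly above the cutoff", {
  expect_true(is_amplified_for_therapy(9))
  expect_false(is_amplified_for_therapy(5.0))   # strict: 5 is not > 5
  expect_false(is_amplified_for_therapy(2))
  expect_true(is_amplified_for_therapy(5.0001))
  expect_error(is_amplified_for_therapy(-1), ">= 0")
})

test_that("a BM-dominant profile yields BM-relevant alternatives", {
  # EGFR exon-19 deletion with BM-only amplification, plus BM-only TP53
  # nonsense mutation: alternatives Erlotinib (B) and AZD1775 (D)
  kb <- load_knowledge()
  pt <- list(variants = vt("EGFR", "E746_A750delELREA", type = "indel"),
             gene_calls = data.frame(gene = "EGFR", status = "neutral",
                                     cn_observed = 1),
             purity = 0.26)
  bm <- list(variants = rbind(vt("EGFR", "E746_A750delELREA", type = "indel"),
                              vt("TP53", "Q331X")),
             gene_calls = data.frame(gene = "EGFR", status = "amplification",
                                     cn_observed = 9),
             purity = 0.32)
  rep6 <- match_therapies(sample_pair("P6x", pt, bm), kb,
                          initial_therapy = "Gefitinib")
  alts <- rep6$alternatives
  expect_setequal(paste(alts$drug, alts$level),
                  c("Erlotinib B", "AZD1775 D"))
  expect_true(all(alts$bm_exclusive))
  # the initial therapy row is present and not an alternative
  ini <- rep6$matches[!rep6$matches$is_alternative, ]
  expect_equal(ini$drug, "Gefitinib")
  expect_equal(ini$level, "A")
})

test_that("without targeted initial therapy all matches are alternatives", {
  kb <- load_knowledge()
  pair <- sample_pair("P17x",
    pt = list(variants = vt("KRAS", "G12C"), gene_calls = NULL, purity = 0.33),
    bm = list(variants = vt("KRAS", "G12C"), gene_calls = NULL, purity = 0.74))
  rep17 <- match_therapies(pair, kb, initial_therapy = "none")
  expect_equal(rep17$matches$drug, "AMG-510")
  expect_equal(rep17$matches$level, "B")
  expect_true(all(rep17$matches$is_alternative))
  expect_equal(nrow(rep17$bm_exclusive), 0)
})

test_that("empty inputs and kb monotonicity behave", {
  kb <- load_knowledge()
  empty <- sample_pair("P0",
    pt = list(variants = vt(character(0), character(0)), gene_calls = NULL,
              purity = 0.5),
    bm = list(variants = vt(character(0), character(0)), gene_calls = NULL,
              purity = 0.5))
  expect_equal(nrow(match_therapies(empty, kb)$matches), 0)

  pair <- sample_pair("P1x",
    pt = list(variants = rbind(vt("KRAS", "G12C"), vt("TP53", "R196X")),
              gene_calls = NULL, purity = 0.5),
    bm = list(variants = rbind(vt("KRAS", "G12C"), vt("TP53", "R196X")),
              gene_calls = NULL, purity = 0.5))
  full <- match_therapies(pair, kb)
  smaller <- match_therapies(pair, kb[kb$gene != "TP53", ])
  expect_lt(nrow(smaller$matches), nrow(full$matches))

  # unknown named initial therapy warns and counts all as alternatives
  expect_warning(r <- match_therapies(pair, kb, initial_therapy = "Imatinib"),
                 "matches no event")
  expect_true(all(r$matches$is_alternative))
})

test_that("label classes map truncating mutations, not missense", {
  kb <- load_knowledge()
  # W3052X is nonsense -> class entry for ATM applies
  pair <- sample_pair("P9x",
    pt = list(variants = vt("ATM", "W3052X"), gene_calls = NULL, purity = 0.6),
    bm = list(variants = vt("ATM", "W3052X"), gene_calls = NULL, purity = 0.57))
  expect_equal(match_therapies(pair, kb)$matches$drug, "Olaparib")
  # frameshift suffix also maps
  pair_fs <- sample_pair("P15x",
    pt = list(variants = vt("TP53", "F134Pfs", type = "indel"),
              gene_calls = NULL, purity = 0.47),
    bm = list(variants = vt("TP53", "F134Pfs", type = "indel"),
              gene_calls = NULL, purity = 0.49))
  expect_equal(match_therapies(pair_fs, kb)$matches$drug, "AZD1775")
  # a missense label with no exact entry matches nothing
  pair_mis <- sample_pair("PXX",
    pt = list(variants = vt("ATM", "V410A"), gene_calls = NULL, purity = 0.5),
    bm = list(variants = vt("ATM", "V410A"), gene_calls = NULL, purity = 0.5))
  expect_equal(nrow(match_therapies(pair_mis, kb)$matches), 0)
})
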