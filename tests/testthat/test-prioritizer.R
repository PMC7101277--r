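test_that("region filter keeps exonic and near-splice variants, literal +/-6 boundary", {
  rf <- region_filter(c("missense", "synonymous", "canonical_splice",
                        "splice_region", "splice_region", "intronic"),
                      splice_offset = c(NA, NA, 1L, 6L, 7L, 40L))
  expect_identical(rf$keep, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(rf$reason[5:6], c("splice_offset_gt_6", "intronic"))
})

test_that("rarity filter applies the 1/1000 bound strictly and the homozygote rule", {
  rf <- rarity_filter(max_freq = c(1 / 945, 0.0005, 0, 0.001, NA),
                      hom_seen = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(rf$keep, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_identical(rf$reason,
                   c("frequency_gt_1_in_1000", "homozygote_seen", "",
                     "", "unannotated"))
})

test_that("pathogenicity cascade: LoF, damaging missense, known functional, constraint flags", {
  ann <- data.frame(
    gene = c("MC4R", "MC4R", "SIM1", "BDNF", "LEPR", "ADRB3", "MC4R"),
    consequence = c("nonsense", "missense", "canonical_splice", "missense",
                    "missense", "synonymous", "frameshift"),
    condel = c(NA, 0.60, NA, 0.60, 0.40, NA, NA),
    cadd = c(NA, 25, NA, 15, 25, NA, NA),
    known_functional = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  constraint <- data.frame(gene = c("MC4R", "SIM1", "BDNF", "LEPR", "ADRB3"),
                           pli = c(0.2, 0.9, 0.9, 0.1, 0.0),
                           mis_z = c(1.5, 2.0, 2.5, -0.5, -1.0),
                           stringsAsFactors = FALSE)
  out <- classify_pathogenicity(ann, constraint)
  expect_identical(out$tier,
                   c("likely_pathogenic",   # nonsense (e.g. R22X)
                     "likely_pathogenic",   # Condel 0.60 & CADD 25
                     "likely_pathogenic",   # canonical splice
                     "rare_RSV",            # CADD 15: conjunction fails
                     "rare_RSV",            # Condel below 0.522
                     "rare_RSV",            # synonymous can never be LP
                     "known_pathogenic"))   # experimentally validated
  expect_identical(out$gene_constrained,
                   c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("the cascade is a pure function of each row: order-invariant tiers", {
  set.seed(5)
  ann <- data.frame(
    gene = sample(c("A", "B"), 30, TRUE),
    consequence = sample(c("missense", "nonsense", "synonymous",
                           "splice_region", "intronic"), 30, TRUE),
    splice_offset = sample(c(NA, 1:10), 30, TRUE),
    max_freq = sample(c(0, 0.0005, 0.002, NA), 30, TRUE),
    hom_seen = sample(c(TRUE, FALSE), 30, TRUE),
    condel = runif(30), cadd = runif(30, 0, 40),
    known_functional = sample(c(TRUE, FALSE), 30, TRUE, prob = c(0.1, 0.9)),
    stringsAsFactors = FALSE)
  ann$key <- sprintf("chr1:%d:A:G", seq_len(30))
  decoded <- data.frame(key = ann$key, carriers = "S1",
                        stringsAsFactors = FALSE)
  a <- prioritize_variants(decoded, ann)
  perm <- sample.int(30)
  b <- prioritize_variants(decoded[perm, , drop = FALSE], ann)
  expect_identical(b$tier, a$tier[perm])
  expect_identical(b$exclusion_reason, a$exclusion_reason[perm])
})

test_that("every excluded variant has exactly one reason and the ledger conserves rows", {
  ann <- data.frame(
    key = sprintf("k%d", 1:6),
    gene = "G",
    consequence = c("intronic", "missense", "missense", "nonsense",
                    "missense", "splice_region"),
    splice_offset = c(40L, NA, NA, NA, NA, 7L),
    max_freq = c(0, 0.01, 0, 0, NA, 0),
    hom_seen = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    condel = 0.9, cadd = 30, known_functional = FALSE,
    stringsAsFactors = FALSE)
  decoded <- data.frame(key = c(ann$key, "missing_key"), carriers = "S1",
                        stringsAsFactors = FALSE)
  out <- prioritize_variants(decoded, ann)
  # hand-computed: intronic, freq, hom, LP, unannotated(NA freq),
  # splice offset 7, unmatched key
  expect_identical(out$tier, c("excluded", "excluded", "excluded",
                               "likely_pathogenic", "excluded", "excluded",
                               "excluded"))
  expect_identical(out$exclusion_reason,
                   c("intronic", "frequency_gt_1_in_1000", "homozygote_seen",
                     "", "unannotated", "splice_offset_gt_6", "unannotated"))
  expect_true(all(nchar(out$exclusion_reason[out$tier == "excluded"]) > 0))
  ledger <- prioritization_ledger(out)
  expect_equal(sum(ledger), nrow(out))
  expect_equal(sum(ledger[setdiff(names(ledger),
                                  c("likely_pathogenic", "known_pathogenic",
                                    "rare_RSV"))]),
               sum(out$tier == "excluded"))
})

test_that("carrier counts over a toy fixture match hand-computed expectations", {
  # 3 likely-pathogenic variants carried by S1 (twice) and S2; rare_RSV by S3
  prio <- data.frame(
    key = c("a", "b", "c", "d"),
    gene = c("MC4R", "MC4R", "BDNF", "LEPR"),
    carriers = c("S1", "S1,S2", "S2", "S3"),
    tier = c("likely_pathogenic", "likely_pathogenic", "known_pathogenic",
             "rare_RSV"),
    stringsAsFactors = FALSE)
  cohorts <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                        cohort = c("cases", "cases", "controls", "controls"),
                        stringsAsFactors = FALSE)
  sizes <- c(cases = 10, controls = 12)
  tab <- tabulate_carriers(prio, cohorts, "cases", "controls", sizes)
  expect_equal(tab$carriers_a, 2)   # S1 counted once despite two variants
  expect_equal(tab$carriers_b, 0)
  tab_all <- tabulate_carriers(prio, cohorts, "cases", "controls", sizes,
                               tiers = c("likely_pathogenic",
                                         "known_pathogenic", "rare_RSV"))
  expect_equal(tab_all$carriers_b, 1)
  empty <- tabulate_carriers(prio, cohorts, "cases", "controls", sizes,
                             genes = "FTO")
  expect_equal(c(empty$carriers_a, empty$carriers_b), c(0, 0))
  prio2 <- prio; prio2$carriers[4] <- "S9"
  expect_error(tabulate_carriers(prio2, cohorts, "cases", "controls", sizes,
                                 tiers = "rare_RSV"),
               "missing cohort")
})
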