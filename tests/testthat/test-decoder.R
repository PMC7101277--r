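test_that("copy estimation inverts the dilution arithmetic", {
  expect_identical(estimate_copies(0.025, 20), 1L)
  expect_identical(estimate_copies(0.05, 20), 2L)
  expect_identical(estimate_copies(0, 20), 0L)
  expect_identical(estimate_copies(c(0.024, 0.051, 0.076), 20), c(1L, 2L, 3L))
  expect_identical(expected_allele_fraction(1, 20), 0.025)
  expect_identical(expected_allele_fraction(2, 20), 0.05)
})

test_that("two-pool, one-pool and shared-pool patterns decode as specified", {
  d <- toy_design(list(A = c(3L, 17L), B = c(22L, 40L), C = c(3L, 22L)),
                  n_pools = 48L)
  # direct pair lookup
  dec <- decode_variants(passing_calls("chr1", 100L, "A", "G", c(3L, 17L)), d)
  expect_equal(dec$status, "unique")
  expect_equal(dec$carriers, "A")

  # single pool: a het carrier must show in both pools
  dec1 <- decode_variants(passing_calls("chr1", 101L, "A", "G", 3L), d)
  expect_equal(dec1$status, "undecodable")
  expect_equal(dec1$carriers, "")

  # four pools covered only by A + B
  dec4 <- decode_variants(
    passing_calls("chr1", 102L, "A", "G", c(3L, 17L, 22L, 40L)), d)
  expect_equal(dec4$status, "multi_carrier")
  expect_equal(dec4$carriers, "A,B")
  expect_equal(brute_covers(d, c(3L, 17L, 22L, 40L)), list(c("A", "B")))

  # two samples sharing pool 3: three pools, shared pool at ~5%
  calls3 <- passing_calls("chr1", 103L, "A", "G", c(3L, 17L, 22L),
                          af = c(0.05, 0.025, 0.025))
  dec3 <- decode_variants(calls3, d)
  expect_equal(dec3$status, "multi_carrier")
  expect_equal(dec3$carriers, "A,C")
  expect_equal(strsplit(dec3$copies, ",")[[1]], c("2", "1", "1"))
})

test_that("a two-pool 5% variant decodes as a single homozygous carrier", {
  d <- toy_design(list(A = c(0L, 1L)), n_pools = 4L)
  dec <- decode_variants(passing_calls("chr1", 50L, "C", "T", c(0L, 1L),
                                       af = 0.05), d)
  expect_equal(dec$status, "unique")
  expect_equal(dec$carriers, "A")
  expect_equal(dec$copies, "2,2")   # two copies per pool: homozygote
})

test_that("decoding matches brute-force carrier-subset enumeration on random designs", {
  set.seed(202)
  for (rep in 1:12) {
    n_pools <- sample(6:12, 1)
    pool_size <- sample(3:5, 1)
    n_samples <- min(sample(8:20, 1),
                     floor(n_pools * pool_size / 2), choose(n_pools, 2))
    d <- build_pool_design(n_samples, n_pools, pool_size, seed = 300 + rep)
    for (k in 1:3) {
      carriers <- sample(d$assignment$sample_id, k)
      rows <- d$assignment[d$assignment$sample_id %in% carriers, ]
      pools <- sort(unique(c(rows$pool_a, rows$pool_b)))
      dec <- decode_variants(
        passing_calls("chr1", 1L, "A", "G", pools), d)
      oracle <- brute_covers(d, pools)
      if (length(oracle) == 0) {
        expect_equal(dec$status, "undecodable")
      } else if (length(oracle) == 1) {
        expect_true(dec$status %in% c("unique", "multi_carrier"))
        expect_equal(strsplit(dec$carriers, ",")[[1]], oracle[[1]])
      } else {
        expect_equal(dec$status, "ambiguous")
        got <- lapply(strsplit(dec$carriers, ";")[[1]],
                      function(s) strsplit(s, ",")[[1]])
        expect_setequal(vapply(got, paste, "", collapse = ","),
                        vapply(oracle, paste, "", collapse = ","))
      }
    }
  }
})

test_that("noiseless end-to-end recovery finds every planted singleton's carrier", {
  d <- build_pool_design(60, 16, 10, seed = 17)
  regions <- demo_regions(len = 150L)
  v <- plant_singletons(d, regions, 25, seed = 9)
  sim <- simulate_cohort(d, regions, v, err = error_model(error_rate = 0),
                         seed = 31)
  calls <- call_variants(sim$pileup, error_rate = 1e-3)
  dec <- decode_variants(calls, d)
  ev <- evaluate_run(dec, sim$truth, calls = calls)
  expect_equal(ev$sensitivity, 1.0)
  i <- match(sim$truth$key, dec$key)
  expect_false(anyNA(i))
  expect_true(all(dec$status[i] == "unique"))
  expect_identical(dec$carriers[i], sim$truth$carriers)
})

test_that("calls from pools outside the design are rejected", {
  d <- toy_design(list(A = c(0L, 1L)), n_pools = 2L)
  expect_error(decode_variants(passing_calls("chr1", 1L, "A", "G", 5L), d),
               "unknown pool_id")
})

test_that("decoded variants round-trip through the minimal VCF", {
  d <- toy_design(list(A = c(3L, 17L), B = c(22L, 40L)), n_pools = 48L)
  calls <- rbind(passing_calls("chr2", 500L, "C", "T", c(3L, 17L)),
                 passing_calls("chr2", 700L, "G", "A", 22L))
  dec <- decode_variants(calls, d)
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  write_decoded_vcf(dec, vcf_path, tsv_path = tsv_path)

  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "toy")
  expect_equal(nrow(vcf), 2L)
  expect_equal(as.integer(GenomicRanges::start(vcf)), c(500L, 700L))
  info <- VariantAnnotation::info(vcf)
  expect_equal(as.character(info$STATUS), c("unique", "undecodable"))
  expect_equal(unlist(info$CARRIERS), c("A", "."), ignore_attr = TRUE)

  mirror <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  expect_equal(mirror$status, dec$status)
  expect_equal(mirror$pos, dec$pos)
})
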