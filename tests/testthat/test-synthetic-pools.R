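test_that("planted singletons dilute to 2.5% (het) and 5% (two copies) of pool reads", {
  # 100 het + 50 hom singleton carriers in a 200-pool design gives >= 200
  # carrier-pool observations per dilution class in a single simulated cohort
  d <- build_pool_design(160, 200, 20, seed = 21)
  region_het <- demo_regions(len = 400L)
  region_hom <- demo_regions(len = 200L, start = 5001L)
  regions <- rbind(region_het, region_hom)
  het <- plant_singletons(d, region_het, 100, seed = 1)
  hom <- plant_singletons(d, region_hom, 50, seed = 2, zygosity = "hom")
  variants <- rbind(het, hom)
  sim <- simulate_cohort(d, regions, variants,
                         cov = coverage_model(2396, 574, 400),
                         err = error_model(error_rate = 0), seed = 77)
  pl <- sim$pileup
  pl$key <- poolRSV:::variant_key(pl$contig, pl$pos, pl$ref, pl$alt)
  af <- pl$alt_count / pl$depth
  is_het <- pl$key %in% sim$truth$key[sim$truth$zygosity == "het"]
  is_hom <- pl$key %in% sim$truth$key[sim$truth$zygosity == "hom"]
  for (cls in list(list(sel = is_het, expect = 0.025),
                   list(sel = is_hom, expect = 0.05))) {
    x <- af[cls$sel]
    expect_gte(length(x), 100)
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - cls$expect), 3 * se)
  }
})

test_that("no signal and no noise yields an empty pileup, with consistent truth", {
  d <- build_pool_design(30, 10, 8, seed = 4)
  regions <- demo_regions(len = 50L)
  none <- variant_spec(character(0), integer(0), character(0), character(0),
                       carriers = list())
  sim <- simulate_cohort(d, regions, none, err = error_model(error_rate = 0),
                         seed = 1)
  expect_equal(nrow(sim$pileup), 0L)
  expect_equal(nrow(sim$truth), 0L)

  v <- plant_singletons(d, regions, 5, seed = 3)
  sim2 <- simulate_cohort(d, regions, v, err = error_model(error_rate = 0),
                          seed = 1)
  # noiseless: rows appear exactly at the carrier's two pools of each variant
  asg <- d$assignment
  for (i in seq_len(nrow(sim2$truth))) {
    tr <- sim2$truth[i, ]
    row <- asg[asg$sample_id == tr$carriers, ]
    expect_equal(sort(as.integer(strsplit(tr$carrier_pools, ",")[[1]])),
                 sort(c(row$pool_a, row$pool_b)))
    obs <- sim2$pileup[sim2$pileup$pos == tr$pos & sim2$pileup$alt == tr$alt, ]
    expect_setequal(obs$pool_id, c(row$pool_a, row$pool_b))
    expect_true(all(obs$alt_count > 0))
  }
})

test_that("simulation is byte-identical under the same seed", {
  d <- build_pool_design(40, 10, 8, seed = 6)
  regions <- demo_regions(len = 120L)
  v <- plant_singletons(d, regions, 8, seed = 5)
  a <- simulate_cohort(d, regions, v, seed = 99)
  b <- simulate_cohort(d, regions, v, seed = 99)
  expect_identical(a, b)
  c <- simulate_cohort(d, regions, v, seed = 100)
  expect_false(identical(a$pileup, c$pileup))
})

test_that("invalid carriers, sites and model parameters are rejected", {
  d <- build_pool_design(10, 6, 4, seed = 1)
  regions <- demo_regions(len = 30L)
  v <- variant_spec("chr1", 1005L, "C", "T", carriers = "ghost")
  expect_error(simulate_cohort(d, regions, v), "carrier")
  v2 <- variant_spec("chr1", 5000L, "A", "G",
                     carriers = d$assignment$sample_id[1])
  expect_error(simulate_cohort(d, regions, v2), "outside target regions")
  expect_error(coverage_model(mean_depth = -1))
  expect_error(error_model(error_rate = 0.5))
})

test_that("artifact injection respects rate zero, strand forcing and truth disjointness", {
  d <- build_pool_design(40, 10, 8, seed = 2)
  regions <- demo_regions(len = 150L)
  v <- plant_singletons(d, regions, 6, seed = 7)
  sim <- simulate_cohort(d, regions, v, seed = 13)

  same <- inject_artifacts(sim$pileup, d, regions, n = 0L)
  expect_equal(nrow(same), nrow(sim$pileup))
  expect_equal(nrow(attr(same, "artifacts")), 0L)

  em <- error_model(artifact_strand = 0.95)
  art <- inject_artifacts(sim$pileup, d, regions, err = em, n = 25L,
                          truth = sim$truth, seed = 3)
  companion <- attr(art, "artifacts")
  expect_equal(nrow(companion), 25L)
  # no artifact may coincide with a planted variant
  expect_length(intersect(
    poolRSV:::variant_key(companion$contig, companion$pos, companion$ref,
                          companion$alt),
    sim$truth$key), 0)
  # strand-type artifacts sit outside the balanced band on the side set by
  # the strand parameter
  added <- art[(nrow(sim$pileup) + 1):nrow(art), ]
  strand_type <- companion$type %in% c("strand", "both")
  expect_true(all(added$fwd_frac[strand_type] > 0.8 |
                    added$fwd_frac[strand_type] < 0.2))
  bq_type <- companion$type %in% c("low_bq", "both")
  expect_true(all(added$mean_bq[bq_type] < 15))
})

test_that("pileup TSV round-trips through write/read", {
  d <- build_pool_design(20, 8, 6, seed = 3)
  regions <- demo_regions(len = 80L)
  v <- plant_singletons(d, regions, 4, seed = 4)
  sim <- simulate_cohort(d, regions, v, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pileup(sim$pileup, f)
  back <- read_pileup(f)
  expect_equal(back, sim$pileup, tolerance = 1e-12, ignore_attr = TRUE)
})
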