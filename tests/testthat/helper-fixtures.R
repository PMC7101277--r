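# Shared fixtures and independent oracles. Oracles here are deliberately
# written from first principles (combn enumeration, choose()-based
# hypergeometric mass) so they never share code with the implementation.

# hand-built design from an explicit sample -> pool-pair map
toy_design <- function(pairs, n_pools, pool_size = 20L, cohort = "toy") {
  asg <- data.frame(
    sample_id = names(pairs),
    pool_a = vapply(pairs, min, 0L),
    pool_b = vapply(pairs, max, 0L),
    stringsAsFactors = FALSE)
  structure(list(cohort = cohort, n_samples = nrow(asg),
                 n_pools = as.integer(n_pools),
                 pool_size = as.integer(pool_size), seed = 0L,
                 assignment = asg),
            class = "pool_design")
}

# a calls data frame that passes every filter, one row per supporting pool
passing_calls <- function(contig, pos, ref, alt, pools, af = 0.025,
                          depth = 2000L) {
  data.frame(pool_id = as.integer(pools), contig = contig, pos = as.integer(pos),
             ref = ref, alt = alt, depth = depth,
             alt_count = as.integer(round(af * depth)), mean_bq = 30,
             fwd_frac = 0.5, allele_fraction = af, score = 50,
             flags = "", pass = TRUE, stringsAsFactors = FALSE)
}

# brute-force carrier-cover oracle: enumerate ALL sample subsets of size <= k
brute_covers <- function(design, pools, max_carriers = 3L) {
  asg <- design$assignment
  for (k in seq_len(min(max_carriers, nrow(asg)))) {
    combos <- utils::combn(nrow(asg), k, simplify = FALSE)
    hits <- Filter(function(rows) {
      setequal(c(asg$pool_a[rows], asg$pool_b[rows]), pools)
    }, combos)
    if (length(hits)) {
      return(lapply(hits, function(rows) sort(asg$sample_id[rows])))
    }
  }
  list()
}

# hypergeometric two-sided p from scratch (choose()-based, minlike rule)
brute_fisher <- function(a, na, b, nb) {
  m <- a + b
  supp <- max(0L, m - nb):min(na, m)
  mass <- choose(na, supp) * choose(nb, m - supp) / choose(na + nb, m)
  p_obs <- choose(na, a) * choose(nb, m - a) / choose(na + nb, m)
  min(1, sum(mass[mass <= p_obs * (1 + 1e-7)]))
}

# plant n singleton variants at distinct sites of `regions`, carriers drawn
# without replacement from the design
plant_singletons <- function(design, regions, n, seed = 1L,
                             zygosity = "het", gene = "GENE",
                             consequence = "missense") {
  set.seed(seed)
  sites <- poolRSV:::region_sites(regions)
  stopifnot(n <= nrow(sites), n <= design$n_samples)
  idx <- sort(sample.int(nrow(sites), n))
  carriers <- sample(design$assignment$sample_id, n)
  ref <- sites$ref[idx]
  variant_spec(sites$contig[idx], sites$pos[idx], ref = ref,
               alt = ifelse(ref == "G", "T", "G"),
               carriers = carriers, zygosity = zygosity,
               gene = gene, consequence = consequence)
}

demo_regions <- function(len = 200L, contig = "chr1", start = 1001L) {
  data.frame(contig = contig, start = start, end = start + len - 1L,
             stringsAsFactors = FALSE)
}
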