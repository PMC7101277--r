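#' Build a two-replicate overlapping pool design
#'
#' Assigns every sample to an unordered pair of distinct pools such that no two
#' samples share the same pair and no pool exceeds its capacity. With this
#' design a heterozygous singleton variant is seen in exactly the carrier's two
#' pools, and intersecting those pools against the design identifies the
#' carrier unambiguously.
#'
#' Construction is a greedy randomized pairing: for each sample an unused pool
#' pair is drawn uniformly among pairs whose both pools still have free slots;
#' on a dead end the construction restarts with a fresh seed-derived stream.
#' Any injective, capacity-respecting assignment is equivalent for decoding.
#'
#' @param n_samples Number of samples to assign.
#' @param n_pools Number of pools (pool ids are dense integers
#'   `0..n_pools-1`).
#' @param pool_size Maximum number of samples per pool.
#' @param cohort Cohort label, used to generate sample ids.
#' @param seed Integer seed; the same seed reproduces the identical design.
#' @param max_restarts Maximum greedy restarts before giving up.
#'
#' @return An object of class `pool_design`: a list with elements `cohort`,
#'   `n_samples`, `n_pools`, `pool_size`, `seed` and `assignment`, a
#'   data frame with columns `sample_id`, `pool_a`, `pool_b`
#'   (`pool_a < pool_b`).
#'
#' @examples
#' d <- build_pool_design(40, 10, 8, cohort = "demo", seed = 1)
#' validate_pool_design(d)
#' @export
build_pool_design <- function(n_samples, n_pools, pool_size,
                              cohort = "cohort", seed = 1L,
                              max_restarts = 200L) {
  n_samples <- as.integer(n_samples)
  n_pools <- as.integer(n_pools)
  pool_size <- as.integer(pool_size)
  if (n_pools < 2L) stop("capacity error: at least 2 pools are required")
  if (pool_size < 1L) stop("capacity error: pool_size must be >= 1")
  if (n_samples < 1L) stop("at least one sample is required")
  if (2L * n_samples > n_pools * pool_size) {
    stop(sprintf(
      "capacity error: %d pool slots needed (2 x %d samples) but only %d available (%d pools x %d)",
      2L * n_samples, n_samples, n_pools * pool_size, n_pools, pool_size))
  }
  n_pairs <- choose(n_pools, 2)
  if (n_samples > n_pairs) {
    stop(sprintf(
      "capacity error: %d samples need distinct pool pairs but only %d pairs exist for %d pools",
      n_samples, n_pairs, n_pools))
  }

  set.seed(seed)
  for (attempt in seq_len(max_restarts)) {
    free <- rep(pool_size, n_pools)
    used <- matrix(FALSE, n_pools, n_pools)
    pool_a <- integer(n_samples)
    pool_b <- integer(n_samples)
    ok <- TRUE
    for (s in seq_len(n_samples)) {
      open <- which(free > 0L)
      if (length(open) < 2L) { ok <- FALSE; break }
      cand <- utils::combn(open, 2L)
      avail <- !used[cbind(cand[1L, ], cand[2L, ])]
      if (!any(avail)) { ok <- FALSE; break }
      cand <- cand[, avail, drop = FALSE]
      j <- if (ncol(cand) == 1L) 1L else sample.int(ncol(cand), 1L)
      a <- cand[1L, j]; b <- cand[2L, j]
      pool_a[s] <- a; pool_b[s] <- b
      used[a, b] <- TRUE
      free[a] <- free[a] - 1L
      free[b] <- free[b] - 1L
    }
    if (ok) {
      assignment <- data.frame(
        sample_id = sprintf("%s_%04d", cohort, seq_len(n_samples)),
        pool_a = pool_a - 1L,  # 0-based pool ids
        pool_b = pool_b - 1L,
        stringsAsFactors = FALSE)
      design <- structure(
        list(cohort = cohort, n_samples = n_samples, n_pools = n_pools,
             pool_size = pool_size, seed = as.integer(seed),
             assignment = assignment),
        class = "pool_design")
      return(design)
    }
  }
  stop(sprintf(
    "could not construct a design for (%d samples, %d pools, size %d) after %d restarts",
    n_samples, n_pools, pool_size, max_restarts))
}

#' Look up the sample assigned to a pool pair
#'
#' Inverse of the design assignment: returns the unique sample whose two pools
#' are exactly `{pool_a, pool_b}`, or `NA_character_` when no sample is
#' assigned to that pair. This lookup is how a variant detected in two pools is
#' traced back to its carrier.
#'
#' @param design A `pool_design`.
#' @param pool_a,pool_b Pool ids (order irrelevant).
#' @return The sample id, or `NA_character_` if the pair is unassigned.
#' @export
pool_pair_sample <- function(design, pool_a, pool_b) {
  stopifnot(inherits(design, "pool_design"))
  pools <- c(pool_a, pool_b)
  if (any(pools < 0L | pools >= design$n_pools)) {
    stop(sprintf("unknown pool id: pools must be in 0..%d", design$n_pools - 1L))
  }
  if (pool_a == pool_b) stop("a pool pair consists of two distinct pools")
  a <- min(pools); b <- max(pools)
  asg <- design$assignment
  hit <- asg$sample_id[asg$pool_a == a & asg$pool_b == b]
  if (length(hit) == 0L) NA_character_ else hit[1L]
}

#' Validate a pool design against its invariants
#'
#' Checks that every sample sits in exactly two distinct pools, that no pool
#' exceeds its capacity, that the sample-to-pool-pair mapping is injective
#' (no two samples share a pair -- the property that makes singleton decoding
#' unambiguous), and that total slot usage fits `n_pools * pool_size`.
#'
#' @param design A `pool_design`.
#' @return A character vector of violated-invariant messages; empty when the
#'   design is valid.
#' @export
validate_pool_design <- function(design) {
  stopifnot(inherits(design, "pool_design"))
  asg <- design$assignment
  bad <- character(0)
  if (nrow(asg) != design$n_samples) {
    bad <- c(bad, sprintf("assignment has %d rows for %d samples",
                          nrow(asg), design$n_samples))
  }
  if (any(asg$pool_a == asg$pool_b)) {
    bad <- c(bad, "some sample is assigned the same pool twice")
  }
  if (any(asg$pool_a < 0L | asg$pool_b < 0L |
          asg$pool_a >= design$n_pools | asg$pool_b >= design$n_pools)) {
    bad <- c(bad, "pool id outside 0..n_pools-1")
  }
  occupancy <- table(factor(c(asg$pool_a, asg$pool_b),
                            levels = 0:(design$n_pools - 1L)))
  if (any(occupancy > design$pool_size)) {
    over <- names(occupancy)[occupancy > design$pool_size]
    bad <- c(bad, sprintf("pool capacity exceeded in pool(s) %s (size %d)",
                          paste(over, collapse = ", "), design$pool_size))
  }
  key <- paste(pmin(asg$pool_a, asg$pool_b), pmax(asg$pool_a, asg$pool_b))
  if (anyDuplicated(key)) {
    bad <- c(bad, "injectivity violated: two samples share the same pool pair")
  }
  if (2L * design$n_samples > design$n_pools * design$pool_size) {
    bad <- c(bad, "slot usage 2*n_samples exceeds n_pools*pool_size")
  }
  bad
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf(
    "pool_design '%s': %d samples in %d pools (size %d), %d/%d slots used, seed %d\n",
    x$cohort, x$n_samples, x$n_pools, x$pool_size,
    2L * x$n_samples, x$n_pools * x$pool_size, x$seed))
  invisible(x)
}

#' Write / read a pool design as TSV
#'
#' The design is serialized as a TSV with columns `sample_id`, `pool_a`,
#' `pool_b` preceded by `#key=value` header lines carrying the design
#' metadata, and round-trips losslessly.
#'
#' @param design A `pool_design`.
#' @param path Output file path.
#' @return `write_pool_design` returns `path` invisibly; `read_pool_design`
#'   returns the `pool_design`.
#' @export
write_pool_design <- function(design, path) {
  stopifnot(inherits(design, "pool_design"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s=%s",
                     c("cohort", "n_samples", "n_pools", "pool_size", "seed"),
                     c(design$cohort, design$n_samples, design$n_pools,
                       design$pool_size, design$seed)), con)
  utils::write.table(design$assignment, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_design
#' @export
read_pool_design <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- sub("^#", "", hdr)
  kv <- strsplit(meta, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  asg <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer"))
  structure(
    list(cohort = meta[["cohort"]],
         n_samples = as.integer(meta[["n_samples"]]),
         n_pools = as.integer(meta[["n_pools"]]),
         pool_size = as.integer(meta[["pool_size"]]),
         seed = as.integer(meta[["seed"]]),
         assignment = asg),
    class = "pool_design")
}
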