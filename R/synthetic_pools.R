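#' Coverage model for pool sequencing depth
#'
#' Per-pool per-site depth is drawn from a rounded normal truncated below at
#' `min_depth`. Defaults reflect a deep targeted pooled experiment: mean
#' 2396x (SD 574) with a 400x floor, the regime in which a singleton
#' heterozygote diluted 1/40 still contributes tens of reads.
#'
#' @param mean_depth Mean depth in reads (> 0).
#' @param sd_depth Depth standard deviation in reads (>= 0).
#' @param min_depth Hard lower truncation in reads (>= 0).
#' @return A `coverage_model` list.
#' @export
coverage_model <- function(mean_depth = 2396, sd_depth = 574, min_depth = 400) {
  stopifnot(mean_depth > 0, sd_depth >= 0, min_depth >= 0)
  structure(list(mean_depth = mean_depth, sd_depth = sd_depth,
                 min_depth = min_depth),
            class = "coverage_model")
}

#' Sequencing error / artifact model
#'
#' `error_rate` is the per-base substitution rate epsilon (each of the three
#' non-reference bases receives epsilon/3). True-variant reads carry high base
#' qualities (normal around `true_bq_mean`); artifact and error reads carry
#' low base qualities (normal around `artifact_bq_mean`), which is what makes
#' the mean-base-quality filter informative. `artifact_strand` controls how
#' far injected artifacts sit from strand balance: the forward-strand fraction
#' of a strand-type artifact is drawn beyond that point (or its mirror image).
#'
#' @param error_rate Per-base substitution error rate, in `[0, 0.01)`.
#' @param true_bq_mean,true_bq_sd Base-quality distribution (Phred) of reads
#'   supporting real alleles.
#' @param artifact_bq_mean,artifact_bq_sd Base-quality distribution (Phred) of
#'   error/artifact reads.
#' @param artifact_strand Strand-imbalance parameter in `(0.5, 1]` for
#'   strand-biased artifacts.
#' @return An `error_model` list.
#' @export
error_model <- function(error_rate = 1e-3, true_bq_mean = 30, true_bq_sd = 3,
                        artifact_bq_mean = 8, artifact_bq_sd = 3,
                        artifact_strand = 0.95) {
  stopifnot(error_rate >= 0, error_rate < 0.01,
            true_bq_mean >= 0, true_bq_sd >= 0,
            artifact_bq_mean >= 0, artifact_bq_sd >= 0,
            artifact_strand > 0.5, artifact_strand <= 1)
  structure(list(error_rate = error_rate,
                 true_bq_mean = true_bq_mean, true_bq_sd = true_bq_sd,
                 artifact_bq_mean = artifact_bq_mean,
                 artifact_bq_sd = artifact_bq_sd,
                 artifact_strand = artifact_strand),
            class = "error_model")
}

#' Expected pool allele fraction for a given allele copy count
#'
#' In a pool of `pool_size` diploid samples, `copies` alternate allele copies
#' dilute to `copies / (2 * pool_size)` of the reads: one heterozygous allele
#' in a 20-sample pool is expected in 1/40 = 2.5% of reads, two alleles in 5%.
#'
#' @param copies Number of alternate allele copies in the pool.
#' @param pool_size Number of diploid samples per pool.
#' @return Expected allele fraction.
#' @export
expected_allele_fraction <- function(copies, pool_size) {
  stopifnot(all(copies >= 0), pool_size >= 1)
  copies / (2 * pool_size)
}

#' Read target regions from a BED file
#'
#' Parses BED (0-based half-open) via [rtracklayer::import] and converts to
#' the 1-based fully-closed coordinates used internally.
#'
#' @param path Path to a BED file.
#' @return A data frame with columns `contig`, `start`, `end` (1-based,
#'   closed).
#' @export
read_bed_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),  # import already shifts to 1-based
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# Enumerate every site of a regions table; reference base assigned cyclically
# by position (the simulation never needs a real genome).
region_sites <- function(regions) {
  stopifnot(all(c("contig", "start", "end") %in% names(regions)),
            nrow(regions) > 0, all(regions$end >= regions$start))
  pos <- unlist(Map(seq.int, regions$start, regions$end), use.names = FALSE)
  contig <- rep(regions$contig, regions$end - regions$start + 1L)
  df <- unique(data.frame(contig = contig, pos = pos,
                          stringsAsFactors = FALSE))
  df$ref <- c("A", "C", "G", "T")[df$pos %% 4L + 1L]
  df[order(df$contig, df$pos), , drop = FALSE]
}

#' Build a planted-variant specification table
#'
#' @param contig,pos,ref,alt Variant site and alleles (1-based positions).
#' @param carriers Carrier sample ids; either a character vector (one carrier
#'   per variant) or a list of character vectors.
#' @param zygosity `"het"` or `"hom"` per carrier, recycled; a het carrier
#'   contributes 1 allele copy to each of its pools, a hom carrier 2.
#' @param ... Further annotation payload columns (e.g. `gene`, `consequence`,
#'   `condel`, `cadd`) carried through to the truth table and usable to build
#'   the prioritizer's annotation input.
#' @return A data frame with one row per variant.
#' @export
variant_spec <- function(contig, pos, ref, alt, carriers, zygosity = "het",
                         ...) {
  if (!is.list(carriers)) carriers <- as.list(carriers)
  n <- length(pos)
  stopifnot(length(carriers) == n, all(ref != alt))
  df <- data.frame(contig = rep_len(contig, n), pos = pos,
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   stringsAsFactors = FALSE)
  df$carriers <- vapply(carriers, paste, "", collapse = ",")
  df$zygosity <- rep_len(zygosity, n)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  df
}

variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

#' Simulate per-pool pileup count tables for a pooled cohort
#'
#' For every pool and every site in `regions`, depth is drawn from the
#' coverage model. At a planted variant site, the alternate read count in a
#' pool holding `c` carrier allele copies is binomial with success probability
#' `p = f(1 - 4*eps/3) + eps/3` where `f = c/(2*pool_size)`: an allele-`f`
#' read keeps its base with probability `1 - eps` and a reference read is
#' misread as the alternate with probability `eps/3`. Every other
#' (site, non-reference base) pair receives pure error counts, binomial with
#' probability `eps/3`; rows with zero alternate reads outside planted sites
#' are dropped, so with `eps = 0` and no planted variants the pileup is empty.
#' Reads supporting real alleles draw base qualities from the true-variant
#' distribution and a balanced binomial strand split; error reads draw from
#' the artifact distribution.
#'
#' @param design A `pool_design`; all carriers must belong to it.
#' @param regions Target regions data frame (`contig`, `start`, `end`,
#'   1-based closed), e.g. from [read_bed_regions()].
#' @param variants Planted variants from [variant_spec()] (may have 0 rows).
#' @param cov A [coverage_model()].
#' @param err An [error_model()].
#' @param seed Integer seed; identical seed gives byte-identical tables.
#' @return A list with `pileup` (data frame: `pool_id`, `contig`, `pos`,
#'   `ref`, `alt`, `depth`, `alt_count`, `mean_bq`, `fwd_frac`) and `truth`
#'   (one row per planted variant: key, carriers, carrier pools, copies per
#'   pool, expected fraction, plus any payload columns).
#' @export
simulate_cohort <- function(design, regions, variants, cov = coverage_model(),
                            err = error_model(), seed = 1L) {
  stopifnot(inherits(design, "pool_design"), inherits(cov, "coverage_model"),
            inherits(err, "error_model"))
  set.seed(seed)
  sites <- region_sites(regions)
  n_sites <- nrow(sites)
  n_pools <- design$n_pools
  K <- design$pool_size
  eps <- err$error_rate

  site_id <- function(contig, pos) match(paste(contig, pos),
                                         paste(sites$contig, sites$pos))
  if (nrow(variants) > 0) {
    vs <- site_id(variants$contig, variants$pos)
    if (anyNA(vs)) stop("variant site outside target regions")
    known <- design$assignment$sample_id
    carr_list <- strsplit(variants$carriers, ",", fixed = TRUE)
    if (!all(unlist(carr_list) %in% known)) {
      stop("carrier sample not found in the design's cohort")
    }
  } else {
    vs <- integer(0)
    carr_list <- list()
  }

  # depth matrix: pools x sites
  depth <- matrix(
    pmax(round(stats::rnorm(n_pools * n_sites, cov$mean_depth, cov$sd_depth)),
         cov$min_depth),
    nrow = n_pools, ncol = n_sites)

  draw_bq <- function(n, true) {
    mu <- if (true) err$true_bq_mean else err$artifact_bq_mean
    sdv <- if (true) err$true_bq_sd else err$artifact_bq_sd
    pmax(stats::rnorm(n, mu, sdv), 0)
  }
  draw_fwd <- function(alt_count, p = 0.5) {
    ifelse(alt_count > 0,
           stats::rbinom(length(alt_count), alt_count, p) / pmax(alt_count, 1L),
           0.5)
  }

  rows <- list()
  truth <- NULL
  if (nrow(variants) > 0) {
    asg <- design$assignment
    copies_per_carrier <- ifelse(variants$zygosity == "hom", 2L, 1L)
    tr_pools <- character(nrow(variants))
    tr_copies <- character(nrow(variants))
    tr_expf <- character(nrow(variants))
    for (v in seq_len(nrow(variants))) {
      cvec <- integer(n_pools)  # allele copies per pool (0-based ids + 1)
      for (cs in carr_list[[v]]) {
        row <- asg[asg$sample_id == cs, ]
        cvec[row$pool_a + 1L] <- cvec[row$pool_a + 1L] + copies_per_carrier[v]
        cvec[row$pool_b + 1L] <- cvec[row$pool_b + 1L] + copies_per_carrier[v]
      }
      f <- cvec / (2 * K)
      p_alt <- f * (1 - 4 * eps / 3) + eps / 3
      dp <- depth[, vs[v]]
      ac <- stats::rbinom(n_pools, dp, p_alt)
      keep <- cvec > 0L | ac > 0L
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          pool_id = which(keep) - 1L,
          contig = variants$contig[v], pos = variants$pos[v],
          ref = variants$ref[v], alt = variants$alt[v],
          depth = dp[keep], alt_count = ac[keep],
          mean_bq = draw_bq(sum(keep), true = FALSE),
          fwd_frac = draw_fwd(ac[keep]),
          stringsAsFactors = FALSE)
        # overwrite BQ for pools that really hold the allele
        isv <- cvec[keep] > 0L
        rows[[length(rows)]]$mean_bq[isv] <- draw_bq(sum(isv), true = TRUE)
      }
      cp <- which(cvec > 0L) - 1L
      tr_pools[v] <- paste(cp, collapse = ",")
      tr_copies[v] <- paste(cvec[cp + 1L], collapse = ",")
      tr_expf[v] <- paste(format(f[cp + 1L], trim = TRUE), collapse = ",")
    }
    truth <- variants
    truth$key <- variant_key(variants$contig, variants$pos,
                             variants$ref, variants$alt)
    truth$carrier_pools <- tr_pools
    truth$copies_per_pool <- tr_copies
    truth$expected_fraction <- tr_expf
  } else {
    truth <- data.frame(key = character(0), carriers = character(0),
                        carrier_pools = character(0),
                        copies_per_pool = character(0),
                        expected_fraction = character(0),
                        stringsAsFactors = FALSE)
  }

  # sequencing-error noise at every other (site, alt base) combination
  if (eps > 0) {
    alt_sets <- lapply(sites$ref, function(r) setdiff(c("A", "C", "G", "T"), r))
    planted <- if (nrow(variants) > 0) {
      paste(vs, variants$alt)
    } else character(0)
    for (k in 1:3) {
      altk <- vapply(alt_sets, `[`, "", k)
      ac <- matrix(stats::rbinom(n_pools * n_sites, depth, eps / 3),
                   nrow = n_pools, ncol = n_sites)
      nz <- which(ac > 0L, arr.ind = TRUE)
      if (nrow(nz) == 0L) next
      skip <- paste(nz[, 2L], altk[nz[, 2L]]) %in% planted
      nz <- nz[!skip, , drop = FALSE]
      if (nrow(nz) == 0L) next
      acv <- ac[nz]
      rows[[length(rows) + 1L]] <- data.frame(
        pool_id = nz[, 1L] - 1L,
        contig = sites$contig[nz[, 2L]], pos = sites$pos[nz[, 2L]],
        ref = sites$ref[nz[, 2L]], alt = altk[nz[, 2L]],
        depth = depth[nz], alt_count = acv,
        mean_bq = draw_bq(length(acv), true = FALSE),
        fwd_frac = draw_fwd(acv),
        stringsAsFactors = FALSE)
    }
  }

  pileup <- if (length(rows)) do.call(rbind, rows) else data.frame(
    pool_id = integer(0), contig = character(0), pos = integer(0),
    ref = character(0), alt = character(0), depth = integer(0),
    alt_count = integer(0), mean_bq = numeric(0), fwd_frac = numeric(0),
    stringsAsFactors = FALSE)
  pileup <- pileup[order(pileup$contig, pileup$pos, pileup$alt,
                         pileup$pool_id), , drop = FALSE]
  rownames(pileup) <- NULL
  list(pileup = pileup, truth = truth)
}

#' Inject sequencing artifacts into a pileup
#'
#' Adds artifact alternate-allele entries at random sites in random single
#' pools. Artifact allele fractions are drawn inside the 1-10% window so that
#' the base-quality and strand-bias filters -- not the fraction filter -- must
#' reject them. Each artifact is one of three types: `low_bq` (mean base
#' quality drawn from the artifact distribution truncated below 15, balanced
#' strand), `strand` (true-variant base quality, forward-strand fraction
#' forced outside `[0.2, 0.8]`), or `both`.
#'
#' @param pileup Pileup data frame from [simulate_cohort()].
#' @param design The `pool_design` the pileup was simulated from.
#' @param regions Target regions (artifact sites are drawn from these).
#' @param err An [error_model()].
#' @param n Number of artifacts to inject.
#' @param cov A [coverage_model()] for artifact-site depths.
#' @param truth Optional truth table; artifact sites avoid planted sites.
#' @param seed Integer seed.
#' @return The pileup with artifact rows appended and an `artifacts`
#'   attribute: a data frame (`pool_id`, `contig`, `pos`, `ref`, `alt`,
#'   `type`) listing every injected entry for specificity scoring.
#' @export
inject_artifacts <- function(pileup, design, regions, err = error_model(),
                             n = 10L, cov = coverage_model(), truth = NULL,
                             seed = 1L) {
  stopifnot(inherits(design, "pool_design"), inherits(err, "error_model"))
  if (n == 0L) {
    attr(pileup, "artifacts") <- data.frame(
      pool_id = integer(0), contig = character(0), pos = integer(0),
      ref = character(0), alt = character(0), type = character(0),
      stringsAsFactors = FALSE)
    return(pileup)
  }
  set.seed(seed)
  sites <- region_sites(regions)
  if (!is.null(truth) && nrow(truth) > 0) {
    sites <- sites[!(paste(sites$contig, sites$pos) %in%
                       paste(truth$contig, truth$pos)), , drop = FALSE]
  }
  if (nrow(sites) == 0L) stop("no artifact-eligible sites in regions")
  idx <- sample.int(nrow(sites), n, replace = n > nrow(sites))
  pool <- sample.int(design$n_pools, n, replace = TRUE) - 1L
  type <- sample(c("low_bq", "strand", "both"), n, replace = TRUE)
  alt <- vapply(sites$ref[idx],
                function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  depth <- pmax(round(stats::rnorm(n, cov$mean_depth, cov$sd_depth)),
                cov$min_depth)
  af <- stats::runif(n, 0.02, 0.08)
  ac <- pmax(round(af * depth), 1L)

  # truncated-below-15 artifact BQ (inverse-CDF draw)
  u <- stats::runif(n) * stats::pnorm(15, err$artifact_bq_mean, err$artifact_bq_sd)
  bq_low <- pmax(stats::qnorm(u, err$artifact_bq_mean, err$artifact_bq_sd), 0)
  bq <- ifelse(type == "strand",
               pmax(stats::rnorm(n, err$true_bq_mean, err$true_bq_sd), 0),
               bq_low)
  hi <- stats::runif(n) < 0.5
  fwd_extreme <- ifelse(hi, stats::runif(n, err$artifact_strand, 1),
                        stats::runif(n, 0, 1 - err$artifact_strand))
  fwd <- ifelse(type == "low_bq",
                stats::rbinom(n, ac, 0.5) / pmax(ac, 1L),
                fwd_extreme)

  art_rows <- data.frame(
    pool_id = pool, contig = sites$contig[idx], pos = sites$pos[idx],
    ref = sites$ref[idx], alt = alt, depth = depth, alt_count = ac,
    mean_bq = bq, fwd_frac = fwd, stringsAsFactors = FALSE)
  out <- rbind(pileup, art_rows)
  rownames(out) <- NULL
  attr(out, "artifacts") <- data.frame(
    pool_id = pool, contig = sites$contig[idx], pos = sites$pos[idx],
    ref = sites$ref[idx], alt = alt, type = type, stringsAsFactors = FALSE)
  out
}

#' Write / read a pileup count table as TSV
#'
#' @param pileup Pileup data frame.
#' @param path File path.
#' @return `write_pileup` returns `path` invisibly; `read_pileup` the data
#'   frame.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(pool_id = "integer", contig = "character",
                                   pos = "integer", ref = "character",
                                   alt = "character", depth = "integer",
                                   alt_count = "integer", mean_bq = "numeric",
                                   fwd_frac = "numeric"))
}
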