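#' Phred-scaled likelihood-ratio score for a low-fraction variant candidate
#'
#' Scores the evidence that a site carries a real low-fraction allele rather
#' than sequencing error alone, under a binomial read-count model:
#' `score = 10 * log10[ L(k | n, f_hat) / L(k | n, eps/3) ]` with
#' `f_hat = max(k/n, eps/3)`, where `k` is the alternate read count, `n` the
#' depth and `eps` the per-base substitution error rate (`eps/3` per specific
#' alternate base). The score is clipped below at 0; with `k = 0` the
#' likelihood ratio is 1 and the score is exactly 0.
#'
#' @param alt_count Alternate read count(s).
#' @param depth Read depth(s); must be positive.
#' @param error_rate Assumed per-base substitution error rate.
#' @return Numeric vector of non-negative Phred-scaled scores.
#' @export
score_candidate <- function(alt_count, depth, error_rate = 1e-3) {
  if (any(depth <= 0)) stop("depth must be positive to score a candidate")
  stopifnot(all(alt_count >= 0), all(alt_count <= depth), error_rate >= 0)
  e3 <- error_rate / 3
  f_hat <- pmax(alt_count / depth, e3)
  s <- 10 / log(10) *
    (stats::dbinom(alt_count, depth, f_hat, log = TRUE) -
       stats::dbinom(alt_count, depth, e3, log = TRUE))
  pmax(s, 0)
}

#' Filter thresholds for pool variant calls
#'
#' Defaults encode the published filter stack: candidate score strictly over
#' 5 Phred, mean base quality strictly over 15, forward-strand fraction kept
#' inside the inclusive `[0.20, 0.80]` band, allele fraction kept inside the
#' inclusive `[0.01, 0.10]` window (a singleton het dilutes to 2.5%, two
#' copies to 5%; more than two copies per pool is "too common" for a rare
#' highly penetrant variant), and a 1000x coverage floor below which calls
#' are flagged for manual review rather than excluded.
#'
#' @param min_score Minimum (exclusive) Phred-scaled score.
#' @param min_bq Minimum (exclusive) mean base quality.
#' @param strand_lo,strand_hi Inclusive forward-strand-fraction keep range.
#' @param af_lo,af_hi Inclusive allele-fraction keep range.
#' @param review_depth Depth (exclusive lower bound) under which calls get the
#'   `low_coverage_review` flag.
#' @return A `call_thresholds` list.
#' @export
call_thresholds <- function(min_score = 5, min_bq = 15,
                            strand_lo = 0.20, strand_hi = 0.80,
                            af_lo = 0.01, af_hi = 0.10,
                            review_depth = 1000) {
  if (strand_lo >= strand_hi) {
    stop("malformed thresholds: strand_lo must be < strand_hi")
  }
  if (af_lo >= af_hi) stop("malformed thresholds: af_lo must be < af_hi")
  stopifnot(strand_lo >= 0, strand_hi <= 1, af_lo >= 0, af_hi <= 1,
            min_score >= 0, min_bq >= 0, review_depth >= 0)
  structure(list(min_score = min_score, min_bq = min_bq,
                 strand_lo = strand_lo, strand_hi = strand_hi,
                 af_lo = af_lo, af_hi = af_hi, review_depth = review_depth),
            class = "call_thresholds")
}

#' Apply the quality filter stack to scored calls
#'
#' Each call is tested against four independent per-call conditions; failing
#' calls are retained with explanatory flags, never deleted. A variant
#' ultimately survives only if its calls pass in both pools of its carrier
#' pair (a variant seen in a single pool cannot be decoded), which is enforced
#' downstream by [decode_variants()] consuming only passing calls.
#'
#' Boundary semantics are literal: score exactly 5 and mean base quality
#' exactly 15 fail ("over 5", "over 15" are strict); strand fraction exactly
#' 0.20 or 0.80 and allele fraction exactly 0.01 or 0.10 pass (inclusive keep
#' ranges). The four filters are independent of one another, so any order of
#' application yields the same surviving set.
#'
#' @param calls Scored calls (must carry `score`, `mean_bq`, `fwd_frac`,
#'   `allele_fraction`).
#' @param thresholds A [call_thresholds()].
#' @return `calls` with a `flags` column (comma-joined subset of
#'   `low_score`, `low_bq`, `strand_bias`, `fraction_out_of_range`; empty
#'   string when clean) and logical `pass`.
#' @export
apply_filters <- function(calls, thresholds = call_thresholds()) {
  stopifnot(inherits(thresholds, "call_thresholds"),
            all(c("score", "mean_bq", "fwd_frac", "allele_fraction")
                %in% names(calls)))
  th <- thresholds
  fl <- cbind(
    low_score = calls$score <= th$min_score,
    low_bq = calls$mean_bq <= th$min_bq,
    strand_bias = calls$fwd_frac < th$strand_lo | calls$fwd_frac > th$strand_hi,
    fraction_out_of_range = calls$allele_fraction < th$af_lo |
      calls$allele_fraction > th$af_hi)
  calls$flags <- apply(fl, 1L, function(r) paste(colnames(fl)[r], collapse = ","))
  calls$pass <- !apply(fl, 1L, any)
  calls
}

#' Flag calls at positions with coverage under a review threshold
#'
#' Calls at depth below `depth_threshold` (strictly under; depth exactly at
#' the threshold is not flagged) receive `low_coverage_review = TRUE`. They
#' are not excluded: the flag marks them for individual assessment, and
#' downstream reports list them separately.
#'
#' @param calls Calls data frame with a `depth` column.
#' @param depth_threshold Review threshold in reads (default 1000).
#' @return `calls` with a logical `low_coverage_review` column.
#' @export
flag_low_coverage <- function(calls, depth_threshold = 1000) {
  calls$low_coverage_review <- calls$depth < depth_threshold
  calls
}

#' Score and filter all candidates in a pileup
#'
#' Convenience wrapper: computes allele fractions and likelihood-ratio scores
#' for every pileup row, applies the filter stack and the low-coverage review
#' flag.
#'
#' @param pileup Pileup data frame (see [simulate_cohort()] for the schema).
#' @param error_rate Per-base substitution error rate used in scoring. This
#'   is a knob independent from the simulation's error model: on real data it
#'   would be estimated from the run.
#' @param thresholds A [call_thresholds()].
#' @return A calls data frame: the pileup columns plus `allele_fraction`,
#'   `score`, `flags`, `pass`, `low_coverage_review`.
#' @export
call_variants <- function(pileup, error_rate = 1e-3,
                          thresholds = call_thresholds()) {
  calls <- pileup
  calls$allele_fraction <- ifelse(calls$depth > 0,
                                  calls$alt_count / calls$depth, 0)
  calls$score <- score_candidate(calls$alt_count, calls$depth, error_rate)
  calls <- apply_filters(calls, thresholds)
  calls <- flag_low_coverage(calls, thresholds$review_depth)
  attr(calls, "artifacts") <- attr(pileup, "artifacts")
  calls
}

#' Per-filter exclusion ledger
#'
#' Tallies calls by their primary exclusion reason (first failing filter in
#' the fixed order score, base quality, strand, fraction) plus the passing
#' count. The ledger sums to the total number of candidate calls.
#'
#' @param calls Filtered calls from [apply_filters()] / [call_variants()].
#' @return Named integer vector: `low_score`, `low_bq`, `strand_bias`,
#'   `fraction_out_of_range`, `pass`.
#' @export
filter_ledger <- function(calls) {
  reasons <- c("low_score", "low_bq", "strand_bias", "fraction_out_of_range")
  primary <- vapply(strsplit(calls$flags, ",", fixed = TRUE),
                    function(f) if (length(f) == 0L || f[1L] == "") "pass"
                    else reasons[min(match(f, reasons))],
                    "")
  out <- stats::setNames(integer(5L), c(reasons, "pass"))
  tab <- table(primary)
  out[names(tab)] <- as.integer(tab)
  out
}
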