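#' Round half away from zero
#'
#' Display rounding used for ratios and percentages (table style), as opposed
#' to R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Carrier percentage
#'
#' @param k Carrier count.
#' @param n Cohort size.
#' @param digits Decimal places (2 for table-style display, 1 for headline
#'   figures).
#' @return Percentage, rounded half away from zero.
#' @export
percent <- function(k, n, digits = 2L) {
  stopifnot(all(n > 0))
  round_half_up(100 * k / n, digits)
}

#' Build a two-cohort carrier table
#'
#' @param carriers_a,n_a Carrier count and size of cohort A.
#' @param carriers_b,n_b Carrier count and size of cohort B.
#' @param label Row label (gene, gene subset, or "all").
#' @param tier Variant tier in force (e.g. "all" or "likely_pathogenic").
#' @return A `carrier_table` (one-row data frame).
#' @export
carrier_table <- function(carriers_a, n_a, carriers_b, n_b,
                          label = "all", tier = "all") {
  stopifnot(carriers_a >= 0, carriers_a <= n_a,
            carriers_b >= 0, carriers_b <= n_b, n_a > 0, n_b > 0)
  structure(data.frame(label = label, tier = tier,
                       carriers_a = carriers_a, n_a = n_a,
                       carriers_b = carriers_b, n_b = n_b,
                       stringsAsFactors = FALSE),
            class = c("carrier_table", "data.frame"))
}

#' Ratio of carrier proportions (risk ratio)
#'
#' The headline burden statistic: `(carriers_a/n_a) / (carriers_b/n_b)`. This
#' is the statistic whose display-rounded values match the published
#' association figures; the classical odds ratio is provided separately by
#' [odds_ratio()]. Returns `Inf` when cohort B has carriers_b = 0 and cohort A
#' does not (undefined marker), and `NaN` when both are 0.
#'
#' @param t A [carrier_table()].
#' @return The proportion ratio (unrounded; use [round_half_up()] for
#'   display).
#' @export
ratio_statistic <- function(t) {
  stopifnot(t$n_a > 0, t$n_b > 0)
  (t$carriers_a / t$n_a) / (t$carriers_b / t$n_b)
}

#' Classical odds ratio of a 2x2 carrier table
#'
#' `(a * (n_b - b)) / ((n_a - a) * b)` for carriers a, b. No continuity
#' correction: any zero cell yields the undefined marker (`Inf` or `NaN`).
#'
#' @param t A [carrier_table()].
#' @return The odds ratio.
#' @export
odds_ratio <- function(t) {
  a <- t$carriers_a; b <- t$carriers_b
  (a * (t$n_b - b)) / ((t$n_a - a) * b)
}

#' Exact two-sided test of a 2x2 carrier table
#'
#' Conditional on the margins, the carrier count of cohort A follows a
#' hypergeometric distribution. The two-sided p-value is computed by full
#' enumeration over the support: the sum of the probabilities of all tables
#' whose probability does not exceed the observed table's (the standard
#' "minimum-likelihood" two-sided rule).
#'
#' @param carriers_a,n_a,carriers_b,n_b The 2x2 cells, or a
#'   [carrier_table()] via [burden_test()].
#' @return Two-sided p-value in `[0, 1]`.
#' @export
fisher_exact_2x2 <- function(carriers_a, n_a, carriers_b, n_b) {
  stopifnot(carriers_a >= 0, carriers_b >= 0,
            carriers_a <= n_a, carriers_b <= n_b)
  m <- carriers_a + carriers_b
  support <- max(0L, m - n_b):min(n_a, m)
  probs <- stats::dhyper(support, n_a, n_b, m)
  p_obs <- stats::dhyper(carriers_a, n_a, n_b, m)
  # tolerance guards against ties lost to floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Burden statistics for a carrier table
#'
#' Combines the carrier table with its proportion ratio, classical odds
#' ratio, per-cohort percentages and exact two-sided p-value.
#'
#' @param t A [carrier_table()].
#' @return A one-row data frame: the table columns plus `pct_a`, `pct_b`
#'   (2-decimal display), `ratio`, `odds_ratio` (unrounded), `ratio_display`
#'   (2-decimal), `p_two_sided`.
#' @export
burden_test <- function(t) {
  stopifnot(inherits(t, "carrier_table"))
  out <- as.data.frame(t)
  out$pct_a <- percent(t$carriers_a, t$n_a)
  out$pct_b <- percent(t$carriers_b, t$n_b)
  out$ratio <- ratio_statistic(t)
  out$ratio_display <- round_half_up(out$ratio, 2L)
  out$odds_ratio <- odds_ratio(t)
  out$p_two_sided <- fisher_exact_2x2(t$carriers_a, t$n_a,
                                      t$carriers_b, t$n_b)
  out
}

#' Tabulate distinct carrier individuals per cohort
#'
#' Counts, per cohort, the distinct individuals carrying at least one
#' qualifying variant (tier in `tiers`, gene in `genes` when given). An
#' individual carrying several qualifying variants is counted once.
#'
#' @param prioritized Prioritized variants from [prioritize_variants()]
#'   (needs `carriers`, `tier` and -- when `genes` is used -- `gene`).
#' @param cohorts Sample-to-cohort mapping: data frame with `sample_id`,
#'   `cohort`, and `n` (cohort size) or a separate `cohort_sizes` named
#'   vector.
#' @param cohort_a,cohort_b The two cohort labels to compare.
#' @param cohort_sizes Named vector of cohort sizes (needed because carriers
#'   are a subset of each cohort).
#' @param genes Optional gene subset; `NULL` means all genes.
#' @param tiers Qualifying tiers.
#' @param label Label for the resulting table row.
#' @return A [carrier_table()].
#' @export
tabulate_carriers <- function(prioritized, cohorts, cohort_a, cohort_b,
                              cohort_sizes, genes = NULL,
                              tiers = c("likely_pathogenic",
                                        "known_pathogenic"),
                              label = NULL) {
  keep <- prioritized$tier %in% tiers
  if (!is.null(genes)) keep <- keep & prioritized$gene %in% genes
  carriers <- unique(unlist(strsplit(
    prioritized$carriers[keep & prioritized$carriers != ""], ",",
    fixed = TRUE)))
  ci <- match(carriers, cohorts$sample_id)
  if (anyNA(ci)) {
    stop(sprintf("carrier sample(s) missing cohort assignment: %s",
                 paste(carriers[is.na(ci)], collapse = ", ")))
  }
  coh <- cohorts$cohort[ci]
  if (is.null(label)) {
    label <- if (is.null(genes)) "all" else paste(genes, collapse = ",")
  }
  carrier_table(sum(coh == cohort_a), cohort_sizes[[cohort_a]],
                sum(coh == cohort_b), cohort_sizes[[cohort_b]],
                label = label, tier = paste(tiers, collapse = "+"))
}

#' Burden report from published per-gene carrier counts
#'
#' Computes the ratio statistic, odds ratio, percentages and exact p for each
#' row of a counts table (columns `label`, `tier`, `carriers_a`, `n_a`,
#' `carriers_b`, `n_b`).
#'
#' @param counts Data frame of carrier counts.
#' @return Data frame with one [burden_test()] row per input row.
#' @export
burden_report <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    burden_test(carrier_table(counts$carriers_a[i], counts$n_a[i],
                              counts$carriers_b[i], counts$n_b[i],
                              label = counts$label[i], tier = counts$tier[i]))
  })
  do.call(rbind, rows)
}
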