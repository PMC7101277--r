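#' Region filter: exonic or near-splice variants only
#'
#' Keeps exonic consequences (missense, nonsense, frameshift, synonymous,
#' other exonic) and splice variants within 6 bases of the exon boundary
#' (canonical splice sites and `splice_region` with offset <= 6). Intronic
#' variants beyond the +/-6 window are excluded as uninterpretable.
#'
#' @param consequence Character vector of consequence classes: one of
#'   `missense`, `nonsense`, `frameshift`, `canonical_splice`,
#'   `splice_region`, `synonymous`, `intronic`, `other`.
#' @param splice_offset Distance from the exon boundary for splice/intronic
#'   classes (positive integer; `NA` otherwise).
#' @return Data frame with logical `keep` and character `reason` (`""` when
#'   kept).
#' @export
region_filter <- function(consequence, splice_offset = NA_integer_) {
  exonic <- c("missense", "nonsense", "frameshift", "synonymous", "other")
  n <- length(consequence)
  splice_offset <- rep_len(splice_offset, n)
  keep <- consequence %in% exonic |
    consequence == "canonical_splice" |
    (consequence == "splice_region" & !is.na(splice_offset) & splice_offset <= 6)
  reason <- ifelse(keep, "",
                   ifelse(consequence == "splice_region", "splice_offset_gt_6",
                          "intronic"))
  data.frame(keep = keep, reason = reason, stringsAsFactors = FALSE)
}

#' Rarity filter: population frequency and homozygote rule
#'
#' Keeps a variant only if its maximum frequency across population databases
#' is at most 1/1000 and it has never been observed in a homozygous state.
#' A variant at 1/945 fails (1/945 > 1/1000: the bound is strict on
#' "higher than"). Variants with missing annotation are excluded
#' conservatively with reason `unannotated`.
#'
#' @param max_freq Maximum population frequency across databases, in
#'   `[0, 1]`; `NA` for unannotated.
#' @param hom_seen Logical: homozygote observed in any database.
#' @return Data frame with logical `keep` and character `reason`
#'   (`""`, `frequency_gt_1_in_1000`, `homozygote_seen`, `unannotated`).
#' @export
rarity_filter <- function(max_freq, hom_seen) {
  n <- max(length(max_freq), length(hom_seen))
  max_freq <- rep_len(max_freq, n)
  hom_seen <- rep_len(hom_seen, n)
  unann <- is.na(max_freq) | is.na(hom_seen)
  too_common <- !unann & max_freq > 1 / 1000
  hom <- !unann & !too_common & hom_seen
  keep <- !unann & !too_common & !hom
  reason <- ifelse(keep, "",
                   ifelse(unann, "unannotated",
                          ifelse(too_common, "frequency_gt_1_in_1000",
                                 "homozygote_seen")))
  data.frame(keep = keep, reason = reason, stringsAsFactors = FALSE)
}

#' Classify pathogenicity of rare variants
#'
#' The cascade, applied to variants that already passed the region and rarity
#' filters: variants with experimentally validated functional consequences are
#' `known_pathogenic`; loss-of-function consequences (nonsense, frameshift,
#' canonical splice) are `likely_pathogenic`; missense variants predicted
#' damaging by both in-silico scores (Condel > 0.522 AND CADD > 20) are
#' `likely_pathogenic`; everything else that survived the filters is
#' `rare_RSV`. Synonymous variants can pass the filters but never reach
#' `likely_pathogenic`. Gene-level constraint (pLI > 0.50 and missense
#' Z > 0) is attached as metadata (`gene_constrained`), not used as a gate:
#' making it a gate would change the carrier counts.
#'
#' @param ann Data frame of annotated variants with columns `consequence`,
#'   `condel`, `cadd`, `known_functional`, and `gene` when `constraint` is
#'   given.
#' @param constraint Optional gene constraint table with columns `gene`,
#'   `pli`, `mis_z`.
#' @return `ann` with `tier` (`known_pathogenic`, `likely_pathogenic`,
#'   `rare_RSV`) and logical `gene_constrained` (NA when no constraint data).
#' @export
classify_pathogenicity <- function(ann, constraint = NULL) {
  lof <- c("nonsense", "frameshift", "canonical_splice")
  damaging <- ann$consequence == "missense" &
    !is.na(ann$condel) & !is.na(ann$cadd) &
    ann$condel > 0.522 & ann$cadd > 20
  tier <- ifelse(!is.na(ann$known_functional) & ann$known_functional,
                 "known_pathogenic",
                 ifelse(ann$consequence %in% lof | damaging,
                        "likely_pathogenic", "rare_RSV"))
  ann$tier <- tier
  if (!is.null(constraint)) {
    i <- match(ann$gene, constraint$gene)
    ann$gene_constrained <- constraint$pli[i] > 0.50 & constraint$mis_z[i] > 0
  } else {
    ann$gene_constrained <- NA
  }
  ann
}

#' Run the full prioritization cascade over decoded variants
#'
#' Joins decoded variants to the annotation table by variant key, applies the
#' region filter, the rarity filter and the pathogenicity classification, and
#' reports every variant with a tier or a single primary exclusion reason.
#' The cascade is a pure function of each annotation row: row order is
#' irrelevant and excluded variants are retained, so the per-reason ledger
#' plus kept variants always sums to the input.
#'
#' @param decoded Decoded variants from [decode_variants()] (needs `key`; the
#'   carrier and status columns are carried through).
#' @param annotations Annotation table with columns `key`, `gene`,
#'   `consequence`, `splice_offset`, `max_freq`, `hom_seen`, `condel`,
#'   `cadd`, `known_functional`.
#' @param constraint Optional gene constraint table (`gene`, `pli`, `mis_z`).
#' @return `decoded` joined to its annotations, with `tier`
#'   (`known_pathogenic`, `likely_pathogenic`, `rare_RSV`, `excluded`),
#'   `exclusion_reason` (`""` unless excluded) and `gene_constrained`.
#' @export
prioritize_variants <- function(decoded, annotations, constraint = NULL) {
  stopifnot("key" %in% names(decoded), "key" %in% names(annotations))
  i <- match(decoded$key, annotations$key)
  ann_cols <- setdiff(names(annotations), "key")
  out <- decoded
  for (cn in ann_cols) out[[cn]] <- annotations[[cn]][i]
  unmatched <- is.na(i)

  rf <- region_filter(out$consequence, out$splice_offset)
  qf <- rarity_filter(out$max_freq, out$hom_seen)
  out <- classify_pathogenicity(out, constraint)

  excl_reason <- ifelse(unmatched, "unannotated",
                        ifelse(!rf$keep, rf$reason,
                               ifelse(!qf$keep, qf$reason, "")))
  excluded <- excl_reason != ""
  out$tier[excluded] <- "excluded"
  out$exclusion_reason <- excl_reason
  out
}

#' Exclusion ledger for a prioritized table
#'
#' @param prioritized Output of [prioritize_variants()].
#' @return Named integer vector of exclusion reasons plus kept tiers; sums to
#'   `nrow(prioritized)`.
#' @export
prioritization_ledger <- function(prioritized) {
  lab <- ifelse(prioritized$tier == "excluded",
                prioritized$exclusion_reason, prioritized$tier)
  tab <- table(lab)
  stats::setNames(as.integer(tab), names(tab))
}
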