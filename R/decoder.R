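#' Estimate allele copy count from a pool allele fraction
#'
#' Inverts the dilution arithmetic: `copies = round(fraction * 2 * pool_size)`
#' (nearest whole allele count, halves away from zero). A 2.5% fraction in a
#' 20-sample pool corresponds to one allele copy, 5% to two.
#'
#' @param fraction Allele fraction(s) in `[0, 1]`.
#' @param pool_size Number of diploid samples per pool.
#' @return Integer copy count(s).
#' @export
estimate_copies <- function(fraction, pool_size) {
  stopifnot(all(fraction >= 0), all(fraction <= 1), pool_size >= 1)
  as.integer(floor(fraction * 2 * pool_size + 0.5))
}

#' Decode variant carriers by pool intersection
#'
#' Groups passing calls by variant and intersects the supporting pools with
#' the design. A variant seen in exactly two pools forming an assigned pair
#' decodes to that pair's sample (`unique`). A variant seen in more than two
#' pools triggers an exhaustive cover search: the smallest set of samples (up
#' to `max_carriers`) whose pool pairs exactly cover the supporting pools. A
#' unique minimal cover gives `multi_carrier`; several minimal covers give
#' `ambiguous`; one supporting pool, or no consistent cover, gives
#' `undecodable` (a het carrier must show in both of its pools). Ambiguous and
#' undecodable variants are reported, never dropped -- they are the method's
#' measurable failure modes.
#'
#' @param calls Calls data frame from [call_variants()]; by default only
#'   passing calls are decoded.
#' @param design The `pool_design` of the cohort.
#' @param max_carriers Cap on carriers per variant in the cover search. The
#'   10% allele-fraction ceiling makes three or more carrier alleles per pool
#'   "too common" by construction, so 3 is the default.
#' @param passing_only If `TRUE` (default), restrict to `pass == TRUE` calls.
#' @return A data frame of decoded variants: `key`, `contig`, `pos`, `ref`,
#'   `alt`, `pools` (comma-joined supporting pool ids), `n_pools`, `carriers`
#'   (comma-joined sorted sample ids, empty when none), `copies`
#'   (comma-joined per supporting pool, via [estimate_copies()]), `max_af`,
#'   `status` (`unique`, `multi_carrier`, `ambiguous`, `undecodable`).
#' @export
decode_variants <- function(calls, design, max_carriers = 3L,
                            passing_only = TRUE) {
  stopifnot(inherits(design, "pool_design"))
  if (passing_only && "pass" %in% names(calls)) {
    calls <- calls[calls$pass, , drop = FALSE]
  }
  if (any(calls$pool_id < 0L | calls$pool_id >= design$n_pools)) {
    stop("unknown pool_id in calls for this design")
  }
  empty <- data.frame(key = character(0), contig = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      pools = character(0), n_pools = integer(0),
                      carriers = character(0), copies = character(0),
                      max_af = numeric(0), status = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(empty)

  key <- variant_key(calls$contig, calls$pos, calls$ref, calls$alt)
  groups <- split(seq_len(nrow(calls)), key)
  asg <- design$assignment

  decode_one <- function(idx) {
    g <- calls[idx, , drop = FALSE]
    g <- g[!duplicated(g$pool_id), , drop = FALSE]
    pools <- sort(g$pool_id)
    af <- g$allele_fraction[order(g$pool_id)]
    copies <- estimate_copies(af, design$pool_size)
    res <- list(key = variant_key(g$contig[1L], g$pos[1L], g$ref[1L], g$alt[1L]),
                contig = g$contig[1L], pos = g$pos[1L],
                ref = g$ref[1L], alt = g$alt[1L],
                pools = paste(pools, collapse = ","),
                n_pools = length(pools),
                carriers = "", copies = paste(copies, collapse = ","),
                max_af = max(af), status = "undecodable")
    if (length(pools) < 2L) return(as.data.frame(res, stringsAsFactors = FALSE))
    if (length(pools) == 2L) {
      s <- pool_pair_sample(design, pools[1L], pools[2L])
      if (!is.na(s)) {
        res$carriers <- s
        res$status <- "unique"
      }
      return(as.data.frame(res, stringsAsFactors = FALSE))
    }
    # >2 pools: minimal exact cover by candidate samples' pool pairs
    cand <- asg[asg$pool_a %in% pools & asg$pool_b %in% pools, , drop = FALSE]
    covers <- find_minimal_covers(cand, pools, max_carriers)
    if (length(covers) == 1L) {
      res$carriers <- paste(sort(covers[[1L]]), collapse = ",")
      res$status <- "multi_carrier"
    } else if (length(covers) > 1L) {
      res$carriers <- paste(
        vapply(covers, function(cv) paste(sort(cv), collapse = ","), ""),
        collapse = ";")
      res$status <- "ambiguous"
    }
    as.data.frame(res, stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(groups, decode_one))
  rownames(out) <- NULL
  out[order(out$contig, out$pos, out$alt), , drop = FALSE]
}

# All minimal-cardinality sample subsets (size <= max_carriers) whose pool
# pairs exactly cover `pools`. `cand` rows are samples whose both pools lie
# within `pools`.
find_minimal_covers <- function(cand, pools, max_carriers) {
  if (nrow(cand) == 0L) return(list())
  need <- ceiling(length(pools) / 2)
  for (k in seq.int(need, max_carriers)) {
    if (k > nrow(cand)) break
    combos <- utils::combn(nrow(cand), k, simplify = FALSE)
    hits <- Filter(function(rows) {
      setequal(c(cand$pool_a[rows], cand$pool_b[rows]), pools)
    }, combos)
    if (length(hits)) {
      return(lapply(hits, function(rows) cand$sample_id[rows]))
    }
  }
  list()
}

#' Write decoded variants as a minimal VCF (with TSV mirror)
#'
#' Emits a minimal VCFv4.2 file with one record per decoded variant; the
#' supporting pools, carrier samples, estimated copies, decoding status and
#' maximum pool allele fraction are stored as INFO fields (no per-sample
#' genotype columns). A TSV mirror of the decoded table is written alongside
#' when `tsv_path` is given.
#'
#' @param decoded Decoded variants from [decode_variants()].
#' @param path Output VCF path.
#' @param tsv_path Optional TSV mirror path.
#' @return `path`, invisibly.
#' @export
write_decoded_vcf <- function(decoded, path, tsv_path = NULL) {
  info_def <- c(
    '##fileformat=VCFv4.2',
    '##INFO=<ID=POOLS,Number=.,Type=String,Description="Supporting pool ids">',
    '##INFO=<ID=CARRIERS,Number=.,Type=String,Description="Decoded carrier sample ids">',
    '##INFO=<ID=COPIES,Number=.,Type=String,Description="Estimated allele copies per supporting pool">',
    '##INFO=<ID=STATUS,Number=1,Type=String,Description="Decoding status: unique, multi_carrier, ambiguous or undecodable">',
    '##INFO=<ID=MAXAF,Number=1,Type=Float,Description="Maximum pool allele fraction">',
    '#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO')
  recs <- character(0)
  if (nrow(decoded) > 0L) {
    info <- sprintf("POOLS=%s;CARRIERS=%s;COPIES=%s;STATUS=%s;MAXAF=%.4g",
                    gsub(",", "|", decoded$pools),
                    ifelse(decoded$carriers == "", ".",
                           gsub(",", "|", decoded$carriers)),
                    gsub(",", "|", decoded$copies),
                    decoded$status, decoded$max_af)
    recs <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    decoded$contig, decoded$pos, decoded$ref, decoded$alt,
                    info)
  }
  writeLines(c(info_def, recs), path)
  if (!is.null(tsv_path)) {
    utils::write.table(decoded, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
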