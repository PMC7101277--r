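#' Assemble a pipeline run configuration
#'
#' A run configuration bundles every parameter of the end-to-end workflow:
#' pool geometry per cohort, coverage and error models, filter thresholds,
#' planted variants, artifact load, optional annotation/constraint tables and
#' the mandatory master seed. Per-cohort stage seeds are derived
#' deterministically from the master seed, so identical configurations give
#' identical outputs.
#'
#' @param seed Master integer seed (mandatory).
#' @param cohorts Named list; each element a list with `n_samples`,
#'   `n_pools`, `coverage` (a [coverage_model()]) and `variants` (a
#'   [variant_spec()] data frame, possibly empty).
#' @param regions Target regions data frame (`contig`, `start`, `end`).
#' @param pool_size Samples per pool.
#' @param error An [error_model()].
#' @param thresholds A [call_thresholds()].
#' @param n_artifacts Artifacts injected per cohort.
#' @param annotations,constraint Optional prioritizer inputs.
#' @param subset_genes Optional gene subset for the burden comparison.
#' @return A `run_config` list.
#' @export
run_config <- function(seed, cohorts, regions, pool_size = 20L,
                       error = error_model(),
                       thresholds = call_thresholds(),
                       n_artifacts = 0L, annotations = NULL,
                       constraint = NULL, subset_genes = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(is.list(cohorts), length(cohorts) >= 1L,
            !is.null(names(cohorts)),
            inherits(error, "error_model"),
            inherits(thresholds, "call_thresholds"))
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    stopifnot(co$n_samples >= 1L, co$n_pools >= 2L,
              inherits(co$coverage, "coverage_model"))
  }
  structure(list(seed = as.integer(seed), cohorts = cohorts,
                 regions = regions, pool_size = as.integer(pool_size),
                 error = error, thresholds = thresholds,
                 n_artifacts = as.integer(n_artifacts),
                 annotations = annotations, constraint = constraint,
                 subset_genes = subset_genes),
            class = "run_config")
}

#' Serialize / deserialize a run configuration as YAML
#'
#' The configuration round-trips unchanged (data frames are stored as
#' per-column lists).
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ser <- unclass(config)
  ser$error <- unclass(ser$error)
  ser$thresholds <- unclass(ser$thresholds)
  ser$regions <- as.list(ser$regions)
  for (nm in names(ser$cohorts)) {
    ser$cohorts[[nm]]$coverage <- unclass(ser$cohorts[[nm]]$coverage)
    ser$cohorts[[nm]]$variants <- as.list(ser$cohorts[[nm]]$variants)
  }
  for (tb in c("annotations", "constraint")) {
    if (!is.null(ser[[tb]])) ser[[tb]] <- as.list(ser[[tb]])
  }
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohorts <- lapply(raw$cohorts, function(co) {
    co$coverage <- do.call(coverage_model, co$coverage)
    co$variants <- as.data.frame(co$variants, stringsAsFactors = FALSE)
    co
  })
  run_config(seed = raw$seed, cohorts = cohorts,
             regions = as.data.frame(raw$regions, stringsAsFactors = FALSE),
             pool_size = raw$pool_size,
             error = do.call(error_model, raw$error),
             thresholds = do.call(call_thresholds, raw$thresholds),
             n_artifacts = raw$n_artifacts,
             annotations = if (is.null(raw$annotations)) NULL else
               as.data.frame(raw$annotations, stringsAsFactors = FALSE),
             constraint = if (is.null(raw$constraint)) NULL else
               as.data.frame(raw$constraint, stringsAsFactors = FALSE),
             subset_genes = unlist(raw$subset_genes))
}

#' Run the full pooled-sequencing discovery pipeline
#'
#' Executes design -> simulate -> inject artifacts -> score/filter -> decode
#' (-> prioritize when annotations are supplied -> burden when two cohorts
#' are prioritized) and evaluates every cohort against its simulation truth.
#' Identical configuration and seed reproduce identical outputs. Any stage
#' failure aborts with the stage and cohort named.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages on stderr.
#' @return A list with per-cohort `designs`, `pileups`, `truths`, `calls`,
#'   `decoded`, `prioritized` (when annotated), a combined `burden` table
#'   (two annotated cohorts), and `evaluation` (per-cohort
#'   [evaluate_run()] reports plus a pooled report under `combined`).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, cohort, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed for cohort '%s': %s",
                   name, cohort, conditionMessage(e)), call. = FALSE)
    })
  }
  out <- list(designs = list(), pileups = list(), truths = list(),
              calls = list(), decoded = list(), prioritized = list(),
              burden = NULL, evaluation = list())
  for (i in seq_along(config$cohorts)) {
    nm <- names(config$cohorts)[i]
    co <- config$cohorts[[i]]
    seed_i <- config$seed + 1000L * i
    say("stage design [%s]", nm)
    design <- stage("design", nm, build_pool_design(
      co$n_samples, co$n_pools, config$pool_size, cohort = nm,
      seed = seed_i))
    say("stage simulate [%s]", nm)
    sim <- stage("simulate", nm, simulate_cohort(
      design, config$regions, co$variants, cov = co$coverage,
      err = config$error, seed = seed_i + 1L))
    pileup <- sim$pileup
    if (config$n_artifacts > 0L) {
      say("stage inject_artifacts [%s]", nm)
      pileup <- stage("inject_artifacts", nm, inject_artifacts(
        pileup, design, config$regions, err = config$error,
        n = config$n_artifacts, cov = co$coverage, truth = sim$truth,
        seed = seed_i + 2L))
    } else {
      pileup <- inject_artifacts(pileup, design, config$regions,
                                 err = config$error, n = 0L)
    }
    say("stage call [%s]", nm)
    calls <- stage("call", nm, call_variants(
      pileup, error_rate = config$error$error_rate,
      thresholds = config$thresholds))
    say("stage decode [%s]", nm)
    decoded <- stage("decode", nm, decode_variants(calls, design))
    out$designs[[nm]] <- design
    out$pileups[[nm]] <- pileup
    out$truths[[nm]] <- sim$truth
    out$calls[[nm]] <- calls
    out$decoded[[nm]] <- decoded
    if (!is.null(config$annotations)) {
      say("stage prioritize [%s]", nm)
      out$prioritized[[nm]] <- stage("prioritize", nm, prioritize_variants(
        decoded, config$annotations, config$constraint))
    }
    out$evaluation[[nm]] <- stage("evaluate", nm, evaluate_run(
      decoded, sim$truth, artifacts = attr(pileup, "artifacts"),
      calls = calls))
  }
  if (length(out$prioritized) == 2L) {
    nms <- names(config$cohorts)
    sizes <- stats::setNames(
      vapply(config$cohorts, function(co) co$n_samples, 0L), nms)
    both <- do.call(rbind, out$prioritized)
    cohorts_map <- do.call(rbind, lapply(nms, function(nm) {
      data.frame(sample_id = out$designs[[nm]]$assignment$sample_id,
                 cohort = nm, stringsAsFactors = FALSE)
    }))
    say("stage burden")
    tabs <- list(
      tabulate_carriers(both, cohorts_map, nms[1L], nms[2L], sizes,
                        tiers = c("likely_pathogenic", "known_pathogenic",
                                  "rare_RSV"), label = "all_rsv"),
      tabulate_carriers(both, cohorts_map, nms[1L], nms[2L], sizes,
                        label = "likely_pathogenic"))
    if (!is.null(config$subset_genes)) {
      tabs <- c(tabs, list(
        tabulate_carriers(both, cohorts_map, nms[1L], nms[2L], sizes,
                          genes = config$subset_genes,
                          tiers = c("likely_pathogenic", "known_pathogenic",
                                    "rare_RSV"), label = "subset_all_rsv")))
    }
    out$burden <- do.call(rbind, lapply(tabs, burden_test))
  }
  out$evaluation$combined <- combine_evaluations(
    out$evaluation[names(config$cohorts)])
  out
}

#' Evaluate pipeline output against simulation truth
#'
#' Sensitivity counts a planted variant as detected only when it is decoded
#' to exactly its true carrier set (status `unique` or `multi_carrier` with
#' matching carriers). The specificity proxy is the number (and fraction) of
#' injected artifact entries whose (pool, site, allele) survives the filter
#' stack. The ambiguity rate is the fraction of decoded variants with status
#' `ambiguous`. The per-filter ledger conserves candidates:
#' exclusions + passing = total calls.
#'
#' @param decoded Decoded variants from [decode_variants()].
#' @param truth Truth table from [simulate_cohort()].
#' @param artifacts Optional artifact companion table (see
#'   [inject_artifacts()]).
#' @param calls Optional filtered calls for the exclusion ledger.
#' @return An `evaluation_report` list: `applicable`, `n_planted`,
#'   `n_detected`, `sensitivity`, `sensitivity_pct` (whole-percent display),
#'   `n_artifacts_injected`, `n_artifacts_surviving`, `artifact_survival`,
#'   `ambiguity_rate`, `ledger`.
#' @export
evaluate_run <- function(decoded, truth, artifacts = NULL, calls = NULL) {
  rep <- list(applicable = nrow(truth) > 0L)
  if (!rep$applicable) {
    rep$note <- "no planted variants: sensitivity evaluation inapplicable"
    rep$n_planted <- 0L
    rep$n_detected <- NA_integer_
    rep$sensitivity <- NA_real_
    rep$sensitivity_pct <- NA_real_
  } else {
    i <- match(truth$key, decoded$key)
    norm <- function(x) vapply(strsplit(x, ",", fixed = TRUE),
                               function(v) paste(sort(v), collapse = ","), "")
    hit <- !is.na(i) &
      decoded$status[i] %in% c("unique", "multi_carrier") &
      norm(decoded$carriers[i]) == norm(truth$carriers)
    rep$n_planted <- nrow(truth)
    rep$n_detected <- sum(hit)
    rep$sensitivity <- rep$n_detected / rep$n_planted
    rep$sensitivity_pct <- round(100 * rep$sensitivity)
  }
  if (!is.null(artifacts) && nrow(artifacts) > 0L && !is.null(calls)) {
    ak <- paste(artifacts$pool_id, artifacts$contig, artifacts$pos,
                artifacts$alt)
    ck <- paste(calls$pool_id, calls$contig, calls$pos, calls$alt)
    surv <- ak %in% ck[calls$pass]
    rep$n_artifacts_injected <- nrow(artifacts)
    rep$n_artifacts_surviving <- sum(surv)
    rep$artifact_survival <- mean(surv)
  } else {
    rep$n_artifacts_injected <- if (is.null(artifacts)) NA_integer_ else 0L
    rep$n_artifacts_surviving <- 0L
    rep$artifact_survival <- NA_real_
  }
  rep$ambiguity_rate <- if (nrow(decoded) > 0L) {
    mean(decoded$status == "ambiguous")
  } else NA_real_
  rep$ledger <- if (!is.null(calls)) filter_ledger(calls) else NULL
  structure(rep, class = "evaluation_report")
}

combine_evaluations <- function(reports) {
  planted <- sum(vapply(reports, function(r) r$n_planted, 0L))
  detected <- sum(vapply(reports, function(r) {
    if (is.na(r$n_detected)) 0L else r$n_detected
  }, 0L))
  inj <- vapply(reports, function(r) r$n_artifacts_injected, 0L)
  surv <- vapply(reports, function(r) r$n_artifacts_surviving, 0L)
  structure(list(
    applicable = planted > 0L,
    n_planted = planted, n_detected = detected,
    sensitivity = if (planted > 0L) detected / planted else NA_real_,
    sensitivity_pct = if (planted > 0L) round(100 * detected / planted)
    else NA_real_,
    n_artifacts_injected = sum(inj, na.rm = TRUE),
    n_artifacts_surviving = sum(surv, na.rm = TRUE),
    artifact_survival = if (sum(inj, na.rm = TRUE) > 0L) {
      sum(surv, na.rm = TRUE) / sum(inj, na.rm = TRUE)
    } else NA_real_,
    ambiguity_rate = NA_real_, ledger = NULL),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  if (x$applicable) {
    cat(sprintf("sensitivity: %d/%d planted variants decoded to their true carriers (%.0f%%)\n",
                x$n_detected, x$n_planted, 100 * x$sensitivity))
  } else {
    cat("sensitivity evaluation inapplicable (no planted variants)\n")
  }
  if (!is.na(x$n_artifacts_injected) && x$n_artifacts_injected > 0L) {
    cat(sprintf("artifacts surviving filters: %d/%d\n",
                x$n_artifacts_surviving, x$n_artifacts_injected))
  }
  if (!is.null(x$ledger)) {
    cat("filter ledger:", paste(names(x$ledger), x$ledger, sep = "=",
                                collapse = " "), "\n")
  }
  invisible(x)
}
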