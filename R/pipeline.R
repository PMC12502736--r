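# End-to-end orchestration: ingest -> dedup -> cohort -> descriptives ->
# time-to-onset -> signals -> modelling -> network -> consistency, with a
# run manifest for reproducibility.

#' Demo pipeline configuration
#'
#' A small synthetic configuration exercising every stage: a catalogue of
#' 40 drugs with 4 planted associations, duplicates, missingness and
#' Weibull latencies.
#'
#' @param seed integer seed
#' @param n_reports corpus size
#' @return a `pipeline_config` list
#' @export
demo_config <- function(seed = 1, n_reports = 20000) {
  catalog <- rbind(default_drug_catalog(),
                   synthetic_drug_catalog(16))
  planted <- c(azacitidine = 12, adalimumab = 8,
               "sulfamethoxazole/trimethoprim" = 10, drug_003 = 6)
  structure(list(
    sim = sim_config(n_reports = n_reports, drug_catalog = catalog,
                     planted_signals = planted, seed = seed),
    event_pt = "Sweet syndrome",
    schemes = c("main", "sensitivity_A", "sensitivity_B"),
    min_cases = 3,
    seed = seed),
    class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes every stage on either a synthetic corpus (when `config$sim` is
#' a [sim_config()]) or FAERS-style quarterly files (when `config$paths`
#' is set), and returns all stage results together with a manifest (seeds,
#' row counts per stage) that makes reruns reproducible.
#'
#' @param config a `pipeline_config`, e.g. [demo_config()]
#' @param out_dir optional directory for TSV exports of the main tables
#' @return object of class `pv_run`: stage results plus `manifest`
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(is.list(config))
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("pvdiss")))
  if (!is.null(config$sim)) {
    corpus <- generate_corpus(config$sim)
    store <- as_faers_store(corpus)
    manifest$truth <- corpus$truth
  } else if (!is.null(config$paths)) {
    store <- read_faers_quarters(config$paths)
  } else stop("config must carry either 'sim' or 'paths'", call. = FALSE)
  manifest$n_raw <- nrow(store$tables$demo)

  dd <- deduplicate_reports(store)
  store <- dd$store
  manifest$n_deduplicated <- nrow(store$tables$demo)
  manifest$n_dropped <- nrow(dd$ledger)

  normalizer <- config$normalizer %||% drug_normalizer(
    atc_map = if (!is.null(config$sim)) config$sim$drug_catalog else NULL)
  classifier <- config$classifier %||% indication_classifier()
  definition <- case_definition(event_pt = config$event_pt)

  cases <- extract_cases(store, definition, normalizer)
  manifest$n_cases <- length(cases$case_ids)

  descr <- summarize_cohort(cases, store)
  atc <- atc_distribution(cases, normalizer)

  lat <- compute_latencies(store, cases)
  tto_sum <- if (nrow(lat$records)) summarize_latency(lat) else NULL
  weib <- if (nrow(lat$records) >= 10) fit_weibull(lat) else NULL

  screen <- screen_signals(store, config$event_pt,
                           min_cases = config$min_cases %||% 3,
                           normalizer = normalizer)
  manifest$n_signals <- sum(screen$signal)

  models <- run_all_schemes(store, config$event_pt,
                            schemes = config$schemes %||% "main",
                            min_cases = config$min_cases %||% 3,
                            normalizer = normalizer,
                            classifier = classifier, seed = config$seed)

  net <- build_cooccurrence(store, cases$case_ids, normalizer = normalizer)

  evidence <- assemble_evidence_matrix(screen, config$external %||% NULL,
                                       config$annotations %||% NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(screen, file.path(out_dir, "signals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(models$forest))
      utils::write.table(models$forest, file.path(out_dir, "forest.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    export_cooccurrence(net, file.path(out_dir, "network_edges.tsv"))
    utils::write.table(evidence, file.path(out_dir, "evidence_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  structure(list(store = store, dedup_ledger = dd$ledger, cases = cases,
                 descriptives = descr, atc = atc, latencies = lat,
                 tto_summary = tto_sum, weibull = weib, screen = screen,
                 models = models, network = net, evidence = evidence,
                 manifest = manifest),
            class = "pv_run")
}

#' @export
print.pv_run <- function(x, ...) {
  m <- x$manifest
  cat("Pharmacovigilance pipeline run\n")
  cat(sprintf("  raw reports %d -> deduplicated %d (dropped %d)\n",
              m$n_raw, m$n_deduplicated, m$n_dropped))
  cat(sprintf("  cases: %d; positive signals: %d\n", m$n_cases, m$n_signals))
  if (!is.null(x$weibull))
    cat(sprintf("  onset: median %.0f d (IQR %.0f-%.0f); Weibull k=%.2f, lambda=%.0f d\n",
                x$tto_summary$median, x$tto_summary$q1, x$tto_summary$q3,
                x$weibull$shape, x$weibull$scale))
  print(x$models)
  invisible(x)
}
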