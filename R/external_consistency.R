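# Cross-database consistency: replicate the disproportionality screen on
# a second corpus supplied in a minimal normalized schema, and assemble
# the multi-source evidence matrix (external signal, literature support,
# product-label listing).

#' Convert a minimal report table to a report store
#'
#' The external corpus (e.g. an extract from a second spontaneous-report
#' database) is consumed through a minimal 4-column schema: `report_id`,
#' `drug`, `role`, `event_pt` — one row per drug-reaction mention. The
#' result is a `faers_store`, so the disproportionality code runs on it
#' unchanged.
#'
#' @param df data frame with the four columns above
#' @return a `faers_store`
#' @export
as_report_store <- function(df) {
  need <- c("report_id", "drug", "role", "event_pt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("mapping error: missing field(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  ids <- unique(as.character(df$report_id))
  demo <- data.frame(primaryid = ids, caseid = ids, fda_dt = "",
                     stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = as.character(df$report_id),
                     caseid = as.character(df$report_id),
                     drug_seq = "1", role_cod = as.character(df$role),
                     drugname = as.character(df$drug),
                     stringsAsFactors = FALSE)
  reac <- unique(data.frame(primaryid = as.character(df$report_id),
                            caseid = as.character(df$report_id),
                            pt = as.character(df$event_pt),
                            stringsAsFactors = FALSE))
  empty <- data.frame(primaryid = character(0), caseid = character(0),
                      stringsAsFactors = FALSE)
  structure(list(tables = list(demo = demo, drug = drug, reac = reac,
                               outc = empty, rpsr = empty, ther = empty,
                               indi = empty),
                 quarters = "external", n_raw = c(demo = nrow(demo))),
            class = "faers_store")
}

#' Replicate the disproportionality screen on an external corpus
#'
#' Runs [screen_signals()] verbatim on the external universe — no logic
#' specific to the primary database leaks in.
#'
#' @param external_store a `faers_store` (e.g. from [as_report_store()])
#' @param drugs standardized drug names to test
#' @param event_pt reaction preferred term
#' @param ... further arguments passed to [screen_signals()]
#' @return a `signal_screen`
#' @export
replicate_screen <- function(external_store, drugs, event_pt, ...) {
  screen_signals(external_store, event_pt, drugs = drugs, ...)
}

#' Assemble the multi-source evidence matrix
#'
#' One row per primary-database signal drug, flagging: the external-corpus
#' signal (at least 3 reports and ROR CI lower bound above 1), literature
#' support and product-label listing. The latter two come from a curated
#' annotation table (columns `drug`, `literature_support`, `citations`,
#' `label_listed`, `label_source`), never from scraping. Annotation rows
#' for drugs outside the signal list are skipped with a warning.
#'
#' @param faers_signals a `signal_screen` from the primary database
#' @param external_signals a `signal_screen` from [replicate_screen()],
#'   or `NULL`
#' @param annotations annotation data frame, or `NULL`
#' @return data frame of class `evidence_matrix`; attribute `overlap`
#'   carries the summary counts
#' @export
assemble_evidence_matrix <- function(faers_signals, external_signals = NULL,
                                     annotations = NULL) {
  drugs <- faers_signals$drug[faers_signals$signal]
  out <- data.frame(drug = drugs, faers_signal = TRUE,
                    external_signal = FALSE, external_n = NA_integer_,
                    external_ror = NA_real_, external_ci_low = NA_real_,
                    external_ci_high = NA_real_,
                    literature_support = FALSE, citations = "",
                    label_listed = FALSE, label_source = "",
                    stringsAsFactors = FALSE)
  if (!is.null(external_signals)) {
    i <- match(drugs, external_signals$drug)
    hit <- !is.na(i)
    out$external_n[hit] <- external_signals$n[i[hit]]
    out$external_ror[hit] <- external_signals$ror[i[hit]]
    out$external_ci_low[hit] <- external_signals$ci_low[i[hit]]
    out$external_ci_high[hit] <- external_signals$ci_high[i[hit]]
    out$external_signal[hit] <- external_signals$signal[i[hit]]
  }
  if (!is.null(annotations) && nrow(annotations)) {
    unknown <- setdiff(annotations$drug, drugs)
    if (length(unknown))
      warning(sprintf("annotation drug(s) not in the signal list, skipped: %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
    ann <- annotations[annotations$drug %in% drugs, , drop = FALSE]
    i <- match(ann$drug, out$drug)
    if ("literature_support" %in% names(ann))
      out$literature_support[i] <- as.logical(ann$literature_support)
    if ("citations" %in% names(ann))
      out$citations[i] <- as.character(ann$citations)
    if ("label_listed" %in% names(ann))
      out$label_listed[i] <- as.logical(ann$label_listed)
    if ("label_source" %in% names(ann))
      out$label_source[i] <- as.character(ann$label_source)
  }
  attr(out, "overlap") <- c(
    n_signals = nrow(out),
    n_external = sum(out$external_signal),
    n_literature = sum(out$literature_support),
    n_label = sum(out$label_listed))
  class(out) <- c("evidence_matrix", "data.frame")
  out
}

#' @export
print.evidence_matrix <- function(x, ...) {
  ov <- attr(x, "overlap")
  cat(sprintf("Evidence matrix: %d signal drug(s); external overlap %d, literature %d, label %d\n",
              ov["n_signals"], ov["n_external"], ov["n_literature"],
              ov["n_label"]))
  invisible(x)
}
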