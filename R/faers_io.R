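# Reading FAERS-style quarterly ASCII extracts and case-level deduplication.

#' Column alias map for quarter-era schema drift
#'
#' Maps header variants seen across quarters onto the canonical lowercase
#' schema. Matching is case-insensitive; unknown columns are preserved under
#' their original (lowercased) names. Users with pre-2012 ISR-era files can
#' extend this map.
#'
#' @return named character vector: alias -> canonical name
#' @export
faers_alias_map <- function() {
  c(isr = "primaryid", "case" = "caseid", gndr_cod = "sex",
    i_f_cod = "i_f_code", pt = "pt", drugname = "drugname",
    indi_pt = "indi_pt")
}

.read_dollar_file <- function(path) {
  df <- utils::read.table(path, sep = "$", header = TRUE, quote = "\"",
                          comment.char = "", colClasses = "character",
                          check.names = FALSE, fill = TRUE,
                          stringsAsFactors = FALSE, na.strings = NULL,
                          encoding = "UTF-8")
  names(df) <- tolower(names(df))
  df
}

.table_of_file <- function(path) {
  base <- toupper(basename(path))
  for (nm in names(.faers_file_names))
    if (startsWith(base, .faers_file_names[[nm]])) return(nm)
  NA_character_
}

#' Read FAERS-style quarterly ASCII tables
#'
#' Accepts directories (scanned for `DEMO*`/`DRUG*`/... files) or
#' individual file paths, reads the $-delimited tables, lowercases and
#' alias-maps headers onto a canonical schema and concatenates quarters.
#' Rows of the DEMO table whose PRIMARYID does not parse as an integer are
#' counted as malformed; if their fraction exceeds `tolerance` reading
#' aborts with an integrity error, otherwise they are dropped with a
#' message.
#'
#' @param paths character vector of directories and/or files
#' @param alias_map header alias map, see [faers_alias_map()]
#' @param tolerance maximum tolerated fraction of malformed DEMO rows
#' @return object of class `faers_store`: list of the seven canonical
#'   tables, the source quarter labels and raw row counts
#' @export
read_faers_quarters <- function(paths, alias_map = faers_alias_map(),
                                tolerance = 0.01) {
  files <- character(0)
  for (p in paths) {
    if (dir.exists(p)) {
      files <- c(files, list.files(p, pattern = "\\.(txt|TXT)$",
                                   full.names = TRUE))
    } else if (file.exists(p)) {
      files <- c(files, p)
    } else stop(sprintf("path '%s' does not exist", p), call. = FALSE)
  }
  tab_of <- vapply(files, .table_of_file, character(1))
  files <- files[!is.na(tab_of)]
  tab_of <- tab_of[!is.na(tab_of)]
  if (!length(files)) stop("no FAERS tables found in the given paths",
                           call. = FALSE)

  tables <- stats::setNames(vector("list", length(.faers_file_names)),
                            names(.faers_file_names))
  for (i in seq_along(files)) {
    df <- .read_dollar_file(files[i])
    hit <- names(df) %in% names(alias_map)
    names(df)[hit] <- unname(alias_map[names(df)[hit]])
    nm <- tab_of[i]
    tables[[nm]] <- if (is.null(tables[[nm]])) df else {
      all_cols <- union(names(tables[[nm]]), names(df))
      for (cl in setdiff(all_cols, names(tables[[nm]])))
        tables[[nm]][[cl]] <- ""
      for (cl in setdiff(all_cols, names(df))) df[[cl]] <- ""
      rbind(tables[[nm]][all_cols], df[all_cols])
    }
  }
  if (is.null(tables$demo))
    stop("schema error: no DEMO table found", call. = FALSE)
  for (must in c("primaryid", "caseid"))
    if (!must %in% names(tables$demo))
      stop(sprintf("schema error: mandatory column '%s' missing from DEMO",
                   must), call. = FALSE)

  n_raw <- nrow(tables$demo)
  bad <- is.na(suppressWarnings(as.numeric(tables$demo$primaryid)))
  if (any(bad)) {
    if (mean(bad) > tolerance)
      stop(sprintf(
        "integrity error: %.1f%% of DEMO rows have unparseable PRIMARYID",
        100 * mean(bad)), call. = FALSE)
    message(sprintf("dropping %d malformed DEMO row(s)", sum(bad)))
    tables$demo <- tables$demo[!bad, , drop = FALSE]
  }
  for (nm in names(tables))
    if (is.null(tables[[nm]]))
      tables[[nm]] <- data.frame(primaryid = character(0), caseid = character(0),
                                 stringsAsFactors = FALSE)

  quarters <- unique(gsub("^[A-Z]+|\\.(txt|TXT)$", "", basename(files)))
  structure(list(tables = tables, quarters = quarters,
                 n_raw = c(demo = n_raw)),
            class = "faers_store")
}

#' Use a synthetic corpus directly as a report store
#'
#' Bypasses the ASCII round trip: the generator's tables are already in the
#' canonical schema, so large simulated corpora can feed the pipeline
#' without touching the file system.
#'
#' @param corpus a `faers_corpus`
#' @return a `faers_store`
#' @export
as_faers_store <- function(corpus) {
  if (inherits(corpus, "faers_store")) return(corpus)
  if (!inherits(corpus, "faers_corpus"))
    stop("expected a faers_corpus or faers_store", call. = FALSE)
  structure(list(tables = corpus$tables, quarters = "synthetic",
                 n_raw = c(demo = nrow(corpus$tables$demo))),
            class = "faers_store")
}

#' @export
print.faers_store <- function(x, ...) {
  cat("FAERS-style report store\n")
  cat(sprintf("  quarters: %s\n", paste(x$quarters, collapse = ", ")))
  for (nm in names(x$tables))
    cat(sprintf("  %s: %d rows\n", toupper(nm), nrow(x$tables[[nm]])))
  invisible(x)
}

#' Case-level deduplication
#'
#' Applies the FDA retention rule: among records sharing a CASEID, keep the
#' one with the most recent FDA receipt date (FDA_DT); when FDA_DT ties,
#' keep the highest PRIMARYID. Partial FDA_DT values (YYYY or YYYYMM) are
#' compared after padding to the earliest date they could denote. Reports
#' without a CASEID are kept as singletons and counted. Child-table rows of
#' dropped PRIMARYIDs are removed. The operation is idempotent and
#' order-independent.
#'
#' @param store a `faers_store`
#' @return list with `store` (deduplicated) and `ledger` (data frame of
#'   dropped PRIMARYIDs with reason `older_fda_dt` or `lower_primaryid`)
#' @export
deduplicate_reports <- function(store) {
  if (!inherits(store, "faers_store"))
    stop("store must be a faers_store", call. = FALSE)
  demo <- store$tables$demo
  empty_ledger <- data.frame(primaryid = character(0), caseid = character(0),
                             reason = character(0), stringsAsFactors = FALSE)
  if (!nrow(demo))
    return(list(store = store, ledger = empty_ledger))

  caseid <- trimws(demo$caseid)
  no_case <- !nzchar(caseid) | is.na(caseid)
  if (any(no_case)) {
    message(sprintf("%d report(s) lack a CASEID; kept as singletons",
                    sum(no_case)))
    caseid[no_case] <- paste0(".nocase.", demo$primaryid[no_case])
  }
  fda_key <- pad_partial_date(demo$fda_dt %||% rep(NA, nrow(demo)))
  fda_key[is.na(fda_key)] <- -Inf
  pid_num <- as.numeric(demo$primaryid)

  ord <- order(caseid, fda_key, pid_num)
  cs <- caseid[ord]
  keep_last <- c(cs[-1] != cs[-length(cs)], TRUE)
  kept_rows <- ord[keep_last]
  dropped_rows <- ord[!keep_last]

  reason <- character(length(dropped_rows))
  if (length(dropped_rows)) {
    # the survivor of each dropped row's CASEID
    surv <- kept_rows[match(caseid[dropped_rows], caseid[kept_rows])]
    reason <- ifelse(fda_key[dropped_rows] < fda_key[surv],
                     "older_fda_dt", "lower_primaryid")
  }
  ledger <- data.frame(primaryid = demo$primaryid[dropped_rows],
                       caseid = demo$caseid[dropped_rows],
                       reason = reason, stringsAsFactors = FALSE)
  ledger <- ledger[order(as.numeric(ledger$primaryid)), , drop = FALSE]
  rownames(ledger) <- NULL

  kept_pid <- demo$primaryid[sort(kept_rows)]
  tables <- store$tables
  tables$demo <- demo[sort(kept_rows), , drop = FALSE]
  rownames(tables$demo) <- NULL
  for (nm in setdiff(names(tables), "demo")) {
    tb <- tables[[nm]]
    if (nrow(tb) && "primaryid" %in% names(tb)) {
      tables[[nm]] <- tb[tb$primaryid %in% kept_pid, , drop = FALSE]
      rownames(tables[[nm]]) <- NULL
    }
  }
  out <- structure(list(tables = tables, quarters = store$quarters,
                        n_raw = store$n_raw),
                   class = "faers_store")
  list(store = out, ledger = ledger)
}
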