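# Time-to-onset: latency computation from therapy start to event onset,
# interval binning, and Weibull maximum-likelihood fitting.

#' Compute onset latencies for a case set
#'
#' For each case report with a complete (8-digit) event onset date and at
#' least one complete therapy start date for a suspect-role drug, the
#' latency is the number of days from the earliest start date not after
#' the event to the event. Reports whose start dates all fall after the
#' event are excluded as negative intervals and counted; partial or
#' missing dates make a report incomplete.
#'
#' @param store deduplicated `faers_store`
#' @param cases a `diss_cases` object
#' @return list of class `latency_set`: `records` (data frame primaryid,
#'   onset_days, drug), `n_cases`, `n_complete`, `n_negative`,
#'   `completeness`
#' @export
compute_latencies <- function(store, cases) {
  demo <- cases$demo
  ther <- store$tables$ther
  event_dt <- demo$event_dt %||% rep("", nrow(demo))
  ev_ok <- is_complete_date(event_dt)
  ev_date <- yyyymmdd_to_date(event_dt)

  # therapy rows attached to a suspect-role drug of the case
  key_drug <- paste(cases$drugs$primaryid, cases$drugs$drug_seq)
  th <- ther[paste(ther$primaryid, ther$dsg_drug_seq) %in% key_drug, ,
             drop = FALSE]
  th <- th[is_complete_date(th$start_dt), , drop = FALSE]
  th$start <- yyyymmdd_to_date(th$start_dt)

  n_cases <- nrow(demo)
  recs <- list(); n_negative <- 0L
  idx <- which(ev_ok & demo$primaryid %in% th$primaryid)
  if (length(idx)) {
    starts <- split(th$start, th$primaryid)
    for (i in idx) {
      pid <- demo$primaryid[i]
      st <- starts[[pid]]
      ok <- st <= ev_date[i]
      if (!any(ok)) { n_negative <- n_negative + 1L; next }
      onset <- as.integer(ev_date[i] - min(st[ok]))
      dr <- cases$drugs$drug[cases$drugs$primaryid == pid][1]
      recs[[length(recs) + 1L]] <- data.frame(
        primaryid = pid, onset_days = onset, drug = dr,
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(primaryid = character(0), onset_days = integer(0),
               drug = character(0), stringsAsFactors = FALSE)
  structure(list(records = records, n_cases = n_cases,
                 n_complete = nrow(records) + n_negative,
                 n_negative = n_negative,
                 completeness = nrow(records) / max(n_cases, 1)),
            class = "latency_set")
}

#' @export
print.latency_set <- function(x, ...) {
  cat(sprintf("Onset latencies: %d of %d cases (%.1f%%); %d negative interval(s) excluded\n",
              nrow(x$records), x$n_cases, 100 * x$completeness, x$n_negative))
  invisible(x)
}

#' Summarize onset latencies
#'
#' Median and interquartile range (linear-interpolation quartiles) plus
#' the percentage of latencies per interval bin.
#'
#' @param onset_days numeric vector of latencies in days, or a
#'   `latency_set`
#' @param breaks upper edges of the finite bins, in days; the default
#'   yields bins 0-30, 31-60, 61-90, 91-180, 181-365, >365
#' @return list with `n`, `median`, `q1`, `q3` and data frame `bins`
#'   (`bin`, `count`, `pct`); percentages sum to 100
#' @export
summarize_latency <- function(onset_days, breaks = c(30, 60, 90, 180, 365)) {
  if (inherits(onset_days, "latency_set"))
    onset_days <- onset_days$records$onset_days
  x <- as.numeric(onset_days)
  x <- x[!is.na(x)]
  if (!length(x)) stop("no latency records", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  edges <- c(-Inf, breaks, Inf)
  labels <- c(paste0("0-", breaks[1]),
              if (length(breaks) > 1)
                paste0(breaks[-length(breaks)] + 1, "-", breaks[-1]),
              paste0(">", breaks[length(breaks)]))
  cnt <- as.integer(table(cut(x, edges, labels = labels)))
  bins <- data.frame(bin = labels, count = cnt, pct = 100 * cnt / length(x),
                     stringsAsFactors = FALSE)
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3], bins = bins)
}

#' Fit a Weibull model to onset latencies
#'
#' Maximum-likelihood Weibull fit on continuous latencies; same-day onsets
#' (0 days) are shifted to 0.5 days so the acute-onset mass is kept rather
#' than discarded. Non-convergence or degenerate inputs yield a flagged
#' result, not an error.
#'
#' @param onset_days numeric vector (days) or a `latency_set`
#' @return object of class `tto_weibull`: `shape`, `scale`, `loglik`,
#'   `n`, `converged`, implied `median`
#' @export
fit_weibull <- function(onset_days) {
  if (inherits(onset_days, "latency_set"))
    onset_days <- onset_days$records$onset_days
  x <- as.numeric(onset_days)
  x <- x[!is.na(x) & x >= 0]
  x[x == 0] <- 0.5
  if (length(x) < 10)
    stop("need at least 10 positive latencies", call. = FALSE)
  if (stats::sd(x) == 0) {
    # point mass: the Weibull likelihood is unbounded (shape -> infinity)
    res <- list(shape = Inf, scale = x[1], loglik = NA_real_,
                n = length(x), converged = FALSE, median = x[1])
    class(res) <- "tto_weibull"
    return(res)
  }
  fit <- tryCatch(
    fitdistrplus::fitdist(x, "weibull",
                          start = list(shape = 1, scale = stats::median(x) /
                                         log(2))),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$estimate) ||
      !is.finite(fit$loglik) || fit$estimate["shape"] > 1e3) {
    res <- list(shape = if (is.null(fit)) NA_real_ else
                  unname(fit$estimate["shape"]),
                scale = if (is.null(fit)) NA_real_ else
                  unname(fit$estimate["scale"]),
                loglik = if (is.null(fit)) NA_real_ else fit$loglik,
                n = length(x), converged = FALSE)
  } else {
    res <- list(shape = unname(fit$estimate["shape"]),
                scale = unname(fit$estimate["scale"]),
                loglik = fit$loglik, n = length(x), converged = TRUE)
  }
  res$median <- res$scale * log(2)^(1 / res$shape)
  class(res) <- "tto_weibull"
  res
}

#' @export
print.tto_weibull <- function(x, ...) {
  cat(sprintf("Weibull time-to-onset fit (n = %d)%s\n", x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  shape k = %.3f, scale lambda = %.1f days, implied median = %.1f days\n",
              x$shape, x$scale, x$median))
  invisible(x)
}
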