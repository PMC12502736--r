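# Disproportionality analysis: drug-event 2x2 tables, reporting odds
# ratios with Wald confidence intervals, Fisher exact tests, false
# discovery rate control and the signal criteria.
#
# For a drug-event pair over a report universe the table is
#     a = reports with the drug and the event     b = drug, other events
#     c = event, other drugs                      d = neither
# and ROR = (a/c)/(b/d) = ad/bc with
#     95% CI = exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
# A signal is a pair with at least `min_cases` reports and a CI lower
# bound above 1.

# Per-report exposure/event flags used by both build_table and the screen.
report_flags <- function(store, event_pt, role_codes = "PS",
                         normalizer = drug_normalizer()) {
  demo_pid <- store$tables$demo$primaryid
  reac <- store$tables$reac
  ev_pid <- unique(reac$primaryid[fold_name(reac$pt) == fold_name(event_pt)])
  drug <- store$tables$drug
  sel <- drug$role_cod %in% role_codes
  pairs <- unique(data.frame(
    primaryid = drug$primaryid[sel],
    drug = as.character(normalize_drug(drug$drugname[sel], normalizer)),
    stringsAsFactors = FALSE))
  pairs <- pairs[pairs$primaryid %in% demo_pid, , drop = FALSE]
  list(universe = demo_pid, event_ids = intersect(ev_pid, demo_pid),
       exposure = pairs)
}

#' Build the 2x2 contingency table for one drug-event pair
#'
#' Counts at the report level (a report contributes once per cell);
#' exposure is restricted to the given role codes (primary suspect by
#' default).
#'
#' @param store deduplicated `faers_store`
#' @param drug standardized drug name
#' @param event_pt reaction preferred term
#' @param role_codes drug roles counted as exposure
#' @param normalizer a [drug_normalizer()]
#' @return object of class `contingency`: named integer vector
#'   `c(a, b, c, d)` with attribute `n` (universe size)
#' @export
build_table <- function(store, drug, event_pt, role_codes = "PS",
                        normalizer = drug_normalizer()) {
  fl <- report_flags(store, event_pt, role_codes, normalizer)
  exp_ids <- unique(fl$exposure$primaryid[fl$exposure$drug ==
                                            fold_name(drug)])
  # standardized names are already folded unless a synonym map renamed them
  if (!length(exp_ids))
    exp_ids <- unique(fl$exposure$primaryid[fl$exposure$drug == drug])
  n <- length(fl$universe)
  a <- length(intersect(exp_ids, fl$event_ids))
  b <- length(exp_ids) - a
  cc <- length(fl$event_ids) - a
  d <- n - a - b - cc
  contingency(a, b, cc, d)
}

#' Construct a contingency object from counts
#' @param a,b,c,d non-negative integer cell counts
#' @return object of class `contingency`
#' @export
contingency <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cells must be non-negative integers", call. = FALSE)
  structure(as.integer(cells), names = c("a", "b", "c", "d"),
            n = sum(cells), class = "contingency")
}

#' Reporting odds ratio with Wald confidence interval
#'
#' ROR = (a/c)/(b/d); the CI is computed on the log scale with the normal
#' quantile for the requested `alpha`. With any zero cell the estimate is
#' undefined and flagged (`NA`) unless `haldane = TRUE`, which adds 0.5 to
#' every cell first.
#'
#' @param table a `contingency` or numeric `c(a,b,c,d)`
#' @param alpha two-sided significance level (0.05 gives z = 1.96)
#' @param haldane apply the Haldane-Anscombe 0.5 correction to zero-cell
#'   tables
#' @return list with `ror`, `ci_low`, `ci_high`, `undefined`
#' @export
ror_ci <- function(table, alpha = 0.05, haldane = FALSE) {
  x <- as.numeric(table)
  if (length(x) != 4) stop("table must have 4 cells", call. = FALSE)
  if (any(x == 0)) {
    if (!haldane)
      return(list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  undefined = TRUE))
    x <- x + 0.5
  }
  z <- stats::qnorm(1 - alpha / 2)
  ror <- (x[1] * x[4]) / (x[2] * x[3])
  se <- sqrt(sum(1 / x))
  list(ror = ror, ci_low = exp(log(ror) - z * se),
       ci_high = exp(log(ror) + z * se), undefined = FALSE)
}

#' Two-sided Fisher exact p-value
#'
#' Conditional on the table margins, sums the probabilities of all tables
#' whose point probability does not exceed that of the observed table
#' (the point-probability convention of `stats::fisher.test`).
#'
#' @param table a `contingency` or numeric `c(a,b,c,d)`
#' @return p-value in (0, 1]
#' @export
fisher_p <- function(table) {
  x <- as.numeric(table)
  m <- matrix(x, nrow = 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: on sorted p-values, `p_adj(i) = min_{j >= i}
#' (m p(j) / j)` capped at 1, returned in the input order.
#'
#' @param p_values numeric vector in [0, 1]
#' @return adjusted p-values
#' @export
fdr_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Disproportionality screen over a drug list
#'
#' Builds the per-drug 2x2 tables over the store's report universe,
#' computes ROR with 95% CI, Fisher exact p, BH-adjusted p across all
#' tested drugs (every drug with at least one event report by default),
#' and applies the signal criteria: `n >= min_cases` and CI lower bound
#' `> ci_bound`. Volcano coordinates (log2 ROR, -log10 adjusted p,
#' log10 n) are included for plotting.
#'
#' @param store deduplicated `faers_store`
#' @param event_pt reaction preferred term
#' @param drugs standardized names to test; `NULL` tests every drug with
#'   at least one event report
#' @param min_cases case-count threshold (default 3, i.e. at least three
#'   reports; use 4 for the strict "more than 3" reading)
#' @param ci_bound CI lower-bound threshold (default 1)
#' @param role_codes exposure roles
#' @param normalizer a [drug_normalizer()]
#' @param reporter_filter optional vector of DEMO `occp_cod` values; the
#'   universe is restricted to reports from those reporters (e.g. `"MD"`
#'   for the medical-doctor subset reanalysis)
#' @param alpha CI level
#' @param haldane zero-cell policy, see [ror_ci()]
#' @return data frame of class `signal_screen`: drug, n (= a), ror,
#'   ci_low, ci_high, p, p_adj, signal, log2_ror, neglog10_p_adj, log10_n
#' @export
screen_signals <- function(store, event_pt, drugs = NULL, min_cases = 3,
                           ci_bound = 1, role_codes = "PS",
                           normalizer = drug_normalizer(),
                           reporter_filter = NULL, alpha = 0.05,
                           haldane = FALSE) {
  if (!is.null(reporter_filter)) {
    demo <- store$tables$demo
    keep <- demo$primaryid[demo$occp_cod %in% reporter_filter]
    store <- subset_store(store, keep)
  }
  fl <- report_flags(store, event_pt, role_codes, normalizer)
  n_univ <- length(fl$universe)
  n_event <- length(fl$event_ids)
  exp_pairs <- fl$exposure
  exp_pairs$event <- exp_pairs$primaryid %in% fl$event_ids
  n_exposed <- table(exp_pairs$drug)
  a_counts <- table(exp_pairs$drug[exp_pairs$event])

  if (is.null(drugs)) drugs <- names(a_counts)
  if (!length(drugs)) stop("no drugs to screen", call. = FALSE)

  a <- as.integer(a_counts[drugs]); a[is.na(a)] <- 0L
  n_exp <- as.integer(n_exposed[drugs]); n_exp[is.na(n_exp)] <- 0L
  b <- n_exp - a
  cc <- n_event - a
  d <- n_univ - a - b - cc

  res <- data.frame(drug = drugs, n = a, ror = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_, p_adj = NA_real_,
                    signal = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(drugs)) {
    rc <- ror_ci(c(a[i], b[i], cc[i], d[i]), alpha = alpha, haldane = haldane)
    res$ror[i] <- rc$ror; res$ci_low[i] <- rc$ci_low
    res$ci_high[i] <- rc$ci_high
    res$p[i] <- fisher_p(c(a[i], b[i], cc[i], d[i]))
  }
  res$p_adj <- fdr_adjust(res$p)
  res$signal <- res$n >= min_cases & !is.na(res$ci_low) &
    res$ci_low > ci_bound
  res$log2_ror <- log2(res$ror)
  res$neglog10_p_adj <- -log10(pmax(res$p_adj, .Machine$double.xmin))
  res$log10_n <- log10(pmax(res$n, 1))
  attr(res, "universe") <- c(n = n_univ, events = n_event)
  attr(res, "criteria") <- c(min_cases = min_cases, ci_bound = ci_bound)
  class(res) <- c("signal_screen", "data.frame")
  res
}

#' @export
print.signal_screen <- function(x, ...) {
  u <- attr(x, "universe")
  need <- c("drug", "n", "ror", "ci_low", "ci_high", "p_adj", "signal")
  if (is.null(u) || !all(need %in% names(x)))
    return(print.data.frame(x, digits = 3, row.names = FALSE))
  cat(sprintf("Disproportionality screen: %d drugs over %d reports (%d with the event)\n",
              nrow(x), u["n"], u["events"]))
  cat(sprintf("  positive signals: %d\n", sum(x$signal)))
  top <- x[order(-x$signal, x$p_adj), , drop = FALSE]
  print.data.frame(utils::head(
    top[c("drug", "n", "ror", "ci_low", "ci_high", "p_adj", "signal")], 10),
    digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.signal_screen <- function(object, ...) {
  list(n_drugs = nrow(object), n_signals = sum(object$signal),
       universe = attr(object, "universe"),
       criteria = attr(object, "criteria"))
}
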