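# Cohort descriptives: Table-1-style summaries, ATC class distributions,
# stratified chi-square tests and annual linear trends.

#' Count/percentage summary of a categorical field
#'
#' Percentages are of the full universe (missing included as an explicit
#' row) and rounded half-up to 2 decimals, the convention of published
#' report-cohort tables.
#'
#' @param x character vector (NA or empty = missing)
#' @param total denominator; defaults to `length(x)`
#' @param top if given, keep the `top` most frequent levels and collapse
#'   the rest into `"Others"`
#' @return data frame of class `summary_table` with columns `level`,
#'   `count`, `pct`
#' @export
summary_table <- function(x, total = length(x), top = NULL) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(trimws(x))] <- NA_character_
  tab <- sort(table(x, useNA = "no"), decreasing = TRUE)
  levels <- names(tab)
  counts <- as.integer(tab)
  if (!is.null(top) && length(levels) > top) {
    head_lv <- levels[seq_len(top)]
    others <- sum(counts[-seq_len(top)])
    levels <- c(head_lv, "Others")
    counts <- c(counts[seq_len(top)], others)
  }
  n_missing <- sum(is.na(x))
  if (n_missing > 0) {
    levels <- c(levels, "Missing")
    counts <- c(counts, n_missing)
  }
  out <- data.frame(level = levels, count = counts,
                    pct = round_half_up(100 * counts / total, 2),
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_table", "data.frame")
  attr(out, "total") <- total
  out
}

# Mean/SD/median/quartile summary of a numeric field; quartiles use the
# linear-interpolation convention (stats::quantile type 7).
numeric_summary <- function(x, total = length(x)) {
  x <- suppressWarnings(as.numeric(x))
  obs <- x[!is.na(x)]
  q <- if (length(obs)) stats::quantile(obs, c(0.25, 0.5, 0.75), type = 7,
                                        names = FALSE) else rep(NA_real_, 3)
  list(n = length(obs), mean = mean(obs), sd = stats::sd(obs),
       median = q[2], q1 = q[1], q3 = q[3],
       n_missing = total - length(obs),
       pct_missing = round_half_up(100 * (total - length(obs)) / total, 2))
}

#' Summarize a case cohort
#'
#' Produces the demographic/clinical summary tables: sex, age, weight,
#' reporter occupation, reporter country (top six + Others), and
#' observed/missing tabulations for indications and outcomes.
#'
#' @param cases a `diss_cases` object, or a DEMO-shaped data frame
#' @param store optional `faers_store` supplying INDI/OUTC rows for the
#'   observed/missing tabulations
#' @return named list of `summary_table`s / numeric summaries, class
#'   `cohort_summary`
#' @export
summarize_cohort <- function(cases, store = NULL) {
  demo <- if (inherits(cases, "diss_cases")) cases$demo else cases
  if (!nrow(demo)) stop("case set is empty", call. = FALSE)
  n <- nrow(demo)
  sex_raw <- demo$sex %||% rep(NA_character_, n)
  out <- list(
    n = n,
    sex = summary_table(ifelse(sex_raw %in% c("M", "F"),
                               ifelse(sex_raw == "M", "Male", "Female"),
                               NA), total = n),
    age = numeric_summary(demo$age %||% rep(NA, n), total = n),
    weight = numeric_summary(demo$wt %||% rep(NA, n), total = n),
    reporter = summary_table(demo$occp_cod %||% rep(NA, n), total = n),
    country = summary_table(demo$reporter_country %||% rep(NA, n),
                            total = n, top = 6)
  )
  if (!is.null(store)) {
    ids <- demo$primaryid
    obs_tab <- function(child) {
      has <- ids %in% store$tables[[child]]$primaryid
      summary_table(ifelse(has, "Observed", NA), total = n)
    }
    out$indications <- obs_tab("indi")
    out$outcomes <- obs_tab("outc")
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d case reports\n", x$n))
  cat("Sex:\n"); print.data.frame(x$sex)
  cat(sprintf("Age: median %.0f [Q1 %.0f, Q3 %.0f], missing %.2f%%\n",
              x$age$median, x$age$q1, x$age$q3, x$age$pct_missing))
  invisible(x)
}

#' ATC class distribution of case reports
#'
#' Counts case reports per ATC level-1 class of their suspect drug(s); a
#' report with suspect drugs in several classes counts once per class.
#' Drugs absent from the ATC map fall into an `"unclassified"` row.
#'
#' @param cases a `diss_cases` object
#' @param normalizer a [drug_normalizer()] carrying the ATC map
#' @param level `1` or `2`
#' @return a `summary_table` (percentages of the case total)
#' @export
atc_distribution <- function(cases, normalizer, level = 1) {
  total <- length(cases$case_ids)
  atc <- atc_lookup(cases$drugs$drug, normalizer)
  cls <- if (level == 1) atc$atc1 else atc$atc2
  pairs <- unique(data.frame(primaryid = cases$drugs$primaryid, class = cls,
                             stringsAsFactors = FALSE))
  if (!nrow(pairs))
    return(summary_table(character(0), total = total))
  tab <- sort(table(pairs$class), decreasing = TRUE)
  out <- data.frame(level = names(tab), count = as.integer(tab),
                    pct = round_half_up(100 * as.integer(tab) / total, 2),
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_table", "data.frame")
  attr(out, "total") <- total
  out
}

#' Stratified chi-square test
#'
#' Pearson chi-square on the cross-tabulation of two factors over case
#' reports, after dropping missing values; no continuity correction.
#' Expected counts are returned for diagnostics.
#'
#' @param row_factor,col_factor vectors of equal length (NA/empty dropped)
#' @return list with `statistic`, `df`, `p.value`, `observed`, `expected`
#' @export
stratified_chisq <- function(row_factor, col_factor) {
  r <- as.character(row_factor); c_ <- as.character(col_factor)
  keep <- !is.na(r) & nzchar(r) & !is.na(c_) & nzchar(c_)
  tab <- table(r[keep], c_[keep])
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("both factors need at least two observed levels", call. = FALSE)
  zero_row <- rownames(tab)[rowSums(tab) == 0]
  zero_col <- colnames(tab)[colSums(tab) == 0]
  if (length(zero_row) || length(zero_col))
    stop(sprintf("degenerate table: zero margin for level(s) %s",
                 paste(c(zero_row, zero_col), collapse = ", ")), call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, observed = tab, expected = ct$expected)
}

#' Annual reporting trends by drug class
#'
#' Ordinary least squares of the annual case count on calendar year, one
#' fit per class; years without reports contribute zero counts.
#'
#' @param years integer vector (one entry per case report)
#' @param classes character vector parallel to `years`
#' @param year_range optional `c(first, last)`; defaults to observed range
#' @return data frame of class `trend_fit` with columns `class`, `slope`,
#'   `r_squared`, `p.value`, `n_years`
#' @export
annual_trend <- function(years, classes, year_range = NULL) {
  years <- as.integer(years)
  keep <- !is.na(years) & !is.na(classes)
  years <- years[keep]; classes <- as.character(classes)[keep]
  if (length(unique(years)) < 3)
    stop("insufficient data: need at least 3 distinct years", call. = FALSE)
  rng <- year_range %||% range(years)
  grid <- seq(rng[1], rng[2])
  res <- lapply(unique(classes), function(cl) {
    cnt <- as.integer(table(factor(years[classes == cl], levels = grid)))
    fit <- stats::lm(cnt ~ grid)
    # constant or exactly linear counts trigger the "essentially perfect
    # fit" note; the slope/R^2 themselves are well defined
    sm <- suppressWarnings(summary(fit))
    p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
    data.frame(class = cl, slope = unname(stats::coef(fit)[2]),
               r_squared = sm$r.squared, p.value = p,
               n_years = length(grid), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("trend_fit", "data.frame")
  out
}
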