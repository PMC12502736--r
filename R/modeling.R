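# Risk-factor modelling: LASSO variable selection with stratified 10-fold
# cross-validation (lambda_min / lambda_1se), multivariable logistic
# regression with Wald odds ratios and FDR-adjusted p-values, and AUC with
# a DeLong confidence interval.

# Design matrix from an analytical dataset: age, sex (M = 1) and the drug
# indicator columns; complete cases only. Returns list(x, y, dropped_rows,
# dropped_cols).
.design_matrix <- function(dataset, variables = NULL) {
  drug_cols <- unname(attr(dataset, "drug_columns"))
  vars <- variables %||% c("age", "sex", drug_cols)
  vars <- intersect(vars, c("age", "sex", names(dataset)))
  cc <- stats::complete.cases(dataset[intersect(vars, names(dataset))])
  d <- dataset[cc, , drop = FALSE]
  cols <- list()
  if ("age" %in% vars) cols$age <- as.numeric(d$age)
  if ("sex" %in% vars) cols$sex <- as.numeric(d$sex == "M")
  for (v in setdiff(vars, c("age", "sex"))) cols[[v]] <- as.numeric(d[[v]])
  x <- do.call(cbind, cols)
  dropped_cols <- colnames(x)[apply(x, 2, function(z) stats::var(z) == 0)]
  if (length(dropped_cols)) {
    message(sprintf("dropping constant predictor(s): %s",
                    paste(dropped_cols, collapse = ", ")))
    x <- x[, setdiff(colnames(x), dropped_cols), drop = FALSE]
  }
  list(x = x, y = d$case, n_dropped_rows = sum(!cc),
       dropped_cols = dropped_cols)
}

# Case-status-stratified fold assignment (rare outcome: unstratified folds
# can lack cases entirely).
.stratified_folds <- function(y, nfolds) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    foldid[i] <- sample(rep_len(seq_len(nfolds), length(i)))
  }
  foldid
}

#' LASSO variable selection with cross-validation
#'
#' L1-penalized logistic regression over a 100-value log-spaced lambda
#' path, scored by stratified k-fold cross-validation. `lambda_min`
#' maximizes the mean CV AUC (or minimizes mean binomial deviance when
#' `criterion = "deviance"`); `lambda_1se` is the largest lambda whose
#' mean CV performance is within one standard error of the optimum.
#'
#' @param dataset an `analytical_dataset` from [build_dataset()]
#' @param nfolds number of CV folds (default 10)
#' @param seed integer seed controlling fold assignment
#' @param criterion `"auc"` (default) or `"deviance"`
#' @return object of class `lasso_result`: the `cv.glmnet` fit plus
#'   `lambda_min`, `lambda_1se`, `selected_min`, `selected_1se`,
#'   `n_dropped_rows`
#' @export
lasso_select <- function(dataset, nfolds = 10, seed = 1,
                         criterion = c("auc", "deviance")) {
  criterion <- match.arg(criterion)
  dm <- .design_matrix(dataset)
  if (length(unique(dm$y)) < 2)
    stop("dataset needs both cases and controls", call. = FALSE)
  set.seed(seed)
  foldid <- .stratified_folds(dm$y, nfolds)
  type <- if (criterion == "auc") "auc" else "deviance"
  cv <- glmnet::cv.glmnet(dm$x, dm$y, family = "binomial", alpha = 1,
                          foldid = foldid, type.measure = type,
                          nlambda = 100, lambda.min.ratio = 1e-4)
  sel <- function(lam) {
    cf <- as.matrix(stats::coef(cv, s = lam))
    rownames(cf)[-1][cf[-1, 1] != 0]
  }
  structure(list(cv = cv, criterion = criterion,
                 lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                 lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
                 selected_min = sel(cv$lambda.min),
                 selected_1se = sel(cv$lambda.1se),
                 n_dropped_rows = dm$n_dropped_rows,
                 dropped_cols = dm$dropped_cols, seed = seed),
            class = "lasso_result")
}

#' @export
print.lasso_result <- function(x, ...) {
  cat(sprintf("LASSO selection (10-fold CV, criterion = %s)\n", x$criterion))
  cat(sprintf("  lambda_min = %.5f -> %d variable(s); lambda_1se = %.5f -> %d variable(s)\n",
              x$lambda_min, length(x$selected_min),
              x$lambda_1se, length(x$selected_1se)))
  invisible(x)
}

#' Multivariable logistic regression with odds ratios
#'
#' Unpenalized maximum-likelihood logistic fit of case status on the given
#' variables (complete cases). Wald confidence intervals on the log-odds
#' scale are exponentiated to odds ratios; per-variable p-values are
#' FDR-adjusted across the model's variables; in-sample discrimination is
#' the AUC with a DeLong CI. The significant set follows the rule
#' adjusted p < 0.05 and OR CI lower bound >= 1.
#'
#' @param dataset an `analytical_dataset`
#' @param variables columns to include (e.g. a `lasso_result$selected_min`)
#' @param alpha CI level
#' @return object of class `logistic_result`: `coefficients` data frame
#'   (variable, or, ci_low, ci_high, p, p_adj, significant), `auc`
#'   (list auc/ci_low/ci_high), `n_cases`, `n_controls`, `converged`,
#'   `separation`
#' @export
logistic_fit <- function(dataset, variables, alpha = 0.05) {
  if (anyDuplicated(variables)) stop("duplicate variables", call. = FALSE)
  dm <- .design_matrix(dataset, variables)
  x <- dm$x; y <- dm$y
  df <- data.frame(case = y, x, check.names = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(case ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  fv <- stats::fitted(fit)
  if (any(fv < 1e-10 | fv > 1 - 1e-10)) separation <- TRUE
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("singular design: collinear column(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  z <- stats::qnorm(1 - alpha / 2)
  co <- data.frame(variable = gsub("^`|`$", "", rownames(sm)),
                   or = exp(sm[, 1]),
                   ci_low = exp(sm[, 1] - z * sm[, 2]),
                   ci_high = exp(sm[, 1] + z * sm[, 2]),
                   p = sm[, 4], stringsAsFactors = FALSE)
  co$p_adj <- fdr_adjust(co$p)
  co$significant <- co$p_adj < 0.05 & co$ci_low >= 1
  rownames(co) <- NULL
  auc <- auc_ci(stats::fitted(fit), y)
  structure(list(coefficients = co, auc = auc,
                 n_cases = sum(y == 1), n_controls = sum(y == 0),
                 n_dropped_rows = dm$n_dropped_rows,
                 converged = fit$converged && !separation,
                 separation = separation, fit = fit),
            class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("Multivariable logistic model: %d cases / %d controls%s\n",
              x$n_cases, x$n_controls,
              if (x$separation) "  [separation detected]" else ""))
  cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f); %d significant variable(s)\n",
              x$auc$auc, x$auc$ci_low, x$auc$ci_high,
              sum(x$coefficients$significant)))
  print.data.frame(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

#' AUC with confidence interval
#'
#' Area under the ROC curve as the tie-corrected Mann-Whitney probability,
#' with a DeLong 95% CI; when the DeLong variance is degenerate (perfect
#' separation, constant scores) a seeded bootstrap (2,000 resamples) is
#' used instead.
#'
#' @param scores numeric risk scores
#' @param labels 0/1 outcome labels
#' @param alpha CI level
#' @param boot_seed seed for the bootstrap fallback
#' @return list with `auc`, `ci_low`, `ci_high`, `method`
#' @export
auc_ci <- function(scores, labels, alpha = 0.05, boot_seed = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  r <- suppressMessages(pROC::roc(response = labels, predictor = scores,
                                  levels = c(0, 1), direction = "<",
                                  quiet = TRUE))
  a <- as.numeric(pROC::auc(r))
  ci <- tryCatch(suppressWarnings(
    as.numeric(pROC::ci.auc(r, conf.level = 1 - alpha, method = "delong"))),
    error = function(e) rep(NA_real_, 3))
  method <- "delong"
  if (anyNA(ci) || ci[1] == ci[3]) {
    set.seed(boot_seed)
    n <- length(labels)
    stat <- replicate(2000, {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[i])) < 2) return(NA_real_)
      ri <- rank(scores[i])
      pos <- labels[i] == 1
      n1 <- sum(pos); n0 <- n - n1
      (sum(ri[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    })
    ci <- stats::quantile(stat, c(alpha / 2, 0.5, 1 - alpha / 2),
                          na.rm = TRUE, names = FALSE)
    method <- "bootstrap"
  }
  list(auc = a, ci_low = ci[1], ci_high = ci[3], method = method)
}

#' Run candidate selection, LASSO and logistic modelling per scheme
#'
#' For each requested indication-exclusion scheme: screen for positive
#' disproportionality signals on the scheme's universe, use the flagged
#' drugs plus age and sex as candidates, select variables by LASSO at
#' `lambda_min`, refit them by unpenalized logistic regression, and report
#' odds ratios and AUC. Also returns the forest-plot table across schemes
#' and the cross-scheme intersection of significant drugs.
#'
#' @param store deduplicated `faers_store`
#' @param event_pt reaction preferred term
#' @param schemes character vector of schemes to run
#' @param min_cases signal case-count threshold
#' @param normalizer a [drug_normalizer()]
#' @param classifier an [indication_classifier()]
#' @param seed integer seed (folds)
#' @return object of class `scheme_models`: per-scheme list(screen, lasso,
#'   logistic), `forest` data frame, `significant_overlap`
#' @export
run_all_schemes <- function(store, event_pt,
                            schemes = c("main", "sensitivity_A",
                                        "sensitivity_B"),
                            min_cases = 3,
                            normalizer = drug_normalizer(),
                            classifier = indication_classifier(),
                            seed = 1) {
  per_scheme <- list()
  forest <- list()
  for (sc in schemes) {
    sub <- subset_store(store, scheme_retained(store, sc, classifier))
    scr <- screen_signals(sub, event_pt, min_cases = min_cases,
                          normalizer = normalizer)
    cand <- scr$drug[scr$signal]
    if (!length(cand)) {
      message(sprintf("scheme '%s': no candidate signals; skipped", sc))
      per_scheme[[sc]] <- list(screen = scr, lasso = NULL, logistic = NULL)
      next
    }
    ds <- build_dataset(store, sc, cand, normalizer = normalizer,
                        classifier = classifier)
    las <- lasso_select(ds, seed = seed)
    vars <- las$selected_min
    if (!length(vars)) vars <- c("age", "sex")
    log_fit <- logistic_fit(ds, vars)
    per_scheme[[sc]] <- list(screen = scr, lasso = las, logistic = log_fit)
    co <- log_fit$coefficients
    co$scheme <- sc
    forest[[sc]] <- co
  }
  forest <- if (length(forest)) do.call(rbind, forest) else NULL
  sig_sets <- lapply(per_scheme, function(s) {
    if (is.null(s$logistic)) return(NULL)
    co <- s$logistic$coefficients
    setdiff(co$variable[co$significant], c("age", "sex"))
  })
  sig_sets <- Filter(Negate(is.null), sig_sets)
  overlap <- if (length(sig_sets)) Reduce(intersect, sig_sets) else character(0)
  structure(list(schemes = per_scheme, forest = forest,
                 significant_overlap = overlap, seed = seed),
            class = "scheme_models")
}

#' @export
print.scheme_models <- function(x, ...) {
  for (sc in names(x$schemes)) {
    s <- x$schemes[[sc]]
    if (is.null(s$logistic)) { cat(sprintf("%s: skipped\n", sc)); next }
    cat(sprintf("%s: %d candidates -> %d selected -> %d significant; AUC %.3f\n",
                sc, sum(s$screen$signal), length(s$lasso$selected_min),
                sum(s$logistic$coefficients$significant), s$logistic$auc$auc))
  }
  cat(sprintf("cross-scheme significant overlap: %d drug(s)\n",
              length(x$significant_overlap)))
  invisible(x)
}
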