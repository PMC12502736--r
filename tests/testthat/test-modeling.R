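# A small analytical dataset built directly (bypassing the store) for
# model-level unit tests.
make_dataset <- function(case, drugs, age = NULL, sex = NULL) {
  n <- length(case)
  ds <- data.frame(primaryid = as.character(seq_len(n)), case = case,
                   age = age %||% round(runif(n, 20, 80)),
                   sex = sex %||% sample(c("M", "F"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
  for (nm in names(drugs)) ds[[nm]] <- drugs[[nm]]
  attr(ds, "drug_columns") <- stats::setNames(names(drugs), names(drugs))
  class(ds) <- c("analytical_dataset", "data.frame")
  ds
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a single binary predictor reproduces the contingency odds ratio", {
  # exposure x outcome structure (20,80; 10,90) -> OR 2.25
  case <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  x <- c(rep(1, 100), rep(0, 100))
  ds <- make_dataset(case, list(dx = x))
  fit <- logistic_fit(ds, "dx")
  expect_equal(fit$coefficients$or[fit$coefficients$variable == "dx"],
               (20 * 90) / (80 * 10), tolerance = 1e-6)
})

test_that("a null predictor's CI covers 1 most of the time", {
  hits <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 2000
    case <- rbinom(n, 1, 0.1)
    x <- rbinom(n, 1, 0.3)
    ds <- make_dataset(case, list(dx = x))
    fit <- logistic_fit(ds, "dx")
    co <- fit$coefficients[fit$coefficients$variable == "dx", ]
    if (co$ci_low <= 1 && co$ci_high >= 1) hits <- hits + 1
  }
  expect_gte(hits, 18)  # nominal 95% coverage
})

test_that("perfect separation is flagged rather than silently reported", {
  case <- c(rep(1, 30), rep(0, 70))
  x <- case
  ds <- make_dataset(case, list(dx = x))
  fit <- logistic_fit(ds, "dx")
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("collinear columns raise an error naming the offender", {
  case <- rbinom(100, 1, 0.3)
  x <- rbinom(100, 1, 0.5)
  ds <- make_dataset(case, list(dx = x, dup = x))
  expect_error(logistic_fit(ds, c("dx", "dup")), "dup")
})

test_that("AUC handles the degenerate and exact cases", {
  expect_equal(auc_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  tied <- auc_ci(rep(0.5, 40), rep(c(0, 1), 20))
  expect_equal(tied$auc, 0.5)
  expect_error(auc_ci(1:5, rep(1, 5)), "both outcome classes")
})

test_that("AUC equals the tie-corrected rank oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- 200
    y <- rbinom(n, 1, 0.4)
    s <- round(rnorm(n, y), 1)  # rounding induces ties
    expect_equal(auc_ci(s, y)$auc, auc_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("the null AUC stays near one half", {
  set.seed(47)
  for (i in 1:10) {
    y <- rbinom(5000, 1, 0.3)
    s <- rnorm(5000)
    a <- auc_ci(s, y)$auc
    expect_gt(a, 0.47); expect_lt(a, 0.53)
  }
})

test_that("LASSO keeps a perfectly informative drug and is seed-deterministic", {
  for (s in 1:5) {
    set.seed(400 + s)
    n <- 2000
    case <- rbinom(n, 1, 0.15)
    noise <- replicate(5, rbinom(n, 1, 0.2), simplify = FALSE)
    names(noise) <- paste0("noise", 1:5)
    ds <- make_dataset(case, c(list(signal_drug = case), noise))
    las <- lasso_select(ds, seed = s)
    expect_true("signal_drug" %in% las$selected_min)
  }
  # determinism
  set.seed(999)
  case <- rbinom(1000, 1, 0.2)
  ds <- make_dataset(case, list(dx = rbinom(1000, 1, 0.3)))
  l1 <- lasso_select(ds, seed = 5)
  l2 <- lasso_select(ds, seed = 5)
  expect_identical(l1$selected_min, l2$selected_min)
  expect_identical(l1$lambda_min, l2$lambda_min)
})

test_that("lambda_1se is at least lambda_min and selects no more variables", {
  set.seed(52)
  n <- 3000
  case <- rbinom(n, 1, 0.1)
  x1 <- ifelse(case == 1, rbinom(n, 1, 0.5), rbinom(n, 1, 0.1))
  ds <- make_dataset(case, list(dx = x1,
                                n1 = rbinom(n, 1, 0.2),
                                n2 = rbinom(n, 1, 0.2)))
  las <- lasso_select(ds, seed = 2)
  expect_gte(las$lambda_1se, las$lambda_min)
  expect_lte(length(las$selected_1se), length(las$selected_min))
})

test_that("an age/sex-only dataset still yields a valid path", {
  set.seed(61)
  n <- 800
  age <- runif(n, 20, 80)
  case <- rbinom(n, 1, plogis(-3 + 0.03 * age))
  ds <- make_dataset(case, list(), age = age)
  las <- lasso_select(ds, seed = 1)
  expect_true(length(las$lambda) > 10)
  fit <- logistic_fit(ds, c("age", "sex"))
  expect_true(fit$converged)
})

test_that("all-zero predictors are dropped with a message", {
  set.seed(71)
  case <- rbinom(500, 1, 0.2)
  ds <- make_dataset(case, list(dx = rbinom(500, 1, 0.4),
                                dead = rep(0, 500)))
  expect_message(las <- lasso_select(ds, seed = 1), "dead")
  expect_false("dead" %in% c(las$selected_min, las$selected_1se))
})

test_that("refitting the lambda_min selection does not lose discrimination", {
  set.seed(83)
  n <- 4000
  case <- rbinom(n, 1, 0.08)
  mk <- function(p1, p0) ifelse(case == 1, rbinom(n, 1, p1), rbinom(n, 1, p0))
  ds <- make_dataset(case, list(d1 = mk(0.5, 0.1), d2 = mk(0.35, 0.12),
                                d3 = mk(0.2, 0.15),
                                n1 = rbinom(n, 1, 0.2),
                                n2 = rbinom(n, 1, 0.2)))
  las <- lasso_select(ds, seed = 3)
  f_min <- logistic_fit(ds, las$selected_min)
  vars_1se <- if (length(las$selected_1se)) las$selected_1se else c("age", "sex")
  f_1se <- logistic_fit(ds, vars_1se)
  expect_gte(f_min$auc$auc, f_1se$auc$auc - 1e-9)
})

test_that("the deviance CV criterion is also available", {
  set.seed(91)
  case <- rbinom(1500, 1, 0.2)
  ds <- make_dataset(case, list(dx = ifelse(case == 1, rbinom(1500, 1, 0.5),
                                            rbinom(1500, 1, 0.1))))
  las <- lasso_select(ds, seed = 4, criterion = "deviance")
  expect_true("dx" %in% las$selected_min)
})

test_that("identical scheme datasets give identical model output", {
  cfg <- sim_config(6000, drug_catalog = synthetic_drug_catalog(10),
                    planted_signals = c(drug_001 = 10),
                    background_event_rate = 0.03,
                    duplicate_fraction = 0, seed = 77)
  store <- as_faers_store(generate_corpus(cfg))
  m1 <- run_all_schemes(store, "Sweet syndrome", schemes = "full", seed = 9)
  m2 <- run_all_schemes(store, "Sweet syndrome", schemes = "full", seed = 9)
  expect_identical(m1$forest, m2$forest)
  expect_identical(m1$significant_overlap, m2$significant_overlap)
})
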