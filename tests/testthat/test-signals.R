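test_that("contingency cells are counted at the report level", {
  # universe 100, drug X suspect in 10 reports, event in 8, overlap 4
  store <- fixture_store(100, exposed = 1:10, with_event = c(1:4, 11:14))
  tab <- build_table(store, "drug x", "Sweet syndrome")
  expect_equal(unclass(tab)[1:4], c(a = 4L, b = 6L, c = 4L, d = 86L),
               ignore_attr = TRUE)
  expect_equal(attr(tab, "n"), 100L)
})

test_that("absent drug or event produce the boundary tables", {
  store <- fixture_store(50, exposed = 1:5, with_event = 6:10)
  none <- build_table(store, "no such drug", "Sweet syndrome")
  expect_equal(none[["a"]], 0L); expect_equal(none[["b"]], 0L)
  no_event <- build_table(store, "drug x", "No such PT")
  expect_equal(no_event[["a"]], 0L); expect_equal(no_event[["c"]], 0L)
  expect_equal(no_event[["b"]], 5L)
})

test_that("ROR and Wald CI match the hand formula", {
  rr <- ror_ci(c(10, 90, 100, 9900))
  expect_equal(rr$ror, 11.0, tolerance = 1e-12)
  expect_equal(rr$ci_low, 5.56, tolerance = 0.01)
  expect_equal(rr$ci_high, 21.77, tolerance = 0.01)

  null_tab <- ror_ci(c(6, 4, 12, 8))  # ad = bc
  expect_equal(null_tab$ror, 1.0, tolerance = 1e-12)
})

test_that("zero cells flag the estimate as undefined unless corrected", {
  rr <- ror_ci(c(0, 10, 5, 100))
  expect_true(rr$undefined)
  expect_true(is.na(rr$ror))
  rh <- ror_ci(c(0, 10, 5, 100), haldane = TRUE)
  expect_false(rh$undefined)
  expect_equal(rh$ror, (0.5 * 100.5) / (10.5 * 5.5), tolerance = 1e-12)
})

test_that("Fisher p equals exhaustive fixed-margin enumeration", {
  expect_equal(fisher_p(c(3, 1, 1, 3)), fisher_oracle(3, 1, 1, 3),
               tolerance = 1e-9)
  # maximally unbalanced table: smallest p among its margin class
  p_extreme <- fisher_p(c(0, 5, 5, 0))
  expect_equal(p_extreme, fisher_oracle(0, 5, 5, 0), tolerance = 1e-9)
  probs <- vapply(0:5, function(k)
    choose(5, k) * choose(5, 5 - k) / choose(10, 5), numeric(1))
  expect_equal(p_extreme, 2 * probs[1], tolerance = 1e-9)
  # proportional table: p = 1
  expect_equal(fisher_p(c(10, 10, 10, 10)), 1)
})

test_that("BH adjustment reproduces the step-up arithmetic", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdr_adjust(0.3), 0.3)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH is order-invariant, monotone and matches the oracle", {
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))^2
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(fdr_adjust(p[perm]), adj[perm], tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("the screen applies the case-count and CI criteria", {
  # drug y: 2 cases with enormous disproportionality -> still no signal
  ids <- as.character(1:60)
  demo <- data.frame(primaryid = ids, caseid = ids, fda_dt = "20200101")
  drugname <- c(rep("drug y", 2), rep("drug z", 28), rep("filler", 30))
  drug <- data.frame(primaryid = ids, caseid = ids, drug_seq = "1",
                     role_cod = "PS", drugname = drugname)
  pt <- c(rep("Sweet syndrome", 2), rep("Sweet syndrome", 10), rep("Rash", 48))
  reac <- data.frame(primaryid = ids, caseid = ids, pt = pt)
  store <- make_store(demo, drug = drug, reac = reac)
  scr <- screen_signals(store, "Sweet syndrome")
  expect_false(scr$signal[scr$drug == "drug y"])
  expect_equal(scr$n[scr$drug == "drug y"], 2L)
  # strict "more than 3" reading via min_cases = 4
  scr4 <- screen_signals(store, "Sweet syndrome", min_cases = 4)
  expect_true(all(scr4$n[scr4$signal] >= 4))
})

test_that("screen RORs agree with brute-force recounts on random fixtures", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(25:40, 1)
    exposed <- sample(n, sample(4:10, 1))
    with_event <- sample(n, sample(4:10, 1))
    store <- fixture_store(n, exposed, with_event)
    cells <- count_cells_oracle(store, "drug x", "Sweet syndrome")
    scr <- screen_signals(store, "Sweet syndrome", drugs = "drug x",
                          haldane = FALSE)
    if (all(cells > 0)) {
      expect_equal(scr$ror,
                   (cells["a"] * cells["d"]) / (cells["b"] * cells["c"]),
                   tolerance = 1e-12, ignore_attr = TRUE)
    } else {
      expect_true(is.na(scr$ror))
    }
    expect_equal(scr$n, unname(cells["a"]))
  }
})

test_that("increasing a at fixed margins raises the ROR", {
  base <- ror_ci(c(5, 20, 10, 100))$ror
  more <- ror_ci(c(6, 19, 9, 101))$ror
  expect_gt(more, base)
})

test_that("the reporter-filtered rerun returns the same schema on its universe", {
  ids <- as.character(1:40)
  demo <- data.frame(primaryid = ids, caseid = ids, fda_dt = "20200101",
                     occp_cod = rep(c("MD", "CN"), 20))
  drug <- data.frame(primaryid = ids, caseid = ids, drug_seq = "1",
                     role_cod = "PS",
                     drugname = rep(c("drug x", "filler"), each = 20))
  reac <- data.frame(primaryid = ids, caseid = ids,
                     pt = c(rep("Sweet syndrome", 10), rep("Rash", 30)))
  store <- make_store(demo, drug = drug, reac = reac)
  full <- screen_signals(store, "Sweet syndrome")
  md <- screen_signals(store, "Sweet syndrome", reporter_filter = "MD")
  expect_identical(names(md), names(full))
  expect_equal(unname(attr(md, "universe")["n"]), 20)
})

test_that("volcano coordinates are consistent with the estimates", {
  store <- fixture_store(200, exposed = 1:20, with_event = c(1:10, 30:35))
  scr <- screen_signals(store, "Sweet syndrome", drugs = "drug x")
  expect_equal(scr$log2_ror, log2(scr$ror))
  expect_equal(scr$neglog10_p_adj, -log10(scr$p_adj))
  expect_equal(scr$log10_n, log10(scr$n))
})
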