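test_that("drug name normalization trims, folds and maps synonyms", {
  nz <- drug_normalizer(synonym_map = c(HUMIRA = "adalimumab"))
  expect_equal(as.character(normalize_drug("HUMIRA", nz)), "adalimumab")
  expect_equal(as.character(normalize_drug("  Azathioprine ", nz)),
               "azathioprine")
  out <- normalize_drug("xyzzy", nz)
  expect_equal(as.character(out), "xyzzy")
  expect_true(attr(out, "unmapped"))
  expect_false(attr(normalize_drug("huMIra  ", nz), "unmapped"))
})

test_that("case extraction matches the event PT case-insensitively", {
  store <- fixture_store(100, exposed = 1:10, with_event = 1:37)
  cases <- extract_cases(store, case_definition("SWEET SYNDROME"))
  expect_length(cases$case_ids, 37L)
})

test_that("cases with only concomitant drugs are retained with zero suspect exposure", {
  demo <- data.frame(primaryid = "1", caseid = "1", fda_dt = "20200101")
  drug <- data.frame(primaryid = "1", caseid = "1", drug_seq = "1",
                     role_cod = "C", drugname = "prednisone")
  reac <- data.frame(primaryid = "1", caseid = "1", pt = "Sweet syndrome")
  store <- make_store(demo, drug = drug, reac = reac)
  expect_message(cases <- extract_cases(store), "no drug in role")
  expect_length(cases$case_ids, 1L)
  expect_equal(nrow(cases$drugs), 0L)
  expect_equal(cases$n_without_suspect, 1L)
})

test_that("an absent PT yields an empty case set with a warning", {
  store <- fixture_store(10, exposed = 1:2, with_event = integer(0))
  expect_warning(cases <- extract_cases(store,
                                        case_definition("No such PT")),
                 "not found")
  expect_length(cases$case_ids, 0L)
})

# fixture: 100 reports; 1-20 malignancy indication, 16-25 immune
# (5 reports carry both), 26-100 other/no indication
scheme_fixture <- function() {
  ids <- as.character(1:100)
  demo <- data.frame(primaryid = ids, caseid = ids, fda_dt = "20200101")
  drug <- data.frame(primaryid = ids, caseid = ids, drug_seq = "1",
                     role_cod = "PS", drugname = "drug x")
  reac <- data.frame(primaryid = ids, caseid = ids,
                     pt = ifelse(as.integer(ids) <= 30,
                                 "Sweet syndrome", "Rash"))
  indi <- rbind(
    data.frame(primaryid = as.character(1:20), caseid = as.character(1:20),
               indi_drug_seq = "1", indi_pt = "Acute myeloid leukaemia"),
    data.frame(primaryid = as.character(16:25), caseid = as.character(16:25),
               indi_drug_seq = "1", indi_pt = "Crohn's disease"),
    data.frame(primaryid = as.character(26:90), caseid = as.character(26:90),
               indi_drug_seq = "1", indi_pt = "Hypertension"))
  make_store(demo, drug = drug, reac = reac, indi = indi)
}

test_that("exclusion schemes retain the inclusion-exclusion counts", {
  store <- scheme_fixture()
  expect_length(scheme_retained(store, "main"), 75L)
  expect_length(scheme_retained(store, "sensitivity_A"), 80L)
  expect_length(scheme_retained(store, "sensitivity_B"), 90L)
  expect_length(scheme_retained(store, "full"), 100L)
})

test_that("main retention is the intersection of the two sensitivity retentions", {
  store <- scheme_fixture()
  expect_setequal(scheme_retained(store, "main"),
                  intersect(scheme_retained(store, "sensitivity_A"),
                            scheme_retained(store, "sensitivity_B")))
})

test_that("case counts are monotone across schemes", {
  store <- scheme_fixture()
  n_cases <- function(sc) {
    sub <- pvdiss:::subset_store(store, scheme_retained(store, sc))
    length(extract_cases(sub)$case_ids)
  }
  expect_lte(n_cases("main"), n_cases("sensitivity_A"))
  expect_lte(n_cases("main"), n_cases("sensitivity_B"))
  expect_lte(n_cases("sensitivity_A"), n_cases("full"))
  expect_lte(n_cases("sensitivity_B"), n_cases("full"))
})

test_that("build_dataset assembles case, demographics and exposure columns", {
  store <- scheme_fixture()
  ds <- build_dataset(store, "full", candidate_drugs = "drug x")
  expect_equal(nrow(ds), 100L)
  expect_equal(sum(ds$case), 30L)
  expect_equal(sum(ds$drug.x), 100L)
  expect_equal(attr(ds, "scheme"), "full")
  prov <- attr(ds, "provenance")
  expect_equal(unname(prov["n_retained"]), 100)

  ds_main <- build_dataset(store, "main", candidate_drugs = "drug x")
  expect_equal(nrow(ds_main), 75L)
})

test_that("a scheme that excludes everything is a degenerate dataset", {
  ids <- as.character(1:5)
  demo <- data.frame(primaryid = ids, caseid = ids, fda_dt = "20200101")
  drug <- data.frame(primaryid = ids, caseid = ids, drug_seq = "1",
                     role_cod = "PS", drugname = "x")
  reac <- data.frame(primaryid = ids, caseid = ids, pt = "Sweet syndrome")
  indi <- data.frame(primaryid = ids, caseid = ids, indi_drug_seq = "1",
                     indi_pt = "Breast cancer")
  store <- make_store(demo, drug = drug, reac = reac, indi = indi)
  expect_error(build_dataset(store, "main", "x"), "degenerate")
  expect_error(build_dataset(store, "full", character(0)), "non-empty")
})

test_that("indication classification returns overlapping flags, not a partition", {
  cl <- indication_classifier()
  fl <- classify_indication(c("Acute myeloid leukaemia", "Crohn's disease",
                              "Hypertension", "Autoimmune lymphoma"), cl)
  expect_equal(fl$malignancy, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(fl$immune, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("reports without indication rows are retained in every scheme", {
  ids <- as.character(1:4)
  demo <- data.frame(primaryid = ids, caseid = ids, fda_dt = "20200101")
  indi <- data.frame(primaryid = "1", caseid = "1", indi_drug_seq = "1",
                     indi_pt = "Breast cancer")
  store <- make_store(demo, indi = indi)
  expect_setequal(scheme_retained(store, "main"), c("2", "3", "4"))
})
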