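# Case definition, drug-name normalization, ATC mapping, indication
# classification and construction of the predefined analytical datasets.

#' Case definition
#'
#' A case is a deduplicated report whose REAC rows contain the event
#' preferred term (exact, case-insensitive match); exposure is restricted
#' to the given drug role codes (primary suspect by default).
#'
#' @param event_pt reaction preferred term (default the Sweet's syndrome
#'   PT, MedDRA code 10042458)
#' @param role_codes subset of `c("PS","SS","C","I")`
#' @return object of class `case_definition`
#' @export
case_definition <- function(event_pt = "Sweet syndrome", role_codes = "PS") {
  role_codes <- unique(role_codes)
  if (!length(role_codes) || !all(role_codes %in% c("PS", "SS", "C", "I")))
    stop("role_codes must be a non-empty subset of PS, SS, C, I",
         call. = FALSE)
  structure(list(event_pt = event_pt, role_codes = role_codes),
            class = "case_definition")
}

#' Drug name normalizer
#'
#' Standardizes free-text drug names: trim, collapse internal whitespace,
#' case-fold, then map through a user-supplied synonym table (the stand-in
#' for a licensed drug dictionary). Names absent from the synonym table
#' pass through (folded) and are flagged unmapped. An optional ATC map
#' assigns level-1/level-2 codes to standardized names.
#'
#' @param synonym_map named character vector: raw (folded) name ->
#'   standardized name; or a 2-column data frame (raw, standard)
#' @param atc_map data frame with columns `drug`, `atc1`, `atc2`
#' @return object of class `drug_normalizer`
#' @export
drug_normalizer <- function(synonym_map = NULL, atc_map = NULL) {
  if (is.data.frame(synonym_map))
    synonym_map <- stats::setNames(as.character(synonym_map[[2]]),
                                   as.character(synonym_map[[1]]))
  if (!is.null(synonym_map)) names(synonym_map) <- fold_name(names(synonym_map))
  if (!is.null(atc_map) &&
      !all(c("drug", "atc1", "atc2") %in% names(atc_map)))
    stop("atc_map needs columns drug, atc1, atc2", call. = FALSE)
  structure(list(synonym_map = synonym_map, atc_map = atc_map),
            class = "drug_normalizer")
}

#' Normalize drug names
#'
#' @param raw_name character vector of free-text names
#' @param normalizer a [drug_normalizer()]
#' @return character vector of standardized names, with a logical
#'   `unmapped` attribute marking names that had no synonym entry
#' @export
normalize_drug <- function(raw_name, normalizer = drug_normalizer()) {
  folded <- fold_name(raw_name)
  out <- folded
  unmapped <- rep(TRUE, length(out))
  if (!is.null(normalizer$synonym_map)) {
    hit <- match(folded, names(normalizer$synonym_map))
    found <- !is.na(hit)
    out[found] <- unname(normalizer$synonym_map[hit[found]])
    unmapped <- !found
  }
  attr(out, "unmapped") <- unmapped
  out
}

# ATC lookup for standardized names; returns data.frame(atc1, atc2) with
# "unclassified" where the map has no entry.
atc_lookup <- function(drugs, normalizer) {
  map <- normalizer$atc_map
  if (is.null(map))
    return(data.frame(atc1 = rep("unclassified", length(drugs)),
                      atc2 = rep("unclassified", length(drugs)),
                      stringsAsFactors = FALSE))
  i <- match(fold_name(drugs), fold_name(map$drug))
  data.frame(atc1 = ifelse(is.na(i), "unclassified", map$atc1[i]),
             atc2 = ifelse(is.na(i), "unclassified", map$atc2[i]),
             stringsAsFactors = FALSE)
}

#' Default malignancy-related indication terms
#'
#' Configurable seed list used for substring matching against indication
#' PTs; users should review and extend it for real analyses.
#' @return character vector
#' @export
default_malignancy_terms <- function() {
  c("neoplasm", "cancer", "leukaemia", "leukemia", "lymphoma", "myeloma",
    "myelodysplastic", "carcinoma", "sarcoma", "melanoma", "tumour",
    "tumor", "malignant", "blast crisis")
}

#' Default immune-related indication terms
#' @return character vector
#' @export
default_immune_terms <- function() {
  c("crohn", "ulcerative colitis", "rheumatoid arthritis", "lupus",
    "psoriasis", "ankylosing spondylitis", "inflammatory bowel",
    "sjogren", "vasculitis", "behcet", "sarcoidosis", "autoimmune")
}

#' Indication classifier
#'
#' Flags indication terms as malignancy-related and/or immune-related. The
#' two term sets may overlap and classification returns flags, not a
#' partition.
#'
#' @param malignancy_terms,immune_terms character term sets
#' @param mode `"substring"` (case-insensitive containment, default) or
#'   `"exact"` (case-insensitive whole-term match)
#' @return object of class `indication_classifier`
#' @export
indication_classifier <- function(malignancy_terms = default_malignancy_terms(),
                                  immune_terms = default_immune_terms(),
                                  mode = c("substring", "exact")) {
  mode <- match.arg(mode)
  structure(list(malignancy_terms = fold_name(malignancy_terms),
                 immune_terms = fold_name(immune_terms), mode = mode),
            class = "indication_classifier")
}

#' Classify indication terms
#'
#' @param terms character vector of indication PTs
#' @param classifier an [indication_classifier()]
#' @return data frame with logical columns `malignancy` and `immune`
#' @export
classify_indication <- function(terms, classifier = indication_classifier()) {
  folded <- fold_name(terms)
  match_set <- function(set) {
    if (classifier$mode == "exact") return(folded %in% set)
    hit <- rep(FALSE, length(folded))
    for (t in set) hit <- hit | grepl(t, folded, fixed = TRUE)
    hit
  }
  data.frame(malignancy = match_set(classifier$malignancy_terms),
             immune = match_set(classifier$immune_terms))
}

# Per-report indication flags over the whole store.
report_indication_flags <- function(store, classifier) {
  demo_pid <- store$tables$demo$primaryid
  indi <- store$tables$indi
  mal <- imm <- rep(FALSE, length(demo_pid))
  if (nrow(indi)) {
    fl <- classify_indication(indi$indi_pt, classifier)
    mal_pid <- unique(indi$primaryid[fl$malignancy])
    imm_pid <- unique(indi$primaryid[fl$immune])
    mal <- demo_pid %in% mal_pid
    imm <- demo_pid %in% imm_pid
  }
  data.frame(primaryid = demo_pid, malignancy = mal, immune = imm,
             stringsAsFactors = FALSE)
}

#' Retained PRIMARYIDs under an indication-exclusion scheme
#'
#' `main` excludes reports with malignancy- and/or immune-related
#' indications; `sensitivity_A` excludes malignancy only; `sensitivity_B`
#' excludes immune only; `full` excludes nothing. Reports without
#' indication rows are retained in all schemes (exclusion criteria cannot
#' be evaluated on missing data).
#'
#' @param store a deduplicated `faers_store`
#' @param scheme one of `"main"`, `"sensitivity_A"`, `"sensitivity_B"`,
#'   `"full"`
#' @param classifier an [indication_classifier()]
#' @return character vector of retained PRIMARYIDs
#' @export
scheme_retained <- function(store, scheme, classifier = indication_classifier()) {
  scheme <- match.arg(scheme, c("main", "sensitivity_A", "sensitivity_B", "full"))
  fl <- report_indication_flags(store, classifier)
  keep <- switch(scheme,
                 main = !(fl$malignancy | fl$immune),
                 sensitivity_A = !fl$malignancy,
                 sensitivity_B = !fl$immune,
                 full = rep(TRUE, nrow(fl)))
  fl$primaryid[keep]
}

# Subset a store to a set of PRIMARYIDs (used for schemes and reporter
# filters); child tables follow DEMO.
subset_store <- function(store, primaryids) {
  tables <- store$tables
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (nrow(tb) && "primaryid" %in% names(tb)) {
      tables[[nm]] <- tb[tb$primaryid %in% primaryids, , drop = FALSE]
      rownames(tables[[nm]]) <- NULL
    }
  }
  structure(list(tables = tables, quarters = store$quarters,
                 n_raw = store$n_raw), class = "faers_store")
}

#' Extract cases
#'
#' Returns the reports whose REAC rows contain the event PT of the case
#' definition, annotated with their normalized suspect drugs under the
#' definition's role codes. Cases without any drug in those roles are
#' retained with zero exposures (and counted).
#'
#' @param store a deduplicated `faers_store`
#' @param definition a [case_definition()]
#' @param normalizer a [drug_normalizer()]
#' @return object of class `diss_cases`: list with `case_ids`, `demo`
#'   (DEMO rows of the cases), `drugs` (data frame primaryid/drug of
#'   normalized role-restricted exposures) and `n_without_suspect`
#' @export
extract_cases <- function(store, definition = case_definition(),
                          normalizer = drug_normalizer()) {
  reac <- store$tables$reac
  hit <- fold_name(reac$pt) == fold_name(definition$event_pt)
  case_ids <- unique(reac$primaryid[hit])
  if (!length(case_ids))
    warning(sprintf("event PT '%s' not found in the corpus",
                    definition$event_pt), call. = FALSE)
  drug <- store$tables$drug
  sel <- drug$primaryid %in% case_ids & drug$role_cod %in% definition$role_codes
  drugs <- data.frame(primaryid = drug$primaryid[sel],
                      drug_seq = drug$drug_seq[sel],
                      drug = as.character(normalize_drug(drug$drugname[sel],
                                                         normalizer)),
                      stringsAsFactors = FALSE)
  drugs <- unique(drugs)
  n_without <- sum(!case_ids %in% drugs$primaryid)
  if (n_without)
    message(sprintf("%d case(s) have no drug in role(s) %s", n_without,
                    paste(definition$role_codes, collapse = "/")))
  demo <- store$tables$demo
  structure(list(case_ids = case_ids,
                 demo = demo[demo$primaryid %in% case_ids, , drop = FALSE],
                 drugs = drugs,
                 n_without_suspect = n_without,
                 definition = definition),
            class = "diss_cases")
}

#' @export
print.diss_cases <- function(x, ...) {
  cat(sprintf("%d case reports for PT '%s' (roles %s); %d distinct suspect drugs\n",
              length(x$case_ids), x$definition$event_pt,
              paste(x$definition$role_codes, collapse = "/"),
              length(unique(x$drugs$drug))))
  invisible(x)
}

#' Build an analytical dataset
#'
#' One row per report retained under the scheme, with the case indicator,
#' age (years, NA if missing), sex (`"M"`, `"F"`, NA) and one 0/1
#' primary-suspect exposure indicator per candidate drug. Exposure columns
#' are named `make.names(drug)`; the mapping is kept in the
#' `drug_columns` attribute.
#'
#' @param store deduplicated `faers_store`
#' @param scheme exclusion scheme, see [scheme_retained()]
#' @param candidate_drugs non-empty character vector of standardized names
#' @param definition a [case_definition()]
#' @param normalizer a [drug_normalizer()]
#' @param classifier an [indication_classifier()]
#' @return data frame of class `analytical_dataset` with attributes
#'   `scheme`, `drug_columns` and `provenance` (exclusion counts)
#' @export
build_dataset <- function(store, scheme, candidate_drugs,
                          definition = case_definition(),
                          normalizer = drug_normalizer(),
                          classifier = indication_classifier()) {
  if (!length(candidate_drugs))
    stop("candidate_drugs must be non-empty", call. = FALSE)
  retained <- scheme_retained(store, scheme, classifier)
  n_total <- nrow(store$tables$demo)
  if (!length(retained))
    stop(sprintf("degenerate dataset: scheme '%s' excludes every report",
                 scheme), call. = FALSE)
  sub <- subset_store(store, retained)
  cases <- extract_cases(sub, definition, normalizer)
  demo <- sub$tables$demo
  nr <- nrow(demo)
  age <- suppressWarnings(as.numeric(demo$age %||% rep(NA, nr)))
  sex <- as.character(demo$sex %||% rep(NA, nr))
  sex[!sex %in% c("M", "F")] <- NA_character_
  out <- data.frame(primaryid = demo$primaryid,
                    case = as.integer(demo$primaryid %in% cases$case_ids),
                    age = age, sex = sex, stringsAsFactors = FALSE)

  drug <- sub$tables$drug
  ps <- drug[drug$role_cod %in% definition$role_codes, , drop = FALSE]
  ps_drug <- as.character(normalize_drug(ps$drugname, normalizer))
  cols <- make.names(candidate_drugs)
  for (k in seq_along(candidate_drugs)) {
    pid <- unique(ps$primaryid[ps_drug == candidate_drugs[k]])
    out[[cols[k]]] <- as.integer(out$primaryid %in% pid)
  }
  attr(out, "scheme") <- scheme
  attr(out, "drug_columns") <- stats::setNames(cols, candidate_drugs)
  attr(out, "provenance") <- c(n_input = n_total,
                               n_retained = length(retained),
                               n_excluded = n_total - length(retained))
  class(out) <- c("analytical_dataset", "data.frame")
  out
}
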