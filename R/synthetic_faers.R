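# Synthetic FAERS-shaped report generator with planted drug-event signals.
#
# The generator exists so that every downstream stage (dedup, case
# definition, disproportionality, time-to-onset, modelling, network) can be
# exercised and power-checked without access to the real quarterly extracts.
# Effects are planted on the odds-ratio scale against the pooled comparator,
# i.e. directly on the ROR estimand, by tilting the event probability of
# reports whose primary-suspect drug carries a multiplier.

#' Default drug catalogue for simulations
#'
#' A small catalogue of drugs reported with Sweet's syndrome, with ATC
#' level-1/level-2 codes and the indication pool their simulated reports
#' draw from (`malignancy`, `immune` or `other`).
#'
#' @return data frame with columns `drug`, `atc1`, `atc2`, `pool`
#' @export
default_drug_catalog <- function() {
  data.frame(
    drug = c("azacitidine", "decitabine", "bortezomib", "venetoclax",
             "hydroxycarbamide", "filgrastim", "pegfilgrastim",
             "azathioprine", "adalimumab", "infliximab", "methotrexate",
             "mesalazine", "sulfamethoxazole/trimethoprim", "amoxicillin",
             "valaciclovir", "lisinopril", "metoprolol", "furosemide",
             "gabapentin", "paracetamol", "metformin", "omeprazole",
             "prednisone", "levothyroxine"),
    atc1 = c("L", "L", "L", "L", "L", "L", "L",
             "L", "L", "L", "L",
             "A", "J", "J",
             "J", "C", "C", "C",
             "N", "N", "A", "A",
             "H", "H"),
    atc2 = c("L01", "L01", "L01", "L01", "L01", "L03", "L03",
             "L04", "L04", "L04", "L04",
             "A07", "J01", "J01",
             "J05", "C09", "C07", "C03",
             "N03", "N02", "A10", "A02",
             "H02", "H03"),
    pool = c("malignancy", "malignancy", "malignancy", "malignancy",
             "malignancy", "malignancy", "malignancy",
             "immune", "immune", "immune", "immune",
             "immune", "other", "other",
             "other", "other", "other", "other",
             "other", "other", "other", "other",
             "other", "other"),
    stringsAsFactors = FALSE
  )
}

#' Generic synthetic drug catalogue
#'
#' Builds an anonymous catalogue (`drug_001`, ...) for power and
#' operating-characteristic simulations where many exchangeable null drugs
#' are needed.
#'
#' @param n number of drugs
#' @param pool indication pool tag recycled over drugs
#' @return data frame as in [default_drug_catalog()]
#' @export
synthetic_drug_catalog <- function(n, pool = "other") {
  atc1 <- rep(c("L", "J", "C", "N", "A"), length.out = n)
  data.frame(
    drug = sprintf("drug_%03d", seq_len(n)),
    atc1 = atc1,
    atc2 = paste0(atc1, "01"),
    pool = rep(pool, length.out = n),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defines one synthetic report corpus: its size, the background probability
#' that a report mentions the target preferred term (PT), the drug
#' catalogue, the drugs carrying planted associations (specified as target
#' reporting odds ratio multipliers), duplicate injection, field-level
#' missingness, the Weibull onset-latency law and the reporter mix.
#'
#' Default missingness and reporter/country mixes follow the demographic
#' profile typical of spontaneous-report cohorts for this event (age ~22.6%
#' missing, weight ~84.5%, sex ~10.3%, indications ~6.3%).
#'
#' @param n_reports number of distinct reports before duplicate injection
#' @param target_pt reaction preferred term of interest
#' @param background_event_rate probability a baseline report carries the
#'   target PT, in (0,1)
#' @param drug_catalog data frame with columns `drug`, `atc1`, `atc2`, `pool`
#' @param planted_signals named numeric vector: drug label -> odds-ratio
#'   multiplier (> 0); unlisted drugs have multiplier 1
#' @param duplicate_fraction fraction of reports cloned under a new
#'   PRIMARYID with a later FDA receipt date, in [0,1)
#' @param missingness named vector of per-field deletion probabilities for
#'   `age`, `sex`, `wt`, `event_dt`, `start_dt`
#' @param tto_weibull length-2 vector `c(shape, scale)` of the onset-latency
#'   Weibull law (scale in days)
#' @param reporter_mix named probability vector over reporter occupation
#'   codes (`MD`, `HP`, `CN`, `PH`, `LW`, `RN`, `OT`, `missing`)
#' @param country_mix named probability vector over reporter countries
#'   (`missing` allowed)
#' @param indication_rate probability a report carries an indication row
#' @param partial_date_fraction fraction of therapy-start / event-onset
#'   dates degraded to YYYYMM or YYYY precision
#' @param seed integer seed; the corpus is a deterministic function of the
#'   configuration including the seed
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_reports,
                       target_pt = "Sweet syndrome",
                       background_event_rate = 0.01,
                       drug_catalog = default_drug_catalog(),
                       planted_signals = NULL,
                       duplicate_fraction = 0.05,
                       missingness = c(age = 0.226, sex = 0.103, wt = 0.845,
                                       event_dt = 0.2, start_dt = 0.4),
                       tto_weibull = c(shape = 0.9, scale = 60),
                       reporter_mix = c(MD = 0.4123, HP = 0.1947, CN = 0.0971,
                                        PH = 0.0382, LW = 0.0010, RN = 0.0005,
                                        OT = 0.2106, missing = 0.0456),
                       country_mix = c(US = 0.3568, FR = 0.1204, CA = 0.0709,
                                       ES = 0.0505, JP = 0.0466, GB = 0.0456,
                                       OTHER = 0.2795, missing = 0.0297),
                       indication_rate = 0.9366,
                       partial_date_fraction = 0.05,
                       seed = 1L) {
  if (!is.numeric(n_reports) || length(n_reports) != 1L || n_reports < 1 ||
      n_reports != floor(n_reports))
    stop_config("n_reports", "must be a positive integer")
  if (!is.numeric(background_event_rate) ||
      background_event_rate <= 0 || background_event_rate >= 1)
    stop_config("background_event_rate", "must lie in (0, 1)")
  if (!is.data.frame(drug_catalog) ||
      !all(c("drug", "atc1", "atc2", "pool") %in% names(drug_catalog)) ||
      nrow(drug_catalog) < 1L)
    stop_config("drug_catalog", "needs columns drug, atc1, atc2, pool")
  if (anyDuplicated(drug_catalog$drug))
    stop_config("drug_catalog", "drug labels must be unique")
  if (!is.null(planted_signals)) {
    if (is.null(names(planted_signals)) || any(!nzchar(names(planted_signals))))
      stop_config("planted_signals", "must be a named numeric vector")
    if (any(planted_signals <= 0))
      stop_config("planted_signals", "multipliers must be > 0")
    missing_drugs <- setdiff(names(planted_signals), drug_catalog$drug)
    if (length(missing_drugs))
      stop_config("planted_signals",
                  paste("drugs not in catalogue:",
                        paste(missing_drugs, collapse = ", ")))
  }
  if (duplicate_fraction < 0 || duplicate_fraction >= 1)
    stop_config("duplicate_fraction", "must lie in [0, 1)")
  for (f in names(missingness))
    if (missingness[[f]] < 0 || missingness[[f]] >= 1)
      stop_config("missingness", sprintf("probability for '%s' out of [0,1)", f))
  if (length(tto_weibull) != 2L || any(tto_weibull <= 0))
    stop_config("tto_weibull", "needs positive shape and scale")
  if (abs(sum(reporter_mix) - 1) > 1e-9)
    stop_config("reporter_mix", "weights must sum to 1")
  if (abs(sum(country_mix) - 1) > 1e-9)
    stop_config("country_mix", "weights must sum to 1")
  if (partial_date_fraction < 0 || partial_date_fraction >= 1)
    stop_config("partial_date_fraction", "must lie in [0, 1)")
  structure(
    list(n_reports = as.integer(n_reports), target_pt = target_pt,
         background_event_rate = background_event_rate,
         drug_catalog = drug_catalog, planted_signals = planted_signals,
         duplicate_fraction = duplicate_fraction, missingness = missingness,
         tto_weibull = c(shape = unname(tto_weibull[1]),
                         scale = unname(tto_weibull[2])),
         reporter_mix = reporter_mix, country_mix = country_mix,
         indication_rate = indication_rate,
         partial_date_fraction = partial_date_fraction,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Indication term pools used by the generator; deliberately overlapping with
# the default classifier term lists in the cohort module.
.indication_pools <- list(
  malignancy = c("Acute myeloid leukaemia", "Plasma cell myeloma",
                 "Myelodysplastic syndrome", "Breast cancer",
                 "Chronic lymphocytic leukaemia", "Colon cancer"),
  immune = c("Crohn's disease", "Ulcerative colitis", "Rheumatoid arthritis",
             "Psoriasis", "Systemic lupus erythematosus"),
  other = c("Hypertension", "Pain", "Type 2 diabetes mellitus", "Epilepsy",
            "Bacterial infection", "Gastrooesophageal reflux disease",
            "Hypothyroidism")
)

.background_pts <- c("Pyrexia", "Rash", "Nausea", "Headache", "Fatigue",
                     "Pruritus", "Arthralgia", "Diarrhoea", "Vomiting",
                     "Dizziness")

# Render a standardized drug label as a free-text variant (case/whitespace
# noise only, so the default normalizer maps it back).
.render_drugname <- function(name, style) {
  out <- name
  up <- style %% 2L == 1L
  out[up] <- toupper(out[up])
  pad <- style >= 2L
  out[pad] <- paste0(" ", out[pad], " ")
  out
}

.degrade_dates <- function(x, frac) {
  if (frac <= 0) return(x)
  n <- length(x)
  hit <- runif(n) < frac & !is.na(x)
  to_month <- hit & runif(n) < 0.5
  to_year <- hit & !to_month
  x[to_month] <- substr(x[to_month], 1L, 6L)
  x[to_year] <- substr(x[to_year], 1L, 4L)
  x
}

#' Generate a synthetic FAERS-shaped corpus
#'
#' Draws `n_reports` spontaneous reports. Each report has one
#' primary-suspect (PS) drug drawn uniformly from the catalogue plus 0-4
#' concomitant (role C) drugs; the target PT occurs with probability
#' `background_event_rate`, tilted on the odds scale by the planted
#' multiplier of the PS drug, so the expected reporting odds ratio of a
#' planted drug equals its multiplier. Onset latency for target-PT reports
#' is Weibull; duplicates are injected by cloning reports under a new
#' PRIMARYID with a later FDA receipt date; configured missingness and
#' partial-date degradation are then applied.
#'
#' @param config a [sim_config()] object
#' @return object of class `faers_corpus`: a list with `tables` (the seven
#'   relational tables, all-character columns), `truth` (named vector of
#'   per-drug odds-ratio multipliers) and `seed_used`
#' @export
generate_corpus <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be created by sim_config()", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_reports
  cat_df <- config$drug_catalog
  nd <- nrow(cat_df)

  mult <- rep(1, nd)
  names(mult) <- cat_df$drug
  if (!is.null(config$planted_signals))
    mult[names(config$planted_signals)] <- as.numeric(config$planted_signals)

  caseid <- 10000000L + seq_len(n)
  primaryid <- caseid * 10L

  ps_idx <- sample.int(nd, n, replace = TRUE)
  p0 <- config$background_event_rate
  m <- mult[ps_idx]
  p_event <- m * p0 / (1 - p0 + m * p0)
  event <- runif(n) < p_event

  day0 <- as.Date("2004-01-01")
  span <- as.integer(as.Date("2024-12-31") - day0)
  fda_date <- day0 + sample.int(span, n, replace = TRUE)
  event_date <- day0 + 365 + sample.int(span - 730, n, replace = TRUE)

  lat <- numeric(n)
  lat[event] <- floor(stats::rweibull(sum(event),
                                      shape = config$tto_weibull["shape"],
                                      scale = config$tto_weibull["scale"]))
  lat[!event] <- sample.int(365L, sum(!event), replace = TRUE)
  start_date <- event_date - lat

  age <- pmin(pmax(round(stats::rnorm(n, 53, 18)), 1), 100)
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.43, 0.57))
  wt <- round(pmax(stats::rnorm(n, 73, 20), 20), 1)
  occp <- sample(names(config$reporter_mix), n, replace = TRUE,
                 prob = config$reporter_mix)
  occp[occp == "missing"] <- NA_character_
  country <- sample(names(config$country_mix), n, replace = TRUE,
                    prob = config$country_mix)
  country[country == "missing"] <- NA_character_

  miss <- function(x, field) {
    p <- config$missingness[field]
    if (is.na(p) || p <= 0) return(x)
    x[runif(length(x)) < p] <- NA
    x
  }
  age <- miss(age, "age")
  sex <- miss(sex, "sex")
  wt <- miss(wt, "wt")

  event_dt <- date_to_yyyymmdd(event_date)
  start_dt <- date_to_yyyymmdd(start_date)
  event_dt <- .degrade_dates(event_dt, config$partial_date_fraction)
  start_dt <- .degrade_dates(start_dt, config$partial_date_fraction)
  event_dt <- miss(event_dt, "event_dt")
  start_dt <- miss(start_dt, "start_dt")

  demo <- data.frame(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid),
    fda_dt = date_to_yyyymmdd(fda_date),
    event_dt = ifelse(is.na(event_dt), "", event_dt),
    age = ifelse(is.na(age), "", as.character(age)),
    age_cod = ifelse(is.na(age), "", "YR"),
    sex = ifelse(is.na(sex), "", sex),
    wt = ifelse(is.na(wt), "", as.character(wt)),
    wt_cod = ifelse(is.na(wt), "", "KG"),
    occp_cod = ifelse(is.na(occp), "", occp),
    reporter_country = ifelse(is.na(country), "", country),
    stringsAsFactors = FALSE
  )

  # DRUG + THER: PS row (drug_seq 1) plus 0-4 concomitants per report.
  n_conc <- sample(0:4, n, replace = TRUE)
  conc_rep <- rep(seq_len(n), n_conc)
  conc_idx <- sample.int(nd, length(conc_rep), replace = TRUE)
  conc_seq <- sequence(n_conc) + 1L
  drug_row_report <- c(seq_len(n), conc_rep)
  drug_row_idx <- c(ps_idx, conc_idx)
  drug_row_seq <- c(rep(1L, n), conc_seq)
  drug_row_role <- c(rep("PS", n), rep("C", length(conc_rep)))
  style <- sample(0:3, length(drug_row_idx), replace = TRUE)
  drug <- data.frame(
    primaryid = as.character(primaryid[drug_row_report]),
    caseid = as.character(caseid[drug_row_report]),
    drug_seq = as.character(drug_row_seq),
    role_cod = drug_row_role,
    drugname = .render_drugname(cat_df$drug[drug_row_idx], style),
    stringsAsFactors = FALSE
  )

  ther <- data.frame(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid),
    dsg_drug_seq = "1",
    start_dt = ifelse(is.na(start_dt), "", start_dt),
    end_dt = "",
    stringsAsFactors = FALSE
  )

  bg_pt <- sample(.background_pts, n, replace = TRUE)
  reac <- data.frame(
    primaryid = as.character(c(primaryid, primaryid[event])),
    caseid = as.character(c(caseid, caseid[event])),
    pt = c(bg_pt, rep(config$target_pt, sum(event))),
    stringsAsFactors = FALSE
  )

  has_outc <- runif(n) < 0.9856
  outc <- data.frame(
    primaryid = as.character(primaryid[has_outc]),
    caseid = as.character(caseid[has_outc]),
    outc_cod = sample(c("HO", "OT", "LT", "DS", "DE"), sum(has_outc),
                      replace = TRUE, prob = c(0.45, 0.35, 0.08, 0.05, 0.07)),
    stringsAsFactors = FALSE
  )

  rpsr <- data.frame(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid),
    rpsr_cod = sample(c("FGN", "SDY", "HP", "CSM"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  has_indi <- runif(n) < config$indication_rate
  pool_tag <- cat_df$pool[ps_idx]
  indi_term <- character(n)
  for (tag in names(.indication_pools)) {
    sel <- pool_tag == tag
    if (any(sel))
      indi_term[sel] <- sample(.indication_pools[[tag]], sum(sel),
                               replace = TRUE)
  }
  indi <- data.frame(
    primaryid = as.character(primaryid[has_indi]),
    caseid = as.character(caseid[has_indi]),
    indi_drug_seq = "1",
    indi_pt = indi_term[has_indi],
    stringsAsFactors = FALSE
  )

  tables <- list(demo = demo, drug = drug, reac = reac, outc = outc,
                 rpsr = rpsr, ther = ther, indi = indi)

  # Duplicate injection: clone under a new PRIMARYID with later FDA_DT.
  n_dup <- round(n * config$duplicate_fraction)
  if (n_dup > 0) {
    dup_i <- sample.int(n, n_dup)
    old_pid <- as.character(primaryid[dup_i])
    new_pid <- as.character(primaryid[dup_i] + 1L)
    dup_demo <- demo[dup_i, , drop = FALSE]
    dup_demo$primaryid <- new_pid
    dup_demo$fda_dt <- date_to_yyyymmdd(
      yyyymmdd_to_date(dup_demo$fda_dt) + sample.int(200L, n_dup, replace = TRUE))
    tables$demo <- rbind(tables$demo, dup_demo)
    for (nm in c("drug", "reac", "outc", "rpsr", "ther", "indi")) {
      tb <- tables[[nm]]
      sel <- tb$primaryid %in% old_pid
      if (any(sel)) {
        cl <- tb[sel, , drop = FALSE]
        cl$primaryid <- new_pid[match(cl$primaryid, old_pid)]
        tables[[nm]] <- rbind(tb, cl)
      }
    }
  }

  for (nm in names(tables)) {
    tb <- tables[[nm]]
    tb <- tb[order(as.numeric(tb$primaryid)), , drop = FALSE]
    rownames(tb) <- NULL
    tables[[nm]] <- tb
  }

  structure(list(tables = tables, truth = mult, seed_used = config$seed,
                 target_pt = config$target_pt),
            class = "faers_corpus")
}

#' @export
print.faers_corpus <- function(x, ...) {
  cat("Synthetic FAERS-shaped corpus\n")
  cat(sprintf("  reports (raw DEMO rows): %d\n", nrow(x$tables$demo)))
  cat(sprintf("  drug rows: %d, reaction rows: %d\n",
              nrow(x$tables$drug), nrow(x$tables$reac)))
  np <- sum(x$truth != 1)
  cat(sprintf("  planted signals: %d of %d drugs; seed %d\n",
              np, length(x$truth), x$seed_used))
  invisible(x)
}

.faers_file_names <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
                       outc = "OUTC", rpsr = "RPSR", ther = "THER",
                       indi = "INDI")

#' Write a corpus as FAERS quarterly ASCII files
#'
#' Emits one $-delimited text file per relational table
#' (`DEMOyyQq.txt`, ...). Fields containing the delimiter or quotes are
#' double-quoted so the round trip through [read_faers_quarters()] is exact.
#'
#' @param corpus a `faers_corpus`
#' @param directory output directory (created if absent)
#' @param quarter label such as `"24Q4"` used in file names
#' @return invisibly, the vector of file paths written
#' @export
write_faers_ascii <- function(corpus, directory, quarter = "24Q4") {
  if (!inherits(corpus, "faers_corpus"))
    stop("corpus must be a faers_corpus", call. = FALSE)
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", directory), call. = FALSE)
  paths <- character(0)
  for (nm in names(.faers_file_names)) {
    path <- file.path(directory,
                      paste0(.faers_file_names[[nm]], quarter, ".txt"))
    tb <- corpus$tables[[nm]]
    lines <- vapply(seq_len(nrow(tb) + 1L), function(i) {
      vals <- if (i == 1L) names(tb) else unlist(tb[i - 1L, ], use.names = FALSE)
      needs_quote <- grepl("[$\"]", vals)
      vals[needs_quote] <- paste0('"', gsub('"', '""', vals[needs_quote]), '"')
      paste(vals, collapse = "$")
    }, character(1))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
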