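# Fixture builders and independent oracles used across the suite.

# Build a faers_store directly from data frames (all columns coerced to
# character); absent tables become empty.
make_store <- function(demo, drug = NULL, reac = NULL, indi = NULL,
                       ther = NULL, outc = NULL, rpsr = NULL) {
  as_chr <- function(df) {
    if (is.null(df)) return(data.frame(primaryid = character(0),
                                       caseid = character(0),
                                       stringsAsFactors = FALSE))
    df[] <- lapply(df, as.character)
    df
  }
  structure(list(tables = list(demo = as_chr(demo), drug = as_chr(drug),
                               reac = as_chr(reac), outc = as_chr(outc),
                               rpsr = as_chr(rpsr), ther = as_chr(ther),
                               indi = as_chr(indi)),
                 quarters = "fixture", n_raw = c(demo = nrow(demo))),
            class = "faers_store")
}

# Report-level fixture: universe of n reports, PS exposure to `drug_name`
# for ids in `exposed`, target PT for ids in `with_event`.
fixture_store <- function(n, exposed, with_event, drug_name = "drug x",
                          event_pt = "Sweet syndrome") {
  ids <- as.character(seq_len(n))
  demo <- data.frame(primaryid = ids, caseid = ids, fda_dt = "20200101")
  drug <- data.frame(primaryid = ids, caseid = ids, drug_seq = "1",
                     role_cod = ifelse(ids %in% as.character(exposed),
                                       "PS", "C"),
                     drugname = ifelse(ids %in% as.character(exposed),
                                       drug_name, "other drug"))
  # unexposed reports get a PS row for a filler drug so every report has
  # a primary suspect
  filler <- data.frame(primaryid = ids[!ids %in% as.character(exposed)],
                       caseid = ids[!ids %in% as.character(exposed)],
                       drug_seq = "2", role_cod = "PS",
                       drugname = "filler drug")
  drug <- rbind(drug, filler)
  reac <- data.frame(
    primaryid = ids, caseid = ids,
    pt = ifelse(ids %in% as.character(with_event), event_pt, "Rash"))
  make_store(demo, drug = drug, reac = reac)
}

# --- independent oracles ---------------------------------------------------

# Two-sided Fisher exact p by exhaustive enumeration over all tables with
# the observed margins, using binomial coefficients directly.
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  prob <- vapply(ks, function(k)
    choose(r1, k) * choose(n - r1, c1 - k) / choose(n, c1), numeric(1))
  p_obs <- prob[ks == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up computed literally from its definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, m * sorted[i] / i)
    adj[i] <- min(run_min, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pearson chi-square brute force: sum (O-E)^2/E.
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Tie-corrected Mann-Whitney AUC from the rank formula.
auc_oracle <- function(scores, labels) {
  r <- rank(scores)
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Brute-force recount of the 2x2 cells from raw store rows.
count_cells_oracle <- function(store, drug_name, event_pt) {
  demo <- store$tables$demo
  drug <- store$tables$drug
  reac <- store$tables$reac
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  a <- b <- c_ <- d <- 0L
  for (pid in demo$primaryid) {
    exposed <- any(drug$primaryid == pid & drug$role_cod == "PS" &
                     norm(drug$drugname) == norm(drug_name))
    event <- any(reac$primaryid == pid & norm(reac$pt) == norm(event_pt))
    if (exposed && event) a <- a + 1L
    else if (exposed) b <- b + 1L
    else if (event) c_ <- c_ + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c_, d = d)
}
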