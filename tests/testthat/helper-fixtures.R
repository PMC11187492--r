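# Fixtures built in code; no data files.

# Small hand-written cohort around the 2015-01-01 index date.
toy_map <- function() {
  data.table::data.table(
    medcode = c("m_asthma1", "m_asthma2", "m_ra1", "m_dep1", "m_dep2",
                "m_af1", "m_ht1", "m_dm1"),
    disease = c("asthma", "asthma", "rheumatoid arthritis", "depression",
                "depression", "atrial fibrillation", "hypertension",
                "diabetes"))
}

toy_records <- function(ids, birth = as.Date("1960-06-15"),
                        registration = as.Date("2005-01-01")) {
  data.table::data.table(
    patient_id = ids, birth_date = birth, gender = "female",
    ethnicity = "White", imd_decile = 4L,
    registration_date = registration,
    deregistration_date = as.Date(NA), death_date = as.Date(NA))
}

# The worked example: asthma, rheumatoid arthritis, depression,
# atrial fibrillation, depression - in observation-date order.
example_events <- function(id = "p1") {
  data.table::data.table(
    patient_id = id,
    event_date = as.Date(c("2001-03-01", "2004-07-12", "2008-02-02",
                           "2011-10-30", "2013-05-06")),
    medcode = c("m_asthma1", "m_ra1", "m_dep1", "m_af1", "m_dep2"))
}

# Deterministic-grammar corpus: token "b" always follows token "a";
# fillers c01..c08. Returns a ready-made cohort for the sequence builder.
grammar_cohort <- function(n_seq = 1500L, len = 10L, seed = 5L) {
  with_seed_local(seed, {
    ids <- sprintf("g%04d", seq_len(n_seq))
    ev <- data.table::rbindlist(lapply(ids, function(id) {
      toks <- sample(sprintf("c%02d", 1:8), len, TRUE)
      i <- sample.int(len - 1L, 1L)
      toks[i] <- "a"; toks[i + 1L] <- "b"
      data.table::data.table(patient_id = id,
                             event_date = as.Date("2014-01-01") + seq_len(len),
                             medcode = toks)
    }))
    map <- data.table::data.table(medcode = c("a", "b", sprintf("c%02d", 1:8)),
                                  disease = c("a", "b", sprintf("c%02d", 1:8)))
    list(records = toy_records(ids, birth = as.Date("1950-01-01"),
                               registration = as.Date("2000-01-01")),
         events = ev, map = map)
  })
}

# Two planted sequence families over near-disjoint vocabularies, optionally
# with exact-duplicate sequences appended (for the identical-sequence score).
make_family_corpus <- function(n_per = 40L, len = 12L, seed = 11L,
                               n_dup = 0L) {
  with_seed_local(seed, {
    fam <- function(base, tag, n) {
      d <- replicate(n, sample(base, len, TRUE), simplify = FALSE)
      names(d) <- sprintf("%s%03d", tag, seq_len(n))
      d
    }
    corpus <- c(fam(sprintf("a%02d", 1:15), "A", n_per),
                fam(sprintf("b%02d", 1:15), "B", n_per))
    if (n_dup > 0) {
      dup <- corpus[seq_len(n_dup)]
      names(dup) <- sprintf("D%03d", seq_len(n_dup))
      corpus <- c(corpus, dup)
    }
    corpus
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# One shared simulated cohort, built lazily and reused across test files.
shared_cohort_env <- new.env(parent = emptyenv())
shared_cohort <- function(n = 3000L, seed = 301L) {
  key <- sprintf("n%d_s%d", n, seed)
  if (is.null(shared_cohort_env[[key]])) {
    shared_cohort_env[[key]] <- simulate_cohort(
      sim_config(n_patients = n, seed = seed))
  }
  shared_cohort_env[[key]]
}

# Run the full representation-vs-outcome pipeline once: simulate, sequence,
# restrict to the eligible cohort, train the desk transformer, evaluate both
# the transformer embeddings and binary indicators on one outcome.
headline_run <- function(seed, order_weight, n_patients = 4000L,
                         outcome = "ed_attendance", epochs = 12L,
                         hidden_layers = 3L) {
  cfg <- sim_config(n_patients = n_patients, order_weight = order_weight,
                    seed = seed)
  coh <- simulate_cohort(cfg)
  seqs <- build_sequences(coh$events, coh$map, coh$records, "diseases",
                          cfg$index_date)
  elig <- eligible_cohort(coh$records, seqs, cfg$index_date)
  rec <- coh$records[coh$records$patient_id %in% elig, ]
  sq <- seqs
  sq$data <- seqs$data[seqs$data$patient_id %in% elig, ]
  cohort <- build_outcome_cohort(rec, sq, coh$outcomes, outcome,
                                 cfg$index_date, markers = coh$params$markers,
                                 eligible_ids = elig)
  covs <- sociodemographic_features(rec, cfg$index_date)
  ec <- eval_config(seed = seed)
  r_bin <- evaluate_representation(binary_indicators(sq), covs, cohort, ec,
                                   outcome, "binary_indicators")
  tcfg <- transformer_config("ehrbert", "desk", hidden_layers = hidden_layers,
                             epochs = epochs, seed = seed + 1000L)
  fit <- fit_ehr_transformer(sq, rec, tcfg)
  r_bert <- evaluate_representation(fit$embeddings, covs, cohort, ec,
                                    outcome, "ehrbert")
  list(bert = unname(r_bert$pooled["roc_auc"]),
       binary = unname(r_bin$pooled["roc_auc"]),
       cohort = cohort, fit = fit)
}
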