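idx <- as.Date("2015-01-01")

make_labeled_embedding <- function(n, prevalence, informative = TRUE,
                                   seed = 1L) {
  with_seed_local(seed, {
    y <- as.integer(stats::runif(n) < prevalence)
    x <- if (informative) y * 3 + stats::rnorm(n, 0, 0.2) else stats::rnorm(n)
    ids <- sprintf("p%05d", seq_len(n))
    m <- cbind(x, stats::rnorm(n))
    rownames(m) <- ids
    list(emb = embedding_set(m, "fixture"),
         cohort = data.table::data.table(patient_id = ids, label = y))
  })
}

test_that("rank AUC agrees with an independent ROC implementation", {
  with_seed_local(3L, {
    y <- rbinom(300, 1, 0.3)
    s <- rnorm(300) + y
    s[1:50] <- round(s[1:50], 1)  # introduce ties
  })
  ours <- roc_auc(y, s)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
  # invariant under strictly monotone transforms
  expect_equal(roc_auc(y, exp(s)), ours, tolerance = 1e-12)
  expect_equal(roc_auc(y, rank(s)), ours, tolerance = 1e-12)
})

test_that("average precision matches a brute-force threshold sweep", {
  with_seed_local(4L, {
    y <- rbinom(200, 1, 0.25)
    s <- round(rnorm(200) + 0.8 * y, 1)  # heavy ties
  })
  # oracle: loop over distinct thresholds in decreasing order
  th <- sort(unique(s), decreasing = TRUE)
  P <- sum(y)
  ap <- 0; r_prev <- 0
  for (t in th) {
    pos <- s >= t
    prec <- sum(y[pos]) / sum(pos)
    rec <- sum(y[pos]) / P
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  expect_equal(average_precision(y, s), ap, tolerance = 1e-12)
})

test_that("a constant score has average precision exactly the prevalence", {
  y <- c(rep(1, 13), rep(0, 87))
  expect_identical(average_precision(y, rep(0.42, 100)), 13 / 100)
})

test_that("label-independent scores give chance-level metrics", {
  with_seed_local(5L, {
    y <- rbinom(10000, 1, 0.1)
    s <- rnorm(10000)
  })
  expect_lt(abs(roc_auc(y, s) - 0.5), 0.02)
  # compare against the realized prevalence of the draw
  expect_lt(abs(average_precision(y, s) - mean(y)), 0.01)
})

test_that("confusion metrics reproduce the printed-fixture arithmetic", {
  m <- confusion_metrics(tp = 40, fn = 60, fp = 129, tn = 771)
  expect_equal(unname(m["sensitivity"]), 0.40)
  expect_equal(round(100 * unname(m["ppv"]), 1), 23.7)
  expect_equal(unname(m["specificity"]), 771 / 900)
  expect_equal(unname(m["npv"]), 771 / 831)
})

test_that("threshold metrics reach the requested sensitivities", {
  with_seed_local(6L, {
    y <- rbinom(2000, 1, 0.2)
    s <- rnorm(2000) + y
  })
  tm <- threshold_metrics(y, s, c(0.4, 0.7, 0.9))
  expect_equal(nrow(tm), 3L)
  expect_true(all(tm$sensitivity >= c(0.4, 0.7, 0.9)))
  # higher sensitivity costs specificity and PPV
  expect_true(all(diff(tm$specificity) < 0))
  expect_true(all(diff(tm$ppv) < 0))
})

test_that("a separable feature yields perfect pooled metrics", {
  fx <- make_labeled_embedding(400, 0.3, informative = TRUE, seed = 7L)
  res <- evaluate_representation(fx$emb, NULL, fx$cohort,
                                 eval_config(seed = 1L), "toy")
  expect_equal(unname(res$pooled["roc_auc"]), 1)
  expect_equal(unname(res$pooled["aps"]), 1)
  expect_equal(res$n, 400L)
})

test_that("fold assignment is stratified and deterministic", {
  y <- c(rep(1, 21), rep(0, 179))
  f1 <- ehrseqrep:::stratified_folds(y, 4L, seed = 9L)
  f2 <- ehrseqrep:::stratified_folds(y, 4L, seed = 9L)
  expect_identical(f1, f2)
  ev_counts <- table(f1[y == 1])
  expect_lte(diff(range(ev_counts)), 1)
  tot_counts <- table(f1)
  expect_lte(diff(range(tot_counts)), 2)
})

test_that("a single-class fold raises a named error", {
  fx <- make_labeled_embedding(40, 0.05, seed = 10L)
  fx$cohort$label <- c(1L, rep(0L, 39))  # one positive cannot stratify
  expect_error(
    evaluate_representation(fx$emb, NULL, fx$cohort, eval_config(seed = 1L),
                            "rare_outcome"),
    "rare_outcome.*fold|fold.*rare_outcome")
})

test_that("outcome cohorts reproduce a hand-enumerated 12-patient fixture", {
  ids <- sprintf("f%02d", 1:12)
  rec <- toy_records(ids)
  rec$deregistration_date[1:2] <- as.Date(c("2015-03-01", "2015-11-30"))
  rec$death_date[3] <- as.Date("2015-06-15")
  ev <- data.table::rbindlist(lapply(ids, function(id) example_events(id)))
  # patients 4, 5, 6 have prevalent hypertension in history
  ev <- rbind(ev, data.table::data.table(
    patient_id = ids[4:6], event_date = as.Date("2012-01-01"),
    medcode = "m_ht1"))
  seqs <- build_sequences(ev, toy_map(), rec, "diseases", idx)
  out <- data.table::data.table(patient_id = ids,
                                new_hypertension = 0L,
                                any_depression = 1L,
                                mortality_60plus = 0L)
  markers <- list(hypertension = "hypertension", depression = "depression")

  # 12 - 2 deregistered - 1 died - 3 prevalent = 6
  ch <- build_outcome_cohort(rec, seqs, out, "new_hypertension", idx,
                             markers = markers)
  expect_equal(nrow(ch), 6L)
  expect_setequal(ch$patient_id, ids[7:12])

  # prevalence exclusion applies only to "new" outcomes: prior depression
  # patients stay in the any_depression cohort (all histories have depression)
  ch_any <- build_outcome_cohort(rec, seqs, out, "any_depression", idx,
                                 markers = markers)
  expect_equal(nrow(ch_any), 9L)  # only dereg/death exclusions apply

  # mortality cohort needs age >= 60 at index: cohort born 1960 is 54
  ch_mort <- build_outcome_cohort(rec, seqs, out, "mortality_60plus", idx)
  expect_equal(nrow(ch_mort), 0L)
  rec60 <- data.table::copy(rec)
  rec60$birth_date <- as.Date("1950-01-01")
  ch_mort60 <- build_outcome_cohort(rec60, seqs, out, "mortality_60plus", idx)
  expect_equal(nrow(ch_mort60), 10L)  # deaths in window stay for mortality

  expect_error(build_outcome_cohort(rec, seqs, out, "nonsense", idx),
               "unknown outcome")
})

test_that("comparisons rank representations and tolerate missing ones", {
  fx <- make_labeled_embedding(300, 0.3, seed = 12L)
  with_seed_local(13L, {
    noise <- matrix(rnorm(300 * 3), 300, 3,
                    dimnames = list(fx$cohort$patient_id, NULL))
  })
  reps <- list(good = fx$emb, noise = embedding_set(noise, "noise"))
  cmp <- run_comparison(reps, list(toy = fx$cohort), NULL,
                        eval_config(seed = 1L))
  expect_equal(nrow(cmp$ranking), 2L)
  expect_equal(cmp$ranking$representation[cmp$ranking$rank == 1], "good")
  expect_true(all(c("outcome", "representation", "metric", "fold", "value")
                  %in% names(cmp$table)))

  # representation missing half the cohort -> recorded absent, not an error
  half <- embedding_set(noise[1:150, , drop = FALSE], "half")
  cmp2 <- run_comparison(list(good = fx$emb, half = half),
                         list(toy = fx$cohort), NULL, eval_config(seed = 1L))
  expect_length(cmp2$absent, 1L)
  expect_match(cmp2$absent, "half")
  md <- comparison_report(cmp)
  expect_true(any(grepl("^\\| 1 \\| good", md)))
})
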