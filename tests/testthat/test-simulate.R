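test_that("simulation is deterministic and structurally valid", {
  cfg <- sim_config(n_patients = 800L, seed = 11L)
  coh <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh$records, coh2$records)
  expect_identical(coh$events, coh2$events)
  expect_identical(coh$outcomes, coh2$outcomes)

  # every patient carries >= 2 distinct disease categories in history
  nd <- coh$events[, list(k = data.table::uniqueN(disease)),
                   by = "patient_id"]
  expect_equal(nrow(nd), 800L)
  expect_true(all(nd$k >= 2L))

  r <- coh$records
  expect_true(all(r$registration_date >= r$birth_date))
  has_death <- !is.na(r$death_date)
  expect_true(all(r$death_date[has_death] >= r$registration_date[has_death]))
  expect_true(all(coh$events$event_date < cfg$index_date))
  expect_true(all(coh$events$medcode %in% coh$map$medcode))
  # map is many-to-one and covers the whole fine vocabulary
  expect_equal(nrow(coh$map), cfg$fine_vocab_size)
  expect_false(anyDuplicated(coh$map$medcode) > 0)
  expect_equal(data.table::uniqueN(coh$map$disease), cfg$category_vocab_size)

  # patients dead before index have no defined outcome labels
  pre_death <- !is.na(r$death_date) & r$death_date < cfg$index_date
  expect_true(all(is.na(coh$outcomes$ed_attendance[pre_death])))
})

test_that("configured marginals are recovered at moderate n", {
  coh <- shared_cohort(n = 6000L, seed = 301L)
  cfg <- coh$config
  r <- coh$records
  age <- as.numeric(cfg$index_date - r$birth_date) / 365.25
  expect_lt(abs(mean(age) - cfg$age_mean), 0.8)
  expect_lt(abs(stats::sd(age) - cfg$age_sd), 0.8)
  expect_lt(abs(mean(r$gender == "female") - 0.531), 0.02)
  expect_lt(abs(mean(r$ethnicity == "White") - 0.862), 0.02)
  expect_lt(abs(mean(is.na(r$imd_decile)) - 0.001), 0.003)
})

test_that("outcome intercepts are calibrated to the target rates", {
  coh <- shared_cohort(n = 6000L, seed = 301L)
  cfg <- coh$config
  r <- coh$records
  idx <- cfg$index_date
  eligible <- r$registration_date <= idx - 365L &
    (is.na(r$death_date) | r$death_date >= idx) &
    (is.na(r$deregistration_date) | r$deregistration_date >= idx) &
    !(!is.na(r$deregistration_date) & r$deregistration_date < idx + 365L)
  p <- outcome_probabilities(coh, "ed_attendance")
  # calibration is on the eligible stratum minus in-window deaths
  died <- coh$outcomes$mortality_60plus %in% 1L
  stratum <- eligible & !died
  expect_lt(abs(mean(p[stratum]) - cfg$target_rates[["ed_attendance"]]), 1e-6)
})

test_that("impossible target rates fail loudly", {
  expect_error(sim_config(target_rates = c(mortality_60plus = 0)),
               "mortality_60plus")
  # no 60+ patients -> empty mortality stratum
  cfg <- sim_config(n_patients = 300L, age_mean = 30, age_sd = 3, seed = 2L)
  expect_error(simulate_cohort(cfg), "mortality_60plus")
})

test_that("with order effects at zero the outcome model ignores event order", {
  cfg0 <- sim_config(n_patients = 1500L, order_weight = 0, seed = 21L)
  coh0 <- simulate_cohort(cfg0)
  p0 <- outcome_probabilities(coh0, "emergency_admission")
  # permute event dates within each patient (breaks order, keeps the multiset)
  ev <- data.table::copy(coh0$events)
  with_seed_local(99L, {
    ev[, event_date := sample(event_date), by = "patient_id"]
  })
  p_perm <- outcome_probabilities(coh0, "emergency_admission", events = ev)
  expect_equal(p0, p_perm, tolerance = 1e-12)

  # with order effects on, the same permutation changes the probabilities
  cfg1 <- sim_config(n_patients = 1500L, order_weight = 1, seed = 21L)
  coh1 <- simulate_cohort(cfg1)
  p1 <- outcome_probabilities(coh1, "emergency_admission")
  ev1 <- data.table::copy(coh1$events)
  with_seed_local(99L, {
    ev1[, event_date := sample(event_date), by = "patient_id"]
  })
  p1_perm <- outcome_probabilities(coh1, "emergency_admission", events = ev1)
  expect_gt(max(abs(p1 - p1_perm)), 0.01)
})

test_that("generating coefficients are recoverable by logistic regression", {
  cfg <- sim_config(n_patients = 40000L, seed = 77L)
  coh <- simulate_cohort(cfg)
  nm <- "emergency_admission"
  p <- coh$params$outcomes[[nm]]
  feats <- outcome_features(coh$records, coh$events, coh$params,
                            cfg$index_date)
  age <- as.numeric(cfg$index_date - coh$records$birth_date) / 365.25
  active <- names(p$w_dis)[p$w_dis != 0]
  X <- cbind(feats$presence[, active] * 1, feats$order,
             recency = feats$recency, age_c = age - cfg$age_mean,
             female = as.numeric(coh$records$gender == "female"))
  beta_true <- c(p$w_dis[active],
                 rep(cfg$precedence_weight, ncol(feats$order)),
                 p$w_recency, p$w_age, p$w_female)
  y <- coh$outcomes[[nm]]
  ok <- !is.na(y)
  fit <- stats::glm.fit(cbind(1, X[ok, ]), y[ok],
                        family = stats::binomial())
  est <- fit$coefficients[-1]
  se <- sqrt(diag(chol2inv(chol(crossprod(
    cbind(1, X[ok, ]) * sqrt(fit$weights))))))[-1]
  expect_true(all(abs(est - beta_true) <= 3 * se))
})

test_that("cohort round-trips through CSV and bad inputs are rejected", {
  coh <- simulate_cohort(sim_config(n_patients = 120L, seed = 5L))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$records), as.data.frame(coh$records))
  expect_equal(as.data.frame(back$events),
               as.data.frame(coh$events[, c("patient_id", "event_date",
                                            "medcode", "disease")]))
  expect_equal(as.data.frame(back$map), as.data.frame(coh$map))

  # event with a medcode absent from the map -> error naming the code
  bad <- data.table::copy(coh$events)
  bad$medcode[1] <- "m_not_in_map"
  data.table::fwrite(bad, file.path(dir, "events.csv"))
  expect_error(read_cohort(dir), "m_not_in_map")

  # empty events file -> empty table, no crash
  data.table::fwrite(coh$events[0, c("patient_id", "event_date", "medcode")],
                     file.path(dir, "events.csv"))
  expect_equal(nrow(read_cohort(dir)$events), 0L)

  # schema violation named per column
  rec2 <- data.table::copy(coh$records)
  rec2$gender <- NULL
  data.table::fwrite(rec2, file.path(dir, "patients.csv"))
  expect_error(read_cohort(dir), "gender")
})
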