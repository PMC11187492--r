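# Synthetic primary-care cohort simulator.
#
# Stands in for a restricted EHR extract: multimorbid adult patients with
# time-ordered, recurrently coded diagnosis events drawn from a latent-topic
# Markov process, a many-to-one fine-code -> disease-category map, sociodemographics
# with explicit missing levels, and binary 1-year outcome labels generated by a
# logistic model over disease presence, sequence-order terms and demographics.

#' Simulation configuration
#'
#' Builds the configuration object consumed by [simulate_cohort()]. Defaults
#' emulate the marginal structure of a large English primary-care multimorbidity
#' cohort: mean (sd) age 53.8 (18.2) years, 53.1% female, predominantly White
#' ethnicity, a near-uniform spread over deprivation deciles with an explicit
#' missing level, and 1-year outcome event rates (e.g. 3.3% mortality in the
#' 60+ stratum, 19.9% emergency-department attendance) hit by calibrating each
#' outcome's intercept on the eligible stratum.
#'
#' @param n_patients number of patients to simulate.
#' @param index_date cut between history (used for representations) and the
#'   1-year follow-up window (used for outcomes).
#' @param fine_vocab_size number of fine-grained codes ("medcodes").
#' @param category_vocab_size number of disease categories; every fine code
#'   maps to exactly one category.
#' @param n_latent_topics latent health states generating visit content.
#' @param markov_persistence probability the latent state persists between
#'   consecutive visits.
#' @param mean_visits,visit_dispersion negative-binomial parameters for the
#'   number of visits beyond the guaranteed minimum of 2.
#' @param events_per_visit_probs probabilities of 1, 2 or 3 codes per visit
#'   (most visits carry a single code).
#' @param recurrent_coding_rate probability an event re-codes one of the
#'   patient's previously recorded codes rather than a new draw.
#' @param recurrent_imd_multipliers length-10 multiplier on the recurrent
#'   coding rate per deprivation decile (missing decile gets 1).
#' @param history_years length of the history window before `index_date`.
#' @param followup_days follow-up window length in days.
#' @param age_mean,age_sd mean and sd of age at index (truncated to 18..105).
#' @param gender_probs,ethnicity_probs,imd_probs marginal distributions;
#'   `imd_probs` has 11 entries (deciles 1..10 plus missing).
#' @param dereg_rate probability of deregistration during follow-up.
#' @param pre_index_dereg_rate probability of deregistration before index.
#' @param pre_index_death_rate probability of death before index.
#' @param short_registration_rate probability registration is < 1 year
#'   before index (such patients fail the eligibility window).
#' @param target_rates named vector of target 1-year event rates (proportions)
#'   for the nine outcomes, each calibrated on its eligible stratum.
#' @param disease_weight_sd sd of the random disease-presence log-odds weights.
#' @param marker_weight log-odds weight of a disease's own history presence on
#'   its "any attendance" outcome.
#' @param order_weight global multiplier on all sequence-order terms
#'   (precedence indicators and the recency-weighted exposure sum); 0 removes
#'   order information from the outcome model entirely.
#' @param n_order_pairs number of disease-precedence pairs entering outcomes.
#' @param precedence_weight log-odds weight per precedence indicator.
#' @param recency_weight weight of the recency-weighted exposure sum.
#' @param recency_halflife_days e-folding time of the recency kernel.
#' @param seed integer RNG seed; all outputs are deterministic given the
#'   config.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 20000L,
                       index_date = as.Date("2015-01-01"),
                       fine_vocab_size = 400L,
                       category_vocab_size = 40L,
                       n_latent_topics = 6L,
                       markov_persistence = 0.8,
                       mean_visits = 8,
                       visit_dispersion = 3,
                       events_per_visit_probs = c(0.80, 0.15, 0.05),
                       recurrent_coding_rate = 0.25,
                       recurrent_imd_multipliers = c(rep(1, 5), rep(1.2, 5)),
                       history_years = 15,
                       followup_days = 365L,
                       age_mean = 53.8,
                       age_sd = 18.2,
                       gender_probs = c(female = 0.531, male = 0.46898,
                                        indeterminate = 0.00002),
                       ethnicity_probs = c(White = 0.862, `South Asian` = 0.059,
                                           Black = 0.035, Other = 0.013,
                                           Mixed = 0.010, missing = 0.020),
                       imd_probs = c(0.113, 0.104, 0.106, 0.105, 0.095,
                                     0.099, 0.099, 0.095, 0.095, 0.088, 0.001),
                       dereg_rate = 0.049,
                       pre_index_dereg_rate = 0.01,
                       pre_index_death_rate = 0.01,
                       short_registration_rate = 0.03,
                       target_rates = c(mortality_60plus = 0.033,
                                        ed_attendance = 0.199,
                                        emergency_admission = 0.073,
                                        any_hypertension = 0.105,
                                        any_diabetes = 0.091,
                                        any_depression = 0.039,
                                        new_hypertension = 0.015,
                                        new_diabetes = 0.008,
                                        new_depression = 0.011),
                       disease_weight_sd = 0.6,
                       marker_weight = 2.0,
                       order_weight = 1.0,
                       n_order_pairs = 3L,
                       precedence_weight = 1.5,
                       recency_weight = 0.15,
                       recency_halflife_days = 1825,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1,
            cfg$fine_vocab_size >= cfg$category_vocab_size,
            cfg$category_vocab_size >= 10L,
            cfg$markov_persistence >= 0, cfg$markov_persistence <= 1,
            cfg$recurrent_coding_rate >= 0, cfg$recurrent_coding_rate <= 1,
            abs(sum(cfg$events_per_visit_probs) - 1) < 1e-8,
            length(cfg$imd_probs) == 11L,
            length(cfg$recurrent_imd_multipliers) == 10L)
  if (any(cfg$target_rates <= 0) || any(cfg$target_rates >= 1)) {
    bad <- names(cfg$target_rates)[cfg$target_rates <= 0 | cfg$target_rates >= 1]
    stop(sprintf("target rate for outcome %s must lie strictly in (0, 1)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cfg$index_date <- as.Date(cfg$index_date)
  class(cfg) <- "sim_config"
  cfg
}

outcome_names <- function() {
  c("mortality_60plus", "ed_attendance", "emergency_admission",
    "any_hypertension", "any_diabetes", "any_depression",
    "new_hypertension", "new_diabetes", "new_depression")
}

category_labels <- function(v) sprintf("c%03d", seq_len(v))
medcode_labels <- function(f) sprintf("m%05d", seq_len(f))

# Marker categories stand for the three evaluated diseases.
marker_categories <- function(cfg) {
  cats <- category_labels(cfg$category_vocab_size)
  c(hypertension = cats[1], diabetes = cats[2], depression = cats[3])
}

order_pair_categories <- function(cfg) {
  cats <- category_labels(cfg$category_vocab_size)
  k <- cfg$n_order_pairs
  lapply(seq_len(k), function(i) c(cats[2 + 2 * i], cats[3 + 2 * i]))
}

# Many-to-one map: each category receives at least one fine code; remaining
# codes are spread uniformly at random.
build_code_map <- function(cfg) {
  v <- cfg$category_vocab_size
  f <- cfg$fine_vocab_size
  assign_cat <- c(seq_len(v), sample.int(v, f - v, replace = TRUE))
  data.table::data.table(medcode = medcode_labels(f),
                         disease = category_labels(v)[assign_cat])
}

# ---------------------------------------------------------------------------

#' Simulate a synthetic multimorbidity cohort
#'
#' Generates patient records, dated coded events, the fine-code to
#' disease-category map, and binary 1-year outcome labels. Every patient has
#' at least 2 distinct disease categories before the index date. Events arise
#' from a per-patient latent-topic Markov chain over visits (a visit is the
#' set of events sharing a calendar date; most visits carry one code), with
#' recurrent re-coding of previously recorded codes. Outcome labels are
#' Bernoulli draws from a logistic model combining disease presence,
#' sequence-order terms (precedence indicators and a recency-weighted exposure
#' sum) and sociodemographics; each outcome's intercept is calibrated so the
#' configured target rate holds on its eligible stratum.
#'
#' @param config a [sim_config()] object.
#' @return list of class `ehr_cohort` with elements `records`, `events`,
#'   `map`, `outcomes` (labels; `NA` where the patient has no follow-up or the
#'   outcome is structurally undefined), `params` (true generating
#'   coefficients) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  idx <- cfg$index_date
  ids <- sprintf("p%07d", seq_len(n))

  ## --- demographics -------------------------------------------------------
  # underlying normal chosen so the truncated (18..105) draw reproduces the
  # configured cohort mean/sd
  ap <- truncnorm_match(cfg$age_mean, cfg$age_sd, 18, 105)
  age <- rtruncnorm(n, ap[["mu"]], ap[["sigma"]], 18, 105)
  # age is continuous age-at-index in years; its fractional part already
  # places the birthday within the year
  birth_date <- idx - round(age * 365.25)
  gender <- sample(names(cfg$gender_probs), n, TRUE, cfg$gender_probs)
  ethnicity <- sample(names(cfg$ethnicity_probs), n, TRUE, cfg$ethnicity_probs)
  imd_lvls <- c(as.character(1:10), NA)
  imd <- sample(imd_lvls, n, TRUE, cfg$imd_probs)
  imd_decile <- suppressWarnings(as.integer(imd))

  reg_offset <- round(stats::rgamma(n, shape = 2, scale = 2500))
  short <- stats::runif(n) < cfg$short_registration_rate
  reg_offset[short] <- sample(30:364, sum(short), replace = TRUE)
  registration_date <- pmax(birth_date, idx - reg_offset)

  death_date <- rep(as.Date(NA), n)
  pre_death <- stats::runif(n) < cfg$pre_index_death_rate
  death_date[pre_death] <- idx - sample.int(365L, sum(pre_death), replace = TRUE)
  death_date[pre_death] <- pmax(death_date[pre_death],
                                registration_date[pre_death] + 1L)

  dereg_date <- rep(as.Date(NA), n)
  pre_dereg <- !pre_death & stats::runif(n) < cfg$pre_index_dereg_rate
  dereg_date[pre_dereg] <- idx - sample.int(300L, sum(pre_dereg), replace = TRUE)
  dereg_date[pre_dereg] <- pmax(dereg_date[pre_dereg],
                                registration_date[pre_dereg] + 1L)
  in_dereg <- !pre_death & !pre_dereg & stats::runif(n) < cfg$dereg_rate
  dereg_date[in_dereg] <- idx + sample.int(cfg$followup_days, sum(in_dereg),
                                           replace = TRUE) - 1L

  records <- data.table::data.table(
    patient_id = ids, birth_date = birth_date, gender = gender,
    ethnicity = ethnicity, imd_decile = imd_decile,
    registration_date = registration_date,
    deregistration_date = dereg_date, death_date = death_date)

  ## --- code map and topic structure ---------------------------------------
  map <- build_code_map(cfg)
  v <- cfg$category_vocab_size
  k <- cfg$n_latent_topics
  cats <- category_labels(v)
  # Topic-specific Dirichlet draws mixed with a background concentrated on the
  # first 10 categories, so marker and precedence-pair diseases are common.
  topic_raw <- matrix(stats::rgamma(k * v, shape = 0.08), k, v)
  topic_raw <- topic_raw / rowSums(topic_raw)
  background <- c(rep(1 / 10, 10), rep(0, v - 10))
  topic_cat <- 0.6 * topic_raw + 0.4 * matrix(background, k, v, byrow = TRUE)
  topic_cum <- t(apply(topic_cat, 1, cumsum))
  codes_by_cat <- split(map$medcode, map$disease)[cats]

  ## --- events -------------------------------------------------------------
  base_topic <- matrix(stats::rgamma(n * k, shape = 0.3), n, k)
  base_topic <- base_topic / rowSums(base_topic)
  n_visits <- 2L + stats::rnbinom(n, size = cfg$visit_dispersion,
                                  mu = max(cfg$mean_visits - 2, 0.1))
  rec_mult <- ifelse(is.na(imd_decile), 1,
                     cfg$recurrent_imd_multipliers[imd_decile])
  rec_rate <- pmin(1, cfg$recurrent_coding_rate * rec_mult)
  hist_start <- pmax(birth_date + 365L, idx - round(cfg$history_years * 365.25))
  hist_end <- rep(idx - 1L, n)
  hist_end[pre_death] <- pmin(hist_end[pre_death], death_date[pre_death] - 1L)

  epp <- cfg$events_per_visit_probs
  ev_pid <- ev_date <- ev_code <- vector("list", n)
  for (i in seq_len(n)) {
    nv <- n_visits[i]
    span <- as.integer(hist_end[i] - hist_start[i])
    if (span < nv) span <- max(nv, 30L)
    vdates <- sort(sample.int(span + 1L, nv, replace = TRUE)) - 1L
    vdates <- hist_start[i] + vdates
    # latent state chain
    topics <- integer(nv)
    topics[1] <- sample.int(k, 1L, prob = base_topic[i, ])
    if (nv > 1) for (t in 2:nv) {
      topics[t] <- if (stats::runif(1) < cfg$markov_persistence) topics[t - 1]
                   else sample.int(k, 1L, prob = base_topic[i, ])
    }
    nev <- sample.int(3L, nv, replace = TRUE, prob = epp)
    total <- sum(nev)
    codes <- character(total)
    dts <- rep(vdates, nev)
    tps <- rep(topics, nev)
    for (e in seq_len(total)) {
      if (e > 1 && stats::runif(1) < rec_rate[i]) {
        codes[e] <- codes[sample.int(e - 1L, 1L)]
      } else {
        cat_i <- findInterval(stats::runif(1), topic_cum[tps[e], ]) + 1L
        cat_i <- min(cat_i, v)
        pool <- codes_by_cat[[cat_i]]
        codes[e] <- pool[sample.int(length(pool), 1L)]
      }
    }
    # guarantee >= 2 distinct disease categories
    cat_of <- map$disease[match(codes, map$medcode)]
    if (length(unique(cat_of)) < 2L) {
      other <- sample(setdiff(seq_len(v), match(cat_of[1], cats)), 1L)
      pool <- codes_by_cat[[other]]
      codes[length(codes)] <- pool[sample.int(length(pool), 1L)]
    }
    ev_pid[[i]] <- rep(ids[i], total)
    ev_date[[i]] <- dts
    ev_code[[i]] <- codes
  }
  events <- data.table::data.table(
    patient_id = unlist(ev_pid),
    event_date = as.Date(unlist(lapply(ev_date, as.integer)),
                         origin = "1970-01-01"),
    medcode = unlist(ev_code))
  events[, disease := map$disease[match(medcode, map$medcode)]]
  data.table::setorder(events, patient_id, event_date, medcode)

  ## --- outcome model ------------------------------------------------------
  params <- draw_outcome_params(cfg)
  feats <- outcome_features(records, events, params, idx)

  eligible <- records$registration_date <= idx - 365L &
    (is.na(records$death_date) | records$death_date >= idx) &
    (is.na(records$deregistration_date) | records$deregistration_date >= idx)
  no_followup <- !(is.na(records$death_date) | records$death_date >= idx) |
    (!is.na(records$deregistration_date) & records$deregistration_date < idx)
  dereg_in_window <- !is.na(records$deregistration_date) &
    records$deregistration_date >= idx &
    records$deregistration_date < idx + cfg$followup_days

  outcomes <- data.table::data.table(patient_id = ids)
  age_at_index <- as.numeric(idx - records$birth_date) / 365.25

  # mortality first: other outcomes exclude deaths-in-window
  died <- rep(NA, n)
  for (nm in outcome_names()) {
    p <- params$outcomes[[nm]]
    eta0 <- drop(feats$presence %*% p$w_dis) +
      cfg$order_weight * (drop(feats$order %*% p$w_order) +
                          p$w_recency * feats$recency) +
      p$w_age * (age_at_index - cfg$age_mean) +
      p$w_female * (records$gender == "female") +
      p$w_imd * (ifelse(is.na(records$imd_decile), 5.5,
                        records$imd_decile) - 5.5)
    stratum <- eligible & !dereg_in_window
    if (nm == "mortality_60plus") {
      stratum <- stratum & age_at_index >= 60
    } else {
      stratum <- stratum & !(died %in% TRUE)
    }
    if (startsWith(nm, "new_")) {
      mk <- params$markers[[sub("new_", "", nm)]]
      stratum <- stratum & !feats$presence[, mk]
    }
    if (!any(stratum)) {
      stop(sprintf("target rate for outcome %s not attainable: empty eligible stratum", nm),
           call. = FALSE)
    }
    icpt <- calibrate_intercept(eta0[stratum], cfg$target_rates[[nm]], nm)
    params$outcomes[[nm]]$intercept <- icpt
    pr <- stats::plogis(icpt + eta0)
    lab <- as.integer(stats::runif(n) < pr)
    if (nm == "mortality_60plus") {
      # death process applies at all ages; evaluation restricts to 60+
      lab_all <- lab
      lab_all[no_followup] <- NA_integer_
      died <- lab_all %in% 1L
      death_day <- idx + sample.int(cfg$followup_days, n, replace = TRUE) - 1L
      records[died, death_date := death_day[died]]
      # deregistration cannot postdate an in-window death
      fix <- died & !is.na(records$deregistration_date) &
        records$deregistration_date > records$death_date
      records[fix, deregistration_date := as.Date(NA)]
      outcomes[[nm]] <- lab_all
    } else {
      lab[no_followup] <- NA_integer_
      if (startsWith(nm, "new_")) {
        mk <- params$markers[[sub("new_", "", nm)]]
        lab[feats$presence[, mk]] <- NA_integer_
      }
      outcomes[[nm]] <- lab
    }
  }

  structure(list(records = records, events = events, map = map,
                 outcomes = outcomes, params = params, config = cfg),
            class = "ehr_cohort")
}

# Per-outcome generating coefficients, drawn from a dedicated sub-stream so
# they depend only on the config seed (not on how many patients were drawn).
draw_outcome_params <- function(cfg) {
  cats <- category_labels(cfg$category_vocab_size)
  markers <- marker_categories(cfg)
  pairs <- order_pair_categories(cfg)
  with_seed(derive_seed(cfg$seed, "outcome-coefficients"), {
    outs <- list()
    for (nm in outcome_names()) {
      w_dis <- stats::setNames(numeric(length(cats)), cats)
      active <- sample(cats, 8L)
      w_dis[active] <- stats::rnorm(8L, 0, cfg$disease_weight_sd)
      if (startsWith(nm, "any_")) {
        w_dis[markers[[sub("any_", "", nm)]]] <- cfg$marker_weight
      }
      if (startsWith(nm, "new_")) {
        w_dis[markers[[sub("new_", "", nm)]]] <- 0  # prevalent cases excluded
      }
      outs[[nm]] <- list(
        w_dis = w_dis,
        w_order = rep(cfg$precedence_weight, cfg$n_order_pairs),
        w_recency = cfg$recency_weight,
        w_age = if (nm == "mortality_60plus") 0.08 else stats::rnorm(1, 0.015, 0.005),
        w_female = stats::rnorm(1, 0, 0.15),
        w_imd = stats::rnorm(1, 0.03, 0.01),
        intercept = NA_real_)
    }
    list(outcomes = outs, markers = as.list(markers), pairs = pairs,
         recency_halflife_days = cfg$recency_halflife_days,
         categories = cats)
  })
}

#' True generating features of the outcome model
#'
#' Recomputes, from the records and event tables, the exact feature blocks the
#' simulator's outcome model uses: disease-presence indicators, per-pair
#' signed precedence terms (+1 if the first occurrence of disease A strictly
#' predates the first occurrence of disease B, -1 for the reverse, 0 unless
#' both are present), and the recency-weighted exposure sum over the
#' precedence-pair diseases.
#'
#' @param records patient records table.
#' @param events coded events table (with `disease` column).
#' @param params the `params` element of a simulated cohort.
#' @param index_date index date.
#' @return list with `presence` (logical matrix patients x categories),
#'   `order` (matrix patients x pairs), `recency` (numeric vector); rows
#'   follow `records$patient_id`.
#' @export
outcome_features <- function(records, events, params, index_date) {
  ids <- records$patient_id
  cats <- params$categories
  pres <- matrix(FALSE, length(ids), length(cats),
                 dimnames = list(ids, cats))
  u <- unique(events[, c("patient_id", "disease")])
  pres[cbind(match(u$patient_id, ids), match(u$disease, cats))] <- TRUE

  firsts <- events[, list(first_date = min(event_date)),
                   by = c("patient_id", "disease")]
  ord <- matrix(0, length(ids), length(params$pairs))
  for (j in seq_along(params$pairs)) {
    pr <- params$pairs[[j]]
    fa <- firsts[firsts$disease == pr[1], ]
    fb <- firsts[firsts$disease == pr[2], ]
    da <- fa$first_date[match(ids, fa$patient_id)]
    db <- fb$first_date[match(ids, fb$patient_id)]
    both <- !is.na(da) & !is.na(db)
    # signed, centered precedence: +1 if A strictly precedes B, -1 if B
    # precedes A, 0 otherwise -- invisible to presence-only representations
    ord[, j] <- as.numeric(both & da < db) - as.numeric(both & db < da)
  }

  pair_cats <- unique(unlist(params$pairs))
  pe <- events[events$disease %in% pair_cats, ]
  tau <- params$recency_halflife_days
  if (nrow(pe)) {
    pe_w <- exp(-as.numeric(index_date - pe$event_date) / tau)
    rec_dt <- data.table::data.table(patient_id = pe$patient_id, w = pe_w)
    rec_agg <- rec_dt[, list(r = sum(w)), by = "patient_id"]
    recency <- rec_agg$r[match(ids, rec_agg$patient_id)]
    recency[is.na(recency)] <- 0
  } else {
    recency <- numeric(length(ids))
  }
  list(presence = pres, order = ord, recency = recency)
}

#' Outcome probabilities under the generating model
#'
#' Recomputes each patient's event probability for one outcome from the
#' cohort's stored coefficients — useful for checking that, with the order
#' weight at zero, permuting event order leaves the generating probabilities
#' unchanged.
#'
#' @param cohort an `ehr_cohort`.
#' @param outcome outcome name.
#' @param events optional replacement events table (e.g. with permuted dates).
#' @return numeric vector of probabilities aligned to `records$patient_id`.
#' @export
outcome_probabilities <- function(cohort, outcome, events = cohort$events) {
  p <- cohort$params$outcomes[[outcome]]
  if (is.null(p)) stop(sprintf("unknown outcome '%s'", outcome), call. = FALSE)
  cfg <- cohort$config
  feats <- outcome_features(cohort$records, events, cohort$params,
                            cfg$index_date)
  age <- as.numeric(cfg$index_date - cohort$records$birth_date) / 365.25
  eta <- p$intercept + drop(feats$presence %*% p$w_dis) +
    cfg$order_weight * (drop(feats$order %*% p$w_order) +
                        p$w_recency * feats$recency) +
    p$w_age * (age - cfg$age_mean) +
    p$w_female * (cohort$records$gender == "female") +
    p$w_imd * (ifelse(is.na(cohort$records$imd_decile), 5.5,
                      cohort$records$imd_decile) - 5.5)
  stats::plogis(eta)
}

calibrate_intercept <- function(eta0, target, name) {
  f <- function(c) mean(stats::plogis(eta0 + c)) - target
  sol <- tryCatch(stats::uniroot(f, c(-40, 40), tol = 1e-10),
                  error = function(e) NULL)
  if (is.null(sol)) {
    stop(sprintf("target rate for outcome %s not attainable by intercept calibration",
                 name), call. = FALSE)
  }
  sol$root
}

# ---------------------------------------------------------------------------
# Cohort I/O: delimiter-separated tables with ISO-8601 dates.

#' Write a simulated cohort to disk
#'
#' Four CSV files (`patients.csv`, `events.csv`, `code_map.csv`,
#' `outcomes.csv`) with ISO-8601 dates.
#' @param cohort an `ehr_cohort` (or a list with records/events/map and
#'   optionally outcomes).
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cohort$records, file.path(path, "patients.csv"))
  data.table::fwrite(cohort$events[, c("patient_id", "event_date", "medcode",
                                       "disease")],
                     file.path(path, "events.csv"))
  data.table::fwrite(cohort$map, file.path(path, "code_map.csv"))
  if (!is.null(cohort$outcomes)) {
    data.table::fwrite(cohort$outcomes, file.path(path, "outcomes.csv"))
  }
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates schemas column-by-column and checks that every event code is
#' present in the map.
#' @param path directory containing the CSV files.
#' @return list with `records`, `events`, `map` and (if present) `outcomes`.
#' @export
read_cohort <- function(path) {
  rec_file <- file.path(path, "patients.csv")
  ev_file <- file.path(path, "events.csv")
  map_file <- file.path(path, "code_map.csv")
  for (f in c(rec_file, ev_file, map_file)) {
    if (!file.exists(f)) stop(sprintf("missing cohort file: %s", f), call. = FALSE)
  }
  records <- data.table::fread(rec_file)
  assert_columns(records, c("patient_id", "birth_date", "gender", "ethnicity",
                            "imd_decile", "registration_date",
                            "deregistration_date", "death_date"),
                 "patients.csv")
  for (col in c("birth_date", "registration_date", "deregistration_date",
                "death_date")) {
    records[[col]] <- as.Date(records[[col]])
  }
  events <- data.table::fread(ev_file)
  if (nrow(events) == 0L) {
    events <- data.table::data.table(patient_id = character(),
                                     event_date = as.Date(character()),
                                     medcode = character(),
                                     disease = character())
  } else {
    assert_columns(events, c("patient_id", "event_date", "medcode"),
                   "events.csv")
    events$event_date <- as.Date(events$event_date)
  }
  map <- data.table::fread(map_file)
  assert_columns(map, c("medcode", "disease"), "code_map.csv")
  if (anyDuplicated(map$medcode)) {
    stop("code_map.csv: duplicated medcode entries (map must be many-to-one)",
         call. = FALSE)
  }
  if (nrow(events)) {
    unknown <- setdiff(unique(events$medcode), map$medcode)
    if (length(unknown)) {
      stop(sprintf("events.csv contains medcode(s) absent from the map: %s",
                   paste(utils::head(unknown, 5), collapse = ", ")),
           call. = FALSE)
    }
    events$disease <- map$disease[match(events$medcode, map$medcode)]
  }
  out <- list(records = records, events = events, map = map)
  of <- file.path(path, "outcomes.csv")
  if (file.exists(of)) out$outcomes <- data.table::fread(of)
  out
}
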