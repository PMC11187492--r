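# Outcome cohorts and the fixed logistic evaluation harness: stratified
# 4-fold cross-validation, L2 logistic classifier (inverse regularization
# strength 1), ROC-AUC, average precision and threshold metrics.

#' ROC area under the curve
#'
#' Rank (Wilcoxon) statistic; ties handled by midranks. Invariant under any
#' strictly monotone transform of the scores.
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more positive.
#' @return scalar in 0..1.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision score
#'
#' Area under the precision-recall curve as the step sum
#' sum_i (R_i - R_{i-1}) P_i over distinct-score thresholds in decreasing
#' order. A constant score yields exactly the prevalence.
#' @inheritParams roc_auc
#' @return scalar in 0..1.
#' @export
average_precision <- function(labels, scores) {
  labels <- as.integer(labels)
  P <- sum(labels == 1)
  if (P == 0) stop("average precision needs at least one positive", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  l <- labels[o]; s <- scores[o]
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tied block
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(prec * diff(c(0, rec)))
}

#' Confusion-matrix metrics
#'
#' @param tp,fn,fp,tn confusion-matrix counts.
#' @return named vector: sensitivity, specificity, ppv, npv.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

#' Threshold metrics at requested sensitivities
#'
#' For each target sensitivity, takes the highest score threshold whose
#' sensitivity reaches the target (scores >= threshold classified positive)
#' and reports the resulting confusion metrics.
#' @inheritParams roc_auc
#' @param sensitivities target sensitivities.
#' @return data.table: target_sensitivity, threshold, sensitivity,
#'   specificity, ppv, npv.
#' @export
threshold_metrics <- function(labels, scores,
                              sensitivities = c(0.4, 0.7, 0.9)) {
  labels <- as.integer(labels)
  o <- order(scores, decreasing = TRUE)
  l <- labels[o]; s <- scores[o]
  P <- sum(l == 1); N <- sum(l == 0)
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  # collapse tied scores: a threshold admits the whole tied block
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpk <- tp[keep]; fpk <- fp[keep]; sk <- s[keep]
  out <- lapply(sensitivities, function(tgt) {
    i <- which(tpk / P >= tgt)[1]
    if (is.na(i)) i <- length(tpk)
    m <- confusion_metrics(tpk[i], P - tpk[i], fpk[i], N - fpk[i])
    data.table::data.table(target_sensitivity = tgt, threshold = sk[i],
                           sensitivity = m["sensitivity"],
                           specificity = m["specificity"],
                           ppv = m["ppv"], npv = m["npv"])
  })
  data.table::rbindlist(out)
}

#' Build a labelled outcome cohort
#'
#' Applies the follow-up eligibility rules: patients deregistering during the
#' follow-up window are removed for every outcome; patients dying during
#' follow-up are removed for every non-mortality outcome; the mortality
#' outcome is restricted to patients aged 60+ at index; incident ("new")
#' disease outcomes drop patients with the disease already present in
#' history. Patients with an undefined label (no follow-up) are dropped.
#'
#' @param records patient records.
#' @param sequences disease-vocabulary `patient_sequences` (history; used for
#'   prevalent-case exclusion).
#' @param outcomes outcome label table (patient_id + one 0/1/NA column per
#'   outcome).
#' @param outcome outcome name.
#' @param index_date index date.
#' @param markers named list mapping disease name (hypertension, diabetes,
#'   depression) to its category token; required for "new_" outcomes.
#' @param eligible_ids optional restriction to an eligible id set (e.g. from
#'   [eligible_cohort()]).
#' @param followup_days follow-up window length.
#' @return data.table (patient_id, label).
#' @export
build_outcome_cohort <- function(records, sequences, outcomes, outcome,
                                 index_date, markers = NULL,
                                 eligible_ids = NULL, followup_days = 365L) {
  if (!outcome %in% outcome_names()) {
    stop(sprintf("unknown outcome '%s' (expected one of: %s)", outcome,
                 paste(outcome_names(), collapse = ", ")), call. = FALSE)
  }
  if (!outcome %in% names(outcomes)) {
    stop(sprintf("outcome table has no column '%s'", outcome), call. = FALSE)
  }
  index_date <- as.Date(index_date)
  win_end <- index_date + followup_days
  rec <- data.table::as.data.table(records)
  keep <- rep(TRUE, nrow(rec))
  if (!is.null(eligible_ids)) keep <- keep & rec$patient_id %in% eligible_ids

  dereg_in <- !is.na(rec$deregistration_date) &
    rec$deregistration_date >= index_date & rec$deregistration_date < win_end
  keep <- keep & !dereg_in

  death_in <- !is.na(rec$death_date) & rec$death_date >= index_date &
    rec$death_date < win_end
  age <- as.numeric(index_date - rec$birth_date) / 365.25
  if (outcome == "mortality_60plus") {
    keep <- keep & age >= 60
  } else {
    keep <- keep & !death_in
  }

  if (startsWith(outcome, "new_")) {
    disease <- sub("new_", "", outcome)
    if (is.null(markers) || is.null(markers[[disease]])) {
      stop(sprintf("markers must map '%s' to its disease category", disease),
           call. = FALSE)
    }
    prev <- unique(sequences$data$patient_id[
      sequences$data$token == markers[[disease]]])
    keep <- keep & !(rec$patient_id %in% prev)
  }

  lab <- outcomes[[outcome]][match(rec$patient_id, outcomes$patient_id)]
  keep <- keep & !is.na(lab)
  data.table::data.table(patient_id = rec$patient_id[keep],
                         label = as.integer(lab[keep]))
}

#' Evaluation configuration
#' @param n_folds cross-validation folds.
#' @param C inverse regularization strength of the L2 logistic classifier.
#' @param max_iter optimizer iteration cap.
#' @param embeddings_only drop the sociodemographic covariates (sensitivity
#'   analysis).
#' @param sensitivities targets for the threshold table.
#' @param seed fold-assignment seed.
#' @export
eval_config <- function(n_folds = 4L, C = 1, max_iter = 100L,
                        embeddings_only = FALSE,
                        sensitivities = c(0.4, 0.7, 0.9), seed = 1L) {
  list(n_folds = as.integer(n_folds), C = C, max_iter = as.integer(max_iter),
       embeddings_only = embeddings_only, sensitivities = sensitivities,
       seed = as.integer(seed))
}

# Stratified fold assignment: within each class, a seeded shuffle then
# round-robin, so per-fold event counts differ by at most 1.
stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Evaluate one representation on one outcome
#'
#' Stratified k-fold cross-validation of an L2-penalized logistic classifier
#' (inverse regularization strength `C`); embedding features are standardized
#' using training-fold statistics only; sociodemographic covariates are
#' appended unless `config$embeddings_only`. Reports per-fold and pooled
#' out-of-fold ROC-AUC and average precision, plus threshold metrics on the
#' pooled out-of-fold scores.
#'
#' @param embeddings an `embedding_set` (or a plain matrix with patient-id
#'   rownames).
#' @param covariates covariate matrix with patient-id rownames (may be NULL
#'   when `config$embeddings_only`).
#' @param cohort labelled cohort from [build_outcome_cohort()].
#' @param config an [eval_config()].
#' @param outcome outcome name (for error messages and the result).
#' @param representation representation name for the result.
#' @return object of class `eval_result`.
#' @export
evaluate_representation <- function(embeddings, covariates, cohort, config,
                                    outcome = "outcome",
                                    representation = NULL) {
  emb <- if (inherits(embeddings, "embedding_set")) embeddings$matrix
         else embeddings
  representation <- representation %||%
    (if (inherits(embeddings, "embedding_set")) embeddings$method else "custom")
  ids <- cohort$patient_id
  missing_ids <- setdiff(ids, rownames(emb))
  if (length(missing_ids)) {
    stop(sprintf("%d cohort patient(s) missing from the embeddings",
                 length(missing_ids)), call. = FALSE)
  }
  x_emb <- emb[ids, , drop = FALSE]
  x_cov <- NULL
  if (!config$embeddings_only && !is.null(covariates)) {
    x_cov <- covariates[ids, , drop = FALSE]
  }
  y <- cohort$label
  fold <- stratified_folds(y, config$n_folds, config$seed)
  scores <- rep(NA_real_, length(y))
  fold_metrics <- list()
  lambda <- NULL

  for (f in seq_len(config$n_folds)) {
    tr <- fold != f; te <- fold == f
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
      stop(sprintf("outcome %s: fold %d contains a single class", outcome, f),
           call. = FALSE)
    }
    mu <- colMeans(x_emb[tr, , drop = FALSE])
    sdv <- apply(x_emb[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    xt <- sweep(sweep(x_emb, 2, mu), 2, sdv, "/")
    X <- if (is.null(x_cov)) xt else cbind(xt, x_cov)
    if (ncol(X) < 2) X <- cbind(X, .dummy = 0)
    lambda <- 1 / (config$C * sum(tr))
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 0, lambda = lambda, standardize = FALSE,
                          maxit = config$max_iter * 1000L)
    p <- drop(stats::predict(fit, X[te, , drop = FALSE], type = "response"))
    scores[te] <- p
    fold_metrics[[f]] <- data.table::data.table(
      fold = f, roc_auc = roc_auc(y[te], p),
      aps = average_precision(y[te], p))
  }

  fold_dt <- data.table::rbindlist(fold_metrics)
  structure(list(
    outcome = outcome, representation = representation,
    pooled = c(roc_auc = roc_auc(y, scores),
               aps = average_precision(y, scores)),
    folds = fold_dt,
    thresholds = threshold_metrics(y, scores, config$sensitivities),
    n = length(y), events = sum(y), event_rate = mean(y),
    scores = data.table::data.table(patient_id = ids, fold = fold,
                                    score = scores, label = y)),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s / %s: pooled AUC %.3f, APS %.3f (n=%d, events=%d, rate=%.3f)\n",
              x$outcome, x$representation, x$pooled["roc_auc"],
              x$pooled["aps"], x$n, x$events, x$event_rate))
  invisible(x)
}

#' Compare representations across outcomes
#'
#' Evaluates every representation on every outcome cohort and assembles a
#' tidy long-format results table plus a per-outcome ranking by pooled
#' ROC-AUC. A representation missing patients for a cohort is recorded as
#' absent, not an error.
#'
#' @param representations named list of `embedding_set`s (or matrices).
#' @param cohorts named list of labelled cohorts (one per outcome).
#' @param covariates covariate matrix.
#' @param config an [eval_config()].
#' @return list: `table` (long format: outcome, representation, metric, fold,
#'   value; fold NA = pooled), `ranking`, `results` (nested eval_results),
#'   `absent`.
#' @export
run_comparison <- function(representations, cohorts, covariates, config) {
  rows <- list()
  results <- list()
  absent <- character()
  for (oc in names(cohorts)) {
    for (rp in names(representations)) {
      res <- tryCatch(
        evaluate_representation(representations[[rp]], covariates,
                                cohorts[[oc]], config, outcome = oc,
                                representation = rp),
        error = function(e) e)
      if (inherits(res, "error")) {
        absent <- c(absent, sprintf("%s/%s: %s", oc, rp, conditionMessage(res)))
        next
      }
      results[[oc]][[rp]] <- res
      rows[[length(rows) + 1L]] <- data.table::data.table(
        outcome = oc, representation = rp,
        metric = c("roc_auc", "aps"), fold = NA_integer_,
        value = unname(res$pooled))
      rows[[length(rows) + 1L]] <- data.table::rbindlist(list(
        data.table::data.table(outcome = oc, representation = rp,
                               metric = "roc_auc", fold = res$folds$fold,
                               value = res$folds$roc_auc),
        data.table::data.table(outcome = oc, representation = rp,
                               metric = "aps", fold = res$folds$fold,
                               value = res$folds$aps)))
    }
  }
  tab <- data.table::rbindlist(rows)
  pooled <- tab[is.na(tab$fold) & tab$metric == "roc_auc", ]
  ranking <- pooled[order(pooled$outcome, -pooled$value), ]
  ranking[, rank := seq_len(.N), by = "outcome"]
  list(table = tab, ranking = ranking, results = results, absent = absent)
}

#' Markdown comparison report
#' @param comparison output of [run_comparison()].
#' @return character vector of markdown lines.
#' @export
comparison_report <- function(comparison) {
  lines <- c("# Representation comparison", "")
  for (oc in unique(comparison$ranking$outcome)) {
    lines <- c(lines, sprintf("## %s", oc), "",
               "| rank | representation | pooled ROC-AUC | pooled APS |",
               "|-----:|----------------|---------------:|-----------:|")
    rk <- comparison$ranking[comparison$ranking$outcome == oc, ]
    for (i in seq_len(nrow(rk))) {
      rp <- rk$representation[i]
      res <- comparison$results[[oc]][[rp]]
      lines <- c(lines, sprintf("| %d | %s | %.3f | %.3f |", rk$rank[i], rp,
                                res$pooled["roc_auc"], res$pooled["aps"]))
    }
    lines <- c(lines, "")
  }
  lines
}
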