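# Latent Dirichlet allocation patient representations, with held-out
# perplexity selection of the topic number. The sampler is a collapsed Gibbs
# implementation (compiled); documents are full patient token sequences with
# order discarded — LDA is the bag-of-words comparator by construction.

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' @param corpus list of character token vectors (one document per patient;
#'   either vocabulary).
#' @param n_topics number of topics K (>= 1).
#' @param alpha symmetric document-topic Dirichlet prior (default 1/K).
#' @param beta symmetric topic-word Dirichlet prior.
#' @param n_iter Gibbs sweeps.
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @return object of class `lda_model`: `n_topics`, `phi` (K x V topic-word
#'   probabilities, rows sum to 1), `theta` (D x K document-topic proportions,
#'   rows sum to 1), `vocab`, priors and seed.
#' @export
fit_lda <- function(corpus, n_topics, alpha = 1 / n_topics, beta = 0.01,
                    n_iter = 200L, seed = 1L) {
  stopifnot(is.list(corpus), length(corpus) >= 1, n_topics >= 1)
  vocab <- sort(unique(unlist(corpus)))
  if (length(vocab) < n_topics) {
    warning(sprintf("vocabulary size (%d) is smaller than n_topics (%d)",
                    length(vocab), n_topics))
  }
  docs <- lapply(corpus, function(d) match(d, vocab) - 1L)
  fit <- with_seed(seed,
                   lda_gibbs_cpp(docs, as.integer(n_topics),
                                 length(vocab), alpha, beta,
                                 as.integer(n_iter)))
  phi <- (fit$nkw + beta) / (fit$nk + length(vocab) * beta)
  nd <- rowSums(fit$ndk)
  theta <- (fit$ndk + alpha) / (nd + n_topics * alpha)
  colnames(phi) <- vocab
  if (!is.null(names(corpus))) rownames(theta) <- names(corpus)
  structure(list(n_topics = as.integer(n_topics), phi = phi, theta = theta,
                 vocab = vocab, alpha = alpha, beta = beta,
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> K=%d, V=%d, D=%d (alpha=%.4g, beta=%.4g)\n",
              x$n_topics, length(x$vocab), nrow(x$theta), x$alpha, x$beta))
  invisible(x)
}

#' Document-topic proportions for new documents (fold-in)
#'
#' Topic-word distributions stay fixed; per-document topic assignments are
#' resampled by Gibbs fold-in.
#' @param model a fitted `lda_model`.
#' @param corpus list of character token vectors.
#' @param n_iter fold-in sweeps per document.
#' @param seed RNG seed.
#' @return matrix D x K of topic proportions (rows sum to 1).
#' @export
lda_infer <- function(model, corpus, n_iter = 50L, seed = 1L) {
  stopifnot(inherits(model, "lda_model"))
  docs <- lapply(corpus, function(d) {
    idx <- match(d, model$vocab)
    idx[!is.na(idx)] - 1L
  })
  if (any(vapply(docs, length, 1L) == 0L)) {
    stop("document with no in-vocabulary tokens", call. = FALSE)
  }
  theta <- with_seed(seed,
                     lda_foldin_cpp(docs, model$phi, model$alpha,
                                    as.integer(n_iter)))
  if (!is.null(names(corpus))) rownames(theta) <- names(corpus)
  theta
}

# Per-token mixture likelihood given fixed proportions; shared by perplexity.
lda_token_loglik <- function(phi, theta, docs_idx) {
  ll <- 0
  n <- 0
  for (d in seq_along(docs_idx)) {
    idx <- docs_idx[[d]]
    p <- drop(theta[d, , drop = FALSE] %*% phi[, idx, drop = FALSE])
    ll <- ll + sum(log(p))
    n <- n + length(idx)
  }
  list(loglik = ll, n_tokens = n)
}

#' Held-out perplexity
#'
#' exp(- held-out log-likelihood / token count) under the fitted topic-word
#' distributions. Two estimators of the held-out document proportions:
#'
#' * `"completion"` (default): document completion - proportions are
#'   inferred by Gibbs fold-in on the odd-position tokens of each held-out
#'   document and the likelihood is evaluated on the even-position tokens.
#'   Because the evaluated tokens are unseen by the per-document fit, extra
#'   topics cannot buy likelihood through per-document adaptivity, which
#'   makes the perplexity curve minimise near the generating topic count.
#' * `"fold_in"`: proportions inferred from the full document and all tokens
#'   scored; simpler, but monotone-biased toward larger K.
#'
#' A model assigning uniform probability over V tokens has perplexity exactly
#' V under either estimator.
#'
#' @inheritParams lda_infer
#' @param method held-out estimator, see above.
#' @return positive scalar (>= 1 for any proper model).
#' @export
lda_perplexity <- function(model, corpus, method = c("completion", "fold_in"),
                           n_iter = 50L, seed = 1L) {
  method <- match.arg(method)
  if (!length(corpus)) stop("perplexity of an empty corpus is undefined",
                            call. = FALSE)
  docs_idx <- lapply(corpus, function(d) {
    idx <- match(d, model$vocab)
    idx[!is.na(idx)]
  })
  dropped <- sum(vapply(corpus, length, 1L)) -
    sum(vapply(docs_idx, length, 1L))
  if (dropped > 0) {
    warning(sprintf("%d out-of-vocabulary token(s) ignored in perplexity",
                    dropped))
  }
  if (method == "fold_in") {
    theta <- lda_infer(model, corpus, n_iter = n_iter, seed = seed)
    r <- lda_token_loglik(model$phi, theta, docs_idx)
  } else {
    est <- lapply(docs_idx, function(i) i[seq_along(i) %% 2 == 1L] - 1L)
    ev <- lapply(docs_idx, function(i) i[seq_along(i) %% 2 == 0L])
    keep <- lengths(est) > 0L & lengths(ev) > 0L
    if (!any(keep)) {
      stop("no document has tokens in both completion halves", call. = FALSE)
    }
    theta <- with_seed(seed,
                       lda_foldin_cpp(est[keep], model$phi, model$alpha,
                                      as.integer(n_iter)))
    r <- lda_token_loglik(model$phi, theta, ev[keep])
  }
  exp(-r$loglik / r$n_tokens)
}

#' Select the number of topics by held-out perplexity
#'
#' Splits the corpus 80:20 (seeded), fits each candidate K on the training
#' part, scores perplexity on the held-out part, picks the argmin (ties go to
#' the smaller K), then refits on the full corpus with the chosen K.
#'
#' @param corpus list of character token vectors.
#' @param candidate_ks integer vector of candidate topic counts.
#' @param train_frac training fraction of the split.
#' @param seed RNG seed (split and fits derive sub-seeds from it).
#' @param ... passed to [fit_lda()] (priors, `n_iter`).
#' @return list: `chosen_k`, `perplexities` (named by K), `model` (refit on
#'   the full corpus), `split` (train indices).
#' @export
select_n_topics <- function(corpus, candidate_ks, train_frac = 0.8,
                            seed = 1L, ...) {
  stopifnot(length(candidate_ks) >= 1)
  candidate_ks <- sort(unique(as.integer(candidate_ks)))
  n <- length(corpus)
  train_idx <- with_seed(derive_seed(seed, "lda-split"),
                         sample.int(n, max(1L, floor(train_frac * n))))
  test_idx <- setdiff(seq_len(n), train_idx)
  pp <- stats::setNames(rep(NA_real_, length(candidate_ks)),
                        candidate_ks)
  if (length(candidate_ks) == 1L) {
    chosen <- candidate_ks
  } else {
    for (k in candidate_ks) {
      m <- fit_lda(corpus[train_idx], k,
                   seed = derive_seed(seed, paste0("lda-k", k)), ...)
      pp[as.character(k)] <- lda_perplexity(
        m, corpus[test_idx], seed = derive_seed(seed, paste0("lda-pp", k)))
    }
    chosen <- candidate_ks[which.min(pp)]  # which.min takes first == smaller K
  }
  final <- fit_lda(corpus, chosen, seed = derive_seed(seed, "lda-final"), ...)
  list(chosen_k = chosen, perplexities = pp, model = final,
       split = train_idx)
}

#' LDA patient embeddings
#'
#' Document-topic proportions as a patient representation.
#' @param model fitted `lda_model` whose `theta` rows are named by patient id.
#' @param vocabulary_tag provenance tag.
#' @return an `embedding_set` of dimension K.
#' @export
lda_embeddings <- function(model, vocabulary_tag = "diseases") {
  stopifnot(inherits(model, "lda_model"), !is.null(rownames(model$theta)))
  embedding_set(model$theta, method = "lda", vocabulary_tag = vocabulary_tag)
}
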