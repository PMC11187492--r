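# Paragraph-vector (doc2vec) patient embeddings: DBOW and DM training with
# negative sampling, and the identical-sequence criterion used to select
# between configurations.

#' Fit doc2vec patient embeddings
#'
#' DBOW predicts each token of a patient's sequence from the document vector
#' alone (order-free); DM predicts a token from the document vector averaged
#' with the surrounding context window. Negative sampling with a
#' unigram^0.75 noise distribution; single-threaded, deterministic per seed.
#'
#' @param corpus named list of character token vectors (>= 2 tokens each).
#' @param algorithm `"dbow"` or `"dm"`.
#' @param dim embedding dimension.
#' @param window context half-width (DM only; DBOW ignores it).
#' @param learning_rate initial learning rate, decayed linearly.
#' @param epochs training epochs (> 0).
#' @param negative_samples negative samples per target token.
#' @param min_lr floor of the learning-rate decay.
#' @param seed RNG seed.
#' @return an `embedding_set` with one `dim`-length vector per document.
#' @export
fit_doc2vec <- function(corpus, algorithm = c("dbow", "dm"), dim = 100L,
                        window = 5L, learning_rate = 0.025, epochs = 20L,
                        negative_samples = 5L, min_lr = 1e-4, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (dim <= 0) stop("embedding dimension must be positive", call. = FALSE)
  if (epochs <= 0) stop("epochs must be positive", call. = FALSE)
  if (learning_rate < 0) stop("learning rate must be non-negative", call. = FALSE)
  lens <- vapply(corpus, length, 1L)
  if (any(lens < 2L)) {
    stop("every document must have at least 2 tokens", call. = FALSE)
  }
  vocab <- sort(unique(unlist(corpus)))
  docs <- lapply(corpus, function(d) match(d, vocab) - 1L)
  counts <- tabulate(unlist(docs) + 1L, nbins = length(vocab))
  noise <- counts^0.75
  unigram_cum <- cumsum(noise / sum(noise))
  m <- with_seed(seed,
                 doc2vec_cpp(docs, length(vocab), as.integer(dim),
                             ifelse(algorithm == "dbow", 0L, 1L),
                             as.integer(window), learning_rate, min_lr,
                             as.integer(epochs), as.integer(negative_samples),
                             unigram_cum))
  rownames(m) <- names(corpus) %||% sprintf("doc%05d", seq_along(corpus))
  embedding_set(m, method = paste0("doc2vec_", algorithm))
}

sequence_keys <- function(sequences) {
  if (inherits(sequences, "patient_sequences")) sequences <- sequence_list(sequences)
  vapply(sequences, function(x) paste(x, collapse = "\x1f"), "")
}

#' Identical-sequence similarity score
#'
#' Patients with byte-identical token sequences should receive similar
#' embeddings. The score is (mean cosine similarity over all identical-sequence
#' pairs) minus (mean cosine over an equal-size random sample of non-identical
#' pairs); higher is better, range -1..1 (up to sampling noise in the second
#' term).
#'
#' @param embeddings an `embedding_set` (rows indexed by the same ids as
#'   `sequences`).
#' @param sequences a `patient_sequences` object or a named list of token
#'   vectors.
#' @param max_pairs cap on identical pairs scored (deterministic subsample).
#' @param seed RNG seed for the random non-identical pair sample.
#' @return scalar score.
#' @export
identical_sequence_score <- function(embeddings, sequences, max_pairs = 2000L,
                                     seed = 1L) {
  stopifnot(inherits(embeddings, "embedding_set"))
  keys <- sequence_keys(sequences)
  ids <- names(keys)
  m <- embeddings$matrix[ids, , drop = FALSE]
  mn <- l2_normalise(m)
  groups <- split(seq_along(keys), keys)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  if (!length(groups)) {
    stop(paste("no groups of patients with identical sequences found;",
               "simulate duplicate sequences to use this selection criterion"),
         call. = FALSE)
  }
  if (length(unique(keys)) < 2L) {
    stop("all sequences are identical: no non-identical pairs to compare against",
         call. = FALSE)
  }
  pairs <- do.call(rbind, lapply(groups, function(g) {
    t(utils::combn(g, 2L))
  }))
  with_seed(derive_seed(seed, "iss-pairs"), {
    if (nrow(pairs) > max_pairs) {
      pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
    }
    same_cos <- rowSums(mn[pairs[, 1], , drop = FALSE] *
                        mn[pairs[, 2], , drop = FALSE])
    # equal-size random sample of non-identical pairs
    n <- nrow(mn)
    want <- nrow(pairs)
    a <- integer(0); b <- integer(0)
    while (length(a) < want) {
      i <- sample.int(n, want, replace = TRUE)
      j <- sample.int(n, want, replace = TRUE)
      ok <- keys[i] != keys[j]
      a <- c(a, i[ok]); b <- c(b, j[ok])
    }
    a <- a[seq_len(want)]; b <- b[seq_len(want)]
    diff_cos <- rowSums(mn[a, , drop = FALSE] * mn[b, , drop = FALSE])
    mean(same_cos) - mean(diff_cos)
  })
}

#' Select a doc2vec configuration by the identical-sequence criterion
#'
#' Fits every row of the candidate grid and picks the configuration with the
#' highest [identical_sequence_score()]; ties go to fewer epochs.
#'
#' @param corpus named list of token vectors.
#' @param grid data.frame with columns `algorithm`, `learning_rate`, `epochs`
#'   (other [fit_doc2vec()] arguments may be added as columns).
#' @param dim embedding dimension used for every candidate.
#' @param seed base RNG seed; each candidate derives its own sub-seed.
#' @param ... passed through to [fit_doc2vec()].
#' @return list: `best` (row of the grid), `scores`, `embeddings` (of the
#'   winning configuration), `grid`.
#' @export
select_doc2vec <- function(corpus, grid, dim = 100L, seed = 1L, ...) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1,
            all(c("algorithm", "learning_rate", "epochs") %in% names(grid)))
  scores <- numeric(nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- fit_doc2vec(corpus,
                             algorithm = as.character(grid$algorithm[i]),
                             dim = dim,
                             learning_rate = grid$learning_rate[i],
                             epochs = as.integer(grid$epochs[i]),
                             seed = derive_seed(seed, paste0("d2v", i)), ...)
    scores[i] <- identical_sequence_score(fits[[i]], corpus,
                                          seed = derive_seed(seed, "score"))
  }
  # argmax; ties broken by fewer epochs
  best_score <- max(scores)
  cand <- which(scores >= best_score - 1e-12)
  best <- cand[which.min(grid$epochs[cand])]
  list(best = grid[best, , drop = FALSE], scores = scores,
       embeddings = fits[[best]], grid = grid)
}
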