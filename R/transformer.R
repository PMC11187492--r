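# A configurable BERT-style encoder family for coded clinical sequences.
# Three input/embedding variants mirror published EHR transformers:
#   medbert : code + visit number (+ absolute position); no special tokens.
#   behrt   : code + visit number + age + segment; [CLS] at the start and
#             [SEP] between consecutive visits.
#   ehrbert : code + visit number + age + gender/ethnicity/IMD/calendar-year;
#             [CLS] at the start and a single [SEP] at the end (no segment,
#             no inter-visit separators).
# Pretraining is masked language modelling alone; patient embeddings are the
# mean of the second-to-last layer's hidden states over code positions.

#' Transformer configuration
#'
#' `scale = "paper"` reproduces the published presets (6 hidden layers;
#' medbert: 6 heads, hidden 192, intermediate 64, lr 5e-5, batch 32;
#' behrt/ehrbert: 12 heads, hidden 288, intermediate 512, lr 3e-5, batch 256).
#' `scale = "desk"` is the small configuration used throughout tests and
#' examples (2 layers, 4 heads, hidden 64, intermediate 128, lr 1e-3,
#' batch 32). Any field can be overridden through `...`.
#'
#' @param variant `"ehrbert"`, `"behrt"` or `"medbert"`.
#' @param scale `"desk"` or `"paper"`.
#' @param ... named overrides of any config field (e.g. `epochs`, `inputs`,
#'   `max_len`, `mask_prob`, `seed`).
#' @return list of class `ehr_transformer_config`.
#' @export
transformer_config <- function(variant = c("ehrbert", "behrt", "medbert"),
                               scale = c("desk", "paper"), ...) {
  variant <- match.arg(variant)
  scale <- match.arg(scale)
  inputs <- switch(variant,
    medbert = c("code", "visit_number", "absolute_position"),
    behrt = c("code", "visit_number", "age", "segment", "absolute_position"),
    ehrbert = c("code", "visit_number", "age", "gender", "ethnicity", "imd",
                "calendar_year", "absolute_position"))
  cfg <- list(
    variant = variant, scale = scale, inputs = inputs,
    hidden_layers = 6L,
    attention_heads = if (variant == "medbert") 6L else 12L,
    hidden_size = if (variant == "medbert") 192L else 288L,
    intermediate_size = if (variant == "medbert") 64L else 512L,
    learning_rate = if (variant == "medbert") 5e-5 else 3e-5,
    batch_size = if (variant == "medbert") 32L else 256L,
    max_len = 128L, mask_prob = 0.15, epochs = 100L,
    tie_mlm_head = TRUE,
    epoch_presets = c(10L, 50L, 100L),
    max_visit = 512L, age_max = 110L, year_range = c(1980L, 2020L),
    warmup_frac = 0.1, seed = 1L)
  if (scale == "desk") {
    cfg$hidden_layers <- 2L
    cfg$attention_heads <- 4L
    cfg$hidden_size <- 64L
    cfg$intermediate_size <- 128L
    cfg$learning_rate <- 1e-3
    cfg$batch_size <- 32L
    cfg$epochs <- 8L
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  if (cfg$hidden_size %% cfg$attention_heads != 0) {
    stop("hidden_size must be divisible by attention_heads", call. = FALSE)
  }
  class(cfg) <- "ehr_transformer_config"
  cfg
}

# Channel id spaces. Row 1 of every non-code table is reserved for special
# tokens / out-of-range; sociodemographic channels broadcast one id per
# sequence and carry a dedicated missing-level id.
channel_sizes <- function(config, vocab_size) {
  sizes <- c(code = vocab_size,
             absolute_position = config$max_len + 3L,
             visit_number = config$max_visit + 1L,
             age = config$age_max + 2L,
             calendar_year = diff(config$year_range) + 3L,
             gender = 4L, ethnicity = 7L, imd = 12L, segment = 3L)
  sizes[config$inputs]
}

GENDER_LEVELS <- c("female", "male", "indeterminate")
ETHNICITY_LEVELS <- c("White", "South Asian", "Black", "Other", "Mixed",
                      "missing")

#' Compose model inputs for one patient
#'
#' Pure function turning a tokenized sequence plus the patient's record into
#' the per-position channel id matrix the encoder consumes. Applies the
#' variant's special-token policy and caps (visit number, age, calendar-year
#' range); missing sociodemographics are routed to a dedicated missing-level
#' id, never an error.
#'
#' @param seq_data rows of `patient_sequences$data` for one patient, in
#'   position order.
#' @param record one-row patient record (or `NULL` when no sociodemographic
#'   channels are enabled).
#' @param config an `ehr_transformer_config`.
#' @param vocab token vocabulary (with special tokens).
#' @return list: `channels` (integer matrix, channels x positions, 1-based
#'   rows into the embedding tables), `is_code` (logical), `tokens`
#'   (character, including special tokens).
#' @export
compose_inputs <- function(seq_data, record, config, vocab) {
  tokens <- seq_data$token
  visits <- seq_data$visit_index
  ages <- seq_data$age_years
  years <- seq_data$calendar_year
  n <- length(tokens)
  if (n > config$max_len) {
    stop("sequence exceeds max_len; truncate upstream", call. = FALSE)
  }

  # special-token layout
  if (config$variant == "medbert") {
    lay_tok <- tokens; lay_visit <- visits; lay_age <- ages
    lay_year <- years; is_code <- rep(TRUE, n)
  } else if (config$variant == "ehrbert") {
    lay_tok <- c("[CLS]", tokens, "[SEP]")
    lay_visit <- c(NA, visits, NA)
    lay_age <- c(NA, ages, NA)
    lay_year <- c(NA, years, NA)
    is_code <- c(FALSE, rep(TRUE, n), FALSE)
  } else {  # behrt: [SEP] between consecutive visits
    lay_tok <- "[CLS]"; lay_visit <- NA; lay_age <- NA; lay_year <- NA
    is_code <- FALSE
    nv <- max(visits)
    for (v in seq_len(nv)) {
      sel <- visits == v
      lay_tok <- c(lay_tok, tokens[sel])
      lay_visit <- c(lay_visit, visits[sel])
      lay_age <- c(lay_age, ages[sel])
      lay_year <- c(lay_year, years[sel])
      is_code <- c(is_code, rep(TRUE, sum(sel)))
      if (v < nv) {
        lay_tok <- c(lay_tok, "[SEP]")
        lay_visit <- c(lay_visit, v)
        lay_age <- c(lay_age, NA)
        lay_year <- c(lay_year, NA)
        is_code <- c(is_code, FALSE)
      }
    }
  }
  Tn <- length(lay_tok)

  rows <- list()
  for (ch in config$inputs) {
    rows[[ch]] <- switch(ch,
      code = {
        idx <- match(lay_tok, vocab$token)
        if (anyNA(idx)) {
          stop(sprintf("token(s) outside vocabulary: %s",
                       paste(utils::head(unique(lay_tok[is.na(idx)]), 5),
                             collapse = ", ")), call. = FALSE)
        }
        idx
      },
      absolute_position = seq_len(Tn),
      visit_number = ifelse(is.na(lay_visit), 0L,
                            pmin(lay_visit, config$max_visit)) + 1L,
      age = ifelse(is.na(lay_age), 1L,
                   pmin(pmax(lay_age, 0L), config$age_max) + 2L),
      calendar_year = {
        y <- pmin(pmax(lay_year, config$year_range[1]), config$year_range[2])
        ifelse(is.na(lay_year), 0L, y - config$year_range[1] + 1L) + 1L
      },
      gender = {
        g <- match(record$gender, GENDER_LEVELS)
        rep(ifelse(is.na(g), 1L, g + 1L), Tn)
      },
      ethnicity = {
        e <- match(record$ethnicity, ETHNICITY_LEVELS)
        if (is.na(e)) e <- match("missing", ETHNICITY_LEVELS)
        rep(e + 1L, Tn)
      },
      imd = {
        d <- record$imd_decile
        rep(ifelse(is.na(d), 12L, as.integer(d) + 1L), Tn)
      },
      segment = ifelse(is.na(lay_visit), 0L, lay_visit %% 2L + 1L) + 1L)
  }
  ch_mat <- do.call(rbind, rows)
  # age channel: ids already 1-based with 0 reserved -> shift specials to row 1
  if ("age" %in% config$inputs) {
    ch_mat["age", ] <- ifelse(is.na(lay_age), 1L, ch_mat["age", ])
  }
  if ("visit_number" %in% config$inputs) {
    ch_mat["visit_number", ] <- ifelse(is.na(lay_visit), 1L,
                                       ch_mat["visit_number", ])
  }
  storage.mode(ch_mat) <- "integer"
  list(channels = ch_mat, is_code = is_code, tokens = lay_tok)
}

#' Compose inputs for every patient in a sequence set
#'
#' @param sequences a `patient_sequences` object.
#' @param records patient records table.
#' @param config an `ehr_transformer_config`.
#' @param vocab token vocabulary.
#' @return named list of [compose_inputs()] results.
#' @export
prepare_inputs <- function(sequences, records, config, vocab) {
  stopifnot(inherits(sequences, "patient_sequences"))
  sl <- split(sequences$data, sequences$data$patient_id)
  rec_idx <- match(names(sl), records$patient_id)
  if (anyNA(rec_idx)) {
    stop("sequences reference patients missing from the records table",
         call. = FALSE)
  }
  out <- vector("list", length(sl))
  names(out) <- names(sl)
  for (i in seq_along(sl)) {
    out[[i]] <- compose_inputs(sl[[i]], records[rec_idx[i], ], config, vocab)
  }
  out
}

init_transformer_params <- function(config, vocab_size, seed) {
  sizes <- channel_sizes(config, vocab_size)
  H <- config$hidden_size
  I <- config$intermediate_size
  with_seed(seed, {
    rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
    tables <- lapply(sizes, function(s) rn(s, H))
    layers <- lapply(seq_len(config$hidden_layers), function(l) {
      list(Wq = rn(H, H), Wk = rn(H, H), Wv = rn(H, H), Wo = rn(H, H),
           bq = numeric(H), bk = numeric(H), bv = numeric(H), bo = numeric(H),
           W1 = rn(H, I), b1 = numeric(I), W2 = rn(I, H), b2 = numeric(H),
           ln1_g = rep(1, H), ln1_b = numeric(H),
           ln2_g = rep(1, H), ln2_b = numeric(H))
    })
    list(tables = tables, ln0_g = rep(1, H), ln0_b = numeric(H),
         layers = layers, Wout = rn(H, vocab_size), bout = numeric(vocab_size))
  })
}

# --- nested parameter-list arithmetic (Adam) -------------------------------

nested_map2 <- function(f, a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- nested_map2(f, a[[nm]], b[[nm]])
    a
  } else f(a, b)
}

nested_map3 <- function(f, a, b, d) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- nested_map3(f, a[[nm]], b[[nm]], d[[nm]])
    a
  } else f(a, b, d)
}

nested_zero <- function(a) rapply(a, function(x) x * 0, how = "replace")

# Mask code positions for MLM: of the selected positions, 80% become [MASK],
# 10% a random code token, 10% stay unchanged; labels are -1 elsewhere.
mask_inputs <- function(inputs, mask_prob, vocab) {
  mask_row <- which(vocab$token == "[MASK]")
  code_rows <- which(!(vocab$token %in% SPECIAL_TOKENS))
  lapply(inputs, function(inp) {
    Tn <- ncol(inp$channels)
    labels <- rep(-1L, Tn)
    ch <- inp$channels
    cand <- which(inp$is_code)
    sel <- cand[stats::runif(length(cand)) < mask_prob]
    if (length(sel)) {
      labels[sel] <- ch["code", sel] - 1L   # 0-based for the compiled core
      r <- stats::runif(length(sel))
      to_mask <- sel[r < 0.8]
      to_rand <- sel[r >= 0.8 & r < 0.9]
      ch["code", to_mask] <- mask_row
      if (length(to_rand)) {
        ch["code", to_rand] <- sample(code_rows, length(to_rand),
                                      replace = TRUE)
      }
    }
    list(channels = ch, labels = labels)
  })
}

#' Pretrain the encoder with masked language modelling
#'
#' Standard MLM: `mask_prob` of code positions are selected; of those, 80%
#' are replaced by `[MASK]`, 10% by a random code token and 10% left
#' unchanged. Cross-entropy is computed on selected positions only; special
#' and padding positions are never selected. Optimised with Adam and linear
#' learning-rate warmup; deterministic per seed (single-threaded).
#'
#' @param inputs output of [prepare_inputs()].
#' @param config an `ehr_transformer_config`.
#' @param vocab token vocabulary.
#' @param verbose print per-epoch loss.
#' @return object of class `ehr_encoder` with the trained parameters, config,
#'   vocabulary and the per-epoch `loss_trajectory`.
#' @export
pretrain_mlm <- function(inputs, config, vocab, verbose = FALSE) {
  n <- length(inputs)
  if (n < config$batch_size) {
    stop(sprintf("corpus (%d sequences) is smaller than one batch (%d)",
                 n, config$batch_size), call. = FALSE)
  }
  params <- init_transformer_params(config, nrow(vocab),
                                    derive_seed(config$seed, "init"))
  m_state <- nested_zero(params)
  v_state <- nested_zero(params)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  steps_per_epoch <- ceiling(n / config$batch_size)
  total_steps <- config$epochs * steps_per_epoch
  warmup <- max(1, floor(config$warmup_frac * total_steps))
  step <- 0L
  losses <- numeric(config$epochs)

  with_seed(derive_seed(config$seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_lab <- 0
      for (bstart in seq(1, n, by = config$batch_size)) {
        bidx <- ord[bstart:min(bstart + config$batch_size - 1L, n)]
        masked <- mask_inputs(inputs[bidx], config$mask_prob, vocab)
        chans <- lapply(masked, function(x) x$channels - 1L)
        labs <- lapply(masked, function(x) x$labels)
        if (isTRUE(config$tie_mlm_head)) {
          # decoder weights are the transposed token-embedding table
          params$Wout <- t(params$tables[[1]])
        }
        res <- bert_batch_cpp(chans, labs, params, config$attention_heads,
                              TRUE, -1L)
        if (res$n_labels == 0) next
        if (isTRUE(config$tie_mlm_head)) {
          res$grads$tables[[1]] <- res$grads$tables[[1]] + t(res$grads$Wout)
          res$grads$Wout[] <- 0
        }
        step <- step + 1L
        # linear warmup then linear decay to zero over the remaining steps
        lr <- if (step <= warmup) config$learning_rate * step / warmup
              else config$learning_rate *
                max(0.02, 1 - (step - warmup) / max(1, total_steps - warmup))
        g <- rapply(res$grads, function(x) x / res$n_labels, how = "replace")
        m_state <- nested_map2(function(m, gr) beta1 * m + (1 - beta1) * gr,
                               m_state, g)
        v_state <- nested_map2(function(v, gr) beta2 * v + (1 - beta2) * gr^2,
                               v_state, g)
        bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
        params <- nested_map3(function(p, m, v)
          p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
          params, m_state, v_state)
        ep_loss <- ep_loss + res$loss_sum
        ep_lab <- ep_lab + res$n_labels
      }
      losses[ep] <- ep_loss / max(ep_lab, 1)
      if (verbose) message(sprintf("epoch %d: mlm loss %.4f", ep, losses[ep]))
    }
  })
  if (isTRUE(config$tie_mlm_head)) params$Wout <- t(params$tables[[1]])
  structure(list(params = params, config = config, vocab = vocab,
                 loss_trajectory = losses),
            class = "ehr_encoder")
}

#' @export
print.ehr_encoder <- function(x, ...) {
  cat(sprintf("<ehr_encoder> variant=%s, %d layers, hidden %d (final mlm loss %.4f)\n",
              x$config$variant, x$config$hidden_layers, x$config$hidden_size,
              utils::tail(x$loss_trajectory, 1)))
  invisible(x)
}

#' Masked-prediction loss and accuracy on a corpus
#'
#' Applies fresh MLM masking (seeded) and evaluates the encoder without
#' updating it.
#' @param encoder an `ehr_encoder`.
#' @param inputs output of [prepare_inputs()].
#' @param seed masking seed.
#' @return list: `loss`, `accuracy`, `n_masked`.
#' @export
mlm_evaluate <- function(encoder, inputs, seed = 1L) {
  cfg <- encoder$config
  masked <- with_seed(seed, mask_inputs(inputs, cfg$mask_prob, encoder$vocab))
  chans <- lapply(masked, function(x) x$channels - 1L)
  labs <- lapply(masked, function(x) x$labels)
  res <- bert_batch_cpp(chans, labs, encoder$params, cfg$attention_heads,
                        FALSE, -1L)
  list(loss = res$loss_sum / max(res$n_labels, 1),
       accuracy = res$n_correct / max(res$n_labels, 1),
       n_masked = res$n_labels)
}

#' Extract pooled patient embeddings
#'
#' Forward pass without masking; hidden states of the second-to-last layer of
#' the stack's outputs are averaged over code positions only (special tokens
#' excluded), giving one vector per patient of length `hidden_size`.
#'
#' @param encoder an `ehr_encoder`.
#' @param inputs output of [prepare_inputs()] (unmasked).
#' @param batch_size forward-pass batch size.
#' @return an `embedding_set` with dimension `hidden_size`.
#' @export
extract_embeddings <- function(encoder, inputs, batch_size = 128L) {
  cfg <- encoder$config
  hid <- cfg$hidden_layers - 1L   # second-to-last of the stack's outputs
  n <- length(inputs)
  out <- matrix(0, n, cfg$hidden_size)
  rownames(out) <- names(inputs)
  for (bstart in seq(1, n, by = batch_size)) {
    bidx <- bstart:min(bstart + batch_size - 1L, n)
    chans <- lapply(inputs[bidx], function(x) x$channels - 1L)
    labs <- lapply(inputs[bidx], function(x) rep(-1L, ncol(x$channels)))
    res <- bert_batch_cpp(chans, labs, encoder$params, cfg$attention_heads,
                          FALSE, hid)
    for (j in seq_along(bidx)) {
      h <- res$hidden[[j]]
      cp <- inputs[[bidx[j]]]$is_code
      out[bidx[j], ] <- colMeans(h[cp, , drop = FALSE])
    }
  }
  embedding_set(out, method = cfg$variant)
}

#' Fit a transformer and return pooled embeddings in one call
#'
#' Convenience wrapper: builds the vocabulary from the sequences, composes
#' inputs, runs MLM pretraining and extracts pooled embeddings.
#' @param sequences a `patient_sequences` object.
#' @param records patient records.
#' @param config an `ehr_transformer_config`.
#' @param verbose print per-epoch loss.
#' @return list: `encoder`, `embeddings` (an `embedding_set`), `inputs`.
#' @export
fit_ehr_transformer <- function(sequences, records, config, verbose = FALSE) {
  vocab <- build_vocabulary(sequences$data$token)
  inputs <- prepare_inputs(sequences, records, config, vocab)
  encoder <- pretrain_mlm(inputs, config, vocab, verbose = verbose)
  emb <- extract_embeddings(encoder, inputs)
  list(encoder = encoder, embeddings = emb, inputs = inputs)
}
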