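idx <- as.Date("2015-01-01")

# 5 codes in 4 visits (visit 1 has two same-day codes)
five_code_events <- function() {
  data.table::data.table(
    patient_id = "p1",
    event_date = as.Date(c("2010-01-05", "2010-01-05", "2011-02-01",
                           "2012-03-01", "2013-04-01")),
    medcode = c("m_asthma1", "m_ra1", "m_dep1", "m_af1", "m_ht1"))
}

five_code_inputs <- function(variant, ...) {
  seqs <- build_sequences(five_code_events(), toy_map(), toy_records("p1"),
                          "diseases", idx)
  cfg <- transformer_config(variant, "desk", ...)
  vocab <- build_vocabulary(seqs$data$token)
  list(inp = compose_inputs(seqs$data, toy_records("p1")[1, ], cfg, vocab),
       cfg = cfg, vocab = vocab, seqs = seqs)
}

test_that("variant presets match the published architecture table", {
  mb <- transformer_config("medbert", "paper")
  expect_equal(mb$hidden_layers, 6L)
  expect_equal(mb$attention_heads, 6L)
  expect_equal(mb$hidden_size, 192L)
  expect_equal(mb$intermediate_size, 64L)
  expect_equal(mb$learning_rate, 5e-5)
  expect_equal(mb$batch_size, 32L)
  for (v in c("behrt", "ehrbert")) {
    pc <- transformer_config(v, "paper")
    expect_equal(pc$hidden_layers, 6L)
    expect_equal(pc$attention_heads, 12L)
    expect_equal(pc$hidden_size, 288L)
    expect_equal(pc$intermediate_size, 512L)
    expect_equal(pc$learning_rate, 3e-5)
    expect_equal(pc$batch_size, 256L)
  }
  expect_false("segment" %in% transformer_config("ehrbert")$inputs)
  expect_true("segment" %in% transformer_config("behrt")$inputs)
  expect_true(all(c("gender", "ethnicity", "imd", "calendar_year") %in%
                    transformer_config("ehrbert")$inputs))
  expect_equal(transformer_config("ehrbert")$epoch_presets,
               c(10L, 50L, 100L))
  expect_error(transformer_config("ehrbert", hidden_size = 65L),
               "divisible")
  expect_error(transformer_config("ehrbert", nonsense = 1), "unknown")
})

test_that("special-token layouts follow each variant's convention", {
  # ehrbert: [CLS] + 5 codes + [SEP]; visit ids 1,1,2,3,4 on code positions
  eh <- five_code_inputs("ehrbert")
  expect_length(eh$inp$tokens, 7L)
  expect_equal(eh$inp$tokens[1], "[CLS]")
  expect_equal(eh$inp$tokens[7], "[SEP]")
  expect_equal(eh$inp$is_code, c(FALSE, rep(TRUE, 5), FALSE))
  # visit channel: reserved id 1 for specials, visit v -> v + 1
  expect_equal(unname(eh$inp$channels["visit_number", ]),
               c(1L, 2L, 2L, 3L, 4L, 5L, 1L))

  # behrt: [CLS] + codes with [SEP] between consecutive visits (3 separators)
  bh <- five_code_inputs("behrt")
  expect_length(bh$inp$tokens, 9L)
  expect_equal(sum(bh$inp$tokens == "[SEP]"), 3L)
  expect_equal(bh$inp$tokens[1], "[CLS]")
  expect_false(bh$inp$tokens[9] == "[SEP]")  # none after the last visit
  expect_equal(sum(bh$inp$is_code), 5L)
  expect_true("segment" %in% rownames(bh$inp$channels))

  # medbert: raw codes, no special tokens
  mb <- five_code_inputs("medbert")
  expect_length(mb$inp$tokens, 5L)
  expect_true(all(mb$inp$is_code))
  expect_false(any(mb$inp$tokens %in% c("[CLS]", "[SEP]")))

  # composing is a pure function
  again <- five_code_inputs("ehrbert")
  expect_identical(eh$inp, again$inp)
})

test_that("missing sociodemographics route to the reserved missing id", {
  seqs <- build_sequences(five_code_events(), toy_map(), toy_records("p1"),
                          "diseases", idx)
  rec <- toy_records("p1")
  rec$imd_decile <- NA_integer_
  rec$ethnicity <- NA_character_
  cfg <- transformer_config("ehrbert", "desk")
  vocab <- build_vocabulary(seqs$data$token)
  inp <- compose_inputs(seqs$data, rec[1, ], cfg, vocab)
  expect_true(all(inp$channels["imd", ] == 12L))       # dedicated missing id
  expect_true(all(inp$channels["ethnicity", ] == 7L))  # "missing" level
})

test_that("analytic gradients match finite differences", {
  cfg <- transformer_config("ehrbert", "desk", hidden_layers = 1L,
                            attention_heads = 2L, hidden_size = 8L,
                            intermediate_size = 12L, seed = 1L)
  vocab <- build_vocabulary(c("x1", "x2", "x3"))
  sizes <- ehrseqrep:::channel_sizes(cfg, nrow(vocab))
  params <- ehrseqrep:::init_transformer_params(cfg, nrow(vocab), 1L)
  with_seed_local(2L, {
    mk <- function(Tn) {
      m <- vapply(sizes, function(s) sample.int(s, Tn, TRUE),
                  integer(Tn))
      t(m)
    }
    chans <- list(mk(4L) - 1L, mk(6L) - 1L)
  })
  labs <- list(c(-1L, 2L, -1L, 5L), c(6L, -1L, -1L, 7L, -1L, 5L))
  res <- ehrseqrep:::bert_batch_cpp(chans, labs, params,
                                    cfg$attention_heads, TRUE, -1L)
  loss_at <- function(p) {
    ehrseqrep:::bert_batch_cpp(chans, labs, p, cfg$attention_heads,
                               FALSE, -1L)$loss_sum
  }
  fd <- function(set, get, eps = 1e-5) {
    (loss_at(set(params, get(params) + eps)) -
       loss_at(set(params, get(params) - eps))) / (2 * eps)
  }
  cases <- list(
    list(g = function(p) p$layers[[1]]$Wq[2, 3],
         s = function(p, v) { p$layers[[1]]$Wq[2, 3] <- v; p },
         a = function(g) g$layers[[1]]$Wq[2, 3]),
    list(g = function(p) p$layers[[1]]$W1[5, 7],
         s = function(p, v) { p$layers[[1]]$W1[5, 7] <- v; p },
         a = function(g) g$layers[[1]]$W1[5, 7]),
    list(g = function(p) p$layers[[1]]$Wo[1, 4],
         s = function(p, v) { p$layers[[1]]$Wo[1, 4] <- v; p },
         a = function(g) g$layers[[1]]$Wo[1, 4]),
    list(g = function(p) p$layers[[1]]$ln1_g[3],
         s = function(p, v) { p$layers[[1]]$ln1_g[3] <- v; p },
         a = function(g) g$layers[[1]]$ln1_g[3]),
    list(g = function(p) p$ln0_g[2],
         s = function(p, v) { p$ln0_g[2] <- v; p },
         a = function(g) g$ln0_g[2]),
    list(g = function(p) p$tables[[1]][3, 5],
         s = function(p, v) { p$tables[[1]][3, 5] <- v; p },
         a = function(g) g$tables[[1]][3, 5]),
    list(g = function(p) p$Wout[2, 6],
         s = function(p, v) { p$Wout[2, 6] <- v; p },
         a = function(g) g$Wout[2, 6]))
  for (cs in cases) {
    num <- fd(cs$s, cs$g)
    ana <- cs$a(res$grads)
    expect_equal(ana, num, tolerance = 1e-3)
  }
})

test_that("pooled embeddings equal a brute-force recount and match preset dims", {
  gc_ <- grammar_cohort(n_seq = 60L, seed = 6L)
  seqs <- build_sequences(gc_$events, gc_$map, gc_$records, "medcodes", idx)
  for (variant in c("ehrbert", "medbert")) {
    cfg <- transformer_config(variant, "paper", epochs = 1L, seed = 2L)
    vocab <- build_vocabulary(seqs$data$token)
    inputs <- prepare_inputs(seqs, gc_$records, cfg, vocab)
    params <- ehrseqrep:::init_transformer_params(cfg, nrow(vocab), 3L)
    enc <- structure(list(params = params, config = cfg, vocab = vocab,
                          loss_trajectory = NA_real_),
                     class = "ehr_encoder")
    emb <- extract_embeddings(enc, inputs)
    expect_equal(emb$dim, if (variant == "medbert") 192L else 288L)

    # oracle: rerun the forward pass, average code-position rows by hand
    pick <- sample(seq_along(inputs), 10L)
    res <- ehrseqrep:::bert_batch_cpp(
      lapply(inputs[pick], function(x) x$channels - 1L),
      lapply(inputs[pick], function(x) rep(-1L, ncol(x$channels))),
      params, cfg$attention_heads, FALSE, cfg$hidden_layers - 1L)
    for (j in seq_along(pick)) {
      h <- res$hidden[[j]]
      cp <- which(inputs[[pick[j]]]$is_code)
      manual <- colSums(h[cp, , drop = FALSE]) / length(cp)
      expect_equal(unname(emb$matrix[names(inputs)[pick[j]], ]),
                   unname(manual), tolerance = 1e-6)
    }
  }
})

test_that("a constant-output encoder pools to that constant", {
  gc_ <- grammar_cohort(n_seq = 40L, seed = 8L)
  seqs <- build_sequences(gc_$events, gc_$map, gc_$records, "medcodes", idx)
  cfg <- transformer_config("ehrbert", "desk", hidden_layers = 2L, seed = 1L)
  vocab <- build_vocabulary(seqs$data$token)
  inputs <- prepare_inputs(seqs, gc_$records, cfg, vocab)
  params <- ehrseqrep:::init_transformer_params(cfg, nrow(vocab), 1L)
  v <- seq_len(cfg$hidden_size) / cfg$hidden_size
  # zeroing the pooled layer's output LayerNorm gain and setting its shift
  # forces every position's hidden state to v
  params$layers[[1]]$ln2_g <- rep(0, cfg$hidden_size)
  params$layers[[1]]$ln2_b <- v
  enc <- structure(list(params = params, config = cfg, vocab = vocab,
                        loss_trajectory = NA_real_), class = "ehr_encoder")
  emb <- extract_embeddings(enc, inputs)
  for (i in c(1L, 17L)) {
    expect_equal(unname(emb$matrix[i, ]), v, tolerance = 1e-12)
  }
})

test_that("masking selects approximately mask_prob of code positions", {
  gc_ <- grammar_cohort(n_seq = 400L, len = 20L, seed = 9L)
  seqs <- build_sequences(gc_$events, gc_$map, gc_$records, "medcodes", idx)
  cfg <- transformer_config("ehrbert", "desk", seed = 1L)
  vocab <- build_vocabulary(seqs$data$token)
  inputs <- prepare_inputs(seqs, gc_$records, cfg, vocab)
  masked <- with_seed_local(3L,
    ehrseqrep:::mask_inputs(inputs, cfg$mask_prob, vocab))
  n_code <- sum(vapply(inputs, function(x) sum(x$is_code), 0L))
  n_sel <- sum(vapply(masked, function(x) sum(x$labels >= 0L), 0L))
  expect_lt(abs(n_sel / n_code - cfg$mask_prob), 0.01)
  # labels appear only at code positions; special positions never selected
  for (i in sample(seq_along(inputs), 30L)) {
    sel <- which(masked[[i]]$labels >= 0L)
    expect_true(all(inputs[[i]]$is_code[sel]))
  }
  # of the selected positions, ~80% carry the [MASK] id
  mask_row <- which(vocab$token == "[MASK]")
  n_masked <- sum(vapply(seq_along(masked), function(i) {
    sel <- masked[[i]]$labels >= 0L
    sum(masked[[i]]$channels["code", sel] == mask_row)
  }, 0))
  expect_lt(abs(n_masked / n_sel - 0.8), 0.05)
})

test_that("with zeroed auxiliary tables the model reduces to code+position", {
  gc_ <- grammar_cohort(n_seq = 30L, seed = 10L)
  seqs <- build_sequences(gc_$events, gc_$map, gc_$records, "medcodes", idx)
  full_cfg <- transformer_config("ehrbert", "desk", seed = 4L)
  base_cfg <- transformer_config("ehrbert", "desk", seed = 4L,
                                 inputs = c("code", "absolute_position"))
  vocab <- build_vocabulary(seqs$data$token)
  inp_full <- prepare_inputs(seqs, gc_$records, full_cfg, vocab)
  inp_base <- prepare_inputs(seqs, gc_$records, base_cfg, vocab)
  p_base <- ehrseqrep:::init_transformer_params(base_cfg, nrow(vocab), 5L)
  p_full <- ehrseqrep:::init_transformer_params(full_cfg, nrow(vocab), 5L)
  # share the code/position tables and encoder weights; zero everything else
  p_full$tables <- lapply(ehrseqrep:::channel_sizes(full_cfg, nrow(vocab)),
                          function(s) matrix(0, s, full_cfg$hidden_size))
  p_full$tables[[1]] <- p_base$tables[[1]]
  pos_i <- which(full_cfg$inputs == "absolute_position")
  p_full$tables[[pos_i]] <- p_base$tables[[2]]
  for (nm in c("ln0_g", "ln0_b", "layers", "Wout", "bout")) {
    p_full[[nm]] <- p_base[[nm]]
  }
  h_full <- ehrseqrep:::bert_batch_cpp(
    lapply(inp_full[1:5], function(x) x$channels - 1L),
    lapply(inp_full[1:5], function(x) rep(-1L, ncol(x$channels))),
    p_full, full_cfg$attention_heads, FALSE, 1L)$hidden
  h_base <- ehrseqrep:::bert_batch_cpp(
    lapply(inp_base[1:5], function(x) x$channels - 1L),
    lapply(inp_base[1:5], function(x) rep(-1L, ncol(x$channels))),
    p_base, base_cfg$attention_heads, FALSE, 1L)$hidden
  for (j in 1:5) expect_equal(h_full[[j]], h_base[[j]], tolerance = 1e-10)
})

test_that("pretraining is seeded, refuses undersized corpora, and learns", {
  gc_ <- grammar_cohort(n_seq = 200L, seed = 12L)
  seqs <- build_sequences(gc_$events, gc_$map, gc_$records, "medcodes", idx)
  cfg <- transformer_config("medbert", "desk", epochs = 2L, seed = 3L)
  vocab <- build_vocabulary(seqs$data$token)
  inputs <- prepare_inputs(seqs, gc_$records, cfg, vocab)
  expect_error(pretrain_mlm(inputs[1:10], cfg, vocab), "smaller than one batch")
  e1 <- pretrain_mlm(inputs, cfg, vocab)
  e2 <- pretrain_mlm(inputs, cfg, vocab)
  expect_identical(e1$params, e2$params)
  expect_length(e1$loss_trajectory, 2L)
  expect_lt(e1$loss_trajectory[2], e1$loss_trajectory[1])
})
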