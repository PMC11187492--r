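---
title: "Patient representations from disease-code sequences: models, simulator and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient representations from disease-code sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Primary-care electronic health records store a patient's diagnoses as a
time-ordered sequence of clinical codes. For people living with multiple
long-term conditions (two or more chronic diseases), this sequence is a rich
but awkward object: its length varies by orders of magnitude, codes recur for
administrative as well as clinical reasons, and the same disease can be coded
at several granularities. A common strategy is to borrow from natural language
processing: treat the code sequence as a "document", learn a fixed-length
unsupervised vector per patient, and use that vector as input to simple
downstream prediction models.

`ehrseqrep` implements and compares a ladder of such representations:

* **Binary disease indicators** and **frequency counts** — the classical
  epidemiological baselines; one column per disease category.
* **Latent Dirichlet allocation (LDA)** — a bag-of-words topic model; the
  patient representation is the fitted topic-proportion vector.
* **doc2vec** — paragraph vectors trained with negative sampling, in both
  distributed-bag-of-words (DBOW) and distributed-memory (DM) modes.
* **A BERT-style transformer family** — one configurable masked-language-model
  encoder reproducing three published input/embedding conventions for coded
  EHR sequences (here called `medbert`, `behrt` and `ehrbert`).

Every representation is evaluated the same way: as features of an L2-penalized
logistic classifier predicting nine binary one-year outcomes (mortality in the
60+ stratum, emergency-department attendance, emergency admission, and
any/new diagnoses of hypertension, diabetes and depression), with ROC-AUC and
average precision as metrics. The scientific question is comparative: do
representations that can see *sequence order* carry predictive content that
co-occurrence-only representations cannot?

Because the real primary-care extracts that motivate this question are access
restricted, the package ships a synthetic cohort generator whose outcome
models contain an explicit, controllable sequence-order signal. Everything
downstream is exercised against that generator.

## The synthetic cohort generator

`sim_config()` + `simulate_cohort()` produce four linked tables: patient
records, dated coded events, a many-to-one fine-code → disease-category map,
and binary one-year outcome labels.

**Demographics.** Age at the index date is drawn from a normal distribution
truncated to 18–105 years whose underlying parameters are moment-matched so
the *realized* cohort has the configured mean 53.8 and SD 18.2 years. Gender
(53.1% female), ethnicity (86.2% White, with a 2% explicit missing level) and
deprivation deciles (near-uniform, 0.1% missing) follow the configured
marginals. Missing ethnicity/IMD are explicit levels end to end — they become
missing-indicator columns in covariates and dedicated embedding ids in the
transformer, never dropped rows.

**Events.** Each patient has 2 + NB(size 3, mean 6) visits at day resolution;
a visit is the set of events sharing one calendar date, and most visits carry
a single code (1/2/3 codes with probability 0.80/0.15/0.05). Visit content
comes from a latent health-state Markov chain: each patient has a Dirichlet
base distribution over six latent topics; the active topic persists between
visits with probability 0.8. Topics are themselves Dirichlet draws over
disease categories, mixed with a background concentrated on the ten
"common" categories so that the marker and precedence-pair diseases used by
the outcome models are reasonably prevalent. With probability 0.25
(multiplied by 1.2 in the five most deprived deciles — a single per-level
multiplier standing in for demographically patterned recurrent coding), an
event re-codes one of the patient's earlier codes instead of drawing fresh.
Every patient is guaranteed at least two distinct disease categories, the
defining property of the multimorbid cohort.

**Outcomes.** Each outcome label is a Bernoulli draw from a logistic model
with four blocks:

1. *presence*: weights on a random subset of eight disease categories
   (SD 0.6), plus a weight of 2.0 on the outcome's own marker disease for the
   "any attendance" outcomes;
2. *order*: three signed precedence terms — for a disease pair (A, B) the
   term is +1 if A's first occurrence strictly predates B's, −1 for the
   reverse and 0 unless both are present (weight 1.5 each) — plus a
   recency-weighted exposure sum (e-folding time 5 years, weight 0.15);
3. *sociodemographics*: linear age (0.08/year for mortality, ~0.015/year
   otherwise), a gender term, and a linear deprivation term;
4. an intercept calibrated by root finding on the eligible stratum so the
   configured target event rate (e.g. 3.3% 60+ mortality, 19.9% ED
   attendance) holds exactly in expectation.

The signed precedence construction is deliberate: given that both diseases
are present, the direction is close to a fair coin, so presence-only
representations receive zero linearly usable information from the order
block. Setting `order_weight = 0` removes the order and recency terms
entirely, giving a co-occurrence-only null world; the package's tests verify
that in that world permuting each patient's event order leaves the generating
probabilities exactly unchanged.

**What the generator does not emulate.** Real disease semantics (categories
are exchangeable labels), care-seeking dynamics, back-dating and entry-date
reconciliation, linkage artefacts, and coding-practice shifts over calendar
time. Consequently, passing tests show that the *pipeline* recovers planted
structure under its stated assumptions — not that any representation will
rank the same way on real records.

## Sequence construction

`build_sequences()` orders each patient's events by observation date, breaking
same-date ties by lexicographic medcode (recorded in the object's metadata;
the choice is arbitrary but must be deterministic for reproducibility).
Sequences shorter than 2 tokens are dropped; longer than `max_len = 128`
keep the most recent 128 codes. Both vocabularies (fine codes and disease
categories) share this path, so truncation provably commutes with category
mapping. One deliberate deviation from per-method conventions: truncation is
applied identically for *all* representation methods, not only the
transformers, so every method sees the same inputs.

Per-token metadata carried alongside the codes: a 1-based visit index that
increments per distinct event date, age in whole years (floor of elapsed
years, clipped to 0–110), and calendar year. `eligible_cohort()` applies the
cohort rules: registered at least one year before the index date, alive and
registered at index, and at least two distinct disease categories in history.

## LDA

`fit_lda()` is a collapsed Gibbs sampler (compiled; uses R's RNG so runs are
seed-reproducible). Documents are full patient token sequences — order is
discarded by construction, which is the point of the bag-of-words comparator.
Priors default to symmetric α = 1/K and β = 0.01 and are exposed in the
interface. Held-out perplexity is exp(−log-likelihood per token); by default
it is computed by *document completion*: for each held-out document, topic
proportions are inferred by Gibbs fold-in on the odd-position tokens under
frozen topic-word distributions, and the likelihood is evaluated on the
even-position tokens. The simpler full-document fold-in estimator is also
available, but it lets extra topics buy per-document adaptivity for free and
is therefore monotone-biased toward larger K — with it, selection on planted
corpora almost always returns the largest candidate, while completion
recovers the generating topic count. A uniform topic-word model scores
exactly the vocabulary size under either estimator, which the tests assert.
`select_n_topics()` does the 80:20 split, fits each candidate K on the
training part, picks the K with the lowest held-out perplexity (ties to the
smaller K) and refits on the full corpus. The default candidate grid is
10–150 in steps of 10.

## doc2vec

`fit_doc2vec()` trains paragraph vectors with negative sampling (5 negatives,
unigram^0.75 noise distribution), single-threaded for determinism. DBOW
predicts each token from the document vector alone; DM averages the document
vector with a ±5-token context window. Because there is no ground truth for
an unsupervised embedding, model selection uses patients with byte-identical
sequences: `identical_sequence_score()` is the mean cosine similarity over
identical-sequence pairs minus the mean cosine over an equal-sized random
sample of non-identical pairs. The score is 1 for embeddings that are one-hot
in sequence identity, 0 when all embeddings are identical, near 0 for random
embeddings, and invariant to global rotations. `select_doc2vec()` maximizes
this score over a configuration grid, breaking ties toward fewer epochs.

## The transformer family

One encoder, three input conventions:

| | `medbert` | `behrt` | `ehrbert` |
|---|---|---|---|
| extra embeddings | visit number (± absolute position) | visit number, age, segment | visit number, age, gender, ethnicity, IMD, calendar year |
| special tokens | none | `[CLS]` at start, `[SEP]` between visits | `[CLS]` at start, one `[SEP]` at end |

The input embedding at each position is the elementwise sum of the enabled
channel tables, followed by LayerNorm. Each encoder layer is standard
multi-head self-attention with residual + LayerNorm and a GELU feed-forward
block. Pretraining is masked language modelling alone (no next-visit or
next-sentence task): 15% of *code* positions are selected; of those 80%
become `[MASK]`, 10% a random code, 10% stay unchanged; cross-entropy is
computed on selected positions only, and special tokens are never selected.
The masked-token decoder shares weights with the input token-embedding table
(`tie_mlm_head`, on by default). The optimizer is Adam with linear warmup
over the first 10% of steps and linear decay after. Both the published "paper" presets (6 layers; hidden
192/288; heads 6/12; intermediate 64/512; lr 5e-5/3e-5; batch 32/256) and a
"desk" configuration used throughout the tests (2–3 layers, 4 heads, hidden
64, intermediate 128, lr 1e-3, batch 32) are available; epoch presets of
10/50/100 are surfaced for sensitivity analyses, while tests train for
5–16 epochs on corpora of 2 000–4 000 sequences to stay within desk-scale
compute. Whether the absolute-position channel is enabled alongside the visit
number is exposed as a flag for every variant (the conventions differ between
published descriptions); it defaults to on.

Patient embeddings are the mean of the second-to-last layer's hidden states
over *code positions only* — the contextualised disease embeddings — giving a
vector of length `hidden_size`. Pooling excludes `[CLS]`/`[SEP]` because
those positions are not disease embeddings. The whole forward/backward pass
is compiled and exact: the test suite checks analytic gradients against
finite differences and the pooled output against a by-hand recount.

## The evaluation harness

`build_outcome_cohort()` applies the outcome-specific eligibility rules:
patients deregistering during follow-up are removed everywhere; deaths during
follow-up are removed for all non-mortality outcomes; mortality is assessed
only in the 60+ stratum; incident-disease ("new") outcomes drop patients with
the disease in history. `evaluate_representation()` then runs a stratified
4-fold cross-validation (stratification is a deliberate addition: incident
outcomes near 1% would otherwise risk single-class folds) of a logistic
classifier with L2 penalty at inverse regularization strength C = 1
(alternatives 0.01/0.1/10 are a config switch). Embedding features are
standardized with training-fold statistics only; the classifier is fitted by
`glmnet` at the single penalty λ = 1/(C·n), which matches the
per-sample-loss parameterization of C in the standard scikit-learn logistic
regression. Sociodemographic covariates (age band, gender, ethnicity, IMD,
each with explicit missing levels) are appended to every representation
unless the embeddings-only sensitivity switch is set. No under- or
over-sampling is applied to rare outcomes.

Both pooled out-of-fold metrics and per-fold metrics are reported; the pooled
out-of-fold ROC-AUC is treated as the headline number (published comparisons
rarely state which convention they use, so the package provides both).
Average precision is computed as the step sum over distinct-score thresholds,
so a constant score yields exactly the prevalence — asserted in tests, along
with agreement of the rank-statistic AUC with an independent ROC
implementation. Threshold tables report sensitivity/specificity/PPV/NPV at
target sensitivities of 40/70/90%.

## Design choices made where the design was open

* **Visit definition**: the set of events sharing one calendar date; nothing
  in a flat coded-event table distinguishes encounters on the same day.
* **Same-date tie order**: lexicographic by medcode, stored in metadata.
* **Masking recipe**: the 15% / 80-10-10 convention, since the sources
  specify "masked language modelling" without details.
* **Fold-in for held-out perplexity**: topic-word distributions frozen,
  document proportions re-inferred; this is the standard held-out treatment
  and makes the uniform-model identity exact.
* **Identical-sequence score**: the paired-vs-random cosine gap defined above
  is this package's concrete realisation of the "identical sequences should
  embed similarly" criterion.
* **Order effects as signed precedence**: see the simulator section; an
  unsigned "A before B" indicator is nearly a co-occurrence feature and
  would not isolate sequence information.
* **Desk-scale problem sizes**: simulator checks run at n = 50 000; the
  transformer comparisons at n = 4 000 patients, hidden size 64 and ~16
  epochs; LDA selection on 200-document corpora. These sizes were chosen so
  the full suite completes on a single CPU in tens of minutes while leaving
  every Monte-Carlo tolerance comfortably above sampling noise.

## Known limitations

* Desk-scale transformer embeddings are strongly compressed summaries; mean
  pooling makes them closer to *frequency* profiles of a sequence than to
  presence indicators, and on outcomes generated purely by disease presence
  a presence-based baseline is structurally hard to beat. The package's own
  comparison reports (see `scripts/acceptance.R` output) quantify this gap
  honestly rather than hiding it.
* The Gibbs sampler and SGD trainers are single-threaded by design —
  determinism is valued over speed at these problem sizes.
* The generator's disease categories are exchangeable labels; nothing should
  be read into which category plays "hypertension".
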