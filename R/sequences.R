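# Sequence construction: dated code events -> tokenized, time-ordered
# per-patient sequences under either of the two vocabularies (fine codes or
# disease categories), with the min-length-2 / max-length-128 rules.

SPECIAL_TOKENS <- c("[PAD]", "[CLS]", "[SEP]", "[MASK]", "[UNK]")

#' Build a token vocabulary
#'
#' Dense, stable indexing with the special tokens `[PAD]`, `[CLS]`, `[SEP]`,
#' `[MASK]`, `[UNK]` reserved at indices 0..4; code tokens follow in sorted
#' order.
#' @param tokens character vector of code tokens (duplicates allowed).
#' @return data.table with columns `token`, `index`.
#' @export
build_vocabulary <- function(tokens) {
  code_tokens <- sort(unique(as.character(tokens)))
  if (any(code_tokens %in% SPECIAL_TOKENS)) {
    stop("code tokens may not collide with special tokens", call. = FALSE)
  }
  data.table::data.table(
    token = c(SPECIAL_TOKENS, code_tokens),
    index = seq_len(length(code_tokens) + 5L) - 1L)
}

#' Map tokens to integer ids and back
#'
#' Unknown tokens map to `[UNK]`; `ids_to_tokens` is the exact inverse for
#' in-vocabulary tokens.
#' @param tokens character vector.
#' @param vocab vocabulary from [build_vocabulary()].
#' @return integer vector of ids.
#' @export
tokens_to_ids <- function(tokens, vocab) {
  idx <- vocab$index[match(tokens, vocab$token)]
  idx[is.na(idx)] <- vocab$index[vocab$token == "[UNK]"]
  as.integer(idx)
}

#' @rdname tokens_to_ids
#' @param ids integer vector of ids.
#' @export
ids_to_tokens <- function(ids, vocab) {
  vocab$token[match(as.integer(ids), vocab$index)]
}

#' Build tokenized patient sequences from dated code events
#'
#' Events are ordered by event date ascending; same-date ties break by
#' medcode lexicographic order (recorded in the object's metadata). Sequences
#' shorter than 2 tokens are excluded; sequences longer than `max_len` keep
#' only the most recent `max_len` codes. Per-token visit index (1-based,
#' incrementing per distinct event date), age in whole years (clipped to
#' 0..110) and calendar year are carried alongside the tokens.
#'
#' @param events events table (`patient_id`, `event_date`, `medcode`).
#' @param map code map (`medcode`, `disease`); every event code must map.
#' @param records patient records (needed for birth dates).
#' @param vocabulary_tag `"diseases"` (mapped categories) or `"medcodes"`.
#' @param index_date all events must fall strictly before this date.
#' @param max_len maximum tokens per patient after truncation.
#' @return object of class `patient_sequences`.
#' @export
build_sequences <- function(events, map, records,
                            vocabulary_tag = c("diseases", "medcodes"),
                            index_date, max_len = 128L) {
  vocabulary_tag <- match.arg(vocabulary_tag)
  index_date <- as.Date(index_date)
  stopifnot(max_len >= 2L)
  assert_columns(events, c("patient_id", "event_date", "medcode"), "events")
  ev <- data.table::as.data.table(events)
  ev$event_date <- as.Date(ev$event_date)
  if (nrow(ev) && any(ev$event_date >= index_date)) {
    stop(sprintf("events on or after the index date (%s) are not allowed in history",
                 format(index_date)), call. = FALSE)
  }
  unmapped <- setdiff(unique(ev$medcode), map$medcode)
  if (length(unmapped)) {
    stop(sprintf("unmapped medcode(s): %s",
                 paste(utils::head(unmapped, 5), collapse = ", ")),
         call. = FALSE)
  }
  ev$disease <- map$disease[match(ev$medcode, map$medcode)]
  ev$token <- if (vocabulary_tag == "diseases") ev$disease else ev$medcode
  data.table::setorder(ev, patient_id, event_date, medcode)

  # truncation: keep the most recent max_len tokens per patient
  ev[, pos := seq_len(.N), by = "patient_id"]
  ev[, n_tok := .N, by = "patient_id"]
  ev <- ev[ev$n_tok >= 2L]
  ev <- ev[ev$pos > ev$n_tok - max_len]
  ev[, pos := seq_len(.N), by = "patient_id"]
  ev[, visit_index := as.integer(factor(event_date, levels = unique(event_date))),
     by = "patient_id"]

  birth <- records$birth_date[match(ev$patient_id, records$patient_id)]
  if (anyNA(birth)) {
    stop("events reference patient ids absent from the records table",
         call. = FALSE)
  }
  ev$age_years <- pmin(110L, pmax(0L, as.integer(
    floor(as.numeric(ev$event_date - birth) / 365.25))))
  ev$calendar_year <- as.integer(format(ev$event_date, "%Y"))

  dat <- ev[, c("patient_id", "pos", "token", "event_date", "visit_index",
                "age_years", "calendar_year")]
  structure(list(data = dat, vocabulary_tag = vocabulary_tag,
                 index_date = index_date, max_len = as.integer(max_len),
                 tie_rule = "event_date then medcode lexicographic"),
            class = "patient_sequences")
}

#' @export
print.patient_sequences <- function(x, ...) {
  np <- length(unique(x$data$patient_id))
  cat(sprintf("<patient_sequences> %d patients, vocabulary=%s, max_len=%d\n",
              np, x$vocabulary_tag, x$max_len))
  invisible(x)
}

#' Token lists per patient
#' @param sequences a `patient_sequences` object.
#' @return named list of character token vectors, ordered by position.
#' @export
sequence_list <- function(sequences) {
  stopifnot(inherits(sequences, "patient_sequences"))
  split(sequences$data$token, sequences$data$patient_id)
}

#' Eligible analysis cohort
#'
#' Keeps patients registered for at least one year before the index date,
#' alive and still registered at index, with a valid disease sequence
#' (at least 2 distinct disease categories in history).
#'
#' @param records patient records.
#' @param sequences disease-vocabulary `patient_sequences`.
#' @param index_date index date.
#' @return character vector of eligible patient ids.
#' @export
eligible_cohort <- function(records, sequences, index_date) {
  stopifnot(inherits(sequences, "patient_sequences"))
  if (sequences$vocabulary_tag != "diseases") {
    stop("eligibility requires the diseases-vocabulary sequences", call. = FALSE)
  }
  index_date <- as.Date(index_date)
  ndis <- sequences$data[, list(k = data.table::uniqueN(token)),
                         by = "patient_id"]
  valid_ids <- ndis$patient_id[ndis$k >= 2L]
  keep <- records$registration_date <= index_date - 365L &
    (is.na(records$death_date) | records$death_date >= index_date) &
    (is.na(records$deregistration_date) |
       records$deregistration_date >= index_date) &
    records$patient_id %in% valid_ids
  records$patient_id[keep]
}

# ---------------------------------------------------------------------------
# Serialization: JSON-lines for sequences, two-column TSV for vocabularies.

#' Write sequences as JSON-lines (one object per patient, parallel arrays)
#' @param sequences a `patient_sequences` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(sequences, path) {
  stopifnot(inherits(sequences, "patient_sequences"))
  sl <- split(sequences$data, sequences$data$patient_id)
  con <- file(path, "w")
  on.exit(close(con))
  header <- jsonlite::toJSON(list(
    vocabulary_tag = sequences$vocabulary_tag,
    index_date = format(sequences$index_date),
    max_len = sequences$max_len, tie_rule = sequences$tie_rule),
    auto_unbox = TRUE)
  writeLines(header, con)
  for (d in sl) {
    obj <- list(patient_id = d$patient_id[1], tokens = d$token,
                event_date = format(d$event_date),
                visit_index = d$visit_index, age_years = d$age_years,
                calendar_year = d$calendar_year)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read sequences written by [write_sequences()]
#' @param path JSON-lines file.
#' @return a `patient_sequences` object.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty sequence file", call. = FALSE)
  header <- jsonlite::fromJSON(lines[1])
  rows <- lapply(lines[-1], function(l) {
    o <- jsonlite::fromJSON(l)
    data.table::data.table(patient_id = o$patient_id,
                           pos = seq_along(o$tokens), token = o$tokens,
                           event_date = as.Date(o$event_date),
                           visit_index = as.integer(o$visit_index),
                           age_years = as.integer(o$age_years),
                           calendar_year = as.integer(o$calendar_year))
  })
  structure(list(data = data.table::rbindlist(rows),
                 vocabulary_tag = header$vocabulary_tag,
                 index_date = as.Date(header$index_date),
                 max_len = as.integer(header$max_len),
                 tie_rule = header$tie_rule),
            class = "patient_sequences")
}

#' Write / read a vocabulary as a two-column TSV
#' @param vocab vocabulary table.
#' @param path TSV path.
#' @return `path` / the vocabulary table.
#' @export
write_vocabulary <- function(vocab, path) {
  data.table::fwrite(vocab, path, sep = "\t")
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  v <- data.table::fread(path, sep = "\t")
  assert_columns(v, c("token", "index"), "vocabulary")
  v
}
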