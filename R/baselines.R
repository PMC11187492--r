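# Baseline (non-NLP) patient representations: binary disease indicators,
# disease frequency counts, and sociodemographic one-hot features.

#' Binary disease indicators
#'
#' One column per disease category; entry 1 iff the disease occurs at least
#' once in the patient's history sequence. Defined at category level only.
#'
#' @param sequences disease-vocabulary `patient_sequences`.
#' @param categories optional full category vocabulary (character); defaults
#'   to the categories observed in the sequences. Supplying the full
#'   vocabulary fixes the dimension at its size.
#' @return an `embedding_set` with dimension `length(categories)`.
#' @export
binary_indicators <- function(sequences, categories = NULL) {
  m <- disease_count_matrix(sequences, categories)
  embedding_set((m > 0) * 1, method = "binary_indicators",
                vocabulary_tag = "diseases")
}

#' Disease frequency counts
#'
#' One column per disease category; entry is the number of times the disease
#' appears in the patient's history. Row sums equal sequence length.
#'
#' @inheritParams binary_indicators
#' @return an `embedding_set`.
#' @export
frequency_counts <- function(sequences, categories = NULL) {
  m <- disease_count_matrix(sequences, categories)
  embedding_set(m, method = "frequency_counts", vocabulary_tag = "diseases")
}

disease_count_matrix <- function(sequences, categories = NULL) {
  stopifnot(inherits(sequences, "patient_sequences"))
  if (sequences$vocabulary_tag != "diseases") {
    stop("binary indicators and frequency counts are defined at disease-category level; pass diseases-vocabulary sequences",
         call. = FALSE)
  }
  d <- sequences$data
  if (is.null(categories)) categories <- sort(unique(d$token))
  ids <- unique(d$patient_id)
  tab <- d[, list(n = .N), by = c("patient_id", "token")]
  m <- matrix(0, length(ids), length(categories),
              dimnames = list(ids, categories))
  unknown <- setdiff(unique(tab$token), categories)
  if (length(unknown)) {
    stop(sprintf("sequence token(s) outside the category vocabulary: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")),
         call. = FALSE)
  }
  m[cbind(match(tab$patient_id, ids), match(tab$token, categories))] <- tab$n
  m
}

AGE_BAND_BREAKS <- c(18, 30, 40, 50, 60, 70, 80, Inf)
AGE_BAND_LABELS <- c("18-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")

#' Sociodemographic covariate features
#'
#' One-hot blocks for age band (18-29 ... 80+), gender, ethnicity (with an
#' explicit missing level) and IMD decile (with an explicit missing level).
#' Each categorical block sums to exactly 1 per patient; missing
#' sociodemographics are indicator levels, never dropped.
#'
#' @param records patient records.
#' @param index_date date at which age is computed.
#' @return numeric matrix with patient-id rownames.
#' @export
sociodemographic_features <- function(records, index_date) {
  index_date <- as.Date(index_date)
  age <- floor(as.numeric(index_date - as.Date(records$birth_date)) / 365.25)
  if (any(age < 18)) {
    stop(sprintf("%d patient(s) aged under 18 at index: the cohort is adults only",
                 sum(age < 18)), call. = FALSE)
  }
  band <- cut(age, AGE_BAND_BREAKS, labels = AGE_BAND_LABELS, right = FALSE)
  gender <- factor(records$gender, levels = c("female", "male", "indeterminate"))
  eth <- as.character(records$ethnicity)
  eth[is.na(eth)] <- "missing"
  eth <- factor(eth, levels = c("White", "South Asian", "Black", "Other",
                                "Mixed", "missing"))
  imd <- ifelse(is.na(records$imd_decile), "missing",
                as.character(records$imd_decile))
  imd <- factor(imd, levels = c(as.character(1:10), "missing"))

  one_hot <- function(f, prefix) {
    m <- stats::model.matrix(~ f - 1)
    colnames(m) <- paste0(prefix, "_", levels(f))
    m
  }
  out <- cbind(one_hot(band, "age"), one_hot(gender, "gender"),
               one_hot(eth, "ethnicity"), one_hot(imd, "imd"))
  rownames(out) <- records$patient_id
  out
}
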