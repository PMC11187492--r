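# EmbeddingSet: patient-id-indexed fixed-length real vectors with provenance.

#' Construct an embedding set
#'
#' @param matrix numeric matrix, one row per patient; rownames are patient
#'   ids.
#' @param method name of the generating method.
#' @param vocabulary_tag which vocabulary the inputs used.
#' @return object of class `embedding_set`.
#' @export
embedding_set <- function(matrix, method, vocabulary_tag = "diseases") {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  if (any(!is.finite(matrix))) stop("embeddings must be finite", call. = FALSE)
  structure(list(matrix = matrix, method = method,
                 vocabulary_tag = vocabulary_tag, dim = ncol(matrix)),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> method=%s, %d patients x %d dims (%s vocabulary)\n",
              x$method, nrow(x$matrix), x$dim, x$vocabulary_tag))
  invisible(x)
}

#' Write / read an embedding set as CSV (patient_id column + dense values)
#' @param es an `embedding_set`.
#' @param path CSV path.
#' @export
write_embeddings <- function(es, path) {
  stopifnot(inherits(es, "embedding_set"))
  dt <- data.table::data.table(patient_id = rownames(es$matrix))
  dt <- cbind(dt, data.table::as.data.table(es$matrix))
  attr_line <- sprintf("#method=%s;vocabulary=%s", es$method, es$vocabulary_tag)
  writeLines(attr_line, path)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  meta <- sub("^#", "", readLines(path, n = 1L))
  kv <- strsplit(strsplit(meta, ";")[[1]], "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  dt <- data.table::fread(path, skip = 1L)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$patient_id
  colnames(m) <- NULL
  embedding_set(m, method = meta[["method"]],
                vocabulary_tag = meta[["vocabulary"]])
}
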