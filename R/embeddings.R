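# Pre-trained word-embedding tables with explicit OOV and padding contracts.
# Row 1 of the matrix is always the reserved padding vector (all zeros);
# vocabulary tokens occupy rows 2..|V|.

#' Build an embedding table from a vocabulary and matrix
#'
#' @param vocab Character vector of tokens (lowercase recommended; lookups
#'   lowercase their input).
#' @param matrix Numeric matrix, one row per vocab token.
#' @param oov_policy How out-of-vocabulary tokens embed: `"zero"` (zero
#'   vector), `"mean"` (arithmetic mean of all non-pad rows) or
#'   `"hash_bucket"` (deterministic hash into the existing rows).
#' @return A `bt_embeddings` object with the pad vector at row 1.
#' @export
embedding_table <- function(vocab, matrix, oov_policy = c("zero", "mean", "hash_bucket")) {
  oov_policy <- match.arg(oov_policy)
  matrix <- as.matrix(matrix)
  if (length(vocab) != nrow(matrix)) abort("vocab length must equal matrix rows")
  if (!all(is.finite(matrix))) abort("embedding matrix contains non-finite values")
  dup <- duplicated(vocab)
  if (any(dup)) {
    warn(paste0(sum(dup), " duplicate token(s) in embedding vocab; keeping first occurrence"))
    matrix <- matrix[!dup, , drop = FALSE]
    vocab <- vocab[!dup]
  }
  full <- rbind(numeric(ncol(matrix)), matrix)
  rownames(full) <- NULL
  structure(
    list(vocab = setNames(seq_along(vocab) + 1L, vocab), matrix = full,
         dim = ncol(full), oov_policy = oov_policy,
         oov_vector = switch(oov_policy,
                             zero = numeric(ncol(full)),
                             mean = colMeans(matrix),
                             hash_bucket = NULL)),
    class = "bt_embeddings")
}

#' @export
print.bt_embeddings <- function(x, ...) {
  cat("<bt_embeddings> |V| = ", nrow(x$matrix), " (incl. pad), dim = ", x$dim,
      ", oov = ", x$oov_policy, "\n", sep = "")
  invisible(x)
}

#' Load word vectors from text format
#'
#' Reads the standard whitespace-delimited word-vector text format
#' (`token v1 ... vd` per row), with or without the `|V| d` count/dim header
#' line. Gzipped files are read transparently.
#'
#' @param path Path to the vector file (optionally `.gz`).
#' @param format `"auto"` detects a numeric two-field header;
#'   `"wordvec_text_with_header"` and `"wordvec_text_headerless"` force it.
#' @param oov_policy Passed to [embedding_table()].
#' @return A `bt_embeddings`; `|V|` is the row count plus one reserved pad
#'   row. Duplicate tokens keep their first occurrence with a warning;
#'   inconsistent dimensionality is an error naming the line.
#' @export
load_word_vectors <- function(path,
                              format = c("auto", "wordvec_text_with_header",
                                         "wordvec_text_headerless"),
                              oov_policy = "zero") {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("empty word-vector file")
  first <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  has_header <- switch(format,
    wordvec_text_with_header = TRUE,
    wordvec_text_headerless = FALSE,
    auto = length(first) == 2 && !anyNA(suppressWarnings(as.numeric(first))))
  offset <- if (has_header) 1L else 0L
  body <- lines[(offset + 1L):length(lines)]
  if (!length(body)) abort("word-vector file has a header but no rows")
  parts <- strsplit(trimws(body), "\\s+")
  d <- length(parts[[1]]) - 1L
  if (d < 1) abort(paste0("malformed word-vector row at line ", offset + 1L))
  vecs <- matrix(NA_real_, nrow = length(parts), ncol = d)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) - 1L != d) {
      abort(paste0("inconsistent dimensionality at line ", i + offset,
                   ": expected ", d, " values, found ", length(p) - 1L))
    }
    v <- suppressWarnings(as.numeric(p[-1]))
    if (anyNA(v)) abort(paste0("non-numeric vector component at line ", i + offset))
    vecs[i, ] <- v
  }
  tokens <- vapply(parts, `[[`, character(1), 1L)
  embedding_table(tokens, vecs, oov_policy = oov_policy)
}

#' Write an embedding table to word-vector text format
#'
#' @param table A `bt_embeddings`.
#' @param path Output path.
#' @param header Write the `|V| d` count/dim header line (pad row excluded
#'   from the count).
#' @return `path`, invisibly.
#' @export
write_word_vectors <- function(table, path, header = FALSE) {
  stopifnot(inherits(table, "bt_embeddings"))
  toks <- names(table$vocab)
  rows <- table$matrix[table$vocab, , drop = FALSE]
  lines <- vapply(seq_along(toks), function(i) {
    paste(toks[i], paste(sprintf("%.17g", rows[i, ]), collapse = " "))
  }, character(1))
  if (header) lines <- c(paste(length(toks), table$dim), lines)
  writeLines(lines, path)
  invisible(path)
}

token_rows <- function(table, tokens) {
  # pad = 1L; OOV resolved per policy (hash_bucket maps into real rows)
  if (!length(tokens)) return(integer())
  tokens <- tolower(tokens)
  idx <- unname(table$vocab[tokens])
  oov <- is.na(idx)
  if (any(oov)) {
    idx[oov] <- switch(table$oov_policy,
      zero = 0L,   # sentinel: embed as oov_vector (zeros)
      mean = -1L,  # sentinel: embed as mean vector
      hash_bucket = {
        h <- vapply(tokens[oov], function(t) {
          sum(utf8ToInt(t) * seq_along(utf8ToInt(t))) %% (nrow(table$matrix) - 1L)
        }, numeric(1))
        as.integer(h) + 2L
      })
  }
  idx
}

#' Embed a token sequence as a fixed-shape matrix
#'
#' Tokens are lowercased, looked up, truncated at `max_len` (keeping the
#' head) and padded at the tail with the zero pad vector, so the output is
#' always `max_len` x `dim`. OOV tokens follow the table's policy.
#'
#' @param table A `bt_embeddings`.
#' @param tokens Character vector of tokens.
#' @param max_len Output rows (default 300, the passage-length guidance under
#'   which these classifiers behave well).
#' @return A `max_len` x `dim` numeric matrix.
#' @export
embed_passage <- function(table, tokens, max_len = 300L) {
  stopifnot(inherits(table, "bt_embeddings"), max_len >= 1)
  out <- matrix(0, nrow = max_len, ncol = table$dim)
  tokens <- head(tokens, max_len)
  idx <- token_rows(table, tokens)
  real <- idx >= 1L
  if (any(real)) out[which(real), ] <- table$matrix[idx[real], , drop = FALSE]
  if (any(idx == -1L)) out[which(idx == -1L), ] <- rep(table$oov_vector, each = sum(idx == -1L))
  out
}

# Batch lookup: list of token vectors -> array (B, T, d) plus lengths.
# T is max_len, or with trim = TRUE the batch's longest sequence (never below
# min_len), which skips computation on all-pad tail columns.
embed_batch <- function(table, token_lists, max_len, trim = FALSE, min_len = 1L) {
  B <- length(token_lists)
  lens <- pmin(vapply(token_lists, length, integer(1)), max_len)
  T_used <- if (trim) max(min_len, min(max_len, max(lens, 1L))) else max_len
  arr <- array(0, dim = c(B, T_used, table$dim))
  for (b in seq_len(B)) {
    toks <- head(token_lists[[b]], T_used)
    if (length(toks)) {
      arr[b, seq_along(toks), ] <- embed_passage(table, toks, T_used)[seq_along(toks), , drop = FALSE]
    }
  }
  list(E = arr, lens = lens)
}
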