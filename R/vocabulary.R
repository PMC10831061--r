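#' Build a most-frequent-word vocabulary
#'
#' Ranks words by corpus frequency and keeps the `size` most frequent as the
#' input-cell inventory; every other word is mapped to a single
#' unknown-word ("UNK") cell appended after the in-vocabulary cells. With the
#' default `size = 3000` the vocabulary mirrors the standard configuration in
#' which 3000 cells code 3000 words and a 3001st cell codes all unknowns.
#' Frequency ties are broken by first occurrence in the corpus, so the
#' vocabulary is deterministic.
#'
#' Cell indices are 1-based: in-vocabulary words occupy cells `1..V` and the
#' UNK cell is `V + 1`.
#'
#' @param corpus A `cann_corpus` tibble (or any data frame with a `token`
#'   column).
#' @param size Requested vocabulary size V. If the corpus has fewer distinct
#'   words, all of them are kept (with a warning) and V shrinks accordingly.
#'
#' @return An object of class `cann_vocabulary` with fields `words`
#'   (character, length V), `unk_index` (`V + 1`) and `size` (V).
#' @export
build_vocabulary <- function(corpus, size = 3000L) {
  check_scalar_number(size, "size", 1)
  tokens <- corpus$token
  if (is.null(tokens) || length(tokens) == 0L) {
    abort("`corpus` must contain at least one token.")
  }
  first_seen <- match(unique(tokens), tokens)
  counts <- table(factor(tokens, levels = unique(tokens)))
  ord <- order(-as.integer(counts), first_seen)
  ranked <- unique(tokens)[ord]
  if (length(ranked) < size) {
    warn(sprintf(
      "Corpus has only %d distinct words; vocabulary shrunk from %d.",
      length(ranked), as.integer(size)))
    size <- length(ranked)
  }
  words <- ranked[seq_len(size)]
  structure(
    list(words = words, size = length(words),
         unk_index = length(words) + 1L,
         word_to_index = stats::setNames(seq_along(words), words)),
    class = "cann_vocabulary")
}

#' @export
print.cann_vocabulary <- function(x, ...) {
  cat(sprintf("<cann_vocabulary> V=%d words + UNK cell (index %d)\n",
              x$size, x$unk_index))
  cat("  head:", paste(utils::head(x$words, 8), collapse = " "), "...\n")
  invisible(x)
}

#' Map tokens to vocabulary cell indices
#'
#' @param tokens Character vector.
#' @param vocab A `cann_vocabulary`.
#' @return Integer cell indices in `1..V+1` (out-of-vocabulary tokens map to
#'   the UNK cell).
#' @export
word_codes <- function(tokens, vocab) {
  idx <- unname(vocab$word_to_index[tokens])
  idx[is.na(idx)] <- vocab$unk_index
  as.integer(idx)
}

#' Filter, truncate and encode sentences
#'
#' Applies the standard corpus filters ahead of training: sentences with fewer
#' than `min_length` tokens are excluded, sentences containing
#' `max_unknown + 1` or more out-of-vocabulary tokens are excluded, and
#' surviving sentences are truncated to their first `max_length` tokens.
#' Remaining tokens are encoded as vocabulary cell indices (out-of-vocabulary
#' tokens get the UNK cell). The operation is idempotent.
#'
#' @param corpus A `cann_corpus` tibble.
#' @param vocab A `cann_vocabulary`.
#' @param min_length Minimum sentence length kept (default 3).
#' @param max_unknown Maximum number of UNK tokens tolerated per sentence
#'   (default 3; sentences with 4 or more unknowns are dropped).
#' @param max_length Truncation length (default 16).
#'
#' @return The filtered corpus with an integer `code` column.
#' @export
filter_and_truncate <- function(corpus, vocab, min_length = 3L,
                                max_unknown = 3L, max_length = 16L) {
  stopifnot(inherits(vocab, "cann_vocabulary"))
  out <- corpus |>
    dplyr::mutate(code = word_codes(.data$token, vocab)) |>
    dplyr::group_by(.data$sentence) |>
    dplyr::filter(dplyr::n() >= min_length,
                  sum(.data$code == vocab$unk_index) <= max_unknown) |>
    dplyr::filter(dplyr::row_number() <= max_length) |>
    dplyr::ungroup()
  if (nrow(out) == 0L) {
    abort(sprintf(
      "No sentences survived filtering: every sentence was shorter than %d words or contained more than %d unknown words.",
      as.integer(min_length), as.integer(max_unknown)))
  }
  new_corpus(out)
}

#' One-hot input-cell activity for a vocabulary cell
#'
#' Returns the granule-layer activity pattern for one word: a vector of length
#' `V + 1` with 1 at the word's cell and 0 elsewhere. Distinct cells give
#' orthogonal patterns (cosine similarity 0), so the input code carries no
#' information about a word beyond its identity.
#'
#' @param code Cell index in `1..V+1`.
#' @param vocab A `cann_vocabulary` (or an integer giving `V + 1` directly).
#' @return A numeric vector of length `V + 1`.
#' @export
encode_one_hot <- function(code, vocab) {
  n <- if (inherits(vocab, "cann_vocabulary")) vocab$unk_index else as.integer(vocab)
  if (!is.numeric(code) || length(code) != 1L || is.na(code) ||
      code < 1L || code > n) {
    abort(sprintf("`code` must be a single index in 1..%d.", n))
  }
  v <- numeric(n)
  v[as.integer(code)] <- 1
  v
}

#' Split a corpus into training and validation sentences
#'
#' Seeded uniform random partition at the sentence level; by default 90% of
#' sentences train the circuit and the held-out 10% monitor prediction
#' performance.
#'
#' @param corpus An encoded `cann_corpus` (see [filter_and_truncate()]).
#' @param fraction Training fraction in (0, 1); default 0.9.
#' @param seed Integer seed; the same seed reproduces the same partition.
#'
#' @return An object of class `corpus_split`: a list with `train` and
#'   `validation` corpora (disjoint sentence sets) and the `seed`.
#' @export
split_train_validation <- function(corpus, fraction = 0.9, seed = 1L) {
  check_scalar_number(fraction, "fraction", 0, 1)
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  ids <- unique(corpus$sentence)
  n_train <- round(length(ids) * fraction)
  train_ids <- with_seed(seed, sample(ids, n_train))
  structure(
    list(train = new_corpus(dplyr::filter(corpus, .data$sentence %in% train_ids)),
         validation = new_corpus(dplyr::filter(corpus, !(.data$sentence %in% train_ids))),
         seed = seed),
    class = "corpus_split")
}

#' @export
print.corpus_split <- function(x, ...) {
  cat(sprintf("<corpus_split> %d train / %d validation sentences (seed %s)\n",
              dplyr::n_distinct(x$train$sentence),
              dplyr::n_distinct(x$validation$sentence),
              format(x$seed)))
  invisible(x)
}

# Internal: corpus tibble -> list of per-sentence integer code vectors
# (plus parallel role/type/token lists when present).
sentence_list <- function(corpus, what = "code") {
  if (is.null(corpus[[what]])) {
    abort(sprintf("Corpus has no `%s` column; run filter_and_truncate() first.", what))
  }
  unname(split(corpus[[what]], corpus$sentence))
}
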