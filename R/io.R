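#' Tokenize raw sentence lines
#'
#' Minimal whitespace tokenizer for plain-text corpora (one sentence per
#' line): lowercases, splits terminal punctuation off words and, by default,
#' drops pure punctuation tokens, since syntactic role labels apply to words.
#'
#' @param lines Character vector of sentences.
#' @param lowercase Lowercase all tokens (default TRUE).
#' @param strip_punctuation Drop punctuation-only tokens (default TRUE).
#' @return A `cann_corpus` tibble with `role = "unlabeled"`, `type = "other"`.
#' @export
tokenize_sentences <- function(lines, lowercase = TRUE,
                               strip_punctuation = TRUE) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("No non-empty sentences to tokenize.")
  if (lowercase) lines <- tolower(lines)
  lines <- gsub("([[:alnum:]])([.,;:!?\"')]+)", "\\1 \\2", lines)
  lines <- gsub("([(\"'])([[:alnum:]])", "\\1 \\2", lines)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  if (strip_punctuation) {
    toks <- lapply(toks, function(x) x[grepl("[[:alnum:]]", x)])
  }
  keep <- lengths(toks) > 0L
  toks <- toks[keep]
  new_corpus(tibble(
    sentence = rep(seq_along(toks), lengths(toks)),
    position = unlist(lapply(toks, seq_along), use.names = FALSE),
    token = unlist(toks, use.names = FALSE),
    role = "unlabeled", type = "other"))
}

#' Read a plain-text corpus (one sentence per line)
#'
#' @param path Path to a UTF-8 text file.
#' @inheritParams tokenize_sentences
#' @return A `cann_corpus` tibble.
#' @export
read_sentences <- function(path, lowercase = TRUE, strip_punctuation = TRUE) {
  tokenize_sentences(readLines(path, encoding = "UTF-8", warn = FALSE),
                     lowercase = lowercase,
                     strip_punctuation = strip_punctuation)
}

#' Read role-annotated evaluation sentences
#'
#' Parses sentences given one per line with tokens as `word/ROLE` or
#' `word/ROLE/TYPE` (for example `man/S/noun will/other/other sail/V/verb`).
#' A missing TYPE field is tolerated and recorded as `"other"`.
#'
#' @param path Path to the annotation file.
#' @return A `cann_corpus` tibble with `role` and `type` columns.
#' @export
read_labeled_sentences <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("No annotated sentences found.")
  parse_tok <- function(x) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      abort(sprintf("Malformed annotated token '%s' (expected word/ROLE[/TYPE]).", x))
    }
    c(word = parts[1], role = parts[2],
      type = if (length(parts) >= 3L) parts[3] else "other")
  }
  rows <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    parsed <- vapply(toks, parse_tok, character(3))
    tibble(sentence = i, position = seq_along(toks),
           token = unname(parsed["word", ]),
           role = unname(parsed["role", ]),
           type = unname(parsed["type", ]))
  })
  new_corpus(dplyr::bind_rows(rows))
}

#' Write role-annotated sentences
#'
#' Inverse of [read_labeled_sentences()]: one sentence per line, tokens as
#' `word/ROLE/TYPE`.
#'
#' @param corpus A labelled `cann_corpus`.
#' @param path Output file path.
#' @export
write_labeled_sentences <- function(corpus, path) {
  lines <- corpus |>
    dplyr::group_by(.data$sentence) |>
    dplyr::summarise(line = paste(sprintf("%s/%s/%s", .data$token, .data$role,
                                          .data$type), collapse = " "),
                     .groups = "drop")
  writeLines(lines$line, path, useBytes = TRUE)
  invisible(path)
}

#' Persist a vocabulary as a two-column text file
#'
#' Writes `index<TAB>word` lines covering cells `1..V` plus the UNK cell
#' (written as `<UNK>`), and reads them back.
#'
#' @param vocab A `cann_vocabulary`.
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(c(sprintf("%d\t%s", seq_along(vocab$words), vocab$words),
               sprintf("%d\t<UNK>", vocab$unk_index)),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           col.names = c("index", "word"),
                           stringsAsFactors = FALSE, quote = "")
  tab <- tab[order(tab$index), ]
  words <- tab$word[tab$word != "<UNK>"]
  structure(
    list(words = words, size = length(words), unk_index = length(words) + 1L,
         word_to_index = stats::setNames(seq_along(words), words)),
    class = "cann_vocabulary")
}
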