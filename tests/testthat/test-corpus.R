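toy_corpus <- function(sentences) {
  toks <- strsplit(sentences, " ", fixed = TRUE)
  cann:::new_corpus(tibble::tibble(
    sentence = rep(seq_along(toks), lengths(toks)),
    position = unlist(lapply(toks, seq_along)),
    token = unlist(toks), role = "unlabeled", type = "other"))
}

test_that("vocabulary keeps the most frequent words and appends an UNK cell", {
  vocab <- build_vocabulary(toy_corpus("a b a c a b"), size = 2)
  expect_equal(vocab$words, c("a", "b"))
  expect_equal(vocab$unk_index, 3L)
  expect_equal(unname(vocab$word_to_index[c("a", "b")]), c(1L, 2L))
})

test_that("frequency ties break by first occurrence and small corpora shrink V", {
  vocab <- build_vocabulary(toy_corpus("b a b a"), size = 2)
  expect_equal(vocab$words, c("b", "a"))
  expect_warning(v2 <- build_vocabulary(toy_corpus("x y x"), size = 5),
                 "shrunk")
  expect_equal(v2$size, 2L)
  expect_equal(v2$unk_index, 3L)
})

test_that("filtering drops short and unknown-heavy sentences and truncates at 16", {
  vocab <- suppressWarnings(
    build_vocabulary(toy_corpus("the man will sail the boat"), size = 10))
  # 2-token sentence fails the <3-word filter
  enc <- filter_and_truncate(
    toy_corpus(c("the man", "the man will sail the boat")), vocab)
  expect_equal(unique(enc$sentence), 2L)
  # 20-token sentence is truncated to its first 16 words
  long <- toy_corpus(paste(rep("the man will sail", 5), collapse = " "))
  expect_equal(nrow(filter_and_truncate(long, vocab)), 16L)
  # exactly 4 unknowns excluded, 3 unknowns retained
  oov4 <- toy_corpus("the man will sail q1 q2 q3 q4 the boat")
  oov3 <- toy_corpus("the man will sail q1 q2 q3 the boat")
  expect_error(filter_and_truncate(oov4, vocab), "No sentences survived")
  kept <- filter_and_truncate(oov3, vocab)
  expect_equal(nrow(kept), 9L)
  expect_equal(sum(kept$code == vocab$unk_index), 3L)
})

test_that("filtering is idempotent and codes stay in range", {
  cx <- small_corpus_fixture()
  once <- filter_and_truncate(cx$corpus, cx$vocab)
  twice <- filter_and_truncate(once, cx$vocab)
  expect_identical(as.data.frame(once), as.data.frame(twice))
  expect_true(all(once$code >= 1 & once$code <= cx$vocab$unk_index))
})

test_that("one-hot codes form an orthonormal, information-free set", {
  vocab <- build_vocabulary(toy_corpus("a b c"), size = 3)
  expect_equal(encode_one_hot(1, vocab), c(1, 0, 0, 0))
  expect_equal(encode_one_hot(4, vocab), c(0, 0, 0, 1))  # UNK cell
  vs <- lapply(1:4, encode_one_hot, vocab = vocab)
  for (i in 1:4) for (j in 1:4) {
    expect_identical(sum(vs[[i]] * vs[[j]]), as.numeric(i == j))
  }
  expect_error(encode_one_hot(5, vocab), "1..4")
  expect_error(encode_one_hot(0, vocab), "1..4")
})

test_that("train/validation split is seeded, sized and disjoint", {
  cx <- small_corpus_fixture()
  s1 <- split_train_validation(cx$enc, 0.9, seed = 5)
  s2 <- split_train_validation(cx$enc, 0.9, seed = 5)
  s3 <- split_train_validation(cx$enc, 0.9, seed = 6)
  n <- length(unique(cx$enc$sentence))
  expect_equal(length(unique(s1$train$sentence)), round(0.9 * n))
  expect_length(intersect(unique(s1$train$sentence),
                          unique(s1$validation$sentence)), 0)
  expect_identical(as.data.frame(s1$train), as.data.frame(s2$train))
  expect_false(identical(sort(unique(s1$train$sentence)),
                         sort(unique(s3$train$sentence))))
  expect_error(split_train_validation(cx$enc, 1.2), "single finite number")
})

test_that("synthetic corpora are reproducible and respect length bounds", {
  g <- grammar_spec()
  c1 <- generate_synthetic_corpus(g, 60, seed = 9)
  c2 <- generate_synthetic_corpus(g, 60, seed = 9)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  lens <- table(c1$sentence)
  expect_true(all(lens >= 3 & lens <= 16))
})

test_that("a single-production grammar yields fixed role patterns", {
  g <- grammar_spec(subject_forms = c(pronoun = 0, det_noun = 1,
                                      det_adj_noun = 0),
                    predicate_forms = c(transitive = 1, verb_pp = 0,
                                        be_adj = 0),
                    object_forms = c(pronoun = 0, noun = 0, det_noun = 1,
                                     det_adj_noun = 0),
                    subject_pp_prob = 0, pp_prob = 0)
  corpus <- generate_synthetic_corpus(g, 20, seed = 3)
  roles <- split(corpus$role, corpus$sentence)
  for (r in roles) expect_equal(r, c("S", "S", "V", "O", "O"))
})

test_that("role sharing reuses nouns across subject and object heads", {
  # homograph-free verb list so noun role sets are exactly {S, O}
  g <- grammar_spec(role_sharing = 1.0,
                    predicate_forms = c(transitive = 1, verb_pp = 0,
                                        be_adj = 0),
                    subject_pp_prob = 0, pp_prob = 0,
                    verb_object_affinity = 0,
                    lexicon = list(verbs = c("sees", "takes", "finds"),
                                   nouns = c("man", "dog", "bird", "boat")))
  corpus <- generate_synthetic_corpus(g, 1000, seed = 5)
  heads <- corpus[corpus$type == "noun" & corpus$role %in% c("S", "O"), ]
  role_sets <- tapply(heads$role, heads$token, function(x) sort(unique(x)))
  for (rs in role_sets) expect_equal(rs, c("O", "S"))
  # with partial sharing at least one noun still appears in both head roles
  corpus2 <- generate_synthetic_corpus(grammar_spec(role_sharing = 0.5),
                                       500, seed = 6)
  heads2 <- corpus2[corpus2$type == "noun" & corpus2$role %in% c("S", "O"), ]
  sets2 <- tapply(heads2$role, heads2$token, function(x) length(unique(x)))
  expect_true(any(sets2 == 2))
})

test_that("unigram skew produces rank-ordered word frequencies", {
  g <- grammar_spec(skew = 1.5, verb_object_affinity = 0)
  corpus <- generate_synthetic_corpus(g, 3000, seed = 8)
  dets <- table(factor(corpus$token[corpus$type == "determiner"],
                       levels = g$lexicon$determiners))
  expect_true(all(diff(as.integer(dets)) <= 0))
  expect_gt(dets[1] / sum(dets), 1 / length(dets))
})

test_that("an unproducible grammar is rejected", {
  expect_error(grammar_spec(lexicon = list(verbs = character(0),
                                           be_verbs = character(0))),
               "at least 3 tokens")
  expect_error(grammar_spec(subject_forms = c(pronoun = 0.5, det_noun = 0.2,
                                              det_adj_noun = 0.2)),
               "sum to 1")
})

test_that("annotated sentences round-trip through the word/ROLE/TYPE format", {
  corpus <- generate_synthetic_corpus(grammar_spec(), 15, seed = 12)
  path <- withr::local_tempfile(fileext = ".txt")
  write_labeled_sentences(corpus, path)
  back <- read_labeled_sentences(path)
  expect_equal(back$token, corpus$token)
  expect_equal(back$role, corpus$role)
  expect_equal(back$type, corpus$type)
  # missing TYPE field tolerated
  writeLines("man/S will/other sail/V", path)
  two <- read_labeled_sentences(path)
  expect_equal(two$type, rep("other", 3))
  expect_equal(two$role, c("S", "other", "V"))
})

test_that("the tokenizer lowercases and strips terminal punctuation", {
  corpus <- tokenize_sentences(c("The man sails.", "Stop!"))
  expect_equal(corpus$token[corpus$sentence == 1], c("the", "man", "sails"))
  expect_equal(corpus$token[corpus$sentence == 2], "stop")
})

test_that("vocabulary files round-trip", {
  cx <- small_corpus_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(cx$vocab, path)
  back <- read_vocabulary(path)
  expect_identical(back$words, cx$vocab$words)
  expect_identical(back$unk_index, cx$vocab$unk_index)
})
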