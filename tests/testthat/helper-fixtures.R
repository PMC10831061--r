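`%||%` <- function(x, y) if (is.null(x)) y else x

# Shared fixtures, built once per test session and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small labelled corpus + encoded split shared across files.
small_corpus_fixture <- function() {
  fixture("small_corpus", function() {
    corpus <- generate_synthetic_corpus(grammar_spec(), 500, seed = 42)
    vocab <- build_vocabulary(corpus, 100)
    enc <- filter_and_truncate(corpus, vocab)
    split <- split_train_validation(enc, 0.9, seed = 43)
    evalc <- filter_and_truncate(
      generate_synthetic_corpus(grammar_spec(), 80, seed = 941), vocab)
    list(corpus = corpus, vocab = vocab, enc = enc, split = split,
         evalc = evalc)
  })
}

# A briefly trained circuit (original variant) for probing tests.
trained_fixture <- function() {
  fixture("trained_small", function() {
    cx <- small_corpus_fixture()
    circuit <- build_circuit(n_input = cx$vocab$unk_index, n_purkinje = 48,
                             seed = 44)
    fit <- train_cann(circuit, cx$split,
                      train_config(epochs = 4, seed = 45), cx$vocab)
    c(cx, list(fit = fit))
  })
}

# Study-scale pair of trained circuits (excitatory/inhibitory-split and
# unconstrained) for synaptic weight-distribution comparisons; the silent-
# synapse peak only builds up over a full-length training run.
weight_study_fixture <- function() {
  fixture("weight_study", function() {
    corpus <- generate_synthetic_corpus(grammar_spec(), 2000, seed = 101)
    vocab <- build_vocabulary(corpus, 100)
    split <- split_train_validation(filter_and_truncate(corpus, vocab), 0.9,
                                    seed = 102)
    cfg <- train_config(epochs = 8, seed = 104)
    ei <- train_cann(build_circuit(vocab$unk_index, n_purkinje = 96,
                                   variant = "ei-split-input", seed = 103),
                     split, cfg, vocab)
    plain <- train_cann(build_circuit(vocab$unk_index, n_purkinje = 96,
                                      seed = 103),
                        split, cfg, vocab)
    list(ei = ei, plain = plain, vocab = vocab, split = split)
  })
}

# Study-scale convergent bank with a step-level gating audit; shared by the
# convergent behaviour tests and the gating-exclusivity audit.
convergent_fixture <- function() {
  fixture("convergent_study", function() {
    corpus <- generate_synthetic_corpus(grammar_spec(), 1200, seed = 42)
    vocab <- build_vocabulary(corpus, 100)
    enc <- filter_and_truncate(corpus, vocab)
    split <- split_train_validation(enc, 0.9, seed = 43)
    evalc <- filter_and_truncate(
      generate_synthetic_corpus(grammar_spec(), 100, seed = 941), vocab)
    emb <- build_embedding(vocab, split$train,
                           source = "synthetic-cooccurrence", seed = 50)
    bank <- build_module_bank(vocab, emb, n_modules = 10, n_purkinje = 64,
                              seed = 51)
    cf <- train_convergent(bank, split,
                           train_config(learning_rate = 0.05, epochs = 4,
                                        seed = 52),
                           audit = TRUE)
    list(vocab = vocab, enc = enc, split = split, evalc = evalc,
         bank = bank, cf = cf)
  })
}

# A toy circuit + sentence for gradient checks.
toy_setup <- function(variant = "original", seed = 7) {
  circuit <- build_circuit(n_input = 7, n_purkinje = 4, variant = variant,
                           seed = seed,
                           n_rec_out = if (variant == "rec-compress") 3,
                           n_rec_in = if (variant == "rec-compress") 4)
  list(circuit = circuit, codes = c(2L, 5L, 1L, 7L, 3L))
}

# Central finite-difference gradient of the summed sentence loss with
# respect to one weight field; the oracle against backpropagation.
fd_gradient <- function(circuit, codes, field, eps = 1e-6) {
  w <- circuit[[field]]
  g <- array(0, dim = dim(w) %||% length(w))
  loss_at <- function(cc) compute_gradients(cc, codes)$loss
  for (i in seq_along(w)) {
    cp <- circuit; cp[[field]][i] <- w[i] + eps
    cm <- circuit; cm[[field]][i] <- w[i] - eps
    g[i] <- (loss_at(cp) - loss_at(cm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-8)
}

# Wrap a plain matrix + role labels as an activity_matrix (each row its own
# sentence, so SVM splits act per row).
as_activity <- function(values, roles, layer = "purkinje",
                        sentences = seq_along(roles)) {
  structure(list(
    values = values,
    labels = tibble::tibble(sentence = sentences,
                            position = 1L, token = "x", role = roles,
                            type = "other", code = 1L),
    layer = layer), class = "activity_matrix")
}

# Unigram top-5 baseline: share of non-UNK targets among the 5 most frequent
# training words.
unigram_top5_baseline <- function(split, vocab) {
  top5 <- as.integer(names(sort(table(split$train$code),
                                decreasing = TRUE))[1:5])
  targets <- unlist(lapply(sentence_targets(split$validation), identity))
  targets <- targets[targets != vocab$unk_index]
  100 * mean(targets %in% top5)
}

# All prediction targets (2nd..last token of each sentence) of a corpus.
sentence_targets <- function(corpus) {
  lapply(unname(split(corpus$code, corpus$sentence)), function(x) x[-1])
}
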