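#' Specify a labelled synthetic S-V-O grammar
#'
#' Defines a small probabilistic grammar that emulates the statistics the
#' circuit is trained on in practice: subject-verb-object sentences of 3--16
#' words with determiners, adjectives, optional prepositional phrases and
#' pronoun arguments, skewed (Zipf-like) word frequencies, and content nouns
#' reused across subject and object positions. Because every token carries its
#' syntactic role (S/V/O/other) and word-type tag, corpora drawn from the
#' grammar support the full probing pipeline without any external download.
#'
#' Role labels are phrase-wise: every token of a subject phrase (determiner,
#' adjective, head noun or pronoun) is labelled `S`, verb and be-verb tokens
#' `V`, every token of an object phrase `O`; prepositional-phrase tokens and
#' predicate adjectives are labelled `other`.
#'
#' @param role_sharing Fraction of nouns usable as both subject and object
#'   heads, in `[0, 1]`. Default 0.8, so that word identity alone cannot
#'   classify S from O (the shared nouns appear in both roles).
#' @param skew Zipf exponent for within-category word sampling; sampling
#'   weights are `rank^-skew` in lexicon order. 0 gives uniform frequencies.
#' @param subject_forms Named probabilities for `pronoun`, `det_noun` and
#'   `det_adj_noun` subject shapes (must sum to 1).
#' @param object_forms Named probabilities for `pronoun`, `noun` (bare
#'   mass/plural object), `det_noun` and `det_adj_noun` object shapes (must
#'   sum to 1).
#' @param predicate_forms Named probabilities for `transitive` (verb + object
#'   phrase), `verb_pp` (verb + prepositional phrase, no object) and `be_adj`
#'   (be-verb + predicate adjective); must sum to 1.
#' @param subject_pp_prob Probability of a prepositional phrase attached to
#'   the subject ("the man near the river sees ..."), labelled `other`. This
#'   and the overlap of continuations it creates (a noun may be followed by a
#'   verb, a preposition or the sentence end, whatever its role) keep the
#'   next-word task from being position-trivial.
#' @param pp_prob Probability of appending a sentence-final prepositional
#'   phrase (`preposition determiner noun`, labelled `other`).
#' @param verb_object_affinity Probability that a transitive verb's object
#'   head noun is drawn from that verb's small preferred-noun set rather than
#'   from the whole object pool. Nonzero affinity gives context real
#'   predictive value for object nouns (as with "sail the boat"), so blocking
#'   the recurrent pathway selectively degrades noun-after-verb prediction.
#' @param affinity_breadth Number of preferred object nouns per verb.
#' @param lexicon Optional named list overriding any of the default word
#'   lists: `determiners`, `adjectives`, `nouns`, `verbs`, `prepositions`,
#'   `subject_pronouns`, `object_pronouns`, `be_verbs`. Note the default verb
#'   list deliberately contains noun homographs (e.g. "fish", "ship"), so the
#'   one-hot input code of those tokens is role-ambiguous.
#' @param max_length Maximum sentence length the grammar may emit (tokens).
#'
#' @return An object of class `cann_grammar`.
#' @seealso [generate_synthetic_corpus()]
#' @export
grammar_spec <- function(role_sharing = 0.8,
                         skew = 1.0,
                         subject_forms = c(pronoun = 0.25, det_noun = 0.40,
                                           det_adj_noun = 0.35),
                         predicate_forms = c(transitive = 0.70,
                                             verb_pp = 0.15, be_adj = 0.15),
                         object_forms = c(pronoun = 0.15, noun = 0.15,
                                          det_noun = 0.35,
                                          det_adj_noun = 0.35),
                         subject_pp_prob = 0.15,
                         pp_prob = 0.30,
                         verb_object_affinity = 0.5,
                         affinity_breadth = 6L,
                         lexicon = list(),
                         max_length = 16L) {
  check_scalar_number(role_sharing, "role_sharing", 0, 1)
  check_scalar_number(skew, "skew", 0, Inf)
  check_scalar_number(pp_prob, "pp_prob", 0, 1)
  check_scalar_number(subject_pp_prob, "subject_pp_prob", 0, 1)
  check_scalar_number(verb_object_affinity, "verb_object_affinity", 0, 1)
  check_scalar_number(affinity_breadth, "affinity_breadth", 1)
  default_lexicon <- list(
    determiners = c("the", "a", "this", "that"),
    adjectives = c("old", "young", "small", "big", "quick", "quiet", "bright",
                   "dark", "gentle", "fierce", "happy", "tired", "clever",
                   "strange", "little"),
    nouns = c("man", "woman", "child", "dog", "cat", "bird", "fish", "boat",
              "book", "gate", "river", "house", "tree", "garden", "road",
              "city", "farmer", "teacher", "sailor", "doctor", "king",
              "queen", "soldier", "horse", "sheep", "wolf", "fox", "rabbit",
              "mouse", "lion", "table", "chair", "window", "door", "letter",
              "song", "story", "picture", "stone", "flower", "bread",
              "apple", "ship", "wagon", "field", "forest", "mountain",
              "lake", "village", "market"),
    # several verb forms are noun homographs (fish, ship, boat, ...), as in
    # natural corpora, so word identity alone cannot tag every V token
    verbs = c("sees", "fish", "takes", "finds", "ship", "holds", "carries",
              "boat", "follows", "watches", "house", "chases", "catches",
              "dog", "loves", "helps", "picture", "calls", "leads", "garden",
              "pushes", "pulls", "market", "reads", "opens"),
    prepositions = c("in", "on", "near", "under", "behind"),
    subject_pronouns = c("he", "she", "they", "we"),
    object_pronouns = c("him", "her", "them", "us"),
    be_verbs = c("is", "are", "was", "were")
  )
  if (length(lexicon)) {
    bad <- setdiff(names(lexicon), names(default_lexicon))
    if (length(bad)) abort(paste0("Unknown lexicon categories: ",
                                  paste(bad, collapse = ", ")))
    default_lexicon[names(lexicon)] <- lexicon
  }
  for (probs in list(subject_forms, predicate_forms, object_forms)) {
    if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
      abort("Production probabilities must be nonnegative and sum to 1.")
    }
  }
  spec <- structure(
    list(lexicon = default_lexicon,
         role_sharing = role_sharing,
         skew = skew,
         subject_forms = subject_forms,
         predicate_forms = predicate_forms,
         object_forms = object_forms,
         subject_pp_prob = subject_pp_prob,
         pp_prob = pp_prob,
         verb_object_affinity = verb_object_affinity,
         affinity_breadth = as.integer(affinity_breadth),
         max_length = as.integer(max_length)),
    class = "cann_grammar")
  validate_grammar(spec)
  spec
}

# Fails when no production path yields a sentence of length in [3, max_length].
validate_grammar <- function(spec) {
  lex <- spec$lexicon
  have <- function(...) all(lengths(lex[c(...)]) > 0)
  prob <- function(forms, nm) {
    isTRUE(forms[nm] > 0)
  }
  np_mins <- function(forms, pronoun_cat) {
    lens <- c(
      if (prob(forms, "pronoun") && have(pronoun_cat)) 1,
      if (prob(forms, "noun") && have("nouns")) 1,
      if (prob(forms, "det_noun") && have("determiners", "nouns")) 2,
      if (prob(forms, "det_adj_noun") &&
          have("determiners", "adjectives", "nouns")) 3)
    if (length(lens)) min(lens) else NULL
  }
  subj_min <- np_mins(spec$subject_forms, "subject_pronouns")
  obj_min <- np_mins(spec$object_forms, "object_pronouns")
  pred_min <- min(c(
    if (prob(spec$predicate_forms, "transitive") && have("verbs") &&
        !is.null(obj_min)) 1 + obj_min,
    if (prob(spec$predicate_forms, "verb_pp") &&
        have("verbs", "prepositions", "determiners", "nouns")) 4,
    if (prob(spec$predicate_forms, "be_adj") &&
        have("be_verbs", "adjectives")) 2,
    Inf))
  if (is.null(subj_min) || !is.finite(pred_min)) {
    abort("Grammar cannot produce any sentence of at least 3 tokens: a subject and a predicate form with positive probability and non-empty lexicons are required.")
  }
  if (subj_min + pred_min > spec$max_length) {
    abort("Grammar cannot produce a sentence within the maximum length.")
  }
  invisible(spec)
}

#' @export
print.cann_grammar <- function(x, ...) {
  sizes <- vapply(x$lexicon, length, integer(1))
  cat("<cann_grammar>\n")
  cat("  lexicon:", sum(sizes), "words (",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), ")\n")
  cat(sprintf("  role_sharing=%.2f skew=%.2f pp_prob=%.2f max_length=%d\n",
              x$role_sharing, x$skew, x$pp_prob, x$max_length))
  invisible(x)
}

# Zipf-weighted sampler over a word list (weights rank^-skew in list order).
sample_word <- function(words, skew, pool = seq_along(words)) {
  w <- pool^(-skew)
  if (length(pool) == 1L) return(words[pool])
  words[sample(pool, 1L, prob = w)]
}

noun_pools <- function(spec) {
  n <- length(spec$lexicon$nouns)
  n_shared <- round(spec$role_sharing * n)
  rest <- setdiff(seq_len(n), seq_len(n_shared))
  half <- length(rest) %/% 2L
  list(subject = sort(c(seq_len(n_shared), rest[seq_len(half)])),
       object = sort(c(seq_len(n_shared),
                       rest[setdiff(seq_along(rest), seq_len(half))])))
}

#' Sample a labelled corpus from a synthetic grammar
#'
#' Draws `n` sentences from a [grammar_spec()] under a fixed seed. The result
#' is a token-level tibble (one row per token) with phrase-wise syntactic role
#' labels and word-type tags, ready for [build_vocabulary()] and
#' [filter_and_truncate()].
#'
#' @param spec A `cann_grammar` from [grammar_spec()].
#' @param n Number of sentences.
#' @param seed Integer seed; corpora are bit-reproducible given the seed.
#'
#' @return A tibble of class `cann_corpus` with columns `sentence`, `position`,
#'   `token`, `role` (one of `"S"`, `"V"`, `"O"`, `"other"`) and `type` (one of
#'   `"determiner"`, `"adjective"`, `"noun"`, `"verb"`, `"be-verb"`,
#'   `"preposition"`, `"object-pronoun"`, `"other"`).
#' @export
generate_synthetic_corpus <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "cann_grammar"))
  validate_grammar(spec)
  check_scalar_number(n, "n", 1)
  lex <- spec$lexicon
  pools <- noun_pools(spec)
  with_seed(seed, {
    sentences <- vector("list", n)
    for (s in seq_len(n)) {
      tok <- character(0); role <- character(0); type <- character(0)
      add <- function(w, r, ty) {
        tok <<- c(tok, w); role <<- c(role, r); type <<- c(type, ty)
      }
      noun_phrase <- function(form, r, pool) {
        if (form == "pronoun") {
          if (r == "S") add(sample_word(lex$subject_pronouns, spec$skew), r, "other")
          else add(sample_word(lex$object_pronouns, spec$skew), r, "object-pronoun")
        } else {
          if (form != "noun") {
            add(sample_word(lex$determiners, spec$skew), r, "determiner")
            if (form == "det_adj_noun") add(sample_word(lex$adjectives, spec$skew), r, "adjective")
          }
          add(sample_word(lex$nouns, spec$skew, pool), r, "noun")
        }
      }
      prep_phrase <- function() {
        add(sample_word(lex$prepositions, spec$skew), "other", "preposition")
        add(sample_word(lex$determiners, spec$skew), "other", "determiner")
        add(sample_word(lex$nouns, spec$skew), "other", "noun")
      }
      sform <- sample(names(spec$subject_forms), 1L, prob = spec$subject_forms)
      noun_phrase(sform, "S", pools$subject)
      if (sform != "pronoun" && length(lex$prepositions) > 0 &&
          stats::runif(1) < spec$subject_pp_prob) {
        prep_phrase()
      }
      pform <- sample(names(spec$predicate_forms), 1L, prob = spec$predicate_forms)
      if (pform == "transitive") {
        vi <- sample(seq_along(lex$verbs), 1L,
                     prob = seq_along(lex$verbs)^(-spec$skew))
        add(lex$verbs[vi], "V", "verb")
        oform <- sample(names(spec$object_forms), 1L, prob = spec$object_forms)
        obj_pool <- pools$object
        if (oform != "pronoun" &&
            stats::runif(1) < spec$verb_object_affinity) {
          pref <- ((vi - 1L) * 3L + seq_len(spec$affinity_breadth) - 1L) %%
            length(lex$nouns) + 1L
          pref <- intersect(pref, pools$object)
          if (length(pref)) obj_pool <- pref
        }
        noun_phrase(oform, "O", obj_pool)
      } else if (pform == "verb_pp") {
        add(sample_word(lex$verbs, spec$skew), "V", "verb")
        prep_phrase()
      } else {
        add(sample_word(lex$be_verbs, spec$skew), "V", "be-verb")
        add(sample_word(lex$adjectives, spec$skew), "other", "adjective")
      }
      if (pform == "transitive" && stats::runif(1) < spec$pp_prob &&
          length(tok) + 3L <= spec$max_length &&
          length(lex$prepositions) > 0) {
        prep_phrase()
      }
      sentences[[s]] <- tibble(sentence = s, position = seq_along(tok),
                               token = tok, role = role, type = type)
    }
    new_corpus(dplyr::bind_rows(sentences))
  })
}

new_corpus <- function(tbl) {
  structure(tbl, class = c("cann_corpus", class(tibble())))
}

#' @export
print.cann_corpus <- function(x, ...) {
  cat(sprintf("<cann_corpus> %d sentences, %d tokens\n",
              dplyr::n_distinct(x$sentence), nrow(x)))
  NextMethod()
}
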