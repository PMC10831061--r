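#' Default experiment configuration
#'
#' The configuration tree consumed by [run_experiment()] and the `cann`
#' command-line script. Defaults describe the package's reference synthetic
#' experiment: a 2000-sentence S-V-O corpus over a ~120-word lexicon, a
#' 96-Purkinje-cell circuit, 8 training laps with plain SGD, and a probing
#' battery of 64-repeat SVM separations over the input, Purkinje and output
#' layers.
#'
#' @return A nested named list (class `cann_config`).
#' @export
default_experiment_config <- function() {
  structure(list(
    version = 1L,
    seed = 1L,
    corpus = list(source = "synthetic", path = NULL, labels_path = NULL,
                  n_sentences = 2000L, vocab_size = 100L,
                  grammar = list(role_sharing = 0.8, skew = 1.0,
                                 pp_prob = 0.35)),
    split = list(fraction = 0.9),
    circuit = list(n_purkinje = 96L, variant = "original"),
    train = list(learning_rate = 0.1, epochs = 8L, batch_size = 32L,
                 optimizer = "plain-sgd", bptt = "full-within-sentence",
                 evals_per_epoch = 1L),
    eval = list(n_sentences = 150L, k = 5L),
    probe = list(n_repeats = 64L, contrasts = c("S", "V", "O"),
                 layers = c("input", "purkinje", "output"),
                 n_components = 2L)),
    class = "cann_config")
}

#' Read an experiment configuration from YAML
#'
#' Unspecified fields take their defaults from
#' [default_experiment_config()]; unknown fields raise a schema error naming
#' the offending field.
#'
#' @param path Path to a YAML file (or a named list already in memory).
#' @return A validated `cann_config`.
#' @export
read_experiment_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  validate_config(user)
}

merge_config <- function(base, user, prefix = "") {
  for (nm in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (!nm %in% names(base)) {
      abort(sprintf("Unknown configuration field `%s`.", full))
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]])) {
        abort(sprintf("Configuration field `%s` must be a mapping.", full))
      }
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], full)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(user) {
  cfg <- merge_config(default_experiment_config(), user %||% list())
  if (!cfg$corpus$source %in% c("synthetic", "text")) {
    abort("Configuration field `corpus.source` must be 'synthetic' or 'text'.")
  }
  if (cfg$corpus$source == "text" && is.null(cfg$corpus$path)) {
    abort("Configuration field `corpus.path` is required when corpus.source = 'text'.")
  }
  variants <- c("original", "rec-compress", "inhib-purkinje-output",
                "ei-split-input")
  if (!cfg$circuit$variant %in% variants) {
    abort(sprintf("Configuration field `circuit.variant` must be one of %s.",
                  paste(variants, collapse = ", ")))
  }
  check_scalar_number(cfg$split$fraction, "split.fraction", 0, 1)
  check_scalar_number(cfg$train$learning_rate, "train.learning_rate", 0)
  structure(cfg, class = "cann_config")
}

config_grammar <- function(cfg) {
  do.call(grammar_spec, cfg$corpus$grammar)
}

config_corpus <- function(cfg, seed_offset = 0L) {
  if (cfg$corpus$source == "synthetic") {
    generate_synthetic_corpus(config_grammar(cfg), cfg$corpus$n_sentences,
                              seed = derive_seed(cfg$seed, seed_offset))
  } else if (!is.null(cfg$corpus$labels_path)) {
    read_labeled_sentences(cfg$corpus$labels_path)
  } else {
    read_sentences(cfg$corpus$path)
  }
}

config_eval_corpus <- function(cfg) {
  if (cfg$corpus$source == "synthetic") {
    generate_synthetic_corpus(config_grammar(cfg), cfg$eval$n_sentences,
                              seed = derive_seed(cfg$seed, 991L))
  } else if (!is.null(cfg$corpus$labels_path)) {
    read_labeled_sentences(cfg$corpus$labels_path)
  } else {
    abort("Evaluation requires `corpus.labels_path` for text corpora.")
  }
}

# Write a tibble as CSV with a commented metadata header (config hash and
# seeds), so every artifact is traceable to its configuration.
write_report_csv <- function(df, path, cfg, extra = character()) {
  meta <- c(sprintf("# config_hash: %s", rlang::hash(unclass(cfg))),
            sprintf("# seed: %s", format(cfg$seed)),
            extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a training log as CSV with a YAML header
#'
#' The training configuration is echoed as commented YAML lines above the
#' CSV columns (`epoch`, `fraction_of_lap`, `val_cross_entropy`,
#' `val_top5_rate`, `seed`).
#'
#' @param fit A `cann_fit`.
#' @param path Output path.
#' @param cfg Optional `cann_config` whose hash is recorded.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(fit, path, cfg = NULL) {
  hdr <- paste0("# ", strsplit(yaml::as.yaml(unclass(fit$config)), "\n")[[1]])
  if (!is.null(cfg)) {
    hdr <- c(sprintf("# config_hash: %s", rlang::hash(unclass(cfg))), hdr)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(fit$log, con, row.names = FALSE)
  invisible(path)
}

#' Run a reproducible experiment recipe
#'
#' Config-driven end-to-end runner behind the `cann` command-line script.
#' All artifacts are pure functions of (config, seed); with the plain-SGD
#' optimizer, rerunning a recipe reproduces every CSV byte for byte.
#'
#' Commands:
#' \describe{
#'   \item{`synth`}{samples the synthetic corpus and writes
#'     `corpus_labeled.txt` (word/ROLE/TYPE) plus `corpus.txt` (plain text),
#'     both readable back by `train`.}
#'   \item{`train`}{builds the vocabulary, filters/encodes, splits, trains the
#'     circuit and writes `checkpoint.rds`, `training_log.csv`,
#'     `vocabulary.txt`.}
#'   \item{`eval`}{scores a checkpoint on a labelled evaluation corpus:
#'     overall and word-type-conditional top-k correct rates to
#'     `eval_rates.csv`.}
#'   \item{`probe`}{separability battery and PCA coordinates from a
#'     checkpoint: `separation.csv`, `pca_coordinates.csv`,
#'     `similarity_index.csv`.}
#'   \item{`block`}{re-evaluates a checkpoint with the recurrent pathway
#'     zeroed and writes the intact-vs-blocked comparison of correct rates
#'     and Purkinje separations to `block_comparison.csv`.}
#' }
#'
#' @param command One of `"synth"`, `"train"`, `"eval"`, `"probe"`,
#'   `"block"`.
#' @param config A `cann_config`, a path to a YAML config, or `NULL` for the
#'   defaults.
#' @param seed Optional seed overriding the config's.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the artifact paths written (plus key
#'   in-memory results).
#' @export
run_experiment <- function(command = c("synth", "train", "eval", "probe",
                                       "block"),
                           config = NULL, seed = NULL, out_dir = ".") {
  command <- match.arg(command)
  cfg <- if (inherits(config, "cann_config")) config else
    read_experiment_config(config %||% list())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  out <- list()

  if (command == "synth") {
    corpus <- config_corpus(cfg)
    write_labeled_sentences(corpus, pth("corpus_labeled.txt"))
    plain <- corpus |>
      dplyr::group_by(.data$sentence) |>
      dplyr::summarise(line = paste(.data$token, collapse = " "),
                       .groups = "drop")
    writeLines(plain$line, pth("corpus.txt"))
    out <- list(labeled = pth("corpus_labeled.txt"), plain = pth("corpus.txt"))
  }

  if (command == "train") {
    corpus <- config_corpus(cfg)
    vocab <- build_vocabulary(corpus, cfg$corpus$vocab_size)
    encoded <- filter_and_truncate(corpus, vocab)
    split <- split_train_validation(encoded, cfg$split$fraction,
                                    seed = derive_seed(cfg$seed, 17L))
    circuit <- build_circuit(n_input = vocab$unk_index,
                             n_purkinje = cfg$circuit$n_purkinje,
                             variant = cfg$circuit$variant,
                             seed = derive_seed(cfg$seed, 29L))
    tc <- train_config(learning_rate = cfg$train$learning_rate,
                       epochs = cfg$train$epochs,
                       batch_size = cfg$train$batch_size,
                       seed = derive_seed(cfg$seed, 43L),
                       optimizer = cfg$train$optimizer,
                       bptt = cfg$train$bptt,
                       evals_per_epoch = cfg$train$evals_per_epoch,
                       top_k = cfg$eval$k)
    fit <- train_cann(circuit, split, tc, vocab)
    save_checkpoint(fit, pth("checkpoint.rds"))
    write_training_log(fit, pth("training_log.csv"), cfg)
    write_vocabulary(vocab, pth("vocabulary.txt"))
    out <- list(checkpoint = pth("checkpoint.rds"),
                log = pth("training_log.csv"),
                vocabulary = pth("vocabulary.txt"), fit = fit)
  }

  if (command %in% c("eval", "probe", "block")) {
    fit <- load_checkpoint(pth("checkpoint.rds"))
    vocab <- fit$vocab
    eval_corpus <- filter_and_truncate(config_eval_corpus(cfg), vocab)
  }

  if (command == "eval") {
    conds <- list(
      list(name = "overall"),
      list(name = "noun-after-verb", target = "noun", role = "O"),
      list(name = "preposition-after-verb", prev = "verb",
           target = "preposition"),
      list(name = "object-pronoun-after-verb", prev = "verb",
           target = "object-pronoun"),
      list(name = "noun-after-preposition", target = "noun", role = "other"),
      list(name = "adjective-after-be-verb", prev = "be-verb",
           target = "adjective"))
    rates <- purrr::map_dfr(conds, function(cd) {
      rate <- tryCatch(
        correct_rate(fit, eval_corpus, k = cfg$eval$k,
                     prev_type = cd$prev, target_type = cd$target,
                     target_role = cd$role),
        error = function(e) NA_real_)
      tibble(condition = cd$name, top_k = cfg$eval$k, correct_rate = rate)
    })
    write_report_csv(rates, pth("eval_rates.csv"), cfg)
    out <- list(rates = pth("eval_rates.csv"), table = rates)
  }

  if (command == "probe") {
    reports <- purrr::map_dfr(cfg$probe$layers, function(ly) {
      am <- activity_matrix(fit, eval_corpus, layer = ly)
      svm_separation(am, cfg$probe$contrasts,
                     n_repeats = cfg$probe$n_repeats,
                     seed = derive_seed(cfg$seed, 57L))
    })
    write_report_csv(reports, pth("separation.csv"), cfg)
    amp <- activity_matrix(fit, eval_corpus, layer = "purkinje")
    pca <- pca_project(amp, cfg$probe$n_components)
    write_report_csv(pca$coordinates, pth("pca_coordinates.csv"), cfg)
    sims <- purrr::map_dfr(cfg$probe$contrasts, function(ct) {
      dir <- linear_separating_direction(amp, ct)
      dplyr::mutate(similarity_index(dir, pca$rotation), contrast = ct)
    })
    write_report_csv(sims, pth("similarity_index.csv"), cfg)
    out <- list(separation = pth("separation.csv"),
                pca = pth("pca_coordinates.csv"),
                similarity = pth("similarity_index.csv"),
                report = reports)
  }

  if (command == "block") {
    blocked_fit <- fit
    blocked_fit$circuit <- block_recurrent(fit$circuit)
    score <- function(f, state) {
      am <- activity_matrix(f, eval_corpus, layer = "purkinje")
      sep <- svm_separation(am, cfg$probe$contrasts,
                            n_repeats = cfg$probe$n_repeats,
                            seed = derive_seed(cfg$seed, 73L))
      nv <- tryCatch(correct_rate(f, eval_corpus, k = cfg$eval$k,
                                  target_type = "noun", target_role = "O"),
                     error = function(e) NA_real_)
      dplyr::bind_rows(
        tibble(state = state, measure = "noun_after_verb_rate",
               contrast = NA_character_, value = nv),
        tibble(state = state,
               measure = "purkinje_separation",
               contrast = sep$contrast, value = sep$mean_accuracy))
    }
    cmp <- dplyr::bind_rows(score(fit, "intact"),
                            score(blocked_fit, "blocked"))
    write_report_csv(cmp, pth("block_comparison.csv"), cfg)
    out <- list(comparison = pth("block_comparison.csv"), table = cmp)
  }

  invisible(out)
}
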