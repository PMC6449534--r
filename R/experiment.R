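# Seeded experiment runner: configuration files, metric computation and
# tidy reports tying corpus generation/loading, passage selection, training
# and multi-restart evaluation together.

#' Classification accuracy
#'
#' Fraction of exact matches between predictions and labels.
#'
#' @param predictions,labels Equal-length vectors (at least one element).
#' @return A number in `[0, 1]`.
#' @examples
#' accuracy(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels)) abort("length mismatch between predictions and labels")
  if (length(predictions) == 0) abort("accuracy of an empty vector is undefined")
  mean(as.character(predictions) == as.character(labels))
}

#' Confusion matrix as a tibble
#'
#' @param predictions,labels Equal-length vectors.
#' @return A tibble `label`, `prediction`, `n`; row sums over predictions
#'   equal class counts.
#' @export
confusion_matrix <- function(predictions, labels) {
  tb <- as.data.frame(table(label = as.character(labels),
                            prediction = as.character(predictions)))
  as_tibble(tb) |> mutate(n = as.integer(.data$Freq)) |> select(-"Freq")
}

majority_rate <- function(labels) max(table(labels)) / length(labels)

default_experiment_keys <- function() {
  c("task", "seed", "n_restarts", "n_docs", "n_passages", "text_source",
    "arch", "encoder", "aggregation", "signal_location", "signal_p",
    "positive_fraction", "n_method_classes", "embedding_dim", "max_len",
    "epochs", "batch_size", "lr", "dropout", "l2", "test_fraction",
    "manifest", "embeddings_path")
}

#' Read a flat key-value experiment configuration file
#'
#' YAML with flat scalar keys. Unknown keys are an error listing them.
#'
#' @param path Config file path.
#' @return Named list of settings.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), default_experiment_keys())
  if (length(bad)) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  if (is.null(cfg$task) || !cfg$task %in% c("triage", "method")) {
    abort("config must set task: triage or method")
  }
  cfg
}

experiment_defaults <- function(task) {
  list(seed = 1L, n_restarts = 3L, n_docs = 200L, n_passages = 400L,
       text_source = "captions", arch = "cnn", encoder = NULL,
       aggregation = "attention", signal_location = "captions",
       signal_p = 0.8, positive_fraction = 537 / 988, n_method_classes = 8L,
       embedding_dim = 32L, max_len = if (task == "triage") 64L else 48L,
       epochs = 8L, batch_size = if (task == "triage") 8L else 32L,
       lr = 1e-3, dropout = 0.25, l2 = 1e-4, test_fraction = 0.2,
       manifest = NULL, embeddings_path = NULL)
}

#' Run a complete, seeded experiment
#'
#' Generates (or loads) a corpus, builds embeddings, trains with multiple
#' random restarts and returns a full report: the config snapshot including
#' every defaulted setting, per-restart accuracies, mean and sample standard
#' deviation, confusion matrix of the last restart, seed list and
#' timestamps. Reruns with the same configuration are identical except
#' timestamps.
#'
#' @param config Named list (see [read_experiment_config()]) or a path to a
#'   YAML config file. `task` is `"triage"` or `"method"`.
#' @param out_dir Optional run directory; when given, the report JSON,
#'   per-restart TSV and (for triage) an attention dump are written there.
#' @return A `bt_experiment_report`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) config <- read_experiment_config(config)
  task <- config$task %||% abort("config must set task")
  cfg <- utils::modifyList(experiment_defaults(task), config)
  started <- Sys.time()
  if (!is.null(cfg$embeddings_path) && !file.exists(cfg$embeddings_path)) {
    abort(paste0("embeddings file not found: ", cfg$embeddings_path))
  }
  cfg$seed <- as.integer(cfg$seed)
  seeds <- cfg$seed + seq_len(cfg$n_restarts) - 1L

  if (task == "triage") {
    if (!is.null(cfg$manifest)) {
      corp <- read_corpus(cfg$manifest)
      sig_tokens <- character()
    } else {
      sc <- synth_config(n_docs = cfg$n_docs, positive_fraction = cfg$positive_fraction,
                         signal_location = cfg$signal_location, signal_p = cfg$signal_p,
                         seed = cfg$seed)
      gen <- generate_triage_corpus(sc)
      corp <- gen[c("docs", "labels")]
      sig_tokens <- gen$signal_tokens
    }
    emb <- experiment_embeddings(cfg, corp$docs)
    tc <- triage_config(text_source = cfg$text_source,
                        encoder = cfg$encoder %||% default_encoder_for(cfg$text_source),
                        aggregation = cfg$aggregation, max_len = cfg$max_len,
                        dropout = cfg$dropout, l2 = cfg$l2, epochs = cfg$epochs,
                        batch_size = cfg$batch_size, lr = cfg$lr, seed = cfg$seed)
    ev <- triage_multirestart(corp$docs, corp$labels$label, tc, emb,
                              seeds = seeds, test_fraction = cfg$test_fraction)
    # confusion matrix from a model retrained at the last restart seed
    sp <- stratified_split(as.character(corp$labels$label), cfg$test_fraction, tc$seed)
    cfg_last <- tc; cfg_last$seed <- tail(seeds, 1L)
    m <- build_triage_model(cfg_last, emb)
    m <- train_triage(m, corp$docs[sp$train], corp$labels$label[sp$train])
    pred <- predict_triage(m, corp$docs[sp$test])
    cm <- confusion_matrix(pred$.pred, corp$labels$label[sp$test])
    model_desc <- paste0(toupper(tc$encoder),
                         if (!cfg$text_source %in% single_passage_sources())
                           paste0(" + ", tc$aggregation))
  } else {
    sc <- synth_config(n_method_classes = cfg$n_method_classes,
                       signal_p = cfg$signal_p, seed = cfg$seed)
    gen <- generate_method_corpus(sc, n_passages = cfg$n_passages)
    emb <- experiment_embeddings(cfg, NULL, texts = gen$passages$text)
    pc <- passage_config(arch = cfg$arch, max_len = cfg$max_len,
                         dropout = cfg$dropout, l2 = cfg$l2, epochs = cfg$epochs,
                         batch_size = cfg$batch_size, lr = cfg$lr, seed = cfg$seed)
    ev <- evaluate_multirestart(gen$passages, pc, emb, seeds = seeds,
                                test_fraction = cfg$test_fraction)
    sp <- stratified_split(gen$passages$label, cfg$test_fraction, pc$seed)
    cfg_last <- pc; cfg_last$seed <- tail(seeds, 1L)
    m <- build_passage_model(cfg_last, emb, sort(unique(gen$passages$label)))
    m <- train_passage_classifier(m, gen$passages[sp$train, ])
    pred <- predict_passage(m, gen$passages[sp$test, ])
    cm <- confusion_matrix(pred$.pred, gen$passages$label[sp$test])
    model_desc <- toupper(cfg$arch)
  }

  report <- structure(
    list(task = task, config = cfg, model_configuration = model_desc,
         seeds = seeds, per_restart = ev$per_restart,
         accuracy_mean = ev$mean, accuracy_sd = ev$sd,
         confusion = cm, started = started, finished = Sys.time()),
    class = "bt_experiment_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_as_list(report),
                         file.path(out_dir, "report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    utils::write.table(ev$per_restart, file.path(out_dir, "restarts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (task == "triage") {
      att <- attention_weights(m, corp$docs[head(sp$test, 20L)])
      write_attention_jsonl(att, file.path(out_dir, "attention.jsonl"))
    }
  }
  report
}

experiment_embeddings <- function(cfg, docs, texts = NULL) {
  if (!is.null(cfg$embeddings_path)) return(load_word_vectors(cfg$embeddings_path))
  vocab <- if (!is.null(texts)) {
    sort(unique(tolower(unlist(lapply(texts, tokenize)))))
  } else corpus_vocab(docs)
  attr(generate_toy_embeddings(vocab, dim = cfg$embedding_dim, seed = cfg$seed), "table")
}

report_as_list <- function(r) {
  list(task = r$task, model_configuration = r$model_configuration,
       config = r$config[!vapply(r$config, is.null, logical(1))],
       seeds = r$seeds,
       per_restart_accuracy = r$per_restart$accuracy,
       accuracy_mean = r$accuracy_mean, accuracy_sd = r$accuracy_sd,
       confusion = r$confusion,
       started = format(r$started), finished = format(r$finished))
}

#' @export
print.bt_experiment_report <- function(x, ...) {
  cat("<bt_experiment_report> ", x$task, " (", x$model_configuration, ")\n",
      "  accuracy ", sprintf("%.3f", x$accuracy_mean), " ± ",
      sprintf("%.3f", x$accuracy_sd), " over ", length(x$seeds), " restart(s)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.bt_experiment_report <- function(x, ...) x$per_restart

#' @export
glance.bt_experiment_report <- function(x, ...) {
  tibble(task = x$task, model_configuration = x$model_configuration,
         text_source = x$config$text_source %||% NA_character_,
         accuracy_mean = x$accuracy_mean, accuracy_sd = x$accuracy_sd,
         n_restarts = length(x$seeds))
}

#' Write a triage results table across text sources
#'
#' One row per condition: `text_source`, `model_configuration`,
#' `accuracy_mean`, `accuracy_sd`, `n_restarts`.
#'
#' @param reports List of `bt_experiment_report` or `bt_eval` rows produced
#'   per text source.
#' @param path Output TSV path.
#' @return The combined tibble, invisibly.
#' @export
write_triage_report <- function(reports, path) {
  rows <- bind_rows(lapply(reports, function(r) {
    if (inherits(r, "bt_experiment_report")) glance(r)
    else glance(r) |> mutate(model_configuration = NA_character_,
                             text_source = sub("^triage/", "", .data$task))
  }))
  rows <- rows[, intersect(c("text_source", "model_configuration", "accuracy_mean",
                             "accuracy_sd", "n_restarts"), names(rows))]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
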