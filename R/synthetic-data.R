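# Synthetic corpora with controllable, plantable class signal: Zipfian
# nonsense background text plus disjoint class-specific signal tokens placed
# in a chosen text source, so every pipeline stage (extraction, embedding,
# classification, attention) is testable without external data.

#' Configuration for synthetic corpus generation
#'
#' The default positive fraction mirrors a 537:451 positive:negative triage
#' corpus so class-balance-sensitive baselines are comparable.
#'
#' @param n_docs Number of documents.
#' @param positive_fraction Fraction of positive documents.
#' @param vocab_size Background vocabulary size (tokens `w0001`...).
#' @param zipf_exponent Exponent of the Zipfian background distribution.
#' @param n_signal_tokens Signal tokens per class (disjoint across classes
#'   and from the background vocabulary, hence from its top-50 tokens).
#' @param signal_location Character subset of [text_sources()] naming where
#'   positive-class signal is planted (triage corpus).
#' @param signal_p Probability that a targeted passage of a positive document
#'   carries at least one signal token.
#' @param signal_passages `"all"`: every targeted passage is an independent
#'   Bernoulli(`signal_p`) signal carrier; `"one"`: exactly one targeted
#'   passage per document is eligible (it carries signal with probability
#'   `signal_p`).
#' @param paragraphs_per_doc,sentences_per_paragraph,tokens_per_sentence
#'   Inclusive integer ranges (length-2 vectors).
#' @param figures_per_doc Inclusive range of figures (each with a caption).
#' @param figure_ref_density Probability that a body sentence carries a
#'   reference to a random figure/panel.
#' @param n_method_classes Classes for the passage-classification corpus.
#' @param seed RNG seed; generation is a pure function of this config.
#' @return A `bt_synth_config`.
#' @export
synth_config <- function(n_docs = 100L, positive_fraction = 537 / (537 + 451),
                         vocab_size = 500L, zipf_exponent = 1.05,
                         n_signal_tokens = 5L, signal_location = "captions",
                         signal_p = 0.8, signal_passages = c("all", "one"),
                         paragraphs_per_doc = c(3L, 6L),
                         sentences_per_paragraph = c(2L, 4L),
                         tokens_per_sentence = c(6L, 12L),
                         figures_per_doc = c(2L, 4L),
                         figure_ref_density = 0.35,
                         n_method_classes = 8L, seed = 1L) {
  signal_passages <- match.arg(signal_passages)
  stopifnot(n_docs >= 0, positive_fraction > 0, positive_fraction < 1,
            signal_p >= 0, signal_p <= 1, vocab_size >= 60)
  bad <- setdiff(signal_location, text_sources())
  if (length(bad)) abort(paste0("unknown signal location(s): ", paste(bad, collapse = ", ")))
  if (any(signal_location %in% c("captions", "evidence_fragments", "captions_plus_fragments")) &&
      figures_per_doc[1] < 1) {
    abort("figure-anchored signal locations require at least one figure per document")
  }
  structure(list(n_docs = as.integer(n_docs), positive_fraction = positive_fraction,
                 vocab_size = as.integer(vocab_size), zipf_exponent = zipf_exponent,
                 n_signal_tokens = as.integer(n_signal_tokens),
                 signal_location = signal_location, signal_p = signal_p,
                 signal_passages = signal_passages,
                 paragraphs_per_doc = as.integer(paragraphs_per_doc),
                 sentences_per_paragraph = as.integer(sentences_per_paragraph),
                 tokens_per_sentence = as.integer(tokens_per_sentence),
                 figures_per_doc = as.integer(figures_per_doc),
                 figure_ref_density = figure_ref_density,
                 n_method_classes = as.integer(n_method_classes),
                 seed = as.integer(seed)),
            class = "bt_synth_config")
}

background_vocab <- function(config) {
  sprintf("w%04d", seq_len(config$vocab_size))
}

signal_vocab <- function(config, n_classes = 1L, prefix = "sig") {
  lapply(seq_len(n_classes), function(k) {
    sprintf("%s%02dx%02d", prefix, k, seq_len(config$n_signal_tokens))
  })
}

zipf_probs <- function(n, s) {
  p <- 1 / seq_len(n)^s
  p / sum(p)
}

rint <- function(range) if (range[1] >= range[2]) range[1] else sample(range[1]:range[2], 1L)

synth_sentence <- function(vocab, probs, n_tokens) {
  toks <- sample(vocab, n_tokens, replace = TRUE, prob = probs)
  toks[1] <- capitalize(toks[1])
  paste0(paste(toks, collapse = " "), ".")
}

capitalize <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

inject_signal <- function(text, signal_tokens, n = 1L) {
  # insert signal token(s) before the terminal period, after any figure refs
  ins <- paste(sample(signal_tokens, n, replace = TRUE), collapse = " ")
  paste0(sub("\\.\\s*$", "", text), " ", ins, " .")
}

#' Generate a synthetic triage corpus
#'
#' Positive documents carry signal tokens in the targeted text source(s)
#' (per-passage Bernoulli(`signal_p`)); negative documents never carry any
#' signal token. Body paragraphs reference the document's figures so
#' evidence extraction is exercised, and every generated reference is
#' recoverable by [find_figure_references()].
#'
#' @param config A [synth_config()].
#' @return A list: `docs` (list of `bt_document`), `labels` (tibble
#'   `doc_id`, `label` with 1 = positive), `signal_tokens` (the positive
#'   class's tokens), `signal_map` (tibble `doc_id`, `kind`, `figure`,
#'   flagging where signal was actually planted).
#' @export
generate_triage_corpus <- function(config) {
  stopifnot(inherits(config, "bt_synth_config"))
  vocab <- background_vocab(config)
  probs <- zipf_probs(config$vocab_size, config$zipf_exponent)
  sig <- signal_vocab(config, 1L, prefix = "sigpos")[[1]]
  # combined sources expand to their component kinds
  loc <- config$signal_location
  if ("captions_plus_fragments" %in% loc) loc <- union(loc, c("captions", "evidence_fragments"))
  if ("title_abstract" %in% loc) loc <- union(loc, c("title", "abstract"))
  config$signal_location <- setdiff(loc, c("captions_plus_fragments", "title_abstract"))
  with_seed(config$seed, {
    n_pos <- round(config$n_docs * config$positive_fraction)
    labels <- c(rep(1L, n_pos), rep(0L, config$n_docs - n_pos))
    docs <- vector("list", config$n_docs)
    sig_map <- list()
    for (i in seq_len(config$n_docs)) {
      doc_id <- sprintf("synth%05d", i)
      pos <- labels[i] == 1L
      n_fig <- rint(config$figures_per_doc)
      n_par <- rint(config$paragraphs_per_doc)

      target <- function(kind) pos && kind %in% config$signal_location
      # which targeted passages are eligible signal carriers
      carrier <- function(kind, n_units) {
        if (!target(kind)) return(rep(FALSE, n_units))
        elig <- if (config$signal_passages == "one") {
          replace(rep(FALSE, n_units), sample.int(n_units, 1L), TRUE)
        } else rep(TRUE, n_units)
        elig & (runif(n_units) < config$signal_p)
      }

      mark <- function(kind, figure = NA_integer_) {
        sig_map[[length(sig_map) + 1L]] <<- tibble(doc_id = doc_id, kind = kind,
                                                   figure = figure)
      }

      title <- synth_sentence(vocab, probs, rint(c(4L, 8L)))
      if (any(carrier("title", 1L))) { title <- inject_signal(title, sig); mark("title") }

      abs_sents <- vapply(seq_len(rint(c(2L, 3L))), function(j)
        synth_sentence(vocab, probs, rint(config$tokens_per_sentence)), character(1))
      abstract <- paste(abs_sents, collapse = " ")
      if (any(carrier("abstract", 1L))) { abstract <- inject_signal(abstract, sig); mark("abstract") }

      mesh <- sample(vocab, rint(c(3L, 6L)), prob = probs, replace = TRUE)
      if (any(carrier("mesh", 1L))) { mesh <- c(mesh, sample(sig, 1L)); mark("mesh") }

      captions <- character(n_fig)
      cap_carry <- carrier("captions", n_fig)
      for (f in seq_len(n_fig)) {
        body <- vapply(seq_len(rint(c(1L, 2L))), function(j)
          synth_sentence(vocab, probs, rint(config$tokens_per_sentence)), character(1))
        captions[f] <- paste0("Figure ", f, " . ", paste(body, collapse = " "))
        if (cap_carry[f]) { captions[f] <- inject_signal(captions[f], sig); mark("caption", f) }
      }
      names(captions) <- as.character(seq_len(n_fig))

      frag_carry <- carrier("evidence_fragments", n_par)
      par_carry <- carrier("all_paragraphs", n_par)
      paragraphs <- character(n_par)
      for (p in seq_len(n_par)) {
        n_sent <- rint(config$sentences_per_paragraph)
        sents <- character(n_sent)
        ref_sent <- NA_integer_
        for (s in seq_len(n_sent)) {
          sents[s] <- synth_sentence(vocab, probs, rint(config$tokens_per_sentence))
          if (n_fig > 0 && runif(1) < config$figure_ref_density) {
            fig <- sample.int(n_fig, 1L)
            panel <- sample(LETTERS[1:4], 1L)
            sents[s] <- sub("\\.$", paste0("( Fig. ", fig, panel, " )."), sents[s])
            if (is.na(ref_sent)) ref_sent <- s
          }
        }
        if (frag_carry[p] && is.na(ref_sent)) {
          # fragment-targeted paragraphs must contain a reference
          fig <- sample.int(n_fig, 1L)
          sents[1] <- sub("\\.$", paste0("( Fig. ", fig, "A )."), sents[1])
          ref_sent <- 1L
        }
        if (frag_carry[p]) {
          sents[ref_sent] <- inject_signal(sents[ref_sent], sig)
          mark("evidence_fragment")
        } else if (par_carry[p]) {
          sents[1] <- inject_signal(sents[1], sig)
          mark("paragraph")
        }
        paragraphs[p] <- paste(sents, collapse = " ")
      }

      docs[[i]] <- document(doc_id, title = title, abstract = abstract,
                            mesh_terms = mesh, paragraphs = paragraphs,
                            captions = captions)
    }
    ord <- sample.int(config$n_docs)   # interleave classes
    list(docs = docs[ord],
         labels = tibble(doc_id = map_chr(docs[ord], "doc_id"), label = labels[ord]),
         signal_tokens = sig,
         signal_map = if (length(sig_map)) bind_rows(sig_map)
                      else tibble(doc_id = character(), kind = character(),
                                  figure = integer()))
  })
}

#' Generate a synthetic method-classification passage corpus
#'
#' Passages of Zipfian background text where class-`c` passages carry tokens
#' from signal set `c` with probability `p`. Fine codes subdivide each
#' grouped class so label-scheme grouping is exercised; presets mirror the
#' grouped-code cardinalities of curated detection-method vocabularies
#' (8 participant-detection groups, 17 interaction-detection groups) plus a
#' binary western-blot yes/no task.
#'
#' @param config A [synth_config()]; `n_method_classes` sets `k` unless a
#'   preset is named.
#' @param n_passages Total passages (class-balanced as evenly as possible).
#' @param preset `NULL`, `"participant8"`, `"interaction17"` or
#'   `"western_blot_yes_no"`.
#' @return A list: `passages` (tibble `passage_id`, `doc_id`, `figure`,
#'   `panels`, `kind`, `fine_code`, `label`, `text`), `scheme` (a
#'   `bt_label_scheme` mapping the generated fine codes to grouped codes),
#'   `signal_sets` (list of per-class token sets).
#' @export
generate_method_corpus <- function(config, n_passages = 400L, preset = NULL) {
  stopifnot(inherits(config, "bt_synth_config"))
  k <- config$n_method_classes
  fine_per_group <- 3L
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("participant8", "interaction17", "western_blot_yes_no"))
    k <- switch(preset, participant8 = 8L, interaction17 = 17L, western_blot_yes_no = 2L)
    fine_per_group <- switch(preset, participant8 = 5L, interaction17 = 4L,
                             western_blot_yes_no = 1L)
  }
  if (k < 2) abort("need at least 2 method classes")
  groups <- if (identical(preset, "western_blot_yes_no")) c("western_blot", "other")
            else sprintf("group%02d", seq_len(k))
  sig_sets <- signal_vocab(config, k, prefix = "sigm")
  if (anyDuplicated(unlist(sig_sets))) abort("signal sets must be disjoint")
  fine <- unlist(lapply(seq_len(k), function(g)
    sprintf("MI:%02d%02d", g, seq_len(fine_per_group))))
  scheme <- label_scheme(
    tibble(fine_code = fine, grouped_code = rep(groups, each = fine_per_group)),
    name = preset %||% paste0("synthetic", k))
  vocab <- background_vocab(config)
  probs <- zipf_probs(config$vocab_size, config$zipf_exponent)
  if (n_passages == 0) {
    return(list(passages = tibble(passage_id = character(), doc_id = character(),
                                  figure = integer(), panels = character(),
                                  kind = character(), fine_code = character(),
                                  label = character(), text = character()),
                scheme = scheme, signal_sets = setNames(sig_sets, groups)))
  }
  with_seed(config$seed, {
    cls <- rep_len(seq_len(k), n_passages)
    rows <- lapply(seq_len(n_passages), function(i) {
      g <- cls[i]
      text <- synth_sentence(vocab, probs, rint(config$tokens_per_sentence + 6L))
      if (runif(1) < config$signal_p) {
        text <- inject_signal(text, sig_sets[[g]], n = sample(1:2, 1L))
      }
      fine_i <- sample(scheme$mapping$fine_code[scheme$mapping$grouped_code == groups[g]], 1L)
      tibble(passage_id = sprintf("p%05d", i),
             doc_id = sprintf("synthm%04d", ((i - 1L) %/% 4L) + 1L),
             figure = ((i - 1L) %% 4L) + 1L, panels = sample(LETTERS[1:4], 1L),
             kind = sample(c("caption", "evidence_fragment"), 1L),
             fine_code = fine_i, label = groups[g], text = text)
    })
    list(passages = bind_rows(rows)[sample.int(n_passages), ],
         scheme = scheme, signal_sets = setNames(sig_sets, groups))
  })
}

#' Generate a toy word-embedding file
#'
#' Unit-norm random Gaussian vectors, one per vocabulary token, written in
#' the headerless word-vector text format; deterministic per seed and
#' round-trippable through [load_word_vectors()].
#'
#' @param vocab Character vector of tokens.
#' @param dim Embedding dimensionality (at least 2).
#' @param seed RNG seed.
#' @param path Output path; a tempfile by default.
#' @return The path, invisibly, with attribute `"table"` holding the loaded
#'   `bt_embeddings`.
#' @export
generate_toy_embeddings <- function(vocab, dim = 16L, seed = 1L,
                                    path = tempfile(fileext = ".vec")) {
  stopifnot(dim >= 2)
  vocab <- unique(tolower(vocab))
  M <- with_seed(seed, {
    m <- matrix(rnorm(length(vocab) * dim), length(vocab), dim)
    m / sqrt(rowSums(m^2))
  })
  tab <- embedding_table(vocab, M)
  write_word_vectors(tab, path)
  out <- path
  attr(out, "table") <- tab
  invisible(out)
}

#' Collect the lowercased token vocabulary of a corpus
#'
#' @param docs List of `bt_document`s.
#' @return Sorted unique lowercase tokens across all passages.
#' @export
corpus_vocab <- function(docs) {
  toks <- unlist(lapply(docs, function(d) tokenize(paste(tidy(d)$text, collapse = " "))))
  sort(unique(tolower(toks)))
}

#' Write a labeled-document manifest and per-document files
#'
#' Emits one plain-dialect document file per document plus a manifest TSV
#' (`doc_id`, `path`, `label`), the on-disk layout consumed by the
#' experiment runner.
#'
#' @param docs List of `bt_document`s.
#' @param labels Tibble with `doc_id`, `label`.
#' @param dir Output directory (created if needed).
#' @return Manifest path, invisibly.
#' @export
write_corpus <- function(docs, labels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(docs, function(d) {
    p <- file.path(dir, paste0(d$doc_id, ".txt"))
    write_document(d, p, dialect = "plain")
    p
  }, character(1))
  manifest <- tibble(doc_id = map_chr(docs, "doc_id"), path = paths)
  manifest <- left_join(manifest, as_tibble(labels), by = "doc_id")
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}

#' Read a corpus back from a manifest
#'
#' @param manifest_path Path to a manifest TSV written by [write_corpus()].
#' @return A list with `docs` and `labels` as in [generate_triage_corpus()].
#' @export
read_corpus <- function(manifest_path) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  docs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    suppressWarnings(read_document(p, dialect = "plain", doc_id = man$doc_id[i]))
  })
  list(docs = docs, labels = tibble(doc_id = man$doc_id, label = man$label))
}
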