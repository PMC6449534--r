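# Document-level triage: encode selected passages (CNN-BiLSTM or simple
# CNN), aggregate passage vectors into one document vector with additive
# attention, and classify relevance with a fully connected sigmoid output.
# The attention weights expose which passages drove the decision.

#' The eight text-source conditions
#'
#' @return Character vector of the valid `text_source` values.
#' @export
text_sources <- function() {
  c("title", "abstract", "title_abstract", "mesh", "all_paragraphs",
    "captions", "evidence_fragments", "captions_plus_fragments")
}

# Sources classified from a single passage (no attention aggregation):
# abstract-like sources use the CNN-BiLSTM encoder, title/MeSH the simple CNN.
single_passage_sources <- function() c("title", "abstract", "title_abstract", "mesh")

default_encoder_for <- function(source) {
  if (source %in% c("title", "mesh")) "simple_cnn" else "cnn_bilstm"
}

#' Select the passages a text source exposes
#'
#' Maps a document to the ordered passage list for one of the eight text
#' sources: single metadata passages (`title`, `abstract`, `title_abstract`,
#' `mesh`), `all_paragraphs`, per-figure `captions`, `evidence_fragments`,
#' or `captions_plus_fragments` (captions first, then fragments, each in
#' document order). Selections longer than `max_passages` keep the first
#' `max_passages` in document order (count reported via a message); an empty
#' selection yields a single empty passage with a warning, so every document
#' classifies.
#'
#' @param doc A `bt_document`.
#' @param source One of [text_sources()].
#' @param fragments Optional precomputed [extract_evidence_fragments()]
#'   output for `doc`; computed on the fly if needed.
#' @param max_passages Passage cap per document.
#' @return A tibble: `doc_id`, `position`, `kind`, `figure`, `panels`
#'   (list-column), `text`.
#' @export
select_passages <- function(doc, source, fragments = NULL, max_passages = 64L) {
  stopifnot(inherits(doc, "bt_document"))
  source <- match.arg(source, text_sources())
  mk <- function(kind, text, figure = NA_integer_, panels = list(character())) {
    if (!length(text)) return(NULL)
    tibble(kind = kind, figure = as.integer(figure),
           panels = rep(panels, length.out = length(text)), text = text)
  }
  frag_rows <- function() {
    fr <- fragments %||% extract_evidence_fragments(doc)
    if (nrow(fr) == 0) return(NULL)
    tibble(kind = "evidence_fragment", figure = fr$figure, panels = fr$panels,
           text = fr$text)
  }
  cap_rows <- function() {
    if (!length(doc$captions)) return(NULL)
    mk("caption", unname(doc$captions), figure = as.integer(names(doc$captions)))
  }
  out <- switch(source,
    title = mk("title", doc$title),
    abstract = mk("abstract", doc$abstract),
    title_abstract = mk("title_abstract", squish(paste(doc$title, doc$abstract))),
    mesh = mk("mesh", paste(doc$mesh_terms, collapse = " ")),
    all_paragraphs = mk("paragraph", doc$paragraphs$text),
    captions = cap_rows(),
    evidence_fragments = frag_rows(),
    captions_plus_fragments = bind_rows(cap_rows(), frag_rows())
  )
  if (!is.null(out)) out <- out[nzchar(out$text), , drop = FALSE]
  if (is.null(out) || nrow(out) == 0) {
    warn(paste0("document ", doc$doc_id, ": empty selection for source ",
                shQuote(source), "; using a single empty passage"))
    out <- tibble(kind = source, figure = NA_integer_,
                  panels = list(character()), text = "")
  }
  if (nrow(out) > max_passages) {
    inform(paste0("document ", doc$doc_id, ": ", nrow(out),
                  " passages truncated to ", max_passages))
    out <- out[seq_len(max_passages), ]
  }
  out$doc_id <- doc$doc_id
  out$position <- seq_len(nrow(out))
  out[, c("doc_id", "position", "kind", "figure", "panels", "text")]
}

#' Configuration for the document triage classifier
#'
#' @param text_source One of [text_sources()].
#' @param encoder `"cnn_bilstm"` (convolution over tokens feeding a
#'   bidirectional LSTM; passage vector = concatenated final states) or
#'   `"simple_cnn"` (multi-width convolution + global max pooling). Default
#'   follows the source: `simple_cnn` for title/MeSH, `cnn_bilstm` otherwise.
#' @param aggregation `"attention"` (additive attention over passage
#'   vectors) or `"mean"` (unweighted average; ablation baseline). Ignored
#'   for single-passage sources.
#' @param filter_width,n_filters Convolution geometry of the encoder.
#' @param lstm_units BiLSTM units per direction (passage vector width
#'   `2 * lstm_units`).
#' @param attention_width Width of the additive attention scorer.
#' @param max_passages Passage cap per document (memory guard for full-text
#'   sources).
#' @param max_len,dropout,l2,trainable_embeddings,epochs,batch_size,lr As in
#'   [passage_config()]; `batch_size` counts documents.
#' @param val_fraction,patience Early stopping on validation loss.
#' @param threshold Decision threshold on the relevance probability.
#' @param seed RNG seed.
#' @return A `bt_triage_config`.
#' @export
triage_config <- function(text_source = "captions",
                          encoder = default_encoder_for(text_source),
                          aggregation = c("attention", "mean"),
                          filter_width = 3L, n_filters = 32L, lstm_units = 32L,
                          attention_width = 32L, max_passages = 64L,
                          max_len = 300L, dropout = 0.5, l2 = 1e-4,
                          trainable_embeddings = FALSE, epochs = 10L,
                          batch_size = 8L, lr = 1e-3, val_fraction = 0.15,
                          patience = 3L, threshold = 0.5, seed = 1L) {
  text_source <- match.arg(text_source, text_sources())
  encoder <- match.arg(encoder, c("cnn_bilstm", "simple_cnn"))
  aggregation <- match.arg(aggregation)
  if (dropout != 0 && (dropout < 0.25 || dropout > 0.5)) {
    warn("dropout outside the recommended [0.25, 0.5] band")
  }
  stopifnot(max_passages >= 1, max_len >= 1, n_filters >= 1, lstm_units >= 1,
            attention_width >= 1, epochs >= 0)
  structure(list(text_source = text_source, encoder = encoder,
                 aggregation = aggregation, filter_width = as.integer(filter_width),
                 filter_widths = c(3L, 4L, 5L),  # simple_cnn widths
                 n_filters = as.integer(n_filters), lstm_units = as.integer(lstm_units),
                 attention_width = as.integer(attention_width),
                 max_passages = as.integer(max_passages), max_len = as.integer(max_len),
                 dropout = dropout, l2 = l2,
                 trainable_embeddings = isTRUE(trainable_embeddings),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, val_fraction = val_fraction, patience = as.integer(patience),
                 threshold = threshold, seed = as.integer(seed)),
            class = "bt_triage_config")
}

#' Build an (untrained) triage model
#'
#' @param config A [triage_config()].
#' @param embeddings A `bt_embeddings`.
#' @return A `bt_triage_model` with seeded initial parameters.
#' @export
build_triage_model <- function(config, embeddings) {
  stopifnot(inherits(config, "bt_triage_config"), inherits(embeddings, "bt_embeddings"))
  d <- embeddings$dim
  params <- with_seed(config$seed, {
    p <- list()
    if (config$encoder == "cnn_bilstm") {
      w <- config$filter_width
      p$conv_W <- glorot(w * d, config$n_filters, c(w * d, config$n_filters))
      p$conv_b <- numeric(config$n_filters)
      lf <- lstm_init(config$n_filters, config$lstm_units)
      lb <- lstm_init(config$n_filters, config$lstm_units)
      p$lstmf_Wx <- lf$Wx; p$lstmf_Wh <- lf$Wh; p$lstmf_b <- lf$b
      p$lstmb_Wx <- lb$Wx; p$lstmb_Wh <- lb$Wh; p$lstmb_b <- lb$b
      m <- 2L * config$lstm_units
    } else {
      for (w in config$filter_widths) {
        p[[paste0("conv", w, "_W")]] <- glorot(w * d, config$n_filters, c(w * d, config$n_filters))
        p[[paste0("conv", w, "_b")]] <- numeric(config$n_filters)
      }
      m <- length(config$filter_widths) * config$n_filters
    }
    at <- attention_init(m, config$attention_width)
    p$att_W <- at$W; p$att_b <- at$b; p$att_v <- at$v
    p$out_W <- glorot(m, 1, c(m, 1))
    p$out_b <- 0
    p
  })
  structure(list(config = config, embeddings = embeddings, params = params,
                 trained = FALSE, history = NULL),
            class = "bt_triage_model")
}

#' @export
print.bt_triage_model <- function(x, ...) {
  cat("<bt_triage_model> source = ", x$config$text_source, ", encoder = ",
      x$config$encoder, ", aggregation = ", x$config$aggregation, ", ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Encode one or more passages into fixed-width vectors
#'
#' Runs the model's passage encoder: convolution over token positions
#' followed by a bidirectional LSTM whose final states are concatenated
#' (`cnn_bilstm`, width `2 * lstm_units`), or multi-width convolution with
#' global max pooling (`simple_cnn`). Deterministic given parameters.
#'
#' @param model A `bt_triage_model`.
#' @param token_lists List of token vectors (one per passage).
#' @return A matrix, one row per passage.
#' @export
encode_passage <- function(model, token_lists) {
  encode_fwd(model, token_lists)$H
}

encode_fwd <- function(model, token_lists) {
  cfg <- model$config; P <- model$params
  eb <- embed_batch(model$embeddings, token_lists, cfg$max_len, trim = TRUE,
                    min_len = if (cfg$encoder == "cnn_bilstm") cfg$filter_width
                              else max(cfg$filter_widths))
  T_used <- dim(eb$E)[2]
  if (cfg$encoder == "cnn_bilstm") {
    cv <- conv1d_fwd(eb$E, P$conv_W, P$conv_b, cfg$filter_width)
    lens_c <- conv_lens(eb$lens, T_used, cfg$filter_width)
    bl <- bilstm_fwd(cv$out, lens_c,
                     list(Wx = P$lstmf_Wx, Wh = P$lstmf_Wh, b = P$lstmf_b),
                     list(Wx = P$lstmb_Wx, Wh = P$lstmb_Wh, b = P$lstmb_b))
    list(H = bl$H, eb = eb, cv = cv, bl = bl)
  } else {
    pooled <- list(); convs <- list(); pools <- list()
    for (w in cfg$filter_widths) {
      cv <- conv1d_fwd(eb$E, P[[paste0("conv", w, "_W")]], P[[paste0("conv", w, "_b")]], w)
      mp <- maxpool_fwd(cv$out, conv_lens(eb$lens, T_used, w))
      convs[[as.character(w)]] <- cv; pools[[as.character(w)]] <- mp
      pooled[[as.character(w)]] <- mp$out
    }
    list(H = do.call(cbind, pooled), eb = eb, convs = convs, pools = pools)
  }
}

encode_bwd <- function(model, cache, dH) {
  cfg <- model$config; P <- model$params
  g <- list()
  if (cfg$encoder == "cnn_bilstm") {
    bb <- bilstm_bwd(cache$bl,
                     list(Wx = P$lstmf_Wx, Wh = P$lstmf_Wh, b = P$lstmf_b),
                     list(Wx = P$lstmb_Wx, Wh = P$lstmb_Wh, b = P$lstmb_b),
                     dH, need_dE = TRUE)
    g$lstmf_Wx <- bb$f$dWx; g$lstmf_Wh <- bb$f$dWh; g$lstmf_b <- bb$f$db
    g$lstmb_Wx <- bb$b$dWx; g$lstmb_Wh <- bb$b$dWh; g$lstmb_b <- bb$b$db
    cb <- conv1d_bwd(cache$cv, P$conv_W, bb$dE, need_dE = FALSE)
    g$conv_W <- cb$dW; g$conv_b <- cb$db
  } else {
    nf <- cfg$n_filters
    for (i in seq_along(cfg$filter_widths)) {
      w <- cfg$filter_widths[i]
      cols <- ((i - 1L) * nf + 1L):(i * nf)
      dA <- maxpool_bwd(cache$pools[[as.character(w)]], dH[, cols, drop = FALSE])
      cb <- conv1d_bwd(cache$convs[[as.character(w)]], P[[paste0("conv", w, "_W")]],
                       dA, need_dE = FALSE)
      g[[paste0("conv", w, "_W")]] <- cb$dW
      g[[paste0("conv", w, "_b")]] <- cb$db
    }
  }
  g
}

#' Aggregate passage vectors with additive attention
#'
#' Scores each passage vector with a single-layer additive scorer
#' `score_i = v' tanh(W h_i + b)`, normalizes scores with softmax and
#' returns the weighted sum as the document vector. The scorer has no
#' positional features: permuting passages permutes weights identically and
#' leaves the document vector unchanged.
#'
#' @param passage_vectors Numeric matrix, one row per passage.
#' @param params List with `W`, `b`, `v`; defaults to the model's attention
#'   parameters when called via [classify_document()].
#' @return A list: `weights` (nonnegative, summing to 1) and `doc_vector`.
#' @export
attend <- function(passage_vectors, params) {
  H <- as.matrix(passage_vectors)
  stopifnot(nrow(H) >= 1)
  fw <- attention_fwd(H, params)
  list(weights = fw$weights, doc_vector = fw$doc)
}

triage_fwd <- function(model, token_lists, train = FALSE) {
  cfg <- model$config; P <- model$params
  enc <- encode_fwd(model, token_lists)
  H <- enc$H
  if (cfg$aggregation == "attention" || nrow(H) == 1L) {
    at <- attention_fwd(H, list(W = P$att_W, b = P$att_b, v = P$att_v))
    doc <- at$doc; weights <- at$weights
  } else {
    at <- NULL
    weights <- rep(1 / nrow(H), nrow(H))
    doc <- colMeans(H)
  }
  dr <- dropout_fwd(doc, cfg$dropout, train)
  logit <- sum(as.numeric(dr$out) * drop(P$out_W)) + P$out_b
  list(prob = sigmoid(logit), logit = logit, weights = weights, doc = doc,
       enc = enc, at = at, dr = dr)
}

triage_bwd <- function(model, fw, dlogit) {
  cfg <- model$config; P <- model$params
  g <- list()
  g$out_W <- matrix(as.numeric(fw$dr$out) * dlogit, ncol = 1)
  g$out_b <- dlogit
  ddoc <- drop(P$out_W) * dlogit
  ddoc <- dropout_bwd(fw$dr, ddoc)
  H <- fw$enc$H
  if (!is.null(fw$at)) {
    ab <- attention_bwd(fw$at, list(W = P$att_W, b = P$att_b, v = P$att_v), ddoc)
    g$att_W <- ab$dW; g$att_b <- ab$db; g$att_v <- ab$dv
    dH <- ab$dH
  } else {
    dH <- matrix(rep(ddoc / nrow(H), each = nrow(H)), nrow(H))
  }
  add_grads2(g, encode_bwd(model, fw$enc, dH))
}

add_grads2 <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

#' Classify a document's triage relevance
#'
#' Selects passages for the model's text source, encodes them, aggregates
#' with attention and returns the relevance probability together with the
#' per-passage attention weights for inspection.
#'
#' @param model A `bt_triage_model`.
#' @param doc A `bt_document`, or a passages tibble from [select_passages()].
#' @param fragments Optional precomputed fragments for fragment sources.
#' @return A list: `prob` (in `[0, 1]`), `attention` (tibble: `doc_id`,
#'   `position`, `kind`, `weight`).
#' @export
classify_document <- function(model, doc, fragments = NULL) {
  stopifnot(inherits(model, "bt_triage_model"))
  passages <- if (inherits(doc, "bt_document")) {
    select_passages(doc, model$config$text_source, fragments = fragments,
                    max_passages = model$config$max_passages)
  } else as_tibble(doc)
  toks <- lapply(passages$text, function(x) head(tokenize(x), model$config$max_len))
  fw <- triage_fwd(model, toks, train = FALSE)
  list(prob = fw$prob,
       attention = tibble(doc_id = passages$doc_id, position = passages$position,
                          kind = passages$kind, weight = fw$weights))
}

# Precompute token lists per document for one text source.
corpus_tokens <- function(docs, config) {
  lapply(docs, function(doc) {
    ps <- select_passages(doc, config$text_source, max_passages = config$max_passages)
    list(doc_id = doc$doc_id, kinds = ps$kind,
         tokens = lapply(ps$text, function(x) head(tokenize(x), config$max_len)))
  })
}

#' Train a triage model
#'
#' Mini-batch Adam over documents: each document's selected passages are
#' encoded, aggregated and scored; binary cross-entropy on the sigmoid
#' output. Early stopping on validation loss with parameter restore. Fully
#' deterministic given the config seed.
#'
#' @param model A `bt_triage_model`.
#' @param docs List of `bt_document` objects.
#' @param labels Integer/numeric vector of 0/1 labels, parallel to `docs`.
#'   Both classes must be present.
#' @return The trained model with `$history`.
#' @export
train_triage <- function(model, docs, labels) {
  stopifnot(inherits(model, "bt_triage_model"), length(docs) == length(labels))
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) abort("training labels contain a single class")
  cfg <- model$config
  if (cfg$epochs == 0) return(model)
  ct <- corpus_tokens(docs, cfg)
  n <- length(ct)
  with_seed(cfg$seed + 1L, {
    idx <- sample.int(n)
    n_val <- if (cfg$val_fraction > 0) max(1L, floor(cfg$val_fraction * n)) else 0L
    val_idx <- head(idx, n_val)
    tr_idx <- setdiff(idx, val_idx)
    hist <- list()
    best <- list(loss = Inf, params = model$params, wait = 0L)
    state <- adam_init(model$params)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        bidx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        grads <- NULL
        for (i in bidx) {
          fw <- triage_fwd(model, ct[[i]]$tokens, train = TRUE)
          bc <- sigmoid_bce(fw$logit, labels[i])
          g <- triage_bwd(model, fw, bc$dlogits)
          grads <- if (is.null(grads)) g else add_grads2(grads, g)
          ep_loss <- ep_loss + bc$loss
          ep_correct <- ep_correct + as.integer((fw$prob >= cfg$threshold) == (labels[i] == 1))
        }
        grads <- scale_grads(grads, 1 / length(bidx))
        grads <- apply_l2(grads, model$params, cfg$l2)
        st <- adam_step(model$params, grads, state, lr = cfg$lr)
        model$params <- st$params; state <- st$state
      }
      row <- tibble(epoch = ep, loss = ep_loss / length(ord),
                    accuracy = ep_correct / length(ord),
                    val_loss = NA_real_, val_accuracy = NA_real_)
      if (n_val > 0) {
        vl <- 0; vc <- 0
        for (i in val_idx) {
          fw <- triage_fwd(model, ct[[i]]$tokens, train = FALSE)
          vl <- vl + sigmoid_bce(fw$logit, labels[i])$loss
          vc <- vc + as.integer((fw$prob >= cfg$threshold) == (labels[i] == 1))
        }
        row$val_loss <- vl / n_val
        row$val_accuracy <- vc / n_val
        if (row$val_loss < best$loss - 1e-6) {
          best$loss <- row$val_loss; best$params <- model$params; best$wait <- 0L
        } else best$wait <- best$wait + 1L
      }
      hist[[ep]] <- row
      if (n_val > 0 && best$wait >= cfg$patience) break
    }
    if (n_val > 0 && is.finite(best$loss)) model$params <- best$params
    model$history <- bind_rows(hist)
  })
  model$trained <- TRUE
  model
}

#' Predict triage relevance for a corpus
#'
#' @param model A trained `bt_triage_model`.
#' @param docs List of `bt_document` objects.
#' @return A tibble: `doc_id`, `prob`, `.pred` (0/1 at the config
#'   threshold).
#' @export
predict_triage <- function(model, docs) {
  cfg <- model$config
  ct <- corpus_tokens(docs, cfg)
  probs <- map_dbl(ct, function(x) triage_fwd(model, x$tokens, train = FALSE)$prob)
  tibble(doc_id = map_chr(ct, "doc_id"), prob = probs,
         .pred = as.integer(probs >= cfg$threshold))
}

#' @export
predict.bt_triage_model <- function(object, newdata, ...) predict_triage(object, newdata)

#' Attention weights for a corpus, one row per passage
#'
#' @param model A trained `bt_triage_model`.
#' @param docs List of `bt_document` objects.
#' @return A tibble: `doc_id`, `position`, `kind`, `weight`.
#' @export
attention_weights <- function(model, docs) {
  bind_rows(lapply(docs, function(d) classify_document(model, d)$attention))
}

#' Write attention weights as JSON lines
#'
#' One JSON object per passage: `doc_id`, `position`, `kind`, `weight`.
#'
#' @param weights Output of [attention_weights()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attention_jsonl <- function(weights, path) {
  lines <- vapply(seq_len(nrow(weights)), function(i) {
    jsonlite::toJSON(as.list(weights[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Evaluate a triage configuration over multiple restarts
#'
#' Fixed stratified train/test split; restarts differ only in the
#' initialization/shuffling seed, mirroring multi-execution reporting of
#' accuracy mean and standard deviation per condition.
#'
#' @param docs List of `bt_document`s.
#' @param labels 0/1 labels parallel to `docs`.
#' @param config A [triage_config()].
#' @param embeddings A `bt_embeddings`.
#' @param n_restarts,seeds As in [evaluate_multirestart()].
#' @param test_fraction Held-out fraction.
#' @param split_seed Seed for the split (fixed across restarts).
#' @return A `bt_eval`.
#' @export
triage_multirestart <- function(docs, labels, config, embeddings,
                                n_restarts = 3L, seeds = NULL,
                                test_fraction = 0.2, split_seed = config$seed) {
  if (is.null(seeds)) seeds <- config$seed + seq_len(n_restarts) - 1L
  sp <- stratified_split(as.character(labels), test_fraction, split_seed)
  accs <- map_dbl(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    m <- build_triage_model(cfg, embeddings)
    m <- train_triage(m, docs[sp$train], labels[sp$train])
    pred <- predict_triage(m, docs[sp$test])
    accuracy(pred$.pred, labels[sp$test])
  })
  new_eval(tibble(restart = seq_along(seeds), seed = as.integer(seeds), accuracy = accs),
           task = paste0("triage/", config$text_source), config = config)
}

#' @export
tidy.bt_triage_model <- function(x, ...) {
  tibble(parameter = names(x$params),
         n_values = map_int(x$params, length),
         l2_norm = map_dbl(x$params, function(p) sqrt(sum(p^2))))
}

#' @export
glance.bt_triage_model <- function(x, ...) {
  h <- x$history
  tibble(text_source = x$config$text_source, encoder = x$config$encoder,
         aggregation = x$config$aggregation,
         n_parameters = sum(map_int(x$params, length)),
         epochs_run = if (is.null(h)) 0L else nrow(h),
         final_train_accuracy = if (is.null(h)) NA_real_ else tail(h$accuracy, 1),
         final_val_accuracy = if (is.null(h)) NA_real_ else tail(h$val_accuracy, 1))
}
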