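# Passage-level classification of experimental-method codes: a passage of
# text anchored to a subfigure (caption or evidence fragment) is classified
# into grouped PSI-MI-style detection-method codes, with CNN and LSTM
# architectures over frozen pre-trained word embeddings.

# ---- Label schemes ---------------------------------------------------------

#' Build a label scheme mapping fine codes to grouped codes
#'
#' Method-code targets are grouped to reduce label sparsity (e.g. 44 fine
#' participant-detection codes to 8 grouped codes; 84 interaction-detection
#' codes to 17 grouped codes). A scheme is a total mapping over its declared
#' fine codes; the grouped label set is the image of the mapping.
#'
#' @param mapping A data frame with columns `fine_code`, `grouped_code`, or a
#'   named character vector (names = fine codes).
#' @param name Scheme name.
#' @return A `bt_label_scheme`.
#' @export
label_scheme <- function(mapping, name = "scheme") {
  if (is.character(mapping) && !is.null(names(mapping))) {
    mapping <- tibble(fine_code = names(mapping), grouped_code = unname(mapping))
  }
  mapping <- as_tibble(mapping)[, c("fine_code", "grouped_code")]
  if (anyDuplicated(mapping$fine_code)) abort("duplicate fine codes in scheme")
  structure(list(name = name, mapping = mapping,
                 grouped = sort(unique(mapping$grouped_code))),
            class = "bt_label_scheme")
}

#' @export
print.bt_label_scheme <- function(x, ...) {
  cat("<bt_label_scheme> ", x$name, ": ", nrow(x$mapping), " fine codes -> ",
      length(x$grouped), " grouped codes\n", sep = "")
  invisible(x)
}

#' Read a label scheme from a two-column TSV
#'
#' @param path TSV with columns `fine_code`, `grouped_code` (header optional:
#'   detected by the literal first field `fine_code`).
#' @param name Scheme name; defaults to the file name.
#' @return A `bt_label_scheme`.
#' @export
read_label_scheme <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  has_header <- length(lines) && startsWith(lines[[1]], "fine_code")
  df <- utils::read.delim(text = lines, header = has_header,
                          col.names = c("fine_code", "grouped_code"),
                          stringsAsFactors = FALSE)
  label_scheme(df, name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' Map a fine method code to its grouped code
#'
#' @param scheme A `bt_label_scheme`.
#' @param fine Fine code(s).
#' @return Grouped code(s); unknown fine codes are an error naming the code
#'   and scheme.
#' @export
group_label <- function(scheme, fine) {
  stopifnot(inherits(scheme, "bt_label_scheme"))
  idx <- match(fine, scheme$mapping$fine_code)
  if (anyNA(idx)) {
    abort(paste0("fine code(s) not in scheme ", shQuote(scheme$name), ": ",
                 paste(shQuote(unique(fine[is.na(idx)])), collapse = ", ")))
  }
  scheme$mapping$grouped_code[idx]
}

# ---- Configuration ---------------------------------------------------------

#' Configuration for a passage classifier
#'
#' @param arch `"cnn"` (1-D convolutions over token positions, global max
#'   pooling) or `"lstm"` (final recurrent state).
#' @param max_len Tokens kept per passage (head-keep truncation).
#' @param filter_widths,n_filters CNN filter widths and filters per width.
#' @param lstm_units LSTM hidden units.
#' @param dense_width Hidden dense layer width; 0 for none.
#' @param dropout Dropout rate before the dense stack. Rates outside
#'   `[0.25, 0.5]` (other than 0) trigger a warning: that band is where these
#'   small text classifiers generalize well.
#' @param l2 L2 penalty on weight matrices (default `1e-4`).
#' @param trainable_embeddings Update the embedding matrix during training
#'   (default `FALSE`: frozen embeddings, the regime that controls
#'   overfitting on small corpora).
#' @param epochs,batch_size,lr Training schedule (Adam optimizer).
#' @param val_fraction Fraction of training passages held out for early
#'   stopping; 0 disables.
#' @param patience Early-stopping patience on validation loss.
#' @param class_weights `NULL`, or `"inverse_frequency"` for imbalance
#'   reweighting.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return A `bt_passage_config` list.
#' @export
passage_config <- function(arch = c("cnn", "lstm"), max_len = 300L,
                           filter_widths = c(3L, 4L, 5L), n_filters = 64L,
                           lstm_units = 128L, dense_width = if (match.arg(arch) == "cnn") 64L else 0L,
                           dropout = 0.5, l2 = 1e-4, trainable_embeddings = FALSE,
                           epochs = 10L, batch_size = 32L, lr = 1e-3,
                           val_fraction = 0.15, patience = 3L,
                           class_weights = NULL, seed = 1L) {
  arch <- match.arg(arch)
  stopifnot(max_len >= 1, n_filters >= 1, lstm_units >= 1, epochs >= 0,
            batch_size >= 1, all(filter_widths >= 1))
  if (dropout != 0 && (dropout < 0.25 || dropout > 0.5)) {
    warn("dropout outside the recommended [0.25, 0.5] band")
  }
  structure(list(arch = arch, max_len = as.integer(max_len),
                 filter_widths = as.integer(filter_widths),
                 n_filters = as.integer(n_filters),
                 lstm_units = as.integer(lstm_units),
                 dense_width = as.integer(dense_width), dropout = dropout,
                 l2 = l2, trainable_embeddings = isTRUE(trainable_embeddings),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, val_fraction = val_fraction, patience = as.integer(patience),
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "bt_passage_config")
}

# ---- Model construction ----------------------------------------------------

#' Build an (untrained) passage classifier
#'
#' @param config A [passage_config()].
#' @param embeddings A `bt_embeddings` table (frozen by default).
#' @param classes Character vector of grouped class labels (output order).
#' @return A `bt_passage_model` with seeded initial parameters.
#' @export
build_passage_model <- function(config, embeddings, classes) {
  stopifnot(inherits(config, "bt_passage_config"), inherits(embeddings, "bt_embeddings"))
  classes <- as.character(classes)
  if (length(classes) < 2) abort("need at least 2 classes")
  d <- embeddings$dim
  K <- length(classes)
  params <- with_seed(config$seed, {
    p <- list()
    if (config$arch == "cnn") {
      for (w in config$filter_widths) {
        p[[paste0("conv", w, "_W")]] <- glorot(w * d, config$n_filters, c(w * d, config$n_filters))
        p[[paste0("conv", w, "_b")]] <- numeric(config$n_filters)
      }
      feat <- length(config$filter_widths) * config$n_filters
    } else {
      lp <- lstm_init(d, config$lstm_units)
      p$lstm_Wx <- lp$Wx; p$lstm_Wh <- lp$Wh; p$lstm_b <- lp$b
      feat <- config$lstm_units
    }
    if (config$dense_width > 0) {
      p$dense_W <- glorot(feat, config$dense_width, c(feat, config$dense_width))
      p$dense_b <- numeric(config$dense_width)
      feat <- config$dense_width
    }
    p$out_W <- glorot(feat, K, c(feat, K))
    p$out_b <- numeric(K)
    p
  })
  structure(list(config = config, embeddings = embeddings, classes = classes,
                 params = params, trained = FALSE, history = NULL),
            class = "bt_passage_model")
}

#' @export
print.bt_passage_model <- function(x, ...) {
  cat("<bt_passage_model> ", toupper(x$config$arch), ", ",
      length(x$classes), " classes, ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

# Forward pass on a list of token vectors. Returns logits plus caches.
passage_fwd <- function(model, token_lists, train = FALSE) {
  cfg <- model$config; P <- model$params
  eb <- embed_batch(model$embeddings, token_lists, cfg$max_len, trim = TRUE,
                    min_len = if (cfg$arch == "cnn") max(cfg$filter_widths) else 1L)
  T_used <- dim(eb$E)[2]
  caches <- list(eb = eb)
  if (cfg$arch == "cnn") {
    pooled <- list(); caches$conv <- list(); caches$pool <- list()
    for (w in cfg$filter_widths) {
      cv <- conv1d_fwd(eb$E, P[[paste0("conv", w, "_W")]], P[[paste0("conv", w, "_b")]], w)
      mp <- maxpool_fwd(cv$out, conv_lens(eb$lens, T_used, w))
      caches$conv[[as.character(w)]] <- cv
      caches$pool[[as.character(w)]] <- mp
      pooled[[as.character(w)]] <- mp$out
    }
    feat <- do.call(cbind, pooled)
  } else {
    ls <- lstm_fwd(eb$E, pmax(eb$lens, 1L), list(Wx = P$lstm_Wx, Wh = P$lstm_Wh, b = P$lstm_b))
    caches$lstm <- ls
    feat <- ls$H
  }
  dr <- dropout_fwd(feat, cfg$dropout, train)
  caches$drop <- dr
  x <- dr$out
  if (cfg$dense_width > 0) {
    dn <- dense_fwd(x, P$dense_W, P$dense_b, relu = TRUE)
    caches$dense <- dn
    x <- dn$out
  }
  out <- dense_fwd(x, P$out_W, P$out_b)
  caches$out <- out
  list(logits = out$out, caches = caches)
}

passage_bwd <- function(model, fw, dlogits) {
  cfg <- model$config; P <- model$params; caches <- fw$caches
  g <- list()
  bo <- dense_bwd(caches$out$X, caches$out$Z, P$out_W, dlogits)
  g$out_W <- bo$dW; g$out_b <- bo$db
  dx <- bo$dX
  if (cfg$dense_width > 0) {
    bd <- dense_bwd(caches$dense$X, caches$dense$Z, P$dense_W, dx, relu = TRUE)
    g$dense_W <- bd$dW; g$dense_b <- bd$db
    dx <- bd$dX
  }
  dfeat <- dropout_bwd(caches$drop, dx)
  if (cfg$arch == "cnn") {
    nf <- cfg$n_filters
    for (i in seq_along(cfg$filter_widths)) {
      w <- cfg$filter_widths[i]
      cols <- ((i - 1L) * nf + 1L):(i * nf)
      dpool <- dfeat[, cols, drop = FALSE]
      dA <- maxpool_bwd(caches$pool[[as.character(w)]], dpool)
      cb <- conv1d_bwd(caches$conv[[as.character(w)]], P[[paste0("conv", w, "_W")]],
                       dA, need_dE = cfg$trainable_embeddings)
      g[[paste0("conv", w, "_W")]] <- cb$dW
      g[[paste0("conv", w, "_b")]] <- cb$db
      if (cfg$trainable_embeddings) g$.dE <- (g$.dE %||% 0) + cb$dE
    }
  } else {
    lb <- lstm_bwd(caches$lstm, list(Wx = P$lstm_Wx, Wh = P$lstm_Wh, b = P$lstm_b),
                   dfeat, need_dE = cfg$trainable_embeddings)
    g$lstm_Wx <- lb$dWx; g$lstm_Wh <- lb$dWh; g$lstm_b <- lb$db
    if (cfg$trainable_embeddings) g$.dE <- lb$dE
  }
  g
}

# Scatter-add a (B, T, d) embedding gradient into the embedding matrix rows.
apply_embedding_grad <- function(model, dE, token_lists, lr) {
  tab <- model$embeddings
  for (b in seq_along(token_lists)) {
    toks <- head(token_lists[[b]], dim(dE)[2])
    idx <- token_rows(tab, toks)
    for (t in seq_along(idx)) {
      if (idx[t] >= 2L) {
        tab$matrix[idx[t], ] <- tab$matrix[idx[t], ] - lr * dE[b, t, ]
      }
    }
  }
  tab
}

# ---- Training --------------------------------------------------------------

prepare_tokens <- function(data, max_len) {
  if ("tokens" %in% names(data)) {
    lapply(data$tokens, function(t) head(t, max_len))
  } else if (!is.null(data$text)) {
    lapply(data$text, function(x) head(tokenize(x), max_len))
  } else abort("data must have a `text` or `tokens` column")
}

#' Train a passage classifier
#'
#' Mini-batch Adam training with optional early stopping on a held-out
#' validation split. With `epochs = 0` the model is returned unchanged from
#' its seeded initialization. All randomness (shuffling, dropout, split)
#' derives from the config seed; reruns are bit-identical.
#'
#' @param model A `bt_passage_model` from [build_passage_model()].
#' @param data A data frame with a `text` (or list-column `tokens`) column
#'   and a `label` column of grouped codes. At least two distinct labels
#'   must be present.
#' @return The trained model; `$history` holds a tibble of per-epoch train
#'   (and validation) loss and accuracy.
#' @export
train_passage_classifier <- function(model, data) {
  stopifnot(inherits(model, "bt_passage_model"))
  cfg <- model$config
  data <- as_tibble(data)
  if (is.null(data$label)) abort("data must have a `label` column")
  if (length(unique(data$label)) < 2) abort("training data contains a single class")
  unknown <- setdiff(unique(data$label), model$classes)
  if (length(unknown)) abort(paste0("label(s) not in model classes: ",
                                    paste(shQuote(unknown), collapse = ", ")))
  if (cfg$epochs == 0) return(model)
  toks <- prepare_tokens(data, cfg$max_len)
  y <- match(data$label, model$classes)

  wts <- NULL
  if (identical(cfg$class_weights, "inverse_frequency")) {
    freq <- table(factor(y, levels = seq_along(model$classes)))
    wvec <- sum(freq) / (length(freq) * pmax(as.numeric(freq), 1))
    wts_all <- wvec[y]
  } else wts_all <- rep(1, length(y))

  with_seed(cfg$seed + 1L, {
    n <- length(y)
    idx <- sample.int(n)
    n_val <- if (cfg$val_fraction > 0) max(1L, floor(cfg$val_fraction * n)) else 0L
    val_idx <- head(idx, n_val)
    tr_idx <- setdiff(idx, val_idx)
    hist <- list()
    best <- list(loss = Inf, params = model$params, emb = model$embeddings, wait = 0L)
    state <- adam_init(model$params)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_n <- 0; ep_correct <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        bidx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        fw <- passage_fwd(model, toks[bidx], train = TRUE)
        ce <- softmax_ce(fw$logits, y[bidx], wts = wts_all[bidx])
        g <- passage_bwd(model, fw, ce$dlogits)
        dE <- g$.dE; g$.dE <- NULL
        g <- apply_l2(g, model$params, cfg$l2)
        st <- adam_step(model$params, g, state, lr = cfg$lr)
        model$params <- st$params; state <- st$state
        if (cfg$trainable_embeddings && !is.null(dE)) {
          model$embeddings <- apply_embedding_grad(model, dE, toks[bidx], cfg$lr)
        }
        ep_loss <- ep_loss + ce$loss * length(bidx)
        ep_n <- ep_n + length(bidx)
        ep_correct <- ep_correct + sum(max.col(ce$probs, ties.method = "first") == y[bidx])
      }
      row <- tibble(epoch = ep, loss = ep_loss / ep_n, accuracy = ep_correct / ep_n,
                    val_loss = NA_real_, val_accuracy = NA_real_)
      if (n_val > 0) {
        fwv <- passage_fwd(model, toks[val_idx], train = FALSE)
        cev <- softmax_ce(fwv$logits, y[val_idx])
        row$val_loss <- cev$loss
        row$val_accuracy <- mean(max.col(cev$probs, ties.method = "first") == y[val_idx])
        if (cev$loss < best$loss - 1e-6) {
          best$loss <- cev$loss; best$params <- model$params
          best$emb <- model$embeddings; best$wait <- 0L
        } else {
          best$wait <- best$wait + 1L
        }
      }
      hist[[ep]] <- row
      if (n_val > 0 && best$wait >= cfg$patience) break
    }
    if (n_val > 0 && is.finite(best$loss)) {
      model$params <- best$params
      model$embeddings <- best$emb
    }
    model$history <- bind_rows(hist)
  })
  model$trained <- TRUE
  model
}

#' Predict class probabilities for passages
#'
#' @param model A `bt_passage_model`.
#' @param data A data frame with `text` (or `tokens`) column, or a character
#'   vector of passage texts.
#' @return A tibble with one `.prob_<class>` column per class plus `.pred`
#'   (argmax, ties broken toward the lowest class index). Probabilities are
#'   softmax-normalized.
#' @export
predict_passage <- function(model, data) {
  stopifnot(inherits(model, "bt_passage_model"))
  if (is.character(data)) data <- tibble(text = data)
  data <- as_tibble(data)
  toks <- prepare_tokens(data, model$config$max_len)
  fw <- passage_fwd(model, toks, train = FALSE)
  P <- softmax_rows(fw$logits)
  out <- as_tibble(as.data.frame(P))
  names(out) <- paste0(".prob_", model$classes)
  out$.pred <- model$classes[max.col(P, ties.method = "first")]
  out
}

#' @export
predict.bt_passage_model <- function(object, newdata, ...) predict_passage(object, newdata)

# ---- Multi-restart evaluation ----------------------------------------------

#' Evaluate a passage classifier over multiple random restarts
#'
#' Repeats train/evaluate with identical data and configuration except the
#' initialization/shuffling seed, to control for variability and local
#' minima. The train/test split is stratified by class and fixed across
#' restarts (driven by `split_seed`).
#'
#' @param data Labeled passages (columns `text`/`tokens` and `label`).
#' @param config A [passage_config()]; its `seed` is ignored in favor of
#'   `seeds`.
#' @param embeddings A `bt_embeddings`.
#' @param n_restarts Number of restarts (ignored if `seeds` given).
#' @param seeds Explicit integer seeds, one per restart.
#' @param test_fraction Held-out fraction for the fixed stratified split.
#' @param split_seed Seed for the split.
#' @return A `bt_eval` object: per-restart accuracies plus mean and sample
#'   standard deviation (0 for a single restart).
#' @export
evaluate_multirestart <- function(data, config, embeddings, n_restarts = 3L,
                                  seeds = NULL, test_fraction = 0.2,
                                  split_seed = config$seed) {
  data <- as_tibble(data)
  if (is.null(seeds)) seeds <- config$seed + seq_len(n_restarts) - 1L
  sp <- stratified_split(data$label, test_fraction, split_seed)
  train <- data[sp$train, , drop = FALSE]
  test <- data[sp$test, , drop = FALSE]
  classes <- sort(unique(data$label))
  accs <- map_dbl(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    m <- build_passage_model(cfg, embeddings, classes)
    m <- train_passage_classifier(m, train)
    pred <- predict_passage(m, test)
    accuracy(pred$.pred, test$label)
  })
  new_eval(tibble(restart = seq_along(seeds), seed = as.integer(seeds), accuracy = accs),
           task = "passage", config = config)
}

stratified_split <- function(labels, test_fraction, seed) {
  with_seed(seed, {
    test <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
      k <- max(1L, round(test_fraction * length(ix)))
      sample(ix, min(k, length(ix)))
    }))
    list(train = setdiff(seq_along(labels), test), test = sort(unname(test)))
  })
}

new_eval <- function(per_restart, task, config) {
  structure(list(per_restart = per_restart,
                 mean = mean(per_restart$accuracy),
                 sd = if (nrow(per_restart) > 1) sd(per_restart$accuracy) else 0,
                 task = task, config = config),
            class = "bt_eval")
}

#' @export
print.bt_eval <- function(x, ...) {
  cat("<bt_eval> ", x$task, ": accuracy ", sprintf("%.3f", x$mean), " ± ",
      sprintf("%.3f", x$sd), " over ", nrow(x$per_restart), " restart(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.bt_eval <- function(x, ...) x$per_restart

#' @export
glance.bt_eval <- function(x, ...) {
  tibble(task = x$task, accuracy_mean = x$mean, accuracy_sd = x$sd,
         n_restarts = nrow(x$per_restart))
}

#' @export
tidy.bt_passage_model <- function(x, ...) {
  tibble(parameter = names(x$params),
         n_values = map_int(x$params, length),
         l2_norm = map_dbl(x$params, function(p) sqrt(sum(p^2))))
}

#' @export
glance.bt_passage_model <- function(x, ...) {
  h <- x$history
  tibble(arch = x$config$arch, n_classes = length(x$classes),
         n_parameters = sum(map_int(x$params, length)),
         epochs_run = if (is.null(h)) 0L else nrow(h),
         final_train_accuracy = if (is.null(h)) NA_real_ else tail(h$accuracy, 1),
         final_val_accuracy = if (is.null(h)) NA_real_ else tail(h$val_accuracy, 1))
}
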