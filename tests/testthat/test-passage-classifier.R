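test_that("label schemes map fine codes to grouped codes and reject unknowns", {
  id <- label_scheme(tibble::tibble(fine_code = c("a", "b"), grouped_code = c("a", "b")))
  expect_identical(group_label(id, "a"), "a")
  sch <- label_scheme(c(a = "X", b = "X", c = "Y"))
  expect_identical(group_label(sch, "b"), "X")
  expect_identical(group_label(sch, c("a", "c")), c("X", "Y"))
  expect_identical(sch$grouped, c("X", "Y"))
  expect_error(group_label(sch, "zz"), "zz")
  expect_error(label_scheme(c(a = "X", a = "Y")), "duplicate")
})

test_that("bundled synthetic scheme files carry the grouped-code cardinalities", {
  p8 <- read_label_scheme(system.file("extdata", "scheme_participant8_synthetic.tsv",
                                      package = "biotriage"))
  expect_identical(nrow(p8$mapping), 44L)
  expect_length(p8$grouped, 8L)
  i17 <- read_label_scheme(system.file("extdata", "scheme_interaction17_synthetic.tsv",
                                       package = "biotriage"))
  expect_identical(nrow(i17$mapping), 84L)
  expect_length(i17$grouped, 17L)
})

test_that("model construction is seeded and sized by the class set", {
  emb <- toy_embeddings(dim = 6)
  cfg <- passage_config("cnn", max_len = 10, n_filters = 4, dense_width = 0,
                        epochs = 1, seed = 7)
  m2 <- build_passage_model(cfg, emb, c("yes", "no"))
  expect_identical(ncol(m2$params$out_W), 2L)
  m17 <- build_passage_model(passage_config("lstm", lstm_units = 4, seed = 7),
                             emb, sprintf("g%02d", 1:17))
  expect_identical(ncol(m17$params$out_W), 17L)
  # same seed -> identical initial parameters
  m2b <- build_passage_model(cfg, emb, c("yes", "no"))
  expect_identical(m2$params, m2b$params)
  expect_error(build_passage_model(cfg, emb, "one"), "2 classes")
  expect_error(passage_config("transformer"), "arg")
})

test_that("predictions are normalized distributions with deterministic argmax", {
  emb <- toy_embeddings(dim = 6)
  cfg <- passage_config("cnn", max_len = 8, n_filters = 4, dense_width = 0,
                        epochs = 0, seed = 3)
  m <- build_passage_model(cfg, emb, c("no", "yes"))
  pr <- predict_passage(m, c("p53 binds mdm2 .", "", "a b c"))
  probs <- as.matrix(pr[, c(".prob_no", ".prob_yes")])
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, 3), tolerance = 1e-6)
  expect_length(pr$.pred, 3L)            # empty passage still classifies
})

test_that("training recovers a deterministic token signal and is seed-reproducible", {
  d <- separable_passages(n = 400)
  emb <- toy_embeddings(separable_vocab(), dim = 16, seed = 21)
  cfg <- passage_config("cnn", max_len = 10, n_filters = 8, dense_width = 8,
                        dropout = 0.25, lr = 1e-2, epochs = 25, patience = 8,
                        seed = 5)
  ev <- evaluate_multirestart(d, cfg, emb, n_restarts = 1)
  expect_gte(ev$mean, 0.95)
  expect_identical(ev$sd, 0)             # single restart reports sd 0
  # bit-identical rerun under the same seeds
  ev2 <- evaluate_multirestart(d, cfg, emb, n_restarts = 1)
  expect_identical(ev$per_restart, ev2$per_restart)
})

test_that("zero epochs leave the model at its initialization", {
  d <- separable_passages(n = 40)
  emb <- toy_embeddings(separable_vocab(), dim = 8)
  cfg <- passage_config("cnn", max_len = 10, n_filters = 4, dense_width = 0,
                        epochs = 0, seed = 2)
  m <- build_passage_model(cfg, emb, c("no", "yes"))
  m2 <- train_passage_classifier(m, d)
  expect_identical(m$params, m2$params)
})

test_that("single-class training data is rejected", {
  d <- separable_passages(n = 30)
  d$label <- "yes"
  emb <- toy_embeddings(separable_vocab(), dim = 8)
  m <- build_passage_model(passage_config("cnn", epochs = 1, seed = 1), emb,
                           c("no", "yes"))
  expect_error(train_passage_classifier(m, d), "single class")
})

test_that("frozen embeddings are bit-identical after training", {
  d <- separable_passages(n = 80)
  emb <- toy_embeddings(separable_vocab(), dim = 10, seed = 4)
  before <- emb$matrix
  cfg <- passage_config("lstm", max_len = 10, lstm_units = 6, dropout = 0.25,
                        epochs = 3, seed = 6)
  m <- build_passage_model(cfg, emb, c("no", "yes"))
  m <- train_passage_classifier(m, d)
  expect_identical(m$embeddings$matrix, before)

  # ... and the trainable flag really updates them
  cfg$trainable_embeddings <- TRUE
  m2 <- build_passage_model(cfg, emb, c("no", "yes"))
  m2 <- train_passage_classifier(m2, d)
  expect_false(identical(m2$embeddings$matrix, before))
})

test_that("label-shuffled training stays near the majority rate", {
  d <- separable_passages(n = 160)
  d$label <- biotriage:::with_seed(99, sample(d$label))
  emb <- toy_embeddings(separable_vocab(), dim = 12, seed = 21)
  cfg <- passage_config("cnn", max_len = 10, n_filters = 8, dense_width = 8,
                        dropout = 0.25, lr = 1e-2, epochs = 8, seed = 5)
  ev <- evaluate_multirestart(d, cfg, emb, n_restarts = 1)
  maj <- max(table(d$label)) / nrow(d)
  expect_lt(abs(ev$mean - maj), 0.15)
})

test_that("held-out accuracy is non-decreasing in planted signal strength", {
  emb_vocab <- c(sprintf("w%04d", 1:200), sprintf("sigm01x%02d", 1:5),
                 sprintf("sigm02x%02d", 1:5), ".")
  emb <- toy_embeddings(emb_vocab, dim = 16, seed = 77)
  accs <- vapply(c(0.2, 0.5, 1.0), function(p) {
    sc <- synth_config(n_method_classes = 2, signal_p = p, vocab_size = 200,
                       seed = 303)
    gen <- generate_method_corpus(sc, n_passages = 300)
    cfg <- passage_config("cnn", max_len = 24, n_filters = 8, dense_width = 8,
                          dropout = 0.25, lr = 1e-2, epochs = 15, patience = 5,
                          seed = 11)
    evaluate_multirestart(gen$passages, cfg, emb, n_restarts = 2)$mean
  }, numeric(1))
  expect_true(all(diff(accs) > -0.05))
})

test_that("tidy and glance summarize models and evaluations", {
  d <- separable_passages(n = 40)
  emb <- toy_embeddings(separable_vocab(), dim = 8)
  cfg <- passage_config("cnn", max_len = 10, n_filters = 4, dense_width = 0,
                        epochs = 2, seed = 2)
  m <- train_passage_classifier(build_passage_model(cfg, emb, c("no", "yes")), d)
  td <- tidy(m)
  expect_true(all(c("parameter", "n_values", "l2_norm") %in% names(td)))
  gl <- glance(m)
  expect_identical(gl$arch, "cnn")
  expect_identical(gl$epochs_run, 2L)
})
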