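triage_doc <- function() {
  document("t1", title = "A triage title",
           abstract = "First point. Second point.",
           mesh_terms = c("Proteins", "Mice"),
           paragraphs = c("We found X ( Fig. 1A ). More.", "Unrelated text."),
           captions = c("1" = "Blot result.", "2" = "Assay result.",
                        "3" = "Control result."))
}

test_that("passage selection follows the eight text-source contracts", {
  doc <- triage_doc()
  caps <- select_passages(doc, "captions")
  expect_identical(nrow(caps), 3L)
  expect_true(all(caps$kind == "caption"))
  expect_identical(caps$figure, 1:3)

  expect_identical(nrow(select_passages(doc, "title")), 1L)
  expect_identical(nrow(select_passages(doc, "abstract")), 1L)
  ta <- select_passages(doc, "title_abstract")
  expect_identical(nrow(ta), 1L)
  expect_match(ta$text, "A triage title First point")
  expect_identical(nrow(select_passages(doc, "mesh")), 1L)
  expect_identical(nrow(select_passages(doc, "all_paragraphs")), 2L)

  ef <- select_passages(doc, "evidence_fragments")
  expect_identical(nrow(ef), 1L)
  expect_identical(ef$kind, "evidence_fragment")

  both <- select_passages(doc, "captions_plus_fragments")
  expect_identical(both$kind, c(rep("caption", 3), "evidence_fragment"))
  expect_identical(both$position, 1:4)
})

test_that("empty selections degrade to a single empty passage; caps truncate", {
  bare <- document("b1", title = "Only a title", abstract = "Abs.")
  expect_warning(ps <- select_passages(bare, "captions"), "empty selection")
  expect_identical(nrow(ps), 1L)
  expect_identical(ps$text, "")

  doc <- triage_doc()
  expect_message(capped <- select_passages(doc, "captions", max_passages = 2),
                 "truncated")
  expect_identical(nrow(capped), 2L)
})

test_that("passage encoding is deterministic with the contracted width", {
  emb <- toy_embeddings(dim = 6)
  cfg <- triage_config("captions", encoder = "cnn_bilstm", n_filters = 4,
                       lstm_units = 5, max_len = 12, epochs = 1, seed = 8)
  m <- build_triage_model(cfg, emb)
  toks <- list(c("p53", "binds", "mdm2"), c("p53", "binds", "mdm2"), character())
  H <- encode_passage(m, toks)
  expect_identical(ncol(H), 10L)                  # 2 x lstm_units
  expect_identical(H[1, ], H[2, ])                # identical passages
  expect_true(all(is.finite(H[3, ])))             # all-pad input, bias-driven
  expect_identical(H, encode_passage(m, toks))    # deterministic
})

test_that("attention weights normalize, localize trivially and ignore order", {
  P <- biotriage:::with_seed(4, biotriage:::attention_init(6, 4))
  H1 <- matrix(rnorm(6), 1, 6)
  a1 <- attend(H1, P)
  expect_equal(a1$weights, 1, tolerance = 1e-12)
  expect_equal(a1$doc_vector, drop(H1), tolerance = 1e-12)

  Hk <- matrix(rep(rnorm(6), each = 5), 5, 6)     # identical rows
  ak <- attend(Hk, P)
  expect_equal(ak$weights, rep(0.2, 5), tolerance = 1e-9)

  H <- matrix(rnorm(24), 4, 6)
  a <- attend(H, P)
  expect_equal(sum(a$weights), 1, tolerance = 1e-6)
  perm <- c(3, 1, 4, 2)
  ap <- attend(H[perm, ], P)
  expect_equal(ap$weights, a$weights[perm], tolerance = 1e-9)
  expect_equal(ap$doc_vector, a$doc_vector, tolerance = 1e-9)
})

test_that("document classification returns a probability and inspectable attention", {
  emb <- toy_embeddings(dim = 6)
  cfg <- triage_config("captions", n_filters = 4, lstm_units = 4,
                       attention_width = 4, max_len = 12, epochs = 0, seed = 9)
  m <- build_triage_model(cfg, emb)
  out <- classify_document(m, triage_doc())
  expect_gte(out$prob, 0)
  expect_lte(out$prob, 1)
  expect_identical(nrow(out$attention), 3L)
  expect_equal(sum(out$attention$weight), 1, tolerance = 1e-6)

  cfg1 <- triage_config("title", max_len = 12, epochs = 0, seed = 9)
  m1 <- build_triage_model(cfg1, emb)
  out1 <- classify_document(m1, triage_doc())
  expect_equal(out1$attention$weight, 1, tolerance = 1e-12)
})

test_that("triage training is seeded, reproducible and rejects single-class labels", {
  sc <- synth_config(n_docs = 40, signal_p = 1, seed = 17)
  gen <- generate_triage_corpus(sc)
  emb <- toy_embeddings(corpus_vocab(gen$docs), dim = 10, seed = 17)
  cfg <- triage_config("captions", n_filters = 6, lstm_units = 6,
                       attention_width = 6, max_len = 24, dropout = 0.25,
                       epochs = 2, seed = 23)
  m <- build_triage_model(cfg, emb)
  expect_error(train_triage(m, gen$docs, rep(1, length(gen$docs))), "single class")
  m1 <- train_triage(m, gen$docs, gen$labels$label)
  m2 <- train_triage(m, gen$docs, gen$labels$label)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  p1 <- predict_triage(m1, gen$docs[1:5])
  expect_true(all(p1$prob >= 0 & p1$prob <= 1))
  expect_identical(p1, predict_triage(m2, gen$docs[1:5]))
})

test_that("attention dumps export one JSON line per passage", {
  sc <- synth_config(n_docs = 4, seed = 3)
  gen <- generate_triage_corpus(sc)
  emb <- toy_embeddings(corpus_vocab(gen$docs), dim = 8, seed = 3)
  cfg <- triage_config("captions", n_filters = 4, lstm_units = 4,
                       attention_width = 4, max_len = 16, epochs = 0, seed = 2)
  m <- build_triage_model(cfg, emb)
  w <- attention_weights(m, gen$docs)
  p <- tempfile(fileext = ".jsonl")
  write_attention_jsonl(w, p)
  lines <- readLines(p)
  expect_length(lines, nrow(w))
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("doc_id", "position", "kind", "weight") %in% names(rec)))
})
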