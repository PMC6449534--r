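test_that("triage corpus plants signal only in targeted passages of positives", {
  sc <- synth_config(n_docs = 60, signal_location = "captions", signal_p = 1,
                     seed = 12)
  gen <- generate_triage_corpus(sc)
  sig <- gen$signal_tokens
  has_sig <- function(text) any(tolower(tokenize(text)) %in% sig)
  for (i in seq_along(gen$docs)) {
    doc <- gen$docs[[i]]
    caption_hit <- any(vapply(doc$captions, has_sig, logical(1)))
    other_hit <- has_sig(paste(doc$title, doc$abstract,
                               paste(doc$paragraphs$text, collapse = " "),
                               paste(doc$mesh_terms, collapse = " ")))
    if (gen$labels$label[i] == 1) {
      expect_true(caption_hit)     # p = 1: every positive carries signal
    } else {
      expect_false(caption_hit)    # negatives never do
    }
    expect_false(other_hit)        # signal never leaks outside the location
  }
})

test_that("generation is a pure function of the config", {
  sc <- synth_config(n_docs = 15, seed = 77)
  g1 <- generate_triage_corpus(sc)
  g2 <- generate_triage_corpus(sc)
  expect_identical(g1$labels, g2$labels)
  expect_identical(lapply(g1$docs, unclass), lapply(g2$docs, unclass))
  m1 <- generate_method_corpus(sc, n_passages = 50)
  m2 <- generate_method_corpus(sc, n_passages = 50)
  expect_identical(m1$passages, m2$passages)
})

test_that("single-carrier mode marks exactly one signal caption per affected positive", {
  sc <- synth_config(n_docs = 50, signal_location = "captions", signal_p = 1,
                     signal_passages = "one", seed = 5)
  gen <- generate_triage_corpus(sc)
  counts <- table(gen$signal_map$doc_id)
  expect_true(all(counts == 1))
  expect_identical(sort(names(counts)),
                   sort(gen$labels$doc_id[gen$labels$label == 1]))
})

test_that("infeasible signal placement is rejected", {
  expect_error(synth_config(signal_location = "captions",
                            figures_per_doc = c(0L, 0L)),
               "at least one figure")
  expect_error(synth_config(signal_location = "nowhere"), "unknown signal location")
})

test_that("generated figure references are all recovered by the reference parser", {
  sc <- synth_config(n_docs = 25, figure_ref_density = 0.5, seed = 41)
  gen <- generate_triage_corpus(sc)
  for (doc in gen$docs) {
    for (p in doc$paragraphs$text) {
      n_written <- lengths(regmatches(p, gregexpr("Fig\\.", p)))
      expect_identical(nrow(find_figure_references(p)), n_written)
    }
  }
})

test_that("method corpus presets mirror the grouped-code task cardinalities", {
  sc <- synth_config(seed = 8, signal_p = 1)
  g8 <- generate_method_corpus(sc, n_passages = 80, preset = "participant8")
  expect_length(unique(g8$passages$label), 8L)
  expect_length(g8$signal_sets, 8L)
  g17 <- generate_method_corpus(sc, n_passages = 170, preset = "interaction17")
  expect_length(unique(g17$passages$label), 17L)
  gwb <- generate_method_corpus(sc, n_passages = 40, preset = "western_blot_yes_no")
  expect_identical(sort(unique(gwb$passages$label)), c("other", "western_blot"))
  # grouping consistency: every fine code maps to the passage's label
  expect_identical(group_label(g8$scheme, g8$passages$fine_code), g8$passages$label)
  # empty corpus is not an error
  g0 <- generate_method_corpus(sc, n_passages = 0)
  expect_identical(nrow(g0$passages), 0L)
})

test_that("a unigram-presence oracle is perfect at p = 1", {
  sc <- synth_config(seed = 19, signal_p = 1)
  gen <- generate_method_corpus(sc, n_passages = 160, preset = "participant8")
  pred <- unigram_oracle(gen$passages$text, gen$signal_sets, "group01")
  expect_identical(accuracy(pred, gen$passages$label), 1)
})

test_that("captions-located signal does not perturb abstract unigram distributions", {
  sc <- synth_config(n_docs = 1000, signal_location = "captions", signal_p = 0.8,
                     seed = 99)
  gen <- generate_triage_corpus(sc)
  pos <- gen$labels$label == 1
  count_tokens <- function(docs) {
    table(unlist(lapply(docs, function(d) tolower(tokenize(d$abstract)))))
  }
  tp <- count_tokens(gen$docs[pos])
  tn <- count_tokens(gen$docs[!pos])
  toks <- union(names(tp), names(tn))
  M <- cbind(pos = as.numeric(tp[toks]), neg = as.numeric(tn[toks]))
  M[is.na(M)] <- 0
  keep <- rowSums(M) >= 10          # chi-square validity
  pval <- suppressWarnings(stats::chisq.test(M[keep, ]))$p.value
  expect_gt(pval, 0.01)
})

test_that("corpus manifests round-trip through disk", {
  sc <- synth_config(n_docs = 6, seed = 13)
  gen <- generate_triage_corpus(sc)
  dir <- file.path(tempdir(), "bt-corpus-test")
  mp <- write_corpus(gen$docs, gen$labels, dir)
  back <- read_corpus(mp)
  expect_identical(back$labels$doc_id, gen$labels$doc_id)
  expect_identical(back$labels$label, gen$labels$label)
  expect_identical(back$docs[[3]]$captions, gen$docs[[3]]$captions)
  expect_identical(back$docs[[3]]$paragraphs$text, gen$docs[[3]]$paragraphs$text)
  unlink(dir, recursive = TRUE)
})
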