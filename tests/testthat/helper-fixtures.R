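# Shared fixtures: tiny embeddings, documents and corpora built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_embeddings <- function(vocab = c(letters, "p53", "binds", "mdm2", "."),
                           dim = 8L, seed = 42L) {
  attr(biotriage::generate_toy_embeddings(vocab, dim = dim, seed = seed), "table")
}

jats_fixture <- function(n_para = 2L, figs = c(1L), title = "A toy study",
                         abstract = "We study binding.") {
  paras <- paste0("<sec><title>Results</title><p>Paragraph ", seq_len(n_para),
                  " text ( Fig. 1A ).</p></sec>", collapse = "")
  figxml <- paste0("<fig><label>Figure ", figs, "</label><caption>Caption for figure ",
                   figs, ".</caption></fig>", collapse = "")
  paste0("<article><front><article-meta><article-id>toy1</article-id>",
         "<title-group><article-title>", title, "</article-title></title-group>",
         "<abstract>", abstract, "</abstract>",
         "<kwd-group><kwd>Proteins</kwd><kwd>Immunoblotting</kwd></kwd-group>",
         "</article-meta></front><body>", if (n_para > 0) paras else "",
         figxml, "</body></article>")
}

write_jats_fixture <- function(..., file = tempfile(fileext = ".xml")) {
  writeLines(jats_fixture(...), file)
  file
}

# Linearly separable two-class passage set: one class carries a signal token.
separable_passages <- function(n = 120L, signal = "blotmark", seed = 9L) {
  biotriage:::with_seed(seed, {
    lab <- rep(c("yes", "no"), length.out = n)
    bg <- sprintf("tok%02d", 1:30)
    text <- vapply(seq_len(n), function(i) {
      toks <- sample(bg, 8, replace = TRUE)
      if (lab[i] == "yes") toks[sample(8, 1)] <- signal
      paste(c(toks, "."), collapse = " ")
    }, character(1))
    tibble::tibble(text = text, label = lab)
  })
}

separable_vocab <- function() c(sprintf("tok%02d", 1:30), "blotmark", ".")

# Unigram-presence oracle for the synthetic method corpus: predict the class
# whose signal set intersects the passage tokens; fall back to the majority
# class. Independent of the neural models.
unigram_oracle <- function(texts, signal_sets, majority) {
  vapply(texts, function(tx) {
    toks <- tolower(biotriage::tokenize(tx))
    for (g in names(signal_sets)) {
      if (any(toks %in% signal_sets[[g]])) return(g)
    }
    majority
  }, character(1), USE.NAMES = FALSE)
}
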