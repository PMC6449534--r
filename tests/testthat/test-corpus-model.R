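test_that("tokenizer splits punctuation but keeps biomedical entity tokens intact", {
  expect_identical(tokenize(""), character())
  expect_identical(tokenize("p53 binds MDM2."), c("p53", "binds", "MDM2", "."))
  expect_identical(tokenize("(Fig. 1A)"), c("(", "Fig", ".", "1A", ")"))
  expect_identical(tokenize("IL-2 and IFN-gamma"), c("IL-2", "and", "IFN-gamma"))
  # idempotence on normal-form token lists
  for (txt in c("p53 binds MDM2 .", "IL-2 ( Fig . 1A )", "a b-c d'e 12")) {
    toks <- tokenize(txt)
    expect_identical(tokenize(join_tokens(toks)), toks)
  }
})

test_that("sentence splitter handles boundaries, headings and abbreviations", {
  expect_identical(nrow(split_sentences("")), 0L)
  s <- split_sentences("A binds B. C binds D.")
  expect_identical(s$text, c("A binds B.", "C binds D."))
  expect_identical(nrow(split_sentences("Results")), 1L)  # heading, no period
  # abbreviation periods do not split
  s2 <- split_sentences("We used Fig. 1A here. Then more.")
  expect_identical(nrow(s2), 2L)
  expect_match(s2$text[1], "Fig. 1A")
})

test_that("sentence spans are ordered, non-overlapping and cover non-whitespace", {
  txt <- "First one here. Second sentence! Third?  Heading"
  s <- split_sentences(txt)
  expect_true(all(diff(s$start) > 0))
  expect_true(all(s$end[-nrow(s)] <= s$start[-1]))
  covered <- unlist(purrr::map2(s$start, s$end, function(a, b) (a + 1):b))
  nonws <- which(strsplit(txt, "")[[1]] != " ")
  expect_true(all(nonws %in% covered))
  # spans reconstruct their sentence text
  for (i in seq_len(nrow(s))) {
    expect_identical(substr(txt, s$start[i] + 1, s$end[i]), s$text[i])
  }
})

test_that("JATS reader captures paragraphs, captions and metadata", {
  doc <- read_document(write_jats_fixture(n_para = 2, figs = 1), "jats")
  expect_s3_class(doc, "bt_document")
  expect_identical(doc$doc_id, "toy1")
  expect_identical(nrow(doc$paragraphs), 2L)
  expect_identical(names(doc$captions), "1")
  expect_identical(doc$mesh_terms, c("Proteins", "Immunoblotting"))

  # title-only degenerate document
  xml <- "<article><front><article-meta><title-group><article-title>T</article-title></title-group><abstract></abstract></article-meta></front></article>"
  f <- tempfile(fileext = ".xml"); writeLines(xml, f)
  doc2 <- read_document(f, "jats")
  expect_identical(nrow(doc2$paragraphs), 0L)
  expect_length(doc2$captions, 0L)

  # figure labeled "Figure 3." with no figures 1-2
  doc3 <- read_document(write_jats_fixture(n_para = 1, figs = 3), "jats")
  expect_identical(names(doc3$captions), "3")
})

test_that("JATS reader warns on missing abstract and errors on malformed XML", {
  xml <- "<article><front><article-meta><title-group><article-title>T</article-title></title-group></article-meta></front><body><p>x.</p></body></article>"
  f <- tempfile(fileext = ".xml"); writeLines(xml, f)
  expect_warning(doc <- read_document(f, "jats"), "abstract")
  expect_identical(doc$abstract, "")
  f2 <- tempfile(fileext = ".xml"); writeLines("<article><unclosed>", f2)
  expect_error(read_document(f2, "jats"), "malformed")
})

test_that("supplementary figure labels are excluded from caption linkage", {
  xml <- paste0("<article><front><article-meta><abstract>a.</abstract>",
                "</article-meta></front><body>",
                "<fig><label>Figure S1</label><caption>Supp.</caption></fig>",
                "<fig><label>Figure 2</label><caption>Real.</caption></fig>",
                "</body></article>")
  f <- tempfile(fileext = ".xml"); writeLines(xml, f)
  expect_warning(doc <- read_document(f, "jats"), "supplementary|unparsed")
  expect_identical(names(doc$captions), "2")
})

test_that("documents round-trip through both dialects", {
  doc <- document("d9", title = "A study of p53",
                  abstract = "We measured binding. It was strong.",
                  mesh_terms = c("Proteins", "Mice"),
                  paragraphs = c("One ( Fig. 1A ). Two.", "Three only."),
                  captions = c("1" = "First caption.", "2" = "Second caption."))
  for (dialect in c("jats", "plain")) {
    p <- tempfile()
    write_document(doc, p, dialect)
    back <- read_document(p, dialect)
    expect_identical(back$doc_id, doc$doc_id)
    expect_identical(back$title, doc$title)
    expect_identical(back$abstract, doc$abstract)
    expect_identical(back$mesh_terms, doc$mesh_terms)
    expect_identical(back$paragraphs$text, doc$paragraphs$text)
    expect_identical(back$captions, doc$captions)
  }
})

test_that("tidy() flattens a document into ordered passages", {
  doc <- document("d1", title = "T", abstract = "A.", mesh_terms = c("m1", "m2"),
                  paragraphs = c("P1.", "P2."), captions = c("1" = "C1."))
  td <- tidy(doc)
  expect_identical(td$kind, c("title", "abstract", "mesh", "mesh",
                              "paragraph", "paragraph", "caption"))
  expect_identical(td$position, 1:7)
  expect_identical(td$figure[7], 1L)
})

test_that("tokenized-corpus writer emits one tokenized sentence per line", {
  doc <- document("d1", title = "Short title",
                  abstract = "One here. Two there.",
                  paragraphs = "Only paragraph.")
  p <- tempfile()
  write_tokenized_corpus(list(doc), p)
  lines <- readLines(p)
  expect_identical(lines[1], "Short title")
  expect_identical(lines[2], "One here .")
  expect_identical(lines[3], "Two there .")
  expect_identical(lines[4], "Only paragraph .")
})

test_that("invalid document construction is rejected", {
  expect_error(document(""), "doc_id")
  expect_error(document("x", captions = c("0" = "bad")), "positive")
  expect_error(document("x", captions = c("1" = "a", "1" = "b")), "distinct")
})
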