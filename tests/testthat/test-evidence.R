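test_that("panel range expansion is inclusive, uppercase and validated", {
  expect_identical(expand_panel_range("A"), "A")
  expect_identical(expand_panel_range("B-D"), c("B", "C", "D"))
  expect_identical(expand_panel_range("B–D"), c("B", "C", "D"))  # en dash
  expect_identical(expand_panel_range("A,C"), c("A", "C"))
  expect_identical(expand_panel_range("a , c-e"), c("A", "C", "D", "E"))
  expect_error(expand_panel_range("D-B"), "descending")
  expect_error(expand_panel_range("A--"), "invalid")
})

test_that("figure references are detected with spans, panels and conjunctions", {
  expect_identical(nrow(find_figure_references("no figures here")), 0L)

  r <- find_figure_references("as shown in Fig. 2B")
  expect_identical(r$figure, 2L)
  expect_identical(r$panels[[1]], "B")
  expect_identical(substr("as shown in Fig. 2B", r$start + 1, r$end), "Fig. 2B")

  r2 <- find_figure_references("(Figures 1A and 1C–E)")
  expect_identical(r2$figure, c(1L, 1L))
  expect_identical(r2$panels[[1]], "A")
  expect_identical(r2$panels[[2]], c("C", "D", "E"))

  # panel continuation inherits the figure number
  r3 <- find_figure_references("see Fig. 2B and C")
  expect_identical(r3$figure, c(2L, 2L))
  expect_identical(r3$panels[[2]], "C")

  # case-insensitive keyword, whole-figure reference, no panel
  r4 <- find_figure_references("see figure 12 for details")
  expect_identical(r4$figure, 12L)
  expect_identical(r4$panels[[1]], character())

  # supplementary figures are outside the integer namespace
  expect_identical(nrow(find_figure_references("see Fig. S1")), 0L)
})

test_that("reference spans are ordered and matches are maximal", {
  txt <- "First Fig. 1A, then ( Fig. 2B-D ) and Figure 3."
  r <- find_figure_references(txt)
  expect_identical(r$figure, c(1L, 2L, 3L))
  expect_true(all(diff(r$start) > 0))
  expect_identical(r$panels[[2]], c("B", "C", "D"))
  for (i in seq_len(nrow(r))) {
    expect_identical(substr(txt, r$start[i] + 1, r$end[i]), r$match[i])
  }
})

frag_doc <- function(paragraphs) {
  document("fx", abstract = "None.", paragraphs = paragraphs,
           captions = c("1" = "Cap 1.", "2" = "Cap 2."))
}

test_that("fragment windows run from the reference sentence to the next key or paragraph end", {
  # reference in sentence 2 of 3: fragment covers sentences 2..3
  d <- frag_doc("Background first. We saw binding ( Fig. 1A ). It was strong.")
  fr <- extract_evidence_fragments(d)
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$sent_from, 2L)
  expect_identical(fr$sent_to, 3L)
  expect_identical(fr$figure, 1L)
  expect_identical(fr$panels[[1]], "A")

  # two different keys in one paragraph: boundary before the second reference
  d2 <- frag_doc("We saw X ( Fig. 1A ). More detail here. Then Y ( Fig. 2 ).")
  fr2 <- extract_evidence_fragments(d2)
  expect_identical(nrow(fr2), 2L)
  expect_identical(fr2$sent_from, c(1L, 3L))
  expect_identical(fr2$sent_to, c(2L, 3L))

  # consecutive sentences with the same key merge into one fragment
  d3 <- frag_doc("X ( Fig. 1A ). Again ( Fig. 1A ). Tail sentence.")
  fr3 <- extract_evidence_fragments(d3)
  expect_identical(nrow(fr3), 1L)
  expect_identical(fr3$sent_from, 1L)
  expect_identical(fr3$sent_to, 3L)

  # no references: no fragments
  expect_identical(nrow(extract_evidence_fragments(frag_doc("Nothing. At all."))), 0L)
})

test_that("include_preceding prepends one unclaimed sentence", {
  d <- frag_doc("Background first. We saw binding ( Fig. 1A ). Tail.")
  fr <- extract_evidence_fragments(d, include_preceding = TRUE)
  expect_identical(fr$sent_from, 1L)
  # a sentence already inside the previous fragment is not stolen
  d2 <- frag_doc("X ( Fig. 1A ). Shared tail. Y ( Fig. 2 ).")
  fr2 <- extract_evidence_fragments(d2, include_preceding = TRUE)
  expect_identical(fr2$sent_from, c(1L, 3L))
})

test_that("fragments never cross paragraphs and cover each reference exactly once", {
  sc <- synth_config(n_docs = 12, figure_ref_density = 0.6, seed = 31)
  gen <- generate_triage_corpus(sc)
  for (doc in gen$docs) {
    fr <- extract_evidence_fragments(doc)
    for (p in seq_len(nrow(doc$paragraphs))) {
      sents <- split_sentences(doc$paragraphs$text[p])
      refs <- dplyr::bind_rows(lapply(seq_len(nrow(sents)), function(i) {
        r <- find_figure_references(sents$text[i])
        if (nrow(r)) r$sentence <- i
        r
      }))
      frp <- fr[fr$paragraph == p, ]
      if (nrow(refs) == 0) {
        expect_identical(nrow(frp), 0L)
        next
      }
      # every reference sentence lies inside exactly one fragment of its key
      for (i in seq_len(nrow(refs))) {
        key <- paste0(refs$figure[i], ":", paste(refs$panels[[i]], collapse = ""))
        hit <- frp[frp$sent_from <= refs$sentence[i] & frp$sent_to >= refs$sentence[i] &
                   paste0(frp$figure, ":", vapply(frp$panels, paste, "", collapse = "")) == key, ]
        expect_identical(nrow(hit), 1L)
      }
      # locality: fragment sentences exist within the paragraph
      expect_true(all(frp$sent_to <= nrow(sents)))
    }
    # determinism
    expect_identical(fr, extract_evidence_fragments(doc))
  }
})

test_that("caption lookup attaches whole captions tagged with panels", {
  d <- document("c1", abstract = "A.",
                captions = c("1" = "(A) Blot. (B) Assay.", "3" = "Other."))
  cp <- caption_for(d, 1, "A")
  expect_identical(cp$text, "(A) Blot. (B) Assay.")  # whole caption, not split
  expect_identical(cp$panels[[1]], "A")
  cp3 <- caption_for(d, 3, c("C", "B"))
  expect_identical(cp3$panels[[1]], c("B", "C"))
  expect_error(caption_for(d, 2), "no caption for figure 2")
})

test_that("fragment exports write TSV rows and BioC-like annotations", {
  d <- frag_doc("We saw X ( Fig. 1A ). Then Y ( Fig. 2 ).")
  fr <- extract_evidence_fragments(d)
  tsv <- tempfile(fileext = ".tsv")
  write_fragments_tsv(fr, tsv)
  tab <- utils::read.delim(tsv)
  expect_identical(nrow(tab), 2L)
  expect_identical(names(tab), c("doc_id", "figure_id", "panels", "fragment_text"))

  xmlp <- tempfile(fileext = ".xml")
  write_fragments_bioc(d, fr, xmlp)
  x <- xml2::read_xml(xmlp)
  passages <- xml2::xml_find_all(x, ".//passage")
  expect_length(passages, 2L)
  ann <- xml2::xml_find_all(x, ".//annotation/location")
  expect_true(length(ann) >= 2L)
})
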