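# Article data model: a light JATS-subset representation of a full-text
# article (title, abstract, MeSH terms, body paragraphs, figure captions),
# plus the tokenizer and sentence splitter used throughout the pipeline.

#' Construct a structured article document
#'
#' A `bt_document` is the in-memory model of one full-text article: metadata,
#' abstract, MeSH terms, ordered body paragraphs and per-figure captions.
#' Figure identifiers are positive integers; supplementary ("S1") and roman
#' numbered figures live in a separate namespace and are not linked to
#' captions by default.
#'
#' @param doc_id Non-empty document identifier.
#' @param title Article title (plain text).
#' @param abstract Abstract text; may be empty.
#' @param mesh_terms Character vector of MeSH terms.
#' @param paragraphs A data frame with columns `section` and `text` (one row
#'   per body paragraph, order preserved), or a character vector of paragraph
#'   texts.
#' @param captions Named character vector or list mapping figure numbers
#'   (coercible to positive integers) to caption text.
#' @return An object of class `bt_document`.
#' @examples
#' doc <- document("d1", title = "p53 signalling",
#'                 paragraphs = c("We assayed binding (Fig. 1A)."),
#'                 captions = c("1" = "Figure 1. Binding assay."))
#' doc
#' @export
document <- function(doc_id, title = "", abstract = "", mesh_terms = character(),
                     paragraphs = character(), captions = character()) {
  if (!is.character(doc_id) || length(doc_id) != 1L || !nzchar(doc_id)) {
    abort("`doc_id` must be a single non-empty string.")
  }
  if (is.character(paragraphs)) {
    paragraphs <- tibble(section = rep("body", length(paragraphs)), text = paragraphs)
  }
  paragraphs <- as_tibble(paragraphs)
  if (nrow(paragraphs) > 0 && !all(c("section", "text") %in% names(paragraphs))) {
    abort("`paragraphs` must have columns `section` and `text`.")
  }
  if (nrow(paragraphs) == 0) paragraphs <- tibble(section = character(), text = character())
  captions <- unlist(captions)
  if (length(captions)) {
    ids <- suppressWarnings(as.integer(names(captions)))
    if (anyNA(ids) || any(ids <= 0)) abort("caption names must be positive integer figure ids")
    if (anyDuplicated(ids)) abort("caption figure ids must be distinct")
    captions <- setNames(as.character(captions), as.character(ids))
    captions <- captions[order(ids)]
  } else {
    captions <- setNames(character(), character())
  }
  structure(
    list(doc_id = doc_id, title = as.character(title)[1] %||% "",
         abstract = as.character(abstract)[1] %||% "",
         mesh_terms = as.character(mesh_terms),
         paragraphs = paragraphs, captions = captions),
    class = "bt_document"
  )
}

#' @export
print.bt_document <- function(x, ...) {
  cat("<bt_document> ", x$doc_id, "\n", sep = "")
  cat("  title:      ", substr(x$title, 1, 60), "\n", sep = "")
  cat("  abstract:   ", nchar(x$abstract), " chars\n", sep = "")
  cat("  mesh terms: ", length(x$mesh_terms), "\n", sep = "")
  cat("  paragraphs: ", nrow(x$paragraphs), "\n", sep = "")
  cat("  captions:   ", length(x$captions),
      if (length(x$captions)) paste0(" (figs ", paste(names(x$captions), collapse = ", "), ")"), "\n", sep = "")
  invisible(x)
}

#' Flatten a document into a tibble of passages
#'
#' One row per passage-like unit: title, abstract, each MeSH term, each body
#' paragraph and each figure caption, in that order.
#'
#' @param x A `bt_document`.
#' @param ... Unused.
#' @return A tibble with columns `doc_id`, `position`, `kind`, `figure`,
#'   `section`, `text`.
#' @export
tidy.bt_document <- function(x, ...) {
  rows <- list(
    tibble(kind = "title", figure = NA_integer_, section = NA_character_, text = x$title),
    tibble(kind = "abstract", figure = NA_integer_, section = NA_character_, text = x$abstract),
    if (length(x$mesh_terms))
      tibble(kind = "mesh", figure = NA_integer_, section = NA_character_, text = x$mesh_terms),
    if (nrow(x$paragraphs))
      tibble(kind = "paragraph", figure = NA_integer_, section = x$paragraphs$section,
             text = x$paragraphs$text),
    if (length(x$captions))
      tibble(kind = "caption", figure = as.integer(names(x$captions)),
             section = NA_character_, text = unname(x$captions))
  )
  out <- bind_rows(compact(rows))
  out$doc_id <- x$doc_id
  out$position <- seq_len(nrow(out))
  out[, c("doc_id", "position", "kind", "figure", "section", "text")]
}

# ---- JATS-subset and plain-dialect IO --------------------------------------

normalize_figure_label <- function(label) {
  # "Figure 3.", "Fig 2", "3" -> 3L; "S1", roman numerals -> NA (separate
  # supplementary/roman namespace, excluded from caption linkage)
  m <- stringr::str_match(label, stringr::regex(
    "^\\s*(?:fig(?:ure)?s?\\.?)?\\s*([0-9]+)\\s*[.:]?\\s*$", ignore_case = TRUE))[, 2]
  out <- suppressWarnings(as.integer(m))
  out[!is.na(out) & out <= 0] <- NA_integer_
  out
}

#' Read an article from a JATS-subset XML or plain-text stream
#'
#' Two dialects are supported. `"jats"` reads a minimal JATS subset:
#' `front/article-meta/title-group/article-title`, `abstract`, `kwd-group/kwd`
#' (MeSH-like keywords), `body//sec/p` and top-level `body/p`, and
#' `fig/label` + `fig/caption`. Unhandled elements are reported via a warning
#' and their text retained where they occur inside handled containers; no text
#' is dropped silently. `"plain"` reads the test fixture dialect: one block
#' per line, `kind<TAB>text`, with kinds `id`, `title`, `abstract`, `mesh`,
#' `paragraph` (optionally `paragraph:<section>`) and `caption:<figure id>`.
#'
#' @param path Path to the file (or a string of XML for `dialect = "jats"`
#'   when `literal = TRUE`).
#' @param dialect `"jats"` or `"plain"`.
#' @param doc_id Identifier to assign; for JATS, defaults to the
#'   `article-id` element if present, else the file name.
#' @param literal If `TRUE`, `path` is the document content itself.
#' @return A [document()] object. A missing abstract yields an empty abstract
#'   with a warning; malformed XML is an error naming the parser failure.
#' @export
read_document <- function(path, dialect = c("jats", "plain"), doc_id = NULL,
                          literal = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "plain") return(read_document_plain(path, doc_id, literal))

  xml <- tryCatch(
    if (literal) xml2::read_xml(path) else xml2::read_xml(path),
    error = function(e) abort(paste0("malformed JATS stream: ", conditionMessage(e)))
  )
  title <- xml_text1(xml, ".//front//article-title | .//article-title")
  abstract <- xml_text1(xml, ".//abstract")
  if (is.na(abstract)) {
    warn("document has no <abstract>; using empty abstract")
    abstract <- ""
  }
  if (is.na(title)) title <- ""
  mesh <- xml2::xml_text(xml2::xml_find_all(xml, ".//kwd-group/kwd | .//kwd"))
  mesh <- unique(trimws(mesh))
  mesh <- mesh[nzchar(mesh)]

  body <- xml2::xml_find_first(xml, ".//body")
  paragraphs <- tibble(section = character(), text = character())
  if (!inherits(body, "xml_missing")) {
    pnodes <- xml2::xml_find_all(body, ".//p[not(ancestor::caption)]")
    sec_of <- function(p) {
      sec <- xml2::xml_find_first(p, "ancestor::sec[1]/title")
      if (inherits(sec, "xml_missing")) "body" else trimws(xml2::xml_text(sec))
    }
    if (length(pnodes)) {
      paragraphs <- tibble(
        section = vapply(pnodes, sec_of, character(1)),
        text = vapply(pnodes, function(p) squish(xml2::xml_text(p)), character(1))
      )
    }
    unhandled <- xml2::xml_find_all(
      body, "./*[not(self::p or self::sec or self::fig)]")
    if (length(unhandled)) {
      warn(paste0("unhandled body elements retained as paragraphs: ",
                  paste(unique(xml2::xml_name(unhandled)), collapse = ", ")))
      extra <- vapply(unhandled, function(n) squish(xml2::xml_text(n)), character(1))
      extra <- extra[nzchar(extra)]
      if (length(extra)) {
        paragraphs <- bind_rows(paragraphs,
                                tibble(section = "unhandled", text = extra))
      }
    }
  }

  figs <- xml2::xml_find_all(xml, ".//fig")
  captions <- character()
  for (fg in figs) {
    lab <- xml_text1(fg, "./label")
    cap <- xml_text1(fg, "./caption")
    id <- normalize_figure_label(lab %||% NA_character_)
    if (is.na(id)) {
      warn(paste0("figure with unparsed or supplementary label ",
                  if (is.na(lab)) "<missing>" else shQuote(lab),
                  " excluded from caption linkage"))
      next
    }
    captions[as.character(id)] <- squish(cap %||% "")
  }

  if (is.null(doc_id)) {
    doc_id <- xml_text1(xml, ".//article-id")
    if (is.na(doc_id) || !nzchar(doc_id)) {
      doc_id <- if (literal) "doc" else tools::file_path_sans_ext(basename(path))
    }
  }
  document(doc_id, title = title, abstract = abstract, mesh_terms = mesh,
           paragraphs = paragraphs, captions = captions)
}

read_document_plain <- function(path, doc_id = NULL, literal = FALSE) {
  lines <- if (literal) strsplit(path, "\n", fixed = TRUE)[[1]] else readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  kinds <- parts[, 1]
  texts <- parts[, 2]
  bad <- !grepl("^(id|title|abstract|mesh|paragraph(:[^\t]*)?|caption:[0-9]+)$", kinds)
  if (any(bad)) {
    abort(paste0("malformed plain-dialect line(s): kind ",
                 paste(shQuote(unique(kinds[bad])), collapse = ", ")))
  }
  id <- texts[kinds == "id"]
  if (is.null(doc_id)) doc_id <- if (length(id)) id[[1]] else "doc"
  para <- kinds == "paragraph" | startsWith(kinds, "paragraph:")
  sections <- ifelse(startsWith(kinds[para], "paragraph:"),
                     sub("^paragraph:", "", kinds[para]), "body")
  capk <- startsWith(kinds, "caption:")
  captions <- setNames(texts[capk], sub("^caption:", "", kinds[capk]))
  abstract <- if (any(kinds == "abstract")) paste(texts[kinds == "abstract"], collapse = " ") else ""
  if (!any(kinds == "abstract")) warn("document has no abstract line; using empty abstract")
  document(doc_id,
           title = if (any(kinds == "title")) texts[kinds == "title"][[1]] else "",
           abstract = abstract,
           mesh_terms = texts[kinds == "mesh"],
           paragraphs = tibble(section = sections, text = texts[para]),
           captions = captions)
}

#' Write a document back to disk
#'
#' `dialect = "jats"` emits the same JATS subset [read_document()] consumes,
#' so `read_document(write_document(doc))` round-trips. `dialect = "plain"`
#' emits the one-block-per-line fixture dialect.
#'
#' @param doc A `bt_document`.
#' @param path Output file path.
#' @param dialect `"jats"` or `"plain"`.
#' @return `path`, invisibly.
#' @export
write_document <- function(doc, path, dialect = c("jats", "plain")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(doc, "bt_document"))
  if (dialect == "plain") {
    lines <- c(
      paste0("id\t", doc$doc_id),
      paste0("title\t", doc$title),
      paste0("abstract\t", doc$abstract),
      paste0("mesh\t", doc$mesh_terms),
      paste0("paragraph:", doc$paragraphs$section, "\t", doc$paragraphs$text),
      paste0("caption:", names(doc$captions), "\t", unname(doc$captions))
    )
    writeLines(lines, path)
    return(invisible(path))
  }
  root <- xml2::xml_new_root("article")
  front <- xml2::xml_add_child(root, "front")
  meta <- xml2::xml_add_child(front, "article-meta")
  xml2::xml_add_child(meta, "article-id", doc$doc_id)
  tg <- xml2::xml_add_child(meta, "title-group")
  xml2::xml_add_child(tg, "article-title", doc$title)
  xml2::xml_add_child(meta, "abstract", doc$abstract)
  if (length(doc$mesh_terms)) {
    kg <- xml2::xml_add_child(meta, "kwd-group")
    for (k in doc$mesh_terms) xml2::xml_add_child(kg, "kwd", k)
  }
  body <- xml2::xml_add_child(root, "body")
  if (nrow(doc$paragraphs)) {
    for (i in seq_len(nrow(doc$paragraphs))) {
      sec <- xml2::xml_add_child(body, "sec")
      xml2::xml_add_child(sec, "title", doc$paragraphs$section[i])
      xml2::xml_add_child(sec, "p", doc$paragraphs$text[i])
    }
  }
  for (fid in names(doc$captions)) {
    fg <- xml2::xml_add_child(body, "fig")
    xml2::xml_add_child(fg, "label", paste0("Figure ", fid))
    xml2::xml_add_child(fg, "caption", doc$captions[[fid]])
  }
  xml2::write_xml(root, path)
  invisible(path)
}

xml_text1 <- function(node, xpath) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) NA_character_ else squish(xml2::xml_text(n))
}

squish <- function(x) stringr::str_squish(x)

# ---- Tokenization ----------------------------------------------------------

# Word tokens keep internal hyphens, apostrophes and digits ("IL-2", "p53",
# "1A" are single tokens); every other punctuation character is its own token.
TOKEN_RE <- "[A-Za-z0-9]+(?:[-'][A-Za-z0-9]+)*|[^A-Za-z0-9\\s]"

#' Tokenize text
#'
#' Deterministic regex tokenizer: splits on whitespace and punctuation while
#' keeping internal hyphens and digits attached, so biomedical entity tokens
#' such as `IL-2`, `p53` and panel references like `1A` survive as single
#' tokens. Case is preserved; lowercasing happens only at embedding lookup.
#'
#' @param text A character scalar.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("p53 binds MDM2.")
#' tokenize("(Fig. 1A)")
#' @export
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  stringr::str_extract_all(text, TOKEN_RE)[[1]]
}

#' Reassemble tokens into normal-form text
#'
#' Joins tokens with single spaces; `tokenize(join_tokens(x))` is the
#' identity for token vectors already in normal form.
#'
#' @param tokens Character vector of tokens.
#' @return A single string.
#' @export
join_tokens <- function(tokens) paste(tokens, collapse = " ")

# ---- Sentence splitting ----------------------------------------------------

# Abbreviations whose trailing period never ends a sentence.
SENT_ABBREV <- c("fig", "figs", "al", "e.g", "i.e", "cf", "vs", "dr", "ref",
                 "refs", "no", "approx", "ca", "etc")

#' Split text into sentences with character spans
#'
#' Rule-based splitter: a sentence ends at `.`, `!` or `?` followed by
#' whitespace and an uppercase letter, unless the period terminates a known
#' abbreviation (`Fig.`, `et al.`, `e.g.` ...). A heading or title without
#' terminal punctuation yields exactly one sentence. Spans are half-open,
#' 0-based character intervals into the input; concatenating the spans plus
#' the intervening whitespace reconstructs the input.
#'
#' @param text A character scalar.
#' @return A tibble with columns `text`, `start`, `end` (0-based, half-open),
#'   one row per sentence; zero rows for empty input.
#' @examples
#' split_sentences("A binds B. C binds D.")
#' split_sentences("Results")  # heading: one sentence
#' @export
split_sentences <- function(text) {
  empty <- tibble(text = character(), start = integer(), end = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  # candidate boundaries: terminal [.!?]+ then whitespace then uppercase
  breaks <- integer()
  i <- 1L
  while (i <= n) {
    if (chars[i] %in% c(".", "!", "?")) {
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "!", "?", "\"", "'", ")")) j <- j + 1L
      k <- j + 1L
      if (k <= n && grepl("\\s", chars[k])) {
        while (k <= n && grepl("\\s", chars[k])) k <- k + 1L
        if (k <= n && grepl("[A-Z]", chars[k]) && !is_abbrev_before(text, i)) {
          breaks <- c(breaks, j)   # sentence ends at position j (1-based)
        }
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  out <- purrr::map2(starts, ends, function(s, e) {
    seg <- substr(text, s, e)
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    tibble(text = trimws(seg), start = s - 1L + lead, end = e - trail)
  })
  out <- bind_rows(out)
  out[nzchar(out$text), ]
}

is_abbrev_before <- function(text, dot_pos) {
  if (dot_pos < 2L) return(FALSE)
  prefix <- substr(text, max(1L, dot_pos - 12L), dot_pos - 1L)
  word <- tolower(stringr::str_extract(prefix, "[A-Za-z][A-Za-z.]*$") %||% "")
  if (!nzchar(word) || is.na(word)) return(FALSE)
  word %in% SENT_ABBREV
}

#' Write a tokenized corpus file
#'
#' One sentence per line, space-separated tokens: the plain-text convention
#' used for training word-embedding models on sentence-split corpora.
#'
#' @param docs A list of `bt_document` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tokenized_corpus <- function(docs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (doc in docs) {
    blocks <- tidy(doc)$text
    for (b in blocks[nzchar(blocks)]) {
      sents <- split_sentences(b)
      for (s in sents$text) writeLines(join_tokens(tokenize(s)), con)
    }
  }
  invisible(path)
}
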