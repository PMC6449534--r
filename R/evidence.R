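# Figure/panel reference detection and evidence-fragment delineation.
#
# An "evidence fragment" is the narrative text surrounding a figure
# reference that directly describes that figure's experimental evidence:
# the unit to which curated interaction records are anchored via the
# designated subfigure.

# Panel spec immediately following a figure number: "B", "C-E", "A,B".
PANEL_RE <- "[A-Za-z](?:[–—-][A-Za-z]|,\\s*[A-Za-z]\\b)*(?![A-Za-z0-9])"
# Bare panel continuation ("Fig. 2B and C"): uppercase only, not a word start.
CONT_RE <- "[A-Z](?:[–—-][A-Z]|,\\s*[A-Z]\\b)*(?![A-Za-z0-9])"
FIGKEY_RE <- "\\bfig(?:ure)?s?\\.?"

#' Expand a panel range specification
#'
#' Expands specs like `"A"`, `"A,C"` or `"B-D"` (hyphen, en- or em-dash) into
#' the inclusive, uppercased list of panel letters.
#'
#' @param spec Panel specification string.
#' @return Character vector of single uppercase letters.
#' @examples
#' expand_panel_range("B-D")
#' expand_panel_range("A,C")
#' @export
expand_panel_range <- function(spec) {
  spec <- gsub("\\s", "", toupper(spec))
  if (!nzchar(spec)) return(character())
  if (!grepl("^[A-Z](([–—-][A-Z])|(,[A-Z]))*$", spec)) {
    abort(paste0("invalid panel spec: ", shQuote(spec)))
  }
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  out <- unlist(lapply(parts, function(p) {
    if (grepl("[–—-]", p)) {
      ends <- strsplit(p, "[–—-]")[[1]]
      from <- utf8ToInt(ends[1]); to <- utf8ToInt(ends[2])
      if (to < from) abort(paste0("descending panel range: ", shQuote(p)))
      intToUtf8(from:to, multiple = TRUE)
    } else p
  }))
  unique(out)
}

#' Find figure/panel references in text
#'
#' Detects mentions such as `Fig. 2B`, `Figure 3`, `(Figures 1A and 1C-E)` or
#' `Fig. 1A, B`, case-insensitively, with comma lists and dash ranges of
#' panel letters and multi-figure conjunctions after a single keyword. Panel
#' continuation without a repeated number (`Fig. 2B and C`) inherits the last
#' figure number. Supplementary (`Fig. S1`) and roman-numbered figures are
#' not matched: they live outside the integer figure namespace.
#'
#' @param text A character scalar.
#' @return A tibble with one row per reference: `figure` (integer), `panels`
#'   (list of uppercase letters; empty = whole figure), `start`, `end`
#'   (half-open 0-based character span) and `match` (the matched text).
#'   Rows are in span order; overlaps resolve to the longest match.
#' @examples
#' find_figure_references("as shown in Fig. 2B")
#' find_figure_references("(Figures 1A and 1C-E)")
#' @export
find_figure_references <- function(text) {
  empty <- tibble(figure = integer(), panels = list(),
                  start = integer(), end = integer(), match = character())
  if (is.na(text) || !nzchar(text)) return(empty)
  keys <- stringr::str_locate_all(text, stringr::regex(FIGKEY_RE, ignore_case = TRUE))[[1]]
  if (nrow(keys) == 0) return(empty)

  group_first <- paste0("^\\s*([0-9]{1,3})(", PANEL_RE, ")?")
  group_next <- paste0("^(\\s*(?:,|;|and|&)\\s*)(?:([0-9]{1,3})(", PANEL_RE, ")?|(",
                       CONT_RE, "))")
  refs <- list()
  consumed_to <- 0L
  for (i in seq_len(nrow(keys))) {
    if (keys[i, 1] <= consumed_to) next  # inside a previous match run
    pos <- keys[i, 2] + 1L              # first char after keyword (1-based)
    rest <- substr(text, pos, nchar(text))
    m <- stringr::str_match(rest, group_first)
    if (is.na(m[1, 1])) next
    fig <- as.integer(m[1, 2])
    panels <- if (!is.na(m[1, 3])) expand_panel_range(m[1, 3]) else character()
    end_here <- pos + nchar(m[1, 1]) - 1L   # last consumed char, 1-based
    # first ref span starts at the keyword
    refs[[length(refs) + 1L]] <- list(figure = fig, panels = sort(panels),
                                      start = keys[i, 1] - 1L, end = end_here)
    pos <- end_here + 1L
    last_fig <- fig
    repeat {
      rest <- substr(text, pos, nchar(text))
      m2 <- stringr::str_match(rest, group_next)
      if (is.na(m2[1, 1])) break
      sep_len <- nchar(m2[1, 2])
      body_len <- nchar(m2[1, 1]) - sep_len
      g_start <- pos + sep_len            # 1-based start of the group body
      g_end <- pos + nchar(m2[1, 1]) - 1L
      if (!is.na(m2[1, 3])) {
        fig2 <- as.integer(m2[1, 3])
        pan2 <- if (!is.na(m2[1, 4])) expand_panel_range(m2[1, 4]) else character()
        last_fig <- fig2
      } else {
        fig2 <- last_fig
        pan2 <- expand_panel_range(m2[1, 5])
      }
      refs[[length(refs) + 1L]] <- list(figure = fig2, panels = sort(pan2),
                                        start = g_start - 1L, end = g_end)
      pos <- g_end + 1L
    }
    consumed_to <- pos - 1L
  }
  if (!length(refs)) return(empty)
  out <- tibble(
    figure = map_int(refs, "figure"),
    panels = map(refs, "panels"),
    start = map_int(refs, function(r) as.integer(r$start)),
    end = map_int(refs, function(r) as.integer(r$end)),
  )
  out$match <- substr(rep(text, nrow(out)), out$start + 1L, out$end)
  arrange(out, .data$start)
}

ref_key <- function(figure, panels) paste0(figure, ":", paste(panels, collapse = ""))

#' Extract evidence fragments from a document
#'
#' Delineates, per paragraph, maximal runs of sentences anchored to the same
#' figure/panel key. The default window starts at the sentence containing the
#' reference and extends through following sentences until the next sentence
#' referencing a different figure/panel set or the paragraph end, whichever
#' comes first; `include_preceding = TRUE` additionally prepends one
#' reference-free sentence where available. Fragments never cross paragraph
#' boundaries, and every detected reference is covered by exactly one
#' fragment (a sentence citing several figures yields one fragment per
#' figure/panel key over the same sentence run).
#'
#' @param doc A `bt_document`.
#' @param include_preceding Prepend one preceding sentence to each fragment.
#' @return A tibble: `doc_id`, `paragraph` (index), `figure`, `panels`
#'   (list-column), `sent_from`, `sent_to` (1-based sentence indexes within
#'   the paragraph), `text`.
#' @export
extract_evidence_fragments <- function(doc, include_preceding = FALSE) {
  stopifnot(inherits(doc, "bt_document"))
  empty <- tibble(doc_id = character(), paragraph = integer(), figure = integer(),
                  panels = list(), sent_from = integer(), sent_to = integer(),
                  text = character())
  if (nrow(doc$paragraphs) == 0) return(empty)
  frags <- list()
  for (p in seq_len(nrow(doc$paragraphs))) {
    sents <- split_sentences(doc$paragraphs$text[p])
    if (nrow(sents) == 0) next
    sent_refs <- map(sents$text, find_figure_references)
    keys <- map_chr(sent_refs, function(r) {
      if (nrow(r) == 0) NA_character_
      else paste(sort(unique(ref_key_rows(r))), collapse = "|")
    })
    runs <- list()   # list of (from, to, refs tibble)
    open <- NULL
    prev_end <- 0L
    for (s in seq_along(keys)) {
      if (is.na(keys[s])) {
        if (!is.null(open)) open$to <- s
        next
      }
      if (!is.null(open) && identical(open$key, keys[s])) {
        open$to <- s
        next
      }
      if (!is.null(open)) { runs[[length(runs) + 1L]] <- open; prev_end <- open$to }
      from <- s
      if (include_preceding && s - 1L > prev_end && is.na(keys[s - 1L])) from <- s - 1L
      open <- list(key = keys[s], from = from, to = s, refs = sent_refs[[s]])
    }
    if (!is.null(open)) runs[[length(runs) + 1L]] <- open
    for (r in runs) {
      uref <- unique_refs(r$refs)
      for (j in seq_len(nrow(uref))) {
        frags[[length(frags) + 1L]] <- tibble(
          doc_id = doc$doc_id, paragraph = p,
          figure = uref$figure[j], panels = uref$panels[j],
          sent_from = r$from, sent_to = r$to,
          text = paste(sents$text[r$from:r$to], collapse = " "))
      }
    }
  }
  if (!length(frags)) return(empty)
  bind_rows(frags)
}

ref_key_rows <- function(refs) {
  vapply(seq_len(nrow(refs)),
         function(i) ref_key(refs$figure[i], refs$panels[[i]]), character(1))
}

unique_refs <- function(refs) {
  keys <- ref_key_rows(refs)
  refs[!duplicated(keys), c("figure", "panels")]
}

#' Look up the caption passage for a figure reference
#'
#' Returns the whole caption of the referenced figure, tagged with the panels
#' of the reference. Panel-level sub-caption splitting is deliberately not
#' attempted: curated records anchor to the subfigure, but the caption is
#' linked as a unit.
#'
#' @param doc A `bt_document`.
#' @param figure Figure number (positive integer).
#' @param panels Optional character vector of panel letters.
#' @return A one-row tibble: `doc_id`, `kind` (`"caption"`), `figure`,
#'   `panels` (list-column), `text`.
#' @export
caption_for <- function(doc, figure, panels = character()) {
  stopifnot(inherits(doc, "bt_document"))
  figure <- as.integer(figure)
  key <- as.character(figure)
  if (!key %in% names(doc$captions)) {
    abort(paste0("document ", doc$doc_id, " has no caption for figure ", figure))
  }
  tibble(doc_id = doc$doc_id, kind = "caption", figure = figure,
         panels = list(sort(unique(toupper(panels)))),
         text = unname(doc$captions[[key]]))
}

#' Write evidence fragments as TSV
#'
#' One row per fragment: `doc_id`, `figure_id`, `panels` (comma-joined),
#' `fragment_text`.
#'
#' @param fragments Output of [extract_evidence_fragments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_tsv <- function(fragments, path) {
  out <- tibble(
    doc_id = fragments$doc_id,
    figure_id = fragments$figure,
    panels = map_chr(fragments$panels, paste, collapse = ","),
    fragment_text = fragments$text)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a document's fragments in a BioC-like XML layout
#'
#' Emits `<collection><document><passage>` elements with `infon` metadata
#' (figure, panels) and `<annotation>` spans for each figure reference found
#' in the fragment text (offsets relative to the fragment).
#'
#' @param doc A `bt_document`.
#' @param fragments Output of [extract_evidence_fragments()] for `doc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bioc <- function(doc, fragments, path) {
  root <- xml2::xml_new_root("collection")
  xml2::xml_add_child(root, "source", "biotriage")
  d <- xml2::xml_add_child(root, "document")
  xml2::xml_add_child(d, "id", doc$doc_id)
  for (i in seq_len(nrow(fragments))) {
    p <- xml2::xml_add_child(d, "passage")
    inf <- xml2::xml_add_child(p, "infon", as.character(fragments$figure[i]))
    xml2::xml_set_attr(inf, "key", "figure")
    inf2 <- xml2::xml_add_child(p, "infon",
                                paste(fragments$panels[[i]], collapse = ","))
    xml2::xml_set_attr(inf2, "key", "panels")
    xml2::xml_add_child(p, "text", fragments$text[i])
    refs <- find_figure_references(fragments$text[i])
    for (j in seq_len(nrow(refs))) {
      a <- xml2::xml_add_child(p, "annotation")
      loc <- xml2::xml_add_child(a, "location")
      xml2::xml_set_attr(loc, "offset", as.character(refs$start[j]))
      xml2::xml_set_attr(loc, "length", as.character(refs$end[j] - refs$start[j]))
      xml2::xml_add_child(a, "text", refs$match[j])
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}
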