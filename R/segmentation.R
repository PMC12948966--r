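#' Construct a document
#'
#' A document is the atomic unit of analysis: one text (written or a
#' transcript of elicited speech) with an identifier and a language tag.
#' Text is NFC-normalized and whitespace-collapsed on construction; case is
#' left untouched because case handling belongs to embedding backends.
#'
#' @param id Opaque identifier, unique within a corpus.
#' @param text UTF-8 text; must be non-empty after whitespace trimming.
#' @param language Language tag, one of `"en"`, `"zh"`, `"da"`, `"other"`.
#' @param is_transcript Logical; `TRUE` for utterance-segmented clinical
#'   speech, where utterance boundaries are pre-marked one per line and must
#'   never be merged or re-split.
#' @return An object of class `semcoh_document`.
#' @export
document <- function(id, text, language = c("en", "zh", "da", "other"),
                     is_transcript = FALSE) {
  language <- match.arg(language)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single character string", call. = FALSE)
  text <- stringi::stri_trans_nfc(enc2utf8(text))
  if (!nzchar(trimws(text)))
    stop("document '", id, "': text is empty after whitespace trim",
         call. = FALSE)
  if (!is_transcript) {
    # collapse runs of blanks but preserve line structure for transcripts
    text <- gsub("[ \t]+", " ", trimws(text))
  }
  structure(
    list(id = id, text = text, language = language,
         is_transcript = isTRUE(is_transcript)),
    class = "semcoh_document"
  )
}

#' @export
print.semcoh_document <- function(x, ...) {
  cat(sprintf("<document '%s' [%s]%s: %d chars>\n", x$id, x$language,
              if (x$is_transcript) " transcript" else "", nchar(x$text)))
  invisible(x)
}

#' Construct a unit sequence
#'
#' Ordered meaningful units of one document at one analysis level. The three
#' levels mirror the three embedding families used downstream: lexical
#' categories (content words), subword tokens, and sentences/utterances.
#'
#' @param level One of `"lexical"`, `"token"`, `"sentence"`.
#' @param units Character vector of units in surface order.
#' @param source_doc Identifier of the originating document.
#' @return An object of class `semcoh_units`.
#' @export
unit_sequence <- function(level = c("lexical", "token", "sentence"),
                          units, source_doc = NA_character_) {
  level <- match.arg(level)
  stopifnot(is.character(units))
  structure(list(level = level, units = units, source_doc = source_doc),
            class = "semcoh_units")
}

#' @export
print.semcoh_units <- function(x, ...) {
  cat(sprintf("<%s units (%d) of '%s'>\n", x$level, length(x$units),
              x$source_doc))
  invisible(x)
}

#' @export
length.semcoh_units <- function(x) length(x$units)

default_sentence_splitter <- function(text) {
  # rule-based splitter: break after terminal punctuation (Latin or CJK)
  # followed by whitespace or end; keeps the punctuation with its sentence
  pieces <- stringi::stri_split_regex(
    text, "(?<=[.!?…。！？][\"'”’）)]?)\\s+"
  )[[1]]
  pieces <- trimws(pieces)
  pieces[nzchar(pieces)]
}

#' Split a document into sentences or utterances
#'
#' Written text is split with a sentence splitter (a function taking the text
#' and returning the ordered sentences); clinical transcripts are split only
#' at their pre-marked utterance boundaries (one utterance per line), which
#' are never merged or re-split.
#'
#' @param doc A [document()].
#' @param splitter Sentence-splitter contract: `function(text)` returning a
#'   character vector of sentences in order. Ignored for transcripts. The
#'   default is a rule-based terminal-punctuation splitter covering Latin and
#'   CJK punctuation.
#' @return A [unit_sequence()] with `level = "sentence"`.
#' @export
segment_sentences <- function(doc, splitter = default_sentence_splitter) {
  stopifnot(inherits(doc, "semcoh_document"))
  if (doc$is_transcript) {
    units <- trimws(strsplit(doc$text, "\n", fixed = TRUE)[[1]])
    units <- units[nzchar(units)]
  } else {
    units <- splitter(doc$text)
  }
  if (length(units) == 0L)
    stop("document '", doc$id, "': no sentences found", call. = FALSE)
  unit_sequence("sentence", units, doc$id)
}

#' Extract lexical units (content words)
#'
#' Lexical units are the nouns, verbs and adjectives of the document, in
#' surface order. The part-of-speech tagger is an injected contract so that
#' tests run with rule-based fixtures and production use can plug in any
#' tagger emitting coarse (universal) POS tags.
#'
#' @param doc A [document()].
#' @param tagger POS-tagger contract: `function(words)` returning one coarse
#'   POS tag (e.g. `"NOUN"`, `"VERB"`, `"ADJ"`, `"DET"`, ...) per word.
#' @param include_propn Count proper nouns (`"PROPN"`) as nouns. Picture
#'   descriptions name entities, so the default is `TRUE`.
#' @return A [unit_sequence()] with `level = "lexical"`. Lexical units are
#'   always a subsequence of the document's surface words.
#' @export
extract_lexical_units <- function(doc, tagger, include_propn = TRUE) {
  stopifnot(inherits(doc, "semcoh_document"), is.function(tagger))
  words <- surface_words(doc$text)
  tags <- tryCatch(tagger(words), error = function(e)
    stop("tagger failed on document '", doc$id, "': ", conditionMessage(e),
         call. = FALSE))
  if (length(tags) != length(words))
    stop("tagger returned ", length(tags), " tags for ", length(words),
         " words (document '", doc$id, "')", call. = FALSE)
  keep <- c("NOUN", "VERB", "ADJ", if (include_propn) "PROPN")
  unit_sequence("lexical", words[tags %in% keep], doc$id)
}

surface_words <- function(text) {
  words <- stringi::stri_split_regex(text, "\\s+")[[1]]
  # strip leading/trailing punctuation but keep word-internal marks
  words <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", words)
  words[nzchar(words)]
}

#' Tokenize a document into subword tokens
#'
#' @param doc A [document()].
#' @param tokenizer Subword-tokenizer contract: `function(text)` returning
#'   the ordered token strings with special boundary markers already removed.
#'   Must be the tokenizer paired with the contextual embedding backend. The
#'   default is a whitespace tokenizer (suitable for synthetic backends).
#' @return A [unit_sequence()] with `level = "token"`.
#' @export
tokenize_subwords <- function(doc, tokenizer = surface_words) {
  stopifnot(inherits(doc, "semcoh_document"), is.function(tokenizer))
  units <- tokenizer(doc$text)
  if (length(units) == 0L)
    stop("document '", doc$id, "': tokenizer produced no tokens",
         call. = FALSE)
  unit_sequence("token", units, doc$id)
}

#' Minimum-unit usability rule
#'
#' A unit sequence enters the semantic analysis only when it has at least
#' `min_units` units; otherwise every feature at that level is treated as a
#' missing value. The default of 4 resolves the boundary status of
#' exactly-four-unit texts in favour of usability.
#'
#' @param units A [unit_sequence()] or a bare count.
#' @param min_units Minimum usable unit count (default 4).
#' @return Logical: is the sequence usable?
#' @export
check_min_units <- function(units, min_units = 4L) {
  n <- if (inherits(units, "semcoh_units")) length(units$units)
       else as.integer(units)
  n >= min_units
}
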