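#' Tokenize clinical text
#'
#' Lower-cases and splits on any run of non-alphanumeric characters;
#' empty tokens are dropped. This is the word definition used by the
#' negation window: punctuation is a separator and sentence boundaries
#' carry no special meaning.
#'
#' @param text A character string (vectors are collapsed element-wise is
#'   not supported; pass one document).
#' @return Character vector of tokens (possibly empty).
#' @examples
#' hlh_tokenize("No splenomegaly.")
#' hlh_tokenize("spleen—enlarged")
#' @export
hlh_tokenize <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || text == "") return(character())
  toks <- stringr::str_split_1(stringr::str_to_lower(text), "[^a-z0-9]+")
  toks[toks != ""]
}

#' Find lexicon phrase mentions in a token stream
#'
#' Scans left to right for matches of any lexicon phrase (1-3 tokens,
#' case-insensitive). Matches are non-overlapping; at a given start
#' position the longest matching phrase wins.
#'
#' @param text Document text, or a pre-tokenized character vector via
#'   `tokens`.
#' @param lexicon Character vector of phrases (e.g. `"enlarged spleen"`).
#' @param tokens Optional pre-computed tokens; overrides `text`.
#' @return A tibble with columns `term` (the matched lexicon entry) and
#'   `start_token_index` (0-based position of the first token of the match).
#' @examples
#' find_term_mentions("marked splenomegaly noted",
#'                    hlh_config()$splenomegaly_terms)
#' @export
find_term_mentions <- function(text, lexicon, tokens = NULL) {
  toks <- tokens %||% hlh_tokenize(text)
  empty <- tibble(term = character(), start_token_index = integer())
  if (!length(lexicon) || !length(toks)) return(empty)
  phrases <- purrr::map(lexicon, function(p) hlh_tokenize(p))
  keep <- lengths(phrases) > 0
  phrases <- phrases[keep]
  lexicon <- lexicon[keep]
  if (!length(phrases)) return(empty)
  out_term <- character(); out_idx <- integer()
  i <- 1L
  n <- length(toks)
  # longest-first at each position, then advance past the match
  ord <- order(-lengths(phrases))
  while (i <= n) {
    hit <- 0L
    for (j in ord) {
      ph <- phrases[[j]]
      L <- length(ph)
      if (i + L - 1L <= n && all(toks[i:(i + L - 1L)] == ph)) {
        hit <- j
        break
      }
    }
    if (hit > 0L) {
      out_term <- c(out_term, lexicon[hit])
      out_idx <- c(out_idx, i - 1L)
      i <- i + length(phrases[[hit]])
    } else {
      i <- i + 1L
    }
  }
  tibble(term = out_term, start_token_index = out_idx)
}

#' Test whether a mention is negated
#'
#' A mention is negated when any negation cue appears among the `window`
#' tokens immediately preceding the mention's first token. The window is
#' counted in tokens and may cross sentence boundaries.
#'
#' @param tokens Token vector (from [hlh_tokenize()]).
#' @param mention_start 0-based index of the mention's first token.
#' @param negation_terms Character vector of single-token cues.
#' @param window Number of preceding tokens scanned (default 3).
#' @return Logical scalar.
#' @examples
#' tk <- hlh_tokenize("no evidence of splenomegaly")
#' is_negated(tk, 3, hlh_config()$negation_terms)
#' @export
is_negated <- function(tokens, mention_start,
                       negation_terms = hlh_config()$negation_terms,
                       window = 3L) {
  stopifnot(window >= 0)
  if (mention_start < 0 || mention_start >= length(tokens)) {
    abort("mention_start out of range")
  }
  if (window == 0L || mention_start == 0L) return(FALSE)
  lo <- max(1L, mention_start - as.integer(window) + 1L)
  any(tokens[lo:mention_start] %in% stringr::str_to_lower(negation_terms))
}

#' Classify a clinical note for splenomegaly
#'
#' Positive iff the note contains at least one mention of a splenomegaly
#' term that is not negated within the preceding token window.
#'
#' @param text Note text.
#' @param config An [hlh_config()].
#' @return Logical scalar.
#' @examples
#' note_positive_for_splenomegaly("no splenomegaly")
#' note_positive_for_splenomegaly("enlarged spleen palpable")
#' @export
note_positive_for_splenomegaly <- function(text, config = hlh_config()) {
  toks <- hlh_tokenize(text)
  m <- find_term_mentions(tokens = toks, lexicon = config$splenomegaly_terms)
  if (!nrow(m)) return(FALSE)
  neg <- purrr::map_lgl(m$start_token_index, function(i)
    is_negated(toks, i, config$negation_terms, config$negation_window_words))
  any(!neg)
}

#' Classify a pathology report for hemophagocytosis
#'
#' If a manual-review adjudication is supplied it is returned unchanged.
#' Otherwise the report is positive iff any hemophagocytosis pattern
#' (both spellings of "hemophagocytosis"/"hemophagocytic") matches the
#' text and the match is not negated under the same preceding-window rule
#' used for splenomegaly; automated negation stands in for the manual
#' review, with `adjudicated_positive` as the override channel.
#'
#' @param text Report text.
#' @param adjudicated_positive Optional logical override (chart-review
#'   label); `NA` means unadjudicated.
#' @param config An [hlh_config()].
#' @return Logical scalar.
#' @examples
#' pathology_positive_for_hemophagocytosis("hemophagocytic activity seen")
#' pathology_positive_for_hemophagocytosis("no hemophagocytosis identified")
#' @export
pathology_positive_for_hemophagocytosis <- function(text,
                                                    adjudicated_positive = NA,
                                                    config = hlh_config()) {
  if (!is.na(adjudicated_positive)) return(isTRUE(adjudicated_positive))
  toks <- hlh_tokenize(text)
  m <- find_term_mentions(tokens = toks,
                          lexicon = config$hemophagocytosis_patterns)
  if (!nrow(m)) {
    # patterns are stems: also accept substring hits inside longer tokens
    pat <- stringr::str_to_lower(config$hemophagocytosis_patterns)
    hits <- which(purrr::map_lgl(toks, function(t)
      any(stringr::str_detect(t, stringr::fixed(pat)))))
    if (!length(hits)) return(FALSE)
    m <- tibble(term = toks[hits], start_token_index = hits - 1L)
  }
  neg <- purrr::map_lgl(m$start_token_index, function(i)
    is_negated(toks, i, config$negation_terms, config$negation_window_words))
  any(!neg)
}
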