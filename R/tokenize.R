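#' Split free text into sentences
#'
#' Splits on `.`, `!` or `?` followed by whitespace (or end of text), after
#' masking the periods of a protected abbreviation list, so that
#' "E. coli" style species names survive intact. Concatenating the returned
#' sentences reconstructs the text modulo whitespace.
#'
#' @param text A single character string (may be empty).
#' @param words Closed word lists, see [rule_words()].
#' @return A character vector of sentences; empty text gives `character(0)`.
#' @export
#' @examples
#' split_sentences("AtuD binds citronellyl-CoA. PA1535 was inactive.")
split_sentences <- function(text, words = rule_words()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  masked <- text
  for (ab in words$abbreviations) {
    masked <- stringr::str_replace_all(
      masked, stringr::fixed(ab),
      stringr::str_replace_all(ab, stringr::fixed("."), ""))
  }
  parts <- strsplit(masked, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- stringr::str_replace_all(parts, stringr::fixed(""), ".")
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Tokenize one sentence with coarse tags
#'
#' Whitespace tokenization with terminal punctuation stripped into its own
#' right; commas and other punctuation clinging to a word are removed but the
#' word is kept. Each token gets a coarse tag in
#' `{N, V, PREP, PRON, CONJ, OTHER}` from the closed word lists; words on no
#' list default to `N` (noun-phrase material), except determiners and
#' connectors which are `OTHER`.
#'
#' @param sentence A single sentence string.
#' @param words Closed word lists, see [rule_words()].
#' @return A tibble with columns `token`, `index` (0-based), `tag`,
#'   `comma_after` (logical: token was followed by a comma).
#' @export
tokenize_sentence <- function(sentence, words = rule_words()) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  raw <- strsplit(trimws(sentence), "\\s+")[[1]]
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) {
    return(tibble(token = character(), index = integer(), tag = character(),
                  comma_after = logical()))
  }
  comma_after <- stringr::str_detect(raw, ",$|;$")
  clean <- stringr::str_remove_all(raw, "^[\\(\\[\"']+|[\\)\\]\"',;:]+$|[.!?]+$")
  keep <- nzchar(clean)
  clean <- clean[keep]
  comma_after <- comma_after[keep]
  lower <- tolower(clean)
  tag <- rep("N", length(clean))
  tag[lower %in% words$prepositions] <- "PREP"
  tag[lower %in% words$conjunctions] <- "CONJ"
  tag[lower %in% words$pronouns] <- "PRON"
  tag[lower %in% words$verbs] <- "V"
  tag[lower %in% words$determiners] <- "OTHER"
  tag[lower %in% words$modifiers] <- "OTHER"
  tag[lower %in% words$connectors] <- "OTHER"
  tibble(token = clean, index = seq_along(clean) - 1L, tag = tag,
         comma_after = comma_after)
}

#' Tokenize a whole text into tagged sentences
#'
#' @param text A single character string.
#' @param words Closed word lists.
#' @return A tibble with columns `sentence` (1-based index), `token`, `index`
#'   (0-based within sentence), `tag`, `comma_after`.
#' @export
tokenize_text <- function(text, words = rule_words()) {
  sents <- split_sentences(text, words)
  if (length(sents) == 0L) {
    return(tibble(sentence = integer(), token = character(),
                  index = integer(), tag = character(),
                  comma_after = logical()))
  }
  imap(sents, function(s, i) {
    mutate(tokenize_sentence(s, words), sentence = i, .before = 1L)
  }) |> list_rbind()
}
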