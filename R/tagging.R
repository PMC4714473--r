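#' Tag protein and molecule mentions by dictionary matching
#'
#' Longest-match-first, case-insensitive matching of lexicon names and
#' synonyms against the token sequence of each sentence. A light stemmer
#' strips a plural "s"/"es" from non-hyphenated words only, so identifiers
#' like "citronellyl-CoA" are matched exactly. When two surface forms of the
#' same length compete for a position, the lexicographically smallest
#' canonical id wins, making tagging independent of lexicon row order. Each
#' token belongs to at most one mention and no mention crosses a sentence
#' boundary.
#'
#' @param tokens Tagged tokens from [tokenize_text()] (or one sentence from
#'   [tokenize_sentence()], in which case a `sentence` column is added).
#' @param lexicon Entity lexicon, see [read_lexicon()].
#' @param forms Optional precompiled surface-form table from
#'   [lexicon_forms()], reused across abstracts for speed.
#' @return A tibble of mentions: `sentence`, `start`, `end` (0-based,
#'   half-open token span), `canonical_id`, `kind`, `surface`, `coref`
#'   (logical, `FALSE` here; see [resolve_surface_coreference()]).
#' @export
tag_entities <- function(tokens, lexicon, forms = NULL) {
  if (!"sentence" %in% names(tokens)) tokens <- mutate(tokens, sentence = 1L)
  if (is.null(forms)) forms <- lexicon_forms(lexicon)
  empty <- tibble(sentence = integer(), start = integer(), end = integer(),
                  canonical_id = character(), kind = character(),
                  surface = character(), coref = logical())
  if (nrow(tokens) == 0L || length(forms$ids) == 0L) return(empty)
  m_sent <- integer(); m_start <- integer(); m_len <- integer()
  m_id <- character(); m_kind <- character(); m_surf <- character()
  for (s in unique(tokens$sentence)) {
    sent_tok <- tokens$token[tokens$sentence == s]
    toks <- stem_token(sent_tok)
    n <- length(toks)
    i <- 1L
    while (i <= n) {
      hit_len <- 0L
      for (len in seq(min(forms$maxlen, n - i + 1L), 1L)) {
        key <- paste(toks[i:(i + len - 1L)], collapse = " ")
        pos <- match(key, forms$keys)
        if (!is.na(pos)) {
          hit_len <- len
          m_sent <- c(m_sent, s); m_start <- c(m_start, i - 1L)
          m_len <- c(m_len, len)
          m_id <- c(m_id, forms$ids[[pos]])
          m_kind <- c(m_kind, forms$kinds[[pos]])
          m_surf <- c(m_surf, paste(sent_tok[i:(i + len - 1L)],
                                    collapse = " "))
          break
        }
      }
      i <- i + max(hit_len, 1L)
    }
  }
  if (length(m_sent) == 0L) return(empty)
  tibble(sentence = m_sent, start = m_start, end = m_start + m_len,
         canonical_id = m_id, kind = m_kind, surface = m_surf,
         coref = FALSE)
}

# lowercase + plural stripping on non-hyphenated alphabetic words >3 chars;
# "es" comes off only after sibilants (boxes -> box) so that words like
# "coenzymes" lose just the "s"
stem_token <- function(x) {
  x <- tolower(x)
  plain <- !stringr::str_detect(x, "-") &
    stringr::str_detect(x, "^[a-z]+$") & nchar(x) > 3L
  x[plain] <- stringr::str_replace(x[plain], "(?<=x|z|ch|sh|ss)es$", "")
  x[plain] <- stringr::str_replace(x[plain], "(?<!s)s$", "")
  x
}

#' Compile a lexicon into a stemmed surface-form lookup
#'
#' Internal representation used by [tag_entities()]; exposed so that a
#' corpus pipeline can compile the lexicon once. Duplicate surface forms are
#' resolved to the lexicographically smallest canonical id.
#'
#' @param lexicon Entity lexicon.
#' @return A list with `keys` (stemmed surface keys), parallel `ids` and
#'   `kinds`, and `maxlen` (longest form in tokens).
#' @export
lexicon_forms <- function(lexicon) {
  rows <- pmap(list(lexicon$canonical_id, lexicon$kind, lexicon$name,
                    lexicon$synonyms),
               function(id, kind, name, syns) {
                 tibble(canonical_id = id, kind = kind,
                        form = c(name, syns))
               })
  forms <- list_rbind(rows)
  forms <- forms[nzchar(forms$form), ]
  keys <- map_chr(forms$form, function(f) {
    toks <- strsplit(trimws(f), "\\s+")[[1]]
    paste(stem_token(toks), collapse = " ")
  })
  forms <- mutate(forms, key = keys) |>
    arrange(.data$key, .data$canonical_id) |>
    distinct(.data$key, .keep_all = TRUE)
  list(keys = forms$key, ids = forms$canonical_id, kinds = forms$kind,
       maxlen = if (nrow(forms) > 0L) {
         max(stringr::str_count(forms$key, " ") + 1L)
       } else 0L)
}

#' Resolve trivial surface coreference of proteins
#'
#' Links the phrases "this protein", "the protein", "it" and "they" in a
#' sentence to the protein mentioned in the immediately preceding sentence,
#' provided that sentence mentions exactly one distinct protein. Ambiguous
#' antecedents (zero or several candidate proteins) leave the phrase
#' unresolved. Resolved phrases are appended as extra mentions flagged
#' `coref = TRUE`; pronoun positions already covered by a mention are
#' skipped.
#'
#' @param tokens Tagged tokens from [tokenize_text()].
#' @param mentions Mentions from [tag_entities()].
#' @param words Closed word lists.
#' @return The mention tibble augmented with coreference mentions.
#' @export
resolve_surface_coreference <- function(tokens, mentions,
                                        words = rule_words()) {
  sents <- sort(unique(tokens$sentence))
  extra <- list()
  current <- mentions  # grows as links resolve, so chains cascade
  for (s in sents[sents > 1L]) {
    prev <- current[current$sentence == s - 1L &
                      current$kind == "protein", ]
    ids <- unique(prev$canonical_id)
    if (length(ids) != 1L) next
    sent <- tokens[tokens$sentence == s, ]
    lower <- tolower(sent$token)
    taken <- unlist(map2(mentions$start[mentions$sentence == s],
                         mentions$end[mentions$sentence == s],
                         function(a, b) seq(a, b - 1L)))
    k <- 1L
    while (k <= nrow(sent)) {
      span <- NULL
      if (k < nrow(sent) && lower[k] %in% c("this", "the") &&
          lower[k + 1L] == "protein") {
        span <- c(sent$index[k], sent$index[k + 1L] + 1L)
      } else if (k == 1L && lower[k] %in% c("it", "they")) {
        # bare pronouns are only linked in sentence-initial position;
        # elsewhere the clause rules resolve them structurally
        span <- c(sent$index[k], sent$index[k] + 1L)
      }
      if (!is.null(span) && !any(seq(span[1], span[2] - 1L) %in% taken)) {
        link <- tibble(
          sentence = s, start = span[1], end = span[2],
          canonical_id = ids, kind = "protein",
          surface = paste(sent$token[k:(k + (span[2] - span[1]) - 1L)],
                          collapse = " "),
          coref = TRUE)
        extra[[length(extra) + 1L]] <- link
        current <- bind_rows(current, link)
        k <- k + (span[2] - span[1])
      } else {
        k <- k + 1L
      }
    }
  }
  bind_rows(mentions, list_rbind(extra)) |>
    arrange(.data$sentence, .data$start)
}
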