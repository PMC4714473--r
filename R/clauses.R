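#' Merge connector-led sentences into analysis units
#'
#' A sentence whose first word is a sentence connector ("moreover",
#' "however", "otherwise", "therefore", "furthermore", "thus", "hence",
#' "in addition") is merged with its predecessor into one analysis unit, and
#' merging is transitive: a chain of connector-led sentences forms a single
#' unit. Entity pairs can only be semantically related across sentences
#' inside one unit.
#'
#' @param tokens Tagged tokens from [tokenize_text()].
#' @param words Closed word lists.
#' @return The token tibble with an added integer `unit` column.
#' @export
merge_connected_sentences <- function(tokens, words = rule_words()) {
  if (nrow(tokens) == 0L) return(mutate(tokens, unit = integer()))
  sents <- sort(unique(tokens$sentence))
  unit_of <- integer(length(sents))
  cur <- 0L
  for (k in seq_along(sents)) {
    first <- tokens[tokens$sentence == sents[k], ]
    lead1 <- tolower(first$token[1])
    lead2 <- if (nrow(first) >= 2L) {
      tolower(paste(first$token[1], first$token[2]))
    } else ""
    connected <- k > 1L && (lead1 %in% words$connectors ||
                              lead2 %in% words$connectors)
    if (!connected) cur <- cur + 1L
    unit_of[k] <- cur
  }
  left_join(tokens, tibble(sentence = sents, unit = unit_of),
            by = "sentence")
}

# global token position within a document (order: sentence, index)
add_positions <- function(tokens) {
  tokens <- arrange(tokens, .data$sentence, .data$index)
  mutate(tokens, pos = row_number())
}

mention_positions <- function(mentions, tokens) {
  offs <- tokens |>
    group_by(.data$sentence) |>
    summarise(off = min(.data$pos) - 1L, .groups = "drop")
  mentions |>
    left_join(offs, by = "sentence") |>
    mutate(pos_start = .data$off + .data$start + 1L,
           pos_end = .data$off + .data$end) |>  # inclusive token positions
    select(-"off")
}

#' Segment one analysis unit into independent clauses
#'
#' A clause boundary opens at (a) a relative pronoun ("which", "who",
#' "whom", or "that" when a verb follows within three tokens), (b) a
#' coordinating conjunction ("and"/"or") followed by an explicit pronoun or
#' directly by a verb (implicit pronoun), (c) a preposition modifier
#' ("but", "while", "whereas"), and (d) every sentence start inside the
#' unit. Each clause records the token that introduced it; clause spans
#' partition the unit's tokens. An unsplittable sentence is one clause.
#'
#' @param unit_tokens Tokens of one unit, with a `pos` column (see
#'   [merge_connected_sentences()]; positions are added automatically when
#'   absent).
#' @param words Closed word lists.
#' @return A tibble with columns `clause` (1-based), `pos_start`, `pos_end`
#'   (inclusive), `introducer` (`none`, `sentence`, `relpron`, `conj_expl`,
#'   `conj_impl`, `modifier`), `intro_token`, `sentence` (of the clause
#'   start).
#' @export
segment_clauses <- function(unit_tokens, words = rule_words()) {
  if (!"pos" %in% names(unit_tokens)) unit_tokens <- add_positions(unit_tokens)
  tk <- arrange(unit_tokens, .data$pos)
  n <- nrow(tk)
  if (n == 0L) {
    return(tibble(clause = integer(), pos_start = integer(),
                  pos_end = integer(), introducer = character(),
                  intro_token = character(), sentence = integer()))
  }
  lower <- tolower(tk$token)
  opens <- rep(NA_character_, n)
  opens[1] <- "none"
  for (i in 2:n) {
    if (n < 2L) break
    if (tk$sentence[i] != tk$sentence[i - 1L]) {
      opens[i] <- "sentence"
      next
    }
    w <- lower[i]
    if (w %in% words$relative_pronouns) {
      if (w != "that") {
        opens[i] <- "relpron"
      } else {
        ahead <- seq(i + 1L, min(i + 3L, n))
        if (length(ahead) > 0L && any(tk$tag[ahead] == "V" &
                                        tk$sentence[ahead] == tk$sentence[i])) {
          opens[i] <- "relpron"
        }
      }
    } else if (tk$tag[i] == "CONJ" && i < n) {
      nxt <- lower[i + 1L]
      if (nxt %in% c("it", "they", "he", "she")) {
        opens[i] <- "conj_expl"
      } else if (tk$tag[i + 1L] == "V") {
        opens[i] <- "conj_impl"
      }
    } else if (w %in% words$modifiers) {
      opens[i] <- "modifier"
    }
  }
  idx <- which(!is.na(opens))
  starts <- tk$pos[idx]
  ends <- c(tk$pos[idx[-1]] - 1L, tk$pos[n])
  tibble(clause = seq_along(idx), pos_start = starts, pos_end = ends,
         introducer = opens[idx],
         intro_token = ifelse(opens[idx] %in% c("none", "sentence"),
                              NA_character_, tk$token[idx]),
         sentence = tk$sentence[idx])
}

# rightmost maximal noun run in span, extended left over CONJ-joined runs
closest_noun_group <- function(tk, pos_from, pos_to) {
  span <- tk[tk$pos >= pos_from & tk$pos <= pos_to, ]
  if (nrow(span) == 0L) return(integer())
  is_n <- span$tag == "N"
  if (!any(is_n)) return(integer())
  r <- max(which(is_n))
  l <- r
  while (l > 1L && is_n[l - 1L]) l <- l - 1L
  group <- seq(l, r)
  # extend across "A and B" style conjunctions
  while (l > 2L && span$tag[l - 1L] == "CONJ" && is_n[l - 2L]) {
    r2 <- l - 2L
    l2 <- r2
    while (l2 > 1L && is_n[l2 - 1L]) l2 <- l2 - 1L
    group <- c(seq(l2, l - 1L), group)
    l <- l2
  }
  span$pos[group]
}

# first-verb-bounded subject noun phrase of a clause body
own_subject_span <- function(tk, pos_from, pos_to, words) {
  span <- tk[tk$pos >= pos_from & tk$pos <= pos_to, ]
  if (nrow(span) == 0L) return(integer())
  vidx <- which(span$tag == "V")
  stop_at <- if (length(vidx) > 0L) vidx[1] - 1L else nrow(span)
  if (stop_at < 1L) return(integer())
  span$pos[seq_len(stop_at)]
}

#' Resolve clause subjects by pronoun substitution
#'
#' Applies the substitution rules in clause order, cascading left to right:
#' a relative pronoun (or a plain pronoun opening a clause) is replaced by
#' the closest noun — the rightmost noun run, extended across "and"/"or" to
#' the maximal conjoined noun group — of the predecessor clause; an explicit
#' or implicit pronoun after a conjunction is replaced by the (already
#' resolved) subject of the closest predecessor clause. Modifier clauses and
#' plain clauses keep their own subject: the noun phrase before the first
#' verb. A pronoun with no predecessor noun leaves the clause subject-less
#' and flagged.
#'
#' @param clauses Clause tibble from [segment_clauses()].
#' @param unit_tokens Tokens of the unit (with `pos`).
#' @param words Closed word lists.
#' @return The clause tibble with added columns `subject_pos` (list of token
#'   positions), `subject` (text), `subject_source` (`own`, `relpron`,
#'   `plain_pron`, `conj`), `subjectless` (logical).
#' @export
substitute_pronouns <- function(clauses, unit_tokens, words = rule_words()) {
  if (!"pos" %in% names(unit_tokens)) unit_tokens <- add_positions(unit_tokens)
  tk <- arrange(unit_tokens, .data$pos)
  lower_of <- function(p) tolower(tk$token[match(p, tk$pos)])
  n <- nrow(clauses)
  subject_pos <- vector("list", n)
  source <- character(n)
  for (i in seq_len(n)) {
    intro <- clauses$introducer[i]
    body_from <- clauses$pos_start[i]
    # skip the introducing token / connector words / leading pronoun slot
    if (intro %in% c("relpron", "modifier")) body_from <- body_from + 1L
    if (intro %in% c("conj_expl")) body_from <- body_from + 2L
    if (intro %in% c("conj_impl")) body_from <- body_from + 1L
    if (intro == "sentence") {
      first <- lower_of(clauses$pos_start[i])
      first2 <- paste(lower_of(clauses$pos_start[i]),
                      lower_of(clauses$pos_start[i] + 1L))
      if (first2 %in% words$connectors) {
        body_from <- body_from + 2L
      } else if (first %in% words$connectors) {
        body_from <- body_from + 1L
      }
    }
    if (intro %in% c("conj_expl", "conj_impl")) {
      if (i > 1L) {
        subject_pos[[i]] <- subject_pos[[i - 1L]]
        source[i] <- "conj"
      } else {
        subject_pos[[i]] <- integer()
        source[i] <- "conj"
      }
    } else if (intro == "relpron") {
      grp <- if (i > 1L) {
        closest_noun_group(tk, clauses$pos_start[i - 1L],
                           clauses$pos_start[i] - 1L)
      } else integer()
      subject_pos[[i]] <- grp
      source[i] <- "relpron"
    } else {
      # plain clause (none / sentence / modifier): pronoun-led or own subject
      first <- lower_of(body_from)
      if (!is.na(first) && first %in% words$pronouns &&
          !(first %in% words$relative_pronouns)) {
        grp <- if (i > 1L) {
          closest_noun_group(tk, clauses$pos_start[i - 1L],
                             clauses$pos_end[i - 1L])
        } else integer()
        subject_pos[[i]] <- grp
        source[i] <- "plain_pron"
      } else {
        subject_pos[[i]] <- own_subject_span(tk, body_from,
                                             clauses$pos_end[i], words)
        source[i] <- "own"
      }
    }
  }
  subj_text <- map_chr(subject_pos, function(p) {
    if (length(p) == 0L) return(NA_character_)
    kept <- tk[match(p, tk$pos), ]
    paste(kept$token[kept$tag %in% c("N", "CONJ")], collapse = " ")
  })
  mutate(clauses, subject_pos = subject_pos, subject = subj_text,
         subject_source = source,
         subjectless = map_int(subject_pos, length) == 0L & source != "own")
}

#' Classify entity pairs of one analysis unit as related or unrelated
#'
#' After substitution, every clause owns its span mentions plus the mentions
#' inside its (possibly inherited) subject. A pair of mentions with distinct
#' canonical ids is semantically related when some clause holds both;
#' the recorded rule distinguishes plain same-clause co-occurrence from
#' relatedness established through a pronoun chain, a conjunction subject, or
#' a connector-merged sentence pair. An unrelated pair whose clauses are
#' separated by a preposition-modifier boundary is labelled
#' `PREP_MODIFIER_SPLIT`; all other unrelated pairs are
#' `DEFAULT_UNRELATED`. Every mention pair receives exactly one verdict.
#'
#' @param clauses Substituted clauses from [substitute_pronouns()].
#' @param unit_tokens Tokens of the unit (with `pos`).
#' @param mentions Mentions of the unit with `pos_start`/`pos_end` columns
#'   (see [analyze_abstract()] for the assembled pipeline).
#' @return A verdict tibble: `id_a`, `kind_a`, `sentence_a`, `id_b`,
#'   `kind_b`, `sentence_b`, `related`, `rule`, `same_sentence`.
#' @export
classify_pairs <- function(clauses, unit_tokens, mentions) {
  empty <- tibble(id_a = character(), kind_a = character(),
                  sentence_a = integer(), id_b = character(),
                  kind_b = character(), sentence_b = integer(),
                  related = logical(), rule = character(),
                  same_sentence = logical())
  if (nrow(mentions) < 2L) return(empty)
  m <- arrange(mentions, .data$pos_start)
  nc <- nrow(clauses)
  clause_of <- function(p) {
    which(clauses$pos_start <= p & clauses$pos_end >= p)[1]
  }
  m$clause <- map_int(m$pos_start, clause_of)
  # effective membership: clause c holds mention i if i's span is in c or i
  # is part of c's (inherited) subject
  member <- matrix(FALSE, nrow = nrow(m), ncol = nc)
  inherited <- matrix(FALSE, nrow = nrow(m), ncol = nc)
  for (ci in seq_len(nc)) {
    member[, ci] <- m$clause == ci
    sp <- clauses$subject_pos[[ci]]
    if (length(sp) > 0L) {
      in_subj <- map_lgl(seq_len(nrow(m)), function(k) {
        any(seq(m$pos_start[k], m$pos_end[k]) %in% sp)
      })
      inherited[, ci] <- in_subj & !member[, ci]
      member[, ci] <- member[, ci] | in_subj
    }
  }
  pairs_a <- integer(); pairs_b <- integer()
  for (a in seq_len(nrow(m) - 1L)) {
    for (b in seq((a + 1L), nrow(m))) {
      if (m$canonical_id[a] == m$canonical_id[b]) next
      pairs_a <- c(pairs_a, a); pairs_b <- c(pairs_b, b)
    }
  }
  if (length(pairs_a) == 0L) return(empty)
  np <- length(pairs_a)
  related <- logical(np); rule <- character(np)
  same_sent <- m$sentence[pairs_a] == m$sentence[pairs_b]
  for (k in seq_len(np)) {
    a <- pairs_a[k]; b <- pairs_b[k]
    shared <- which(member[a, ] & member[b, ])
    if (length(shared) > 0L) {
      ci <- shared[1]
      rule[k] <- if (!inherited[a, ci] && !inherited[b, ci]) {
        "SAME_CLAUSE"
      } else if (!same_sent[k]) {
        "CONNECTED_SENTENCES"
      } else if (clauses$introducer[ci] %in% c("conj_expl", "conj_impl")) {
        "CONJ_SUBJECT"
      } else {
        "PRONOUN_CHAIN"
      }
      related[k] <- TRUE
    } else {
      lo <- min(m$clause[a], m$clause[b])
      hi <- max(m$clause[a], m$clause[b])
      crosses_mod <- hi > lo &&
        any(clauses$introducer[seq(lo + 1L, hi)] == "modifier")
      rule[k] <- if (crosses_mod) "PREP_MODIFIER_SPLIT" else {
        "DEFAULT_UNRELATED"
      }
      related[k] <- FALSE
    }
  }
  tibble(id_a = m$canonical_id[pairs_a], kind_a = m$kind[pairs_a],
         sentence_a = m$sentence[pairs_a],
         id_b = m$canonical_id[pairs_b], kind_b = m$kind[pairs_b],
         sentence_b = m$sentence[pairs_b],
         related = related, rule = rule, same_sentence = same_sent)
}

#' Run the full clause analysis on one abstract
#'
#' Tokenizes, tags entities, optionally resolves surface coreference, merges
#' connector-led sentences into units, segments and substitutes clauses, and
#' classifies every entity mention pair. Mention pairs that never share a
#' unit are classified `DEFAULT_UNRELATED` (cross-sentence): connectors are
#' the only licence for cross-sentence relatedness.
#'
#' @param text Abstract text.
#' @param lexicon Entity lexicon.
#' @param words Closed word lists.
#' @param coref Resolve surface coreference first? Default `TRUE`.
#' @param forms Optional precompiled [lexicon_forms()] lookup.
#' @return A list with `tokens`, `mentions`, `clauses` (per unit, list) and
#'   `verdicts` (one row per mention pair).
#' @export
analyze_abstract <- function(text, lexicon, words = rule_words(),
                             coref = TRUE, forms = NULL) {
  tokens <- tokenize_text(text, words)
  mentions <- tag_entities(tokens, lexicon, forms)
  if (coref) mentions <- resolve_surface_coreference(tokens, mentions, words)
  tokens <- add_positions(merge_connected_sentences(tokens, words))
  mentions <- mention_positions(mentions, tokens)
  sent_unit <- distinct(select(tokens, "sentence", "unit"))
  mentions <- left_join(mentions, sent_unit, by = "sentence")
  units <- sort(unique(tokens$unit))
  all_clauses <- list()
  verdicts <- list()
  for (u in units) {
    utk <- filter(tokens, .data$unit == u)
    um <- filter(mentions, .data$unit == u)
    cl <- substitute_pronouns(segment_clauses(utk, words), utk, words)
    all_clauses[[as.character(u)]] <- cl
    verdicts[[length(verdicts) + 1L]] <- classify_pairs(cl, utk, um)
  }
  # cross-unit pairs: one DEFAULT_UNRELATED verdict per mention pair
  if (nrow(mentions) >= 2L && length(units) > 1L) {
    idx <- which(upper.tri(diag(nrow(mentions))), arr.ind = TRUE)
    a <- idx[, 1]; b <- idx[, 2]
    keep <- mentions$unit[a] != mentions$unit[b] &
      mentions$canonical_id[a] != mentions$canonical_id[b]
    a <- a[keep]; b <- b[keep]
    if (length(a) > 0L) {
      verdicts[[length(verdicts) + 1L]] <- tibble(
        id_a = mentions$canonical_id[a], kind_a = mentions$kind[a],
        sentence_a = mentions$sentence[a],
        id_b = mentions$canonical_id[b], kind_b = mentions$kind[b],
        sentence_b = mentions$sentence[b],
        related = FALSE, rule = "DEFAULT_UNRELATED",
        same_sentence = FALSE)
    }
  }
  list(tokens = tokens, mentions = mentions, clauses = all_clauses,
       verdicts = list_rbind(verdicts))
}

#' Render a clause table as indented debug text
#'
#' One clause per line with its introducer, resolved subject and token span,
#' for fixture review.
#'
#' @param clauses Substituted clauses from [substitute_pronouns()].
#' @param unit_tokens Tokens of the unit (with `pos`).
#' @return A character vector, one element per clause.
#' @export
clause_tree_text <- function(clauses, unit_tokens) {
  if (!"pos" %in% names(unit_tokens)) unit_tokens <- add_positions(unit_tokens)
  tk <- arrange(unit_tokens, .data$pos)
  map_chr(seq_len(nrow(clauses)), function(i) {
    txt <- paste(tk$token[tk$pos >= clauses$pos_start[i] &
                            tk$pos <= clauses$pos_end[i]], collapse = " ")
    indent <- strrep("  ", i - 1L)
    sprintf("%s[%s] subject=<%s> %s", indent, clauses$introducer[i],
            clauses$subject[i] %||% "", txt)
  })
}
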