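test_that("connector-led sentences merge transitively into one unit", {
  two <- tokenize_text("P binds X. Moreover, it binds Y.")
  expect_equal(length(unique(merge_connected_sentences(two)$unit)), 1L)
  plain <- tokenize_text("P binds X. Q binds Y.")
  expect_equal(length(unique(merge_connected_sentences(plain)$unit)), 2L)
  chain <- tokenize_text(paste(
    "P binds X.", "Moreover, it binds Y.", "Furthermore, it binds Z.",
    "In addition, it binds W."))
  merged <- merge_connected_sentences(chain)
  expect_equal(length(unique(merged$unit)), 1L)
  expect_equal(length(unique(merged$sentence)), 4L)
})

test_that("clause segmentation opens at relative pronouns and conjunctions", {
  ex <- worked_sentences()
  tk4 <- tokenize_text(ex$coenzymes_relative_pronoun$text)
  cl4 <- segment_clauses(tk4)
  expect_equal(nrow(cl4), 2L)
  expect_equal(cl4$introducer, c("none", "relpron"))
  expect_equal(cl4$intro_token[2], "that")
  tk8 <- tokenize_text(ex$fkh2p_which_chain$text)
  cl8 <- segment_clauses(tk8)
  expect_equal(nrow(cl8), 4L)
  expect_equal(cl8$introducer, c("none", "relpron", "relpron", "conj_impl"))
  one <- segment_clauses(tokenize_text("P binds X."))
  expect_equal(nrow(one), 1L)
  # clause spans partition the sentence's tokens
  expect_equal(sum(cl8$pos_end - cl8$pos_start + 1L), nrow(tk8))
})

test_that("'that' only opens a clause when a verb follows within 3 tokens", {
  split <- segment_clauses(tokenize_text("P is a molecule that binds X."))
  expect_equal(split$introducer, c("none", "relpron"))
  det <- segment_clauses(tokenize_text("P binds that molecule near X."))
  expect_equal(nrow(det), 1L)
})

test_that("pronoun substitution resolves the worked-example subjects", {
  ex <- worked_sentences()
  resolve <- function(text) {
    tk <- add_positions_for_test(text)
    substitute_pronouns(segment_clauses(tk), tk)
  }
  cl5 <- resolve(ex$cleaved_which_chain$text)
  expect_equal(cl5$subject[2], "53 amino-acid molecule")
  expect_equal(cl5$subject[3], "53 amino-acid molecule")
  expect_true(cl5$subjectless[1])  # sentence-initial "It", no predecessor
  cl6 <- resolve(ex$mshd_conjunction_pronoun$text)
  expect_match(cl6$subject[2], "MshD")
  cl8 <- resolve(ex$fkh2p_which_chain$text)
  expect_equal(cl8$subject[2], "Mcm1p")
  expect_equal(cl8$subject[3], "Sid2p")
  expect_equal(cl8$subject[4], "Sid2p")
})

test_that("verdicts reproduce all related/unrelated pairs of the worked sentences", {
  for (ex in worked_sentences()) {
    v <- analyze_abstract(ex$text, ex$lexicon)$verdicts
    for (pair in ex$related) {
      expect_true(isTRUE(pair_related(v, pair[1], pair[2])),
                  label = paste("related:", pair[1], "-", pair[2]))
    }
    for (pair in ex$unrelated) {
      expect_false(isTRUE(pair_related(v, pair[1], pair[2])),
                   label = paste("unrelated:", pair[1], "-", pair[2]))
    }
  }
})

test_that("preposition-modifier splits dominate and defaults are unrelated", {
  lex <- make_lexicon(c("P1", "P2", "M1"),
                      c("protein", "protein", "molecule"),
                      names = c("ProtA", "ProtB", "molX"))
  # unconnected sentences: cross-sentence pairs default to unrelated
  v <- analyze_abstract("ProtA binds molX. ProtB was purified.", lex)$verdicts
  cross <- v[(v$id_a == "P2" | v$id_b == "P2") &
               (v$id_a == "M1" | v$id_b == "M1"), ]
  expect_false(any(cross$related))
  expect_equal(unique(cross$rule), "DEFAULT_UNRELATED")
  expect_false(any(cross$same_sentence))
})

test_that("every mention pair in a unit receives exactly one verdict", {
  ex <- worked_sentences()$mshd_whereas_split
  an <- analyze_abstract(ex$text, ex$lexicon)
  n_mentions <- nrow(an$mentions)
  n_pairs <- choose(n_mentions, 2)
  # all canonical ids are distinct here, so every pair is classified once
  expect_equal(nrow(an$verdicts), n_pairs)
  expect_false(any(duplicated(
    an$verdicts[, c("id_a", "id_b", "sentence_a", "sentence_b")])))
})

test_that("a clause without modifiers or pronouns relates all its pairs", {
  lex <- make_lexicon(c("P1", "M1", "M2"),
                      c("protein", "molecule", "molecule"),
                      names = c("ProtA", "molX", "molY"))
  v <- analyze_abstract("ProtA binds molX and molY.", lex)$verdicts
  expect_true(all(v$related))
  expect_equal(unique(v$rule), "SAME_CLAUSE")
  expect_equal(nrow(v), 3L)
})

test_that("connector merging licenses cross-sentence relatedness", {
  lex <- make_lexicon(c("P1", "M1", "M2"),
                      c("protein", "molecule", "molecule"),
                      names = c("ProtA", "molX", "molY"))
  v <- analyze_abstract("molX binds ProtA. Moreover, it binds molY.",
                        lex)$verdicts
  got <- v[(v$id_a == "P1" & v$id_b == "M2") |
             (v$id_a == "M2" & v$id_b == "P1"), ]
  expect_true(any(got$related))
  expect_true(any(got$rule == "CONNECTED_SENTENCES" & !got$same_sentence))
})

test_that("the clause debug dump renders one annotated line per clause", {
  tk <- add_positions_for_test("ProtA binds molX, which binds molY.")
  cl <- substitute_pronouns(segment_clauses(tk), tk)
  txt <- clause_tree_text(cl, tk)
  expect_length(txt, 2L)
  expect_match(txt[1], "\\[none\\]")
  expect_match(txt[2], "\\[relpron\\]")
})
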