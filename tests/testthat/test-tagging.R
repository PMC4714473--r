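test_that("sentence splitting respects abbreviations and reconstructs text", {
  expect_equal(split_sentences("A. B."), c("A.", "B."))
  expect_length(split_sentences("The E. coli strain was grown."), 1L)
  expect_equal(split_sentences(""), character())
  txt <- paste("Purified AtuD showed citronellyl-CoA dehydrogenase",
               "activity. AtuD was inactive with octanoyl-CoA. Potential",
               "other dehydrogenases were found.")
  sents <- split_sentences(txt)
  expect_length(sents, 3L)
  # concatenation reconstructs the text modulo whitespace
  expect_equal(gsub("\\s+", " ", paste(sents, collapse = " ")),
               gsub("\\s+", " ", txt))
})

test_that("coarse tags come from the closed word lists with noun default", {
  tk <- tokenize_sentence("Protein MshD is composed of two domains, and it binds AcCoA.")
  expect_true(all(tk$tag %in% c("N", "V", "PREP", "PRON", "CONJ", "OTHER")))
  expect_equal(tk$tag[tk$token == "is"], "V")
  expect_equal(tk$tag[tk$token == "of"], "PREP")
  expect_equal(tk$tag[tk$token == "and"], "CONJ")
  expect_equal(tk$tag[tk$token == "it"], "PRON")
  expect_equal(tk$tag[tk$token == "AcCoA"], "N")
  expect_equal(tk$index, seq_len(nrow(tk)) - 1L)
})

test_that("dictionary tagging is longest-match and counts repeat mentions", {
  lex <- dplyr::bind_rows(ten_molecule_lexicon(),
                          make_lexicon("AtuD-rel", "protein", "PA1535"))
  tk <- tokenize_text(paste(
    "Purified AtuD showed citronellyl-CoA dehydrogenase activity and high",
    "affinity to citronellyl-CoA."))
  hits <- tag_entities(tk, lex)
  expect_equal(sum(hits$canonical_id == "AtuD"), 1L)
  expect_equal(sum(hits$canonical_id == "citronellyl-CoA"), 2L)
  # no lexicon names present -> no mentions
  expect_equal(nrow(tag_entities(tokenize_text("Nothing to see here."), lex)),
               0L)
})

test_that("overlapping candidates resolve to the single longest match", {
  lex <- make_lexicon(c("GC", "GCC"), c("molecule", "molecule"),
                      names = c("geranyl-CoA", "geranyl-CoA carboxylase"))
  tk <- tokenize_text("AtuC constitutes geranyl-CoA carboxylase in cells.")
  hits <- tag_entities(tk, lex)
  expect_equal(hits$canonical_id, "GCC")
  expect_equal(hits$end - hits$start, 2L)
})

test_that("tagging is independent of lexicon row order with id tie-break", {
  lex <- make_lexicon(c("B2", "A1"), c("molecule", "molecule"),
                      names = c("kinase", "kinase"))
  tk <- tokenize_text("The kinase was purified.")
  expect_equal(tag_entities(tk, lex)$canonical_id, "A1")
  expect_equal(tag_entities(tk, lex[2:1, ])$canonical_id, "A1")
})

test_that("plural stemming applies to plain words but never hyphenated names", {
  lex <- make_lexicon(c("m1", "m2"), c("molecule", "molecule"),
                      names = c("coenzyme", "citronellyl-CoA"))
  hits <- tag_entities(tokenize_text("Two coenzymes were bound."), lex)
  expect_equal(hits$canonical_id, "m1")
  # a hyphenated identifier with a stray trailing s must not match
  none <- tag_entities(tokenize_text("We assayed citronellyl-CoAs here."),
                       lex)
  expect_equal(nrow(none), 0L)
})

test_that("surface coreference links only unique previous-sentence proteins", {
  lex <- make_lexicon(c("PX", "PY", "M1"),
                      c("protein", "protein", "molecule"),
                      names = c("ProtX", "ProtY", "molY"))
  tk <- tokenize_text("ProtX binds molY. This protein also binds molY.")
  m <- tag_entities(tk, lex)
  aug <- resolve_surface_coreference(tk, m)
  link <- aug[aug$coref, ]
  expect_equal(nrow(link), 1L)
  expect_equal(link$canonical_id, "PX")
  expect_equal(link$sentence, 2L)
  # two candidate antecedents leave the phrase unresolved
  tk2 <- tokenize_text("ProtX binds ProtY. This protein also binds molY.")
  aug2 <- resolve_surface_coreference(tk2, tag_entities(tk2, lex))
  expect_false(any(aug2$coref))
})

test_that("a planted pronoun chain across sentences is fully recovered", {
  lex <- make_lexicon(c("PX", paste0("M", 1:4)),
                      c("protein", rep("molecule", 4)),
                      names = c("ProtX", paste0("mol", 1:4)))
  txt <- paste("ProtX binds mol1.", "It binds mol2.",
               "This protein binds mol3.", "It binds mol4.")
  tk <- tokenize_text(txt)
  aug <- resolve_surface_coreference(tk, tag_entities(tk, lex))
  links <- aug[aug$coref, ]
  expect_equal(links$sentence, 2:4)
  expect_equal(unique(links$canonical_id), "PX")
  # no mention crosses a sentence boundary
  expect_true(all(aug$end <= vapply(aug$sentence, function(s) {
    sum(tk$sentence == s)
  }, integer(1))))
})
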