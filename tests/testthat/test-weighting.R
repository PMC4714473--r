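test_that("note-2 frequency multiplier reproduces the log10 ladder", {
  cfg <- weighting_config(f_variant = "note2", log_base = 10)
  expect_equal(round(frequency_multiplier(4, cfg), 1), 1.6)
  expect_equal(round(frequency_multiplier(3, cfg), 1), 1.5)
  expect_equal(round(frequency_multiplier(2, cfg), 1), 1.3)
  expect_equal(frequency_multiplier(1, cfg), 1.0)
  expect_equal(frequency_multiplier(0, cfg), 0)
})

test_that("note-1 and note-3 multipliers follow their formulas", {
  cfg1 <- weighting_config(f_variant = "note1", c = 0.5)
  expect_equal(frequency_multiplier(6, cfg1, max_n = 6), 1.0)
  expect_equal(frequency_multiplier(3, cfg1, max_n = 6), 0.75)
  cfg3 <- weighting_config(f_variant = "note3")
  expect_equal(frequency_multiplier(5, cfg3, a_mp = 4), 0.25)
  expect_equal(frequency_multiplier(5, cfg3, a_mp = 0), 0)
  expect_error(weighting_config(c = 1), "strictly between")
})

test_that("abstract multiplier variants match direct evaluation", {
  cfg <- weighting_config(fa_variant = "note4", log_base = 10)
  expect_equal(abstract_frequency_multiplier(1, cfg, universe_size = 9), 1.0)
  # the log damps single-abstract pairs below twice the two-abstract value
  v1 <- abstract_frequency_multiplier(1, cfg, universe_size = 12)
  v2 <- abstract_frequency_multiplier(2, cfg, universe_size = 12)
  expect_lt(v1, 2 * v2)
  expect_equal(abstract_frequency_multiplier(0, cfg, universe_size = 12), 0)
  blk <- weighting_config(fa_variant = "note4_block")
  expect_equal(abstract_frequency_multiplier(3, blk, universe_size = 12),
               log10(1 + 3 / 12))
  n5 <- weighting_config(fa_variant = "note5")
  expect_equal(abstract_frequency_multiplier(4, n5, max_n = 6),
               log10(1 + 6 / 4))
})

test_that("contingency tables satisfy the expected-frequency identities", {
  zero <- build_contingency(
    list(n_rel_same = 0L, n_rel_cross = 0L, n_unrel_same = 0L,
         n_unrel_cross = 0L), a_rel = 0, a_unrel = 0, universe_size = 12)
  expect_true(all(zero$o == 0))
  expect_true(all(zero$e == 0))
  # an empty unrelated row forces e row 2 to zero and T' = 0
  tab <- build_contingency(
    list(n_rel_same = 3L, n_rel_cross = 1L, n_unrel_same = 0L,
         n_unrel_cross = 0L), a_rel = 2, a_unrel = 0, universe_size = 12)
  expect_true(all(tab$e[2, ] == 0))
  expect_equal(abstract_weight(tab)$t_unrelated, 0)
  # randomized counts: e_xy equals brute-force R_x * C_y / N
  set.seed(42)
  for (i in 1:25) {
    n <- as.list(stats::rpois(4, 2))
    names(n) <- c("n_rel_same", "n_rel_cross", "n_unrel_same",
                  "n_unrel_cross")
    t2 <- build_contingency(n, a_rel = 1 + (n$n_rel_same + n$n_rel_cross > 0),
                            a_unrel = 1, universe_size = 10)
    if (t2$n > 0) {
      for (x in 1:2) for (y in 1:2) {
        expect_equal(t2$e[x, y],
                     sum(t2$o[x, ]) * sum(t2$o[, y]) / sum(t2$o))
      }
      expect_equal(sum(t2$e), sum(t2$o))
    }
  }
})

test_that("per-abstract weight is T minus T-prime", {
  stats_tbl <- pa1535_abstract_stats()
  expect_equal(stats_tbl$t_related - stats_tbl$t_unrelated, stats_tbl$w,
               tolerance = 1e-12)
  # equality of the two components cancels the weight
  tab <- build_contingency(
    list(n_rel_same = 2L, n_rel_cross = 0L, n_unrel_same = 2L,
         n_unrel_cross = 0L), a_rel = 3, a_unrel = 3, universe_size = 12)
  expect_equal(abstract_weight(tab)$w, 0)
})

test_that("doubling observed cells scales expected cells and T linearly", {
  o <- matrix(c(0.4, 0.1, 0.2, 0.3), 2, byrow = TRUE)
  mk <- function(o) {
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    structure(list(o = o, e = e, n = sum(o)), class = "contingency_table")
  }
  w1 <- abstract_weight(mk(o))
  w2 <- abstract_weight(mk(2 * o))
  expect_equal(mk(2 * o)$e, 2 * mk(o)$e)
  expect_equal(w2$t_related, 2 * w1$t_related)
  expect_equal(w2$w, 2 * w1$w)
})

test_that("corpus weight is the plain mean with absent abstracts as zero", {
  expect_equal(corpus_weight(c(0.2, 0, 0.4)), 0.2)
  expect_equal(corpus_weight(rep(0, 5)), 0)
  expect_error(corpus_weight(numeric()), "no associated abstracts")
})

test_that("pair counting tallies verdicts by flag and sentence origin", {
  v <- tibble::tibble(
    id_a = c("m1", "m1", "m1", "m2"), kind_a = "molecule",
    sentence_a = c(1L, 1L, 2L, 1L),
    id_b = "p", kind_b = "protein", sentence_b = c(1L, 2L, 3L, 1L),
    related = c(TRUE, TRUE, FALSE, FALSE),
    rule = c("SAME_CLAUSE", "CONNECTED_SENTENCES", "DEFAULT_UNRELATED",
             "PREP_MODIFIER_SPLIT"),
    same_sentence = c(TRUE, FALSE, FALSE, TRUE))
  counts <- count_pair(v, "p", "m1")
  expect_equal(counts$n_rel_same, 1L)
  expect_equal(counts$n_rel_cross, 1L)
  expect_equal(counts$n_unrel_cross, 1L)
  absent <- count_pair(v, "p", "m9")
  expect_true(all(absent[, -1] == 0L))
})

test_that("planted same-clause pairs are counted exactly", {
  # k related pairs built from plain sentences only (no pronouns in play)
  lex <- make_lexicon(c("P1", "M1", "M2", "M3"),
                      c("protein", rep("molecule", 3)),
                      names = c("ProtA", "molX", "molY", "molZ"))
  txt <- "ProtA binds molX and molY. ProtA binds molZ."
  v <- analyze_abstract(txt, lex, coref = FALSE)$verdicts
  counts <- count_pair(v, "P1")
  expect_equal(sum(counts$n_rel_same), 3L)
  expect_equal(sum(counts$n_rel_cross), 0L)
})

test_that("absent molecules get zero weight across the protein pipeline", {
  gen <- generate_corpus(synthetic_config(
    n_categories = 2, proteins_per_category = 2, abstracts_per_protein = 3,
    sentences_per_abstract = 3, seed = 5))
  p <- gen$annotations$protein[[1]]
  w <- abstract_weights(gen$corpus, gen$lexicon, p)
  # weights exist only for abstracts of this protein; molecules missing from
  # an abstract carry exactly zero
  mine <- gen$corpus$abstract_id[vapply(gen$corpus$proteins,
                                        function(x) p %in% x, logical(1))]
  expect_setequal(unique(w$abstract_id), mine)
  v <- corpus_verdicts(gen$corpus[gen$corpus$abstract_id %in% mine, ],
                       gen$lexicon)
  for (i in seq_len(nrow(w))) {
    cnt <- count_pair(v[[w$abstract_id[i]]], p, w$molecule[i])
    if (sum(cnt[, -1]) == 0L) expect_equal(w$weight[i], 0)
  }
})
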