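vec <- function(mols, wts, protein = NULL) {
  out <- tibble::tibble(molecule = mols, weight = wts)
  if (!is.null(protein)) out <- dplyr::mutate(out, protein = protein,
                                              .before = 1L)
  out
}

test_that("centered cosine similarity behaves like restricted correlation", {
  a <- vec(c("m1", "m2"), c(0.2, 0.8))
  expect_equal(similarity(a, a), 1)
  b <- vec(c("m1", "m2"), c(0.8, 0.2))
  expect_equal(similarity(a, b), -1)
  expect_equal(similarity(a, b), similarity(b, a))
  # random overlaps equal the brute-force Pearson correlation oracle
  set.seed(33)
  for (i in 1:30) {
    shared <- paste0("s", 1:5)
    x <- vec(c(shared, "only_x"), stats::runif(6))
    y <- vec(c("only_y", shared), stats::runif(6))
    xs <- x$weight[match(shared, x$molecule)]
    ys <- y$weight[match(shared, y$molecule)]
    expect_equal(similarity(x, y), stats::cor(xs, ys))
  }
})

test_that("incomparable vector pairs are reported as NA", {
  a <- vec(c("m1", "m2", "m3"), c(0.1, 0.4, 0.5))
  expect_true(is.na(similarity(a, vec("m1", 1))))          # 1 shared
  expect_true(is.na(similarity(a, vec(c("x", "y"), c(1, 2)))))  # 0 shared
  flat <- vec(c("m1", "m2"), c(0.5, 0.5))                  # zero variance
  expect_true(is.na(similarity(a, flat)))
})

test_that("the similar set applies threshold, cap and id tie-break", {
  train <- dplyr::bind_rows(
    vec(c("m1", "m2", "m3"), c(0.1, 0.4, 0.5), "pB"),
    vec(c("m1", "m2", "m3"), c(0.1, 0.4, 0.5), "pA"),
    vec(c("m1", "m2", "m3"), c(0.5, 0.4, 0.1), "pC"))
  q <- vec(c("m1", "m2", "m3"), c(0.1, 0.4, 0.5))
  s <- similar_set(q, train, prediction_config(sim_threshold = 0.5))
  expect_equal(s$protein, c("pA", "pB"))  # tie broken by id
  expect_equal(s$similarity, c(1, 1))
  none <- similar_set(q, train, prediction_config(sim_threshold = 1.1))
  expect_equal(nrow(none), 0L)
  capped <- similar_set(q, train, prediction_config(sim_threshold = -2,
                                                    top_k = 1))
  expect_equal(nrow(capped), 1L)
})

test_that("a planted cohort of same-profile proteins is recovered exactly", {
  set.seed(7)
  profile <- stats::runif(4)
  planted <- paste0("match", 1:3)
  train <- dplyr::bind_rows(
    purrr::map(planted, function(p) {
      vec(paste0("m", 1:4), profile + stats::rnorm(4, sd = 0.01), p)
    }),
    purrr::map(paste0("other", 1:3), function(p) {
      vec(paste0("m", 1:4), sample(profile), p)
    }))
  q <- vec(paste0("m", 1:4), profile)
  s <- similar_set(q, train, prediction_config(sim_threshold = 0.9))
  expect_setequal(s$protein, planted)
})

# small skewed annotation world: the FC1 protein "hub" occurs in every FC1
# abstract while ten FC2 background proteins occur in one abstract each, so
# hub's occurrence skew is strongly significant
skewed_world <- function() {
  corpus <- tibble::tibble(
    abstract_id = sprintf("a%02d", 1:15),
    text = c(rep("hub binds things.", 5), rep("background text.", 10)),
    proteins = c(rep(list("hub"), 5),
                 purrr::map(paste0("q", 1:10), identity)))
  ann <- tibble::tibble(protein = c("hub", paste0("q", 1:10)),
                        category = c("FC1", rep("FC2", 10)))
  lex <- make_lexicon(unique(ann$protein), rep("protein", 11))
  idx <- annotation_index(ann, corpus)
  occ <- protein_occurrences(corpus, lex, unique(ann$protein))
  list(corpus = corpus, ann = ann, lex = lex, idx = idx, occ = occ)
}

test_that("z-scores measure occurrence skew and vanish for balance", {
  w <- skewed_world()
  z_hub <- zscore("hub", "FC1", w$idx, w$occ)
  z_q <- zscore("q1", "FC1", w$idx, w$occ)
  expect_gt(z_hub, 0)
  expect_lt(z_q, 0)
  expect_gt(z_hub, z_q)
  # independent recomputation: numerator over population sd
  nums <- purrr::map_dbl(unique(w$ann$protein), function(p) {
    occ_p <- w$occ$abstract_id[w$occ$protein == p]
    length(intersect(occ_p, sprintf("a%02d", 1:5))) / 5 -
      length(intersect(occ_p, sprintf("a%02d", 6:15))) / 10
  })
  sigma <- sqrt(mean((nums - mean(nums))^2))
  expect_equal(z_hub, nums[1] / sigma)
  # direct arithmetic of the statistic: proportions 1 and 0 over sigma
  expect_equal(z_hub, 1 / sigma)
})

test_that("z-scores are invariant to uniform scaling of abstract counts", {
  w <- skewed_world()
  z1 <- zscore("hub", "FC1", w$idx, w$occ)
  doubled <- w$corpus
  copy <- dplyr::mutate(doubled, abstract_id = paste0(.data$abstract_id,
                                                      "_dup"))
  corpus2 <- dplyr::bind_rows(doubled, copy)
  idx2 <- annotation_index(w$ann, corpus2)
  occ2 <- protein_occurrences(corpus2, w$lex, unique(w$ann$protein))
  expect_equal(zscore("hub", "FC1", idx2, occ2), z1)
})

test_that("category assignment follows the configured significance rule", {
  w <- skewed_world()
  s_r <- tibble::tibble(protein = "hub", similarity = 1)
  cats <- assign_categories(s_r, w$idx, w$occ,
                            prediction_config(z_mode = "conventional"))
  expect_true(cats$assigned[cats$category == "FC1"])
  expect_false(cats$assigned[cats$category == "FC2"])
  expect_equal(cats$category[1], "FC1")
  expect_true(all(cats$confidence >= 0 & cats$confidence <= 1))
  # a protein present in every abstract has no skew: nothing is assigned
  bal_corpus <- dplyr::mutate(w$corpus,
                              proteins = purrr::map(.data$proteins, c,
                                                    "everywhere"))
  bal_ann <- dplyr::bind_rows(w$ann,
                              tibble::tibble(protein = "everywhere",
                                             category = "FC1"))
  idx_b <- annotation_index(bal_ann, bal_corpus)
  occ_b <- protein_occurrences(bal_corpus, w$lex, unique(bal_ann$protein))
  cats_b <- assign_categories(tibble::tibble(protein = "everywhere",
                                             similarity = 1),
                              idx_b, occ_b, prediction_config())
  expect_false(any(cats_b$assigned[cats_b$category == "FC1"]))
})

test_that("the literal mode assigns both categories matching half of S_r", {
  w <- skewed_world()
  s_r <- tibble::tibble(protein = c("hub", "q1"), similarity = c(1, 1))
  lit <- assign_categories(s_r, w$idx, w$occ,
                           prediction_config(z_mode = "literal"))
  expect_true(all(lit$assigned))
  conv <- assign_categories(s_r, w$idx, w$occ, prediction_config())
  expect_true(sum(conv$assigned) < sum(lit$assigned))
})

test_that("end-to-end prediction recovers the planted category", {
  gen <- generate_corpus(synthetic_config(
    n_categories = 2, proteins_per_category = 3, abstracts_per_protein = 3,
    sentences_per_abstract = 3, p_noise_pair = 0, seed = 21))
  verdicts <- corpus_verdicts(gen$corpus, gen$lexicon)
  held <- gen$annotations$protein[[1]]
  train <- setdiff(gen$annotations$protein, held)
  training <- protein_vectors(gen$corpus, gen$lexicon, train,
                              verdicts = verdicts)
  train_ann <- dplyr::filter(gen$annotations, .data$protein %in% train)
  train_abs <- gen$corpus[purrr::map_lgl(gen$corpus$proteins,
                                         function(x) any(x %in% train)), ]
  idx <- annotation_index(train_ann, train_abs)
  occ <- protein_occurrences(train_abs, gen$lexicon, train)
  q <- protein_vector(gen$corpus, gen$lexicon, held, verdicts = verdicts)
  pred <- predict_functions(q, training, idx, occ,
                            prediction_config(fallback_top_k = TRUE))
  expect_equal(tidy(pred)$category[1],
               gen$annotations$category[gen$annotations$protein == held])
  expect_equal(glance(pred)$protein, held)
  # an empty similar set aborts with the documented message
  expect_error(predict_functions(vec(c("zz1", "zz2"), c(0.3, 0.7)),
                                 training, idx, occ),
               "no similar annotated proteins")
})
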