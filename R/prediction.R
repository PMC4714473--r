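#' Prediction configuration
#'
#' @param sim_threshold Minimum centered-cosine similarity for membership in
#'   the similar set `S_r` (default 0.5).
#' @param top_k Cap on `|S_r|`, keeping the most similar proteins (ties
#'   broken by protein id; default 20).
#' @param z_mode `"conventional"` (default): a category is assigned when the
#'   aggregated member Z-score exceeds `z_threshold`; `"literal"`: it is
#'   assigned when the aggregate exceeds `-z_threshold` (the permissive
#'   reading of the significance direction, kept for fidelity experiments).
#' @param z_threshold Significance cut-off (default 1.96).
#' @param aggregate How member Z-scores are pooled per category: `"mean"`
#'   (default) or `"any"` (a single significant member suffices).
#' @param fallback_top_k When no training protein passes `sim_threshold`,
#'   fall back to the `top_k` most similar comparable proteins instead of
#'   aborting (default `FALSE`).
#' @return A list of class `prediction_config`.
#' @export
prediction_config <- function(sim_threshold = 0.5, top_k = 20,
                              z_mode = c("conventional", "literal"),
                              z_threshold = 1.96,
                              aggregate = c("mean", "any"),
                              fallback_top_k = FALSE) {
  structure(list(sim_threshold = sim_threshold, top_k = top_k,
                 z_mode = match.arg(z_mode), z_threshold = z_threshold,
                 aggregate = match.arg(aggregate),
                 fallback_top_k = fallback_top_k),
            class = "prediction_config")
}

#' Centered cosine similarity of two molecule weight vectors
#'
#' Computed over the shared molecules only, with both vectors centered by
#' their mean over the intersection — a Pearson correlation restricted to
#' the common support. Undefined (NA) when fewer than two molecules are
#' shared or either side has zero variance over them; such pairs are "not
#' comparable" and excluded from the similar set.
#'
#' @param v_query,v_train Weight vectors: tibbles with columns `molecule`
#'   and `weight` (extra columns ignored).
#' @return A value in `[-1, 1]`, or `NA` when not comparable.
#' @export
#' @examples
#' a <- tibble::tibble(molecule = c("m1", "m2"), weight = c(0.2, 0.8))
#' similarity(a, a)
similarity <- function(v_query, v_train) {
  shared <- intersect(v_query$molecule, v_train$molecule)
  if (length(shared) < 2L) return(NA_real_)
  x <- v_query$weight[match(shared, v_query$molecule)]
  y <- v_train$weight[match(shared, v_train$molecule)]
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sqrt(sum(dx^2))
  sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / (sx * sy)
}

#' Dominant-molecule vector of one protein
#'
#' Weighting, tournament and dominant-set selection chained for one
#' protein: the protein's representation for similarity matching.
#'
#' @param corpus Corpus tibble.
#' @param lexicon Entity lexicon.
#' @param protein Protein id.
#' @param config A [weighting_config()].
#' @param verdicts Optional precomputed [corpus_verdicts()] list.
#' @param words Closed word lists.
#' @return A tibble `protein`, `molecule`, `weight` (normalized tournament
#'   weights of the dominant molecules).
#' @export
protein_vector <- function(corpus, lexicon, protein,
                           config = weighting_config(), verdicts = NULL,
                           words = rule_words()) {
  w <- abstract_weights(corpus, lexicon, protein, config, verdicts, words)
  if (nrow(w) == 0L) {
    return(tibble(protein = character(), molecule = character(),
                  weight = double()))
  }
  dom <- dominance(w)
  keep <- filter(dom$scores, .data$dominant)
  tibble(protein = protein, molecule = keep$molecule, weight = keep$weight)
}

#' Dominant-molecule vectors of many proteins
#'
#' @param corpus Corpus tibble.
#' @param lexicon Entity lexicon.
#' @param proteins Character vector of protein ids.
#' @param config A [weighting_config()].
#' @param verdicts Optional precomputed [corpus_verdicts()] list.
#' @param words Closed word lists.
#' @return A tibble `protein`, `molecule`, `weight`; proteins without
#'   literature are skipped with a warning.
#' @export
protein_vectors <- function(corpus, lexicon, proteins,
                            config = weighting_config(), verdicts = NULL,
                            words = rule_words()) {
  if (is.null(verdicts)) verdicts <- corpus_verdicts(corpus, lexicon, words)
  rows <- map(proteins, function(p) {
    tryCatch(protein_vector(corpus, lexicon, p, config, verdicts, words),
             error = function(e) {
               warn(paste0("skipping ", p, ": ", conditionMessage(e)))
               NULL
             })
  })
  list_rbind(keep(rows, function(r) !is.null(r) && nrow(r) > 0L))
}

#' Similar set S_r of a query protein
#'
#' Training proteins whose dominant-molecule vectors are comparable to the
#' query's and at least `sim_threshold` similar, capped at the `top_k` most
#' similar (ties broken by protein id).
#'
#' @param query Query weight vector (`molecule`, `weight`).
#' @param training Training vectors tibble (`protein`, `molecule`,
#'   `weight`).
#' @param config A [prediction_config()].
#' @return A tibble `protein`, `similarity`, sorted by decreasing
#'   similarity; zero rows when nothing passes.
#' @export
similar_set <- function(query, training, config = prediction_config()) {
  prots <- unique(training$protein)
  sims <- map_dbl(prots, function(p) {
    similarity(query, filter(training, .data$protein == p))
  })
  out <- tibble(protein = prots, similarity = sims) |>
    filter(!is.na(.data$similarity)) |>
    arrange(desc(.data$similarity), .data$protein)
  hits <- filter(out, .data$similarity >= config$sim_threshold)
  if (nrow(hits) == 0L && config$fallback_top_k) hits <- out
  slice_head(hits, n = config$top_k)
}

#' Occurrence table of proteins in abstracts
#'
#' A protein occurs in an abstract when the abstract is associated with it
#' (its id is in the record's protein list) or its name or a synonym
#' appears in the text (case-insensitive, delimited by non-alphanumerics).
#'
#' @param corpus Corpus tibble.
#' @param lexicon Entity lexicon.
#' @param proteins Protein ids to look for.
#' @return A tibble `abstract_id`, `protein` with one row per occurrence.
#' @export
protein_occurrences <- function(corpus, lexicon, proteins) {
  prot_lex <- filter(lexicon, .data$kind == "protein",
                     .data$canonical_id %in% proteins)
  patterns <- map(setNames(prot_lex$canonical_id, prot_lex$canonical_id),
                  function(id) {
                    row <- prot_lex[prot_lex$canonical_id == id, ]
                    forms <- c(row$name, row$synonyms[[1]])
                    paste0("(?i)(?<![A-Za-z0-9])(",
                           paste(map_chr(forms, escape_regex),
                                 collapse = "|"),
                           ")(?![A-Za-z0-9])")
                  })
  rows <- map(proteins, function(p) {
    assoc <- map_lgl(corpus$proteins, function(ids) p %in% ids)
    mentioned <- if (p %in% names(patterns)) {
      stringr::str_detect(corpus$text, patterns[[p]])
    } else rep(FALSE, nrow(corpus))
    tibble(abstract_id = corpus$abstract_id[assoc | mentioned], protein = p)
  })
  list_rbind(rows)
}

escape_regex <- function(x) stringr::str_replace_all(x, "([\\W])", "\\\\\\1")

#' Z-score of a protein's occurrence skew toward one category
#'
#' `z = (N_FC / M_FC - N_FC' / M_FC') / sigma`, where `N_FC` counts the
#' category's abstracts containing occurrences of the protein, `M_FC` all of
#' the category's abstracts, the primed quantities the same over all other
#' categories, and `sigma` is the population standard deviation of the
#' numerator across all training proteins for the same category (making the
#' statistic unit-free).
#'
#' @param protein Protein id (a member of the similar set).
#' @param category Functional category id.
#' @param index Annotation index from [annotation_index()].
#' @param occurrences Occurrence table from [protein_occurrences()]; must
#'   cover all training proteins for the `sigma` population.
#' @return The Z-score, or `NA` when the category is degenerate
#'   (`M_FC = 0`, `M_FC' = 0`, or `sigma = 0`).
#' @export
zscore <- function(protein, category, index, occurrences) {
  d <- zscore_numerators(category, index, occurrences)
  if (is.null(d)) return(NA_real_)
  sigma <- pop_sd(d$numerator)
  if (is.na(sigma) || sigma == 0) {
    warn(paste0("zero-variance population for category ", category,
                "; skipped"))
    return(NA_real_)
  }
  val <- d$numerator[match(protein, d$protein)]
  if (is.na(val)) val <- raw_numerator(protein, category, index, occurrences)
  val / sigma
}

pop_sd <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

raw_numerator <- function(protein, category, index, occurrences) {
  cat_row <- index$categories[index$categories$category == category, ]
  abs_in <- cat_row$abstracts[[1]]
  other <- index$categories[index$categories$category != category, ]
  abs_out <- unique(unlist(other$abstracts))
  m_fc <- length(abs_in)
  m_fc2 <- length(abs_out)
  if (m_fc == 0L || m_fc2 == 0L) return(NA_real_)
  occ <- occurrences$abstract_id[occurrences$protein == protein]
  length(intersect(occ, abs_in)) / m_fc -
    length(intersect(occ, abs_out)) / m_fc2
}

zscore_numerators <- function(category, index, occurrences) {
  cat_row <- index$categories[index$categories$category == category, ]
  if (nrow(cat_row) == 0L) return(NULL)
  abs_in <- cat_row$abstracts[[1]]
  other <- index$categories[index$categories$category != category, ]
  abs_out <- unique(unlist(other$abstracts))
  if (length(abs_in) == 0L || length(abs_out) == 0L) return(NULL)
  prots <- unique(index$annotations$protein)
  nums <- map_dbl(prots, function(q) {
    occ <- occurrences$abstract_id[occurrences$protein == q]
    length(intersect(occ, abs_in)) / length(abs_in) -
      length(intersect(occ, abs_out)) / length(abs_out)
  })
  tibble(protein = prots, numerator = nums)
}

#' Assign functional categories from a similar set
#'
#' Scores every category by the Z-scores of the `S_r` members and assigns
#' those passing the configured significance rule. Confidences are the
#' min-max-normalized aggregated Z-scores across the scored categories.
#'
#' @param s_r Similar set tibble (`protein`, `similarity`).
#' @param index Annotation index from [annotation_index()].
#' @param occurrences Occurrence table covering the training proteins.
#' @param config A [prediction_config()].
#' @return A tibble `category`, `mean_z`, `n_supporting`, `assigned`,
#'   `confidence`, sorted by decreasing `mean_z`.
#' @export
assign_categories <- function(s_r, index, occurrences,
                              config = prediction_config()) {
  if (nrow(s_r) == 0L) abort("no similar annotated proteins")
  cats <- index$categories$category
  rows <- map(cats, function(fc) {
    d <- zscore_numerators(fc, index, occurrences)
    if (is.null(d)) return(NULL)
    sigma <- pop_sd(d$numerator)
    if (is.na(sigma) || sigma == 0) return(NULL)
    z <- d$numerator[match(s_r$protein, d$protein)] / sigma
    z <- z[!is.na(z)]
    if (length(z) == 0L) return(NULL)
    agg <- if (config$aggregate == "mean") mean(z) else max(z)
    tibble(category = fc, mean_z = agg, n_supporting = length(z))
  })
  out <- list_rbind(keep(rows, function(r) !is.null(r)))
  if (nrow(out) == 0L) {
    return(tibble(category = character(), mean_z = double(),
                  n_supporting = integer(), assigned = logical(),
                  confidence = double()))
  }
  cut <- if (config$z_mode == "conventional") config$z_threshold else {
    -config$z_threshold
  }
  rng <- range(out$mean_z)
  conf <- if (diff(rng) > 0) (out$mean_z - rng[1]) / diff(rng) else {
    rep(1, nrow(out))
  }
  mutate(out, assigned = .data$mean_z > cut, confidence = conf) |>
    arrange(desc(.data$mean_z), .data$category)
}

#' Predict the functional categories of an unannotated protein
#'
#' Chains similarity matching and Z-score category assignment: the query's
#' dominant-molecule vector (built from its reference abstracts) is matched
#' against the training vectors; categories are scored over the resulting
#' similar set.
#'
#' @param query Query weight vector (`molecule`, `weight`; a `protein`
#'   column, if present, names the query).
#' @param training Training vectors tibble (`protein`, `molecule`,
#'   `weight`).
#' @param index Annotation index from [annotation_index()].
#' @param occurrences Occurrence table from [protein_occurrences()].
#' @param config A [prediction_config()].
#' @return An object of class `litfun_prediction`: the similar set, the
#'   category score table and the assigned categories. [tidy()] returns the
#'   per-category table, [glance()] a one-row summary.
#' @export
predict_functions <- function(query, training, index, occurrences,
                              config = prediction_config()) {
  qid <- if ("protein" %in% names(query) && nrow(query) > 0L) {
    query$protein[[1]]
  } else NA_character_
  s_r <- similar_set(query, training, config)
  if (nrow(s_r) == 0L) abort("no similar annotated proteins")
  cats <- assign_categories(s_r, index, occurrences, config)
  structure(list(protein = qid, s_r = s_r, categories = cats,
                 assigned = cats$category[cats$assigned]),
            class = "litfun_prediction")
}

#' @export
print.litfun_prediction <- function(x, ...) {
  cat(sprintf("Function prediction for %s: |S_r| = %d, %d categories assigned\n",
              x$protein %||% "<query>", nrow(x$s_r), length(x$assigned)))
  print(x$categories)
  invisible(x)
}

#' @rdname predict_functions
#' @param x A `litfun_prediction` object.
#' @param ... Unused.
#' @method tidy litfun_prediction
#' @export
tidy.litfun_prediction <- function(x, ...) x$categories

#' @rdname predict_functions
#' @method glance litfun_prediction
#' @export
glance.litfun_prediction <- function(x, ...) {
  tibble(protein = x$protein, n_similar = nrow(x$s_r),
         n_scored = nrow(x$categories), n_assigned = length(x$assigned),
         top_category = if (nrow(x$categories) > 0L) {
           x$categories$category[[1]]
         } else NA_character_)
}
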