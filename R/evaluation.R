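#' Recall, precision and F-value for one protein
#'
#' `recall = c_p / n_p`, `precision = c_p / m_p`, F their harmonic mean,
#' with `c_p` the correctly predicted categories, `n_p` the true ones and
#' `m_p` the predicted ones. Precision is undefined when nothing was
#' predicted; disjoint sets give (0, 0, 0) by convention.
#'
#' @param predicted Character vector of predicted category ids.
#' @param truth Character vector of true category ids (non-empty).
#' @return A tibble `c_p`, `n_p`, `m_p`, `recall`, `precision`, `f`.
#' @export
#' @examples
#' prf(c("a", "b", "x"), c("a", "b", "c"))
prf <- function(predicted, truth) {
  predicted <- unique(predicted)
  truth <- unique(truth)
  if (length(truth) == 0L) {
    warn("protein has no true categories; skipped")
    return(tibble(c_p = NA_integer_, n_p = 0L, m_p = length(predicted),
                  recall = NA_real_, precision = NA_real_, f = NA_real_))
  }
  c_p <- length(intersect(predicted, truth))
  n_p <- length(truth)
  m_p <- length(predicted)
  recall <- c_p / n_p
  precision <- if (m_p > 0L) c_p / m_p else NA_real_
  f <- if (!is.na(precision) && recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else if (!is.na(precision)) 0 else NA_real_
  tibble(c_p = c_p, n_p = n_p, m_p = m_p, recall = recall,
         precision = precision, f = f)
}

#' Protein-centric precision-recall curve (CAFA style)
#'
#' At each threshold `t` in 0, 0.01, ..., 1, a protein's predictions are
#' the categories scored at confidence `>= t`. Precision at `t` is averaged
#' over the `m(t)` proteins with at least one prediction above the
#' threshold; recall is averaged over all `n` proteins (a protein without
#' predictions contributes zero recall). `pr(t)` is missing where
#' `m(t) = 0`.
#'
#' @param predictions Tibble `protein`, `category`, `confidence` (in
#'   `[0, 1]`).
#' @param truth Tibble `protein`, `category` of experimentally determined
#'   categories.
#' @return A tibble of class `litfun_pr_curve`: `t`, `pr`, `rc`, `m`, `n`.
#' @export
cafa_curve <- function(predictions, truth) {
  stopifnot(all(c("protein", "category", "confidence") %in%
                  names(predictions)))
  if (nrow(predictions) > 0L &&
      (min(predictions$confidence) < 0 || max(predictions$confidence) > 1)) {
    abort("confidences must lie in [0, 1]")
  }
  prots <- unique(truth$protein)
  n <- length(prots)
  if (n == 0L) abort("truth table is empty")
  ts <- seq(0, 1, by = 0.01)
  rows <- map(ts, function(t) {
    pr_i <- double()
    rc_i <- double(n)
    m <- 0L
    for (k in seq_len(n)) {
      p <- prots[k]
      ti <- truth$category[truth$protein == p]
      pi <- predictions$category[predictions$protein == p &
                                   predictions$confidence >= t]
      hits <- length(intersect(pi, ti))
      rc_i[k] <- if (length(ti) > 0L) hits / length(ti) else 0
      if (length(pi) > 0L) {
        m <- m + 1L
        pr_i <- c(pr_i, hits / length(pi))
      }
    }
    tibble(t = t, pr = if (m > 0L) mean(pr_i) else NA_real_,
           rc = mean(rc_i), m = m, n = n)
  })
  out <- list_rbind(rows)
  class(out) <- c("litfun_pr_curve", class(out))
  out
}

# shared harness: train on train_proteins, predict each test protein
evaluate_split <- function(corpus, lexicon, annotations, train_proteins,
                           test_proteins, weighting = weighting_config(),
                           prediction = prediction_config(),
                           verdicts = NULL, words = rule_words()) {
  if (is.null(verdicts)) verdicts <- corpus_verdicts(corpus, lexicon, words)
  train_ann <- filter(annotations, .data$protein %in% train_proteins)
  train_abs <- corpus[map_lgl(corpus$proteins, function(ids) {
    any(ids %in% train_proteins)
  }), ]
  index <- annotation_index(train_ann, train_abs)
  occ <- protein_occurrences(train_abs, lexicon,
                             unique(train_ann$protein))
  training <- protein_vectors(corpus, lexicon, train_proteins, weighting,
                              verdicts, words)
  rows <- map(test_proteins, function(p) {
    truth <- annotations$category[annotations$protein == p]
    res <- tryCatch({
      q <- protein_vector(corpus, lexicon, p, weighting, verdicts, words)
      predict_functions(q, training, index, occ, prediction)
    }, error = function(e) NULL)
    if (is.null(res)) {
      metrics <- prf(character(), truth)
      return(mutate(metrics, protein = p, .before = 1L) |>
               mutate(predictions = list(
                 tibble(category = character(), confidence = double(),
                        assigned = logical(), mean_z = double()))))
    }
    metrics <- prf(res$assigned, truth)
    mutate(metrics, protein = p, .before = 1L) |>
      mutate(predictions = list(select(res$categories, "category",
                                       "confidence", "assigned", "mean_z")))
  })
  list_rbind(rows)
}

#' K-fold cross-validation of the prediction pipeline
#'
#' Proteins are partitioned into `k` disjoint random folds; each fold is
#' predicted with the other folds as training. Mean recall, precision and F
#' are reported per fold and overall.
#'
#' @param corpus Corpus tibble.
#' @param lexicon Entity lexicon.
#' @param annotations Annotation tibble.
#' @param k Number of folds (default 5).
#' @param seed Integer seed making the partition reproducible.
#' @param weighting,prediction Configurations.
#' @param verdicts Optional precomputed [corpus_verdicts()] list.
#' @param words Closed word lists.
#' @return A list with `folds` (tibble `protein`, `fold`), `per_protein`
#'   (metrics and prediction list-column) and `summary` (per-fold mean
#'   R/P/F plus an `overall` row).
#' @export
kfold <- function(corpus, lexicon, annotations, k = 5, seed = 1,
                  weighting = weighting_config(),
                  prediction = prediction_config(), verdicts = NULL,
                  words = rule_words()) {
  prots <- sort(unique(annotations$protein))
  if (length(prots) < k) abort("fewer proteins than folds")
  if (k < 2) abort("k must be at least 2")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), length(prots)))
  folds <- tibble(protein = prots, fold = fold)
  if (is.null(verdicts)) verdicts <- corpus_verdicts(corpus, lexicon, words)
  per <- map(seq_len(k), function(i) {
    test <- folds$protein[folds$fold == i]
    train <- folds$protein[folds$fold != i]
    evaluate_split(corpus, lexicon, annotations, train, test, weighting,
                   prediction, verdicts, words) |>
      mutate(fold = i)
  }) |> list_rbind()
  by_fold <- per |>
    group_by(.data$fold) |>
    summarise(recall = mean(.data$recall, na.rm = TRUE),
              precision = mean(.data$precision, na.rm = TRUE),
              f = mean(.data$f, na.rm = TRUE), n = dplyr::n(),
              .groups = "drop")
  overall <- summarise(per, fold = NA_integer_,
                       recall = mean(.data$recall, na.rm = TRUE),
                       precision = mean(.data$precision, na.rm = TRUE),
                       f = mean(.data$f, na.rm = TRUE), n = dplyr::n())
  list(folds = folds, per_protein = per,
       summary = bind_rows(by_fold, overall))
}

#' Cumulative validation with a growing training set
#'
#' Runs a schedule of test batches: after each run the tested proteins (with
#' their abstracts) join the training pool, dominant-molecule vectors and
#' category abstract counts are rebuilt, and the next batch is predicted.
#' Mirrors the accumulating-training-set protocol under which prediction
#' quality should not degrade as annotation grows.
#'
#' @param corpus Corpus tibble.
#' @param lexicon Entity lexicon.
#' @param annotations Annotation tibble.
#' @param schedule Integer vector of per-run test-batch sizes.
#' @param seed Integer seed for the protein shuffle.
#' @param weighting,prediction Configurations.
#' @param verdicts Optional precomputed [corpus_verdicts()] list.
#' @param words Closed word lists.
#' @return A tibble with one row per run: `run`, `n_train`, `n_test`,
#'   `recall`, `precision`, `f`; an empty schedule yields zero rows.
#' @export
cumulative_runs <- function(corpus, lexicon, annotations, schedule, seed = 1,
                            weighting = weighting_config(),
                            prediction = prediction_config(),
                            verdicts = NULL, words = rule_words()) {
  if (length(schedule) == 0L) {
    return(tibble(run = integer(), n_train = integer(), n_test = integer(),
                  recall = double(), precision = double(), f = double()))
  }
  prots <- sort(unique(annotations$protein))
  set.seed(seed)
  shuffled <- sample(prots)
  need <- sum(schedule)
  if (need > length(prots)) {
    warn("schedule exhausts the protein set; stopping early")
    schedule <- schedule[cumsum(schedule) <= length(prots)]
    need <- sum(schedule)
  }
  test_pool <- shuffled[seq_len(need)]
  train <- setdiff(shuffled, test_pool)
  if (length(train) == 0L) abort("schedule leaves no training proteins")
  if (is.null(verdicts)) verdicts <- corpus_verdicts(corpus, lexicon, words)
  out <- list()
  offset <- 0L
  for (r in seq_along(schedule)) {
    batch <- test_pool[seq(offset + 1L, offset + schedule[r])]
    offset <- offset + schedule[r]
    per <- evaluate_split(corpus, lexicon, annotations, train, batch,
                          weighting, prediction, verdicts, words)
    out[[r]] <- tibble(run = r, n_train = length(train),
                       n_test = length(batch),
                       recall = mean(per$recall, na.rm = TRUE),
                       precision = mean(per$precision, na.rm = TRUE),
                       f = mean(per$f, na.rm = TRUE))
    train <- c(train, batch)
  }
  list_rbind(out)
}

#' Write per-run or per-fold metrics as TSV
#'
#' @param metrics A metrics tibble (e.g. `summary` from [kfold()] or the
#'   result of [cumulative_runs()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  readr::write_tsv(metrics, path, progress = FALSE)
  invisible(path)
}
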