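#' Pairwise beat counts of two molecules
#'
#' Per-abstract strict comparison of the two molecules' weights:
#' `wins + losses + ties` equals the number of abstracts. Comparing a
#' molecule with itself yields all ties.
#'
#' @param weights Long weight tibble (`molecule`, `abstract_id`, `weight`).
#' @param m_i,m_j Molecule ids present in the table.
#' @return A named list `wins`, `losses`, `ties` (from `m_i`'s viewpoint).
#' @export
beat_counts <- function(weights, m_i, m_j) {
  wide <- weight_matrix(weights)
  if (!all(c(m_i, m_j) %in% names(wide))) {
    abort("both molecules must be present in the weight table")
  }
  wi <- wide[[m_i]]
  wj <- wide[[m_j]]
  if (m_i == m_j) return(list(wins = 0L, losses = 0L, ties = length(wi)))
  list(wins = sum(wi > wj), losses = sum(wj > wi), ties = sum(wi == wj))
}

#' Beats/looses tournament scores
#'
#' Molecule `m_i` dominates `m_j` when it wins strictly more per-abstract
#' weight comparisons than it loses; a tie in wins and losses leaves neither
#' dominating. The score is the number of molecules dominated minus the
#' number dominating, so scores are bounded by `+/-(n - 1)` and sum to zero.
#'
#' @param weights Long weight tibble (`molecule`, `abstract_id`, `weight`).
#' @return A tibble `molecule`, `score`, in molecule order of appearance.
#' @export
tournament_scores <- function(weights) {
  wide <- weight_matrix(weights)
  mols <- setdiff(names(wide), "abstract_id")
  W <- as.matrix(wide[, mols, drop = FALSE])
  n <- length(mols)
  score <- integer(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        wins <- sum(W[, i] > W[, j])
        losses <- sum(W[, j] > W[, i])
        if (wins > losses) {
          score[i] <- score[i] + 1L
          score[j] <- score[j] - 1L
        } else if (losses > wins) {
          score[i] <- score[i] - 1L
          score[j] <- score[j] + 1L
        }
      }
    }
  }
  tibble(molecule = mols, score = score)
}

#' Normalize tournament scores into weights
#'
#' Shifts every score by the magnitude of the most negative score and
#' divides by the sum of shifted scores. When all shifted scores are zero
#' the normalized weights are all zero.
#'
#' @param scores Tibble `molecule`, `score` from [tournament_scores()], or a
#'   named/plain numeric vector of scores.
#' @return A tibble `molecule`, `score`, `shifted`, `weight`.
#' @export
normalize_scores <- function(scores) {
  if (is.numeric(scores)) {
    scores <- tibble(
      molecule = names(scores) %||% paste0("m", seq_along(scores)),
      score = as.numeric(scores))
  }
  shifted <- scores$score + abs(min(scores$score))
  total <- sum(shifted)
  weight <- if (total > 0) shifted / total else rep(0, length(shifted))
  mutate(scores, shifted = shifted, weight = weight)
}

#' Dominance threshold beta
#'
#' `beta = (1 - sqrt(sum_j (w_j - 1/n)^2)) / n`: the mean normalized weight
#' lowered by the root sum of squared deviations from it, so
#' `beta <= 1/n` always, with equality for a uniform weight vector.
#'
#' @param weight Numeric vector of normalized weights.
#' @return The threshold.
#' @export
beta_threshold <- function(weight) {
  n <- length(weight)
  stopifnot(n >= 1L)
  (1 - sqrt(sum((weight - 1 / n)^2))) / n
}

#' Dominant molecule set
#'
#' Molecules whose normalized weight strictly exceeds `beta`. The threshold
#' totally orders membership: every member's weight is at least every
#' non-member's. An empty set is allowed (flagged with a warning). A lone
#' molecule with positive weight is kept: with nothing to dominate it is
#' trivially the maximal-weight set, even though `beta` equals its weight.
#'
#' @param normalized Tibble from [normalize_scores()].
#' @param beta Threshold from [beta_threshold()]; computed when `NULL`.
#' @return The rows of `normalized` for the dominant molecules.
#' @export
dominant_set <- function(normalized, beta = NULL) {
  if (is.null(beta)) beta <- beta_threshold(normalized$weight)
  if (nrow(normalized) == 1L && normalized$weight[1] > 0) {
    return(normalized)
  }
  out <- filter(normalized, .data$weight > beta)
  if (nrow(out) == 0L) warn("dominant set is empty")
  out
}

#' Run the full dominance tournament for one weight table
#'
#' @param weights Long weight tibble (`molecule`, `abstract_id`, `weight`),
#'   e.g. from [abstract_weights()].
#' @return An object of class `litfun_dominance` with the per-molecule score
#'   table, `beta`, and the dominant set. Use [tidy()] for the per-molecule
#'   table and [glance()] for the one-row summary.
#' @export
#' @examples
#' w <- tidyr::expand_grid(molecule = c("m1", "m2"), abstract_id = c("a", "b"))
#' w$weight <- c(0.4, 0.1, 0.2, 0.3)
#' dominance(w)
dominance <- function(weights) {
  scores <- normalize_scores(tournament_scores(weights))
  beta <- beta_threshold(scores$weight)
  scores <- mutate(scores, dominant = .data$weight > beta |
                     (nrow(scores) == 1L & .data$weight > 0))
  structure(
    list(scores = scores, beta = beta,
         n_molecules = nrow(scores),
         n_abstracts = length(unique(weights$abstract_id))),
    class = "litfun_dominance")
}

#' @export
print.litfun_dominance <- function(x, ...) {
  cat(sprintf(
    "Dominance tournament: %d molecules over %d abstracts (beta = %.4f)\n",
    x$n_molecules, x$n_abstracts, x$beta))
  print(x$scores)
  invisible(x)
}

#' @rdname dominance
#' @param x A `litfun_dominance` object.
#' @param ... Unused.
#' @method tidy litfun_dominance
#' @export
tidy.litfun_dominance <- function(x, ...) x$scores

#' @rdname dominance
#' @method glance litfun_dominance
#' @export
glance.litfun_dominance <- function(x, ...) {
  tibble(n_molecules = x$n_molecules, n_abstracts = x$n_abstracts,
         beta = x$beta, n_dominant = sum(x$scores$dominant))
}

#' Write a dominance report as TSV
#'
#' Columns: molecule, score, shifted score, normalized weight, dominant
#' flag.
#'
#' @param x A `litfun_dominance` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dominance <- function(x, path) {
  readr::write_tsv(x$scores, path, progress = FALSE)
  invisible(path)
}
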