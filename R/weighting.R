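#' Weighting configuration
#'
#' Controls how relatedness verdicts are turned into per-abstract
#' association weights. The frequency multiplier `f` has three variants:
#' `note1`, `c + (1 - c) n / max|n|`, emphasising the first appearances of a
#' pair; `note2` (default), `1 + log(n)`, giving diminishing returns as the
#' pair's frequency grows; `note3`, `1 / A`, a global rarity measure. The
#' abstract multiplier `f_A` has variants `note4` (default),
#' `log(1 + |A| / A)`, damping the advantage of pairs seen in a single
#' abstract; `note4_block`, the reciprocal form `log(1 + A / |A|)`; and
#' `note5`, `log(1 + max|n| / A)`, which disregards abstracts not containing
#' the pair. `A` is the number of abstracts containing the pair in the given
#' channel, `|A|` the abstract universe.
#'
#' @param f_variant One of `"note1"`, `"note2"`, `"note3"`.
#' @param fa_variant One of `"note4"`, `"note4_block"`, `"note5"`.
#' @param c Constant in (0, 1) balancing first and later appearances
#'   (`note1` only).
#' @param log_base Base of all logarithms, 10 (default) or `exp(1)`.
#' @param universe `"per-protein"` (default): `|A|` counts the abstracts
#'   associated with the protein; `"whole-corpus"`: all corpus records.
#' @return A list of class `weighting_config`.
#' @export
weighting_config <- function(f_variant = c("note2", "note1", "note3"),
                             fa_variant = c("note4", "note4_block", "note5"),
                             c = 0.5, log_base = 10,
                             universe = c("per-protein", "whole-corpus")) {
  f_variant <- match.arg(f_variant)
  fa_variant <- match.arg(fa_variant)
  universe <- match.arg(universe)
  if (!is.numeric(c) || length(c) != 1L || c <= 0 || c >= 1) {
    abort("c must lie strictly between 0 and 1")
  }
  structure(list(f_variant = f_variant, fa_variant = fa_variant, c = c,
                 log_base = log_base, universe = universe),
            class = "weighting_config")
}

#' Frequency multiplier f for one co-occurrence channel
#'
#' @param n Co-occurrence count of the pair in the abstract (one channel:
#'   related or unrelated; one column: same- or cross-sentence).
#' @param config A [weighting_config()].
#' @param max_n Maximum of the pair's channel count over the abstracts
#'   (used by `note1`).
#' @param a_mp Number of abstracts containing the pair in this channel
#'   (used by `note3`).
#' @return The multiplier; 0 when `n = 0` (and for `note3` when `a_mp = 0`).
#' @export
frequency_multiplier <- function(n, config = weighting_config(),
                                 max_n = NULL, a_mp = NULL) {
  if (n <= 0) return(0)
  switch(config$f_variant,
         note1 = {
           if (is.null(max_n) || max_n <= 0) abort("note1 needs max_n > 0")
           config$c + (1 - config$c) * n / max_n
         },
         note2 = 1 + log(n, base = config$log_base),
         note3 = {
           if (is.null(a_mp) || a_mp <= 0) return(0)
           1 / a_mp
         })
}

#' Abstract-frequency multiplier f_A for one channel
#'
#' @param a_mp Number of abstracts containing the pair in this channel.
#' @param config A [weighting_config()].
#' @param universe_size `|A|`, the abstract universe size (`note4` forms).
#' @param max_n Maximum channel count over abstracts (`note5`).
#' @return The multiplier; 0 when `a_mp = 0`.
#' @export
abstract_frequency_multiplier <- function(a_mp, config = weighting_config(),
                                          universe_size = NULL,
                                          max_n = NULL) {
  if (a_mp <= 0) return(0)
  switch(config$fa_variant,
         note4 = {
           if (is.null(universe_size)) abort("note4 needs universe_size")
           log(1 + universe_size / a_mp, base = config$log_base)
         },
         note4_block = {
           if (is.null(universe_size)) abort("note4_block needs universe_size")
           log(1 + a_mp / universe_size, base = config$log_base)
         },
         note5 = {
           if (is.null(max_n)) abort("note5 needs max_n")
           log(1 + max_n / a_mp, base = config$log_base)
         })
}

#' Tally a pair's verdicts in one abstract
#'
#' @param verdicts Verdict tibble for one abstract (see
#'   [analyze_abstract()]).
#' @param protein Protein-of-interest id. Every other entity co-occurring
#'   with it — molecule or protein — counts as a candidate molecule.
#' @param molecule Optional molecule id; when `NULL`, counts for all
#'   co-occurring entities are returned.
#' @return A tibble with columns `molecule`, `n_rel_same`, `n_rel_cross`,
#'   `n_unrel_same`, `n_unrel_cross`.
#' @export
count_pair <- function(verdicts, protein, molecule = NULL) {
  empty <- tibble(molecule = character(), n_rel_same = integer(),
                  n_rel_cross = integer(), n_unrel_same = integer(),
                  n_unrel_cross = integer())
  if (nrow(verdicts) == 0L) {
    if (is.null(molecule)) return(empty)
    return(mutate(empty[0, ], molecule = molecule)[0, ] |>
             bind_rows(tibble(molecule = molecule, n_rel_same = 0L,
                              n_rel_cross = 0L, n_unrel_same = 0L,
                              n_unrel_cross = 0L)))
  }
  v <- filter(verdicts, .data$id_a == protein | .data$id_b == protein)
  v <- mutate(v, molecule = if_else(.data$id_a == protein, .data$id_b,
                                    .data$id_a))
  if (!is.null(molecule)) {
    mol <- molecule
    v <- filter(v, .data$molecule == mol)
  }
  counts <- v |>
    group_by(.data$molecule) |>
    summarise(
      n_rel_same = sum(.data$related & .data$same_sentence),
      n_rel_cross = sum(.data$related & !.data$same_sentence),
      n_unrel_same = sum(!.data$related & .data$same_sentence),
      n_unrel_cross = sum(!.data$related & !.data$same_sentence),
      .groups = "drop")
  if (!is.null(molecule) && nrow(counts) == 0L) {
    counts <- tibble(molecule = molecule, n_rel_same = 0L, n_rel_cross = 0L,
                     n_unrel_same = 0L, n_unrel_cross = 0L)
  }
  counts
}

#' Build the 2x2 observed/expected contingency table for a pair
#'
#' Row 1 holds the semantically related channel, row 2 the unrelated
#' channel; column 1 holds same-sentence co-occurrences, column 2
#' cross-sentence (connector-linked) ones. Each observed cell is
#' `f x f_A` (equation-3 style); expected cells are `e_xy = R_x C_y / N`.
#' An all-zero count vector yields an all-zero table.
#'
#' @param counts One-row count tibble from [count_pair()] (or a named list
#'   with the four `n_*` fields).
#' @param a_rel,a_unrel Numbers of abstracts with at least one related
#'   (resp. unrelated) co-occurrence of the pair.
#' @param universe_size `|A|`.
#' @param max_n_rel,max_n_unrel Per-channel maxima of the pair's counts over
#'   abstracts.
#' @param config A [weighting_config()].
#' @return A list of class `contingency_table` with matrices `o` and `e`.
#' @export
build_contingency <- function(counts, a_rel, a_unrel, universe_size,
                              max_n_rel = NULL, max_n_unrel = NULL,
                              config = weighting_config()) {
  fa_rel <- abstract_frequency_multiplier(a_rel, config, universe_size,
                                          max_n_rel)
  fa_unrel <- abstract_frequency_multiplier(a_unrel, config, universe_size,
                                            max_n_unrel)
  f_of <- function(n, max_n, a) frequency_multiplier(n, config, max_n, a)
  o <- matrix(c(
    f_of(counts$n_rel_same, max_n_rel, a_rel) * fa_rel,
    f_of(counts$n_rel_cross, max_n_rel, a_rel) * fa_rel,
    f_of(counts$n_unrel_same, max_n_unrel, a_unrel) * fa_unrel,
    f_of(counts$n_unrel_cross, max_n_unrel, a_unrel) * fa_unrel),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("related", "unrelated"), c("same", "cross")))
  N <- sum(o)
  e <- if (N > 0) outer(rowSums(o), colSums(o)) / N else o * 0
  structure(list(o = o, e = e, n = N), class = "contingency_table")
}

#' Per-abstract association weight of a molecule-protein pair
#'
#' `T` is the normalized sum of squared deviations of the related row from
#' its expected cells, `T'` the same for the unrelated row; the weight is
#' `T - T'`. Cells with zero expected frequency contribute nothing (limit
#' convention). A pair absent from the abstract has weight 0.
#'
#' @param table A `contingency_table` from [build_contingency()].
#' @return A list with `t_related`, `t_unrelated`, `w`.
#' @export
abstract_weight <- function(table) {
  chi_row <- function(o, e) {
    ok <- e > 0
    if (!any(ok)) return(0)
    sum((o[ok] - e[ok])^2 / e[ok])
  }
  t1 <- chi_row(table$o[1, ], table$e[1, ])
  t2 <- chi_row(table$o[2, ], table$e[2, ])
  list(t_related = t1, t_unrelated = t2, w = t1 - t2)
}

#' Corpus-level weight of a pair
#'
#' Arithmetic mean of the per-abstract weights over all `|A|` abstracts
#' associated with the protein; abstracts where the molecule is absent
#' contribute zero.
#'
#' @param weights Numeric vector of per-abstract weights, one per abstract
#'   in the protein's universe.
#' @return The mean weight.
#' @export
corpus_weight <- function(weights) {
  if (length(weights) == 0L) abort("protein has no associated abstracts")
  mean(weights)
}

#' Clause-analyse every abstract of a corpus once
#'
#' @param corpus Corpus tibble.
#' @param lexicon Entity lexicon.
#' @param words Closed word lists.
#' @param coref Resolve surface coreference? Default `TRUE`.
#' @return A named list of verdict tibbles, one per `abstract_id`.
#' @export
corpus_verdicts <- function(corpus, lexicon, words = rule_words(),
                            coref = TRUE) {
  forms <- lexicon_forms(lexicon)
  out <- map(corpus$text,
             function(tx) {
               analyze_abstract(tx, lexicon, words, coref, forms)$verdicts
             })
  setNames(out, corpus$abstract_id)
}

#' Per-abstract weight table of one protein
#'
#' Runs counts, contingency and Eq.-style weighting for every entity
#' co-occurring with the protein across its abstract universe.
#'
#' @param corpus Corpus tibble.
#' @param lexicon Entity lexicon.
#' @param protein Protein id.
#' @param config A [weighting_config()].
#' @param verdicts Optional precomputed [corpus_verdicts()] list.
#' @param words Closed word lists.
#' @return A tibble `molecule`, `abstract_id`, `weight` covering the full
#'   molecule x abstract grid (absent pairs have weight 0).
#' @export
abstract_weights <- function(corpus, lexicon, protein,
                             config = weighting_config(), verdicts = NULL,
                             words = rule_words()) {
  mine <- corpus[map_lgl(corpus$proteins, function(p) protein %in% p), ]
  universe <- if (config$universe == "per-protein") mine else corpus
  if (nrow(mine) == 0L) {
    abort(paste0("protein has no associated abstracts: ", protein))
  }
  if (is.null(verdicts)) verdicts <- corpus_verdicts(mine, lexicon, words)
  counts <- imap(setNames(mine$text, mine$abstract_id), function(tx, id) {
    mutate(count_pair(verdicts[[id]], protein), abstract_id = id)
  }) |> list_rbind()
  if (nrow(counts) == 0L) {
    return(tibble(molecule = character(), abstract_id = character(),
                  weight = double()))
  }
  grid <- tidyr::expand_grid(molecule = unique(counts$molecule),
                             abstract_id = mine$abstract_id)
  counts <- left_join(grid, counts, by = c("molecule", "abstract_id")) |>
    mutate(dplyr::across(dplyr::starts_with("n_"),
                         function(x) tidyr::replace_na(x, 0L)))
  stats <- counts |>
    group_by(.data$molecule) |>
    summarise(
      a_rel = sum(.data$n_rel_same + .data$n_rel_cross > 0L),
      a_unrel = sum(.data$n_unrel_same + .data$n_unrel_cross > 0L),
      max_n_rel = max(.data$n_rel_same + .data$n_rel_cross),
      max_n_unrel = max(.data$n_unrel_same + .data$n_unrel_cross),
      .groups = "drop")
  counts <- left_join(counts, stats, by = "molecule")
  usize <- nrow(universe)
  counts$weight <- pmap(
    list(counts$n_rel_same, counts$n_rel_cross, counts$n_unrel_same,
         counts$n_unrel_cross, counts$a_rel, counts$a_unrel,
         counts$max_n_rel, counts$max_n_unrel),
    function(nrs, nrc, nus, nuc, ar, au, mr, mu) {
      if (nrs + nrc + nus + nuc == 0L) return(0)
      tab <- build_contingency(
        list(n_rel_same = nrs, n_rel_cross = nrc, n_unrel_same = nus,
             n_unrel_cross = nuc),
        a_rel = ar, a_unrel = au, universe_size = usize,
        max_n_rel = mr, max_n_unrel = mu, config = config)
      abstract_weight(tab)$w
    }) |> unlist()
  select(counts, "molecule", "abstract_id", "weight")
}

#' Wide molecule-by-abstract weight matrix
#'
#' @param weights Long weight tibble from [abstract_weights()] (or any
#'   tibble with `molecule`, `abstract_id`, `weight`).
#' @return A tibble with one row per abstract and one column per molecule,
#'   mirroring the conventional printed layout.
#' @export
weight_matrix <- function(weights) {
  tidyr::pivot_wider(weights, names_from = "molecule",
                     values_from = "weight", values_fill = 0) |>
    arrange(.data$abstract_id)
}

#' Write a weight matrix as TSV
#'
#' @param weights Long weight tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weight_matrix <- function(weights, path) {
  readr::write_tsv(weight_matrix(weights), path, progress = FALSE)
  invisible(path)
}
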