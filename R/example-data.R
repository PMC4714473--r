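# Bundled worked example: the Pseudomonas aeruginosa protein PA1535 and the
# 10 molecules co-occurring with it across its 12 UniProtKB-referenced
# abstracts. Shipped as code so the tournament and weighting operations can
# be exercised (and the tournament reproduced) without any text processing.

pa1535_molecules <- c(
  "AtuD", "citronellyl-CoA", "octanoyl-CoA", "terpenoid-CoA",
  "isovaleryl-CoA", "Docosenoyl-CoA", "OPC4-CoA", "Sirodesmin H",
  "OPC8-CoA", "3-dipole")

#' Worked-example weight table for protein PA1535
#'
#' Per-abstract association weights of 10 molecules with the Pseudomonas
#' aeruginosa protein PA1535 over its 12 associated abstracts — the
#' classical worked example for the beats/looses tournament.
#'
#' @return A long weight tibble (`molecule`, `abstract_id`, `weight`)
#'   suitable for [dominance()].
#' @export
#' @examples
#' dominance(pa1535_weight_table())
pa1535_weight_table <- function() {
  w <- matrix(c(
    0.020, 0.017, 0.012, 0.008, 0.003, 0,     0,     0,     0,     0,
    0.060, 0,     0,     0,     0.778, 0,     0.060, 0.270, 0.060, 0,
    0,     0.060, 0.778, 0.060, 0,     0,     0,     0.060, 0,     0.088,
    0.060, 0.060, 0.118, 0,     0,     0.270, 0,     0,     0.088, 0,
    0.060, 0,     0,     0,     0.778, 0,     0.060, 0.270, 0.060, 0,
    0,     0.652, 0,     0.055, 0.121, 0,     0.004, 0,     0,     0.058,
    0.493, 0.116, 0,     0.008, 0.072, 0.002, 0,     0.603, 0,     0,
    0,     0,     0.387, 0.184, 0,     0,     0.035, 0,     0.004, 0.002,
    0,     0.002, 0.0548, 0,    0.735, 0.017, 0,     0.357, 0,     0.085,
    0.664, 0.183, 0,     0.006, 0,     0,     0.736, 0,     0.002, 0.006,
    0.068, 0.389, 0.216, 0.003, 0,     0.047, 0.009, 0,     0,     0.364,
    0.213, 0,     0.735, 0,     0.043, 0.003, 0,     0.007, 0,     0),
    nrow = 12, byrow = TRUE,
    dimnames = list(sprintf("A%02d", 1:12), pa1535_molecules))
  as_tibble(w, rownames = "abstract_id") |>
    tidyr::pivot_longer(-"abstract_id", names_to = "molecule",
                        values_to = "weight") |>
    select("molecule", "abstract_id", "weight")
}

#' Worked-example single-abstract pair statistics for PA1535
#'
#' Per-molecule co-occurrence statistics of the same 10 molecules with
#' PA1535 in one abstract (the acyclic-terpene-utilization study): related
#' and unrelated co-occurrence counts `n`, abstract counts `A`, and the
#' reported `T`, `T'` chi-square-style components from which the
#' per-abstract weight is `T - T'`.
#'
#' @return A tibble with columns `molecule`, `n_related`, `n_unrelated`,
#'   `a_related`, `a_unrelated`, `f_related`, `f_unrelated`, `t_related`,
#'   `t_unrelated`, `w`.
#' @export
pa1535_abstract_stats <- function() {
  tibble(
    molecule = pa1535_molecules,
    n_related   = c(4L, 2L, 2L, 1L, 1L, 0L, 0L, 0L, 0L, 0L),
    n_unrelated = c(3L, 2L, 1L, 1L, 2L, 0L, 0L, 0L, 0L, 0L),
    a_related   = c(11L, 12L, 10L, 10L, 2L, 9L, 11L, 5L, 7L, 4L),
    a_unrelated = c(9L, 8L, 9L, 8L, 6L, 7L, 6L, 8L, 3L, 2L),
    f_related   = c(1.6, 1.3, 1.3, 1, 1, 0, 0, 0, 0, 0),
    f_unrelated = c(1.5, 1.3, 1, 1, 1.3, 0, 0, 0, 0, 0),
    t_related   = c(0.069, 0.116, 0.115, 0.009, 0.005, 0, 0, 0, 0, 0),
    t_unrelated = c(0.049, 0.099, 0.103, 0.001, 0.002, 0, 0, 0, 0, 0),
    w           = c(0.020, 0.017, 0.012, 0.008, 0.003, 0, 0, 0, 0, 0))
}

#' Worked-example printed tournament summary for PA1535
#'
#' The reported beats/looses scores and normalized weights of the 10
#' molecules. Note the reported score column sums to 4 rather than 0: one
#' score (terpenoid-CoA) disagrees in sign with the tournament recomputed
#' from [pa1535_weight_table()], whose scores do sum to zero as the scoring
#' definition requires.
#'
#' @return A tibble `molecule`, `score`, `weight`.
#' @export
pa1535_reported_scores <- function() {
  tibble(molecule = pa1535_molecules,
         score = c(6L, 5L, 8L, 2L, 3L, -6L, -5L, 1L, -9L, -1L),
         weight = c(0.16, 0.15, 0.18, 0.12, 0.13, 0.03, 0.04, 0.10, 0,
                    0.09))
}
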