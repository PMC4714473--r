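---
title: "Clause rules, tournament weighting and Z-score annotation: the litfun methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clause rules, tournament weighting and Z-score annotation: the litfun methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litfun)
library(dplyr)
```

`litfun` annotates proteins with functional categories using only the
abstracts associated with them. This vignette explains the model behind
each stage, the parameters that matter, the numerical conventions, and
what the synthetic-corpus tests do and do not establish about real
literature.

## 1. Semantic relatedness by clause analysis

The unit of evidence is a *semantically related co-occurrence* of a
molecule name and a protein name. The engine does not use a statistical
parser; it applies a small set of deterministic rules that only require
closed word lists (see `rule_words()`), which makes every verdict
reproducible and auditable:

* **Sentence connectors** ("moreover", "however", "therefore",
  "furthermore", "thus", "hence", "otherwise", "in addition") merge a
  sentence with its predecessor into one analysis unit, transitively.
  Connectors are the *only* licence for cross-sentence relatedness; pairs
  in different units are always unrelated.
* **Clause openers**: relative pronouns ("which", "who", "whom", and
  "that" when a verb follows within three tokens — otherwise "that" is a
  determiner), a coordinating conjunction ("and"/"or") followed by an
  explicit pronoun or directly by a verb (an implicit pronoun), and the
  preposition modifiers "but", "while", "whereas".
* **Subject substitution**, cascading left to right: a relative or plain
  pronoun opening a clause is replaced by the *closest noun* of the
  predecessor clause — implemented as the rightmost maximal noun run,
  extended across "and"/"or" to the conjoined noun group, which is what
  makes "the molecules X and Y that bind…" relate both X and Y to the
  clause that follows. A pronoun after a conjunction instead inherits the
  predecessor clause's (already resolved) *subject*, so chains like
  "… Mcm1p, which interacts with Sid2p, which interacts with Blt1p and
  binds to mob1p" resolve clause four's subject to Sid2p, not to Fkh2p.
* **Verdicts**: a pair is related iff both names end up in one clause
  after substitution. Modifier clauses never inherit subjects, so a
  "but"/"while"/"whereas" boundary isolates its clause and every pair
  across it is unrelated (`PREP_MODIFIER_SPLIT`); everything else falls to
  `DEFAULT_UNRELATED`.

Part-of-speech tagging is a closed-list affair: prepositions, pronouns,
conjunctions, determiners and a list of ~90 relation verbs common in
abstracts; any other word counts as noun-phrase material. That default is
deliberately generous — chemical identifiers, gene symbols and numerals
all behave as nouns — and is the right bias for dictionary-tagged
biomedical text, at the cost of treating adjectives as part of noun
groups (harmless, since only entity mentions inside a group matter).

Entity tagging is longest-match dictionary lookup, case-insensitive, with
a light plural stemmer that strips "s"/"es" from plain alphabetic words
only; hyphenated names like "citronellyl-CoA" must match exactly, so the
stemmer cannot corrupt identifiers. Ties between equally long surface
forms resolve to the smallest canonical id, making tagging independent of
lexicon row order. A thin coreference layer links "this protein"/"the
protein" (anywhere) and sentence-initial "it"/"they" to the previous
sentence's protein when that sentence mentions exactly one; anything
ambiguous is left alone.

## 2. Per-abstract contingency weighting

For a molecule--protein pair in one abstract the engine tallies four
counts: related/unrelated × same-/cross-sentence. These fill a 2×2 table
of observed frequencies

\[ o_{xy} = f \cdot f_A, \qquad e_{xy} = R_x C_y / N , \]

and the per-abstract weight is \(w_{A_j} = T - T'\), where \(T\) (row 1,
related) and \(T'\) (row 2, unrelated) are the normalized sums of squared
deviations \(\sum_y (o_{xy}-e_{xy})^2/e_{xy}\). Cells with zero expected
frequency contribute nothing (the continuity limit), and a pair absent
from an abstract has weight exactly zero. The corpus-level weight is the
plain mean of the per-abstract weights over all \(|A|\) abstracts
associated with the protein, zeros included.

Tunable pieces (`weighting_config()`), all dimensionless:

| parameter | default | meaning |
|---|---|---|
| `f_variant` | `note2` | `1 + log n`: diminishing returns in the pair's in-abstract count |
| `fa_variant` | `note4` | `log(1 + |A|/A)`: damps pairs seen in very few abstracts |
| `c` | 0.5 | first-vs-later appearance balance (`note1` only), in (0, 1) |
| `log_base` | 10 | all logarithms |
| `universe` | per-protein | whether `|A|` counts the protein's abstracts or the whole corpus |

The defaults are the variants that reproduce the printed worked example's
frequency-multiplier column (n = 4 → 1.6, 3 → 1.5, 2 → 1.3, 1 → 1.0 under
base-10 logs). Two genuinely open points are resolved as follows and
isolated behind `build_contingency()`: the column split of the 2×2 table
is same-sentence vs cross-sentence (connector-linked) co-occurrences, and
the abstract multiplier uses the `log(1 + |A|/A)` form — the reciprocal
form appears in some statements of the formula but fails the stated
purpose of preventing an `A = 1` pair from counting double an `A = 2`
pair; it remains available as `fa_variant = "note4_block"`. The
co-occurrence counting unit is one verdict per mention pair per analysis
unit; mention pairs never sharing a unit contribute one cross-sentence
unrelated verdict each.

## 3. The beats/looses tournament

```{r tournament}
dom <- dominance(pa1535_weight_table())
glance(dom)
arrange(tidy(dom), desc(weight))
```

Molecule \(m_i\) dominates \(m_j\) when it has the strictly larger weight
in more abstracts than the reverse (per-abstract ties count for neither
side, and equal wins/losses leave neither dominating). The score
\(S(m_i,p)\) is #dominated − #dominating, bounded by \(\pm(n-1)\) and
summing to zero over the molecules — a conservation law the test suite
asserts on a thousand random tables. Scores are shifted by \(|\min S|\)
and normalized by the sum of shifted scores; the dominance threshold

\[ \beta = \frac{1 - \sqrt{\sum_j (\bar w_j - 1/|V_p|)^2}}{|V_p|} \]

is the uniform mean lowered by the root sum of squared deviations, so
\(\beta \le 1/|V_p|\) always. Molecules with \(\bar w > \beta\) form the
protein's dominant vector. Degenerate cases are pinned down explicitly:
an all-zero shifted vector yields all-zero weights (no dominant set); a
uniform weight vector has \(\beta\) exactly at the mean and the strict
inequality empties the set; a lone molecule with positive weight is kept,
since with nothing to dominate it is trivially the maximal-weight set.
In the bundled worked example one reported score (terpenoid-CoA, +2)
disagrees in sign with the tournament recomputed from the weight matrix
(−2); the package enforces the zero-sum definition and treats the matrix
as authoritative.

## 4. Similarity and Z-score annotation

Similarity between a query vector and a training vector is the centered
cosine over the *shared* molecules only — a Pearson correlation restricted
to the intersection. It is undefined when fewer than two molecules are
shared or either side is constant over them; such pairs are "not
comparable" and never enter the similar set \(S_r\) (threshold 0.5, top-20
by similarity, ties broken by protein id; both exposed in
`prediction_config()` since no canonical values exist for them).

For each category FC, each member \(p\) of \(S_r\) is scored

\[ z = \frac{N^p_{FC}/M_{FC} - N^p_{FC'}/M_{FC'}}{\sigma}, \]

with \(N^p_{FC}\) the FC-associated abstracts containing occurrences of
\(p\), \(M\) the category abstract totals, and \(\sigma\) the *population*
standard deviation of the numerator across all training proteins for the
same FC — the only population in scope, and it makes \(z\) unit-free and
invariant to uniformly scaling all abstract counts. Categories with a
degenerate population (\(M = 0\) on either side, or \(\sigma = 0\)) are
skipped with a warning.

The significance rule is configurable because the two natural readings
differ sharply: the default (`conventional`) assigns FC when the mean
member z exceeds +1.96; the `literal` mode assigns when it exceeds −1.96,
which treats any not-significantly-depleted category as assignable and is
retained for fidelity to the original validation protocol. Mean
aggregation has a structural consequence worth knowing: if categories are
balanced and every protein occurs only in its own abstracts, a member's z
cannot exceed \(\sqrt{(1-f)/f}\) where \(f\) is the category's share of
training proteins — about 1.41 for three balanced categories. The
conventional rule therefore only fires when occurrence is genuinely
skewed (hub-like proteins, many categories, or unbalanced classes); the
package's evaluation fixtures use six categories for exactly this reason.
Prediction confidences for threshold-based evaluation are the
min-max-normalized aggregated z over the scored categories.

## 5. Evaluation harnesses

Per-protein recall \(c_p/n_p\), precision \(c_p/m_p\) and their harmonic
mean F; precision is undefined (and the protein excluded from precision
averaging) when nothing was predicted. The protein-centric curve sweeps
confidence thresholds 0, 0.01, …, 1: at each threshold precision is
averaged over the \(m(t)\) proteins with at least one prediction at or
above it, recall over all proteins. `kfold()` partitions proteins into
disjoint random folds; `cumulative_runs()` implements growing-training-set
validation, rebuilding dominant vectors and category abstract counts after
each run — in both, only training-protein abstracts enter the annotation
index, so test literature never leaks into the category counts.

## 6. The synthetic corpus: what it shows and what it cannot

`generate_corpus()` writes abstracts from a closed template grammar with
five sentence patterns — plain ("P binds M1 and M2."), relative-pronoun
chain ("It is cleaved to release M1, which binds to the protein P."),
conjunction with implicit subject ("P is composed of two domains, and
binds M1."), preposition-modifier split ("P binds M1 but M2 was absent."),
and connector pair ("M1 binds P. Moreover, it binds M2.") — so every
planted molecule--protein pair has a known related/unrelated flag and
same-/cross-sentence origin. Because the grammar is closed, the rule
engine must agree with the ground truth exactly, and does; that closure is
the one oracle real text can never provide.

Default study conditions, chosen once at desk scale: 3 categories × 6
proteins, 4-molecule disjoint signatures, 6 abstracts per protein, 5
sentence slots per abstract, pattern rates 0.2 (chain), 0.2 (conjunction),
0.15 (modifier), 0.15 (connector) with the remaining 0.3 plain, and a 0.2
noise rate planting non-signature molecules as unrelated via the modifier
template. `recovery_experiment()` holds out one protein per category,
scores recovery top-1 (the category with the highest aggregated z must be
the true one), and falls back to the whole training pool when no training
vector is comparable, so that the erased-signature control measures chance
(1/n categories) rather than abstention. Under the defaults without noise,
recovery is 1.0; with signatures erased it sits at chance across seeds.
The acceptance suite runs the clean arm at the default sizes, the
erased-signature arm at 3 × 2 proteins with 3 abstracts × 4 sentences over
20 seeds, and the cumulative trend at 6 categories × 3 proteins with 2
abstracts × 3 sentences over 5 seeds — sizes picked to exercise the full
pipeline many times in a single test run.

One property of the generator deserves emphasis: signature molecules are
planted uniformly, so the *ordering* of tournament weights within a
signature is noise and the centered cosine between two same-category
vectors is small or even negative. Recovery therefore flows through
*comparability* — disjoint signatures make cross-category pairs share
fewer than two molecules, hence "not comparable", hence excluded — and
through the Z-score stage, not through large similarity values. On real
literature, where association strengths differ across a protein's
molecules, the correlation itself is informative; on the synthetic corpus
it is the support overlap that separates categories.

What passing these tests does *not* show: the generator's language is a
closed grammar with unambiguous dictionary names, one protein per
abstract, no nested clauses, no abbreviations, no real anaphora, and
signatures that are exactly disjoint. Real abstracts violate all of that;
on real text the clause rules are a precision-oriented heuristic, the
lexicon bounds recall, and the tournament's value depends on how many
abstracts a protein actually has. The corpus-scale figures of the original
validation (tens of thousands of proteins against UniProtKB/SGD/GO
literature) are out of scope here and would require those downloads.

## 7. Numerical conventions

* All tie-breaks are deterministic: lexicographic ids for tagging and
  similarity ties, first category in sorted z-order for top-1 recovery.
* Contingency cells with zero expected value contribute zero to T/T′.
* Internal arithmetic is full double precision; comparisons against
  printed two-decimal tables round half-up at two decimals.
* Every stochastic component (generator, fold assignment, schedules) is
  driven by an explicit integer seed and is reproducible across platforms;
  nothing depends on hash or iteration order.

## 8. Known limitations

Dictionary NER misses unlisted synonyms and misspellings; the verb list is
finite, so an unlisted verb can hide a clause boundary (the sentence then
stays one clause, which errs toward relatedness); subject detection takes
the pre-verb noun phrase and does not handle passives specially; the
coreference layer resolves only the listed surface forms. The Z-score
stage assumes category abstract sets are large enough that occurrence
proportions are meaningful — with a handful of abstracts per category the
population standard deviation is dominated by discreteness.
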