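#' Closed word lists driving the clause rules
#'
#' The clause analysis needs no statistical part-of-speech tagger: the rules
#' only consult closed lists of pronouns, conjunctions, preposition modifiers,
#' sentence connectors, prepositions, determiners and a small list of
#' relation verbs common in abstracts. Any word not on a list is treated as a
#' noun-phrase word, which is the right default for chemical and protein
#' names. All lists are replaceable for experimentation.
#'
#' @param pronouns Words tagged `PRON`.
#' @param relative_pronouns Pronouns that open a new independent clause.
#' @param conjunctions Coordinating conjunctions (`CONJ`).
#' @param modifiers Preposition modifiers that isolate clauses; entity pairs
#'   across them are semantically unrelated.
#' @param connectors Discourse adverbs that merge a sentence with its
#'   predecessor into one analysis unit.
#' @param prepositions Words tagged `PREP`.
#' @param determiners Words that break noun runs (tagged `OTHER`).
#' @param verbs Words tagged `V`.
#' @param abbreviations Dotted strings protected from sentence splitting.
#' @return A named list of character vectors, class `rule_words`.
#' @export
rule_words <- function(
    pronouns = c("it", "they", "he", "she", "them", "this", "these", "those",
                 "which", "who", "whom", "that"),
    relative_pronouns = c("which", "who", "whom", "that"),
    conjunctions = c("and", "or"),
    modifiers = c("but", "while", "whereas"),
    connectors = c("moreover", "however", "otherwise", "therefore",
                   "furthermore", "thus", "hence", "in addition"),
    prepositions = c("of", "to", "in", "on", "with", "by", "for", "from",
                     "at", "into", "as", "under", "between", "within",
                     "against", "during", "through"),
    determiners = c("the", "a", "an", "its", "their", "each", "every", "all",
                    "some", "such", "other", "another", "most", "both", "two",
                    "three", "several", "many", "few", "no"),
    verbs = c("is", "are", "was", "were", "be", "been", "being", "has",
              "have", "had", "binds", "bind", "bound", "interacts",
              "interact", "interacted", "associates", "associate",
              "associated", "catalyzes", "catalyze", "catalyzed", "cleaves",
              "cleave", "cleaved", "releases", "release", "released",
              "constitutes", "constitute", "shows", "show", "showed",
              "shown", "reveals", "reveal", "revealed", "participates",
              "participate", "participated", "contains", "contain",
              "contained", "composed", "utilizes", "utilize", "utilized",
              "expresses", "express", "expressed", "inhibits", "inhibit",
              "inhibited", "activates", "activate", "activated", "regulates",
              "regulate", "regulated", "requires", "require", "required",
              "encodes", "encode", "encoded", "phosphorylates",
              "phosphorylate", "acetylates", "acetylate", "modulates",
              "modulate", "indicates", "indicate", "indicated",
              "investigates", "investigate", "investigated", "suggests",
              "suggest", "suggested", "found", "demonstrates", "demonstrate",
              "demonstrated", "remains", "remain", "remained", "lacks",
              "lack", "lacked", "forms", "form", "formed"),
    abbreviations = c("et al.", "e.g.", "i.e.", "vs.", "cf.", "ca.", "approx.",
                      "Fig.", "fig.", "sp.", "spp.", "E. coli",
                      "P. aeruginosa", "S. cerevisiae", "M. tuberculosis",
                      "B. subtilis")) {
  structure(list(pronouns = pronouns, relative_pronouns = relative_pronouns,
                 conjunctions = conjunctions, modifiers = modifiers,
                 connectors = connectors, prepositions = prepositions,
                 determiners = determiners, verbs = verbs,
                 abbreviations = abbreviations),
            class = "rule_words")
}
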