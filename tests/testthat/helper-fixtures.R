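# shared fixtures: tiny lexicons and the worked sentences with their
# expected related/unrelated pair sets

make_lexicon <- function(ids, kinds, names = ids, synonyms = NULL) {
  tibble::tibble(
    canonical_id = ids, kind = kinds, name = names,
    synonyms = synonyms %||% rep(list(character()), length(ids)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the ten molecules of the PA1535 worked example
ten_molecule_lexicon <- function() {
  mols <- c("AtuD", "citronellyl-CoA", "octanoyl-CoA", "terpenoid-CoA",
            "isovaleryl-CoA", "Docosenoyl-CoA", "OPC4-CoA", "Sirodesmin H",
            "OPC8-CoA", "3-dipole")
  make_lexicon(mols, rep("molecule", 10))
}

# worked sentences exercising every clause rule, with the pair verdicts
# each analysis must reproduce (related and unrelated stated explicitly)
worked_sentences <- function() {
  list(
    coenzymes_relative_pronoun = list(
      text = paste("Coenzymes are the organic molecules Citronellyl-CoA and",
                   "OPC4-CoA that bind to the active site of the GGPS1",
                   "protein."),
      lexicon = make_lexicon(
        c("Citronellyl-CoA", "OPC4-CoA", "GGPS1"),
        c("molecule", "molecule", "protein")),
      related = list(c("Citronellyl-CoA", "GGPS1"), c("OPC4-CoA", "GGPS1")),
      unrelated = list()),
    cleaved_which_chain = list(
      text = paste("It is cleaved to release 53 amino-acid molecule, which",
                   "binds to the protein ADIPOR1 and interacts with the",
                   "protein BMPR1A."),
      lexicon = make_lexicon(
        c("53 amino-acid molecule", "ADIPOR1", "BMPR1A"),
        c("molecule", "protein", "protein")),
      related = list(c("53 amino-acid molecule", "ADIPOR1"),
                     c("53 amino-acid molecule", "BMPR1A")),
      unrelated = list()),
    mshd_conjunction_pronoun = list(
      text = paste("Protein MshD acetyltransferase is composed of two GNAT",
                   "domains, and it binds molecule AcCoA."),
      lexicon = make_lexicon(c("MshD", "AcCoA"), c("protein", "molecule")),
      related = list(c("MshD", "AcCoA")),
      unrelated = list()),
    acetylcoa_conjunction = list(
      text = paste("Molecule acetyl CoA is a purified recombinant and it",
                   "catalyzes the hydration of the yeast protein mak3."),
      lexicon = make_lexicon(c("acetyl CoA", "mak3"),
                             c("molecule", "protein")),
      related = list(c("acetyl CoA", "mak3")),
      unrelated = list()),
    fkh2p_which_chain = list(
      text = paste("Fkh2p binds cooperatively with Mcm1p, which interacts",
                   "with the Sid2p, which interacts with Blt1p and binds to",
                   "mob1p."),
      lexicon = make_lexicon(
        c("Fkh2p", "Mcm1p", "Sid2p", "Blt1p", "mob1p"), rep("protein", 5)),
      related = list(c("Fkh2p", "Mcm1p"), c("Mcm1p", "Sid2p"),
                     c("Sid2p", "Blt1p"), c("Sid2p", "mob1p")),
      unrelated = list()),
    ggps1_but_split = list(
      text = paste("Citronellyl-CoA and OPC4-CoA participate in the",
                   "catalysis of GGPS1 but OPC8-CoA is a substrate of the",
                   "reaction of OPCL1."),
      lexicon = make_lexicon(
        c("Citronellyl-CoA", "OPC4-CoA", "OPC8-CoA", "GGPS1", "OPCL1"),
        c("molecule", "molecule", "molecule", "protein", "protein")),
      related = list(c("Citronellyl-CoA", "GGPS1"), c("OPC4-CoA", "GGPS1"),
                     c("OPC8-CoA", "OPCL1")),
      unrelated = list(c("Citronellyl-CoA", "OPC8-CoA"),
                       c("Citronellyl-CoA", "OPCL1"),
                       c("OPC4-CoA", "OPC8-CoA"), c("OPC4-CoA", "OPCL1"),
                       c("GGPS1", "OPC8-CoA"), c("GGPS1", "OPCL1"))),
    mshd_whereas_split = list(
      text = paste("The sequence of MshD is twice the length of GNAT and it",
                   "binds CoASH and HSCoA, whereas ARL1 binds SCOCO and",
                   "Golgin-245."),
      lexicon = make_lexicon(
        c("MshD", "CoASH", "HSCoA", "ARL1", "SCOCO", "Golgin-245"),
        c("protein", "molecule", "molecule", "protein", "molecule",
          "molecule")),
      related = list(c("MshD", "CoASH"), c("MshD", "HSCoA"),
                     c("ARL1", "SCOCO"), c("ARL1", "Golgin-245")),
      unrelated = list(c("MshD", "ARL1"), c("MshD", "SCOCO"),
                       c("MshD", "Golgin-245"), c("CoASH", "ARL1"),
                       c("CoASH", "SCOCO"), c("CoASH", "Golgin-245"),
                       c("HSCoA", "ARL1"), c("HSCoA", "SCOCO"),
                       c("HSCoA", "Golgin-245"))),
    caveolin_while_split = list(
      text = paste("caveolin-1 and caveolin-2 interact with c-src and",
                   "Ha-ras, while cRAF-1 interacts with protein CDK4."),
      lexicon = make_lexicon(
        c("caveolin-1", "caveolin-2", "c-src", "Ha-ras", "cRAF-1", "CDK4"),
        c("protein", "protein", "molecule", "molecule", "protein",
          "protein")),
      related = list(c("caveolin-1", "c-src"), c("caveolin-1", "Ha-ras"),
                     c("caveolin-2", "c-src"), c("caveolin-2", "Ha-ras"),
                     c("cRAF-1", "CDK4")),
      unrelated = list(c("caveolin-1", "cRAF-1"), c("caveolin-1", "CDK4"),
                       c("caveolin-2", "cRAF-1"), c("caveolin-2", "CDK4"),
                       c("c-src", "cRAF-1"), c("c-src", "CDK4"),
                       c("Ha-ras", "cRAF-1"), c("Ha-ras", "CDK4"))))
}

# verdict lookup: aggregated relatedness of an id pair in a verdict table
pair_related <- function(verdicts, a, b) {
  hit <- verdicts[(verdicts$id_a == a & verdicts$id_b == b) |
                    (verdicts$id_a == b & verdicts$id_b == a), ]
  if (nrow(hit) == 0L) return(NA)
  any(hit$related)
}

# independent tournament oracle: vectorized outer-comparison formulation,
# distinct from the package's pairwise accumulation loop
oracle_scores <- function(W) {
  n <- ncol(W)
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) D[i, j] <- sum(W[, i] > W[, j])
  vapply(seq_len(n), function(i) {
    sum(D[i, ] > D[, i]) - sum(D[, i] > D[i, ])
  }, integer(1))
}

# random long-format weight table
random_weight_table <- function(n_mol, n_abs, zero_frac = 0.3) {
  w <- matrix(stats::runif(n_mol * n_abs), n_abs, n_mol)
  w[stats::runif(length(w)) < zero_frac] <- 0
  tibble::tibble(
    molecule = rep(sprintf("m%02d", seq_len(n_mol)), each = n_abs),
    abstract_id = rep(sprintf("a%02d", seq_len(n_abs)), n_mol),
    weight = as.vector(w))
}

# tokenized text with unit and global position columns, for clause tests
add_positions_for_test <- function(text) {
  litfun:::add_positions(merge_connected_sentences(tokenize_text(text)))
}
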