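#' Read an abstract corpus from JSON-lines
#'
#' One JSON object per line with fields `id` (string), `text` (string) and
#' `proteins` (array of canonical protein ids associated with the abstract —
#' the abstracts referenced in a protein's database entry). The number of
#' corpus records carrying a protein id is that protein's abstract universe
#' `|A|`.
#'
#' @param path Path to a JSONL file.
#' @param lexicon Optional entity lexicon (see [read_lexicon()]); when
#'   supplied, protein ids appearing as surface names are normalized to
#'   canonical ids.
#' @return A tibble with columns `abstract_id`, `text`, `proteins`
#'   (list-column of character vectors), in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".jsonl")
#' writeLines('{"id":"a1","text":"AtuD binds citronellyl-CoA.","proteins":["PA1535"]}', tf)
#' read_corpus(tf)
read_corpus <- function(path, lexicon = NULL) {
  if (!file.exists(path)) abort(paste0("corpus file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(abstract_id = character(), text = character(),
                  proteins = list()))
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$id) || is.null(rec$text)) {
      abort(paste0("malformed corpus record on line ", i))
    }
    recs[[i]] <- tibble(
      abstract_id = as.character(rec$id),
      text = as.character(rec$text),
      proteins = list(as.character(rec$proteins %||% character()))
    )
  }
  corpus <- list_rbind(recs)
  dup <- unique(corpus$abstract_id[duplicated(corpus$abstract_id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate abstract_id: ", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(corpus$text))) abort("corpus records must have non-empty text")
  if (!is.null(lexicon)) {
    corpus$proteins <- map(corpus$proteins, normalize_protein_ids,
                           lexicon = lexicon)
  }
  corpus
}

normalize_protein_ids <- function(ids, lexicon) {
  prot <- filter(lexicon, .data$kind == "protein")
  surface <- setNames(prot$canonical_id, tolower(prot$name))
  syn <- tidyr::unnest(select(prot, "canonical_id", "synonyms"),
                       "synonyms")
  surface <- c(surface, setNames(syn$canonical_id, tolower(syn$synonyms)))
  hit <- surface[tolower(ids)]
  ifelse(is.na(hit), ids, unname(hit))
}

#' Write an abstract corpus as JSON-lines
#'
#' @param corpus A corpus tibble as returned by [read_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- pmap(list(corpus$abstract_id, corpus$text, corpus$proteins),
                function(id, text, proteins) {
                  jsonlite::toJSON(list(id = jsonlite::unbox(id),
                                        text = jsonlite::unbox(text),
                                        proteins = proteins))
                })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read an entity lexicon
#'
#' Tab-separated file with columns `id`, `kind` (`protein` or `molecule`),
#' `name`, and `synonyms` (pipe-separated, may be empty). Synonyms are merged
#' under the canonical id; lookups during tagging are case-insensitive.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `canonical_id`, `kind`, `name`, `synonyms`
#'   (list-column).
#' @export
read_lexicon <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("id", "kind", "name")
  if (!all(needed %in% names(raw))) {
    abort("lexicon needs columns id, kind, name (and optional synonyms)")
  }
  if (any(is.na(raw$id) | !nzchar(trimws(raw$id)))) {
    abort("lexicon rows must have a canonical id")
  }
  bad <- setdiff(unique(raw$kind), c("protein", "molecule"))
  if (length(bad) > 0L) {
    abort(paste0("unknown entity kind: ", paste(bad, collapse = ", ")))
  }
  if (any(!nzchar(trimws(raw$name)))) abort("lexicon names must be non-empty")
  syn_raw <- raw$synonyms %||% rep(NA_character_, nrow(raw))
  syn <- map(syn_raw, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character())
    out <- trimws(strsplit(s, "|", fixed = TRUE)[[1]])
    out[nzchar(out)]
  })
  lex <- tibble(canonical_id = trimws(raw$id), kind = raw$kind,
                name = trimws(raw$name), synonyms = syn)
  dup <- unique(lex$canonical_id[duplicated(lex$canonical_id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate canonical_id in lexicon: ",
                 paste(dup, collapse = ", ")))
  }
  lex
}

#' Write an entity lexicon as TSV
#'
#' @param lexicon A lexicon tibble as returned by [read_lexicon()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  out <- tibble(id = lexicon$canonical_id, kind = lexicon$kind,
                name = lexicon$name,
                synonyms = map_chr(lexicon$synonyms, paste, collapse = "|"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a protein-to-category annotation table
#'
#' Two-column tab-separated file (`protein`, `category`), one row per
#' annotation. Duplicate rows are rejected. Protein ids absent from a supplied
#' lexicon raise a warning but are kept (ids may be external).
#'
#' @param path Path to a TSV file.
#' @param lexicon Optional lexicon used only to warn about unknown proteins.
#' @return A tibble with columns `protein`, `category`.
#' @export
read_annotations <- function(path, lexicon = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2L) abort("annotation table needs two columns")
  ann <- tibble(protein = trimws(raw[[1]]), category = trimws(raw[[2]]))
  if (anyDuplicated(ann) > 0L) {
    abort("duplicate (protein, category) rows in annotation table")
  }
  if (!is.null(lexicon)) {
    known <- lexicon$canonical_id[lexicon$kind == "protein"]
    miss <- setdiff(unique(ann$protein), known)
    if (length(miss) > 0L) {
      warn(paste0("annotation proteins absent from lexicon: ",
                  paste(miss, collapse = ", ")))
    }
  }
  ann
}

#' Write an annotation table as TSV
#'
#' @param annotations Annotation tibble (`protein`, `category`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(select(annotations, "protein", "category"), path,
                   progress = FALSE)
  invisible(path)
}

#' Index an annotation table against a corpus
#'
#' Builds, for every functional category `FC`, the set of member proteins and
#' the set of abstracts associated with those proteins. `M_FC` is the number
#' of abstracts whose protein list intersects the category's protein set;
#' `M_FC'` counts abstracts associated with proteins annotated with any other
#' category.
#'
#' @param annotations Annotation tibble (`protein`, `category`).
#' @param corpus Corpus tibble.
#' @return A list with elements `categories` (tibble: `category`, `proteins`,
#'   `abstracts`, `m_fc`, `m_fc_other`), `annotations` and `corpus`.
#' @export
annotation_index <- function(annotations, corpus) {
  abs_prot <- tidyr::unnest(
    select(corpus, "abstract_id", protein = "proteins"), "protein")
  cats <- unique(annotations$category)
  rows <- map(cats, function(fc) {
    prots <- annotations$protein[annotations$category == fc]
    abs_in <- unique(abs_prot$abstract_id[abs_prot$protein %in% prots])
    other_prots <- annotations$protein[annotations$category != fc]
    abs_out <- unique(abs_prot$abstract_id[abs_prot$protein %in% other_prots])
    tibble(category = fc, proteins = list(prots), abstracts = list(abs_in),
           m_fc = length(abs_in), m_fc_other = length(abs_out))
  })
  list(categories = list_rbind(rows), annotations = annotations,
       corpus = corpus)
}
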