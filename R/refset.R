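#' Load a reference set of known drug-disease pairs
#'
#' The reference set links the drug and disease vector spaces: each row
#' pairs a DrugBank-style drug accession (`DBnnnnn`) with a KEGG-style
#' disease accession (`Hnnnnn`) for a known indication. Duplicate
#' `(drug_id, disease_id)` rows are collapsed with a message; malformed
#' accessions fail with the offending line numbers.
#'
#' The packaged fixture `lwas_example("table1_pairs.tsv")` holds the
#' 18 diseases found near the target disease together with their 24 unique
#' known drugs (67 pairs).
#'
#' @param path Path to a TSV with header
#'   `drug_id<TAB>drug_name<TAB>disease_id<TAB>disease_name<TAB>source`.
#' @param pairs A data frame with those columns (for `as_refset()`).
#' @return A `lwas_refset`: tibble of unique pairs, with attribute
#'   `n_duplicates` (rows collapsed on load).
#' @examples
#' refset <- read_reference_pairs(lwas_example("table1_pairs.tsv"))
#' dplyr::n_distinct(refset$disease_id)
#' @export
read_reference_pairs <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0L) {
    abort("reference pair file is empty")
  }
  as_refset(df)
}

#' @rdname read_reference_pairs
#' @export
as_refset <- function(pairs) {
  pairs <- as_tibble(pairs)
  required <- c("drug_id", "drug_name", "disease_id", "disease_name", "source")
  missing_cols <- setdiff(required, names(pairs))
  if (length(missing_cols)) {
    abort(paste0("pair table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_drug <- !grepl("^DB[0-9]{5}$", pairs$drug_id)
  bad_disease <- !grepl("^H[0-9]{5}$", pairs$disease_id)
  bad_name <- is.na(pairs$drug_name) | !nzchar(pairs$drug_name) |
    is.na(pairs$disease_name) | !nzchar(pairs$disease_name)
  bad <- bad_drug | bad_disease | bad_name
  if (any(bad)) {
    lines <- which(bad) + 1L  # account for the header line
    abort(paste0("malformed reference pair row(s) at line(s): ",
                 paste(head(lines, 10), collapse = ", ")),
          class = "lwas_pair_error")
  }
  pairs$source <- ifelse(pairs$source %in% c("drugbank", "kegg"),
                         pairs$source, "other")
  n_before <- nrow(pairs)
  pairs <- distinct(pairs, .data$drug_id, .data$disease_id, .keep_all = TRUE)
  n_dup <- n_before - nrow(pairs)
  if (n_dup > 0L) {
    rlang::inform(paste0("collapsed ", n_dup, " duplicate drug-disease pair(s)"))
  }
  structure(pairs, class = c("lwas_refset", class(tibble())),
            n_duplicates = n_dup)
}

# normalize the many shapes a "vocabulary" argument can take
vocab_tokens <- function(vocab) {
  if (inherits(vocab, "lwas_embedding")) {
    return(vocab$vocab)
  }
  if (is.character(vocab)) {
    return(tibble(token = vocab, index = seq_along(vocab),
                  count = rep(1L, length(vocab))))
  }
  as_tibble(vocab)
}

# corpus tokens of every lexicon surface form for one canonical id,
# most frequent in-vocabulary token first
resolve_entity_token <- function(lexicon, canonical_id, vocab) {
  tokens <- unique(lexicon$token[lexicon$canonical_id == canonical_id])
  hit <- vocab$token %in% tokens
  if (!any(hit)) {
    return(NA_character_)
  }
  in_vocab <- vocab[hit, , drop = FALSE]
  in_vocab$token[order(-in_vocab$count, in_vocab$token, method = "radix")][1L]
}

#' Restrict a reference set to entities present in a vocabulary
#'
#' Entity names are resolved to corpus tokens through the lexicon (same
#' hyphenation as the corpus pipeline); a pair is retained only when both
#' its drug and its disease have at least one surface-form token in the
#' vocabulary. An entity with several surface forms (e.g. an acronym and the
#' spelled-out name sharing one canonical id) passes if any form is
#' embedded; the retained token (most frequent form) is recorded in the
#' `drug_token` / `disease_token` columns.
#'
#' Filtering is idempotent and can only shrink the set.
#'
#' @param refset A `lwas_refset`.
#' @param vocab A vocabulary tibble from [build_vocabulary()], a
#'   `lwas_embedding`, or a character vector of tokens.
#' @param lexicon An entity lexicon covering the reference entities; pairs
#'   whose ids are absent from the lexicon fall back to tokenizing their
#'   `drug_name` / `disease_name` with [entity_token()].
#' @return A filtered `lwas_refset` with `drug_token` and `disease_token`
#'   columns and attribute `counts` (surviving drugs, diseases, pairs).
#' @export
filter_to_vocabulary <- function(refset, vocab, lexicon = NULL) {
  vocab <- vocab_tokens(vocab)
  lex <- if (is.null(lexicon)) {
    tibble(surface_form = character(), canonical_id = character(),
           entity_type = character(), token = character())
  } else {
    as_lexicon(lexicon)
  }
  resolve <- function(id, name) {
    tok <- if (id %in% lex$canonical_id) {
      resolve_entity_token(lex, id, vocab)
    } else {
      candidate <- entity_token(name)
      if (candidate %in% vocab$token) candidate else NA_character_
    }
    tok
  }
  drug_token <- vapply(seq_len(nrow(refset)), function(i) {
    resolve(refset$drug_id[i], refset$drug_name[i])
  }, character(1))
  disease_token <- vapply(seq_len(nrow(refset)), function(i) {
    resolve(refset$disease_id[i], refset$disease_name[i])
  }, character(1))
  keep <- !is.na(drug_token) & !is.na(disease_token)
  out <- refset[keep, , drop = FALSE]
  out$drug_token <- drug_token[keep]
  out$disease_token <- disease_token[keep]
  counts <- list(drugs = dplyr::n_distinct(out$drug_id),
                 diseases = dplyr::n_distinct(out$disease_id),
                 pairs = nrow(out))
  structure(out, class = c("lwas_refset", class(tibble())),
            n_duplicates = attr(refset, "n_duplicates") %||% 0L,
            counts = counts)
}

#' Known drugs of a disease
#'
#' @param refset A `lwas_refset`.
#' @param disease_id A disease accession (e.g. `"H01665"`).
#' @return Tibble with columns `drug_id`, `drug_name` (empty when the
#'   disease is absent from the set).
#' @examples
#' refset <- read_reference_pairs(lwas_example("table1_pairs.tsv"))
#' drugs_for_disease(refset, "H01665")
#' @export
drugs_for_disease <- function(refset, disease_id) {
  id <- disease_id
  out <- filter(as_tibble(refset), .data$disease_id == id)
  distinct(select(out, "drug_id", "drug_name"))
}
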