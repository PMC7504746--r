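#' Normalize raw abstract text
#'
#' Uppercases the text and replaces punctuation with single spaces, following
#' the corpus-preparation protocol: all ASCII punctuation is stripped
#' (including hyphens, so that "-" is later unambiguous as the multiword
#' entity joiner), except that sentence-terminal marks (`.`, `?`, `!`
#' immediately followed by whitespace or end of text) are kept as standalone
#' tokens for [split_sentences()] to consume. Runs of whitespace collapse to
#' one space.
#'
#' `clean_text()` is total and idempotent: any string is accepted, and
#' cleaning an already-clean string changes nothing.
#'
#' @param text Character vector of raw text (e.g. abstract bodies).
#' @return Character vector of normalized text, same length as `text`.
#' @examples
#' clean_text("Tumor growth was inhibited.")
#' clean_text("anti-HER2 (trastuzumab)")
#' @export
clean_text <- function(text) {
  x <- toupper(as.character(text))
  x[is.na(x)] <- ""
  # protect terminal marks (followed by whitespace or end) with sentinels
  x <- gsub("\\.(?=\\s|$)", " \x01", x, perl = TRUE)
  x <- gsub("\\?(?=\\s|$)", " \x02", x, perl = TRUE)
  x <- gsub("!(?=\\s|$)",   " \x03", x, perl = TRUE)
  # every remaining ASCII punctuation character becomes a space
  x <- gsub("[\\x21-\\x2f\\x3a-\\x40\\x5b-\\x60\\x7b-\\x7e]", " ", x, perl = TRUE)
  x <- chartr("\x01\x02\x03", ".?!", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Abbreviations that suppress a sentence break
#'
#' A period after one of these tokens is treated as part of an abbreviation
#' (e.g. "E. COLI", "FIG. 2") rather than a sentence terminal. All single
#' letters are included, plus a small list of common scientific-prose
#' abbreviations. Tokens are compared after [clean_text()], i.e. uppercase.
#'
#' @return Character vector of abbreviation tokens.
#' @export
sentence_abbreviations <- function() {
  c(LETTERS,
    "FIG", "FIGS", "VS", "ET", "AL", "NO", "DR", "EG", "IE", "CF",
    "ST", "SPP", "APPROX", "REF", "REFS", "RESP")
}

#' Split cleaned text into sentences
#'
#' Splits on the terminal marks (`.`, `?`, `!`) that [clean_text()] preserved
#' as standalone tokens, removing the marks from the output. A period is not
#' a boundary when the preceding token is a known abbreviation (see
#' [sentence_abbreviations()]). Concatenating the returned sentences
#' reproduces the input token stream minus the terminal marks.
#'
#' @param text A single cleaned string (output of [clean_text()]).
#' @param abbreviations Tokens after which a period does not end a sentence.
#' @return Character vector of sentences (possibly empty).
#' @examples
#' split_sentences(clean_text("Cells grew. Cells died."))
#' split_sentences(clean_text("E. coli was cultured."))
#' @export
split_sentences <- function(text, abbreviations = sentence_abbreviations()) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(character())
  }
  toks <- strsplit(text, " ", fixed = TRUE)[[1L]]
  terminal <- toks %in% c(".", "?", "!")
  # a guarded period continues the sentence
  prev <- c("", toks[-length(toks)])
  guarded <- terminal & toks == "." & prev %in% abbreviations
  boundary <- terminal & !guarded
  keep <- !terminal
  sent_id <- cumsum(c(FALSE, boundary[-length(boundary)]))[keep]
  words <- toks[keep]
  if (length(words) == 0L) {
    return(character())
  }
  unname(vapply(split(words, sent_id), paste, character(1), collapse = " "))
}

#' Tokenize cleaned sentences
#'
#' @param sentences Character vector of cleaned sentence strings.
#' @return List of character vectors, one per sentence.
#' @export
tokenize_sentences <- function(sentences) {
  strsplit(sentences, " ", fixed = TRUE)
}

#' Read or validate an entity lexicon
#'
#' The lexicon maps drug and disease surface forms (possibly multiword) to
#' canonical identifiers. It drives multiword-entity hyphenation
#' ([hyphenate_entities()]) and name-to-token resolution
#' ([entity_token()]). A disease known under several names (e.g. an acronym
#' and its spelled-out form) has one row per surface form, sharing a
#' canonical id.
#'
#' @param path Path to a TSV file with header
#'   `surface_form<TAB>canonical_id<TAB>entity_type`.
#' @param lexicon A data frame with those three columns (for `as_lexicon()`).
#' @return A tibble with columns `surface_form`, `canonical_id`,
#'   `entity_type` and a derived `token` column (the hyphenated corpus token
#'   for each surface form).
#' @examples
#' lex <- read_lexicon(lwas_example("ibc_lexicon.tsv"))
#' dplyr::filter(lex, canonical_id == "IBC")
#' @export
read_lexicon <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  as_lexicon(df)
}

#' @rdname read_lexicon
#' @export
as_lexicon <- function(lexicon) {
  lexicon <- as_tibble(lexicon)
  required <- c("surface_form", "canonical_id", "entity_type")
  missing_cols <- setdiff(required, names(lexicon))
  if (length(missing_cols)) {
    abort(paste0("lexicon is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(lexicon$surface_form) | !nzchar(trimws(lexicon$surface_form)))) {
    abort("lexicon surface forms must be non-empty")
  }
  bad_type <- setdiff(unique(lexicon$entity_type), c("drug", "disease"))
  if (length(bad_type)) {
    abort(paste0("unknown entity_type: ", paste(bad_type, collapse = ", ")))
  }
  key <- paste(toupper(lexicon$surface_form), lexicon$entity_type)
  if (anyDuplicated(key)) {
    abort("duplicate (surface_form, entity_type) rows in lexicon")
  }
  lexicon$token <- entity_token(lexicon$surface_form)
  lexicon
}

#' Canonical corpus token for an entity name
#'
#' Applies the same normalization as the corpus pipeline — uppercase,
#' punctuation to spaces — and joins multiword names with hyphens, so that a
#' lexicon name resolves to exactly the token [build_corpus()] produces for
#' it. This is the bridge used when linking a reference pair file to an
#' embedding vocabulary.
#'
#' @param name Character vector of entity names.
#' @return Character vector of tokens (no spaces; hyphen-joined).
#' @examples
#' entity_token("Ewing sarcoma")
#' entity_token("primary peritoneal carcinoma")
#' @export
entity_token <- function(name) {
  x <- toupper(as.character(name))
  x <- gsub("[\\x21-\\x2f\\x3a-\\x40\\x5b-\\x60\\x7b-\\x7e]", " ", x, perl = TRUE)
  x <- trimws(gsub("[[:space:]]+", " ", x))
  gsub(" ", "-", x, fixed = TRUE)
}

# first-token index over multiword lexicon entries; candidates at each first
# token are sorted longest-first so greedy matching is leftmost-longest
entity_index <- function(lexicon) {
  lexicon <- as_lexicon(lexicon)
  seqs <- tokenize_sentences(gsub("-", " ", lexicon$token, fixed = TRUE))
  seqs <- unique(seqs[lengths(seqs) >= 2L])
  if (!length(seqs)) {
    return(list())
  }
  first <- vapply(seqs, `[`, character(1), 1L)
  idx <- split(seqs, first)
  lapply(idx, function(s) s[order(-lengths(s))])
}

hyphenate_with_index <- function(tokens, index) {
  n <- length(tokens)
  if (n == 0L || length(index) == 0L) {
    return(tokens)
  }
  out <- character(0)
  i <- 1L
  while (i <= n) {
    cands <- index[[tokens[i]]]
    matched <- FALSE
    if (!is.null(cands)) {
      for (s in cands) {
        L <- length(s)
        if (i + L - 1L <= n && all(tokens[i:(i + L - 1L)] == s)) {
          out <- c(out, paste(s, collapse = "-"))
          i <- i + L
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) {
      out <- c(out, tokens[i])
      i <- i + 1L
    }
  }
  out
}

#' Collapse multiword entities into hyphenated tokens
#'
#' Every maximal lexicon match of two or more consecutive tokens is replaced
#' by a single token joining its words with `-`. Matching is greedy
#' leftmost-longest over the token sequence and case-insensitive (tokens are
#' already uppercase after [clean_text()]). Single-word entities and tokens
#' matching no lexicon entry pass through unchanged.
#'
#' @param tokens Character vector of uppercase tokens (one sentence).
#' @param lexicon An entity lexicon (see [read_lexicon()]).
#' @return Character vector of tokens, never longer than the input.
#' @examples
#' lex <- read_lexicon(lwas_example("ibc_lexicon.tsv"))
#' hyphenate_entities(c("INFLAMMATORY", "BREAST", "CANCER"), lex)
#' hyphenate_entities(c("EWING", "SARCOMA", "CELLS"), lex)
#' @export
hyphenate_entities <- function(tokens, lexicon) {
  hyphenate_with_index(tokens, entity_index(lexicon))
}

#' Build a sentence corpus from raw documents
#'
#' Runs the full preparation pipeline per document — [clean_text()],
#' [split_sentences()], [tokenize_sentences()], [hyphenate_entities()] — and
#' records sentence provenance. Documents with a missing text field are
#' skipped and counted (see `attr(corpus, "n_skipped")`).
#'
#' @param docs A data frame with columns `doc_id` and `text`, one row per
#'   abstract.
#' @param lexicon An entity lexicon (see [read_lexicon()]), or `NULL` to skip
#'   hyphenation.
#' @return A `lwas_corpus`: a tibble with columns `doc_id`, `sentence_id`
#'   (1-based within document) and `tokens` (list column of character
#'   vectors), with count attributes `n_documents`, `n_skipped`,
#'   `n_sentences`, `n_tokens`.
#' @examples
#' docs <- tibble::tibble(doc_id = "d1",
#'   text = "Ewing sarcoma cells died. Growth stopped.")
#' lex <- read_lexicon(lwas_example("ibc_lexicon.tsv"))
#' build_corpus(docs, lex)
#' @export
build_corpus <- function(docs, lexicon = NULL) {
  docs <- as_tibble(docs)
  if (!all(c("doc_id", "text") %in% names(docs))) {
    abort("docs must have columns 'doc_id' and 'text'")
  }
  if (anyDuplicated(docs$doc_id)) {
    abort("doc_id must be unique")
  }
  bad <- is.na(docs$text)
  if (any(bad)) {
    warn(paste0("skipping ", sum(bad), " document(s) with missing text"))
    docs <- docs[!bad, , drop = FALSE]
  }
  index <- if (is.null(lexicon)) list() else entity_index(lexicon)
  per_doc <- lapply(seq_len(nrow(docs)), function(i) {
    sents <- split_sentences(clean_text(docs$text[i]))
    toks <- lapply(tokenize_sentences(sents), hyphenate_with_index, index = index)
    toks <- toks[lengths(toks) > 0L]
    if (!length(toks)) {
      return(NULL)
    }
    tibble(doc_id = docs$doc_id[i], sentence_id = seq_along(toks), tokens = toks)
  })
  out <- bind_rows(per_doc)
  if (nrow(out) == 0L) {
    out <- tibble(doc_id = character(), sentence_id = integer(), tokens = list())
  }
  new_corpus(out, n_documents = nrow(docs), n_skipped = sum(bad))
}

new_corpus <- function(df, n_documents = NA_integer_, n_skipped = 0L) {
  structure(df,
    class = c("lwas_corpus", class(tibble())),
    n_documents = n_documents,
    n_skipped = n_skipped,
    n_sentences = nrow(df),
    n_tokens = sum(lengths(df$tokens)))
}

#' Corpus input/output
#'
#' `write_corpus()` writes one sentence per line (space-separated tokens)
#' plus a JSON sidecar `<path>.json` with document, sentence and token
#' counts. `read_corpus()` reads such a file back; per-sentence document
#' provenance is not stored in the flat text format, so `doc_id` is `NA`
#' after a round trip.
#'
#' @param corpus A `lwas_corpus` (see [build_corpus()]).
#' @param path Path of the sentences text file.
#' @return `write_corpus()` returns `path` invisibly; `read_corpus()` returns
#'   a `lwas_corpus`.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus$tokens, paste, character(1), collapse = " ")
  writeLines(lines, path)
  counts <- list(
    documents = attr(corpus, "n_documents"),
    sentences = attr(corpus, "n_sentences"),
    tokens = attr(corpus, "n_tokens"))
  jsonlite::write_json(counts, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  df <- tibble(
    doc_id = rep(NA_character_, length(lines)),
    sentence_id = seq_along(lines),
    tokens = tokenize_sentences(lines))
  new_corpus(df)
}
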