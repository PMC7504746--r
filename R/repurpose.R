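#' Diseases most similar to a target disease
#'
#' Ranks candidate disease tokens by cosine similarity to the target token
#' in the full embedding space and returns the top `k`. The target itself is
#' excluded, as are its synonyms — tokens whose lexicon entries share a
#' canonical id with the target (e.g. an acronym and its spelled-out form),
#' which would otherwise be returned as vacuously similar diseases.
#'
#' @param model A `lwas_embedding`.
#' @param target Target disease token (or a name resolvable via
#'   [entity_token()]).
#' @param disease_tokens Character vector of eligible disease tokens.
#' @param k Number of similar diseases to return (>= 1).
#' @param lexicon Optional lexicon used for synonym exclusion and to attach
#'   `disease_id` to the result.
#' @param min_similarity Optional cosine threshold; neighbors below it are
#'   dropped (an alternative "vicinity" definition to a fixed `k`).
#' @return Tibble with columns `disease_token`, `similarity` (descending)
#'   and, when a lexicon is given, `disease_id`.
#' @seealso [map_neighbors()] for the 2D-map radius neighborhood mode.
#' @export
similar_diseases <- function(model, target, disease_tokens, k,
                             lexicon = NULL, min_similarity = NULL) {
  stopifnot(k >= 1L)
  target <- entity_token(target)
  exclude <- target
  lex <- if (is.null(lexicon)) NULL else as_lexicon(lexicon)
  if (!is.null(lex)) {
    target_ids <- unique(lex$canonical_id[lex$token == target])
    synonyms <- unique(lex$token[lex$canonical_id %in% target_ids])
    exclude <- union(exclude, synonyms)
  }
  eligible <- setdiff(unique(disease_tokens), exclude)
  eligible <- intersect(eligible, model$vocab$token)
  nn <- nearest_neighbors(model, target, k = k, restrict_to = eligible)
  if (!is.null(min_similarity)) {
    nn <- nn[nn$similarity >= min_similarity, , drop = FALSE]
  }
  out <- rename(nn, disease_token = "token")
  if (!is.null(lex)) {
    ids <- distinct(lex[lex$entity_type == "disease", ],
                    .data$token, .keep_all = TRUE)
    out <- left_join(out, select(ids, disease_token = "token",
                                 disease_id = "canonical_id"),
                     by = "disease_token")
  }
  out
}

#' Propose candidate drugs from similar diseases
#'
#' Collects the known drugs of every similar disease from the reference set
#' and deduplicates them into one candidate per unique drug. Each
#' candidate's `rank_score` is the maximum similarity among its supporting
#' diseases (a single strongly similar indication suffices); candidates are
#' sorted by descending score with alphabetical drug-name tie-breaking, and
#' full provenance is kept in the `supporting_diseases` list column.
#'
#' @param similar Tibble from [similar_diseases()] (needs `disease_id` or a
#'   `disease_token` matching the reference set's `disease_token` column,
#'   plus `similarity`).
#' @param refset A `lwas_refset`.
#' @param score Aggregation of supporting similarities: `"max"` (default) or
#'   `"mean"`.
#' @return A `lwas_candidates` tibble: `drug_id`, `drug_name`, `rank_score`,
#'   `n_support`, `supporting_diseases` (list of tibbles with `disease_id`,
#'   `similarity`).
#' @examples
#' refset <- read_reference_pairs(lwas_example("table1_pairs.tsv"))
#' similar <- tibble::tibble(disease_id = unique(refset$disease_id),
#'                           similarity = 0.9)
#' nrow(propose_drugs(similar, refset))
#' @export
propose_drugs <- function(similar, refset, score = c("max", "mean")) {
  score <- match.arg(score)
  similar <- as_tibble(similar)
  if (nrow(similar) == 0L) {
    return(structure(tibble(drug_id = character(), drug_name = character(),
                            rank_score = numeric(), n_support = integer(),
                            supporting_diseases = list()),
                     class = c("lwas_candidates", class(tibble()))))
  }
  pairs <- as_tibble(refset)
  if ("disease_id" %in% names(similar)) {
    joined <- inner_join(pairs, select(similar, "disease_id", "similarity"),
                         by = "disease_id")
  } else if ("disease_token" %in% names(similar) &&
             "disease_token" %in% names(pairs)) {
    joined <- inner_join(pairs,
                         select(similar, "disease_token", "similarity"),
                         by = "disease_token")
  } else {
    abort("similar diseases must carry 'disease_id' or a 'disease_token' matching the reference set")
  }
  agg <- if (score == "max") max else mean
  out <- joined |>
    group_by(.data$drug_id) |>
    summarise(
      drug_name = .data$drug_name[1L],
      rank_score = agg(.data$similarity),
      n_support = dplyr::n_distinct(.data$disease_id),
      supporting_diseases = {
        support <- unique(data.frame(disease_id = .data$disease_id,
                                     similarity = .data$similarity))
        support <- support[order(-support$similarity, support$disease_id), ]
        list(as_tibble(support))
      },
      .groups = "drop") |>
    arrange(desc(.data$rank_score), tolower(.data$drug_name))
  structure(out, class = c("lwas_candidates", class(tibble())))
}

#' Read a drug annotation table
#'
#' @param path TSV with header `drug_name<TAB>pubmed<TAB>clinicaltrials`,
#'   values yes/no (case-insensitive).
#' @return Tibble with `drug_name` and logical `pubmed`, `clinicaltrials`.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("drug_name", "pubmed", "clinicaltrials")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("annotation table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  to_logical <- function(x) {
    v <- tolower(trimws(x))
    bad <- !v %in% c("yes", "no")
    if (any(bad)) {
      abort("annotation values must be yes or no")
    }
    v == "yes"
  }
  mutate(df, pubmed = to_logical(.data$pubmed),
         clinicaltrials = to_logical(.data$clinicaltrials))
}

#' Evaluate candidate drugs against a literature annotation table
#'
#' Joins candidates to the annotation table by exact drug-name match after
#' case folding. Candidates with no annotation row are counted as negative
#' in both sources (with a message); duplicate annotation rows for one drug
#' are an error. A candidate supported by neither source is flagged
#' `novel`. Use [glance()] for the four summary counts.
#'
#' @param candidates A `lwas_candidates` tibble (see [propose_drugs()]).
#' @param annotations Tibble from [read_annotations()] (or equivalent, with
#'   logical or yes/no `pubmed` / `clinicaltrials`).
#' @return A `lwas_annotated` tibble: candidates plus logical `pubmed`,
#'   `clinicaltrials`, `novel` columns.
#' @export
annotate_candidates <- function(candidates, annotations) {
  ann <- as_tibble(annotations)
  if (is.character(ann$pubmed)) {
    ann$pubmed <- tolower(ann$pubmed) == "yes"
  }
  if (is.character(ann$clinicaltrials)) {
    ann$clinicaltrials <- tolower(ann$clinicaltrials) == "yes"
  }
  ann$.name_key <- tolower(trimws(ann$drug_name))
  if (anyDuplicated(ann$.name_key)) {
    dup <- unique(ann$drug_name[duplicated(ann$.name_key)])
    abort(paste0("duplicate annotation row(s) for drug(s): ",
                 paste(dup, collapse = ", ")),
          class = "lwas_annotation_error")
  }
  out <- as_tibble(candidates)
  out$.name_key <- tolower(trimws(out$drug_name))
  out <- left_join(out, select(ann, ".name_key", "pubmed", "clinicaltrials"),
                   by = ".name_key")
  n_missing <- sum(is.na(out$pubmed))
  if (n_missing > 0L) {
    rlang::inform(paste0(n_missing, " candidate(s) had no annotation row; ",
                         "counted as negative in both sources"))
  }
  out$pubmed[is.na(out$pubmed)] <- FALSE
  out$clinicaltrials[is.na(out$clinicaltrials)] <- FALSE
  out$novel <- !out$pubmed & !out$clinicaltrials
  out$.name_key <- NULL
  structure(out, class = c("lwas_annotated", class(tibble())))
}

#' @export
glance.lwas_annotated <- function(x, ...) {
  tibble(n_candidates = nrow(x),
         n_pubmed_supported = sum(x$pubmed),
         n_clinicaltrials = sum(x$clinicaltrials),
         n_novel = sum(x$novel))
}

#' @rdname annotate_candidates
#' @param annotated A `lwas_annotated` tibble.
#' @export
evaluation_counts <- function(annotated) {
  glance.lwas_annotated(annotated)
}

#' Plot candidate drugs by rank score
#'
#' @param object A `lwas_candidates` or `lwas_annotated` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lwas_candidates <- function(object, ...) {
  df <- mutate(as_tibble(object),
               drug_name = factor(.data$drug_name,
                                  levels = rev(.data$drug_name)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_score,
                                        y = .data$drug_name))
  if ("novel" %in% names(df)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$novel))
  } else {
    p <- p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = "rank score (max supporting similarity)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lwas_annotated <- function(object, ...) {
  autoplot.lwas_candidates(object, ...)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)),
          class = "lwas_pipeline_error", parent = e)
  })
}

#' Run the full repurposing pipeline
#'
#' Executes prepare -> train -> similar diseases -> candidate drugs ->
#' (optional) annotation in one call, from a single configuration list. With
#' an `out` directory, all artifacts (corpus, vectors, similar diseases,
#' candidate report, evaluation counts and a machine-readable run log) are
#' written as plain text.
#'
#' @param config A list with fields:
#'   * `docs` — data frame of `doc_id`, `text`, or a TSV path with those
#'     columns;
#'   * `lexicon` — lexicon data frame or TSV path (see [read_lexicon()]);
#'   * `pairs` — reference pair data frame or TSV path
#'     (see [read_reference_pairs()]);
#'   * `target` — target disease name or token;
#'   * `k` — neighborhood size (default 18);
#'   * `annotations` — optional annotation table or TSV path;
#'   * `train` — optional [train_config()] or list of its arguments;
#'   * `out` — optional output directory.
#' @return A `lwas_result` list: `corpus`, `model`, `similar`, `candidates`,
#'   `evaluation` (or `NULL`), `config`.
#' @export
run_pipeline <- function(config) {
  required <- c("docs", "lexicon", "pairs", "target")
  missing_fields <- setdiff(required, names(config))
  missing_fields <- union(missing_fields,
                          required[vapply(config[required], is.null, NA)])
  if (length(missing_fields)) {
    abort(paste0("pipeline configuration is missing field(s): ",
                 paste(sort(missing_fields), collapse = ", ")),
          class = "lwas_config_error")
  }
  k <- config$k %||% 18L
  docs <- if (is.character(config$docs)) {
    readr::read_tsv(config$docs, col_types = readr::cols(.default = readr::col_character()))
  } else {
    config$docs
  }
  lexicon <- if (is.character(config$lexicon)) {
    read_lexicon(config$lexicon)
  } else {
    as_lexicon(config$lexicon)
  }
  refset <- if (is.character(config$pairs)) {
    read_reference_pairs(config$pairs)
  } else {
    as_refset(config$pairs)
  }
  tc <- config$train %||% train_config()
  if (!inherits(tc, "lwas_train_config")) {
    tc <- do.call(train_config, as.list(tc))
  }

  corpus <- pipeline_stage("prepare", build_corpus(docs, lexicon))
  model <- pipeline_stage("train", train_embeddings(corpus, tc))
  refset_v <- pipeline_stage("filter",
                             filter_to_vocabulary(refset, model, lexicon))
  similar <- pipeline_stage("similar_diseases", {
    similar_diseases(model, config$target,
                     unique(refset_v$disease_token), k = k,
                     lexicon = lexicon)
  })
  candidates <- pipeline_stage("propose_drugs", {
    sim <- similar
    if (!"disease_id" %in% names(sim) || anyNA(sim$disease_id)) {
      propose_drugs(select(sim, "disease_token", "similarity"), refset_v)
    } else {
      propose_drugs(sim, refset_v)
    }
  })
  evaluation <- NULL
  annotated <- NULL
  if (!is.null(config$annotations)) {
    ann <- if (is.character(config$annotations)) {
      read_annotations(config$annotations)
    } else {
      config$annotations
    }
    annotated <- pipeline_stage("annotate", annotate_candidates(candidates, ann))
    evaluation <- glance(annotated)
  }

  result <- structure(list(corpus = corpus, model = model, similar = similar,
                           candidates = candidates, annotated = annotated,
                           evaluation = evaluation,
                           config = list(target = entity_token(config$target),
                                         k = k, train = tc)),
                      class = "lwas_result")
  if (!is.null(config$out)) {
    write_pipeline_result(result, config$out)
  }
  result
}

write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(result$corpus, file.path(dir, "sentences.txt"))
  write_embedding(result$model, file.path(dir, "vectors.tsv"))
  readr::write_tsv(as_tibble(result$similar),
                   file.path(dir, "similar_diseases.tsv"))
  flat <- mutate(as_tibble(result$candidates),
                 supporting_diseases = vapply(
                   .data$supporting_diseases,
                   function(s) paste(s$disease_id, collapse = ";"),
                   character(1)))
  readr::write_tsv(flat, file.path(dir, "candidates.tsv"))
  if (!is.null(result$evaluation)) {
    jsonlite::write_json(as.list(result$evaluation),
                         file.path(dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  log <- list(target = result$config$target, k = result$config$k,
              train = unclass(result$config$train),
              n_sentences = attr(result$corpus, "n_sentences"),
              n_tokens = attr(result$corpus, "n_tokens"),
              vocab_size = nrow(result$model$vocab),
              n_similar = nrow(result$similar),
              n_candidates = nrow(result$candidates))
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.lwas_result <- function(x, ...) {
  cat(sprintf("<lwas_result> target %s, k = %d: %d similar diseases -> %d candidate drugs\n",
              x$config$target, x$config$k, nrow(x$similar),
              nrow(x$candidates)))
  invisible(x)
}

#' @export
tidy.lwas_result <- function(x, ...) {
  as_tibble(x$annotated %||% x$candidates)
}

#' @export
glance.lwas_result <- function(x, ...) {
  base <- tibble(target = x$config$target, k = x$config$k,
                 vocab_size = nrow(x$model$vocab),
                 n_similar = nrow(x$similar),
                 n_candidates = nrow(x$candidates))
  if (!is.null(x$evaluation)) {
    base <- dplyr::bind_cols(base, select(x$evaluation, -"n_candidates"))
  }
  base
}
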