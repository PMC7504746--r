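#' Configuration for the planted-world corpus generator
#'
#' The generator emulates the co-occurrence structure the repurposing method
#' relies on: diseases of one group share a theme vocabulary at the sentence
#' level, and each disease's drugs are mentioned in the same abstracts, so a
#' faithful embedding should place group-mates close together. Defaults
#' define the standard validation world: 10 groups x 3 diseases x 2 drugs,
#' 2,000 abstracts of 4-8 sentences, with theme words dominating sentence
#' content (p = 0.5) over disease (0.2) and drug (0.1) mentions against a
#' 500-token background vocabulary.
#'
#' @param n_groups Number of disease groups.
#' @param diseases_per_group Diseases per group (>= 2 for recovery tests).
#' @param drugs_per_disease Known drugs per disease.
#' @param n_abstracts Number of abstracts to generate.
#' @param sentences_per_abstract Length-2 integer range (min, max).
#' @param theme_pool_size Theme words per group.
#' @param background_vocab_size Shared background token pool size.
#' @param p_theme_word,p_disease_mention,p_drug_mention Per-position
#'   probabilities of drawing a theme word, a disease mention, or a drug
#'   mention; the remainder draws a background token. Must sum to <= 1.
#' @param seed Integer seed; world and abstracts are deterministic given it.
#' @return A `lwas_generator_config` list.
#' @export
generator_config <- function(n_groups = 10L, diseases_per_group = 3L,
                             drugs_per_disease = 2L, n_abstracts = 2000L,
                             sentences_per_abstract = c(4L, 8L),
                             theme_pool_size = 8L,
                             background_vocab_size = 500L,
                             p_theme_word = 0.5, p_disease_mention = 0.2,
                             p_drug_mention = 0.1, seed = 1L) {
  config <- list(n_groups = as.integer(n_groups),
                 diseases_per_group = as.integer(diseases_per_group),
                 drugs_per_disease = as.integer(drugs_per_disease),
                 n_abstracts = as.integer(n_abstracts),
                 sentences_per_abstract = as.integer(sentences_per_abstract),
                 theme_pool_size = as.integer(theme_pool_size),
                 background_vocab_size = as.integer(background_vocab_size),
                 p_theme_word = p_theme_word,
                 p_disease_mention = p_disease_mention,
                 p_drug_mention = p_drug_mention,
                 seed = as.integer(seed))
  counts <- unlist(config[c("n_groups", "diseases_per_group",
                            "drugs_per_disease", "n_abstracts",
                            "theme_pool_size", "background_vocab_size")])
  if (any(counts < 1L)) {
    abort("all generator counts must be >= 1", class = "lwas_config_error")
  }
  if (length(config$sentences_per_abstract) != 2L ||
      any(config$sentences_per_abstract < 1L) ||
      diff(config$sentences_per_abstract) < 0L) {
    abort("sentences_per_abstract must be an increasing (min, max) range",
          class = "lwas_config_error")
  }
  probs <- c(config$p_theme_word, config$p_disease_mention,
             config$p_drug_mention)
  if (any(probs < 0) || any(probs > 1) || sum(probs) > 1) {
    abort("mention probabilities must lie in [0,1] and sum to at most 1",
          class = "lwas_config_error")
  }
  structure(config, class = "lwas_generator_config")
}

# disease surface-name patterns cycling 1-, 2- and 3-word forms so every
# world exercises multiword hyphenation
disease_surface <- function(group, j) {
  code <- sprintf("G%02d%s", group, LETTERS[(j - 1L) %% 26L + 1L])
  switch((j - 1L) %% 3L + 1L,
         sprintf("%s syndrome", code),
         sprintf("%s storiform disease", code),
         sprintf("chronic %s lesion", code))
}

#' Generate a planted world of disease groups and drugs
#'
#' Builds the ground-truth structure the synthetic corpus is sampled from:
#' disease groups with 1-3-word disease names, per-disease drugs (one drug
#' is shared between the first diseases of groups 1 and 2 when possible, to
#' exercise candidate deduplication), per-group theme vocabularies, a
#' background token pool, and the matching entity lexicon and reference
#' pair table.
#'
#' @param config A [generator_config()].
#' @return A `lwas_world` list with elements `diseases` (tibble: `group_id`,
#'   `disease_id`, `disease_name`, `token`), `drugs` (tibble: `drug_id`,
#'   `drug_name`, `token`, `disease_id`, `group_id`), `themes` (list of
#'   token vectors by group), `background` (character), `lexicon`, `pairs`
#'   (reference-pair tibble) and `config`.
#' @export
generate_world <- function(config = generator_config()) {
  stopifnot(inherits(config, "lwas_generator_config"))
  G <- config$n_groups
  J <- config$diseases_per_group
  D <- config$drugs_per_disease

  diseases <- bind_rows(lapply(seq_len(G), function(g) {
    tibble(group_id = g, j = seq_len(J),
           disease_id = sprintf("H9%02d%02d", g, seq_len(J)),
           disease_name = vapply(seq_len(J), disease_surface, character(1),
                                 group = g))
  }))
  diseases$token <- entity_token(diseases$disease_name)

  drugs <- bind_rows(lapply(seq_len(nrow(diseases)), function(i) {
    g <- diseases$group_id[i]
    j <- diseases$j[i]
    name <- vapply(seq_len(D), function(d) {
      if (g == 1L && j == 1L && d == 1L) {
        sprintf("compound X%02d", d)  # a multiword drug name
      } else {
        sprintf("drg%02d%02d%02d", g, j, d)
      }
    }, character(1))
    tibble(group_id = g, disease_id = diseases$disease_id[i],
           drug_name = name,
           drug_id = sprintf("DB9%02d%01d%01d", g, j, seq_len(D)))
  }))
  # share one drug between groups 1 and 2 (same drug, two indications)
  if (G >= 2L && J >= 1L) {
    donor <- which(drugs$group_id == 1L)[1L]
    recip <- which(drugs$group_id == 2L)[1L]
    drugs$drug_name[recip] <- drugs$drug_name[donor]
    drugs$drug_id[recip] <- drugs$drug_id[donor]
  }
  drugs$token <- entity_token(drugs$drug_name)

  themes <- lapply(seq_len(G), function(g) {
    sprintf("thm%02dw%02d", g, seq_len(config$theme_pool_size))
  })
  background <- sprintf("bkg%04d", seq_len(config$background_vocab_size))

  lexicon <- as_lexicon(bind_rows(
    tibble(surface_form = diseases$disease_name,
           canonical_id = diseases$disease_id, entity_type = "disease"),
    distinct(tibble(surface_form = drugs$drug_name,
                    canonical_id = drugs$drug_id, entity_type = "drug"))))
  pairs <- tibble(drug_id = drugs$drug_id, drug_name = drugs$drug_name,
                  disease_id = drugs$disease_id,
                  disease_name = diseases$disease_name[
                    match(drugs$disease_id, diseases$disease_id)],
                  source = "other")

  structure(list(diseases = select(diseases, -"j"), drugs = drugs,
                 themes = themes, background = background,
                 lexicon = lexicon, pairs = pairs, config = config),
            class = "lwas_world")
}

#' @export
print.lwas_world <- function(x, ...) {
  cat(sprintf("<lwas_world> %d groups x %d diseases x %d drugs (%d unique drugs)\n",
              x$config$n_groups, x$config$diseases_per_group,
              x$config$drugs_per_disease, dplyr::n_distinct(x$drugs$drug_id)))
  invisible(x)
}

#' Sample synthetic abstracts from a planted world
#'
#' Each abstract is assigned one disease group; every sentence position then
#' draws a theme word, a disease mention, a drug mention (of that group) or
#' a background token at the configured probabilities. Same-group diseases
#' therefore share context distributions, which is exactly the signal the
#' embedding is expected to recover. With `shuffle_groups = TRUE` the
#' disease-to-group assignment is randomly permuted before sampling (drugs
#' follow their disease), destroying the planted association — the null
#' control for recovery tests.
#'
#' @param world A `lwas_world` from [generate_world()].
#' @param config A [generator_config()] (defaults to the world's own).
#' @param shuffle_groups Permute disease group labels (null control).
#' @return Tibble of raw documents: `doc_id`, `text`, plus the sampled
#'   `group_id` per abstract.
#' @export
generate_abstracts <- function(world, config = world$config,
                               shuffle_groups = FALSE) {
  stopifnot(inherits(world, "lwas_world"))
  G <- config$n_groups
  diseases <- world$diseases
  drugs <- world$drugs
  with_local_seed(config$seed, {
    if (shuffle_groups) {
      perm <- sample(diseases$group_id)
      diseases$group_id <- perm
      drugs$group_id <- perm[match(drugs$disease_id, diseases$disease_id)]
    }
    disease_by_group <- split(diseases$disease_name, diseases$group_id)
    drug_by_group <- split(drugs$drug_name, drugs$group_id)
    smin <- config$sentences_per_abstract[1L]
    smax <- config$sentences_per_abstract[2L]
    probs <- c(config$p_theme_word, config$p_disease_mention,
               config$p_drug_mention)
    p_bkg <- max(0, 1 - sum(probs))

    texts <- character(config$n_abstracts)
    groups <- integer(config$n_abstracts)
    for (a in seq_len(config$n_abstracts)) {
      g <- sample.int(G, 1L)
      groups[a] <- g
      n_sent <- smin + sample.int(smax - smin + 1L, 1L) - 1L
      sents <- vapply(seq_len(n_sent), function(s) {
        n_tok <- sample(8:14, 1L)
        cat_draw <- sample.int(4L, n_tok, replace = TRUE,
                               prob = c(probs, p_bkg))
        words <- character(n_tok)
        for (ti in seq_len(n_tok)) {
          words[ti] <- switch(cat_draw[ti],
            sample(world$themes[[g]], 1L),
            sample(disease_by_group[[as.character(g)]], 1L),
            sample(drug_by_group[[as.character(g)]], 1L),
            sample(world$background, 1L))
        }
        paste(words, collapse = " ")
      }, character(1))
      texts[a] <- paste0(paste(sents, collapse = ". "), ".")
    }
    tibble(doc_id = sprintf("doc%05d", seq_len(config$n_abstracts)),
           text = texts, group_id = groups)
  })
}

#' Planted ground truth for a target disease
#'
#' `true_group_mates()` returns the tokens of the other diseases in the
#' target's group; `true_group_drugs()` the drug ids known for those
#' group-mates — the sets a perfect recovery of the planted structure would
#' return.
#'
#' @param world A `lwas_world`.
#' @param target_token A disease token from the world.
#' @return Character vector of tokens (mates) or drug ids.
#' @export
true_group_mates <- function(world, target_token) {
  d <- world$diseases
  g <- d$group_id[d$token == target_token]
  if (length(g) != 1L) {
    abort(paste0("unknown planted disease token: ", target_token))
  }
  setdiff(d$token[d$group_id == g], target_token)
}

#' @rdname true_group_mates
#' @export
true_group_drugs <- function(world, target_token) {
  d <- world$diseases
  g <- d$group_id[d$token == target_token]
  if (length(g) != 1L) {
    abort(paste0("unknown planted disease token: ", target_token))
  }
  mates <- setdiff(d$disease_id[d$group_id == g],
                   d$disease_id[d$token == target_token])
  unique(world$drugs$drug_id[world$drugs$disease_id %in% mates])
}

#' Set precision and recall of a prediction against planted truth
#'
#' @param predicted Character vector of predicted identifiers (or tokens).
#' @param truth Non-empty character vector of true identifiers.
#' @return One-row tibble with `precision` and `recall` (precision is 0 for
#'   an empty prediction).
#' @examples
#' evaluate_recovery(c("a", "b", "x"), c("a", "b", "c", "d"))
#' @export
evaluate_recovery <- function(predicted, truth) {
  truth <- unique(truth)
  if (length(truth) == 0L) {
    abort("truth set is empty")
  }
  predicted <- unique(predicted)
  tp <- length(intersect(predicted, truth))
  tibble(precision = if (length(predicted) == 0L) 0 else tp / length(predicted),
         recall = tp / length(truth))
}

#' Write a planted world to plain-text files
#'
#' Writes `documents.tsv` (doc_id, text), `lexicon.tsv`, `pairs.tsv` and
#' `truth.json` (group structure) under `dir`.
#'
#' @param world A `lwas_world`.
#' @param docs Abstracts from [generate_abstracts()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, docs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(select(docs, "doc_id", "text"),
                   file.path(dir, "documents.tsv"))
  readr::write_tsv(select(world$lexicon, "surface_form", "canonical_id",
                          "entity_type"),
                   file.path(dir, "lexicon.tsv"))
  readr::write_tsv(world$pairs, file.path(dir, "pairs.tsv"))
  truth <- list(
    groups = split(world$diseases$disease_id, world$diseases$group_id),
    drug_pairs = setNames(as.list(world$drugs$disease_id),
                          world$drugs$drug_id))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = FALSE)
  invisible(dir)
}
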