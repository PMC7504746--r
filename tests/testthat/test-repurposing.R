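table1_refset <- function() read_reference_pairs(lwas_example("table1_pairs.tsv"))

test_that("the 18 similar diseases yield exactly the 24 unique known drugs", {
  refset <- table1_refset()
  similar <- tibble::tibble(disease_id = unique(refset$disease_id),
                            similarity = seq(0.99, 0.8,
                                             length.out = 18))
  cand <- propose_drugs(similar, refset)
  expect_identical(nrow(cand), 24L)
  expect_setequal(cand$drug_id, unique(refset$drug_id))
  # deduplication can only shrink the union of per-disease drug lists
  expect_lte(nrow(cand), nrow(refset))
  # provenance: every candidate is reachable from a similar disease
  for (i in seq_len(nrow(cand))) {
    support <- cand$supporting_diseases[[i]]
    expect_gte(nrow(support), 1L)
    expect_true(all(support$disease_id %in% similar$disease_id))
    for (d in support$disease_id) {
      expect_true(cand$drug_id[i] %in% drugs_for_disease(refset, d)$drug_id)
    }
  }
})

test_that("a single similar disease proposes exactly its own drugs", {
  refset <- table1_refset()
  cand <- propose_drugs(tibble::tibble(disease_id = "H01554",
                                       similarity = 0.9), refset)
  expect_setequal(cand$drug_name, c("carboplatin", "paclitaxel"))
  empty <- propose_drugs(tibble::tibble(disease_id = character(),
                                        similarity = numeric()), refset)
  expect_identical(nrow(empty), 0L)
})

test_that("rank_score aggregates supporting similarities as documented", {
  refset <- table1_refset()
  # carboplatin is supported by several diseases; its score is the max
  similar <- tibble::tibble(disease_id = c("H01665", "H01554", "H01513"),
                            similarity = c(0.95, 0.85, 0.75))
  cand <- propose_drugs(similar, refset)
  carbo <- cand[cand$drug_name == "carboplatin", ]
  expect_equal(carbo$rank_score, 0.95)
  expect_identical(carbo$n_support, 3L)
  mean_cand <- propose_drugs(similar, refset, score = "mean")
  expect_equal(mean_cand$rank_score[mean_cand$drug_name == "carboplatin"],
               mean(c(0.95, 0.85, 0.75)))
  # equal scores fall back to alphabetical drug names
  tied <- propose_drugs(tibble::tibble(disease_id = "H01556",
                                       similarity = 0.5), refset)
  expect_identical(tied$drug_name, sort(tied$drug_name))
})

test_that("candidate sets are monotone in the neighborhood size k", {
  fit <- fit_tiny_world(seed = 15, n_groups = 4, n_abstracts = 200, dim = 20,
                        epochs = 4)
  refset <- filter_to_vocabulary(as_refset(fit$world$pairs), fit$model,
                                 fit$world$lexicon)
  target <- fit$world$diseases$token[1]
  prev <- character()
  for (k in c(1, 3, 5, 8)) {
    sim <- similar_diseases(fit$model, target, fit$world$diseases$token,
                            k = k, lexicon = fit$world$lexicon)
    cand <- propose_drugs(sim, refset)
    expect_true(all(prev %in% cand$drug_id))
    prev <- cand$drug_id
  }
})

test_that("synonyms of the target are excluded from its similar diseases", {
  fit <- fit_tiny_world(seed = 18, n_groups = 3, n_abstracts = 80, dim = 12,
                        epochs = 3)
  target <- fit$world$diseases$token[1]
  # alias the second disease to the target's canonical id: it becomes a
  # synonym surface form and must no longer be returned as "similar"
  lex <- fit$world$lexicon
  synonym_token <- fit$world$diseases$token[2]
  lex$canonical_id[lex$token == synonym_token] <-
    fit$world$diseases$disease_id[1]
  sim <- similar_diseases(fit$model, target, fit$world$diseases$token,
                          k = 50, lexicon = lex)
  expect_false(target %in% sim$disease_token)
  expect_false(synonym_token %in% sim$disease_token)
  expect_true(synonym_token %in%
                similar_diseases(fit$model, target,
                                 fit$world$diseases$token, k = 50,
                                 lexicon = fit$world$lexicon)$disease_token)
  # small pools return what exists
  sim3 <- similar_diseases(fit$model, target,
                           fit$world$diseases$token[1:3], k = 10,
                           lexicon = fit$world$lexicon)
  expect_identical(nrow(sim3), 2L)
  expect_error(similar_diseases(fit$model, "ABSENT-DISEASE",
                                fit$world$diseases$token, k = 2),
               class = "lwas_missing_term")
})

test_that("annotation evaluation reproduces the literature-review counts", {
  refset <- table1_refset()
  similar <- tibble::tibble(disease_id = unique(refset$disease_id),
                            similarity = 0.9)
  cand <- propose_drugs(similar, refset)
  ann <- read_annotations(lwas_example("table3_annotations.tsv"))
  annotated <- annotate_candidates(cand, ann)
  counts <- glance(annotated)
  expect_identical(counts$n_candidates, 24L)
  expect_identical(counts$n_pubmed_supported, 19L)
  expect_identical(counts$n_clinicaltrials, 11L)
  expect_identical(counts$n_novel, 4L)
  expect_setequal(annotated$drug_name[annotated$novel],
                  c("cytarabine", "dacarbazine", "hydroxyurea", "topotecan"))
  # counts are invariant to candidate order
  reordered <- annotate_candidates(cand[rev(seq_len(nrow(cand))), ], ann)
  expect_identical(glance(reordered), counts)
  expect_identical(evaluation_counts(annotated), counts)
})

test_that("annotation joins are strict about duplicates and log missing rows", {
  cand <- propose_drugs(tibble::tibble(disease_id = "H01556",
                                       similarity = 0.7), table1_refset())
  dup <- tibble::tibble(drug_name = c("imatinib", "Imatinib", "octreotide"),
                        pubmed = c(TRUE, TRUE, FALSE),
                        clinicaltrials = c(FALSE, TRUE, FALSE))
  expect_error(annotate_candidates(cand, dup),
               class = "lwas_annotation_error")
  partial <- tibble::tibble(drug_name = "imatinib", pubmed = TRUE,
                            clinicaltrials = FALSE)
  expect_message(annotated <- annotate_candidates(cand, partial),
                 "no annotation row")
  expect_identical(glance(annotated)$n_novel, 2L)
})

test_that("the pipeline is deterministic and composes its stages", {
  world <- generate_world(generator_config(n_groups = 4, n_abstracts = 150,
                                           seed = 21))
  docs <- generate_abstracts(world, world$config)
  target <- world$diseases$disease_name[1]
  config <- list(docs = docs, lexicon = world$lexicon, pairs = world$pairs,
                 target = target, k = 2,
                 train = train_config(dim = 20, epochs = 3, seed = 21))
  res1 <- run_pipeline(config)
  res2 <- run_pipeline(config)
  expect_identical(res1$candidates, res2$candidates)
  expect_identical(res1$similar, res2$similar)

  # stagewise composition oracle
  corpus <- build_corpus(docs, world$lexicon)
  model <- train_embeddings(corpus, config$train)
  refset_v <- filter_to_vocabulary(as_refset(world$pairs), model,
                                   world$lexicon)
  sim <- similar_diseases(model, target, unique(refset_v$disease_token),
                          k = 2, lexicon = world$lexicon)
  cand <- propose_drugs(sim, refset_v)
  expect_identical(res1$candidates$drug_id, cand$drug_id)
  expect_equal(res1$candidates$rank_score, cand$rank_score)
})

test_that("the pipeline reports missing configuration and failing stages", {
  world <- generate_world(generator_config(n_groups = 3, n_abstracts = 20,
                                           seed = 2))
  docs <- generate_abstracts(world, world$config)
  config <- list(docs = docs, pairs = world$pairs,
                 target = world$diseases$disease_name[1])
  expect_error(run_pipeline(config), "lexicon", class = "lwas_config_error")
  bad <- list(docs = docs, lexicon = world$lexicon, pairs = world$pairs,
              target = "no such disease")
  err <- tryCatch(run_pipeline(bad), error = identity)
  expect_s3_class(err, "lwas_pipeline_error")
  expect_match(conditionMessage(err), "similar_diseases")
})

test_that("pipeline artifacts are written as plain text", {
  world <- generate_world(generator_config(n_groups = 3, n_abstracts = 60,
                                           seed = 6))
  docs <- generate_abstracts(world, world$config)
  out <- withr::local_tempdir()
  res <- run_pipeline(list(docs = docs, lexicon = world$lexicon,
                           pairs = world$pairs,
                           target = world$diseases$disease_name[1], k = 2,
                           train = train_config(dim = 10, epochs = 2,
                                                seed = 6),
                           out = out))
  expect_true(all(file.exists(file.path(out, c(
    "sentences.txt", "vectors.tsv", "similar_diseases.tsv",
    "candidates.tsv", "run_log.json")))))
  log <- jsonlite::read_json(file.path(out, "run_log.json"))
  expect_equal(log$n_candidates, nrow(res$candidates))
  expect_s3_class(tidy(res), "tbl_df")
  expect_s3_class(glance(res), "tbl_df")
})

test_that("a similarity threshold trims the neighborhood", {
  fit <- fit_tiny_world(seed = 25, n_groups = 3, n_abstracts = 80, dim = 12,
                        epochs = 3)
  target <- fit$world$diseases$token[1]
  all_sim <- similar_diseases(fit$model, target, fit$world$diseases$token,
                              k = 50, lexicon = fit$world$lexicon)
  cut <- stats::median(all_sim$similarity)
  trimmed <- similar_diseases(fit$model, target, fit$world$diseases$token,
                              k = 50, lexicon = fit$world$lexicon,
                              min_similarity = cut)
  expect_true(all(trimmed$similarity >= cut))
  expect_identical(trimmed$disease_token,
                   all_sim$disease_token[all_sim$similarity >= cut])
})
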