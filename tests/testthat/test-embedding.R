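make_corpus <- function(sentences) {
  df <- tibble::tibble(doc_id = "d", sentence_id = seq_along(sentences),
                       tokens = lapply(sentences, function(s) strsplit(s, " ")[[1]]))
  lwas:::new_corpus(df)
}

test_that("vocabulary counts match a brute-force tally and honor min_count", {
  corpus <- make_corpus(c("A A B", "A C", "C C"))
  v1 <- build_vocabulary(corpus, min_count = 1)
  expect_setequal(v1$token, c("A", "B", "C"))
  v2 <- build_vocabulary(corpus, min_count = 2)
  expect_setequal(v2$token, c("A", "C"))

  set.seed(31)
  sents <- replicate(50, paste(sample(LETTERS[1:8], sample(2:10, 1),
                                      replace = TRUE), collapse = " "))
  corpus <- make_corpus(sents)
  vocab <- build_vocabulary(corpus)
  tally <- table(unlist(strsplit(sents, " ")))
  expect_identical(setNames(vocab$count, vocab$token)[names(tally)],
                   setNames(as.integer(tally), names(tally)))
  # indices are dense, most frequent first
  expect_identical(vocab$index, seq_len(nrow(vocab)))
  expect_true(all(diff(vocab$count) <= 0))

  empty <- make_corpus(character())
  expect_error(build_vocabulary(empty), "empty corpus")
})

test_that("analytic gradients match central differences for both architectures", {
  set.seed(99)
  V <- 5L; dim <- 4L
  input <- matrix(rnorm(V * dim, sd = 0.5), V, dim)
  context <- matrix(rnorm(V * dim, sd = 0.5), V, dim)
  cases <- expand.grid(arch = c("cbow", "skipgram"), n_neg = c(1L, 5L),
                       stringsAsFactors = FALSE)
  for (case in seq_len(nrow(cases))) {
    arch <- cases$arch[case]
    negs <- sample(V, cases$n_neg[case], replace = TRUE)
    got <- ns_loss_grad(input, context, center = 2L, context_idx = c(1L, 3L, 4L),
                        negative_idx = negs, architecture = arch)
    expect_equal(got$loss,
                 r_ns_loss(input, context, 2L, c(1L, 3L, 4L), negs, arch),
                 tolerance = 1e-10)
    for (which in c("input", "context")) {
      num <- numeric_gradient(which, input, context, 2L, c(1L, 3L, 4L),
                              negs, arch)
      ana <- if (which == "input") got$grad_input else got$grad_context
      rel <- max(abs(ana - num)) / max(max(abs(num)), 1e-8)
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("training is deterministic and produces finite vectors", {
  corpus <- make_corpus(c("ONLY ONE SENTENCE HERE"))
  m <- train_embeddings(corpus, train_config(dim = 6, epochs = 1, seed = 2))
  expect_true(all(is.finite(m$input)))
  expect_identical(dim(m$input), c(4L, 6L))

  fit <- fit_tiny_world(seed = 4, n_groups = 3, n_abstracts = 60, dim = 12,
                        epochs = 2)
  again <- train_embeddings(fit$corpus, train_config(dim = 12, epochs = 2,
                                                     seed = 4))
  expect_identical(fit$model$input, again$input)
  expect_identical(fit$model$context, again$context)
  other_seed <- train_embeddings(fit$corpus, train_config(dim = 12, epochs = 2,
                                                          seed = 5))
  expect_false(identical(fit$model$input, other_seed$input))
})

test_that("training lowers the negative-sampling objective", {
  for (arch in c("cbow", "skipgram")) {
    fit <- fit_tiny_world(seed = 8, n_groups = 3, n_abstracts = 80, dim = 16,
                          epochs = 3)
    model <- train_embeddings(fit$corpus,
                              train_config(dim = 16, epochs = 3, seed = 8,
                                           architecture = arch))
    untrained <- model
    set.seed(8)
    untrained$input <- matrix(runif(length(model$input), -0.5, 0.5) / 16,
                              nrow(model$input), ncol(model$input),
                              dimnames = dimnames(model$input))
    untrained$context <- matrix(0, nrow(model$context), ncol(model$context),
                                dimnames = dimnames(model$context))
    expect_lt(embedding_mean_loss(model, fit$corpus, seed = 123),
              embedding_mean_loss(untrained, fit$corpus, seed = 123))
  }
})

test_that("tokens with identical contexts embed closer than unrelated tokens", {
  # A and B always appear in the same contexts; Z lives in a disjoint pool
  set.seed(20)
  ctx <- sprintf("CTX%02d", 1:10)
  far <- sprintf("FAR%02d", 1:10)
  sents <- c(
    replicate(150, paste(c(sample(c("A", "B"), 1), sample(ctx, 4)), collapse = " ")),
    replicate(150, paste(c("Z", sample(far, 4)), collapse = " ")))
  corpus <- make_corpus(sample(sents))
  hits <- 0L
  for (seed in 1:20) {
    m <- train_embeddings(corpus, train_config(dim = 16, epochs = 5,
                                               seed = seed, subsample = 0))
    ab <- cosine_similarity(get_vector(m, "A"), get_vector(m, "B"))
    az <- cosine_similarity(get_vector(m, "A"), get_vector(m, "Z"))
    bz <- cosine_similarity(get_vector(m, "B"), get_vector(m, "Z"))
    if (ab > max(az, bz)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("vector lookup returns input rows and flags missing terms", {
  fit <- fit_tiny_world(seed = 6, n_groups = 3, n_abstracts = 50, dim = 10,
                        epochs = 2)
  tok <- fit$model$vocab$token[1]
  v <- get_vector(fit$model, tok)
  expect_length(v, 10L)
  expect_identical(unname(v), unname(fit$model$input[tok, ]))
  expect_error(get_vector(fit$model, "NOT-A-TOKEN"),
               class = "lwas_missing_term")
})

test_that("cosine similarity follows the formula and its invariances", {
  expect_equal(cosine_similarity(c(3, 1, 2), c(3, 1, 2)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 0.7071, tolerance = 1e-4)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), class = "lwas_zero_vector")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "equal length")
  set.seed(13)
  for (i in 1:20) {
    u <- rnorm(5); v <- rnorm(5)
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    expect_equal(cosine_similarity(a * u, b * v), cosine_similarity(u, v),
                 tolerance = 1e-12)
  }
})

test_that("nearest_neighbors equals a brute-force all-pairs sort", {
  fit <- fit_tiny_world(seed = 12, n_groups = 3, n_abstracts = 40, dim = 8,
                        epochs = 2)
  vocab <- fit$model$vocab$token[1:min(30, nrow(fit$model$vocab))]
  query <- vocab[5]
  got <- nearest_neighbors(fit$model, query, k = 10, restrict_to = vocab)
  # oracle: explicit pairwise cosines, sorted with the same tie rule
  sims <- vapply(setdiff(vocab, query), function(t) {
    cosine_similarity(get_vector(fit$model, query), get_vector(fit$model, t))
  }, numeric(1))
  ord <- order(-sims, names(sims), method = "radix")
  expect_identical(got$token, names(sims)[ord][1:10])
  expect_equal(got$similarity, unname(sims[ord][1:10]), tolerance = 1e-12)
  expect_false(query %in% got$token)
  # k larger than the pool returns everything, still sorted
  all_got <- nearest_neighbors(fit$model, query, k = 1000, restrict_to = vocab)
  expect_identical(nrow(all_got), length(vocab) - 1L)
  expect_error(nearest_neighbors(fit$model, "ABSENT", k = 3),
               class = "lwas_missing_term")
})

test_that("exact similarity ties break lexicographically", {
  model <- structure(list(
    vocab = tibble::tibble(token = c("Q", "B", "A", "C"), index = 1:4,
                           count = c(4L, 3L, 2L, 1L)),
    input = matrix(c(1, 0, 2, 0, 2, 0, 0, 1), 4, 2, byrow = TRUE,
                   dimnames = list(c("Q", "B", "A", "C"), NULL)),
    context = matrix(0, 4, 2), config = train_config(dim = 2)),
    class = "lwas_embedding")
  nn <- nearest_neighbors(model, "Q", k = 3)
  expect_identical(nn$token, c("A", "B", "C"))
})

test_that("an embedding model round-trips through its TSV format", {
  fit <- fit_tiny_world(seed = 9, n_groups = 3, n_abstracts = 30, dim = 7,
                        epochs = 2)
  path <- file.path(withr::local_tempdir(), "vectors.tsv")
  write_embedding(fit$model, path)
  back <- read_embedding(path)
  expect_equal(back$input, fit$model$input, tolerance = 1e-12)
  expect_equal(back$context, fit$model$context, tolerance = 1e-12)
  expect_identical(back$vocab$token, fit$model$vocab$token)
  expect_identical(back$config$dim, fit$model$config$dim)
})

test_that("train_config validates its arguments", {
  expect_error(train_config(dim = 0), "dim")
  expect_error(train_config(window = 0), "window")
  expect_error(train_config(negative = -1), "negative")
  expect_error(train_config(epochs = 0), "epochs")
  expect_s3_class(glance(fit_tiny_world(seed = 2, n_groups = 3,
                                        n_abstracts = 20, dim = 5,
                                        epochs = 1)$model), "tbl_df")
})
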