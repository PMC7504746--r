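#' Training configuration for the embedding model
#'
#' Bundles the hyperparameters of the shallow-network trainer. The defaults
#' are the study settings: 150-dimensional vectors, a symmetric window of 5,
#' every token embedded (`min_count = 1`), CBOW architecture, and a single
#' deterministic worker. Hyperparameters the protocol leaves open are fixed
#' at the ecosystem's conventional values and can be overridden: 5 negative
#' samples, 5 epochs, learning rate annealed linearly from 0.025 to 1e-4
#' over all training words, and frequency subsampling at threshold 1e-3.
#'
#' @param dim Vector dimensionality (>= 1).
#' @param window Maximum one-sided context window; the effective window per
#'   center word is drawn uniformly from `1..window`.
#' @param min_count Minimum corpus frequency for a token to be embedded.
#' @param architecture `"cbow"` (predict the center word from the averaged
#'   context) or `"skipgram"` (predict each context word from the center).
#' @param negative Number of negative (noise) samples per example, drawn from
#'   the unigram distribution raised to the 3/4 power.
#' @param epochs Number of passes over the corpus.
#' @param initial_lr,final_lr Linear learning-rate annealing endpoints.
#' @param subsample Frequency-subsampling threshold (0 disables).
#' @param seed Integer seed; training is bit-reproducible given the same
#'   corpus, configuration and seed.
#' @return A `lwas_train_config` list.
#' @export
train_config <- function(dim = 150L, window = 5L, min_count = 1L,
                         architecture = c("cbow", "skipgram"),
                         negative = 5L, epochs = 5L,
                         initial_lr = 0.025, final_lr = 1e-4,
                         subsample = 1e-3, seed = 1L) {
  architecture <- match.arg(architecture)
  config <- list(dim = as.integer(dim), window = as.integer(window),
                 min_count = as.integer(min_count),
                 architecture = architecture,
                 negative = as.integer(negative), epochs = as.integer(epochs),
                 initial_lr = initial_lr, final_lr = final_lr,
                 subsample = subsample, seed = as.integer(seed))
  if (config$dim < 1L) abort("dim must be >= 1")
  if (config$window < 1L) abort("window must be >= 1")
  if (config$negative < 0L) abort("negative must be >= 0")
  if (config$epochs < 1L) abort("epochs must be >= 1")
  if (config$min_count < 1L) abort("min_count must be >= 1")
  structure(config, class = "lwas_train_config")
}

#' Build the token vocabulary of a corpus
#'
#' Tallies token frequencies over all sentences and keeps tokens occurring at
#' least `min_count` times. Tokens are indexed densely, most frequent first
#' (ties broken lexicographically), the order the trainer and noise sampler
#' use.
#'
#' @param corpus A `lwas_corpus` (see [build_corpus()]).
#' @param min_count Minimum frequency to retain a token.
#' @return A tibble with columns `token`, `index` (1-based, dense), `count`.
#' @export
build_vocabulary <- function(corpus, min_count = 1L) {
  all_tokens <- unlist(corpus$tokens, use.names = FALSE)
  if (length(all_tokens) == 0L) {
    abort("empty corpus")
  }
  tab <- table(all_tokens)
  vocab <- tibble(token = names(tab), count = as.integer(tab))
  vocab <- vocab[vocab$count >= min_count, , drop = FALSE]
  ord <- order(-vocab$count, vocab$token, method = "radix")
  vocab <- vocab[ord, , drop = FALSE]
  vocab$index <- seq_len(nrow(vocab))
  vocab[, c("token", "index", "count")]
}

# map sentences to 0-based vocabulary indices, dropping unembedded tokens
corpus_to_ids <- function(corpus, vocab) {
  lookup <- setNames(vocab$index - 1L, vocab$token)
  lapply(corpus$tokens, function(toks) {
    ids <- lookup[toks]
    as.integer(ids[!is.na(ids)])
  })
}

#' Train word embeddings on a sentence corpus
#'
#' Learns dense vectors for every vocabulary token by stochastic gradient
#' descent on the negative-sampling objective, so that tokens sharing
#' sentence-level context receive similar vectors. Both CBOW and skip-gram
#' architectures are available; context windows never cross sentence
#' boundaries. Training is single-threaded and fully determined by
#' `(corpus, config)`.
#'
#' @param corpus A `lwas_corpus` (see [build_corpus()]).
#' @param config A [train_config()].
#' @return A `lwas_embedding` object: list with `vocab` (tibble), `input`
#'   and `context` (V x dim matrices, rows named by token) and `config`.
#' @examples
#' docs <- tibble::tibble(doc_id = "d1", text = "drug inhibits tumor growth.")
#' corpus <- build_corpus(docs)
#' model <- train_embeddings(corpus, train_config(dim = 8, epochs = 1))
#' glance(model)
#' @export
train_embeddings <- function(corpus, config = train_config()) {
  if (!inherits(config, "lwas_train_config")) {
    config <- do.call(train_config, as.list(config))
  }
  vocab <- build_vocabulary(corpus, config$min_count)
  sentences <- corpus_to_ids(corpus, vocab)
  fit <- w2v_train_cpp(sentences, vocab$count, config$dim, config$window,
                       config$negative, config$epochs, config$initial_lr,
                       config$final_lr, config$subsample,
                       config$architecture == "cbow", config$seed)
  input <- fit$input
  context <- fit$context
  rownames(input) <- rownames(context) <- vocab$token
  if (!all(is.finite(input)) || !all(is.finite(context))) {
    abort("training produced non-finite weights")
  }
  structure(list(vocab = vocab, input = input, context = context,
                 config = config),
            class = "lwas_embedding")
}

#' @export
print.lwas_embedding <- function(x, ...) {
  cat(sprintf("<lwas_embedding> %d tokens x %d dims (%s, window %d, %d epochs, seed %d)\n",
              nrow(x$vocab), x$config$dim, x$config$architecture,
              x$config$window, x$config$epochs, x$config$seed))
  invisible(x)
}

#' @export
tidy.lwas_embedding <- function(x, ...) {
  vecs <- lapply(seq_len(nrow(x$input)), function(i) unname(x$input[i, ]))
  mutate(x$vocab, vector = vecs)
}

#' @export
glance.lwas_embedding <- function(x, ...) {
  tibble(vocab_size = nrow(x$vocab), dim = x$config$dim,
         architecture = x$config$architecture, window = x$config$window,
         negative = x$config$negative, epochs = x$config$epochs,
         seed = x$config$seed)
}

#' Look up the embedding vector of a token
#'
#' @param model A `lwas_embedding`.
#' @param token A single token (the input-layer row is returned).
#' @return Numeric vector of length `model$config$dim`.
#' @export
get_vector <- function(model, token) {
  stopifnot(inherits(model, "lwas_embedding"), length(token) == 1L)
  if (!token %in% model$vocab$token) {
    abort(paste0("token '", token, "' is not in the embedding vocabulary"),
          class = "lwas_missing_term")
  }
  model$input[token, ]
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length; neither may be all zeros.
#' @return `sum(u * v) / (||u|| * ||v||)`, in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    abort("vectors must have equal length")
  }
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) {
    abort("cosine similarity is undefined for a zero vector",
          class = "lwas_zero_vector")
  }
  sum(u * v) / (nu * nv)
}

# cosine of one row against all (or a subset of) rows of the input matrix
cosine_to_all <- function(model, token, eligible = NULL) {
  q <- get_vector(model, token)
  M <- model$input
  if (!is.null(eligible)) {
    eligible <- intersect(eligible, rownames(M))
    M <- M[eligible, , drop = FALSE]
  }
  norms <- sqrt(rowSums(M * M))
  qn <- sqrt(sum(q * q))
  sims <- as.numeric(M %*% q) / (norms * qn)
  sims[norms == 0 | qn == 0] <- NA_real_
  setNames(sims, rownames(M))
}

#' Nearest neighbors of a token in the embedding space
#'
#' Ranks tokens by descending cosine similarity to the query (the query
#' itself is excluded), breaking ties lexicographically. `restrict_to`
#' limits the candidate pool, e.g. to disease tokens only.
#'
#' @param model A `lwas_embedding`.
#' @param token Query token (must be in the vocabulary).
#' @param k Number of neighbors (>= 1); fewer are returned when fewer are
#'   eligible.
#' @param restrict_to Optional character vector of eligible tokens.
#' @return A tibble with columns `token`, `similarity`, sorted descending.
#' @export
nearest_neighbors <- function(model, token, k, restrict_to = NULL) {
  stopifnot(k >= 1L)
  sims <- cosine_to_all(model, token, eligible = restrict_to)
  sims <- sims[names(sims) != token & !is.na(sims)]
  if (length(sims) == 0L) {
    return(tibble(token = character(), similarity = numeric()))
  }
  ord <- order(-sims, names(sims), method = "radix")
  out <- tibble(token = names(sims)[ord], similarity = unname(sims[ord]))
  slice_head(out, n = min(k, nrow(out)))
}

#' Negative-sampling loss and analytic gradient for one example
#'
#' Evaluates the per-example objective
#' `-log sigmoid(h . c_pos) - sum(log sigmoid(-h . c_neg))` and its exact
#' gradient with respect to every input and context vector, with the
#' negative samples supplied explicitly. `h` is the mean context input
#' vector (CBOW) or the center word's input vector (skip-gram, where the
#' loss sums over all context words). This mirrors the trainer's update rule
#' and exists so the gradient can be checked against finite differences.
#'
#' @param input,context V x dim weight matrices.
#' @param center 1-based row index of the center word.
#' @param context_idx 1-based indices of the context words.
#' @param negative_idx 1-based indices of the negative samples.
#' @param architecture `"cbow"` or `"skipgram"`.
#' @return List with `loss` (scalar), `grad_input`, `grad_context`
#'   (V x dim matrices).
#' @keywords internal
#' @export
ns_loss_grad <- function(input, context, center, context_idx, negative_idx,
                         architecture = c("cbow", "skipgram")) {
  architecture <- match.arg(architecture)
  w2v_loss_grad_cpp(input, context, as.integer(center - 1L),
                    as.integer(context_idx - 1L),
                    as.integer(negative_idx - 1L),
                    architecture == "cbow")
}

#' Mean negative-sampling loss of a model over a corpus
#'
#' Scores a model on the corpus with seeded dynamic windows and noise draws
#' (no subsampling), so two models scored with the same seed see identical
#' examples. Used to verify that training lowers the objective.
#'
#' @param model A `lwas_embedding`.
#' @param corpus The corpus to score on.
#' @param seed Seed for window and noise draws.
#' @return Mean per-example loss (scalar).
#' @keywords internal
#' @export
embedding_mean_loss <- function(model, corpus, seed = 1L) {
  sentences <- corpus_to_ids(corpus, model$vocab)
  w2v_mean_loss_cpp(model$input, model$context, sentences, model$vocab$count,
                    model$config$window, model$config$negative,
                    model$config$architecture == "cbow", as.integer(seed))
}

#' Embedding model input/output
#'
#' `write_embedding()` writes the input vectors as a TSV
#' (`token<TAB>v1 ... v_dim`), the context vectors to
#' `<stem>_context.tsv`, and a JSON sidecar `<stem>.json` holding the
#' configuration and vocabulary counts; doubles are written at full
#' round-trip precision. `read_embedding()` restores the model.
#'
#' @param model A `lwas_embedding`.
#' @param path Path of the vector TSV (e.g. `"vectors.tsv"`).
#' @return `write_embedding()` returns `path` invisibly; `read_embedding()`
#'   a `lwas_embedding`.
#' @export
write_embedding <- function(model, path) {
  stem <- sub("\\.tsv$", "", path)
  write_matrix <- function(M, p) {
    df <- as.data.frame(M)
    names(df) <- paste0("v", seq_len(ncol(M)))
    df <- cbind(token = rownames(M), df)
    readr::write_tsv(as_tibble(df), p)
  }
  write_matrix(model$input, path)
  write_matrix(model$context, paste0(stem, "_context.tsv"))
  meta <- list(config = unclass(model$config),
               vocab_size = nrow(model$vocab),
               counts = setNames(as.list(model$vocab$count), model$vocab$token))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  stem <- sub("\\.tsv$", "", path)
  read_matrix <- function(p) {
    df <- readr::read_tsv(p, col_types = readr::cols(
      token = readr::col_character(), .default = readr::col_double()))
    M <- as.matrix(df[, -1, drop = FALSE])
    rownames(M) <- df$token
    dimnames(M)[[2]] <- NULL
    M
  }
  input <- read_matrix(path)
  context <- read_matrix(paste0(stem, "_context.tsv"))
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  config <- do.call(train_config, meta$config)
  counts <- unlist(meta$counts)
  vocab <- tibble(token = names(counts), index = seq_along(counts),
                  count = as.integer(counts))
  stopifnot(identical(vocab$token, rownames(input)))
  structure(list(vocab = vocab, input = input, context = context,
                 config = config),
            class = "lwas_embedding")
}
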