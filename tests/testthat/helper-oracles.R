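# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (plain loops, explicit formulas) rather
# than calling the package code paths they check.

# negative-sampling loss written directly from the objective, for finite
# differencing against the package's analytic gradient
r_ns_loss <- function(input, context, center, context_idx, negative_idx,
                      architecture) {
  sigm <- function(x) 1 / (1 + exp(-x))
  if (architecture == "cbow") {
    h <- colMeans(input[context_idx, , drop = FALSE])
    loss <- -log(sigm(sum(h * context[center, ])))
    for (ni in negative_idx) {
      loss <- loss - log(sigm(-sum(h * context[ni, ])))
    }
    loss
  } else {
    loss <- 0
    v <- input[center, ]
    for (ci in context_idx) {
      loss <- loss - log(sigm(sum(v * context[ci, ])))
      for (ni in negative_idx) {
        loss <- loss - log(sigm(-sum(v * context[ni, ])))
      }
    }
    loss
  }
}

# central-difference gradient of r_ns_loss with respect to one weight matrix
numeric_gradient <- function(which, input, context, center, context_idx,
                             negative_idx, architecture, eps = 1e-6) {
  M <- if (which == "input") input else context
  G <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      up <- M; up[i, j] <- up[i, j] + eps
      dn <- M; dn[i, j] <- dn[i, j] - eps
      fu <- if (which == "input") {
        r_ns_loss(up, context, center, context_idx, negative_idx, architecture)
      } else {
        r_ns_loss(input, up, center, context_idx, negative_idx, architecture)
      }
      fd <- if (which == "input") {
        r_ns_loss(dn, context, center, context_idx, negative_idx, architecture)
      } else {
        r_ns_loss(input, dn, center, context_idx, negative_idx, architecture)
      }
      G[i, j] <- (fu - fd) / (2 * eps)
    }
  }
  G
}

# trustworthiness evaluated straight from its definition, one term at a time
oracle_trustworthiness <- function(high, low, k) {
  n <- nrow(high)
  total <- 0
  for (i in seq_len(n)) {
    dh <- sqrt(colSums((t(high) - high[i, ])^2))
    dl <- sqrt(colSums((t(low) - low[i, ])^2))
    others <- setdiff(seq_len(n), i)
    high_order <- others[order(dh[others])]
    low_order <- others[order(dl[others])]
    high_knn <- high_order[1:k]
    for (j in low_order[1:k]) {
      if (!(j %in% high_knn)) {
        total <- total + (which(high_order == j) - k)
      }
    }
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * total
}

# all tilings of a token sequence by lexicon entries (non-overlapping,
# left-to-right), each tiling expressed as the resulting token vector
enumerate_tilings <- function(tokens, entities) {
  if (length(tokens) == 0L) {
    return(list(character()))
  }
  out <- list()
  # leave the first token untouched
  for (rest in enumerate_tilings(tokens[-1L], entities)) {
    out <- c(out, list(c(tokens[1L], rest)))
  }
  # or consume an entity starting here
  for (e in entities) {
    L <- length(e)
    if (L >= 2L && L <= length(tokens) && all(tokens[1:L] == e)) {
      for (rest in enumerate_tilings(tokens[-(1:L)], entities)) {
        out <- c(out, list(c(paste(e, collapse = "-"), rest)))
      }
    }
  }
  out
}

# a small world + corpus + trained model, shared by several suites
fit_tiny_world <- function(seed = 1L, n_groups = 4L, n_abstracts = 400L,
                           dim = 30L, epochs = 5L) {
  cfg <- generator_config(n_groups = n_groups, n_abstracts = n_abstracts,
                          seed = seed)
  world <- generate_world(cfg)
  docs <- generate_abstracts(world, cfg)
  corpus <- build_corpus(docs, world$lexicon)
  model <- train_embeddings(corpus, train_config(dim = dim, epochs = epochs,
                                                 seed = seed))
  list(config = cfg, world = world, docs = docs, corpus = corpus,
       model = model)
}
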