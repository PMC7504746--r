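# run code under a fixed RNG seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Extract the vector matrix for a set of terms
#'
#' @param model A `lwas_embedding`.
#' @param terms Tokens to extract (all must be in the vocabulary).
#' @return A `length(terms)` x dim matrix with terms as row names.
#' @export
embedding_matrix <- function(model, terms) {
  missing_terms <- setdiff(terms, model$vocab$token)
  if (length(missing_terms)) {
    abort(paste0("token(s) not in the embedding vocabulary: ",
                 paste(head(missing_terms, 5), collapse = ", ")),
          class = "lwas_missing_term")
  }
  model$input[terms, , drop = FALSE]
}

#' Project term vectors to 2D with t-SNE
#'
#' Exact (non-approximate) t-Distributed Stochastic Neighbor Embedding:
#' per-point bandwidths are calibrated by bisection to the target
#' perplexity, the joint similarity matrix is symmetrized, and the layout is
#' optimized by gradient descent with momentum, adaptive gains and early
#' exaggeration. Initialization is the first two principal components
#' (scaled small, with a seeded jitter), which makes the layout reproducible
#' for a given input and seed. The 2D map is a visualization aid: distances
#' in it are not metrically faithful, and candidate selection in the
#' repurposing pipeline never depends on these coordinates.
#'
#' @param vectors Numeric matrix, one named row per term (>= 3 rows), or a
#'   named list of equal-length numeric vectors.
#' @param perplexity Target perplexity; must be `< nrow(vectors)`.
#' @param seed Integer seed for the jittered initialization.
#' @param iterations Gradient-descent iterations.
#' @return A `lwas_map`: tibble with columns `term`, `x`, `y`; the
#'   parameters are stored in `attr(map, "params")`.
#' @export
project_2d <- function(vectors, perplexity = 30, seed = 1L,
                       iterations = 1000L) {
  if (is.list(vectors) && !is.matrix(vectors)) {
    vectors <- do.call(rbind, vectors)
  }
  X <- as.matrix(vectors)
  n <- nrow(X)
  if (n < 3L) {
    abort("at least 3 terms are required for a 2D projection",
          class = "lwas_parameter_error")
  }
  if (is.null(rownames(X))) {
    abort("vectors must have term names")
  }
  if (perplexity >= n) {
    abort("perplexity must be smaller than the number of terms",
          class = "lwas_parameter_error")
  }

  P <- tsne_affinities(X, perplexity)
  Y <- with_local_seed(seed, {
    pcs <- prcomp(X, rank. = 2L, center = TRUE, scale. = FALSE)$x
    if (ncol(pcs) < 2L) pcs <- cbind(pcs, 0)
    init <- scale(pcs, center = TRUE, scale = FALSE)
    sds <- apply(init, 2, stats::sd)
    sds[sds == 0] <- 1
    sweep(init, 2, sds, "/") * 1e-4 + matrix(stats::rnorm(n * 2, sd = 1e-6), n, 2)
  })

  exaggeration_until <- min(250L, iterations %/% 4L)
  momentum_switch <- 250L
  eta <- 200
  gains <- matrix(1, n, 2)
  update <- matrix(0, n, 2)
  Pe <- P * 12  # early exaggeration

  for (it in seq_len(iterations)) {
    Pcur <- if (it <= exaggeration_until) Pe else P
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (Pcur - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (it <= momentum_switch) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(update), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    update <- momentum * update - eta * gains * grad
    Y <- Y + update
    Y <- sweep(Y, 2, colMeans(Y))
  }

  structure(tibble(term = rownames(X), x = unname(Y[, 1]),
                   y = unname(Y[, 2])),
            class = c("lwas_map", class(tibble())),
            params = list(perplexity = perplexity, seed = seed,
                          iterations = iterations))
}

# symmetrized joint affinities with per-point bandwidth matched to the
# target perplexity by bisection on the conditional-entropy
tsne_affinities <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    beta_lo <- 0
    beta_hi <- Inf
    beta <- 1
    for (iter in 1:64) {
      p <- exp(-d * beta)
      s <- sum(p)
      if (s == 0) {
        p <- rep(1 / length(d), length(d))
        s <- 1
        entropy <- log(length(d))
      } else {
        p <- p / s
        entropy <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(entropy - target) < tol) break
      if (entropy > target) {  # too flat: increase beta
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- (beta + beta_lo) / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  P
}

#' Neighborhood preservation of a 2D projection
#'
#' Rank-based trustworthiness: for each point, low-dimensional k-nearest
#' neighbors that are not also high-dimensional k-nearest neighbors are
#' penalized by how far down the high-dimensional ranking they sit. A score
#' of 1 means every 2D neighborhood is faithful; random layouts score
#' substantially lower.
#'
#' @param high Numeric matrix of high-dimensional vectors (named rows).
#' @param low A `lwas_map` from [project_2d()], or a 2-column matrix with
#'   the same row names.
#' @param k Neighborhood size; `1 <= k < n/2`.
#' @return Scalar in `[0, 1]`.
#' @export
trustworthiness <- function(high, low, k) {
  high <- as.matrix(high)
  if (inherits(low, "lwas_map") || is.data.frame(low)) {
    Ylow <- as.matrix(low[, c("x", "y")])
    rownames(Ylow) <- low$term
  } else {
    Ylow <- as.matrix(low)
  }
  n <- nrow(high)
  if (!setequal(rownames(high), rownames(Ylow)) || n != nrow(Ylow)) {
    abort("high- and low-dimensional spaces must contain the same terms")
  }
  Ylow <- Ylow[rownames(high), , drop = FALSE]
  if (k < 1 || k >= n / 2) {
    abort("k must satisfy 1 <= k < n/2", class = "lwas_parameter_error")
  }
  Dh <- as.matrix(dist(high))
  Dl <- as.matrix(dist(Ylow))
  penalty <- 0
  for (i in seq_len(n)) {
    oh <- order(Dh[i, -i])            # high-dim neighbor order (1 = nearest)
    rank_high <- integer(n - 1)
    rank_high[oh] <- seq_len(n - 1)
    ol <- order(Dl[i, -i])
    low_knn <- ol[seq_len(k)]
    intruders <- low_knn[rank_high[low_knn] > k]
    penalty <- penalty + sum(rank_high[intruders] - k)
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * penalty
}

#' Attach entity metadata to a map and optionally write it out
#'
#' Joins the lexicon onto the layout by corpus token, yielding one row per
#' term with `term`, `x`, `y`, `entity_type`, `canonical_id`. Terms absent
#' from the lexicon get `NA` metadata.
#'
#' @param map A `lwas_map`.
#' @param lexicon An entity lexicon (see [read_lexicon()]).
#' @param path Optional TSV output path.
#' @param entity_type Optional filter (`"drug"` or `"disease"`).
#' @return The annotated tibble (invisibly if `path` is given).
#' @export
export_map <- function(map, lexicon, path = NULL, entity_type = NULL) {
  lex <- as_lexicon(lexicon)
  lex <- distinct(lex, .data$token, .keep_all = TRUE)
  out <- left_join(as_tibble(map),
                   select(lex, term = "token", "entity_type", "canonical_id"),
                   by = "term")
  if (!is.null(entity_type)) {
    type <- entity_type
    out <- filter(out, .data$entity_type %in% type)
  }
  if (!is.null(path)) {
    readr::write_tsv(out, path)
    return(invisible(out))
  }
  out
}

#' Terms within a Euclidean radius on a 2D map
#'
#' The "map mode" neighborhood: mimics reading a vicinity off the 2D
#' similarity map, returning all terms within `radius` of the target point
#' (target excluded), nearest first. Because 2D distances are not metrically
#' faithful, this mode is for comparison with the default cosine k-NN
#' neighborhood in the original space, not a replacement for it.
#'
#' @param map A `lwas_map`.
#' @param target A term present in the map.
#' @param radius Euclidean radius in map units.
#' @return Tibble with columns `term`, `distance`, ascending.
#' @export
map_neighbors <- function(map, target, radius) {
  if (!target %in% map$term) {
    abort(paste0("term '", target, "' is not on the map"),
          class = "lwas_missing_term")
  }
  stopifnot(radius > 0)
  p <- map[map$term == target, ]
  d <- sqrt((map$x - p$x)^2 + (map$y - p$y)^2)
  out <- tibble(term = map$term, distance = d)
  out <- out[out$term != target & out$distance <= radius, , drop = FALSE]
  arrange(out, .data$distance, .data$term)
}

#' Plot a 2D similarity map
#'
#' @param object A `lwas_map`.
#' @param lexicon Optional lexicon; when given, points are colored by entity
#'   type.
#' @param label Label points with their term names.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lwas_map <- function(object, lexicon = NULL, label = FALSE, ...) {
  df <- if (is.null(lexicon)) {
    mutate(as_tibble(object), entity_type = "term")
  } else {
    export_map(object, lexicon)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$entity_type)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = NULL) +
    ggplot2::theme_minimal()
  if (label) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$term),
                                size = 2.5, vjust = -0.6, show.legend = FALSE)
  }
  p
}
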