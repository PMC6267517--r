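# fixtures and independent oracles used across test files

# g well-separated directional clusters on the unit sphere: orthonormal
# center directions plus gaussian angular noise
make_directional_clusters <- function(g, per, d = 10, sigma = 0.1, seed = 1) {
  set.seed(seed)
  centers <- qr.Q(qr(matrix(stats::rnorm(d * g), d, g)))
  X <- do.call(rbind, lapply(seq_len(g), function(j) {
    sweep(matrix(stats::rnorm(per * d, sd = sigma), per, d), 2, centers[, j], "+")
  }))
  list(X = X, labels = rep(seq_len(g), each = per), centers = centers)
}

# unit vectors with a prescribed Gram (pairwise-cosine) matrix
vectors_with_cosines <- function(G) {
  t(chol(G))
}

# brute-force O(n^2) mean pairwise cosine
mean_pairwise_cosine_oracle <- function(V) {
  n <- nrow(V)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(V[i, ] * V[j, ]) /
        (sqrt(sum(V[i, ]^2)) * sqrt(sum(V[j, ]^2)))
    }
  }
  tot / (n * (n - 1) / 2)
}

# per-member within-group cosine distance, independent recomputation
within_oracle <- function(assignments, centroids, V) {
  tot <- 0
  for (i in seq_len(nrow(V))) {
    c_i <- centroids[assignments[i], ]
    tot <- tot + 1 - sum(V[i, ] * c_i) /
      (sqrt(sum(V[i, ]^2)) * sqrt(sum(c_i^2)))
  }
  tot / nrow(V)
}

# random orthogonal matrix
random_orthogonal <- function(d, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
}

# a tiny deterministic two-topic corpus for interface tests
tiny_corpus <- function(n_docs = 24, doc_len = 30, seed = 7) {
  set.seed(seed)
  vocA <- paste0("a", 1:12)
  vocB <- paste0("b", 1:12)
  docs <- lapply(seq_len(n_docs), function(i) {
    voc <- if (i %% 2 == 0) vocA else vocB
    sample(voc, doc_len, replace = TRUE)
  })
  as_tokenized_corpus(docs)
}

# agreement of a clustering with ground-truth labels up to relabeling
# (exact match required: every cluster maps to one label and vice versa)
matches_up_to_relabeling <- function(assign, labels) {
  tab <- table(assign, labels)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
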