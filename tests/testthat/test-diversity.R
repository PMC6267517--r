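# shared small matrix: 4 words x 6 contexts with known occurrence pattern
cs_fixture <- function() {
  cc <- chunk_documents(as_tokenized_corpus(list(
    c("a", "a", "b"), c("a", "c"), c("b", "c"), c("c", "c"), c("a", "b"),
    c("d", "d", "d", "d", "d")
  )), 150)
  voc <- build_vocabulary(cc, top_fraction = 0, min_count = 1)
  build_cooccurrence(cc, voc)
}

test_that("context sets keep all contexts under the cap and the busiest above it", {
  m <- cs_fixture()
  cs <- context_set(m, "a", cap = 2000)
  expect_equal(nrow(cs), 3)
  expect_equal(attr(cs, "n_total"), 3L)

  # above the cap: contexts with the highest per-context occurrence win,
  # ties broken by context order
  cs2 <- context_set(m, "a", cap = 2)
  expect_equal(nrow(cs2), 2)
  expect_equal(cs2$occ_count[1], 2L) # the a,a,b context has count 2
  expect_equal(attr(cs2, "n_total"), 3L)

  expect_error(context_set(m, "zzz"), "not in vocabulary")
})

test_that("contextual diversity counts contexts and logs in base 10", {
  m <- cs_fixture()
  cd <- contextual_diversity(m, c("a", "c", "d"))
  expect_equal(cd$cd, c(3L, 3L, 1L))
  expect_equal(cd$log_cd, c(log10(3), log10(3), 0))
})

test_that("adding one context with a word raises only that word's CD by one", {
  set.seed(21)
  docs <- lapply(1:15, function(i) sample(letters[1:6], 20, replace = TRUE))
  corp <- as_tokenized_corpus(docs)
  cc <- chunk_documents(corp, 150)
  voc <- build_vocabulary(cc, top_fraction = 0, min_count = 1)
  m1 <- build_cooccurrence(cc, voc)
  before <- contextual_diversity(m1)

  corp2 <- as_tokenized_corpus(c(docs, list(c("a", "a"))),
                               doc_ids = c(corp$doc_id, "extra"))
  m2 <- build_cooccurrence(chunk_documents(corp2, 150), voc)
  after <- contextual_diversity(m2)
  expect_equal(after$cd[after$word == "a"], before$cd[before$word == "a"] + 1L)
  other <- before$word != "a"
  expect_equal(after$cd[other], before$cd[other])
})

# a fake space whose context vectors are given directly; context ids are
# always c1..cn so fake_cs(ctx_ids(V)) matches
ctx_ids <- function(V) paste0("c", seq_len(nrow(V)))
space_from_vectors <- function(V, ids = ctx_ids(V)) {
  rownames(V) <- ids
  structure(list(word_vectors = NULL, context_vectors = V,
                 singular_values = rep(1, ncol(V)), d = ncol(V)),
            class = "semantic_space")
}

fake_cs <- function(ids, word = "w") {
  out <- tibble::tibble(context_id = ids, occ_count = 1L)
  attr(out, "word") <- word
  class(out) <- c("context_set", class(out))
  out
}

test_that("SemD follows -log10(mean pairwise cosine) on closed-form cases", {
  # identical vectors: mean cosine 1 -> SemD 0
  V <- matrix(rep(c(1, 2, 2), 4), 4, 3, byrow = TRUE)
  sp <- space_from_vectors(V)
  expect_equal(semantic_diversity(sp, fake_cs(ctx_ids(V))), 0,
               tolerance = 1e-12)

  # two contexts at cosine 0.1 -> SemD 1
  V2 <- vectors_with_cosines(matrix(c(1, .1, .1, 1), 2, 2))
  sp2 <- space_from_vectors(V2)
  expect_equal(semantic_diversity(sp2, fake_cs(ctx_ids(V2))), 1,
               tolerance = 1e-10)

  # three contexts with pairwise cosines .5, .2, .8 -> mean .5
  G <- matrix(c(1, .5, .2, .5, 1, .8, .2, .8, 1), 3, 3)
  V3 <- vectors_with_cosines(G)
  sp3 <- space_from_vectors(V3)
  expect_equal(semantic_diversity(sp3, fake_cs(ctx_ids(V3))), -log10(0.5),
               tolerance = 1e-10)
})

test_that("SemD equals the brute-force pairwise oracle", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(5:200, 1)
    d <- sample(3:20, 1)
    V <- matrix(stats::rnorm(n * d), n, d)
    sp <- space_from_vectors(V)
    got <- suppressWarnings(semantic_diversity(sp, fake_cs(ctx_ids(V))))
    mc <- mean_pairwise_cosine_oracle(V)
    if (mc <= 0) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, -log10(mc), tolerance = 1e-10)
    }
  }
})

test_that("SemD is invariant under rotation and uniform rescaling", {
  set.seed(14)
  V <- matrix(stats::rnorm(40 * 8), 40, 8) + 0.5
  sp <- space_from_vectors(V)
  base <- semantic_diversity(sp, fake_cs(ctx_ids(V)))
  Q <- random_orthogonal(8, seed = 2)
  expect_equal(semantic_diversity(space_from_vectors(V %*% Q), fake_cs(ctx_ids(V))),
               base, tolerance = 1e-10)
  expect_equal(semantic_diversity(space_from_vectors(V * 7.3), fake_cs(ctx_ids(V))),
               base, tolerance = 1e-10)
})

test_that("near-duplicate contexts score lower SemD than mutually dissimilar ones", {
  set.seed(4)
  tight <- matrix(rep(c(3, 1, 2, 1), each = 30), 30, 4) +
    matrix(stats::rnorm(120, sd = 0.01), 30, 4)
  spread <- make_directional_clusters(g = 4, per = 8, d = 4, sigma = 0.05,
                                      seed = 6)$X
  semd_tight <- semantic_diversity(space_from_vectors(tight),
                                   fake_cs(paste0("c", 1:30)))
  semd_spread <- semantic_diversity(space_from_vectors(spread),
                                    fake_cs(paste0("c", 1:32)))
  expect_lt(semd_tight, semd_spread)
})

test_that("degenerate context sets yield missing SemD with a warning", {
  V <- matrix(c(1, 0, 0, 1), 2, 2)
  sp <- space_from_vectors(V)
  expect_warning(out <- semantic_diversity(sp, fake_cs("c1")), "fewer than 2")
  expect_true(is.na(out))
  # antipodal pair: mean cosine -1 -> missing
  V2 <- matrix(c(1, 0, -1, 0), 2, 2, byrow = TRUE)
  expect_warning(out2 <- semantic_diversity(space_from_vectors(V2),
                                            fake_cs(c("c1", "c2"))),
                 "non-positive")
  expect_true(is.na(out2))
})
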