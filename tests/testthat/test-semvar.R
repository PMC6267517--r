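test_that("spherical k-means solves separable cases exactly", {
  # two antipodal duplicated bundles: perfect split, zero SSE
  u <- c(1, 0, 0)
  X <- rbind(matrix(rep(u, 5), 5, 3, byrow = TRUE),
             matrix(rep(-u, 5), 5, 3, byrow = TRUE))
  sol <- cluster_contexts(X, 2, seed = 1)
  expect_equal(sol$sse, 0, tolerance = 1e-12)
  expect_equal(length(unique(sol$assignments[1:5])), 1)
  expect_equal(length(unique(sol$assignments[6:10])), 1)
  expect_false(sol$assignments[1] == sol$assignments[6])

  # k = n singletons: zero SSE
  set.seed(2)
  Y <- matrix(stats::rnorm(24), 8, 3)
  solN <- cluster_contexts(Y, 8, seed = 3)
  expect_equal(solN$sse, 0, tolerance = 1e-10)

  expect_error(cluster_contexts(Y, 9, seed = 1), "k must be")
  expect_error(cluster_contexts(rbind(Y, 0), 2, seed = 1), "zero-norm")
})

test_that("k-means recovers four well-separated directions in >=95% of seeds", {
  fx <- make_directional_clusters(g = 4, per = 10, d = 6, sigma = 0.08,
                                  seed = 100)
  hits <- sapply(1:50, function(s) {
    sol <- cluster_contexts(fx$X, 4, seed = s)
    matches_up_to_relabeling(sol$assignments, fx$labels)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("SSE profiles are zero for identical vectors and never increase", {
  X <- matrix(rep(c(2, 1, 1), 6), 6, 3, byrow = TRUE)
  prof <- sse_profile(X, k_max = 5, seed = 1)
  expect_equal(prof$sse, rep(0, 5), tolerance = 1e-12)

  set.seed(9)
  for (rep in 1:5) {
    Y <- matrix(stats::rnorm(30 * 6), 30, 6)
    p <- sse_profile(Y, k_max = 15, seed = rep)
    expect_true(all(diff(p$sse) <= 1e-12))
    expect_gte(min(p$sse), 0)
  }
})

test_that("select_k applies the 90%-of-achievable-reduction rule", {
  prof <- function(sse) tibble::tibble(k = seq_along(sse), sse = sse)
  expect_equal(select_k(prof(c(100, 10, 5, 2))), 2L)
  expect_equal(select_k(prof(c(100, 60, 30, 12, 8))), 4L)
  expect_equal(select_k(prof(c(50, 50, 50))), 1L)
})

test_that("within-group distance matches a per-member oracle", {
  # degenerate cases
  set.seed(12)
  Y <- matrix(stats::rnorm(15), 5, 3)
  singl <- cluster_contexts(Y, 5, seed = 1)
  expect_equal(within_group_distance(singl, Y), 0, tolerance = 1e-10)

  dup <- rbind(matrix(rep(c(1, 2, 0), 4), 4, 3, byrow = TRUE),
               matrix(rep(c(0, 1, 5), 4), 4, 3, byrow = TRUE))
  sdup <- cluster_contexts(dup, 2, seed = 1)
  expect_equal(within_group_distance(sdup, dup), 0, tolerance = 1e-12)

  # hand-built two-cluster set in 3 dims vs independent recomputation
  fx <- make_directional_clusters(g = 2, per = 12, d = 3, sigma = 0.2,
                                  seed = 5)
  sol <- cluster_contexts(fx$X, 2, seed = 7)
  U <- fx$X / sqrt(rowSums(fx$X^2))
  expect_equal(within_group_distance(sol, fx$X),
               within_oracle(sol$assignments, sol$centroids, U),
               tolerance = 1e-12)
})

test_that("between-group distance averages centroid pairs unweighted", {
  mk <- function(C) list(k = nrow(C), centroids = C)
  expect_equal(between_group_distance(mk(diag(2))), 1)
  expect_equal(between_group_distance(mk(diag(3))), 1)
  C <- vectors_with_cosines(matrix(c(1, .9, .8, .9, 1, .7, .8, .7, 1), 3, 3))
  expect_equal(between_group_distance(mk(C)), 0.2, tolerance = 1e-10)
  expect_warning(out <- between_group_distance(mk(matrix(1, 1, 3))), "k >= 2")
  expect_true(is.na(out))
})

test_that("SemVar is near 0 for two tight far-apart bundles and higher for one diffuse cloud", {
  sp_ids <- function(n) paste0("c", seq_len(n))
  mk_space <- function(V) {
    rownames(V) <- sp_ids(nrow(V))
    structure(list(context_vectors = V, singular_values = rep(1, ncol(V)),
                   d = ncol(V)), class = "semantic_space")
  }
  mk_cs <- function(n, word = "w") {
    out <- tibble::tibble(context_id = sp_ids(n), occ_count = 1L)
    attr(out, "word") <- word
    out
  }
  set.seed(31)
  # two tight antipodal bundles
  u <- c(1, 0.2, 0, 0.1); u <- u / sqrt(sum(u^2))
  tight <- rbind(
    matrix(rep(u, 15), 15, 4, byrow = TRUE),
    matrix(rep(-u, 15), 15, 4, byrow = TRUE)
  ) + matrix(stats::rnorm(120, sd = 0.005), 30, 4)
  res_tight <- semantic_variability(mk_space(tight), mk_cs(30), k_max = 10,
                                    seed = 3)
  expect_lt(res_tight$semvar, 0.05)
  expect_equal(res_tight$k_best, 2L)

  # one diffuse cloud
  diffuse <- matrix(stats::rnorm(30 * 4, sd = 0.35), 30, 4) +
    matrix(rep(u, 30), 30, 4, byrow = TRUE)
  res_diff <- semantic_variability(mk_space(diffuse), mk_cs(30), k_max = 10,
                                   seed = 3)
  expect_gt(res_diff$semvar, res_tight$semvar * 5)

  # below the context minimum: missing with reason
  res_small <- semantic_variability(mk_space(diffuse[1:5, ]), mk_cs(5),
                                    seed = 1)
  expect_true(is.na(res_small$semvar))
  expect_equal(res_small$missing_reason, "insufficient contexts")

  # identical vectors: degenerate, marked missing rather than 0/0
  same <- matrix(rep(u, 12), 12, 4, byrow = TRUE)
  res_same <- semantic_variability(mk_space(same), mk_cs(12), seed = 1)
  expect_true(is.na(res_same$semvar))
})

test_that("SemVar is invariant under orthogonal rotation of the space", {
  fx <- make_directional_clusters(g = 3, per = 15, d = 8, sigma = 0.15,
                                  seed = 17)
  V <- fx$X
  rownames(V) <- paste0("c", seq_len(nrow(V)))
  mk <- function(M) structure(list(context_vectors = M,
                                   singular_values = rep(1, ncol(M)),
                                   d = ncol(M)), class = "semantic_space")
  cs <- tibble::tibble(context_id = rownames(V), occ_count = 1L)
  attr(cs, "word") <- "w"
  base <- semantic_variability(mk(V), cs, k_max = 15, seed = 11)
  Q <- random_orthogonal(8, seed = 23)
  VQ <- V %*% Q
  rownames(VQ) <- rownames(V)
  rot <- semantic_variability(mk(VQ), cs, k_max = 15, seed = 11)
  expect_equal(rot$semvar, base$semvar, tolerance = 1e-8)
  expect_equal(rot$k_best, base$k_best)
})

test_that("planted directional clusters are recovered by select_k (g +/- 1)", {
  for (g in c(3, 5, 8)) {
    hits <- sapply(1:20, function(s) {
      fx <- make_directional_clusters(g, per = 40, d = 10, sigma = 0.1,
                                      seed = 1000 * g + s)
      select_k(sse_profile(fx$X, k_max = 25, seed = s, n_restarts = 10))
    })
    expect_gte(mean(abs(hits - g) <= 1), 0.8)
  }
})

test_that("residualization is exact OLS with orthogonal residuals", {
  # perfect fit
  rec <- tibble::tibble(word = c("a", "b", "c"), semvar = c(1, 3, 5),
                        log_cd = c(0, 1, 2))
  out <- residualize_semvar(rec)
  expect_equal(out$records$semvar_res, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(out$slope, 2, tolerance = 1e-12)

  # random 50-word table vs closed-form normal equations
  set.seed(77)
  rec2 <- tibble::tibble(word = sprintf("w%02d", 1:50),
                         log_cd = stats::runif(50, 0.5, 3),
                         semvar = stats::runif(50, 0, 1))
  out2 <- residualize_semvar(rec2)
  Xd <- cbind(1, rec2$log_cd)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% rec2$semvar)
  expect_equal(out2$records$semvar_res,
               as.numeric(rec2$semvar - Xd %*% beta), tolerance = 1e-10)
  expect_lt(abs(sum(out2$records$semvar_res)), 1e-10)
  expect_lt(abs(stats::cor(out2$records$semvar_res, rec2$log_cd)), 1e-10)

  # missing semvar propagates, fit uses the rest
  rec3 <- rec2
  rec3$semvar[7] <- NA
  out3 <- residualize_semvar(rec3)
  expect_true(is.na(out3$records$semvar_res[7]))
  expect_equal(sum(is.na(out3$records$semvar_res)), 1)

  # degenerate regressor
  rec4 <- tibble::tibble(word = c("a", "b", "c"), semvar = 1:3,
                         log_cd = rep(1, 3))
  expect_error(residualize_semvar(rec4), "degenerate regressor")
})

test_that("tidy and glance summarise the residualization fit", {
  set.seed(5)
  rec <- tibble::tibble(word = sprintf("w%02d", 1:30),
                        log_cd = stats::runif(30, 0.5, 3))
  rec$semvar <- 0.1 + 0.2 * rec$log_cd + stats::rnorm(30, sd = 0.05)
  out <- residualize_semvar(rec)
  td <- tidy(out)
  expect_equal(td$term, c("(Intercept)", "log_cd"))
  gl <- glance(out)
  expect_equal(gl$nobs, 30L)
  expect_gt(gl$r.squared, 0.5)
})
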