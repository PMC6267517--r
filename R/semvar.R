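#' Spherical k-means clustering of context vectors
#'
#' Lloyd-style k-means on unit-normalised vectors with plus-plus seeding,
#' best of `n_restarts` by SSE. Distance is cosine distance (1 - cosine);
#' centroids are normalised cluster means; SSE is the summed cosine
#' distance of members to their centroid. Deterministic given `seed`.
#'
#' @param vectors Numeric matrix, one vector per row; rows must be
#'   nonzero.
#' @param k Number of clusters, `1 <= k <= nrow(vectors)`.
#' @param seed Integer seed.
#' @param n_restarts Restarts of the plus-plus/Lloyd cycle (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return A `cluster_solution`: list with `k`, `assignments` (1-based
#'   integer per row), `centroids` (k x d, unit rows), `sse`.
#' @export
cluster_contexts <- function(vectors, k, seed = 1L, n_restarts = 10,
                             max_iter = 100) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (k < 1 || k > n) stop("k must be in [1, nrow(vectors)]", call. = FALSE)
  U <- unit_rows(vectors)
  set.seed(as.integer(seed))
  fit <- sph_kmeans_cpp(U, as.integer(k), as.integer(n_restarts),
                        as.integer(max_iter))
  structure(
    list(k = as.integer(k),
         assignments = fit$assignments + 1L,
         centroids = fit$centroids,
         sse = fit$sse),
    class = "cluster_solution"
  )
}

#' SSE profile over candidate cluster counts
#'
#' Runs spherical k-means for k = 1..min(k_max, n) and records the best
#' SSE per k. The profile is monotone-repaired (sse[k] <- min(sse[k],
#' sse[k-1])) so restart noise cannot make it increase. The k = 1 value is
#' the total cosine dispersion about the global centroid.
#'
#' @inheritParams cluster_contexts
#' @param k_max Largest cluster count examined (default 200); capped at
#'   the number of vectors.
#' @return An `sse_profile`: tibble with columns `k` and `sse`.
#' @export
sse_profile <- function(vectors, k_max = 200, seed = 1L, n_restarts = 10,
                        max_iter = 100) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 2) stop("need at least 2 vectors for an SSE profile", call. = FALSE)
  k_max <- min(as.integer(k_max), n)
  U <- unit_rows(vectors)
  set.seed(as.integer(seed))
  sse <- sse_profile_cpp(U, k_max, as.integer(n_restarts),
                         as.integer(max_iter))
  sse <- cummin(pmax(sse, 0))
  out <- tibble::tibble(k = seq_len(k_max), sse = sse)
  class(out) <- c("sse_profile", class(tibble::as_tibble(out)))
  out
}

#' Select the cluster count from an SSE profile
#'
#' The best k is the smallest k whose SSE reduction relative to k = 1
#' reaches `threshold` of the total achievable reduction
#' (sse[1] - sse[k_max]). A flat profile returns 1.
#'
#' @param profile An `sse_profile` (or any data frame with `k` and `sse`).
#' @param threshold Required fraction of the achievable SSE reduction
#'   (default 0.9).
#' @return The selected integer k.
#' @export
select_k <- function(profile, threshold = 0.9) {
  sse <- profile$sse
  if (length(sse) == 0) stop("empty SSE profile", call. = FALSE)
  total <- sse[1] - sse[length(sse)]
  if (total <= 0) return(1L)
  drop <- sse[1] - sse
  as.integer(profile$k[which(drop >= threshold * total)[1]])
}

#' Mean within-group distance of a cluster solution
#'
#' Mean over all members of the cosine distance to their own centroid,
#' pooled across clusters (clusters weight by size).
#'
#' @param sol A `cluster_solution`.
#' @param vectors The matrix that was clustered.
#' @return Mean within-group cosine distance, >= 0.
#' @export
within_group_distance <- function(sol, vectors) {
  U <- unit_rows(as.matrix(vectors))
  C <- unit_rows(sol$centroids)
  sims <- rowSums(U * C[sol$assignments, , drop = FALSE])
  mean(pmax(1 - sims, 0))
}

#' Mean between-group distance of a cluster solution
#'
#' Mean cosine distance over all unordered pairs of cluster centroids
#' (unweighted by cluster size).
#'
#' @param sol A `cluster_solution` with `k >= 2`.
#' @return Mean between-group cosine distance, or `NA` with a warning when
#'   `k < 2`.
#' @export
between_group_distance <- function(sol) {
  if (sol$k < 2) {
    warning("between-group distance needs k >= 2", call. = FALSE)
    return(NA_real_)
  }
  cm <- cosine_matrix(sol$centroids)
  mean(1 - cm[upper.tri(cm)])
}

#' Semantic variability of one word
#'
#' The word's context vectors (capped as in SemD) are profiled over
#' candidate cluster counts, the count is selected by the SSE-reduction
#' rule, the vectors are clustered at that count, and SemVar is the mean
#' within-group distance divided by the mean between-group distance. Low
#' SemVar marks tight, well-separated context clusters (homonym-like);
#' high SemVar marks a diffuse overlapping context cloud (polyseme-like).
#' If the selection rule returns k = 1, the smallest k >= 2 meeting the
#' threshold is used instead so a between-group distance exists.
#'
#' @param space A `semantic_space`.
#' @param cs A `context_set`.
#' @param k_max,sse_threshold,n_restarts,seed Clustering controls (see
#'   [sse_profile()] and [select_k()]).
#' @param min_contexts Minimum context count for a defined score
#'   (default 10).
#' @return A `semvar_result`: one-row tibble with columns `word`, `n_contexts_used`,
#'   `k_best`, `within`, `between`, `semvar`, `missing_reason`.
#' @export
semantic_variability <- function(space, cs, k_max = 200, sse_threshold = 0.9,
                                 n_restarts = 10, seed = 1L,
                                 min_contexts = 10) {
  word <- attr(cs, "word")
  miss <- function(reason, n_used = nrow(cs)) {
    out <- tibble::tibble(word = word %||% NA_character_,
                          n_contexts_used = n_used,
                          k_best = NA_integer_, within = NA_real_,
                          between = NA_real_, semvar = NA_real_,
                          missing_reason = reason)
    class(out) <- c("semvar_result", class(tibble::as_tibble(out)))
    out
  }
  n <- nrow(cs)
  if (n < min_contexts) return(miss("insufficient contexts"))
  rows <- match(cs$context_id, rownames(space$context_vectors))
  if (anyNA(rows)) stop("context_set refers to contexts missing from the space",
                        call. = FALSE)
  V <- space$context_vectors[rows, , drop = FALSE]
  prof <- sse_profile(V, k_max = k_max, seed = seed, n_restarts = n_restarts)
  k_best <- select_k(prof, threshold = sse_threshold)
  if (k_best < 2) {
    # flat-at-1 selection: restart the search at k = 2 so between-group
    # distance is defined
    total <- prof$sse[1] - prof$sse[nrow(prof)]
    drop <- prof$sse[1] - prof$sse
    ok <- which(prof$k >= 2 & drop >= sse_threshold * total)
    if (length(ok) == 0) return(miss("no k >= 2 meets threshold"))
    k_best <- as.integer(prof$k[ok[1]])
  }
  sol <- cluster_contexts(V, k_best, seed = seed, n_restarts = n_restarts)
  within <- within_group_distance(sol, V)
  between <- between_group_distance(sol)
  if (!is.finite(between) || between <= .Machine$double.eps * 100) {
    return(miss("degenerate_between"))
  }
  out <- tibble::tibble(word = word %||% NA_character_,
                        n_contexts_used = n,
                        k_best = k_best, within = within, between = between,
                        semvar = within / between,
                        missing_reason = NA_character_)
  class(out) <- c("semvar_result", class(tibble::as_tibble(out)))
  out
}

#' Residualize SemVar on log contextual diversity
#'
#' Ordinary least squares of `semvar` on `log_cd` across the lexicon; the
#' per-word residual (SemVarRes) is the clustering signal orthogonal to
#' context count. Words with missing `semvar` get a missing residual.
#'
#' @param records Data frame with columns `word`, `semvar`, `log_cd`.
#' @return A `semvar_residualization`: list with `records` (the input
#'   tibble plus a `semvar_res` column), `slope`, `intercept`, and the
#'   underlying `lm` fit.
#' @export
residualize_semvar <- function(records) {
  stopifnot(all(c("semvar", "log_cd") %in% names(records)))
  ok <- is.finite(records$semvar) & is.finite(records$log_cd)
  if (sum(ok) < 3) stop("need >= 3 words with non-missing semvar", call. = FALSE)
  if (stats::sd(records$log_cd[ok]) == 0) {
    stop("degenerate regressor: log_cd is constant", call. = FALSE)
  }
  fit <- stats::lm(semvar ~ log_cd, data = records[ok, , drop = FALSE])
  res <- rep(NA_real_, nrow(records))
  res[ok] <- stats::residuals(fit)
  out <- dplyr::mutate(tibble::as_tibble(records), semvar_res = res)
  structure(
    list(records = out,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         fit = fit),
    class = "semvar_residualization"
  )
}

#' @export
print.semvar_residualization <- function(x, ...) {
  cat("<semvar_residualization> semvar ~ log_cd: intercept ",
      signif(x$intercept, 4), ", slope ", signif(x$slope, 4), ", n = ",
      length(stats::residuals(x$fit)), "\n", sep = "")
  invisible(x)
}

#' Per-term summary of a SemVar residualization
#'
#' @param x A `semvar_residualization`.
#' @param ... Unused.
#' @return Tibble of OLS coefficients with standard errors.
#' @export
tidy.semvar_residualization <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std.error = sm[, 2], statistic = sm[, 3],
                 p.value = sm[, 4])
}

#' One-row fit summary of a SemVar residualization
#'
#' @param x A `semvar_residualization`.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `sigma`, `nobs`.
#' @export
glance.semvar_residualization <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r.squared = sm$r.squared, sigma = sm$sigma,
                 nobs = length(stats::residuals(x$fit)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
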