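#' Build the word-by-context co-occurrence matrix
#'
#' Entry (w, c) is the number of occurrences of vocabulary word `w` in
#' context `c`. Contexts containing no retained word are dropped from the
#' column index with a warning.
#'
#' @param contexts A `context_collection`.
#' @param vocab A `vocabulary` built from the same contexts.
#' @return A sparse `dgCMatrix` (words x contexts) with dimnames giving
#'   the word and context ids.
#' @export
build_cooccurrence <- function(contexts, vocab) {
  words <- vocab$word
  ctx_ids <- contexts$context_id
  tok <- unlist(contexts$tokens, use.names = FALSE)
  ctx_of_tok <- rep.int(seq_along(ctx_ids), lengths(contexts$tokens))
  row <- match(tok, words)
  keep <- !is.na(row)
  m <- Matrix::sparseMatrix(
    i = row[keep], j = ctx_of_tok[keep], x = 1,
    dims = c(length(words), length(ctx_ids)),
    dimnames = list(words, ctx_ids)
  )
  empty <- Matrix::colSums(m) == 0
  if (any(empty)) {
    warning(sum(empty), " context(s) with no retained word dropped",
            call. = FALSE)
    m <- m[, !empty, drop = FALSE]
  }
  methods::as(m, "CsparseMatrix")
}

#' Log-weight a count matrix
#'
#' Replaces each entry c by ln(1 + c), damping the influence of very
#' frequent words while keeping zeros at zero (sparsity preserved).
#'
#' @param m Sparse or dense non-negative count matrix.
#' @return Matrix of the same shape with entries ln(1 + c).
#' @export
weight_matrix <- function(m) {
  if (inherits(m, "sparseMatrix")) {
    m <- methods::as(m, "CsparseMatrix")
    m@x <- log1p(m@x)
    m
  } else {
    log1p(m)
  }
}

#' Reduce a weighted matrix to a low-dimensional semantic space
#'
#' Exact truncated SVD X = U S V' keeping the top `d` singular triplets,
#' computed deterministically via the eigen-decomposition of the smaller
#' Gram matrix. Word vectors are rows of U S and context vectors rows of
#' V S, so at full rank cosines between context vectors equal cosines
#' between the columns of the weighted matrix.
#'
#' @param weighted Weighted word-by-context matrix (sparse or dense), with
#'   dimnames.
#' @param d Target dimensionality (default 300); capped at
#'   `min(nrow, ncol)` with a warning if larger.
#' @param seed Accepted for interface stability; the exact decomposition
#'   used here is deterministic and draws no random numbers.
#' @return A `semantic_space`: list with `word_vectors` (words x d),
#'   `context_vectors` (contexts x d), `singular_values` (length d,
#'   non-increasing), and `d`.
#' @export
reduce_dimensions <- function(weighted, d = 300, seed = NULL) {
  stopifnot(d >= 1)
  nr <- nrow(weighted)
  nc <- ncol(weighted)
  if (d > min(nr, nc)) {
    warning("d = ", d, " exceeds min(n_words, n_contexts) = ", min(nr, nc),
            "; capped", call. = FALSE)
    d <- min(nr, nc)
  }
  d <- as.integer(d)
  X <- as.matrix(weighted)
  if (!all(is.finite(X))) stop("non-finite entries in weighted matrix", call. = FALSE)

  # eigen on the smaller Gram matrix; recover the other side via X
  if (nr <= nc) {
    G <- tcrossprod(X)                      # nr x nr
    eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
    s2 <- pmax(eg$values[seq_len(d)], 0)
    s <- sqrt(s2)
    U <- eg$vectors[, seq_len(d), drop = FALSE]
    V <- crossprod(X, U)                    # = V S, columns scaled by s
    pos <- s > max(s[1], .Machine$double.eps) * 1e-12
    V[, !pos] <- 0
    V[, pos] <- sweep(V[, pos, drop = FALSE], 2, s[pos], "/")
  } else {
    G <- crossprod(X)                       # nc x nc
    eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
    s2 <- pmax(eg$values[seq_len(d)], 0)
    s <- sqrt(s2)
    V <- eg$vectors[, seq_len(d), drop = FALSE]
    U <- X %*% V
    pos <- s > max(s[1], .Machine$double.eps) * 1e-12
    U[, !pos] <- 0
    U[, pos] <- sweep(U[, pos, drop = FALSE], 2, s[pos], "/")
  }

  # deterministic sign: make the largest-magnitude loading of each left
  # singular vector positive
  for (j in seq_len(d)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }

  word_vectors <- sweep(U, 2, s, "*")
  context_vectors <- sweep(V, 2, s, "*")
  rownames(word_vectors) <- rownames(weighted)
  rownames(context_vectors) <- colnames(weighted)

  structure(
    list(word_vectors = word_vectors,
         context_vectors = context_vectors,
         singular_values = s,
         d = d),
    class = "semantic_space"
  )
}

#' @export
print.semantic_space <- function(x, ...) {
  cat("<semantic_space> ", nrow(x$word_vectors), " words x ",
      nrow(x$context_vectors), " contexts, d = ", x$d,
      ", leading singular value ", signif(x$singular_values[1], 4), "\n",
      sep = "")
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length with positive norm.
#' @return `u.v / (|u||v|)`, in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for zero-norm vector", call. = FALSE)
  sum(u * v) / (nu * nv)
}

# all pairwise cosines between rows of a matrix
cosine_matrix <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) stop("cosine undefined for zero-norm vector", call. = FALSE)
  tcrossprod(m / n)
}

# unit-normalise rows, erroring on zero rows
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) stop("zero-norm context vector", call. = FALSE)
  m / n
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a semantic space
#'
#' @param x A `semantic_space`.
#' @param ... Unused.
#' @return Tibble with dimensions and the share of squared singular mass
#'   carried by the retained components' leading half.
#' @export
glance.semantic_space <- function(x, ...) {
  s2 <- x$singular_values^2
  tibble::tibble(
    n_words = nrow(x$word_vectors),
    n_contexts = nrow(x$context_vectors),
    d = x$d,
    sigma_max = x$singular_values[1],
    top_half_mass = sum(s2[seq_len(ceiling(x$d / 2))]) / sum(s2)
  )
}

#' Singular spectrum of a semantic space
#'
#' @param x A `semantic_space`.
#' @param ... Unused.
#' @return Tibble with `component` and `singular_value`.
#' @export
tidy.semantic_space <- function(x, ...) {
  tibble::tibble(component = seq_len(x$d), singular_value = x$singular_values)
}

#' Write a semantic space to a directory
#'
#' Serialises singular values, word vectors, context vectors, and index
#' files as plain TSV.
#'
#' @param space A `semantic_space`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_space <- function(space, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tibble::tibble(singular_value = space$singular_values),
                   file.path(dir, "singular_values.tsv"), progress = FALSE)
  wv <- tibble::as_tibble(space$word_vectors, .name_repair = ~ paste0("d", seq_along(.)))
  cv <- tibble::as_tibble(space$context_vectors, .name_repair = ~ paste0("d", seq_along(.)))
  readr::write_tsv(wv, file.path(dir, "word_vectors.tsv"), progress = FALSE)
  readr::write_tsv(cv, file.path(dir, "context_vectors.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(row = seq_len(nrow(space$word_vectors)),
                                  word = rownames(space$word_vectors)),
                   file.path(dir, "word_index.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(row = seq_len(nrow(space$context_vectors)),
                                  context_id = rownames(space$context_vectors)),
                   file.path(dir, "context_index.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read a semantic space written by [write_space()]
#'
#' @param dir Directory containing the serialized space.
#' @return A `semantic_space`.
#' @export
read_space <- function(dir) {
  sv <- readr::read_tsv(file.path(dir, "singular_values.tsv"),
                        show_col_types = FALSE, progress = FALSE)$singular_value
  wv <- as.matrix(readr::read_tsv(file.path(dir, "word_vectors.tsv"),
                                  show_col_types = FALSE, progress = FALSE))
  cv <- as.matrix(readr::read_tsv(file.path(dir, "context_vectors.tsv"),
                                  show_col_types = FALSE, progress = FALSE))
  wi <- readr::read_tsv(file.path(dir, "word_index.tsv"),
                        show_col_types = FALSE, progress = FALSE)
  ci <- readr::read_tsv(file.path(dir, "context_index.tsv"),
                        show_col_types = FALSE, progress = FALSE)
  dimnames(wv) <- list(wi$word, NULL)
  dimnames(cv) <- list(ci$context_id, NULL)
  structure(list(word_vectors = wv, context_vectors = cv,
                 singular_values = sv, d = length(sv)),
            class = "semantic_space")
}
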