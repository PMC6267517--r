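#' Contexts associated with a word
#'
#' All contexts in which `word` occurs at least once, with its per-context
#' occurrence count. If there are more than `cap` such contexts, the `cap`
#' contexts where the word occurs most often are retained (ties broken by
#' context order), keeping pairwise computations tractable.
#'
#' @param m Word-by-context co-occurrence matrix (from
#'   [build_cooccurrence()]).
#' @param word A vocabulary word (row name of `m`).
#' @param cap Maximum retained contexts (default 2000).
#' @return A `context_set`: tibble with columns `context_id`, `occ_count`,
#'   and attributes `word`, `n_total` (uncapped context count).
#' @export
context_set <- function(m, word, cap = 2000) {
  row <- match(word, rownames(m))
  if (is.na(row)) stop("word not in vocabulary: ", word, call. = FALSE)
  counts <- m[row, ]
  hit <- which(counts >= 1)
  n_total <- length(hit)
  occ <- counts[hit]
  if (n_total > cap) {
    keep <- order(-occ, seq_along(occ))[seq_len(cap)]
    keep <- sort(keep)
    hit <- hit[keep]
    occ <- occ[keep]
  }
  out <- tibble::tibble(context_id = colnames(m)[hit], occ_count = as.integer(occ))
  attr(out, "word") <- word
  attr(out, "n_total") <- n_total
  class(out) <- c("context_set", class(tibble::as_tibble(out)))
  out
}

#' Contextual diversity
#'
#' CD is the number of contexts a word occurs in at least once, counted on
#' the full (uncapped) context set; `log_cd` is its base-10 logarithm.
#'
#' @param m Word-by-context co-occurrence matrix.
#' @param words Words to score; defaults to every vocabulary word.
#' @param log_base Base of the logarithm (default 10).
#' @return Tibble with columns `word`, `cd`, `log_cd`.
#' @export
contextual_diversity <- function(m, words = rownames(m), log_base = 10) {
  rows <- match(words, rownames(m))
  if (anyNA(rows)) {
    stop("word(s) not in vocabulary: ",
         paste(utils::head(words[is.na(rows)], 5), collapse = ", "),
         call. = FALSE)
  }
  bin <- m[rows, , drop = FALSE]
  cd <- as.integer(Matrix::rowSums(bin >= 1))
  tibble::tibble(word = words, cd = cd, log_cd = log(cd, base = log_base))
}

#' Semantic diversity
#'
#' The mean cosine over all unordered pairs of contexts containing the
#' word is log-transformed and sign-reversed: SemD = -log10(mean cosine).
#' High SemD means the word's contexts are mutually dissimilar, i.e. the
#' word is used in semantically diverse contexts. Uses the closed form
#' mean = (|sum of unit vectors|^2 - n) / (n (n - 1)).
#'
#' @param space A `semantic_space`.
#' @param cs A `context_set` (from [context_set()]).
#' @param log_base Base of the logarithm (default 10).
#' @return A length-1 double: the SemD score, or `NA` (with a warning)
#'   when the word has fewer than 2 contexts or the mean cosine is not
#'   positive.
#' @export
semantic_diversity <- function(space, cs, log_base = 10) {
  ids <- cs$context_id
  rows <- match(ids, rownames(space$context_vectors))
  if (anyNA(rows)) stop("context_set refers to contexts missing from the space",
                        call. = FALSE)
  n <- length(rows)
  if (n < 2) {
    warning("fewer than 2 contexts; SemD undefined", call. = FALSE)
    return(NA_real_)
  }
  U <- unit_rows(space$context_vectors[rows, , drop = FALSE])
  mean_cos <- (sum(colSums(U)^2) - n) / (n * (n - 1))
  if (mean_cos <= 0) {
    warning("non-positive mean pairwise cosine; SemD undefined", call. = FALSE)
    return(NA_real_)
  }
  -log(mean_cos, base = log_base)
}
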