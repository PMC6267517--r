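#' Read a pre-segmented corpus
#'
#' Reads a whitespace-tokenised UTF-8 corpus, either as one document per
#' line of a single file (`layout = "lines"`) or as one document per file
#' in a directory (`layout = "files"`, files taken in lexicographic name
#' order). No segmentation is performed: tokens are whatever is separated
#' by whitespace in the input.
#'
#' @param path Path to a text file (`layout = "lines"`) or a directory of
#'   text files (`layout = "files"`).
#' @param layout Corpus layout, `"lines"` or `"files"`.
#' @return A `tokenized_corpus`: a tibble with columns `doc_id` (unique
#'   character) and `tokens` (list-column of character vectors).
#' @examples
#' tmp <- tempfile()
#' writeLines(c("a b c", "d e"), tmp)
#' read_corpus(tmp)
#' @export
read_corpus <- function(path, layout = c("lines", "files")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop("corpus path does not exist: ", path, call. = FALSE)
  }
  if (layout == "lines") {
    lines <- tryCatch(
      readr::read_lines(path, progress = FALSE),
      error = function(e) stop("unreadable corpus file: ", path, call. = FALSE)
    )
    docs <- strsplit(lines, "[[:space:]]+")
    ids <- sprintf("doc%05d", seq_along(docs))
  } else {
    if (!dir.exists(path)) {
      stop("layout 'files' needs a directory: ", path, call. = FALSE)
    }
    files <- sort(list.files(path, full.names = TRUE))
    files <- files[!dir.exists(files)]
    docs <- lapply(files, function(f) {
      txt <- tryCatch(
        readr::read_lines(f, progress = FALSE),
        error = function(e) stop("unreadable corpus file: ", f, call. = FALSE)
      )
      unlist(strsplit(txt, "[[:space:]]+"), use.names = FALSE)
    })
    ids <- basename(files)
  }
  docs <- lapply(docs, function(x) x[nzchar(x)])
  keep <- lengths(docs) > 0L
  docs <- docs[keep]
  ids <- ids[keep]
  if (length(docs) == 0L) {
    stop("empty corpus: ", path, call. = FALSE)
  }
  new_tokenized_corpus(tibble::tibble(doc_id = ids, tokens = docs))
}

new_tokenized_corpus <- function(tbl) {
  stopifnot(all(c("doc_id", "tokens") %in% names(tbl)))
  if (anyDuplicated(tbl$doc_id)) stop("doc_ids must be unique", call. = FALSE)
  class(tbl) <- c("tokenized_corpus", class(tibble::as_tibble(tbl)))
  tbl
}

#' Construct a corpus from in-memory documents
#'
#' @param docs List of character vectors (one per document) or a single
#'   character vector of whitespace-joined documents.
#' @param doc_ids Optional document identifiers; generated if missing.
#' @return A `tokenized_corpus` tibble.
#' @export
as_tokenized_corpus <- function(docs, doc_ids = NULL) {
  if (is.character(docs)) docs <- strsplit(docs, "[[:space:]]+")
  docs <- lapply(docs, function(x) as.character(x[nzchar(x)]))
  if (is.null(doc_ids)) doc_ids <- sprintf("doc%05d", seq_along(docs))
  keep <- lengths(docs) > 0L
  if (!any(keep)) stop("empty corpus", call. = FALSE)
  new_tokenized_corpus(tibble::tibble(doc_id = doc_ids[keep], tokens = docs[keep]))
}

#' Classify tokens into filterable classes
#'
#' A total rule: every token receives exactly one class. Classes, checked
#' in order: `name` (membership in `name_stoplist`), `markup` (contains an
#' HTML/XML-style tag), `numeric` (digits with optional numeric
#' punctuation), `alphabetic` (ASCII letters only), `punctuation` (Unicode
#' punctuation only), `symbol` (Unicode symbols only), otherwise `word`.
#'
#' @param tokens Character vector.
#' @param name_stoplist Character vector of tokens to class as `name`
#'   (proper-name removal is stoplist-based; no NER is attempted).
#' @return Character vector of classes, same length as `tokens`.
#' @export
classify_tokens <- function(tokens, name_stoplist = character()) {
  cls <- rep("word", length(tokens))
  cls[grepl("^[\\p{S}]+$", tokens, perl = TRUE)] <- "symbol"
  cls[grepl("^[\\p{P}]+$", tokens, perl = TRUE)] <- "punctuation"
  cls[grepl("^[A-Za-z]+$", tokens)] <- "alphabetic"
  cls[grepl("^[0-9]+([.,:/%-][0-9]+)*%?$", tokens)] <- "numeric"
  cls[grepl("<[^<>]+>", tokens)] <- "markup"
  if (length(name_stoplist)) cls[tokens %in% name_stoplist] <- "name"
  cls
}

#' Filter a corpus by token class
#'
#' Removes tokens whose class (per [classify_tokens()]) is in
#' `drop_classes`, preserving the order of the remaining tokens.
#' Documents emptied by filtering are dropped with a warning.
#'
#' @param corpus A `tokenized_corpus`.
#' @param drop_classes Token classes to remove.
#' @param name_stoplist Tokens to treat as names (see [classify_tokens()]).
#' @return A filtered `tokenized_corpus`.
#' @export
preprocess_corpus <- function(corpus,
                              drop_classes = c("numeric", "symbol", "markup",
                                               "name", "punctuation",
                                               "alphabetic"),
                              name_stoplist = character()) {
  if (length(drop_classes) == 0L) return(corpus)
  docs <- lapply(corpus$tokens, function(tok) {
    tok[!(classify_tokens(tok, name_stoplist) %in% drop_classes)]
  })
  keep <- lengths(docs) > 0L
  if (!all(keep)) {
    warning(sum(!keep), " document(s) emptied by filtering and dropped: ",
            paste(utils::head(corpus$doc_id[!keep], 5), collapse = ", "),
            call. = FALSE)
  }
  if (!any(keep)) stop("empty corpus after preprocessing", call. = FALSE)
  new_tokenized_corpus(tibble::tibble(doc_id = corpus$doc_id[keep],
                                      tokens = docs[keep]))
}

#' Cut documents into fixed-size contexts
#'
#' Each document is split into consecutive non-overlapping blocks of
#' `chunk_size` tokens; a final remainder block of any positive length is
#' kept as its own context, so concatenating a document's chunks in
#' `chunk_index` order restores the document exactly.
#'
#' @param corpus A `tokenized_corpus`.
#' @param chunk_size Target tokens per context (default 150).
#' @return A `context_collection`: tibble with columns `context_id`,
#'   `doc_id`, `chunk_index` (0-based), `n_tokens`, `tokens` (list-column).
#' @examples
#' corp <- as_tokenized_corpus(list(letters[1:5]))
#' chunk_documents(corp, chunk_size = 2)
#' @export
chunk_documents <- function(corpus, chunk_size = 150) {
  if (!is.numeric(chunk_size) || length(chunk_size) != 1L || chunk_size < 1) {
    stop("chunk_size must be a positive integer", call. = FALSE)
  }
  chunk_size <- as.integer(chunk_size)
  pieces <- purrr::map2(corpus$tokens, corpus$doc_id, function(tok, id) {
    idx <- (seq_along(tok) - 1L) %/% chunk_size
    chunks <- unname(split(tok, idx))
    tibble::tibble(
      doc_id = id,
      chunk_index = seq_along(chunks) - 1L,
      tokens = chunks
    )
  })
  out <- dplyr::bind_rows(pieces)
  out <- dplyr::mutate(
    out,
    context_id = paste0(.data$doc_id, "#", .data$chunk_index),
    n_tokens = lengths(.data$tokens)
  )
  out <- dplyr::select(out, "context_id", "doc_id", "chunk_index",
                       "n_tokens", "tokens")
  attr(out, "chunk_size") <- chunk_size
  class(out) <- c("context_collection", class(tibble::as_tibble(out)))
  out
}

#' Build the filtered vocabulary
#'
#' Word types are counted over all contexts; types with corpus count below
#' `min_count` are removed first, then the `ceiling(top_fraction * n)` most
#' frequent of the `n` remaining types are excluded as high-frequency
#' types. Frequency ties are broken by lexicographic token order (the
#' earlier token counts as more frequent), making the cut deterministic.
#'
#' @param contexts A `context_collection` (or `tokenized_corpus`).
#' @param top_fraction Fraction of (min-count-passing) types excluded from
#'   the top of the frequency distribution (default 0.03).
#' @param min_count Minimum corpus frequency for retention (default 5).
#' @return A `vocabulary`: tibble with columns `word` and `count`, sorted
#'   by decreasing count (ties lexicographic), with attributes
#'   `top_fraction`, `min_count`, `n_excluded_top`.
#' @export
build_vocabulary <- function(contexts, top_fraction = 0.03, min_count = 5) {
  stopifnot(top_fraction >= 0, top_fraction <= 1, min_count >= 0)
  all_tokens <- unlist(contexts$tokens, use.names = FALSE)
  if (length(all_tokens) == 0L) stop("no tokens in contexts", call. = FALSE)
  tab <- table(all_tokens)
  tbl <- tibble::tibble(word = names(tab), count = as.integer(tab))
  tbl <- dplyr::filter(tbl, .data$count >= min_count)
  # decreasing count; ties broken so the lexicographically earlier token
  # ranks as more frequent
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$count), .data$word)
  n_top <- ceiling(top_fraction * nrow(tbl))
  if (n_top > 0) tbl <- tbl[-seq_len(n_top), , drop = FALSE]
  if (nrow(tbl) == 0L) {
    stop("vocabulary empty after filtering (min_count = ", min_count,
         ", top_fraction = ", top_fraction, ")", call. = FALSE)
  }
  attr(tbl, "top_fraction") <- top_fraction
  attr(tbl, "min_count") <- min_count
  attr(tbl, "n_excluded_top") <- as.integer(n_top)
  class(tbl) <- c("vocabulary", class(tibble::as_tibble(tbl)))
  tbl
}

#' Serialize a context collection to TSV
#'
#' Writes columns `context_id`, `doc_id`, `chunk_index`, `n_tokens`,
#' `tokens` (space-joined) to a UTF-8 TSV.
#'
#' @param contexts A `context_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contexts <- function(contexts, path) {
  flat <- dplyr::mutate(
    tibble::as_tibble(contexts),
    tokens = purrr::map_chr(.data$tokens, paste, collapse = " ")
  )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
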