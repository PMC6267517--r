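#' Default pipeline configuration
#'
#' Flat list of the tunable parameters of the full pipeline. `chunk_size`
#' is the context length in tokens; `top_fraction`/`min_count` control the
#' vocabulary filter; `svd_dim` the LSA dimensionality (capped at the
#' matrix rank bound for small corpora); `context_cap` the per-word
#' context ceiling for SemD/SemVar; `k_max`, `sse_threshold`,
#' `n_restarts`, `min_contexts` the SemVar clustering controls;
#' `log_base` the base for log CD and SemD.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(chunk_size = 150, top_fraction = 0.03, min_count = 5,
              svd_dim = 300, context_cap = 2000, k_max = 200,
              sse_threshold = 0.9, n_restarts = 10, min_contexts = 10,
              seed = 1L, log_base = 10)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(cfg, dots)
}

#' Build a semantic space from a corpus
#'
#' Chunks the corpus, builds and filters the vocabulary, forms the
#' log-weighted co-occurrence matrix, and reduces it by SVD.
#'
#' @param corpus A `tokenized_corpus` (already preprocessed if class
#'   filtering is wanted; see [preprocess_corpus()]).
#' @param config A [pipeline_config()] list.
#' @return List with `space` (a `semantic_space`), `matrix` (the count
#'   matrix), `vocab`, and `contexts`.
#' @export
build_space <- function(corpus, config = pipeline_config()) {
  contexts <- chunk_documents(corpus, chunk_size = config$chunk_size)
  vocab <- build_vocabulary(contexts, top_fraction = config$top_fraction,
                            min_count = config$min_count)
  m <- build_cooccurrence(contexts, vocab)
  w <- weight_matrix(m)
  d <- min(config$svd_dim, nrow(w), ncol(w))
  space <- if (d < config$svd_dim) {
    suppressWarnings(reduce_dimensions(w, d = config$svd_dim, seed = config$seed))
  } else {
    reduce_dimensions(w, d = config$svd_dim, seed = config$seed)
  }
  list(space = space, matrix = m, vocab = vocab, contexts = contexts)
}

#' Compute the full per-word ambiguity record table
#'
#' For every requested word: contextual diversity (CD and log CD),
#' semantic diversity (SemD), and semantic variability (selected cluster
#' count, within- and between-group distances, SemVar), then SemVarRes
#' (the residual of SemVar on log CD) across the whole set. Per-word
#' clustering seeds are derived deterministically from `config$seed`, so
#' identical corpus + config + seed gives an identical table.
#'
#' @param corpus A `tokenized_corpus`, or the list returned by
#'   [build_space()] (to reuse an already-built space).
#' @param words Optional character vector of words to score; defaults to
#'   the whole vocabulary. Words missing from the vocabulary are dropped
#'   with a warning and reported in the `rejects` attribute.
#' @param config A [pipeline_config()] list.
#' @return An `ambiguity_table`: tibble with columns `word`, `cd`,
#'   `log_cd`, `semd`, `k_best`, `within`, `between`, `semvar`,
#'   `semvar_res`, `n_contexts_used`, `missing_reason`.
#' @export
ambiguity_measures <- function(corpus, words = NULL,
                               config = pipeline_config()) {
  built <- if (is.list(corpus) && !is.data.frame(corpus) &&
               !is.null(corpus$space)) corpus
           else build_space(corpus, config)
  m <- built$matrix
  space <- built$space

  all_words <- rownames(m)
  if (is.null(words)) {
    words <- all_words
    rejects <- character()
  } else {
    rejects <- setdiff(words, all_words)
    if (length(rejects)) {
      warning(length(rejects), " requested word(s) not in vocabulary",
              call. = FALSE)
    }
    words <- intersect(words, all_words)
  }
  if (length(words) == 0L) stop("no requested word is in the vocabulary",
                                call. = FALSE)

  cd_tbl <- contextual_diversity(m, words, log_base = config$log_base)

  per_word <- purrr::map(seq_along(words), function(i) {
    w <- words[i]
    cs <- context_set(m, w, cap = config$context_cap)
    semd <- if (nrow(cs) >= 2) {
      suppressWarnings(semantic_diversity(space, cs, log_base = config$log_base))
    } else NA_real_
    word_seed <- (config$seed + 97L * i) %% 2147483629L
    sv <- semantic_variability(
      space, cs, k_max = config$k_max, sse_threshold = config$sse_threshold,
      n_restarts = config$n_restarts, seed = word_seed,
      min_contexts = config$min_contexts
    )
    dplyr::mutate(sv, semd = semd)
  })
  sv_tbl <- dplyr::bind_rows(per_word)

  records <- dplyr::left_join(cd_tbl, sv_tbl, by = "word")
  resid <- tryCatch(residualize_semvar(records), error = function(e) NULL)
  records <- if (is.null(resid)) {
    dplyr::mutate(records, semvar_res = NA_real_)
  } else {
    resid$records
  }
  records <- dplyr::select(records, "word", "cd", "log_cd", "semd", "k_best",
                           "within", "between", "semvar", "semvar_res",
                           "n_contexts_used", "missing_reason")
  attr(records, "rejects") <- rejects
  attr(records, "residualization") <- resid
  attr(records, "config") <- config
  class(records) <- c("ambiguity_table", class(tibble::as_tibble(records)))
  records
}

#' Write an ambiguity record table to TSV
#'
#' UTF-8, header row, missing values as "NA".
#'
#' @param records An `ambiguity_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  readr::write_tsv(tibble::as_tibble(records), path, na = "NA",
                   progress = FALSE)
  invisible(path)
}

#' Summary correlations of an ambiguity table
#'
#' Pairwise Pearson correlations of `log_cd`, `semd`, `semvar`, and
#' `semvar_res` over words with complete measures.
#'
#' @param records An `ambiguity_table`.
#' @return Tibble in long form: `var1`, `var2`, `r`.
#' @export
measure_correlations <- function(records) {
  vars <- c("log_cd", "semd", "semvar", "semvar_res")
  sub <- records[, vars]
  cm <- stats::cor(sub, use = "pairwise.complete.obs")
  out <- tibble::as_tibble(as.data.frame(as.table(cm)),
                           .name_repair = ~ c("var1", "var2", "r"))
  dplyr::filter(out, match(as.character(.data$var1), vars) <
                  match(as.character(.data$var2), vars))
}

# ---- command-style entry points -------------------------------------------

write_config <- function(config, path) {
  lines <- paste0(names(config), " = ", unlist(config))
  writeLines(lines, path)
  invisible(path)
}

read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  num <- suppressWarnings(as.numeric(vals))
  parsed <- ifelse(is.na(num), vals, num)
  do.call(pipeline_config, stats::setNames(as.list(parsed), keys))
}

#' Build and serialize a semantic space (command entry point)
#'
#' Runs corpus reading, preprocessing, chunking, vocabulary filtering and
#' SVD, then writes the space directory, the context table, the
#' vocabulary, a build log, and the exact configuration used.
#'
#' @param input Corpus path.
#' @param layout Corpus layout (`"lines"` or `"files"`).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()] list.
#' @return `out_dir`, invisibly.
#' @export
cmd_build_space <- function(input, layout = "lines", out_dir,
                            config = pipeline_config()) {
  corpus <- read_corpus(input, layout)
  corpus <- preprocess_corpus(corpus)
  built <- build_space(corpus, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_space(built$space, file.path(out_dir, "space"))
  write_contexts(built$contexts, file.path(out_dir, "contexts.tsv"))
  readr::write_tsv(tibble::as_tibble(built$vocab),
                   file.path(out_dir, "vocabulary.tsv"), progress = FALSE)
  write_config(config, file.path(out_dir, "config.txt"))
  writeLines(c(
    sprintf("documents: %d", nrow(corpus)),
    sprintf("contexts: %d", nrow(built$contexts)),
    sprintf("vocabulary: %d", nrow(built$vocab)),
    sprintf("matrix: %d x %d", nrow(built$matrix), ncol(built$matrix)),
    sprintf("svd_dim: %d", built$space$d)
  ), file.path(out_dir, "build.log"))
  invisible(out_dir)
}

#' Compute ambiguity measures for a corpus (command entry point)
#'
#' @param input Corpus path.
#' @param layout Corpus layout.
#' @param out_dir Output directory; receives `records.tsv`,
#'   `correlations.tsv`, `rejects.txt`, and `config.txt`.
#' @param wordlist Optional character vector of words to score.
#' @param config A [pipeline_config()] list.
#' @return The `ambiguity_table`, invisibly.
#' @export
cmd_measures <- function(input, layout = "lines", out_dir, wordlist = NULL,
                         config = pipeline_config()) {
  corpus <- preprocess_corpus(read_corpus(input, layout))
  records <- ambiguity_measures(corpus, words = wordlist, config = config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_records(records, file.path(out_dir, "records.tsv"))
  readr::write_tsv(measure_correlations(records),
                   file.path(out_dir, "correlations.tsv"), progress = FALSE)
  writeLines(attr(records, "rejects"), file.path(out_dir, "rejects.txt"))
  write_config(config, file.path(out_dir, "config.txt"))
  invisible(records)
}

#' Simulate, measure, and evaluate separation (command entry point)
#'
#' Generates a synthetic corpus with planted homonyms/polysemes, runs the
#' full measurement pipeline on it, and evaluates whether the measures
#' recover the planted distinction.
#'
#' @param spec A [synthetic_spec()].
#' @param config A [pipeline_config()] list; defaults to the synthetic
#'   profile (40-token chunks, 100 SVD dims, k_max 30) sized to these
#'   corpora.
#' @param out_dir Optional output directory for the corpus, ground truth,
#'   records, report, and config.
#' @return List with `records`, `truth`, and `report`
#'   (a `separation_report`).
#' @export
cmd_simulate <- function(spec = synthetic_spec(),
                         config = synthetic_profile(seed = spec$seed),
                         out_dir = NULL) {
  gen <- generate_corpus(spec)
  records <- ambiguity_measures(gen$corpus, config = config)
  report <- evaluate_separation(records, gen$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(purrr::map_chr(gen$corpus$tokens, paste, collapse = " "),
               file.path(out_dir, "corpus.txt"))
    readr::write_tsv(gen$truth, file.path(out_dir, "ground_truth.tsv"),
                     progress = FALSE)
    write_records(records, file.path(out_dir, "records.tsv"))
    write_config(config, file.path(out_dir, "config.txt"))
    utils::capture.output(print(report),
                          file = file.path(out_dir, "report.txt"))
  }
  list(records = records, truth = gen$truth, report = report)
}

#' Pipeline configuration profile for synthetic corpora
#'
#' The default [pipeline_config()] is sized for a real corpus
#' (150-token contexts, 300 dimensions, cluster counts up to 200). The
#' synthetic corpora generated by [synthetic_spec()] are much smaller:
#' this profile keeps the 150-token context but reduces the space to 20
#' dimensions (about 2% of the context count, the same order as 300
#' dimensions against tens of thousands of contexts) and examines
#' cluster counts up to 30, past the SSE plateau for context sets of
#' the size the generator produces.
#'
#' @param ... Named overrides, as in [pipeline_config()].
#' @return Named list of configuration values.
#' @export
synthetic_profile <- function(...) {
  base <- list(chunk_size = 150, svd_dim = 20, k_max = 30)
  do.call(pipeline_config, utils::modifyList(base, list(...)))
}
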