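#' Specification for a topic-structured synthetic corpus
#'
#' Defines a document-level topic mixture with unigram emissions, plus
#' planted target words whose context geometry is known by construction:
#' unambiguous words live in one topic, polysemes in two correlated
#' topics (one diffuse context cloud), homonyms in two unrelated topics
#' (two separate context clusters). Topics are arranged in consecutive
#' correlated pairs (1,2), (3,4), ...; a document of topic t draws each
#' token from its pair partner with a per-document blend weight drawn
#' uniformly from `[0, topic_correlation]`, so the documents of a pair
#' populate a continuum of sense blends between the two topic poles
#' (at the default 0.5 the two half-continua meet, making the pair one
#' connected cloud). Planted homonyms take their two topics from two
#' different pairs (there is no mixing between pairs, so their contexts
#' fall in two unrelated clusters); planted polysemes take both topics
#' of one pair (one diffuse connected cloud).
#'
#' Defaults emulate a small balanced corpus in which each planted word
#' accumulates a few dozen contexts, enough for the clustering measures
#' to be defined while staying desk-scale.
#'
#' @param n_topics Number of topics (even; default 8).
#' @param vocab_per_topic Word types per topic (default 60).
#' @param n_background Shared background types occurring in all topics
#'   (default 40).
#' @param background_mass Probability mass of background types in every
#'   document (default 0.2).
#' @param n_documents Number of documents (default 480).
#' @param doc_length Tokens per document (default 300).
#' @param topic_correlation Upper bound of the per-document blend weight
#'   toward the partner topic, in \[0, 1\] (default 0.5).
#' @param n_homonyms,n_polysemes,n_unambiguous Planted words per class
#'   (defaults 30, 30, 15).
#' @param target_rate Expected per-topic emission probability of a
#'   planted word: a word is emitted (once, at a random position) in
#'   each document of one of its topics with this probability on
#'   average (default 0.5). Expected context counts are thereby matched
#'   between homonyms and polysemes.
#' @param dominance_range Range of the per-word meaning dominance for
#'   two-topic words (default `c(0.55, 0.95)`): a word's first topic is
#'   hit at rate `2 * dominance * target_rate` and its second at
#'   `2 * (1 - dominance) * target_rate`, emulating the dominant /
#'   subordinate meaning-frequency imbalance of real ambiguous words
#'   without changing the expected total context count.
#' @param min_contexts Minimum contexts each planted word must reach;
#'   generation retries with a perturbed seed until satisfied
#'   (default 10).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_topics = 8, vocab_per_topic = 60,
                           n_background = 40, background_mass = 0.2,
                           n_documents = 480, doc_length = 300,
                           topic_correlation = 0.5,
                           n_homonyms = 30, n_polysemes = 30,
                           n_unambiguous = 15,
                           target_rate = 0.5, dominance_range = c(0.55, 0.95),
                           min_contexts = 10,
                           seed = 1L) {
  if (n_topics %% 2 != 0 || n_topics < 4) {
    stop("n_topics must be an even number >= 4", call. = FALSE)
  }
  stopifnot(topic_correlation >= 0, topic_correlation <= 1,
            target_rate > 0, target_rate <= 1,
            length(dominance_range) == 2, dominance_range[1] >= 0.5,
            dominance_range[2] <= 1, dominance_range[1] <= dominance_range[2])
  structure(
    list(n_topics = n_topics, vocab_per_topic = vocab_per_topic,
         n_background = n_background, background_mass = background_mass,
         n_documents = n_documents, doc_length = doc_length,
         topic_correlation = topic_correlation,
         n_homonyms = n_homonyms, n_polysemes = n_polysemes,
         n_unambiguous = n_unambiguous,
         target_rate = target_rate, dominance_range = dominance_range,
         min_contexts = min_contexts,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# cycle planted words over the available topic assignments
plant_words <- function(spec) {
  pairs <- matrix(seq_len(spec$n_topics), ncol = 2, byrow = TRUE) # correlated pairs
  n_pairs <- nrow(pairs)
  planted <- list()
  # homonyms: one topic from each of two different pairs -> unrelated
  if (spec$n_homonyms > 0) {
    combos <- utils::combn(n_pairs, 2)
    for (i in seq_len(spec$n_homonyms)) {
      cp <- combos[, (i - 1) %% ncol(combos) + 1]
      side <- (i - 1) %/% ncol(combos) %% 2 + 1
      planted[[length(planted) + 1]] <- list(
        word = sprintf("hom%03d", i), class = "homonym",
        topics = c(pairs[cp[1], side], pairs[cp[2], side]))
    }
  }
  # polysemes: both topics of one correlated pair
  for (i in seq_len(spec$n_polysemes)) {
    p <- (i - 1) %% n_pairs + 1
    planted[[length(planted) + 1]] <- list(
      word = sprintf("pol%03d", i), class = "polyseme",
      topics = pairs[p, ])
  }
  for (i in seq_len(spec$n_unambiguous)) {
    planted[[length(planted) + 1]] <- list(
      word = sprintf("una%03d", i), class = "unambiguous",
      topics = (i - 1) %% spec$n_topics + 1)
  }
  planted
}

generate_once <- function(spec, seed) {
  set.seed(seed)
  n_topics <- spec$n_topics
  # per-topic vocabularies with a 1/rank unigram law, plus shared background
  topic_vocab <- lapply(seq_len(n_topics), function(t) {
    sprintf("t%02d_w%03d", t, seq_len(spec$vocab_per_topic))
  })
  rank_p <- (1 / seq_len(spec$vocab_per_topic))
  rank_p <- rank_p / sum(rank_p)
  bg_vocab <- sprintf("bg_w%03d", seq_len(spec$n_background))
  bg_p <- (1 / seq_len(spec$n_background))
  bg_p <- bg_p / sum(bg_p)

  planted <- plant_words(spec)
  partner <- ifelse(seq_len(n_topics) %% 2 == 1,
                    seq_len(n_topics) + 1, seq_len(n_topics) - 1)

  doc_topic <- rep_len(seq_len(n_topics), spec$n_documents) # balanced
  doc_topic <- sample(doc_topic)

  docs <- vector("list", spec$n_documents)
  for (dd in seq_len(spec$n_documents)) {
    t <- doc_topic[dd]
    n <- spec$doc_length
    # per-document blend toward the partner topic: documents of a
    # correlated pair populate a continuum of sense blends rather than
    # two fixed mixtures
    theta <- stats::runif(1, 0, spec$topic_correlation)
    src <- stats::runif(n)
    from_bg <- src < spec$background_mass
    from_partner <- !from_bg &
      (src < spec$background_mass + (1 - spec$background_mass) * theta)
    from_own <- !(from_bg | from_partner)
    tok <- character(n)
    if (any(from_bg)) {
      tok[from_bg] <- sample(bg_vocab, sum(from_bg), replace = TRUE, prob = bg_p)
    }
    if (any(from_partner)) {
      tok[from_partner] <- sample(topic_vocab[[partner[t]]], sum(from_partner),
                                  replace = TRUE, prob = rank_p)
    }
    if (any(from_own)) {
      tok[from_own] <- sample(topic_vocab[[t]], sum(from_own),
                              replace = TRUE, prob = rank_p)
    }
    docs[[dd]] <- tok
  }

  # plant target words: once, at a random position, in each eligible doc
  # with a per-topic rate. Two-topic words get a sampled meaning
  # dominance delta: their first topic is hit at rate 2*delta*target_rate
  # and the second at 2*(1-delta)*target_rate, so the expected context
  # count stays at 2*target_rate*docs-per-topic while the split between
  # the two meanings varies word to word, as meaning frequencies do in
  # real lexicons.
  dominance <- rep(NA_real_, length(planted))
  hits_by_doc <- vector("list", spec$n_documents)
  for (i in seq_along(planted)) {
    pw <- planted[[i]]
    if (length(pw$topics) == 2) {
      delta <- stats::runif(1, spec$dominance_range[1], spec$dominance_range[2])
      dominance[i] <- delta
      rates <- pmin(2 * spec$target_rate * c(delta, 1 - delta), 1)
    } else {
      rates <- rep(spec$target_rate, length(pw$topics))
    }
    for (j in seq_along(pw$topics)) {
      eligible <- which(doc_topic == pw$topics[j])
      hit <- eligible[stats::runif(length(eligible)) < rates[j]]
      for (dd in hit) {
        hits_by_doc[[dd]] <- c(hits_by_doc[[dd]], pw$word)
      }
    }
  }
  # place all planted words of a document at distinct positions, so no
  # planted occurrence can overwrite another
  for (dd in seq_len(spec$n_documents)) {
    words_here <- hits_by_doc[[dd]]
    if (length(words_here)) {
      pos <- sample.int(length(docs[[dd]]), length(words_here))
      docs[[dd]][pos] <- words_here
    }
  }

  corpus <- new_tokenized_corpus(
    tibble::tibble(doc_id = sprintf("doc%05d", seq_len(spec$n_documents)),
                   tokens = docs)
  )
  truth <- tibble::tibble(
    word = purrr::map_chr(planted, "word"),
    class = purrr::map_chr(planted, "class"),
    topics = purrr::map_chr(planted, ~ paste(.x$topics, collapse = ",")),
    dominance = dominance
  )
  list(corpus = corpus, truth = truth, doc_topic = doc_topic)
}

#' Generate a synthetic topic-structured corpus
#'
#' Emits a corpus according to a [synthetic_spec()], plus a ground-truth
#' table for the planted words. Each document samples a topic; each token
#' comes from that topic's unigram distribution, its correlated partner
#' topic's (with probability `topic_correlation`), or the shared
#' background. Planted words are inserted into documents of their
#' assigned topics. If any planted word ends up occurring (as counted at
#' the planted emission step) in fewer than `min_contexts` documents, the
#' corpus is regenerated with a perturbed seed (bounded retries).
#'
#' @param spec A `synthetic_spec`.
#' @param max_retries Regeneration attempts before failing (default 5).
#' @return A list with `corpus` (a `tokenized_corpus`), `truth` (tibble
#'   `word`, `class`, `topics`), and `doc_topic` (integer topic per
#'   document).
#' @export
generate_corpus <- function(spec, max_retries = 5) {
  expected <- spec$target_rate * spec$n_documents / spec$n_topics
  if (expected < spec$min_contexts / 2) {
    stop("infeasible spec: target_rate * documents-per-topic = ",
         round(expected, 1), " cannot reach min_contexts = ",
         spec$min_contexts, call. = FALSE)
  }
  for (try in seq_len(max_retries)) {
    seed <- spec$seed + (try - 1L) * 1000003L
    out <- generate_once(spec, seed)
    counts <- table(factor(unlist(out$corpus$tokens, use.names = FALSE),
                           levels = out$truth$word))
    if (all(counts >= spec$min_contexts)) {
      out$seed_used <- seed
      return(out)
    }
  }
  stop("could not satisfy min_contexts for all planted words after ",
       max_retries, " attempts; raise target_rate or n_documents",
       call. = FALSE)
}

#' Evaluate homonym/polyseme separation of the ambiguity measures
#'
#' Joins per-word measures with ground truth and reports, per class, the
#' mean SemVar and SemD; a one-sided Wilcoxon rank-sum comparison of
#' homonyms vs polysemes per measure (homonyms are expected to score
#' *lower* SemVar and *higher* SemD); the standardized group difference
#' (Cohen's d on class means) per measure; and which measure separates
#' the classes more strongly.
#'
#' @param records Ambiguity record tibble (from [ambiguity_measures()]).
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @return A `separation_report` list with elements `class_means`,
#'   `tests` (tibble: measure, statistic, p.value, cohens_d), and
#'   `stronger_measure`.
#' @export
evaluate_separation <- function(records, truth) {
  joined <- dplyr::inner_join(truth, records, by = "word")
  n_class <- table(joined$class)
  if (any(n_class[c("homonym", "polyseme")] < 10)) {
    stop("need >= 10 planted words per class", call. = FALSE)
  }
  frac_missing <- mean(!is.finite(joined$semvar) | !is.finite(joined$semd))
  if (frac_missing > 0.5) {
    stop("measures missing for ", round(100 * frac_missing),
         "% of planted words", call. = FALSE)
  }
  class_means <- joined |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_semvar = mean(.data$semvar, na.rm = TRUE),
                     mean_semd = mean(.data$semd, na.rm = TRUE),
                     mean_cd = mean(.data$cd), .groups = "drop")
  hom <- dplyr::filter(joined, .data$class == "homonym")
  pol <- dplyr::filter(joined, .data$class == "polyseme")
  one_measure <- function(x, y, alternative) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    wt <- stats::wilcox.test(x, y, alternative = alternative, exact = FALSE)
    sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    d <- if (sp > 0) abs(mean(x) - mean(y)) / sp else 0
    # rank-biserial correlation: 2 * (U / (n1 n2)) - 1, signed so that
    # positive means the first group ranks higher
    rb <- 2 * unname(wt$statistic) / (length(x) * length(y)) - 1
    tibble::tibble(statistic = unname(wt$statistic),
                   p.value = wt$p.value, cohens_d = d, rank_biserial = rb)
  }
  tests <- dplyr::bind_rows(
    dplyr::mutate(one_measure(hom$semvar, pol$semvar, "less"),
                  measure = "semvar", .before = 1),
    dplyr::mutate(one_measure(hom$semd, pol$semd, "greater"),
                  measure = "semd", .before = 1)
  )
  stronger <- tests$measure[which.max(tests$cohens_d)]
  structure(list(class_means = class_means, tests = tests,
                 stronger_measure = stronger),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("Homonym/polyseme separation report\n\nClass means:\n")
  print(as.data.frame(x$class_means), row.names = FALSE)
  cat("\nRank-sum comparisons (homonym vs polyseme):\n")
  print(as.data.frame(x$tests), row.names = FALSE)
  cat("\nStronger separating measure:", x$stronger_measure, "\n")
  invisible(x)
}
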