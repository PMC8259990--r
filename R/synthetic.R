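# Synthetic condition-dependent corpus generator.
#
# Emits MEDLINE-style records whose word distribution depends on the
# record's keyword conditions through a known mixture, with deterministic
# per-word POS/dependency/entity labels, so every downstream module can be
# tested against closed-form statistics.

#' Define a synthetic conditional grammar
#'
#' The grammar owns a word inventory partitioned into per-keyword topic
#' supports plus a background support. Words of a document are drawn i.i.d.
#' from `mixing * mean(topic distributions of its keywords) +
#' (1 - mixing) * background`; documents without keywords use the
#' background distribution alone. Within each support the distribution is
#' Zipf-like (probability proportional to 1/rank). Every word carries fixed
#' POS/dependency/entity labels assigned deterministically at grammar
#' construction, so annotation is a pure function of the word.
#'
#' @param n_words total word inventory size (default 200).
#' @param n_keywords number of keyword conditions (default 4).
#' @param topic_size words per topic support; the remainder of the
#'   inventory is background. Defaults to `n_words %/% (2 * n_keywords)`.
#' @param mixing weight of the topic mixture against the background, in
#'   `[0, 1]` (default 0.75).
#' @param year_range inclusive calendar-year span of the corpus.
#' @param sentence_words integer range of words per sentence.
#' @param seed integer seed fixing the inventory and label assignment.
#' @return An object of class `synthetic_grammar`.
#' @export
synthetic_grammar <- function(n_words = 200L, n_keywords = 4L,
                              topic_size = NULL, mixing = 0.75,
                              year_range = c(1990L, 2019L),
                              sentence_words = c(5L, 9L), seed = 1L) {
  stopifnot(n_words >= 2L * n_keywords, n_keywords >= 1L,
            mixing >= 0, mixing <= 1)
  topic_size <- as.integer(topic_size %||% (n_words %/% (2L * n_keywords)))
  if (topic_size * n_keywords >= n_words)
    stopf("topic supports exhaust the inventory; reduce topic_size")
  words <- with_seed(seed, {
    w <- character(0)
    while (length(w) < n_words) {
      cand <- vapply(seq_len(n_words), function(i) {
        k <- sample(3:7, 1L)
        paste(sample(letters, k, replace = TRUE), collapse = "")
      }, "")
      w <- unique(c(w, cand))
    }
    w[seq_len(n_words)]
  })
  keywords <- sprintf("topic%02d", seq_len(n_keywords))
  idx <- seq_len(n_words)
  topic_support <- lapply(seq_len(n_keywords), function(k)
    idx[((k - 1L) * topic_size + 1L):(k * topic_size)])
  background_support <- idx[(n_keywords * topic_size + 1L):n_words]
  zipf <- function(support) {
    p <- numeric(n_words)
    p[support] <- 1 / seq_along(support)
    p / sum(p)
  }
  topics <- lapply(topic_support, zipf)
  names(topics) <- keywords
  background <- zipf(background_support)
  labels <- with_seed(seed + 1L, {
    content_pos <- c("NOUN", "VERB", "ADJ", "ADV", "PROPN")
    content_dep <- c("nsubj", "dobj", "amod", "advmod", "ROOT", "pobj",
                     "compound", "conj")
    ent_cycle <- ENTITY_CLASSES[-length(ENTITY_CLASSES)]
    data.frame(
      word = words,
      pos = sample(content_pos, n_words, replace = TRUE),
      dep = sample(content_dep, n_words, replace = TRUE),
      # topic words carry entity classes; background is mostly non-entity
      ent = ifelse(idx <= n_keywords * topic_size,
                   ent_cycle[(idx - 1L) %% length(ent_cycle) + 1L],
                   ifelse(stats::runif(n_words) < 0.15,
                          sample(ent_cycle, n_words, replace = TRUE),
                          NULL_ENT)),
      stringsAsFactors = FALSE)
  })
  structure(list(words = words, keywords = keywords,
                 topics = topics, background = background,
                 topic_support = stats::setNames(topic_support, keywords),
                 background_support = background_support,
                 mixing = mixing, year_range = as.integer(year_range),
                 sentence_words = as.integer(sentence_words),
                 labels = labels, seed = as.integer(seed)),
            class = "synthetic_grammar")
}

#' @export
print.synthetic_grammar <- function(x, ...) {
  cat(sprintf(
    "<synthetic_grammar> %d words, %d keyword topics (%d words each), mixing %.2f\n",
    length(x$words), length(x$keywords),
    length(x$topic_support[[1]]), x$mixing))
  invisible(x)
}

#' Exact conditional word distribution of a grammar
#'
#' Returns the next-word distribution the generator draws from under a
#' given keyword set: the mixing-weighted average of the selected topic
#' distributions against the background, or the background alone when the
#' condition set is empty.
#'
#' @param grammar a [synthetic_grammar()].
#' @param conditions character vector of grammar keywords (may be empty).
#' @return Named probability vector over the word inventory (sums to 1).
#' @export
true_conditional_distribution <- function(grammar, conditions = character()) {
  stopifnot(inherits(grammar, "synthetic_grammar"))
  if (length(conditions) == 0L)
    return(stats::setNames(grammar$background, grammar$words))
  unknown <- setdiff(conditions, grammar$keywords)
  if (length(unknown))
    stopf("unknown condition(s): %s", paste(unknown, collapse = ", "))
  topic <- Reduce(`+`, grammar$topics[conditions]) / length(conditions)
  p <- grammar$mixing * topic + (1 - grammar$mixing) * grammar$background
  stats::setNames(p / sum(p), grammar$words)
}

cap_first <- function(s) {
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

# Build one sentence and its word annotations, offset to start at `offset`.
synth_sentence <- function(grammar, p, offset) {
  k <- sample(grammar$sentence_words[1]:grammar$sentence_words[2], 1L)
  wi <- sample(length(grammar$words), k, replace = TRUE, prob = p)
  ws <- grammar$words[wi]
  shown <- c(cap_first(ws[1]), ws[-1])
  starts <- offset + cumsum(c(0L, nchar(shown[-k]) + 1L))
  ann <- data.frame(start = starts, end = starts + nchar(shown) - 1L,
                    pos = grammar$labels$pos[wi],
                    dep = grammar$labels$dep[wi],
                    ent = grammar$labels$ent[wi],
                    stringsAsFactors = FALSE)
  list(text = paste0(paste(shown, collapse = " "), "."),
       ann = ann,
       len = sum(nchar(shown)) + (k - 1L) + 1L)
}

#' Sample a synthetic citation corpus
#'
#' Each record draws 1--3 keyword conditions (capped by the grammar's
#' keyword count), a year, a one-sentence title and a 2--6 sentence
#' abstract whose words follow the conditional mixture distribution, plus
#' word-level annotations from the grammar's deterministic label map
#' (offsets are into the document text, title first).
#'
#' @param grammar a [synthetic_grammar()].
#' @param n_docs number of records (>= 1).
#' @param seed integer seed; a fixed seed reproduces the corpus exactly.
#' @param keyword_range integer range of keyword conditions per record.
#' @return List of [medline_record()] objects with annotations.
#' @export
sample_corpus <- function(grammar, n_docs, seed = 1L,
                          keyword_range = c(1L, 3L)) {
  stopifnot(inherits(grammar, "synthetic_grammar"))
  if (!is.numeric(n_docs) || n_docs < 1L)
    stopf("`n_docs` must be at least 1")
  kmax <- min(keyword_range[2], length(grammar$keywords))
  kmin <- min(keyword_range[1], kmax)
  with_seed(seed, {
    lapply(seq_len(n_docs), function(i) {
      nk <- sample(kmin:kmax, 1L)
      kws <- sample(grammar$keywords, nk)
      p <- true_conditional_distribution(grammar, kws)
      year <- sample(grammar$year_range[1]:grammar$year_range[2], 1L)
      title <- synth_sentence(grammar, p, offset = 1L)
      n_sent <- sample(2:6, 1L)
      off <- title$len + 2L  # title text + joining space
      sents <- vector("list", n_sent)
      for (s in seq_len(n_sent)) {
        sents[[s]] <- synth_sentence(grammar, p, offset = off)
        off <- off + sents[[s]]$len + 1L
      }
      medline_record(
        id = sprintf("SYN%06d", i),
        title = title$text,
        abstract = paste(vapply(sents, `[[`, "", "text"), collapse = " "),
        year = year, keywords = kws, language = "eng",
        annotations = do.call(rbind, c(list(title$ann),
                                       lapply(sents, `[[`, "ann"))))
    })
  })
}
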