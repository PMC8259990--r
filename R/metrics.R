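# NLG evaluation suite: per-order BLEU (no brevity penalty, summed across
# orders rather than geometric-mean), ROUGE-L with the F-measure constant
# beta, TF-IDF n-gram consensus scoring (CIDEr) with a title-masked
# variant, a stem-matching METEOR score, and the sentence-wise
# multi-reference evaluation protocol with cumulative score distributions.

#' Word tokenization for metrics
#'
#' Lowercases and splits on whitespace and punctuation (punctuation runs
#' become their own tokens). Independent of the subword tokenizer.
#'
#' @param text single string.
#' @return Character vector of word tokens.
#' @export
tokenize_words <- function(text) {
  m <- gregexpr("[[:alnum:]]+|[^[:alnum:][:space:]]", tolower(text))[[1]]
  if (m[1] == -1L) return(character(0))
  regmatches(tolower(text), list(m))[[1]]
}

as_tokens <- function(x) {
  if (length(x) == 1L && !inherits(x, "AsIs")) tokenize_words(x)
  else as.character(x)
}

as_ref_list <- function(refs) {
  if (is.list(refs)) lapply(refs, as_tokens) else list(as_tokens(refs))
}

ngram_counts <- function(tokens, k) {
  n <- length(tokens)
  if (n < k) return(integer(0))
  grams <- if (k == 1L) tokens
  else vapply(seq_len(n - k + 1L), function(i)
    paste(tokens[i:(i + k - 1L)], collapse = " "), "")
  tab <- table(grams)
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-order BLEU score
#'
#' The fraction of the hypothesis's k-gram positions whose grams also occur
#' in the reference, with per-gram counts clipped at the reference count
#' (the maximum across references when several are given). No brevity
#' penalty is applied and orders are never combined; see [bleu_sum()] for
#' the summed variant. A hypothesis shorter than `k` tokens scores 0.
#'
#' @param hyp hypothesis: a string or a token vector.
#' @param ref reference: a string, a token vector, or a list of either.
#' @param k n-gram order (>= 1).
#' @param distinct_denominator divide by the number of distinct k-grams
#'   instead of k-gram positions (default FALSE).
#' @return Score in `[0, 1]`.
#' @export
bleu_k <- function(hyp, ref, k, distinct_denominator = FALSE) {
  stopifnot(k >= 1L)
  h <- as_tokens(hyp)
  if (length(h) == 0L) {
    warning("empty hypothesis; BLEU = 0", call. = FALSE)
    return(0)
  }
  ch <- ngram_counts(h, k)
  if (length(ch) == 0L) return(0)
  refs <- as_ref_list(ref)
  clip <- rep(0L, length(ch))
  for (r in refs) {
    cr <- ngram_counts(r, k)
    hit <- match(names(ch), names(cr))
    clip <- pmax(clip, ifelse(is.na(hit), 0L, cr[hit]))
  }
  denom <- if (distinct_denominator) length(ch) else length(h) - k + 1L
  sum(pmin(ch, clip)) / denom
}

#' Summed BLEU over orders 1--4
#'
#' `bleu_1 + bleu_2 + bleu_3 + bleu_4`; range `[0, 4]`.
#'
#' @inheritParams bleu_k
#' @return Score in `[0, 4]`.
#' @export
bleu_sum <- function(hyp, ref) {
  sum(vapply(1:4, function(k)
    suppressWarnings(bleu_k(hyp, ref, k)), numeric(1)))
}

lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    eq <- a[i] == b
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (eq[j]) prev[j] + 1L
                     else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' ROUGE-L score
#'
#' Longest-common-subsequence F-measure: with `S` the LCS of hypothesis and
#' reference, precision `p = |S|/|H|` and recall `r = |S|/|R|` combine as
#' `(1 + beta^2) p r / (r + beta^2 p)`. With several references the
#' maximum score is returned.
#'
#' @inheritParams bleu_k
#' @param beta precision/recall trade-off constant (default 1.2).
#' @return Score in `[0, 1]`.
#' @export
rouge_l <- function(hyp, ref, beta = 1.2) {
  h <- as_tokens(hyp)
  if (length(h) == 0L) return(0)
  refs <- as_ref_list(ref)
  best <- 0
  for (r in refs) {
    if (length(r) == 0L) next
    s <- lcs_length(h, r)
    if (s == 0L) next
    p <- s / length(h); rc <- s / length(r)
    best <- max(best, (1 + beta^2) * p * rc / (rc + beta^2 * p))
  }
  best
}

#' n-gram IDF statistics for CIDEr
#'
#' Computes, per n-gram order, `log(N / df)` document frequencies over a
#' reference corpus (each corpus element is one document; `df` is the
#' number of documents containing the gram).
#'
#' @param corpus list of documents (strings or token vectors); non-empty.
#' @param orders n-gram orders (default 1--4).
#' @return List of class `cider_idf` with per-order idf tables and `N`.
#' @export
cider_idf <- function(corpus, orders = 1:4) {
  if (length(corpus) == 0L) stopf("empty reference corpus for IDF")
  toks <- lapply(corpus, as_tokens)
  N <- length(toks)
  idf <- lapply(orders, function(k) {
    df <- table(unlist(lapply(toks, function(t) names(ngram_counts(t, k)))))
    stats::setNames(log(N / as.numeric(df)), names(df))
  })
  structure(list(idf = stats::setNames(idf, paste0("n", orders)),
                 orders = orders, N = N),
            class = "cider_idf")
}

tfidf_vec <- function(tokens, k, idf_tab, N, masked = character(0)) {
  counts <- ngram_counts(tokens, k)
  if (length(counts) == 0L) return(numeric(0))
  hit <- match(names(counts), names(idf_tab))
  w <- as.numeric(counts) * ifelse(is.na(hit), log(N), idf_tab[hit])
  names(w) <- names(counts)
  if (length(masked)) w[names(w) %in% masked] <- 0
  w
}

cosine_named <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) return(0)
  sum(a[shared] * b[shared]) / (na * nb)
}

cider_score <- function(hyp, refs, idf, title_tokens = NULL) {
  stopifnot(inherits(idf, "cider_idf"))
  h <- as_tokens(hyp)
  refs <- as_ref_list(refs)
  per_order <- vapply(seq_along(idf$orders), function(oi) {
    k <- idf$orders[oi]
    masked <- if (is.null(title_tokens)) character(0)
              else names(ngram_counts(title_tokens, k))
    vh <- tfidf_vec(h, k, idf$idf[[oi]], idf$N, masked)
    mean(vapply(refs, function(r) {
      vr <- tfidf_vec(r, k, idf$idf[[oi]], idf$N, masked)
      cosine_named(vh, vr)
    }, numeric(1)))
  }, numeric(1))
  10 * mean(per_order)
}

#' CIDEr consensus score
#'
#' For each n-gram order, the cosine similarity between the TF-IDF n-gram
#' vectors of the hypothesis and each reference, averaged over references;
#' the final score is the mean over orders scaled by 10 (the reference
#' convention for this metric family).
#'
#' @inheritParams bleu_k
#' @param refs reference(s): string, token vector or list of either.
#' @param idf a [cider_idf()] object computed over the reference corpus.
#' @return Non-negative score.
#' @export
cider <- function(hyp, refs, idf) {
  cider_score(hyp, refs, idf, title_tokens = NULL)
}

#' Title-masked CIDEr
#'
#' Identical to [cider()] except that every n-gram occurring in the title
#' has its TF-IDF weight forced to zero in both hypothesis and reference
#' vectors, so sentences that only recycle title n-grams score 0. This
#' measures non-trivial content generation beyond the prompt.
#'
#' @inheritParams cider
#' @param title title text (string or token vector); empty title masks
#'   nothing.
#' @return Non-negative score.
#' @export
cider_title <- function(hyp, refs, title, idf) {
  tt <- as_tokens(title)
  if (length(tt) == 0L) return(cider(hyp, refs, idf))
  cider_score(hyp, refs, idf, title_tokens = tt)
}

# Unigram alignment: exact matches first, then Porter-stem matches, each
# hypothesis token matched to the earliest unused reference token.
meteor_align <- function(h, r) {
  used <- rep(FALSE, length(r))
  map <- rep(NA_integer_, length(h))
  for (i in seq_along(h)) {
    j <- which(!used & r == h[i])
    if (length(j)) { map[i] <- j[1]; used[j[1]] <- TRUE }
  }
  hs <- vapply(h, porter_stem, "")
  rs <- vapply(r, porter_stem, "")
  for (i in seq_along(h)) {
    if (!is.na(map[i])) next
    j <- which(!used & rs == hs[i])
    if (length(j)) { map[i] <- j[1]; used[j[1]] <- TRUE }
  }
  map
}

count_chunks <- function(map) {
  idx <- which(!is.na(map))
  if (length(idx) == 0L) return(0L)
  breaks <- diff(idx) != 1L | diff(map[idx]) != 1L
  1L + sum(breaks)
}

#' Stem-matching METEOR score
#'
#' Classic alignment-based scoring restricted to exact and Porter-stem
#' unigram matches (no synonym stage): with `m` matched unigrams,
#' precision `P = m/|H|` and recall `R = m/|R|` combine as
#' `F = 10 P R / (R + 9 P)`; a fragmentation penalty
#' `0.5 (chunks/m)^3` discounts scattered matches. Multiple references:
#' maximum score.
#'
#' @inheritParams bleu_k
#' @return Score in `[0, 1]`; 0 when nothing matches.
#' @export
meteor_lite <- function(hyp, ref) {
  h <- as_tokens(hyp)
  if (length(h) == 0L) return(0)
  refs <- as_ref_list(ref)
  best <- 0
  for (r in refs) {
    if (length(r) == 0L) next
    map <- meteor_align(h, r)
    m <- sum(!is.na(map))
    if (m == 0L) next
    P <- m / length(h); R <- m / length(r)
    F <- 10 * P * R / (R + 9 * P)
    pen <- 0.5 * (count_chunks(map) / m)^3
    best <- max(best, F * (1 - pen))
  }
  best
}

# Case-insensitive sentence splitter for (lowercased) generated text.
split_sentences_loose <- function(text) {
  out <- strsplit(text, "(?<=[.?!])\\s+", perl = TRUE)[[1]]
  trimws(out[nzchar(trimws(out))])
}

#' Sentence-wise multi-reference evaluation
#'
#' Splits the generated abstract into sentences and scores every sentence
#' against the full set of reference sentences (the human-written
#' abstract's sentences) for each metric, reporting per-sentence scores,
#' aggregate means and cumulative score distributions (fraction of
#' sentences at or above each threshold).
#'
#' @param generated generated abstract text.
#' @param reference human-written reference abstract text.
#' @param title the prompt title (used by the title-masked metric).
#' @param idf optional [cider_idf()]; defaults to statistics over the
#'   reference sentences of this abstract.
#' @param beta ROUGE-L constant.
#' @return Object of class `metric_report` with `scores` (long
#'   data.frame), `means`, `cumulative` (threshold/fraction points per
#'   metric) and `n_sentences`.
#' @export
evaluate_generation <- function(generated, reference, title = "",
                                idf = NULL, beta = 1.2) {
  gen_sents <- split_sentences_loose(generated)
  ref_sents <- lapply(split_sentences_loose(reference), tokenize_words)
  ref_sents <- ref_sents[vapply(ref_sents, length, 1L) > 0L]
  if (length(ref_sents) == 0L) stopf("reference abstract has no sentences")
  idf <- idf %||% cider_idf(ref_sents)
  metrics <- c("bleu_1", "bleu_sum", "rouge_l", "cider", "cider_title",
               "meteor")
  if (length(gen_sents) == 0L) {
    warning("empty generation; report has zero sentences", call. = FALSE)
    return(structure(list(
      scores = data.frame(sentence = integer(0), metric = character(0),
                          score = numeric(0)),
      means = stats::setNames(rep(NA_real_, length(metrics)), metrics),
      cumulative = data.frame(metric = character(0), threshold = numeric(0),
                              fraction = numeric(0)),
      n_sentences = 0L), class = "metric_report"))
  }
  rows <- list()
  for (si in seq_along(gen_sents)) {
    h <- tokenize_words(gen_sents[si])
    vals <- c(
      bleu_1 = suppressWarnings(bleu_k(h, ref_sents, 1L)),
      bleu_sum = bleu_sum(h, ref_sents),
      rouge_l = rouge_l(h, ref_sents, beta = beta),
      cider = cider(h, ref_sents, idf),
      cider_title = cider_title(h, ref_sents, title, idf),
      meteor = meteor_lite(h, ref_sents))
    rows[[si]] <- data.frame(sentence = si, metric = names(vals),
                             score = unname(vals))
  }
  scores <- do.call(rbind, rows)
  means <- vapply(metrics, function(m)
    mean(scores$score[scores$metric == m]), numeric(1))
  cumulative <- do.call(rbind, lapply(metrics, function(m) {
    sc <- scores$score[scores$metric == m]
    thr <- seq(0, max(sc, 1e-12), length.out = 51L)
    data.frame(metric = m, threshold = thr,
               fraction = vapply(thr, function(t) mean(sc >= t),
                                 numeric(1)))
  }))
  structure(list(scores = scores, means = means, cumulative = cumulative,
                 n_sentences = length(gen_sents)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d generated sentence(s)\n", x$n_sentences))
  if (x$n_sentences > 0L) {
    cat("  mean scores:\n")
    for (m in names(x$means))
      cat(sprintf("    %-12s %.4f\n", m, x$means[[m]]))
  }
  invisible(x)
}

#' Write a metric report as TSV
#'
#' Emits the per-sentence long table (`sentence`, `metric`, `score`) and,
#' alongside it, a `<path>.cumulative.tsv` with the distribution points.
#'
#' @param report a [evaluate_generation()] result.
#' @param path output TSV path.
#' @export
write_metric_report <- function(report, path) {
  utils::write.table(report$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$cumulative,
                     paste0(sub("\\.tsv$", "", path), ".cumulative.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
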