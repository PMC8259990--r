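# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# All segmentations of `text` into pieces drawn from `pieces`
# (character vector); returns list of character vectors.
enumerate_segmentations <- function(text, pieces) {
  n <- nchar(text)
  if (n == 0L) return(list(character(0)))
  out <- list()
  for (p in pieces) {
    k <- nchar(p)
    if (k <= n && substr(text, 1, k) == p) {
      for (rest in enumerate_segmentations(substring(text, k + 1L), pieces))
        out[[length(out) + 1L]] <- c(p, rest)
    }
  }
  out
}

segmentation_score <- function(seg, vocab) {
  sum(vocab$pieces$logp[match(seg, vocab$pieces$piece)])
}

# Naive clipped n-gram precision (position denominator, multi-ref max
# clipping), written with explicit loops.
bf_bleu_k <- function(h, refs, k) {
  if (!is.list(refs)) refs <- list(refs)
  n <- length(h)
  if (n < k) return(0)
  grams_of <- function(x) {
    if (length(x) < k) return(character(0))
    vapply(seq_len(length(x) - k + 1L), function(i)
      paste(x[i:(i + k - 1L)], collapse = "\r"), "")
  }
  hg <- grams_of(h)
  hits <- 0
  for (g in unique(hg)) {
    ch <- sum(hg == g)
    cr <- max(vapply(refs, function(r) sum(grams_of(r) == g), numeric(1)))
    hits <- hits + min(ch, cr)
  }
  hits / (n - k + 1L)
}

# Exponential LCS: enumerate every subsequence of `a`, test containment
# in `b`, take the longest.
bf_lcs <- function(a, b) {
  is_subseq <- function(s, x) {
    j <- 1L
    for (ch in x) {
      if (j <= length(s) && identical(s[j], ch)) j <- j + 1L
    }
    j > length(s)
  }
  best <- 0L
  n <- length(a)
  for (m in seq_len(2^n) - 1L) {
    pick <- as.logical(bitwAnd(m, 2^(seq_len(n) - 1L)))
    s <- a[pick]
    if (length(s) > best && is_subseq(s, b)) best <- length(s)
  }
  best
}

bf_rouge_l <- function(h, r, beta = 1.2) {
  s <- bf_lcs(h, r)
  if (s == 0L) return(0)
  p <- s / length(h); rc <- s / length(r)
  (1 + beta^2) * p * rc / (rc + beta^2 * p)
}

# Hand-built TF-IDF cosine for a toy corpus: raw counts times
# log(N / df), cosine over the full gram union per order, mean over
# orders, times 10.
bf_cider <- function(h, refs, corpus, orders = 1:4,
                     masked_tokens = NULL) {
  if (!is.list(refs)) refs <- list(refs)
  N <- length(corpus)
  grams_of <- function(x, k) {
    if (length(x) < k) return(character(0))
    vapply(seq_len(length(x) - k + 1L), function(i)
      paste(x[i:(i + k - 1L)], collapse = " "), "")
  }
  per_order <- vapply(orders, function(k) {
    all_grams <- unique(unlist(c(lapply(corpus, grams_of, k = k),
                                 list(grams_of(h, k)),
                                 lapply(refs, grams_of, k = k))))
    if (length(all_grams) == 0L) return(0)
    df <- vapply(all_grams, function(g)
      sum(vapply(corpus, function(d) g %in% grams_of(d, k), logical(1))),
      numeric(1))
    idf <- log(N / pmax(df, 1))
    vec <- function(x) {
      gx <- grams_of(x, k)
      w <- vapply(all_grams, function(g) sum(gx == g), numeric(1)) * idf
      if (!is.null(masked_tokens)) {
        mg <- grams_of(masked_tokens, k)
        w[all_grams %in% mg] <- 0
      }
      w
    }
    vh <- vec(h)
    mean(vapply(refs, function(r) {
      vr <- vec(r)
      den <- sqrt(sum(vh^2)) * sqrt(sum(vr^2))
      if (den == 0) 0 else sum(vh * vr) / den
    }, numeric(1)))
  }, numeric(1))
  10 * mean(per_order)
}

random_tokens <- function(n, alphabet = c("a", "b", "c")) {
  sample(alphabet, n, replace = TRUE)
}
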