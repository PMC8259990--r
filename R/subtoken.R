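# Unigram subword vocabulary and probabilistic segmentation.
#
# The vocabulary is trained with a self-contained unigram procedure:
# every character observed in the (lowercased) training sample receives its
# own piece, frequent multi-character substrings are proposed as candidates,
# and piece log-probabilities are refined by EM over the segmentation
# lattice.  Segmentation is either Viterbi (max log-probability path) or
# sampled, where a path with score S (sum of piece log-probabilities) is
# drawn with probability proportional to exp(S / alpha).

SPECIAL_PIECES <- c("<s>", "</s>", "<unk>", "<pad>")
UNK_LOGP <- -20  # penalty score for characters outside the vocabulary

#' Construct a subword vocabulary object
#'
#' Usually called via [build_vocab()] or [read_vocab_tsv()]; builds the
#' piece lookup used by the segmenter.
#'
#' @param pieces data.frame with columns `piece` (character) and `logp`
#'   (non-positive finite log-probability). The four special pieces
#'   `<s>`, `</s>`, `<unk>`, `<pad>` must occupy rows 1--4.
#' @return An object of class `subword_vocab`.
#' @export
subword_vocab <- function(pieces) {
  stopifnot(is.data.frame(pieces), all(c("piece", "logp") %in% names(pieces)))
  if (!identical(pieces$piece[1:4], SPECIAL_PIECES))
    stopf("first four pieces must be the specials: %s",
          paste(SPECIAL_PIECES, collapse = " "))
  if (anyDuplicated(pieces$piece))
    stopf("duplicate pieces in vocabulary")
  if (any(!is.finite(pieces$logp)) || any(pieces$logp > 0))
    stopf("piece log-probabilities must be finite and <= 0")
  lookup <- new.env(parent = emptyenv(), size = nrow(pieces) * 2L)
  for (i in seq_len(nrow(pieces)))
    assign(pieces$piece[i], i, envir = lookup)
  structure(
    list(pieces = pieces,
         size = nrow(pieces),
         bos_id = 1L, eos_id = 2L, unk_id = 3L, pad_id = 4L,
         max_piece_len = max(nchar(pieces$piece[-(1:4)]), 1L),
         lookup = lookup),
    class = "subword_vocab")
}

#' @export
print.subword_vocab <- function(x, ...) {
  cat(sprintf("<subword_vocab> %d pieces (4 special), max piece length %d\n",
              x$size, x$max_piece_len))
  ex <- utils::head(x$pieces$piece[-(1:4)], 8L)
  cat("  e.g.:", paste(sprintf("'%s'", ex), collapse = " "), "\n")
  invisible(x)
}

piece_id <- function(vocab, piece) {
  get0(piece, envir = vocab$lookup, ifnotfound = NA_integer_)
}

#' Train a unigram subword vocabulary
#'
#' Lowercases the training sentences, guarantees a single-character piece for
#' every observed character, proposes frequent within-word substrings as
#' multi-character candidates, refines unigram log-probabilities by EM over
#' Viterbi segmentations, and prunes to exactly `size` pieces (the four
#' special tokens included).
#'
#' @param sentences character vector of training sentences (non-empty).
#' @param size total number of pieces, specials included (default 16000).
#' @param seed integer seed controlling the EM sentence subsample.
#' @param max_piece_len maximum length of a multi-character piece.
#' @param em_iters number of EM refinement sweeps.
#' @param em_sample maximum number of sentences used per EM sweep.
#' @return A [subword_vocab()] object with exactly `size` pieces.
#' @export
build_vocab <- function(sentences, size = 16000L, seed = 1L,
                        max_piece_len = 8L, em_iters = 2L,
                        em_sample = 2000L) {
  if (length(sentences) == 0L || all(!nzchar(sentences)))
    stopf("`sentences` must contain at least one non-empty sentence")
  size <- as.integer(size)
  sents <- tolower(sentences)
  sents <- sents[nzchar(sents)]

  chars <- sort(unique(unlist(strsplit(sents, "", fixed = TRUE))))
  min_size <- length(chars) + 4L
  if (size < min_size)
    stopf(paste0("vocabulary size %d too small for character coverage: ",
                 "%d distinct characters + 4 specials require size >= %d"),
          size, length(chars), min_size)

  # candidate multi-character substrings, counted within whitespace chunks
  chunk_tab <- table(unlist(strsplit(sents, "[ \t\r\n]+")))
  chunk_tab <- chunk_tab[nchar(names(chunk_tab)) > 1L]
  cand_env <- new.env(parent = emptyenv())
  for (w in names(chunk_tab)) {
    cnt <- as.numeric(chunk_tab[[w]])
    nw <- nchar(w)
    for (L in 2:min(max_piece_len, nw)) {
      for (s in 1:(nw - L + 1L)) {
        sub <- substr(w, s, s + L - 1L)
        cand_env[[sub]] <- (cand_env[[sub]] %||% 0) + cnt
      }
    }
  }
  cand <- ls(cand_env)
  cand_freq <- vapply(cand, function(k) cand_env[[k]], numeric(1))
  # favour long frequent substrings for the initial pool
  ord <- order(-cand_freq * (nchar(cand) - 1), cand)
  # keep the pool generous: EM usage, not raw frequency, decides survival
  pool_n <- min(length(cand),
                max(8L * (size - min_size), 4L * size, 20000L))
  cand <- cand[ord][seq_len(min(pool_n, length(cand)))]
  cand_freq <- cand_freq[ord][seq_len(min(pool_n, length(cand_freq)))]

  char_freq <- table(unlist(strsplit(sents, "", fixed = TRUE)))
  inv_piece <- c(SPECIAL_PIECES, chars, cand)
  inv_freq <- c(rep(1, 4L),
                as.numeric(char_freq[chars]),
                cand_freq)
  logp <- log(inv_freq / sum(inv_freq))

  em_sents <- with_seed(seed, {
    if (length(sents) > em_sample) sample(sents, em_sample) else sents
  })

  vocab <- subword_vocab(data.frame(piece = inv_piece, logp = pmin(logp, -1e-9),
                                    stringsAsFactors = FALSE))
  usage <- NULL
  for (it in seq_len(em_iters)) {
    usage <- em_usage_counts(em_sents, vocab)
    logp <- log((usage + 0.1) / sum(usage + 0.1))
    vocab <- subword_vocab(data.frame(piece = inv_piece,
                                      logp = pmin(logp, -1e-9),
                                      stringsAsFactors = FALSE))
  }

  # prune candidates to reach exactly `size`, keeping specials + chars
  keep_n <- size - min_size
  cand_idx <- seq_along(cand) + min_size
  cand_use <- usage[cand_idx]
  keep <- cand_idx[order(-cand_use, -cand_freq, cand)][seq_len(keep_n)]
  sel <- c(seq_len(min_size), sort(keep))
  vocab <- subword_vocab(data.frame(piece = inv_piece[sel],
                                    logp = pmin(logp[sel], -1e-9),
                                    stringsAsFactors = FALSE))
  # one refit on the final inventory
  usage <- em_usage_counts(em_sents, vocab)
  logp <- log((usage + 0.1) / sum(usage + 0.1))
  subword_vocab(data.frame(piece = inv_piece[sel], logp = pmin(logp, -1e-9),
                           stringsAsFactors = FALSE))
}

# Viterbi piece-usage counts over a sentence sample (hard-EM E-step).
em_usage_counts <- function(sents, vocab) {
  ids <- unlist(lapply(sents, viterbi_ids, vocab = vocab))
  as.numeric(tabulate(ids, nbins = vocab$size))
}

viterbi_ids <- function(text, vocab) {
  seg <- segment_lattice(text, vocab, mode = "viterbi", alpha = 1)
  seg$ids
}

# Shared lattice walker: Viterbi decoding or forward-filtering /
# backward-sampling with path weight exp(score / alpha).
segment_lattice <- function(text, vocab, mode, alpha) {
  n <- nchar(text)
  maxL <- vocab$max_piece_len
  # best[j+1]: score of best (or logsumexp of all) segmentations of prefix j
  acc <- c(0, rep(-Inf, n))
  back_id <- integer(n)   # viterbi backpointers: piece id ending at j
  back_len <- integer(n)
  # for sampling we need, per end position, the full arc list
  arcs <- if (mode == "sample") vector("list", n) else NULL
  inv_alpha <- 1 / max(alpha, 1e-8)
  lookup <- vocab$lookup
  logps <- vocab$pieces$logp
  unk <- vocab$unk_id
  for (j in seq_len(n)) {
    lo <- max(1L, j - maxL + 1L)
    nc <- j - lo + 1L
    cand_id <- integer(nc); cand_len <- integer(nc); cand_sc <- numeric(nc)
    m <- 0L
    for (s in lo:j) {
      if (!is.finite(acc[s])) next
      pid <- get0(substr(text, s, j), envir = lookup,
                  ifnotfound = NA_integer_)
      if (is.na(pid)) {
        if (s == j) pid <- unk else next  # unknown single character
      }
      lp <- if (pid == unk) UNK_LOGP else logps[pid]
      m <- m + 1L
      cand_id[m] <- pid
      cand_len[m] <- j - s + 1L
      cand_sc[m] <- acc[s] + lp * inv_alpha
    }
    if (m == 0L) next
    cand_id <- cand_id[seq_len(m)]
    cand_len <- cand_len[seq_len(m)]
    cand_sc <- cand_sc[seq_len(m)]
    if (mode == "viterbi") {
      b <- which.max(cand_sc)
      acc[j + 1L] <- cand_sc[b]
      back_id[j] <- cand_id[b]
      back_len[j] <- cand_len[b]
    } else {
      acc[j + 1L] <- logsumexp(cand_sc)
      arcs[[j]] <- list(id = cand_id, len = cand_len, sc = cand_sc)
    }
  }
  if (!is.finite(acc[n + 1L]))
    stopf("text cannot be segmented with this vocabulary")
  ids <- integer(0); lens <- integer(0)
  j <- n
  while (j > 0L) {
    if (mode == "viterbi") {
      id <- back_id[j]; L <- back_len[j]
    } else {
      a <- arcs[[j]]
      # previous accumulated mass is already inside sc
      w <- exp(a$sc - acc[j + 1L])
      k <- sample.int(length(w), 1L, prob = w)
      id <- a$id[k]; L <- a$len[k]
    }
    ids <- c(id, ids); lens <- c(L, lens)
    j <- j - L
  }
  starts <- cumsum(c(1L, lens[-length(lens)]))
  list(ids = ids, starts = starts, ends = starts + lens - 1L)
}

#' Segment text into subword token ids
#'
#' Lowercases `text` internally, then segments it against the unigram
#' vocabulary. In `"viterbi"` mode the maximum log-probability segmentation
#' is returned deterministically; in `"sample"` mode a segmentation with
#' path score S is drawn with probability proportional to `exp(S / alpha)`,
#' so `alpha -> 0` recovers the Viterbi path. Characters absent from the
#' vocabulary are emitted as the unknown id. Concatenating the piece strings
#' of the result reproduces the lowercased input exactly (unknown characters
#' excepted).
#'
#' @param text single non-empty string.
#' @param vocab a [subword_vocab()].
#' @param mode `"viterbi"` (default) or `"sample"`.
#' @param alpha sampling smoothing; smaller is greedier. Ignored for viterbi.
#' @param seed optional integer seed for `"sample"` mode.
#' @return Integer vector of token ids with attributes `starts` and `ends`
#'   (1-based character offsets of each piece in the lowercased text).
#' @export
segment_text <- function(text, vocab, mode = c("viterbi", "sample"),
                         alpha = 1, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(vocab, "subword_vocab"))
  if (length(text) != 1L || is.na(text) || !nzchar(tolower(text)))
    stopf("`text` must be a single non-empty string")
  lower <- tolower(text)
  seg <- with_seed(seed, segment_lattice(lower, vocab, mode, alpha))
  structure(seg$ids, starts = seg$starts, ends = seg$ends)
}

#' Convert token ids back to text
#'
#' Concatenates piece strings; the four special ids are dropped.
#'
#' @param ids integer vector of token ids (may be empty).
#' @param vocab a [subword_vocab()].
#' @return Single string.
#' @export
detokenize <- function(ids, vocab) {
  stopifnot(inherits(vocab, "subword_vocab"))
  ids <- as.integer(ids)
  if (length(ids) == 0L) return("")
  if (any(is.na(ids)) || any(ids < 1L) || any(ids > vocab$size))
    stopf("token id out of range for this vocabulary")
  keep <- ids > 4L
  paste(vocab$pieces$piece[ids[keep]], collapse = "")
}

escape_piece <- function(p) {
  p <- gsub("\\", "\\\\", p, fixed = TRUE)
  p <- gsub("\t", "\\t", p, fixed = TRUE)
  gsub("\n", "\\n", p, fixed = TRUE)
}

unescape_piece <- function(p) {
  out <- character(length(p))
  for (i in seq_along(p)) {
    s <- p[i]
    s <- gsub("(^|[^\\\\])((\\\\\\\\)*)\\\\t", "\\1\\2\t", s)
    s <- gsub("(^|[^\\\\])((\\\\\\\\)*)\\\\n", "\\1\\2\n", s)
    out[i] <- gsub("\\\\", "\\", s, fixed = TRUE)
  }
  out
}

#' Write a vocabulary as TSV
#'
#' One piece per line, `piece TAB log-probability`, UTF-8, specials first in
#' fixed order. Round-trips bit-exactly through [read_vocab_tsv()].
#'
#' @param vocab a [subword_vocab()].
#' @param path output file path.
#' @export
write_vocab_tsv <- function(vocab, path) {
  stopifnot(inherits(vocab, "subword_vocab"))
  lines <- sprintf("%s\t%s", escape_piece(vocab$pieces$piece),
                   formatC(vocab$pieces$logp, format = "g", digits = 17))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a vocabulary written by [write_vocab_tsv()]
#'
#' @param path TSV file path.
#' @return A [subword_vocab()].
#' @export
read_vocab_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stopf("malformed vocab line(s): %s", which(bad)[1])
  subword_vocab(data.frame(
    piece = unescape_piece(vapply(parts, `[[`, "", 1L)),
    logp = as.numeric(vapply(parts, `[[`, "", 2L)),
    stringsAsFactors = FALSE))
}
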