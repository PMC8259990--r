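# Conditional ancestral generation: extend a title prompt token-by-token
# under a keyword/year condition until the end-of-abstract token or a
# length cap.

#' Sampler configuration
#'
#' @param temperature softmax temperature (`>= 0`; 0 selects the argmax).
#' @param top_k optional: restrict sampling to the k highest logits.
#' @param top_p optional nucleus bound in `(0, 1]`: smallest probability
#'   mass whose cumulative sum reaches `top_p`.
#' @param max_new_tokens generation length cap.
#' @param seed optional integer seed for reproducible draws.
#' @return List of class `sampler_config`.
#' @export
sampler_config <- function(temperature = 1.0, top_k = NULL, top_p = NULL,
                           max_new_tokens = 256L, seed = NULL) {
  if (temperature < 0) stopf("temperature must be >= 0")
  if (!is.null(top_p) && (top_p <= 0 || top_p > 1))
    stopf("top_p must be in (0, 1]")
  if (!is.null(top_k) && top_k < 1L) stopf("top_k must be >= 1")
  structure(list(temperature = temperature, top_k = top_k, top_p = top_p,
                 max_new_tokens = as.integer(max_new_tokens), seed = seed),
            class = "sampler_config")
}

#' Draw the next token id from a logit vector
#'
#' Applies temperature scaling, then optional top-k and nucleus (top-p)
#' truncation with renormalization, and samples from the resulting
#' distribution. Temperature 0 returns the argmax deterministically.
#'
#' @param logits numeric logit vector (finite entries; `-Inf` marks
#'   forbidden ids).
#' @param config a [sampler_config()].
#' @return Integer token id.
#' @export
sample_next <- function(logits, config = sampler_config()) {
  ok <- is.finite(logits)
  if (!any(ok)) stopf("all logits are -Inf; nothing to sample")
  if (config$temperature == 0) return(which.max(logits))
  z <- logits / config$temperature
  if (!is.null(config$top_k) && config$top_k < sum(ok)) {
    thr <- sort(z[ok], decreasing = TRUE)[config$top_k]
    z[z < thr] <- -Inf
  }
  p <- exp(z - max(z[is.finite(z)]))
  p[!is.finite(z)] <- 0
  p <- p / sum(p)
  if (!is.null(config$top_p) && config$top_p < 1) {
    ord <- order(p, decreasing = TRUE)
    keep_n <- which(cumsum(p[ord]) >= config$top_p)[1]
    drop <- ord[-seq_len(keep_n)]
    p[drop] <- 0
    p <- p / sum(p)
  }
  sample.int(length(p), 1L, prob = p)
}

#' Generate an abstract conditioned on keywords and a year
#'
#' Prompts the decoder with the start-of-abstract token plus the Viterbi
#' segmentation of the title, then repeatedly samples the next token from
#' the model's conditional distribution until the end-of-abstract token or
#' `max_new_tokens`. Unknown (unindexed) keywords are dropped with a
#' warning. When the context outgrows the model's maximum sequence length
#' the most recent `max_seq - 1` tokens are kept. The padding id is never
#' produced.
#'
#' @param title non-empty title string (the prompt).
#' @param year publication year condition.
#' @param keywords character vector of keyword conditions (may be empty).
#' @param params trained model parameters.
#' @param config the [model_config()].
#' @param vocab the [subword_vocab()] used in training.
#' @param cond_index the `condition_index` used in training.
#' @param sampler a [sampler_config()].
#' @return List with `token_ids` (generated ids, end token excluded),
#'   `text` (detokenized abstract, prompt excluded) and `stopped`
#'   (`"eos"` or `"length"`).
#' @export
generate_abstract <- function(title, year, keywords = character(),
                              params, config, vocab, cond_index,
                              sampler = sampler_config()) {
  if (!is.character(title) || length(title) != 1L || !nzchar(trimws(title)))
    stopf("`title` must be a non-empty string")
  cond <- condition_ids(cond_index, year, keywords, warn = TRUE)
  prompt <- c(vocab$bos_id, as.integer(segment_text(title, vocab)))
  ids <- prompt
  gen <- integer(0)
  stopped <- "length"
  with_seed(sampler$seed, {
    while (length(gen) < sampler$max_new_tokens) {
      ctx <- if (length(ids) > config$max_seq)
        ids[(length(ids) - config$max_seq + 2L):length(ids)]
      else ids
      out <- fwd_model(ctx, cond, params, config, training = FALSE)$out
      logits <- out$token[nrow(out$token), ]
      logits[vocab$pad_id] <- -Inf
      logits[vocab$bos_id] <- -Inf
      nxt <- sample_next(logits, sampler)
      if (nxt == vocab$eos_id) {
        stopped <- "eos"
        break
      }
      gen <- c(gen, nxt)
      ids <- c(ids, nxt)
    }
  })
  list(token_ids = gen, text = detokenize(gen, vocab), stopped = stopped)
}
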