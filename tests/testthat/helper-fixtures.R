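# Shared fixtures, memoized so expensive objects (vocabularies, trained
# models) are built once per test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Hand-built vocabulary from explicit pieces (specials prepended).
manual_vocab <- function(pieces, logps) {
  subword_vocab(data.frame(
    piece = c("<s>", "</s>", "<unk>", "<pad>", pieces),
    logp = c(rep(-9, 4), logps),
    stringsAsFactors = FALSE))
}

# Single-character vocabulary over a character inventory.
char_vocab <- function(chars) {
  manual_vocab(chars, rep(log(1 / length(chars)), length(chars)))
}

piece_id_of <- function(vocab, piece) {
  match(piece, vocab$pieces$piece)
}

# 20-word synthetic language and a trained subword vocabulary over it.
word_language <- function() memo_fixture("word_language", {
  words <- with_seed_test(421, unique(replicate(40, paste(
    sample(letters[1:12], sample(3:6, 1), TRUE), collapse = "")))[1:20])
  sents <- with_seed_test(422, replicate(1000, paste(
    sample(words, sample(4:8, 1), TRUE), collapse = " ")))
  list(words = words, sentences = sents)
})

word_language_vocab <- function() memo_fixture("word_language_vocab", {
  build_vocab(word_language()$sentences, size = 64, seed = 7)
})

# Local RNG isolation for test fixtures.
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Small memorization study: 16 short documents from a synthetic grammar,
# a tiny transformer trained on one fixed 16-window batch until the token
# loss memorizes (capped at 2000 steps). Shared by the trainer,
# generation and acceptance tests.
memorization_fixture <- function() memo_fixture("memorization", {
  g <- synthetic_grammar(n_words = 30, n_keywords = 2, topic_size = 8,
                         mixing = 0.8, sentence_words = c(4, 6),
                         seed = 11)
  recs <- sample_corpus(g, 16, seed = 21, keyword_range = c(1, 2))
  sents <- unlist(lapply(recs, function(r)
    split_sentences(paste(r$title, r$abstract))))
  vocab <- build_vocab(sents, size = 64, seed = 3)
  ci <- build_condition_index(recs, min_count = 1L, cutoff_year = 2020L)
  docs <- lapply(recs, encode_record, vocab = vocab, cond_index = ci)
  # the shortest document becomes the generation target; its window spans
  # the whole document so greedy decoding can be checked token-for-token
  lens <- vapply(docs, function(d) length(d$tokens), 1L)
  target <- which.min(lens)
  full_window <- function(doc) {
    n <- length(doc$tokens)
    idx <- 1:(n - 1L)
    structure(list(input_ids = doc$tokens[idx],
                   token_targets = doc$tokens[idx + 1L],
                   pos_targets = doc$pos_ids[idx + 1L],
                   dep_targets = doc$dep_ids[idx + 1L],
                   ent_targets = doc$ent_ids[idx + 1L],
                   condition_ids = doc$cond_ids),
              class = "training_window")
  }
  windows <- lapply(seq_along(docs), function(i) {
    if (i == target || lens[i] <= 65L) full_window(docs[[i]])
    else sample_window(docs[[i]], window = 64L, seed = 100L + i)
  })
  cfg <- tiny_model_config(vocab_size = vocab$size,
                           cond_vocab_size = ci$n_conditions,
                           max_seq = 64L)
  params <- init_model_params(cfg, seed = 7)
  tc <- train_config(batch_size = 16L, lr = 0.002, warmup = 100L,
                     max_steps = 250L, seed = 5L)
  prov <- fixed_window_provider(windows)
  log <- NULL
  opt <- NULL
  step0 <- 1L
  initial_loss <- NULL
  repeat {
    res <- train_model(prov, params, cfg, tc, opt_state = opt,
                       start_step = step0)
    params <- res$params; opt <- res$opt_state
    log <- rbind(log, res$log)
    if (is.null(initial_loss)) initial_loss <- res$log$token[1]
    step0 <- step0 + tc$max_steps
    if (tail(res$log$token, 1) < 0.03 || step0 > 2000L) break
  }
  list(grammar = g, records = recs, vocab = vocab, cond_index = ci,
       docs = docs, windows = windows, config = cfg, params = params,
       log = log, target = target, initial_loss = initial_loss)
})

# Conditional-control study: 500 documents from a 2-keyword
# disjoint-topic grammar, tiny transformer trained with fresh window
# resampling. Shared by the acceptance tests.
conditional_control_fixture <- function(seed = 1L)
  memo_fixture(paste0("condctl", seed), {
    g <- synthetic_grammar(n_words = 36, n_keywords = 2, topic_size = 10,
                           mixing = 0.8, sentence_words = c(5, 8),
                           seed = seed + 100L)
    recs <- sample_corpus(g, 500, seed = seed + 200L,
                          keyword_range = c(1, 2))
    sents <- unlist(lapply(recs, function(r)
      split_sentences(paste(r$title, r$abstract))))
    vocab <- build_vocab(sents, size = 96, seed = seed + 3L)
    ci <- build_condition_index(recs, min_count = 10L,
                                cutoff_year = 2020L)
    docs <- lapply(recs, encode_record, vocab = vocab, cond_index = ci)
    cfg <- tiny_model_config(vocab_size = vocab$size,
                             cond_vocab_size = ci$n_conditions,
                             max_seq = 48L)
    params <- init_model_params(cfg, seed = seed + 7L)
    tc <- train_config(batch_size = 16L, lr = 0.002, warmup = 100L,
                       max_steps = 2400L, seed = seed + 5L, window = 48L)
    res <- train_model(window_provider(docs, 16L, window = 48L), params,
                       cfg, tc)
    list(grammar = g, records = recs, vocab = vocab, cond_index = ci,
         config = cfg, params = res$params, log = res$log)
  })

# Averaged model next-word distribution under a condition: softmax rows at
# positions following the inter-word space piece, restricted to the
# grammar's word pieces and renormalized.
model_word_distribution <- function(fx, keyword, year = 2005L,
                                    n_contexts = 4L) {
  g <- fx$grammar; vocab <- fx$vocab
  space_id <- piece_id_of(vocab, " ")
  word_ids <- piece_id_of(vocab, g$words)
  stopifnot(!anyNA(word_ids))
  p_true <- true_conditional_distribution(g, keyword)
  cond <- c(year_index(fx$cond_index, year),
            unname(fx$cond_index$keywords[keyword]))
  rows <- NULL
  for (s in seq_len(n_contexts)) {
    ctx_text <- with_seed_test(300 + s, {
      ws <- sample(names(p_true), 30, TRUE, prob = p_true)
      paste(vapply(split(ws, rep(1:5, each = 6)), function(x)
        paste0(paste(x, collapse = " "), "."), ""), collapse = " ")
    })
    ids <- c(vocab$bos_id, as.integer(segment_text(ctx_text, vocab)))
    ids <- ids[seq_len(min(length(ids), fx$config$max_seq))]
    logits <- model_forward(ids, cond, fx$params, fx$config)$token
    sm <- exp(logits - apply(logits, 1, max))
    sm <- sm / rowSums(sm)
    at <- which(ids == space_id)
    rows <- rbind(rows, sm[at[at <= nrow(sm)], , drop = FALSE])
  }
  avg <- colMeans(rows)[word_ids]
  stats::setNames(avg / sum(avg), g$words)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# Minimal training setup (8 documents, 16-dim single-layer model) for
# trainer behaviour tests.
tiny_train_setup <- function() {
  memo_fixture("tiny_train_setup", {
    g <- synthetic_grammar(n_words = 24, n_keywords = 2, topic_size = 6,
                           sentence_words = c(4, 6), seed = 31)
    recs <- sample_corpus(g, 8, seed = 32)
    v <- build_vocab(unlist(lapply(recs, function(r)
      split_sentences(paste(r$title, r$abstract)))), size = 56, seed = 1)
    ci <- build_condition_index(recs, min_count = 1L)
    docs <- lapply(recs, encode_record, vocab = v, cond_index = ci)
    cfg <- model_config(vocab_size = v$size,
                        cond_vocab_size = ci$n_conditions,
                        embed_dim = 16L, heads = 2L, encoder_layers = 1L,
                        decoder_layers = 1L, ff_dim = 32L, dropout = 0,
                        max_seq = 48L)
    list(docs = docs, vocab = v, ci = ci, cfg = cfg)
  })
}
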