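# Conditional transformer: a shallow self-attention encoder over the
# condition set (keyword + year embeddings, no positional encoding) and a
# deep causally masked decoder over subword tokens with encoder-decoder
# attention, post-norm residual blocks, and four linear classification
# heads (next token, POS, dependency, entity).

LN_EPS <- 1e-5

#' Model architecture configuration
#'
#' Defaults follow a GPT-2 "medium"-sized layout: 1024-dimensional
#' embeddings, 16 attention heads, 2 encoder blocks, 16 decoder blocks, a
#' 3072-wide feed-forward inner layer, dropout 0.1 and a maximum sequence
#' length of 128, with 16,000 token pieces. Desk-scale experiments shrink
#' these (see [tiny_model_config()]).
#'
#' @param vocab_size token vocabulary size.
#' @param cond_vocab_size number of condition embeddings (years + keywords).
#' @param embed_dim embedding dimensionality (even, divisible by `heads`).
#' @param heads attention heads per layer.
#' @param encoder_layers,decoder_layers stack depths.
#' @param ff_dim feed-forward inner width.
#' @param dropout inner-block dropout rate in `[0, 1)`.
#' @param max_seq maximum decoder sequence length.
#' @param pos_vocab_size,dep_vocab_size,ent_vocab_size label-track widths.
#' @return An object of class `model_config`.
#' @export
model_config <- function(vocab_size = 16000L, cond_vocab_size = 48363L,
                         embed_dim = 1024L, heads = 16L,
                         encoder_layers = 2L, decoder_layers = 16L,
                         ff_dim = 3072L, dropout = 0.1, max_seq = 128L,
                         pos_vocab_size = length(POS_TAGS),
                         dep_vocab_size = length(DEP_TAGS),
                         ent_vocab_size = length(ENTITY_CLASSES)) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              cond_vocab_size = as.integer(cond_vocab_size),
              embed_dim = as.integer(embed_dim), heads = as.integer(heads),
              encoder_layers = as.integer(encoder_layers),
              decoder_layers = as.integer(decoder_layers),
              ff_dim = as.integer(ff_dim), dropout = dropout,
              max_seq = as.integer(max_seq),
              pos_vocab_size = as.integer(pos_vocab_size),
              dep_vocab_size = as.integer(dep_vocab_size),
              ent_vocab_size = as.integer(ent_vocab_size))
  with(cfg, {
    if (any(c(vocab_size, cond_vocab_size, embed_dim, heads, encoder_layers,
              decoder_layers, ff_dim, max_seq, pos_vocab_size,
              dep_vocab_size, ent_vocab_size) < 1L))
      stopf("all model sizes must be positive")
    if (embed_dim %% heads != 0L)
      stopf("embed_dim (%d) must be divisible by heads (%d)",
            embed_dim, heads)
    if (embed_dim %% 2L != 0L)
      stopf("embed_dim must be even for the sinusoidal encoding")
    if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  })
  structure(cfg, class = "model_config")
}

#' Small diagnostic configuration
#'
#' The desk-scale configuration used throughout the test corpus
#' experiments: 64-dimensional embeddings, 2 heads, 1 encoder and 2 decoder
#' blocks, a 128-wide feed-forward layer and no dropout (diagnostic runs
#' measure memorization and conditional control, which dropout would only
#' mask).
#'
#' @param vocab_size,cond_vocab_size vocabulary sizes for the experiment.
#' @param max_seq maximum sequence length.
#' @param ... overrides passed to [model_config()].
#' @export
tiny_model_config <- function(vocab_size, cond_vocab_size, max_seq = 128L,
                              ...) {
  model_config(vocab_size = vocab_size, cond_vocab_size = cond_vocab_size,
               embed_dim = 64L, heads = 2L, encoder_layers = 1L,
               decoder_layers = 2L, ff_dim = 128L, dropout = 0,
               max_seq = max_seq, ...)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "<model_config> d=%d heads=%d enc=%d dec=%d ff=%d | %d tokens, %d conditions, max_seq=%d\n",
    x$embed_dim, x$heads, x$encoder_layers, x$decoder_layers, x$ff_dim,
    x$vocab_size, x$cond_vocab_size, x$max_seq))
  invisible(x)
}

rand_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

new_attn_params <- function(d, sd) {
  list(Wq = rand_mat(d, d, sd), Wk = rand_mat(d, d, sd),
       Wv = rand_mat(d, d, sd), Wo = rand_mat(d, d, sd))
}

new_ln_params <- function(d) list(g = rep(1, d), b = rep(0, d))

#' Initialize model parameters
#'
#' Scaled-normal initialization (sd 0.02) for all weight matrices and
#' embedding tables; layer-norm gains start at one and offsets at zero.
#'
#' @param config a [model_config()].
#' @param seed integer seed.
#' @param init_sd standard deviation of the weight initialization.
#' @return Nested list of parameter arrays (class `model_params`).
#' @export
init_model_params <- function(config, seed = 1L, init_sd = 0.02) {
  stopifnot(inherits(config, "model_config"))
  d <- config$embed_dim
  with_seed(seed, {
    enc <- lapply(seq_len(config$encoder_layers), function(i)
      list(attn = new_attn_params(d, init_sd), ln1 = new_ln_params(d),
           ff = list(W1 = rand_mat(d, config$ff_dim, init_sd),
                     W2 = rand_mat(config$ff_dim, d, init_sd)),
           ln2 = new_ln_params(d)))
    dec <- lapply(seq_len(config$decoder_layers), function(i)
      list(self = new_attn_params(d, init_sd), ln1 = new_ln_params(d),
           cross = new_attn_params(d, init_sd), ln2 = new_ln_params(d),
           ff = list(W1 = rand_mat(d, config$ff_dim, init_sd),
                     W2 = rand_mat(config$ff_dim, d, init_sd)),
           ln3 = new_ln_params(d)))
    structure(
      list(tok_emb = rand_mat(config$vocab_size, d, init_sd),
           cond_emb = rand_mat(config$cond_vocab_size, d, init_sd),
           enc = enc, dec = dec,
           heads = list(token = rand_mat(d, config$vocab_size, init_sd),
                        pos = rand_mat(d, config$pos_vocab_size, init_sd),
                        dep = rand_mat(d, config$dep_vocab_size, init_sd),
                        ent = rand_mat(d, config$ent_vocab_size, init_sd))),
      class = "model_params")
  })
}

#' Sinusoidal positional encoding
#'
#' Entry `(pos, 2i)` is `sin(pos / 10000^(2i/dim))` and entry
#' `(pos, 2i+1)` is the cosine of the same argument (positions and
#' dimension pairs counted from zero; row 1 of the returned matrix is
#' position 0).
#'
#' @param length number of positions.
#' @param dim embedding dimensionality (must be even).
#' @return `length x dim` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(length, dim) {
  stopifnot(length >= 1L)
  if (dim %% 2L != 0L) stopf("positional encoding requires an even dim")
  pos <- seq_len(length) - 1
  i <- seq_len(dim %/% 2L) - 1
  ang <- outer(pos, 1 / 10000^(2 * i / dim))
  out <- matrix(0, length, dim)
  out[, 2L * i + 1L] <- sin(ang)
  out[, 2L * i + 2L] <- cos(ang)
  out
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d)) V` with `d = ncol(K)`; rows of the softmax are
#' stochastic over the unmasked keys. `mask[i, j] = FALSE` removes key `j`
#' for query `i` (exactly zero weight).
#'
#' @param Q,K,V real matrices; `ncol(Q) == ncol(K)`, `nrow(K) == nrow(V)`.
#' @param mask optional logical matrix, `nrow(Q) x nrow(K)`; TRUE = attend.
#' @return `nrow(Q) x ncol(V)` matrix.
#' @export
attention <- function(Q, K, V, mask = NULL) {
  if (ncol(Q) != ncol(K)) stopf("Q and K must share column count")
  if (nrow(K) != nrow(V)) stopf("K and V must share row count")
  S <- Q %*% t(K) / sqrt(ncol(K))
  if (!is.null(mask)) {
    if (!all(dim(mask) == c(nrow(Q), nrow(K))))
      stopf("mask must be nrow(Q) x nrow(K)")
    if (any(rowSums(mask) == 0L))
      stopf("attention row is fully masked; softmax undefined")
    S[!mask] <- -Inf
  }
  softmax_rows(S) %*% V
}

#' Multi-headed attention
#'
#' Projects `X` to queries and `Y` to keys/values, runs scaled dot-product
#' attention per head on column blocks of the projections, concatenates
#' the heads and mixes them through the output matrix.
#'
#' @param X query-side embeddings (rows = query positions).
#' @param Y key/value-side embeddings.
#' @param params list with `Wq`, `Wk`, `Wv`, `Wo` (`d x d` each).
#' @param heads number of heads (divides `ncol(X)`).
#' @param mask optional logical attention mask (TRUE = attend).
#' @return `nrow(X) x d` matrix.
#' @export
multi_head <- function(X, Y, params, heads, mask = NULL) {
  mh_forward(X, Y, params, heads, mask)$out
}

mh_forward <- function(X, Y, W, heads, mask = NULL) {
  d <- ncol(X)
  if (ncol(Y) != d) stopf("X and Y must share embedding width")
  if (d %% heads != 0L) stopf("heads must divide the embedding width")
  Q <- X %*% W$Wq; K <- Y %*% W$Wk; V <- Y %*% W$Wv
  dh <- d %/% heads
  scal <- 1 / sqrt(dh)
  O <- matrix(0, nrow(X), d)
  P <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) * scal
    if (!is.null(mask)) {
      if (any(rowSums(mask) == 0L))
        stopf("attention row is fully masked; softmax undefined")
      S[!mask] <- -Inf
    }
    P[[h]] <- softmax_rows(S)
    O[, cols] <- P[[h]] %*% V[, cols, drop = FALSE]
  }
  list(out = O %*% W$Wo,
       cache = list(X = X, Y = Y, Q = Q, K = K, V = V, P = P, O = O,
                    heads = heads, dh = dh, scal = scal))
}

mh_backward <- function(dout, cache, W) {
  X <- cache$X; Y <- cache$Y
  dWo <- t(cache$O) %*% dout
  dO <- dout %*% t(W$Wo)
  dQ <- matrix(0, nrow(X), ncol(X))
  dK <- matrix(0, nrow(Y), ncol(Y))
  dV <- dK
  for (h in seq_len(cache$heads)) {
    cols <- ((h - 1L) * cache$dh + 1L):(h * cache$dh)
    P <- cache$P[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dP <- dOh %*% t(Vh)
    dV[, cols] <- t(P) %*% dOh
    dS <- P * (dP - rowSums(dP * P))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] * cache$scal
    dK[, cols] <- t(dS) %*% cache$Q[, cols, drop = FALSE] * cache$scal
  }
  list(dX = dQ %*% t(W$Wq),
       dY = dK %*% t(W$Wk) + dV %*% t(W$Wv),
       grads = list(Wq = t(X) %*% dQ, Wk = t(Y) %*% dK,
                    Wv = t(Y) %*% dV, Wo = dWo))
}

#' Position-wise feed-forward layer
#'
#' `max(0, X W1) W2`: expand to the inner width, ReLU, contract back to the
#' embedding width.
#'
#' @param X input matrix (`n x d`).
#' @param params list with `W1` (`d x ff`) and `W2` (`ff x d`).
#' @return `n x d` matrix.
#' @export
feed_forward <- function(X, params) {
  ff_forward(X, params)$out
}

ff_forward <- function(X, W) {
  H <- X %*% W$W1
  A <- H * (H > 0)
  list(out = A %*% W$W2, cache = list(X = X, H = H, A = A))
}

ff_backward <- function(dout, cache, W) {
  dA <- dout %*% t(W$W2)
  dH <- dA * (cache$H > 0)
  list(dX = dH %*% t(W$W1),
       grads = list(W1 = t(cache$X) %*% dH, W2 = t(cache$A) %*% dout))
}

#' Layer normalization
#'
#' Normalizes each row to zero mean and unit variance (population variance,
#' epsilon 1e-5), then applies the learned gain and offset.
#'
#' @param X input matrix.
#' @param g,b gain and offset vectors of length `ncol(X)`.
#' @return Matrix of the same shape.
#' @export
layer_norm <- function(X, g, b) {
  ln_forward(X, g, b)$out
}

ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  inv_sig <- 1 / sqrt(rowMeans(Xc * Xc) + LN_EPS)
  xhat <- Xc * inv_sig
  n <- nrow(X)
  out <- xhat * rep(g, each = n) + rep(b, each = n)
  list(out = out, cache = list(xhat = xhat, inv_sig = inv_sig))
}

ln_backward <- function(dout, cache, g) {
  n <- nrow(dout)
  xhat <- cache$xhat
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- dout * rep(g, each = n)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
    cache$inv_sig
  list(dX = dX, dg = dg, db = db)
}

drop_forward <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, mask = NULL))
  m <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(out = X * m, mask = m)
}

drop_backward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

#' Transformer encoder block
#'
#' Post-norm residual layout: `alpha = LayerNorm(MH(X, X) + X)`, output
#' `LayerNorm(FF(alpha) + alpha)`. Dropout is applied to each sublayer
#' output before its residual add, in training mode only.
#'
#' @param X condition embedding matrix (`m x d`).
#' @param layer parameter list with `attn`, `ln1`, `ff`, `ln2`.
#' @param heads attention head count.
#' @param dropout dropout rate.
#' @param training logical; dropout active only when TRUE.
#' @return `m x d` matrix.
#' @export
encoder_block <- function(X, layer, heads, dropout = 0, training = FALSE) {
  enc_block_forward(X, layer, heads, dropout, training)$out
}

enc_block_forward <- function(X, layer, heads, dropout, training) {
  mh <- mh_forward(X, X, layer$attn, heads)
  dr1 <- drop_forward(mh$out, dropout, training)
  ln1 <- ln_forward(dr1$out + X, layer$ln1$g, layer$ln1$b)
  ff <- ff_forward(ln1$out, layer$ff)
  dr2 <- drop_forward(ff$out, dropout, training)
  ln2 <- ln_forward(dr2$out + ln1$out, layer$ln2$g, layer$ln2$b)
  list(out = ln2$out,
       cache = list(mh = mh$cache, dr1 = dr1$mask, ln1 = ln1$cache,
                    ff = ff$cache, dr2 = dr2$mask, ln2 = ln2$cache))
}

enc_block_backward <- function(dout, cache, layer) {
  b2 <- ln_backward(dout, cache$ln2, layer$ln2$g)
  dff_out <- drop_backward(b2$dX, cache$dr2)
  bff <- ff_backward(dff_out, cache$ff, layer$ff)
  dalpha <- b2$dX + bff$dX
  b1 <- ln_backward(dalpha, cache$ln1, layer$ln1$g)
  dmh_out <- drop_backward(b1$dX, cache$dr1)
  bmh <- mh_backward(dmh_out, cache$mh, layer$attn)
  dX <- b1$dX + bmh$dX + bmh$dY  # self-attention: X feeds both sides
  list(dX = dX,
       grads = list(attn = bmh$grads,
                    ln1 = list(g = b1$dg, b = b1$db),
                    ff = bff$grads,
                    ln2 = list(g = b2$dg, b = b2$db)))
}

#' Transformer decoder block
#'
#' `beta = LayerNorm(MH_masked(X, X) + X)`;
#' `alpha = LayerNorm(MH(beta, Y) + beta)`;
#' output `LayerNorm(FF(alpha) + alpha)`. The self-attention mask is
#' causal, so output row `i` depends only on rows `<= i` of `X` (and all of
#' `Y`).
#'
#' @param X decoder-stream embeddings (`n x d`).
#' @param Y encoder output (`m x d`).
#' @param layer parameter list with `self`, `ln1`, `cross`, `ln2`, `ff`,
#'   `ln3`.
#' @param heads attention head count.
#' @param dropout dropout rate.
#' @param training logical; dropout active only when TRUE.
#' @return `n x d` matrix.
#' @export
decoder_block <- function(X, Y, layer, heads, dropout = 0,
                          training = FALSE) {
  n <- nrow(X)
  causal <- outer(seq_len(n), seq_len(n), `>=`)
  dec_block_forward(X, Y, layer, heads, causal, dropout, training)$out
}

dec_block_forward <- function(X, Y, layer, heads, causal, dropout,
                              training) {
  mh1 <- mh_forward(X, X, layer$self, heads, mask = causal)
  dr1 <- drop_forward(mh1$out, dropout, training)
  ln1 <- ln_forward(dr1$out + X, layer$ln1$g, layer$ln1$b)       # beta
  mh2 <- mh_forward(ln1$out, Y, layer$cross, heads)
  dr2 <- drop_forward(mh2$out, dropout, training)
  ln2 <- ln_forward(dr2$out + ln1$out, layer$ln2$g, layer$ln2$b) # alpha
  ff <- ff_forward(ln2$out, layer$ff)
  dr3 <- drop_forward(ff$out, dropout, training)
  ln3 <- ln_forward(dr3$out + ln2$out, layer$ln3$g, layer$ln3$b)
  list(out = ln3$out,
       cache = list(mh1 = mh1$cache, dr1 = dr1$mask, ln1 = ln1$cache,
                    mh2 = mh2$cache, dr2 = dr2$mask, ln2 = ln2$cache,
                    ff = ff$cache, dr3 = dr3$mask, ln3 = ln3$cache))
}

dec_block_backward <- function(dout, cache, layer) {
  b3 <- ln_backward(dout, cache$ln3, layer$ln3$g)
  bff <- ff_backward(drop_backward(b3$dX, cache$dr3), cache$ff, layer$ff)
  dalpha <- b3$dX + bff$dX
  b2 <- ln_backward(dalpha, cache$ln2, layer$ln2$g)
  bmh2 <- mh_backward(drop_backward(b2$dX, cache$dr2), cache$mh2,
                      layer$cross)
  dbeta <- b2$dX + bmh2$dX
  b1 <- ln_backward(dbeta, cache$ln1, layer$ln1$g)
  bmh1 <- mh_backward(drop_backward(b1$dX, cache$dr1), cache$mh1,
                      layer$self)
  dX <- b1$dX + bmh1$dX + bmh1$dY
  list(dX = dX, dY = bmh2$dY,
       grads = list(self = bmh1$grads, ln1 = list(g = b1$dg, b = b1$db),
                    cross = bmh2$grads, ln2 = list(g = b2$dg, b = b2$db),
                    ff = bff$grads, ln3 = list(g = b3$dg, b = b3$db)))
}

# Full forward pass over one sequence. Returns the four logit tracks and,
# when `keep_cache`, everything backward_model needs.
fwd_model <- function(input_ids, condition_ids, params, config,
                      training = FALSE, keep_cache = FALSE) {
  n <- length(input_ids)
  if (n < 1L) stopf("empty input sequence")
  if (n > config$max_seq)
    stopf("sequence length %d exceeds max_seq %d", n, config$max_seq)
  if (any(input_ids < 1L) || any(input_ids > config$vocab_size))
    stopf("token id out of range")
  if (length(condition_ids) < 1L) stopf("at least one condition required")
  if (any(condition_ids < 1L) || any(condition_ids > config$cond_vocab_size))
    stopf("condition id out of range")
  drp <- config$dropout
  E <- params$cond_emb[condition_ids, , drop = FALSE]
  enc_caches <- vector("list", config$encoder_layers)
  for (l in seq_len(config$encoder_layers)) {
    eb <- enc_block_forward(E, params$enc[[l]], config$heads, drp, training)
    enc_caches[[l]] <- eb$cache
    E <- eb$out
  }
  D <- params$tok_emb[input_ids, , drop = FALSE] +
    positional_encoding(n, config$embed_dim)
  causal <- outer(seq_len(n), seq_len(n), `>=`)
  dec_caches <- vector("list", config$decoder_layers)
  for (l in seq_len(config$decoder_layers)) {
    db <- dec_block_forward(D, E, params$dec[[l]], config$heads, causal,
                            drp, training)
    dec_caches[[l]] <- db$cache
    D <- db$out
  }
  out <- list(token = D %*% params$heads$token,
              pos = D %*% params$heads$pos,
              dep = D %*% params$heads$dep,
              ent = D %*% params$heads$ent)
  if (!keep_cache) return(list(out = out))
  list(out = out,
       cache = list(input_ids = input_ids, condition_ids = condition_ids,
                    enc = enc_caches, dec = dec_caches, D_final = D))
}

#' Run the conditional transformer forward
#'
#' Encodes the condition set (order-free: no positional encoding is added
#' to condition embeddings), then runs the causally masked decoder over the
#' token sequence with cross-attention into the encoder output, and applies
#' the four classification heads.
#'
#' @param input_ids integer token ids (length `<= max_seq`).
#' @param condition_ids integer condition embedding ids (length >= 1).
#' @param params a [init_model_params()] parameter set.
#' @param config the matching [model_config()].
#' @param mode `"eval"` (deterministic) or `"train"` (dropout active).
#' @return List of four logit matrices (`token`, `pos`, `dep`, `ent`), one
#'   row per input position.
#' @export
model_forward <- function(input_ids, condition_ids, params, config,
                          mode = c("eval", "train")) {
  mode <- match.arg(mode)
  fwd_model(as.integer(input_ids), as.integer(condition_ids), params,
            config, training = (mode == "train"))$out
}

#' Four-task training loss
#'
#' Mean cross-entropy per track (negative log-likelihood of the true label
#' under the softmax of the head's logits, averaged over positions); the
#' total is the sum of the four components.
#'
#' @param output a [model_forward()] result.
#' @param targets list with integer vectors `token`, `pos`, `dep`, `ent`,
#'   each as long as the input sequence.
#' @return List with `total` and named `components`.
#' @export
multitask_loss <- function(output, targets) {
  comp <- vapply(c("token", "pos", "dep", "ent"), function(tr) {
    logits <- output[[tr]]
    tg <- as.integer(targets[[tr]])
    if (length(tg) != nrow(logits))
      stopf("%s targets length %d != %d positions", tr, length(tg),
            nrow(logits))
    if (any(tg < 1L) || any(tg > ncol(logits)))
      stopf("%s label id out of range 1..%d", tr, ncol(logits))
    P <- softmax_rows(logits)
    -mean(log(pmax(P[cbind(seq_along(tg), tg)], 1e-300)))
  }, numeric(1))
  list(total = sum(comp), components = comp)
}

# d(mean NLL)/d(logits) for each head: (softmax - onehot) / n.
loss_grad_logits <- function(output, targets) {
  lapply(stats::setNames(nm = c("token", "pos", "dep", "ent")),
         function(tr) {
    P <- softmax_rows(output[[tr]])
    tg <- as.integer(targets[[tr]])
    P[cbind(seq_along(tg), tg)] <- P[cbind(seq_along(tg), tg)] - 1
    P / length(tg)
  })
}

# Backward pass matching fwd_model(keep_cache = TRUE). `dlogits` is a list
# of gradients of the scalar loss w.r.t. the four logit tracks.
backward_model <- function(dlogits, fwd, params, config) {
  cache <- fwd$cache
  D <- cache$D_final
  g_heads <- list(token = t(D) %*% dlogits$token,
                  pos = t(D) %*% dlogits$pos,
                  dep = t(D) %*% dlogits$dep,
                  ent = t(D) %*% dlogits$ent)
  dD <- dlogits$token %*% t(params$heads$token) +
    dlogits$pos %*% t(params$heads$pos) +
    dlogits$dep %*% t(params$heads$dep) +
    dlogits$ent %*% t(params$heads$ent)
  g_dec <- vector("list", config$decoder_layers)
  dE <- NULL
  for (l in rev(seq_len(config$decoder_layers))) {
    bb <- dec_block_backward(dD, cache$dec[[l]], params$dec[[l]])
    g_dec[[l]] <- bb$grads
    dD <- bb$dX
    dE <- if (is.null(dE)) bb$dY else dE + bb$dY
  }
  g_enc <- vector("list", config$encoder_layers)
  for (l in rev(seq_len(config$encoder_layers))) {
    bb <- enc_block_backward(dE, cache$enc[[l]], params$enc[[l]])
    g_enc[[l]] <- bb$grads
    dE <- bb$dX
  }
  g_tok <- matrix(0, config$vocab_size, config$embed_dim)
  part <- rowsum(dD, group = cache$input_ids)
  g_tok[as.integer(rownames(part)), ] <- part
  g_cond <- matrix(0, config$cond_vocab_size, config$embed_dim)
  part <- rowsum(dE, group = cache$condition_ids)
  g_cond[as.integer(rownames(part)), ] <- part
  list(tok_emb = g_tok, cond_emb = g_cond, enc = g_enc, dec = g_dec,
       heads = g_heads)
}

window_targets <- function(window) {
  list(token = window$token_targets, pos = window$pos_targets,
       dep = window$dep_targets, ent = window$ent_targets)
}

#' Loss and parameter gradients for a batch of training windows
#'
#' Runs the cached forward and the hand-derived backward pass per window
#' and averages the per-window mean losses and gradients over the batch.
#'
#' @param windows list of `training_window` objects.
#' @param params model parameters.
#' @param config model configuration.
#' @param training logical; activates dropout.
#' @return List with `loss` (as [multitask_loss()]) and `grads` (parameter
#'   tree matching `params`).
#' @export
batch_loss_grads <- function(windows, params, config, training = TRUE) {
  nb <- length(windows)
  grads <- NULL
  total <- 0
  comps <- c(token = 0, pos = 0, dep = 0, ent = 0)
  for (w in windows) {
    fw <- fwd_model(w$input_ids, w$condition_ids, params, config,
                    training = training, keep_cache = TRUE)
    tg <- window_targets(w)
    ls <- multitask_loss(fw$out, tg)
    g <- backward_model(loss_grad_logits(fw$out, tg), fw, params, config)
    grads <- if (is.null(grads)) g else tree_map2(`+`, grads, g)
    total <- total + ls$total
    comps <- comps + ls$components
  }
  list(loss = list(total = total / nb, components = comps / nb),
       grads = tree_map(function(x) x / nb, grads))
}

# ---- parameter-tree utilities ----

tree_map <- function(f, x) {
  if (is.list(x)) {
    out <- lapply(x, tree_map, f = f)
    attributes(out) <- attributes(x)
    out
  } else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- mapply(tree_map2, x, y, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    attributes(out) <- attributes(x)
    out
  } else f(x, y)
}
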