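# Optimization loop: linear-warmup learning-rate schedule, Adam and LAMB
# optimizers, per-epoch window re-sampling, checkpointing and loss logging.

#' Training configuration
#'
#' @param batch_size windows per optimizer step (desk default 16; the
#'   full-scale reference setting is an effective 480 via accumulation).
#' @param grad_accum gradient-accumulation factor; the effective batch size
#'   is `batch_size * grad_accum`.
#' @param lr base learning rate (default 0.001).
#' @param warmup linear warmup length in steps (default 500).
#' @param max_steps number of optimizer steps to run.
#' @param checkpoint_frac corpus fraction between checkpoints (default
#'   0.05).
#' @param optimizer `"adam"` or `"lamb"`.
#' @param seed integer seed governing batch and window sampling (and
#'   dropout).
#' @param window training-window length in tokens; defaults to the model's
#'   `max_seq`.
#' @param checkpoint_dir optional directory for checkpoint files.
#' @return List of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, grad_accum = 1L, lr = 0.001,
                         warmup = 500L, max_steps = 1000L,
                         checkpoint_frac = 0.05,
                         optimizer = c("adam", "lamb"), seed = 13L,
                         window = NULL, checkpoint_dir = NULL) {
  optimizer <- match.arg(optimizer)
  if (warmup < 1L) stopf("warmup must be >= 1")
  if (checkpoint_frac <= 0 || checkpoint_frac > 1)
    stopf("checkpoint_frac must be in (0, 1]")
  structure(list(batch_size = as.integer(batch_size),
                 grad_accum = as.integer(grad_accum), lr = lr,
                 warmup = as.integer(warmup),
                 max_steps = as.integer(max_steps),
                 checkpoint_frac = checkpoint_frac, optimizer = optimizer,
                 seed = as.integer(seed), window = window,
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Linear warmup to the base rate over `warmup` steps, flat afterwards (no
#' decay).
#'
#' @param step optimizer step (1-based).
#' @param config a [train_config()] (or any list with `lr` and `warmup`).
#' @return Learning rate for `step`.
#' @export
lr_schedule <- function(step, config) {
  stopifnot(step >= 1L)
  if (step <= config$warmup) config$lr * step / config$warmup
  else config$lr
}

make_opt_state <- function(params) {
  list(t = 0L,
       m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params))
}

# One Adam/LAMB step over the parameter tree. LAMB rescales each tensor's
# Adam direction by the trust ratio |w| / |update|.
opt_step <- function(params, grads, state, lr, optimizer,
                     b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g * g,
                       state$v, grads)
  c1 <- 1 / (1 - b1^state$t)
  c2 <- 1 / (1 - b2^state$t)
  dir <- tree_map2(function(m, v) (m * c1) / (sqrt(v * c2) + eps),
                   state$m, state$v)
  params <- if (optimizer == "lamb") {
    tree_map2(function(w, r) {
      wn <- sqrt(sum(w * w)); rn <- sqrt(sum(r * r))
      trust <- if (wn > 0 && rn > 0) wn / rn else 1
      w - lr * trust * r
    }, params, dir)
  } else {
    tree_map2(function(w, r) w - lr * r, params, dir)
  }
  list(params = params, state = state)
}

#' Window provider over encoded documents
#'
#' Returns a provider closure for [train_model()]: each call draws
#' `batch_size` documents (uniformly, with replacement across the corpus)
#' and samples a fresh training window from each, so every viewing of a
#' document can contribute a different window.
#'
#' @param docs list of [encode_record()] results.
#' @param batch_size windows per batch.
#' @param window window length in tokens.
#' @return Function `(step) -> list of training_window`, with the corpus
#'   size attached as attribute `n_docs`.
#' @export
window_provider <- function(docs, batch_size, window = 128L) {
  stopifnot(length(docs) >= 1L)
  f <- function(step) {
    idx <- sample.int(length(docs), batch_size, replace = TRUE)
    lapply(docs[idx], sample_window, window = window)
  }
  attr(f, "n_docs") <- length(docs)
  f
}

#' Fixed-batch provider
#'
#' Always returns the same windows; used for memorization diagnostics.
#'
#' @param windows list of `training_window` objects.
#' @return Provider function for [train_model()].
#' @export
fixed_window_provider <- function(windows) {
  f <- function(step) windows
  attr(f, "n_docs") <- length(windows)
  f
}

#' Train the conditional transformer
#'
#' Runs `max_steps` optimizer steps with the linear-warmup schedule,
#' logging the total loss and the four task components at every step, and
#' writing checkpoints each time a `checkpoint_frac` fraction of the corpus
#' has been viewed (when `checkpoint_dir` is set). Deterministic given the
#' config seed. Aborts with a diagnostic naming the step if the loss turns
#' non-finite.
#'
#' @param provider batch provider, e.g. [window_provider()] or
#'   [fixed_window_provider()].
#' @param params initial [init_model_params()] parameters.
#' @param config the [model_config()].
#' @param tconfig a [train_config()].
#' @param opt_state optional optimizer state to resume from.
#' @param start_step first step number (for resumed runs).
#' @return List with final `params`, `opt_state`, the per-step `log`
#'   data.frame (step, lr, total, token, pos, dep, ent) and any
#'   `checkpoints` written.
#' @export
train_model <- function(provider, params, config, tconfig,
                        opt_state = NULL, start_step = 1L,
                        rng_state = NULL) {
  stopifnot(inherits(config, "model_config"),
            inherits(tconfig, "train_config"))
  if (!is.null(rng_state)) {
    assign(".Random.seed", rng_state, envir = globalenv())
  } else {
    set.seed(tconfig$seed + start_step - 1L)
  }
  opt_state <- opt_state %||% make_opt_state(params)
  n_docs <- attr(provider, "n_docs") %||% NA_integer_
  ckpt_every <- if (!is.na(n_docs)) {
    max(1L, as.integer(round(tconfig$checkpoint_frac * n_docs /
                               (tconfig$batch_size * tconfig$grad_accum))))
  } else max(1L, as.integer(round(tconfig$checkpoint_frac *
                                    tconfig$max_steps)))
  steps <- start_step:(start_step + tconfig$max_steps - 1L)
  log <- data.frame(step = steps, lr = NA_real_, total = NA_real_,
                    token = NA_real_, pos = NA_real_, dep = NA_real_,
                    ent = NA_real_)
  ckpts <- character(0)
  for (k in seq_along(steps)) {
    step <- steps[k]
    lr <- lr_schedule(step, tconfig)
    grads <- NULL
    tot <- 0; comp <- c(token = 0, pos = 0, dep = 0, ent = 0)
    for (a in seq_len(tconfig$grad_accum)) {
      batch <- provider(step)
      bg <- batch_loss_grads(batch, params, config, training = TRUE)
      grads <- if (is.null(grads)) bg$grads
               else tree_map2(`+`, grads, bg$grads)
      tot <- tot + bg$loss$total
      comp <- comp + bg$loss$components
    }
    if (tconfig$grad_accum > 1L) {
      grads <- tree_map(function(x) x / tconfig$grad_accum, grads)
      tot <- tot / tconfig$grad_accum
      comp <- comp / tconfig$grad_accum
    }
    if (!is.finite(tot))
      stopf("non-finite loss at step %d; aborting", step)
    st <- opt_step(params, grads, opt_state, lr, tconfig$optimizer)
    params <- st$params
    opt_state <- st$state
    log[k, -1] <- c(lr, tot, comp)
    if (!is.null(tconfig$checkpoint_dir) && step %% ckpt_every == 0L) {
      p <- file.path(tconfig$checkpoint_dir,
                     sprintf("ckpt_%06d.rds", step))
      save_checkpoint(p, params, config, opt_state, step, tconfig,
                      rng_state = get(".Random.seed",
                                      envir = globalenv()))
      ckpts <- c(ckpts, p)
    }
  }
  list(params = params, opt_state = opt_state, log = log,
       checkpoints = ckpts)
}

#' Write a training checkpoint
#'
#' A single archive holding the configuration, every parameter tensor, the
#' optimizer state and the step counter; reloading reproduces eval-mode
#' logits bit-identically on the same hardware.
#'
#' @param path file path (`.rds`).
#' @param params,config,opt_state,step,tconfig checkpoint contents.
#' @param rng_state the generator state at checkpoint time, so a resumed
#'   run replays the exact window-sampling trajectory.
#' @export
save_checkpoint <- function(path, params, config, opt_state, step,
                            tconfig = NULL, rng_state = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(params = params, config = config, opt_state = opt_state,
               step = step, tconfig = tconfig, rng_state = rng_state),
          path)
  invisible(path)
}

#' Read a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return List with `params`, `config`, `opt_state`, `step`, `tconfig`.
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Write a loss log as TSV
#'
#' Columns: step, lr, total and the four component losses.
#'
#' @param log the `log` data.frame from [train_model()].
#' @param path output path.
#' @export
write_loss_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
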