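# recursive helpers over nested parameter trees (lists of numeric leaves)
.tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) .tree_map(f, e)) else f(x)
}

.tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    if (!is.null(names(x)) && !is.null(names(y))) y <- y[names(x)]
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- .tree_map2(f, x[[i]], y[[i]])
    out
  } else {
    f(x, y)
  }
}

.tree_zeros <- function(x) .tree_map(function(v) v * 0, x)

# one Adam step over a parameter tree; returns list(params, m, v)
.adam_step <- function(params, grads, m, v, lr, step,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- .tree_map2(function(a, g) beta1 * a + (1 - beta1) * g, m, grads)
  v <- .tree_map2(function(a, g) beta2 * a + (1 - beta2) * g * g, v, grads)
  c1 <- 1 - beta1^step
  c2 <- 1 - beta2^step
  upd <- .tree_map2(function(a, b) (a / c1) / (sqrt(b / c2) + eps), m, v)
  params <- .tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, m = m, v = v)
}

#' Training configuration
#'
#' @param epochs Number of passes over the corpus (default 6).
#' @param batch_size Sequences per optimizer step (default 16).
#' @param learning_rate Adam learning rate (default 3e-3; sized for the tiny
#'   reference model, not for billion-parameter bases).
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param freeze_base If `TRUE`, only the adapter projections are updated
#'   and the base transformer weights stay bit-identical.
#' @param verbose Print per-epoch losses.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 6, batch_size = 16, learning_rate = 3e-3,
                         seed = 1, freeze_base = FALSE, verbose = FALSE) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = seed,
                 freeze_base = isTRUE(freeze_base),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train the adapter language model
#'
#' Minimizes the mean next-token cross-entropy of the conditional objective
#' \eqn{-\log p(s \mid \psi)} over a corpus of scored messages with Adam.
#' Trait scores are assumed standardized. With `freeze_base = TRUE` only the
#' adapter projection matrices receive updates. Deterministic for a fixed
#' seed.
#'
#' @param corpus List of [scored_message()]s (standardized scores).
#' @param model An [adapter_lm()] to train, or `NULL` to build one from
#'   `model_cfg`/`adapter_cfg`/`vocab`.
#' @param model_cfg,adapter_cfg,vocab Used when `model` is `NULL`.
#' @param train_cfg A [train_config()].
#' @return Object of class `lm_checkpoint`: list with `model` (trained
#'   [adapter_lm()]), `train_cfg`, `epoch_loss` (mean per-token NLL per
#'   epoch, epoch 0 = pre-training loss), and `std_constants` (carried from
#'   attr(corpus, "standardization") when present).
#' @export
train_adapter <- function(corpus, model = NULL, model_cfg = NULL,
                          adapter_cfg = NULL, vocab = NULL,
                          train_cfg = train_config()) {
  if (length(corpus) < 1L) stop("corpus must be non-empty", call. = FALSE)
  stopifnot(inherits(train_cfg, "train_config"))
  if (is.null(model)) {
    model <- adapter_lm(model_cfg, adapter_cfg, vocab, seed = train_cfg$seed)
  }
  cfg <- model$model_cfg
  for (msg in corpus) {
    if (!inherits(msg, "scored_message")) {
      stop("corpus entries must be scored_message objects", call. = FALSE)
    }
  }
  trainable <- if (train_cfg$freeze_base) {
    list(adapter = unclass(model$projections))
  } else {
    list(base = model$params, adapter = unclass(model$projections))
  }
  m_state <- .tree_zeros(trainable)
  v_state <- .tree_zeros(trainable)
  step <- 0L
  n <- length(corpus)
  epoch_loss <- numeric(train_cfg$epochs + 1L)
  epoch_loss[1] <- corpus_nll(model, corpus)
  if (train_cfg$verbose) {
    message(sprintf("epoch 0: mean NLL %.4f", epoch_loss[1]))
  }
  for (ep in seq_len(train_cfg$epochs)) {
    ord <- .with_seed(.sub_seed(train_cfg$seed, ep), sample.int(n))
    tok_total <- 0; nll_total <- 0
    starts <- seq(1L, n, by = train_cfg$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + train_cfg$batch_size - 1L, n)]
      acc <- NULL
      btok <- 0L
      for (i in idx) {
        msg <- corpus[[i]]
        inputs <- c(cfg$sos_id, msg$tokens)
        targets <- c(msg$tokens, cfg$eos_id)
        fw <- .forward(model, inputs, msg$scores, keep_cache = TRUE)
        ce <- .ce_loss(fw$logits, targets)
        if (!is.finite(ce$nll)) {
          stop(sprintf(
            "non-finite loss at epoch %d (message %d); lower the learning rate",
            ep, i), call. = FALSE)
        }
        gr <- .backward(model, fw, ce$dlogits)
        gr <- if (train_cfg$freeze_base) list(adapter = gr$adapter) else gr
        acc <- if (is.null(acc)) gr else .tree_map2(`+`, acc, gr)
        btok <- btok + length(targets)
        nll_total <- nll_total + ce$nll
        tok_total <- tok_total + length(targets)
      }
      acc <- .tree_map(function(g) g / btok, acc)
      step <- step + 1L
      upd <- .adam_step(trainable, acc, m_state, v_state,
                        lr = train_cfg$learning_rate, step = step)
      trainable <- upd$params
      m_state <- upd$m
      v_state <- upd$v
      if (!train_cfg$freeze_base) model$params <- trainable$base
      model$projections <- structure(trainable$adapter,
                                     class = "projection_set")
    }
    epoch_loss[ep + 1L] <- nll_total / tok_total
    if (train_cfg$verbose) {
      message(sprintf("epoch %d: mean NLL %.4f", ep, epoch_loss[ep + 1L]))
    }
  }
  structure(list(model = model, train_cfg = train_cfg,
                 epoch_loss = epoch_loss,
                 std_constants = attr(corpus, "standardization")),
            class = "lm_checkpoint")
}

#' @export
print.lm_checkpoint <- function(x, ...) {
  cat(sprintf("Trained checkpoint: %d epoch(s), NLL %.4f -> %.4f\n",
              length(x$epoch_loss) - 1L,
              x$epoch_loss[1], x$epoch_loss[length(x$epoch_loss)]))
  invisible(x)
}
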