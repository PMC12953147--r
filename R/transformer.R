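# Tiny decoder-only pre-norm transformer with RMSNorm, GELU feed-forward,
# learned absolute positions, and per-layer trait injection: at every
# injected layer the (bias-augmented) trait vector, projected by that
# layer's adapter matrices, supplies the key and value states of a dummy
# position prepended to the attention window. The dummy position emits no
# prediction and receives no loss; real tokens occupy positions 1..T and may
# attend to the dummy and to positions <= their own (causal masking).
# Gradients are hand-derived; a finite-difference check lives in the tests.

.rmsnorm_eps <- 1e-6

.rmsnorm_fwd <- function(x, g) {
  r <- sqrt(rowMeans(x * x) + .rmsnorm_eps)
  list(y = (x / r) * rep(g, each = nrow(x)), r = r)
}

.rmsnorm_bwd <- function(x, g, r, dy) {
  H <- ncol(x)
  gy <- dy * rep(g, each = nrow(x))
  dg <- colSums(dy * (x / r))
  dx <- gy / r - x * (rowSums(gy * x) / (H * r^3))
  list(dx = dx, dg = dg)
}

.gelu <- function(x) x * stats::pnorm(x)
.gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# row-wise softmax over a masked score matrix (-Inf marks masked slots)
.softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# causal mask: query row i may attend key column j iff j <= i + off
# (off = 1 when a dummy key/value slot is prepended)
.causal_mask <- function(Tn, off) {
  M <- matrix(0, Tn, Tn + off)
  M[col(M) > row(M) + off] <- -Inf
  M
}

.head_cols <- function(h, head_dim) ((h - 1L) * head_dim + 1L):(h * head_dim)

.kv_group <- function(h, cfg) (h - 1L) %/% (cfg$num_heads %/% cfg$num_kv_heads) + 1L

# initialize base transformer parameters (normal(0, 0.02), unit norm gains)
.init_base_params <- function(cfg, seed) {
  H <- cfg$hidden_size; Fd <- cfg$ff_mult * H; kvw <- .kv_width(cfg)
  rn <- function(n1, n2) matrix(stats::rnorm(n1 * n2, sd = 0.02), n1, n2)
  .with_seed(seed, {
    layers <- lapply(seq_len(cfg$num_layers), function(l) {
      list(g_attn = rep(1, H),
           Wq = rn(H, H), Wk = rn(H, kvw), Wv = rn(H, kvw), Wo = rn(H, H),
           g_mlp = rep(1, H), W1 = rn(H, Fd), W2 = rn(Fd, H))
    })
    list(tok_emb = rn(cfg$vocab_size, H),
         pos_emb = rn(cfg$max_seq_len, H),
         layers = layers,
         g_final = rep(1, H),
         out_proj = rn(H, cfg$vocab_size))
  })
}

#' Construct an adapter language model
#'
#' Builds the tiny reference decoder-only transformer together with its
#' adapter projection set. Freshly initialized (training is done by
#' [train_adapter()]).
#'
#' @param model_cfg A [model_config()].
#' @param adapter_cfg An [adapter_config()].
#' @param vocab Character vector of token strings of length
#'   `model_cfg$vocab_size` (special tokens included at their configured
#'   ids).
#' @param seed Integer seed for parameter initialization.
#' @param adapter_init_scale SD of the adapter initializer (default 0:
#'   neutral start).
#' @return Object of class `adapter_lm` with fields `model_cfg`,
#'   `adapter_cfg`, `vocab`, `params`, `projections`.
#' @export
adapter_lm <- function(model_cfg, adapter_cfg, vocab, seed = 1,
                       adapter_init_scale = 0) {
  stopifnot(inherits(model_cfg, "model_config"),
            inherits(adapter_cfg, "adapter_config"))
  vocab <- as.character(vocab)
  if (length(vocab) != model_cfg$vocab_size) {
    stop("vocab length must equal model_cfg$vocab_size", call. = FALSE)
  }
  structure(list(model_cfg = model_cfg,
                 adapter_cfg = adapter_cfg,
                 vocab = vocab,
                 params = .init_base_params(model_cfg, seed),
                 projections = make_projection_set(model_cfg, adapter_cfg,
                                                   init_scale = adapter_init_scale,
                                                   seed = .sub_seed(seed, 7L))),
            class = "adapter_lm")
}

#' @export
print.adapter_lm <- function(x, ...) {
  cat(sprintf(
    "Adapter LM: %d layer(s), hidden %d, %d head(s), vocab %d, %d trait dim(s); %d adapter parameter(s)\n",
    x$model_cfg$num_layers, x$model_cfg$hidden_size, x$model_cfg$num_heads,
    x$model_cfg$vocab_size, x$adapter_cfg$latent_size,
    count_adapter_params(x$model_cfg, x$adapter_cfg)))
  invisible(x)
}

# full forward pass over one input sequence (1-based token ids).
# Returns logits (T x V) for next-token prediction at every position, plus
# the activation cache needed for the backward pass.
.forward <- function(model, ids, scores, keep_cache = FALSE) {
  cfg <- model$model_cfg
  p <- model$params
  Tn <- length(ids)
  if (Tn > cfg$max_seq_len) stop("sequence exceeds max_seq_len", call. = FALSE)
  X <- p$tok_emb[ids, , drop = FALSE] + p$pos_emb[seq_len(Tn), , drop = FALSE]
  ptil <- NULL
  injected <- .injected_layers(cfg, model$adapter_cfg)
  if (length(injected) > 0) {
    ptil <- .augment_profile(scores, model$adapter_cfg)
  }
  dh <- cfg$head_dim
  caches <- if (keep_cache) vector("list", cfg$num_layers) else NULL
  for (l in seq_len(cfg$num_layers)) {
    ly <- p$layers[[l]]
    n1 <- .rmsnorm_fwd(X, ly$g_attn)
    Q <- n1$y %*% ly$Wq
    K <- n1$y %*% ly$Wk
    V <- n1$y %*% ly$Wv
    if (l %in% injected) {
      pl <- model$projections[[as.character(l)]]
      Kf <- rbind(ptil %*% pl$key, K)
      Vf <- rbind(ptil %*% pl$value, V)
      off <- 1L
    } else {
      Kf <- K; Vf <- V; off <- 0L
    }
    mask <- .causal_mask(Tn, off)
    O <- matrix(0, Tn, cfg$hidden_size)
    Ph <- vector("list", cfg$num_heads)
    for (h in seq_len(cfg$num_heads)) {
      qc <- .head_cols(h, dh)
      kc <- .head_cols(.kv_group(h, cfg), dh)
      S <- (Q[, qc, drop = FALSE] %*% t(Kf[, kc, drop = FALSE])) / sqrt(dh) + mask
      P <- .softmax_rows(S)
      O[, qc] <- P %*% Vf[, kc, drop = FALSE]
      Ph[[h]] <- P
    }
    attn <- O %*% ly$Wo
    Xmid <- X + attn
    n2 <- .rmsnorm_fwd(Xmid, ly$g_mlp)
    H1pre <- n2$y %*% ly$W1
    H1 <- .gelu(H1pre)
    Xout <- Xmid + H1 %*% ly$W2
    if (keep_cache) {
      caches[[l]] <- list(Xin = X, n1 = n1, Q = Q, Kf = Kf, Vf = Vf,
                          off = off, Ph = Ph, O = O, Xmid = Xmid,
                          n2 = n2, H1pre = H1pre, H1 = H1)
    }
    X <- Xout
  }
  nf <- .rmsnorm_fwd(X, p$g_final)
  logits <- nf$y %*% p$out_proj
  list(logits = logits, caches = caches, Xlast = X, nf = nf, ptil = ptil,
       ids = ids, injected = injected)
}

# cross-entropy of next-token targets given logits; returns per-token log
# probabilities, the total NLL, and d(loss)/d(logits) for total (summed) NLL
.ce_loss <- function(logits, targets) {
  n <- length(targets)
  m <- apply(logits, 1, max)
  ls <- logits - m
  lz <- log(rowSums(exp(ls)))
  logp <- ls - lz
  pick <- cbind(seq_len(n), targets)
  tok_lp <- logp[pick]
  dlogits <- exp(logp)
  dlogits[pick] <- dlogits[pick] - 1
  list(log_probs = tok_lp, nll = -sum(tok_lp), dlogits = dlogits)
}

# backward pass: gradients of a scalar loss (whose d/dlogits is supplied)
# w.r.t. all base parameters and adapter projections
.backward <- function(model, fw, dlogits) {
  cfg <- model$model_cfg
  p <- model$params
  Tn <- length(fw$ids)
  dh <- cfg$head_dim
  g <- list(tok_emb = matrix(0, cfg$vocab_size, cfg$hidden_size),
            pos_emb = matrix(0, cfg$max_seq_len, cfg$hidden_size),
            layers = vector("list", cfg$num_layers),
            g_final = NULL, out_proj = NULL)
  gproj <- lapply(model$projections, function(pl) {
    list(key = matrix(0, nrow(pl$key), ncol(pl$key)),
         value = matrix(0, nrow(pl$value), ncol(pl$value)))
  })
  g$out_proj <- t(fw$nf$y) %*% dlogits
  dnfy <- dlogits %*% t(p$out_proj)
  bf <- .rmsnorm_bwd(fw$Xlast, p$g_final, fw$nf$r, dnfy)
  g$g_final <- bf$dg
  dX <- bf$dx
  for (l in rev(seq_len(cfg$num_layers))) {
    cc <- fw$caches[[l]]
    ly <- p$layers[[l]]
    # feed-forward block: Xout = Xmid + gelu(rmsnorm(Xmid)) W2
    dW2 <- t(cc$H1) %*% dX
    dH1 <- dX %*% t(ly$W2)
    dH1pre <- dH1 * .gelu_grad(cc$H1pre)
    dW1 <- t(cc$n2$y) %*% dH1pre
    dn2y <- dH1pre %*% t(ly$W1)
    b2 <- .rmsnorm_bwd(cc$Xmid, ly$g_mlp, cc$n2$r, dn2y)
    dXmid <- dX + b2$dx
    # attention block: Xmid = Xin + (heads(rmsnorm(Xin))) Wo
    dWo <- t(cc$O) %*% dXmid
    dO <- dXmid %*% t(ly$Wo)
    dQ <- matrix(0, Tn, cfg$hidden_size)
    dKf <- matrix(0, nrow(cc$Kf), ncol(cc$Kf))
    dVf <- matrix(0, nrow(cc$Vf), ncol(cc$Vf))
    for (h in seq_len(cfg$num_heads)) {
      qc <- .head_cols(h, dh)
      kc <- .head_cols(.kv_group(h, cfg), dh)
      P <- cc$Ph[[h]]
      dOh <- dO[, qc, drop = FALSE]
      dP <- dOh %*% t(cc$Vf[, kc, drop = FALSE])
      dVf[, kc] <- dVf[, kc] + t(P) %*% dOh
      dS <- P * (dP - rowSums(dP * P))
      dQ[, qc] <- dQ[, qc] +
        (dS %*% cc$Kf[, kc, drop = FALSE]) / sqrt(dh)
      dKf[, kc] <- dKf[, kc] +
        (t(dS) %*% cc$Q[, qc, drop = FALSE]) / sqrt(dh)
    }
    if (cc$off == 1L) {
      key <- as.character(l)
      gproj[[key]]$key <- gproj[[key]]$key + t(fw$ptil) %*% dKf[1, , drop = FALSE]
      gproj[[key]]$value <- gproj[[key]]$value + t(fw$ptil) %*% dVf[1, , drop = FALSE]
      dK <- dKf[-1, , drop = FALSE]
      dV <- dVf[-1, , drop = FALSE]
    } else {
      dK <- dKf; dV <- dVf
    }
    dn1y <- dQ %*% t(ly$Wq) + dK %*% t(ly$Wk) + dV %*% t(ly$Wv)
    b1 <- .rmsnorm_bwd(cc$Xin, ly$g_attn, cc$n1$r, dn1y)
    # same field order as the parameter tree so trees align elementwise
    g$layers[[l]] <- list(g_attn = b1$dg,
                          Wq = t(cc$n1$y) %*% dQ,
                          Wk = t(cc$n1$y) %*% dK,
                          Wv = t(cc$n1$y) %*% dV,
                          Wo = dWo,
                          g_mlp = b2$dg,
                          W1 = dW1, W2 = dW2)
    dX <- dXmid + b1$dx
  }
  emb <- rowsum(dX, group = fw$ids, reorder = FALSE)
  g$tok_emb[as.integer(rownames(emb)), ] <-
    g$tok_emb[as.integer(rownames(emb)), , drop = FALSE] + emb
  g$pos_emb[seq_len(Tn), ] <- dX
  list(base = g, adapter = gproj)
}

#' A scored message
#'
#' The atomic training record: a body of token ids (no special tokens) plus
#' the standardized trait scores conditioning it.
#'
#' @param tokens Integer vector of 1-based token ids (body only, n >= 1).
#' @param scores Numeric standardized trait-score vector.
#' @return Object of class `scored_message`.
#' @export
scored_message <- function(tokens, scores) {
  tokens <- as.integer(tokens)
  if (length(tokens) < 1L) stop("a message needs at least one token",
                                call. = FALSE)
  structure(list(tokens = tokens, scores = as.numeric(scores)),
            class = "scored_message")
}

#' Conditional log-likelihood of a message
#'
#' Evaluates the autoregressive factorization
#' \eqn{p(s \mid \psi) = \prod_j p(w_j \mid w_1..w_{j-1}, \psi)} on the
#' sequence `[SOS] w_1 .. w_n [EOS]` with the trait dummy position
#' prepended at every injected layer. The dummy emits no prediction; the
#' returned log-probabilities cover the n body tokens plus `[EOS]`.
#'
#' @param model An [adapter_lm()] (or trained checkpoint's `$model`).
#' @param message A [scored_message()].
#' @return List with `log_probs` (length n + 1), `nll` (total negative log
#'   likelihood), `mean_nll` (per predicted token).
#' @export
conditional_log_likelihood <- function(model, message) {
  stopifnot(inherits(model, "adapter_lm"), inherits(message, "scored_message"))
  cfg <- model$model_cfg
  toks <- message$tokens
  if (any(toks < 1L | toks > cfg$vocab_size)) {
    stop("token id outside the vocabulary", call. = FALSE)
  }
  special <- c(cfg$sos_id, cfg$eos_id, cfg$pad_id)
  if (any(toks %in% special)) {
    stop("special tokens are not allowed inside the message body",
         call. = FALSE)
  }
  if (length(toks) > cfg$max_seq_len - 2L) {
    stop(sprintf("message of %d tokens exceeds the %d-token limit",
                 length(toks), cfg$max_seq_len - 2L), call. = FALSE)
  }
  inputs <- c(cfg$sos_id, toks)
  targets <- c(toks, cfg$eos_id)
  fw <- .forward(model, inputs, message$scores)
  ce <- .ce_loss(fw$logits, targets)
  list(log_probs = ce$log_probs, nll = ce$nll,
       mean_nll = ce$nll / length(targets))
}

#' Mean conditional NLL over a corpus
#'
#' @param model An [adapter_lm()].
#' @param corpus List of [scored_message()]s.
#' @return Mean per-token negative log likelihood.
#' @export
corpus_nll <- function(model, corpus) {
  tot <- 0; n <- 0
  for (msg in corpus) {
    cl <- conditional_log_likelihood(model, msg)
    tot <- tot + cl$nll
    n <- n + length(cl$log_probs)
  }
  tot / n
}
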