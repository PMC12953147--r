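test_that("adapter parameter accounting follows 2 * L * (t+1) * kv_width", {
  gemma <- model_config(vocab_size = 1000, num_layers = 18,
                        hidden_size = 2048, num_heads = 8, num_kv_heads = 1,
                        head_dim = 256)
  expect_equal(count_adapter_params(gemma, adapter_config(5)), 55296L)
  minimal <- model_config(vocab_size = 5, num_layers = 1, hidden_size = 1,
                          num_heads = 1, num_kv_heads = 1, head_dim = 1)
  expect_equal(count_adapter_params(minimal, adapter_config(0)), 2L)
  # restricting the injected layer set scales the count
  expect_equal(count_adapter_params(gemma,
                                    adapter_config(5, inject_layers = 1:9)),
               55296L / 2)
  expect_equal(count_adapter_params(gemma,
                                    adapter_config(5, include_bias = FALSE)),
               2 * 18 * 5 * 256)
})

test_that("projection sets have the configured shapes and are seed-deterministic", {
  gemma <- model_config(vocab_size = 1000, num_layers = 18,
                        hidden_size = 2048, num_heads = 8, num_kv_heads = 1,
                        head_dim = 256)
  ps <- make_projection_set(gemma, adapter_config(5), init_scale = 0.02,
                            seed = 5)
  expect_length(ps, 18)
  expect_equal(dim(ps[["1"]]$key), c(6L, 256L))
  expect_equal(dim(ps[["18"]]$value), c(6L, 256L))
  ps2 <- make_projection_set(gemma, adapter_config(5), init_scale = 0.02,
                             seed = 5)
  expect_identical(ps, ps2)
  ps0 <- make_projection_set(gemma, adapter_config(5), init_scale = 0)
  expect_true(all(ps0[["7"]]$key == 0) && all(ps0[["7"]]$value == 0))
})

test_that("trait states are the affine image of the profile", {
  acfg <- adapter_config(2)
  W <- matrix(seq(0.1, 1.2, by = 0.1), nrow = 3, ncol = 4)  # (t+1) x kv
  proj <- list("1" = list(key = W, value = 2 * W))
  st <- inject_trait_state(c(1, -1), proj, 1, acfg)
  expect_equal(st$key, as.numeric(c(1, -1, 1) %*% W))
  expect_equal(st$value, as.numeric(c(1, -1, 1) %*% (2 * W)))
  # explicit hand product for the first coordinate: 1*0.1 - 1*0.2 + 1*0.3
  expect_equal(st$key[1], 0.2)
  # zero profile with bias returns the bias row
  st0 <- inject_trait_state(c(0, 0), proj, 1, acfg)
  expect_equal(st0$key, as.numeric(W[3, ]))
  # zero matrices kill any profile
  proj0 <- list("1" = list(key = 0 * W, value = 0 * W))
  expect_equal(inject_trait_state(c(3, -3), proj0, 1, acfg)$key, rep(0, 4))
  expect_error(inject_trait_state(c(1, -1), proj, 2, acfg), "not an injected")
})

test_that("a zero output head yields the uniform distribution NLL", {
  model <- tiny_model()
  model$params$out_proj[] <- 0
  msg <- scored_message(c(5L, 6L, 7L), c(1, -1))
  cl <- conditional_log_likelihood(model, msg)
  V <- model$model_cfg$vocab_size
  expect_equal(cl$nll, (3 + 1) * log(V), tolerance = 1e-9)
  expect_equal(cl$log_probs, rep(-log(V), 4), tolerance = 1e-9)
})

test_that("zero projections make likelihood and generation profile-invariant", {
  model <- tiny_model(adapter_init_scale = 0)
  msg1 <- scored_message(c(5L, 7L, 6L, 5L), c(3, -3))
  msg2 <- scored_message(c(5L, 7L, 6L, 5L), c(-2, 0.5))
  expect_identical(conditional_log_likelihood(model, msg1)$log_probs,
                   conditional_log_likelihood(model, msg2)$log_probs)
  g1 <- generate_text(model, generation_request(c(3, -3), max_new_tokens = 8,
                                                seed = 4))
  g2 <- generate_text(model, generation_request(c(-2, 0.5), max_new_tokens = 8,
                                                seed = 4))
  expect_identical(g1$ids, g2$ids)
  # with non-zero projections the same comparison detects the conditioning
  model2 <- tiny_model(adapter_init_scale = 0.5)
  expect_false(identical(conditional_log_likelihood(model2, msg1)$log_probs,
                         conditional_log_likelihood(model2, msg2)$log_probs))
})

test_that("causal masking: perturbing a token never changes earlier log-probs", {
  model <- tiny_model(adapter_init_scale = 0.1)
  base <- c(5L, 6L, 7L, 8L, 5L)
  cl0 <- conditional_log_likelihood(model, scored_message(base, c(1, -1)))
  for (j in 2:5) {
    pert <- base
    pert[j] <- if (base[j] == 5L) 6L else 5L
    cl1 <- conditional_log_likelihood(model, scored_message(pert, c(1, -1)))
    expect_equal(cl1$log_probs[seq_len(j - 1)], cl0$log_probs[seq_len(j - 1)],
                 tolerance = 1e-12)
  }
})

test_that("a naive single-head reimplementation reproduces the forward NLL", {
  # independent oracle: explicit-loop forward pass for a 1-layer, 1-head model
  mcfg <- model_config(vocab_size = 7, num_layers = 1, hidden_size = 4,
                       num_heads = 1, num_kv_heads = 1, head_dim = 4,
                       max_seq_len = 10)
  model <- adapter_lm(mcfg, adapter_config(2), build_vocab(letters[1:3]),
                      seed = 8, adapter_init_scale = 0.3)
  toks <- c(5L, 6L, 5L)
  scores <- c(1.5, -0.5)
  cl <- conditional_log_likelihood(model, scored_message(toks, scores))

  p <- model$params
  eps <- 1e-6
  rms <- function(v, g) g * v / sqrt(mean(v^2) + eps)
  inputs <- c(mcfg$sos_id, toks)
  targets <- c(toks, mcfg$eos_id)
  Tn <- length(inputs)
  X <- matrix(0, Tn, 4)
  for (i in seq_len(Tn)) X[i, ] <- p$tok_emb[inputs[i], ] + p$pos_emb[i, ]
  ly <- p$layers[[1]]
  pr <- model$projections[["1"]]
  ptil <- c(scores, 1)
  kd <- as.numeric(ptil %*% pr$key)
  vd <- as.numeric(ptil %*% pr$value)
  Xmid <- X
  for (i in seq_len(Tn)) {
    xn_i <- rms(X[i, ], ly$g_attn)
    q <- as.numeric(xn_i %*% ly$Wq)
    keys <- list(kd)
    vals <- list(vd)
    for (j in seq_len(i)) {
      xn_j <- rms(X[j, ], ly$g_attn)
      keys[[j + 1]] <- as.numeric(xn_j %*% ly$Wk)
      vals[[j + 1]] <- as.numeric(xn_j %*% ly$Wv)
    }
    s <- sapply(keys, function(k) sum(q * k)) / sqrt(4)
    a <- exp(s - max(s)); a <- a / sum(a)
    o <- Reduce(`+`, Map(function(w, v) w * v, as.list(a), vals))
    Xmid[i, ] <- X[i, ] + as.numeric(o %*% ly$Wo)
  }
  Xout <- Xmid
  for (i in seq_len(Tn)) {
    h <- as.numeric(rms(Xmid[i, ], ly$g_mlp) %*% ly$W1)
    h <- h * stats::pnorm(h)
    Xout[i, ] <- Xmid[i, ] + as.numeric(h %*% ly$W2)
  }
  nll_oracle <- 0
  for (i in seq_len(Tn)) {
    z <- as.numeric(rms(Xout[i, ], p$g_final) %*% p$out_proj)
    pvec <- exp(z - max(z)); pvec <- pvec / sum(pvec)
    nll_oracle <- nll_oracle - log(pvec[targets[i]])
  }
  expect_equal(cl$nll, nll_oracle, tolerance = 1e-8)
})

test_that("analytic gradients match finite differences", {
  tl <- asNamespace("traitlm")
  model <- tiny_model(adapter_init_scale = 0.05)
  msg <- scored_message(c(5L, 6L, 7L, 5L), c(1.2, -0.7))
  inputs <- c(model$model_cfg$sos_id, msg$tokens)
  targets <- c(msg$tokens, model$model_cfg$eos_id)
  loss_fn <- function(m) {
    fw <- tl$.forward(m, inputs, msg$scores)
    tl$.ce_loss(fw$logits, targets)$nll
  }
  fw <- tl$.forward(model, inputs, msg$scores, keep_cache = TRUE)
  gr <- tl$.backward(model, fw, tl$.ce_loss(fw$logits, targets)$dlogits)
  h <- 1e-5
  set.seed(31)
  probe <- function(get, set, ga, n = 4) {
    arr <- get(model)
    for (i in sample(length(arr), min(n, length(arr)))) {
      up <- model; a <- arr; a[i] <- a[i] + h; up <- set(up, a)
      dn <- model; a <- arr; a[i] <- a[i] - h; dn <- set(dn, a)
      num <- (loss_fn(up) - loss_fn(dn)) / (2 * h)
      expect_equal(ga[i], num, tolerance = 1e-4)
    }
  }
  probe(function(m) m$params$tok_emb,
        function(m, a) {m$params$tok_emb <- a; m}, gr$base$tok_emb)
  probe(function(m) m$params$out_proj,
        function(m, a) {m$params$out_proj <- a; m}, gr$base$out_proj)
  for (l in 1:2) {
    for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2", "g_attn", "g_mlp")) {
      probe(function(m) m$params$layers[[l]][[nm]],
            function(m, a) {m$params$layers[[l]][[nm]] <- a; m},
            gr$base$layers[[l]][[nm]], 3)
    }
    for (nm in c("key", "value")) {
      probe(function(m) m$projections[[as.character(l)]][[nm]],
            function(m, a) {m$projections[[as.character(l)]][[nm]] <- a; m},
            gr$adapter[[as.character(l)]][[nm]], 3)
    }
  }
})

test_that("overlong and malformed messages are rejected", {
  model <- tiny_model()
  expect_error(conditional_log_likelihood(
    model, scored_message(rep(5L, 11), c(0, 0))), "exceeds")
  expect_error(conditional_log_likelihood(
    model, scored_message(c(5L, model$model_cfg$sos_id), c(0, 0))),
    "special tokens")
  expect_error(conditional_log_likelihood(
    model, scored_message(c(5L, 99L), c(0, 0))), "vocabulary")
})

test_that("generation is deterministic, respects max_new_tokens, and greedy is argmax", {
  model <- tiny_model(adapter_init_scale = 0.2)
  req0 <- generation_request(c(1, -1), prompt_ids = c(5L, 6L),
                             max_new_tokens = 0, seed = 2)
  expect_equal(generate_text(model, req0)$ids, c(5L, 6L))
  req <- generation_request(c(1, -1), max_new_tokens = 10, seed = 9)
  g1 <- generate_text(model, req)
  g2 <- generate_text(model, req)
  expect_identical(g1$ids, g2$ids)
  cfg <- model$model_cfg
  expect_false(any(g1$ids %in% c(cfg$sos_id, cfg$eos_id, cfg$pad_id)))

  # greedy trace: every emitted token maximizes the step distribution as
  # recovered independently through conditional_log_likelihood
  prompt <- 5L
  gg <- generate_text(model, generation_request(
    c(1, -1), prompt_ids = prompt, max_new_tokens = 4,
    policy = sampling_policy("greedy"), seed = 1))
  body <- gg$ids
  candidates <- setdiff(seq_len(cfg$vocab_size),
                        c(cfg$sos_id, cfg$pad_id, cfg$eos_id))
  step_logp <- function(prefix_body, w) {
    cl <- conditional_log_likelihood(model,
                                     scored_message(c(prefix_body, w), c(1, -1)))
    cl$log_probs[length(prefix_body) + 1]
  }
  eos_logp <- function(prefix_body) {
    cl <- conditional_log_likelihood(model,
                                     scored_message(prefix_body, c(1, -1)))
    cl$log_probs[length(prefix_body) + 1]
  }
  n_new <- length(body) - length(prompt)
  for (step in seq_len(n_new)) {
    prefix <- body[seq_len(length(prompt) + step - 1)]
    chosen <- body[length(prompt) + step]
    lp <- vapply(candidates, function(w) step_logp(prefix, w), numeric(1))
    best <- c(stats::setNames(lp, candidates), eos = eos_logp(prefix))
    expect_equal(chosen, candidates[which.max(lp)])
    expect_gte(max(lp), best["eos"] - 1e-12)
  }
  if (n_new < 4) {
    # generation stopped early, so EOS must have been the argmax there
    prefix <- body
    lp <- vapply(candidates, function(w) step_logp(prefix, w), numeric(1))
    expect_gt(eos_logp(prefix), max(lp))
  }
})
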