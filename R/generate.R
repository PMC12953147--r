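# special token strings; ids fixed by their position in the built vocab
.special_tokens <- c("[PAD]", "[SOS]", "[EOS]", "[UNK]")

#' Build a model vocabulary from a word list
#'
#' Prepends the four special tokens (`[PAD]`, `[SOS]`, `[EOS]`, `[UNK]` at
#' ids 1..4) to the supplied words.
#'
#' @param words Character vector of word types.
#' @return Character vocabulary for [model_config()]'s `vocab_size`.
#' @export
build_vocab <- function(words) {
  words <- as.character(words)
  if (anyDuplicated(words)) stop("duplicate words in vocabulary", call. = FALSE)
  if (any(words %in% .special_tokens)) {
    stop("word list must not contain the reserved special tokens",
         call. = FALSE)
  }
  c(.special_tokens, words)
}

#' Encode tokens to ids
#'
#' @param tokens Character vector of tokens.
#' @param vocab Vocabulary from [build_vocab()].
#' @param unk_id Id substituted for out-of-vocabulary tokens (default 4).
#' @return Integer vector of 1-based ids.
#' @export
encode_tokens <- function(tokens, vocab, unk_id = 4L) {
  ids <- match(as.character(tokens), vocab)
  ids[is.na(ids)] <- as.integer(unk_id)
  ids
}

#' Decode ids to tokens
#'
#' @param ids Integer vector of 1-based ids.
#' @param vocab Vocabulary from [build_vocab()].
#' @return Character vector of tokens.
#' @export
decode_tokens <- function(ids, vocab) vocab[as.integer(ids)]

#' Sampling policy
#'
#' @param method One of `"greedy"`, `"temperature"`, `"top_k"`, `"nucleus"`.
#' @param temperature Softmax temperature (> 0), used by all stochastic
#'   methods (default 1).
#' @param k Top-k cutoff for `top_k` (default 40).
#' @param p Cumulative-probability cutoff for `nucleus` (default 0.9).
#' @return Object of class `sampling_policy`.
#' @export
sampling_policy <- function(method = c("top_k", "greedy", "temperature",
                                       "nucleus"),
                            temperature = 1.0, k = 40L, p = 0.9) {
  method <- match.arg(method)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (p <= 0 || p > 1) stop("p must be in (0, 1]", call. = FALSE)
  structure(list(method = method, temperature = temperature,
                 k = as.integer(k), p = p),
            class = "sampling_policy")
}

#' Generation request
#'
#' @param profile A [trait_profile()] or numeric score vector conditioning
#'   the generation.
#' @param prompt_ids Integer vector of prompt token ids (possibly empty).
#' @param max_new_tokens Maximum number of tokens to generate (>= 0).
#' @param policy A [sampling_policy()].
#' @param seed Integer seed; the same request with the same seed always
#'   yields the same output.
#' @return Object of class `generation_request`.
#' @export
generation_request <- function(profile, prompt_ids = integer(0),
                               max_new_tokens = 20L,
                               policy = sampling_policy(), seed = 1) {
  if (max_new_tokens < 0) stop("max_new_tokens must be >= 0", call. = FALSE)
  stopifnot(inherits(policy, "sampling_policy"))
  structure(list(profile = profile,
                 prompt_ids = as.integer(prompt_ids),
                 max_new_tokens = as.integer(max_new_tokens),
                 policy = policy, seed = seed),
            class = "generation_request")
}

# draw one token id from a logits vector under a sampling policy
.sample_token <- function(logits, policy) {
  if (policy$method == "greedy") return(which.max(logits))
  z <- logits / policy$temperature
  z <- z - max(z)
  pr <- exp(z); pr <- pr / sum(pr)
  if (policy$method == "top_k") {
    keep <- order(pr, decreasing = TRUE)[seq_len(min(policy$k, length(pr)))]
    sub <- pr[keep] / sum(pr[keep])
    keep[sample.int(length(keep), 1L, prob = sub)]
  } else if (policy$method == "nucleus") {
    ordx <- order(pr, decreasing = TRUE)
    cum <- cumsum(pr[ordx])
    n_keep <- which(cum >= policy$p)[1]
    keep <- ordx[seq_len(n_keep)]
    sub <- pr[keep] / sum(pr[keep])
    keep[sample.int(length(keep), 1L, prob = sub)]
  } else {
    sample.int(length(pr), 1L, prob = pr)
  }
}

#' Generate text conditioned on a trait profile
#'
#' Autoregressive sampling from the adapter model: the sequence starts as
#' `[SOS]` + prompt and grows token by token, conditioned at every layer on
#' the injected trait states, until `[EOS]` is drawn or `max_new_tokens` is
#' reached. `[EOS]` terminates generation and never appears in the returned
#' body. Deterministic for a fixed request seed.
#'
#' @param checkpoint An `lm_checkpoint` from [train_adapter()] or a bare
#'   [adapter_lm()].
#' @param request A [generation_request()].
#' @return List with `ids` (prompt + continuation, no special tokens) and
#'   `tokens` (decoded strings).
#' @export
generate_text <- function(checkpoint, request) {
  stopifnot(inherits(request, "generation_request"))
  model <- if (inherits(checkpoint, "lm_checkpoint")) checkpoint$model
           else checkpoint
  stopifnot(inherits(model, "adapter_lm"))
  cfg <- model$model_cfg
  if (length(request$prompt_ids) > 0 &&
      any(request$prompt_ids < 1L | request$prompt_ids > cfg$vocab_size)) {
    stop("prompt token id outside the vocabulary", call. = FALSE)
  }
  scores <- if (inherits(request$profile, "trait_profile")) {
    request$profile$scores
  } else {
    as.numeric(request$profile)
  }
  seq_ids <- c(cfg$sos_id, request$prompt_ids)
  .with_seed(request$seed, {
    for (i in seq_len(request$max_new_tokens)) {
      if (length(seq_ids) >= cfg$max_seq_len) break
      fw <- .forward(model, seq_ids, scores)
      logits <- fw$logits[nrow(fw$logits), ]
      # never emit structural tokens mid-body
      logits[c(cfg$pad_id, cfg$sos_id)] <- -Inf
      nxt <- .sample_token(logits, request$policy)
      if (nxt == cfg$eos_id) break
      seq_ids <- c(seq_ids, nxt)
    }
  })
  body <- seq_ids[-1L]
  list(ids = body, tokens = decode_tokens(body, model$vocab))
}
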