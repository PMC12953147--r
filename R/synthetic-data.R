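# run expr with a temporary RNG seed, restoring any prior RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# derive a stream-specific sub-seed, kept within 32-bit integer range
.sub_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483629
}

#' Configuration for the synthetic trait-conditioned corpus
#'
#' The simulator emulates the statistical structure of a message corpus whose
#' authors carry latent continuous trait scores: each author has a trait
#' profile psi drawn i.i.d. standard normal per dimension, and each of their
#' messages draws tokens i.i.d. from a log-linear (softmax) vocabulary
#' distribution in which designated "marker" tokens have log-odds shifted by
#' `+beta * psi_i` (high-pole markers) or `-beta * psi_i` (low-pole markers)
#' for their trait dimension.
#'
#' @param t Number of trait dimensions (>= 1).
#' @param vocab_size Base vocabulary size (words; special tokens are added by
#'   the tokenizer later). Must be at least `2 * t * markers_per_trait + 10`.
#' @param markers_per_trait Marker tokens per trait pole (default 5).
#' @param beta Marker effect size: log-odds slope per SD of the trait
#'   (default 1.0).
#' @param message_length_range Integer range of message lengths, inclusive
#'   (default `c(8, 16)`, matching short social-media messages).
#' @param n_participants Number of authors (default 200).
#' @param messages_per_participant Messages per author (default 10).
#' @param seed Integer seed controlling the whole corpus (default 1).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(t = 2, vocab_size = 60, markers_per_trait = 5,
                             beta = 1.0, message_length_range = c(8L, 16L),
                             n_participants = 200,
                             messages_per_participant = 10, seed = 1) {
  t <- as.integer(t)
  if (is.na(t) || t < 1L) {
    stop("t must be a positive integer (got a degenerate trait count)",
         call. = FALSE)
  }
  vocab_size <- as.integer(vocab_size)
  markers_per_trait <- as.integer(markers_per_trait)
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  if (vocab_size < 2L * t * markers_per_trait + 10L) {
    stop("vocab_size must be at least 2*t*markers_per_trait + 10",
         call. = FALSE)
  }
  message_length_range <- as.integer(message_length_range)
  if (length(message_length_range) != 2L ||
      any(message_length_range < 1L) ||
      message_length_range[1] > message_length_range[2]) {
    stop("message_length_range must be an increasing positive integer pair",
         call. = FALSE)
  }
  structure(list(t = t, vocab_size = vocab_size,
                 markers_per_trait = markers_per_trait, beta = beta,
                 message_length_range = message_length_range,
                 n_participants = as.integer(n_participants),
                 messages_per_participant = as.integer(messages_per_participant),
                 seed = seed),
            class = "synthetic_config")
}

#' Base vocabulary of a synthetic configuration
#'
#' @param config A [synthetic_config()].
#' @return Character vector of word-like tokens (`w001`, `w002`, ...).
#' @export
synthetic_vocabulary <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sprintf("w%03d", seq_len(config$vocab_size))
}

#' Marker-token table of a synthetic configuration
#'
#' Lists which vocabulary tokens are high- and low-pole markers for each
#' trait dimension. The first `2 * markers_per_trait` words of each trait's
#' block are its markers (high pole first).
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `token`, `trait_index` (0-based) and
#'   `pole` (`"high"`/`"low"`).
#' @export
marker_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  vocab <- synthetic_vocabulary(config)
  m <- config$markers_per_trait
  rows <- lapply(seq_len(config$t), function(i) {
    base <- (i - 1L) * 2L * m
    data.frame(token = vocab[base + seq_len(2L * m)],
               trait_index = i - 1L,
               pole = rep(c("high", "low"), each = m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# t x vocab matrix of log-odds slopes beta_{i,w}
.marker_slopes <- function(config) {
  B <- matrix(0, config$t, config$vocab_size)
  mt <- marker_table(config)
  vocab <- synthetic_vocabulary(config)
  idx <- match(mt$token, vocab)
  B[cbind(mt$trait_index + 1L, idx)] <-
    ifelse(mt$pole == "high", config$beta, -config$beta)
  B
}

#' Token sampling distribution for a trait profile
#'
#' The exact softmax vocabulary distribution
#' \eqn{p(w) \propto \exp(\sum_i \psi_i \beta_{i,w})} used by the simulator,
#' computable in closed form for oracle checks.
#'
#' @param config A [synthetic_config()].
#' @param scores Numeric trait-score vector of length `config$t`.
#' @return Named numeric probability vector over the base vocabulary.
#' @export
token_probabilities <- function(config, scores) {
  stopifnot(inherits(config, "synthetic_config"))
  scores <- as.numeric(scores)
  if (length(scores) != config$t) {
    stop("scores length must equal config$t", call. = FALSE)
  }
  logits <- as.numeric(t(.marker_slopes(config)) %*% scores)
  logits <- logits - max(logits)
  p <- exp(logits)
  p <- p / sum(p)
  names(p) <- synthetic_vocabulary(config)
  p
}

#' Sample one synthetic message
#'
#' Draws a message length uniformly from `message_length_range` and its
#' tokens i.i.d. from the author's softmax vocabulary distribution.
#'
#' @param scores Numeric trait-score vector of length `config$t` (the
#'   author's psi).
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed for this draw; if `NULL`, the current
#'   RNG stream is used.
#' @return Character vector of tokens.
#' @export
sample_message <- function(scores, config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- token_probabilities(config, scores)
  draw <- function() {
    len <- sample(seq(config$message_length_range[1],
                      config$message_length_range[2]), 1L)
    sample(names(p), len, replace = TRUE, prob = p)
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Sample a synthetic participant population with messages
#'
#' Draws each participant's trait profile i.i.d. standard normal per
#' dimension, then samples their messages from the trait-coupled vocabulary
#' model. Fully deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List of [participant_record()]s; each record's `trait_scores` are
#'   the true standardized psi.
#' @export
sample_participants <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(config$seed, {
    lapply(seq_len(config$n_participants), function(pi) {
      psi <- stats::rnorm(config$t)
      msgs <- lapply(seq_len(config$messages_per_participant),
                     function(mi) sample_message(psi, config))
      participant_record(sprintf("p%04d", pi), msgs, psi)
    })
  })
}

#' Materialize a synthetic fixture on disk
#'
#' Samples a population, converts it to corpus records, splits it into a
#' training and a held-out partition (the last `holdout_per_participant`
#' messages of each author are held out), and writes `train.jsonl`,
#' `holdout.jsonl` and a `truth.csv` table of each participant's true psi.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @param holdout_per_participant Messages per author held out (default 1).
#' @return List with `train`, `holdout` (lists of corpus records), `truth`
#'   (data frame), and `paths`.
#' @export
make_fixture <- function(config, dir, holdout_per_participant = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (holdout_per_participant >= config$messages_per_participant) {
    stop("holdout_per_participant must leave at least one training message",
         call. = FALSE)
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", dir, call. = FALSE)
  }
  participants <- sample_participants(config)
  train <- list(); holdout <- list()
  for (p in participants) {
    nm <- length(p$messages)
    cut <- nm - holdout_per_participant
    for (mi in seq_len(nm)) {
      rec <- list(message_id = sprintf("%s_m%03d", p$participant_id, mi),
                  participant_id = p$participant_id,
                  text = paste(p$messages[[mi]], collapse = " "),
                  tokens = p$messages[[mi]],
                  scores_raw = p$trait_scores,
                  scores_std = p$trait_scores)
      if (mi <= cut) train[[length(train) + 1L]] <- rec
      else holdout[[length(holdout) + 1L]] <- rec
    }
  }
  truth <- data.frame(participant_id = vapply(participants,
                                              `[[`, character(1),
                                              "participant_id"),
                      stringsAsFactors = FALSE)
  psi <- t(vapply(participants, `[[`, numeric(config$t), "trait_scores"))
  colnames(psi) <- sprintf("psi_%d", seq_len(config$t))
  truth <- cbind(truth, as.data.frame(psi))
  paths <- list(train = file.path(dir, "train.jsonl"),
                holdout = file.path(dir, "holdout.jsonl"),
                truth = file.path(dir, "truth.csv"))
  write_corpus(train, paths$train)
  write_corpus(holdout, paths$holdout)
  utils::write.csv(truth, paths$truth, row.names = FALSE)
  list(train = train, holdout = holdout, truth = truth, paths = paths)
}
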