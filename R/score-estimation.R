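#' Extract a feature vector from a token sequence
#'
#' Maps a tokenized message onto a fixed feature vocabulary, either as
#' relative word frequencies (counts over the vocabulary normalized to sum to
#' 1) or as topic loadings (the average of per-token topic-loading rows).
#' Out-of-vocabulary tokens are ignored; a message with no in-vocabulary
#' token yields an all-zero vector flagged via the `"empty"` attribute.
#'
#' @param tokens Character vector of tokens.
#' @param vocabulary Ordered character vector of feature labels (words).
#' @param mode Either `"relative_frequency"` (default) or `"topic_loading"`.
#' @param topic_loadings For `topic_loading` mode: a numeric matrix with one
#'   row per vocabulary word (rownames = vocabulary) and one column per
#'   topic; the feature vector is the mean of the rows of the in-vocabulary
#'   tokens.
#' @return Numeric feature vector (length `length(vocabulary)` in
#'   relative-frequency mode, `ncol(topic_loadings)` in topic mode), with
#'   attributes `empty` (logical) and `n_in_vocab` (count used).
#' @examples
#' extract_features(c("a", "b", "a"), c("a", "b"))
#' @export
extract_features <- function(tokens, vocabulary,
                             mode = c("relative_frequency", "topic_loading"),
                             topic_loadings = NULL) {
  mode <- match.arg(mode)
  if (length(vocabulary) == 0L) {
    stop("feature vocabulary must be non-empty", call. = FALSE)
  }
  vocabulary <- as.character(vocabulary)
  tokens <- as.character(tokens)
  idx <- match(tokens, vocabulary)
  idx <- idx[!is.na(idx)]
  if (mode == "relative_frequency") {
    counts <- tabulate(idx, nbins = length(vocabulary))
    total <- sum(counts)
    out <- if (total > 0) counts / total else numeric(length(vocabulary))
    names(out) <- vocabulary
  } else {
    if (is.null(topic_loadings)) {
      stop("topic_loading mode requires a topic_loadings matrix",
           call. = FALSE)
    }
    topic_loadings <- as.matrix(topic_loadings)
    if (nrow(topic_loadings) != length(vocabulary)) {
      stop("topic_loadings must have one row per vocabulary word",
           call. = FALSE)
    }
    if (length(idx) > 0) {
      out <- colMeans(topic_loadings[idx, , drop = FALSE])
    } else {
      out <- numeric(ncol(topic_loadings))
    }
  }
  attr(out, "empty") <- length(idx) == 0L
  attr(out, "n_in_vocab") <- length(idx)
  out
}

#' A participant record
#'
#' One training unit for the participant-level trait estimator: a
#' participant id, their collection of tokenized messages, and their raw
#' trait scores.
#'
#' @param participant_id Scalar identifier.
#' @param messages List of character token vectors (at least one).
#' @param trait_scores Numeric vector of raw trait scores, length t.
#' @return An object of class `participant_record`.
#' @export
participant_record <- function(participant_id, messages, trait_scores) {
  if (!is.list(messages) || length(messages) < 1L) {
    stop("a participant needs at least one message", call. = FALSE)
  }
  trait_scores <- as.numeric(trait_scores)
  if (!all(is.finite(trait_scores))) {
    stop("trait scores must be finite", call. = FALSE)
  }
  structure(list(participant_id = participant_id,
                 messages = messages,
                 trait_scores = trait_scores),
            class = "participant_record")
}

#' Fit the participant-level linear trait estimator
#'
#' Fits, for each trait dimension i, a ridge-penalized least-squares row
#' vector W_i mapping a participant's pooled word-frequency vector to that
#' participant's raw trait score:
#' \deqn{W_i = \arg\min_W \sum_p (\psi_{p,i} - W X_p)^2 + \lambda \|W\|^2.}
#' Participant features pool all the participant's messages into one
#' relative-frequency vector. With `lambda = 0` and a rank-deficient design
#' the minimum-norm solution is returned with a singular-fit warning.
#'
#' @param records List of [participant_record()]s.
#' @param spec A [trait_spec()]; `spec$t` must match the score length.
#' @param vocabulary Ordered character feature vocabulary.
#' @param lambda Ridge penalty, >= 0. Default `1e-3`.
#' @return An object of class `trait_estimator`: fields `W` (t x d matrix,
#'   rows named by trait), `lambda`, `vocabulary`, `spec`.
#' @export
fit_participant_estimator <- function(records, spec, vocabulary,
                                      lambda = 1e-3) {
  stopifnot(inherits(spec, "trait_spec"))
  if (length(records) < 1L) stop("need at least one participant", call. = FALSE)
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    stop("lambda must be a single non-negative number", call. = FALSE)
  }
  d <- length(vocabulary)
  if (d == 0L) stop("feature vocabulary must be non-empty", call. = FALSE)
  X <- do.call(rbind, lapply(records, function(r) {
    as.numeric(extract_features(unlist(r$messages), vocabulary))
  }))
  psi <- do.call(rbind, lapply(records, function(r) {
    if (length(r$trait_scores) != spec$t) {
      stop("participant score length does not match the trait space",
           call. = FALSE)
    }
    r$trait_scores
  }))
  if (lambda > 0) {
    A <- crossprod(X) + diag(lambda, d)
    W <- t(solve(A, crossprod(X, psi)))
  } else {
    qrX <- qr(X)
    if (qrX$rank < d) {
      warning("singular fit (rank-deficient design with lambda = 0); ",
              "returning the minimum-norm solution", call. = FALSE)
      W <- t(MASS::ginv(X) %*% psi)
    } else {
      W <- t(solve(crossprod(X), crossprod(X, psi)))
    }
  }
  dimnames(W) <- list(spec$names, vocabulary)
  structure(list(W = W, lambda = lambda, vocabulary = vocabulary,
                 spec = spec),
            class = "trait_estimator")
}

#' @export
print.trait_estimator <- function(x, ...) {
  cat(sprintf("Linear trait estimator: %d trait(s) x %d feature(s), lambda = %g\n",
              nrow(x$W), ncol(x$W), x$lambda))
  invisible(x)
}

#' Score a single message with a fitted estimator
#'
#' Applies the participant-level matrices at message level: entry i of the
#' result is the inner product of W_i with the message's feature vector.
#'
#' @param estimator A [fit_participant_estimator()] result.
#' @param features Numeric feature vector over the estimator's vocabulary.
#' @return Numeric raw trait-score vector of length t.
#' @export
score_message <- function(estimator, features) {
  stopifnot(inherits(estimator, "trait_estimator"))
  features <- as.numeric(features)
  if (length(features) != ncol(estimator$W)) {
    stop(sprintf("feature vector length %d does not match estimator width %d",
                 length(features), ncol(estimator$W)), call. = FALSE)
  }
  as.numeric(estimator$W %*% features)
}

#' Score and standardize a whole corpus of messages
#'
#' Assigns every message an estimated raw trait vector via [score_message()],
#' then standardizes each dimension to mean 0 / SD 1 across the corpus. The
#' standardization constants are attached to the result so that
#' generation-time input vectors (e.g. `(0, 0, +3, 0, 0)`) refer to the same
#' scale the model was trained on. Messages with no in-vocabulary token
#' receive the corpus-mean estimated score and are flagged.
#'
#' @param estimator A [fit_participant_estimator()] result.
#' @param messages List of character token vectors.
#' @param spec A [trait_spec()].
#' @return An object of class `scored_corpus`: list with `scores_raw`
#'   (n x t matrix), `scores_std` (n x t, per-dimension mean 0 / SD 1),
#'   `flagged_empty` (logical vector), and `standardization`
#'   (list of `mean` and `sd` per dimension).
#' @export
score_corpus <- function(estimator, messages, spec) {
  stopifnot(inherits(estimator, "trait_estimator"), inherits(spec, "trait_spec"))
  n <- length(messages)
  if (n < 1L) stop("corpus must be non-empty", call. = FALSE)
  t_dim <- nrow(estimator$W)
  if (t_dim != spec$t) {
    stop("estimator and trait space disagree on dimension count",
         call. = FALSE)
  }
  raw <- matrix(NA_real_, n, t_dim)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    f <- extract_features(messages[[i]], estimator$vocabulary)
    flagged[i] <- isTRUE(attr(f, "empty"))
    raw[i, ] <- score_message(estimator, f)
  }
  if (any(flagged)) {
    if (all(flagged)) {
      stop("every message is out of vocabulary; cannot score corpus",
           call. = FALSE)
    }
    mean_ok <- colMeans(raw[!flagged, , drop = FALSE])
    raw[flagged, ] <- matrix(mean_ok, sum(flagged), t_dim, byrow = TRUE)
  }
  mu <- colMeans(raw)
  # population SD so that a two-point corpus standardizes to exactly (-1, +1)
  sdv <- sqrt(colMeans(sweep(raw, 2, mu)^2))
  if (any(sdv < 1e-12)) {
    bad <- spec$names[sdv < 1e-12]
    stop("zero variance in estimated scores for dimension(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  std <- sweep(sweep(raw, 2, mu), 2, sdv, "/")
  colnames(raw) <- colnames(std) <- spec$names
  structure(list(scores_raw = raw, scores_std = std,
                 flagged_empty = flagged,
                 standardization = list(mean = stats::setNames(mu, spec$names),
                                        sd = stats::setNames(sdv, spec$names))),
            class = "scored_corpus")
}

#' @export
print.scored_corpus <- function(x, ...) {
  cat(sprintf("Scored corpus: %d message(s), %d trait dimension(s), %d flagged empty\n",
              nrow(x$scores_std), ncol(x$scores_std), sum(x$flagged_empty)))
  invisible(x)
}
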