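# Glue between the corpus dialect and the typed module inputs.

#' Group corpus records into participant records
#'
#' Collects the messages of each `participant_id` and takes the participant
#' trait scores from the records' `scores_raw` field (which is constant
#' within a participant for participant-labelled corpora).
#'
#' @param records List of corpus records (see [read_corpus()]) carrying
#'   `participant_id`, `tokens` and `scores_raw`.
#' @return List of [participant_record()]s.
#' @export
records_to_participants <- function(records) {
  pid <- vapply(records, function(r) as.character(r$participant_id %||% NA),
                character(1))
  if (anyNA(pid)) {
    stop("all records need a participant_id to form participant records",
         call. = FALSE)
  }
  lapply(split(seq_along(records), pid), function(ix) {
    msgs <- lapply(records[ix], function(r) as.character(r$tokens))
    scores <- as.numeric(records[[ix[1]]]$scores_raw)
    participant_record(pid[ix[1]], msgs, scores)
  })
}

#' Build a trainable corpus of scored messages
#'
#' Encodes each record's tokens against the model vocabulary and pairs them
#' with standardized trait scores — either the per-message columns of a
#' [score_corpus()] result (the estimated-score route) or the records' own
#' `scores_std` field (ground-truth route). The standardization constants,
#' when available, travel along as an attribute so the trained checkpoint
#' can record the score scale.
#'
#' @param records List of corpus records with `tokens`.
#' @param vocab Model vocabulary from [build_vocab()].
#' @param scored Optional `scored_corpus` aligned with `records`.
#' @return List of [scored_message()]s with attribute `standardization`.
#' @export
prepare_training_corpus <- function(records, vocab, scored = NULL) {
  n <- length(records)
  if (!is.null(scored)) {
    stopifnot(inherits(scored, "scored_corpus"))
    if (nrow(scored$scores_std) != n) {
      stop("scored corpus is not aligned with the records", call. = FALSE)
    }
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- if (!is.null(scored)) scored$scores_std[i, ]
          else as.numeric(records[[i]]$scores_std)
    if (length(sc) == 0 || anyNA(sc)) {
      stop("record ", i, " has no standardized scores", call. = FALSE)
    }
    out[[i]] <- scored_message(encode_tokens(records[[i]]$tokens, vocab), sc)
  }
  if (!is.null(scored)) {
    attr(out, "standardization") <- scored$standardization
  }
  out
}
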