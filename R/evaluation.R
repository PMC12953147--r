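#' Construct a matching trial
#'
#' One blinded evaluation instance: per level, a group of generated samples;
#' groups are stored in presentation order, and `true_assignment[q]` records
#' which level (index into `levels`) the group presented at slot `q` was
#' actually generated from.
#'
#' @param trait_index 0-based trait dimension under evaluation.
#' @param levels Numeric vector of distinct level values (e.g.
#'   `c(-3, 0, 3)`).
#' @param groups List (presentation order) of groups; each group is a list
#'   of generated token-string vectors. All groups must be the same size.
#' @param true_assignment Integer permutation: presented slot -> level index.
#' @param seed Seed the trial was generated with.
#' @return Object of class `matching_trial`.
#' @export
matching_trial <- function(trait_index, levels, groups, true_assignment,
                           seed = NA) {
  levels <- as.numeric(levels)
  m <- length(levels)
  if (m < 2L || anyDuplicated(levels)) {
    stop("need at least 2 distinct levels", call. = FALSE)
  }
  if (length(groups) != m) {
    stop("one group per level required", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (length(unique(sizes)) != 1L) {
    stop("all groups must have the same size", call. = FALSE)
  }
  true_assignment <- as.integer(true_assignment)
  if (!identical(sort(true_assignment), seq_len(m))) {
    stop("true_assignment must be a permutation of the level indices",
         call. = FALSE)
  }
  structure(list(trait_index = as.integer(trait_index), levels = levels,
                 groups = groups, true_assignment = true_assignment,
                 seed = seed),
            class = "matching_trial")
}

#' Generate blinded matching trials from a trained checkpoint
#'
#' For each trial, generates a group of samples per level by conditioning
#' the model on the focal input vector (level `k` on `trait_index`, 0
#' elsewhere), then shuffles the presentation order deterministically from
#' the trial seed.
#'
#' @param checkpoint `lm_checkpoint` from [train_adapter()] (must carry at
#'   least one training epoch) or an [adapter_lm()].
#' @param trait_index 0-based trait dimension.
#' @param levels Numeric vector of distinct levels (default `c(-3, 0, 3)`).
#' @param samples_per_group Samples per level per trial (default 5).
#' @param n_trials Number of independently seeded trials (default 10).
#' @param base_seed Base seed; every generation and shuffle derives from it.
#' @param prompt_ids Optional prompt token ids prepended to each generation.
#' @param max_new_tokens Tokens generated per sample (default 16).
#' @param policy A [sampling_policy()].
#' @return List of [matching_trial()]s.
#' @export
build_trials <- function(checkpoint, trait_index, levels = c(-3, 0, 3),
                         samples_per_group = 5L, n_trials = 10L,
                         base_seed = 1, prompt_ids = integer(0),
                         max_new_tokens = 16L, policy = sampling_policy()) {
  if (inherits(checkpoint, "lm_checkpoint")) {
    if (length(checkpoint$epoch_loss) < 2L) {
      stop("checkpoint has not been trained", call. = FALSE)
    }
    model <- checkpoint$model
  } else {
    model <- checkpoint
  }
  stopifnot(inherits(model, "adapter_lm"))
  levels <- as.numeric(levels)
  m <- length(levels)
  if (m < 2L || anyDuplicated(levels)) {
    stop("need at least 2 distinct levels", call. = FALSE)
  }
  t_dim <- model$adapter_cfg$latent_size
  if (trait_index < 0 || trait_index >= t_dim) {
    stop("trait_index out of range for this adapter", call. = FALSE)
  }
  spec <- trait_spec(sprintf("dim%d", seq_len(t_dim)))
  lapply(seq_len(n_trials), function(tr) {
    trial_seed <- .sub_seed(base_seed, tr)
    by_level <- lapply(seq_len(m), function(e) {
      profile <- build_input_vector(spec, trait_index, levels[e])
      lapply(seq_len(samples_per_group), function(s) {
        req <- generation_request(
          profile, prompt_ids = prompt_ids,
          max_new_tokens = max_new_tokens, policy = policy,
          seed = .sub_seed(trial_seed, e * 1000L + s))
        generate_text(model, req)$tokens
      })
    })
    perm <- .with_seed(.sub_seed(trial_seed, 999983L), sample.int(m))
    # presented slot q shows the group generated at level perm[q]
    matching_trial(trait_index, levels,
                   groups = by_level[perm],
                   true_assignment = perm, seed = trial_seed)
  })
}

#' Score a rater's assignment on a matching trial
#'
#' The rater's assignment must be a bijection from presented slots to level
#' labels. The score is the fixed-point fraction: with 3 levels this yields
#' 1 point for all correct, 1/3 for exactly one correct, and 0 otherwise
#' (two correct is impossible for a bijection on three elements).
#'
#' @param assignment Integer vector: presented slot -> level index
#'   (a permutation of `seq_along(trial$levels)`).
#' @param trial A [matching_trial()].
#' @return Points in \eqn{[0, 1]}.
#' @export
score_matching <- function(assignment, trial) {
  stopifnot(inherits(trial, "matching_trial"))
  assignment <- as.integer(assignment)
  m <- length(trial$levels)
  if (!identical(sort(assignment), seq_len(m))) {
    stop("assignment must be a bijection over the level set", call. = FALSE)
  }
  mean(assignment == trial$true_assignment)
}

#' Chance baseline of the level-matching task
#'
#' Expected points of a uniformly random bijective rater: the expected
#' fixed-point fraction of a uniform random permutation of m elements,
#' which is exactly 1/m (a permutation has 1 fixed point in expectation).
#' For 3 levels this is the 33.33% chance baseline.
#'
#' @param m Number of levels (>= 2).
#' @return Expected points, `1/m`.
#' @export
chance_baseline <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 2L) stop("m must be an integer >= 2", call. = FALSE)
  1 / m
}

# net marker score of a group of generated samples for one trait:
# mean relative frequency of high-pole markers minus low-pole markers
.net_marker_score <- function(group, marker_tbl, trait_index) {
  rows <- marker_tbl[marker_tbl$trait_index == trait_index, ]
  high <- rows$token[rows$pole == "high"]
  low <- rows$token[rows$pole == "low"]
  toks <- unlist(group)
  if (length(toks) == 0) return(0)
  (sum(toks %in% high) - sum(toks %in% low)) / length(toks)
}

#' Programmatic oracle rater for synthetic-vocabulary trials
#'
#' Ranks the presented groups by their mean net marker score for the
#' trial's trait (high-pole minus low-pole marker frequency) and assigns
#' level labels in rank order: the group with the lowest net score gets the
#' lowest level, and so on. Ties are broken by presentation order.
#'
#' @param trial A [matching_trial()] whose generations use the synthetic
#'   vocabulary.
#' @param marker_tbl A [marker_table()] for the generating configuration.
#' @return Integer assignment vector (presented slot -> level index),
#'   usable with [score_matching()].
#' @export
oracle_rater <- function(trial, marker_tbl) {
  stopifnot(inherits(trial, "matching_trial"))
  net <- vapply(trial$groups, .net_marker_score, numeric(1),
                marker_tbl = marker_tbl, trait_index = trial$trait_index)
  r <- rank(net, ties.method = "first")
  level_order <- order(trial$levels)
  assignment <- level_order[r]
  as.integer(assignment)
}

#' Weighted Cohen's kappa for ordinal ratings
#'
#' Chance-corrected agreement between two raters over an ordered level set:
#' \deqn{\kappa_w = 1 - \frac{\sum_{ij} w_{ij} O_{ij}}{\sum_{ij} w_{ij} E_{ij}}}
#' with observed counts O, expected counts E from the marginals, and
#' disagreement weights `w_ij = |i-j|/(m-1)` (linear, default) or its square
#' (quadratic).
#'
#' @param ratings_a,ratings_b Equal-length vectors of ordinal labels.
#' @param levels Ordered level set; defaults to the sorted union of the
#'   observed labels.
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @return Kappa in \eqn{[-1, 1]}, or `NA` (with a warning) when undefined
#'   (empty input, or a single category used by both raters).
#' @export
weighted_kappa <- function(ratings_a, ratings_b, levels = NULL,
                           weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating vectors must have equal length", call. = FALSE)
  }
  if (length(ratings_a) == 0L) {
    warning("kappa undefined on empty input", call. = FALSE)
    return(NA_real_)
  }
  if (is.null(levels)) levels <- sort(unique(c(ratings_a, ratings_b)))
  a <- factor(ratings_a, levels = levels)
  b <- factor(ratings_b, levels = levels)
  if (anyNA(a) || anyNA(b)) {
    stop("ratings contain labels outside the level set", call. = FALSE)
  }
  m <- length(levels)
  if (m < 2L) {
    warning("kappa undefined: both raters used a single category",
            call. = FALSE)
    return(NA_real_)
  }
  O <- table(a, b)
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  w <- abs(outer(seq_len(m), seq_len(m), "-")) / (m - 1)
  if (weights == "quadratic") w <- w^2
  denom <- sum(w * E)
  if (denom < .Machine$double.eps) {
    warning("kappa undefined: both raters used a single category",
            call. = FALSE)
    return(NA_real_)
  }
  1 - sum(w * O) / denom
}

#' Run a full oracle-rated level-matching evaluation
#'
#' Builds `n_trials` blinded trials per requested trait, rates each with the
#' [oracle_rater()], and returns (optionally writes) the per-trial report.
#'
#' @param checkpoint `lm_checkpoint` or [adapter_lm()].
#' @param marker_tbl A [marker_table()].
#' @param trait_indices Integer vector of 0-based trait dimensions.
#' @param levels,samples_per_group,n_trials,base_seed,prompt_ids,max_new_tokens,policy
#'   Passed to [build_trials()].
#' @param out_csv Optional path; when given the report is written as CSV.
#' @return Data frame with columns `trial`, `trait_index`, `levels`,
#'   `points`, `rater`; the mean points per trait are attached as attribute
#'   `summary`.
#' @export
run_level_matching <- function(checkpoint, marker_tbl, trait_indices = 0L,
                               levels = c(-3, 0, 3), samples_per_group = 5L,
                               n_trials = 10L, base_seed = 1,
                               prompt_ids = integer(0), max_new_tokens = 16L,
                               policy = sampling_policy(),
                               out_csv = NULL) {
  rows <- list()
  for (ti in trait_indices) {
    trials <- build_trials(checkpoint, ti, levels, samples_per_group,
                           n_trials, .sub_seed(base_seed, ti + 1L),
                           prompt_ids, max_new_tokens, policy)
    for (j in seq_along(trials)) {
      pts <- score_matching(oracle_rater(trials[[j]], marker_tbl),
                            trials[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        trial = j, trait_index = ti,
        levels = paste(levels, collapse = "/"),
        points = pts, rater = "oracle", stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  summ <- stats::aggregate(points ~ trait_index, data = report, FUN = mean)
  summ$chance <- chance_baseline(length(levels))
  attr(report, "summary") <- summ
  if (!is.null(out_csv)) {
    utils::write.csv(report, out_csv, row.names = FALSE)
  }
  report
}
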