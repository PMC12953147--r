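test_that("relative-frequency features count in-vocabulary tokens", {
  f <- extract_features(c("a", "b", "a"), c("a", "b"))
  expect_equal(unname(f[1:2]), c(2 / 3, 1 / 3))
  expect_false(attr(f, "empty"))
  g <- extract_features("z", c("a", "b"))
  expect_equal(unname(g[1:2]), c(0, 0))
  expect_true(attr(g, "empty"))
  expect_error(extract_features("a", character(0)), "non-empty")
})

test_that("topic-loading features average the per-token loading rows", {
  L <- matrix(c(0.9, 0.1,
                0.2, 0.8,
                0.5, 0.5), nrow = 3, byrow = TRUE)
  f <- extract_features(c("a", "c", "a"), c("a", "b", "c"),
                        mode = "topic_loading", topic_loadings = L)
  # hand-computed mean of rows (a, c, a): ((0.9+0.5+0.9)/3, (0.1+0.5+0.1)/3)
  expect_equal(unname(f[1:2]), c(2.3 / 3, 0.7 / 3), tolerance = 1e-12)
  expect_equal(attr(f, "n_in_vocab"), 3L)
})

test_that("a one-participant scalar fit returns the minimum-norm ratio", {
  spec <- trait_spec("d")
  rec <- participant_record("p1", list(c("a", "a", "a", "a")), 2)
  # pooled feature over vocab ("a") is 1; psi = 2 -> exact fit W = 2
  est <- fit_participant_estimator(list(rec), spec, "a", lambda = 0)
  expect_equal(unname(est$W[1, 1]), 2)
})

test_that("an exactly determined fit matches the frozen normal-equations solution", {
  # X = [[1,0],[0,1],[1,1]] built from single-token messages; psi chosen so
  # the normal equations give W = (7/6, 13/6) (hand-solved: XtX = [[2,1],[1,2]],
  # Xt psi = (4.5, 5.5))
  spec <- trait_spec("d")
  recs <- list(
    participant_record("p1", list(c("a")), 1),
    participant_record("p2", list(c("b")), 2),
    participant_record("p3", list(c("a", "b")), 3.5))
  # pooled relative frequencies: (1,0), (0,1), (.5,.5) -- rescale the third
  # participant's contribution by using the frequency design directly
  X <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  psi <- c(1, 2, 3.5)
  W_oracle <- solve(crossprod(X), crossprod(X, psi))
  est <- fit_participant_estimator(recs, spec, c("a", "b"), lambda = 0)
  expect_equal(unname(est$W[1, ]), as.numeric(W_oracle), tolerance = 1e-10)
  # and the fitted estimator scores a listed feature vector by matrix product
  feat <- c(0.5, 0.25)
  expect_equal(score_message(est, feat),
               as.numeric(W_oracle[1] * 0.5 + W_oracle[2] * 0.25),
               tolerance = 1e-10)
})

test_that("ridge shrinks coefficients monotonically and raises training error", {
  set.seed(4)
  spec <- trait_spec(c("d1", "d2"))
  vocab <- letters[1:6]
  recs <- lapply(1:12, function(i) {
    toks <- sample(vocab, 30, replace = TRUE, prob = stats::runif(6, 0.5, 2))
    participant_record(paste0("p", i), list(toks), stats::rnorm(2))
  })
  lambdas <- c(0, 1e-3, 1e-1, 10, 1e4)
  norms <- numeric(length(lambdas))
  mses <- numeric(length(lambdas))
  X <- t(sapply(recs, function(r) as.numeric(
    extract_features(unlist(r$messages), vocab))))
  psi <- t(sapply(recs, `[[`, "trait_scores"))
  for (i in seq_along(lambdas)) {
    est <- fit_participant_estimator(recs, spec, vocab, lambda = lambdas[i])
    norms[i] <- sqrt(sum(est$W^2))
    mses[i] <- mean((psi - X %*% t(est$W))^2)
  }
  expect_true(all(diff(norms) < 1e-12))
  expect_true(all(diff(mses) > -1e-12))
  expect_lt(norms[length(norms)], 0.01 * norms[1])
})

test_that("a noiseless linear teacher is recovered under a full-rank design", {
  set.seed(9)
  vocab <- letters[1:4]
  W_star <- matrix(c(1.5, -2, 0.5, 3,
                     -1, 0.25, 2, -0.75), nrow = 2, byrow = TRUE)
  spec <- trait_spec(c("d1", "d2"))
  recs <- lapply(1:10, function(i) {
    toks <- sample(vocab, 40, replace = TRUE, prob = stats::runif(4, 0.5, 2))
    x <- as.numeric(extract_features(toks, vocab))
    participant_record(paste0("p", i), list(toks), as.numeric(W_star %*% x))
  })
  est <- fit_participant_estimator(recs, spec, vocab, lambda = 0)
  # frequencies sum to 1 so W* is identified only up to a constant shift per
  # row; compare predictions instead of coefficients
  X <- t(sapply(recs, function(r) as.numeric(
    extract_features(unlist(r$messages), vocab))))
  expect_equal(X %*% t(est$W), X %*% t(W_star), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("rank-deficient lambda=0 designs fall back to minimum norm with a warning", {
  spec <- trait_spec("d")
  recs <- list(participant_record("p1", list(c("a", "b")), 1),
               participant_record("p2", list(c("a", "b")), 1))
  expect_warning(
    est <- fit_participant_estimator(recs, spec, c("a", "b", "c"), lambda = 0),
    "singular")
  expect_true(all(is.finite(est$W)))
})

test_that("message scoring is linear and validates dimensions", {
  spec <- trait_spec("d")
  est <- structure(list(W = matrix(2, 1, 1, dimnames = list("d", "a")),
                        lambda = 0, vocabulary = "a", spec = spec),
                   class = "trait_estimator")
  expect_equal(score_message(est, 0.5), 1.0)
  expect_equal(score_message(est, 0), 0)
  set.seed(2)
  est2 <- structure(list(W = matrix(stats::rnorm(6), 2, 3), lambda = 0,
                         vocabulary = letters[1:3],
                         spec = trait_spec(c("d1", "d2"))),
                    class = "trait_estimator")
  x <- stats::rnorm(3)
  for (cc in c(-2, 0.5, 3)) {
    expect_equal(score_message(est2, cc * x), cc * score_message(est2, x),
                 tolerance = 1e-12)
  }
  expect_error(score_message(est2, c(1, 2)), "length")
})

test_that("corpus scoring standardizes to mean 0 / SD 1 and flags empty messages", {
  spec <- trait_spec("d")
  est <- structure(list(W = matrix(c(4, 0), 1, 2,
                                   dimnames = list("d", c("a", "b"))),
                        lambda = 0, vocabulary = c("a", "b"), spec = spec),
                   class = "trait_estimator")
  # two messages with raw scores 1 and 3 standardize to -1 and +1
  sc <- score_corpus(est, list(c("a", "b", "a", "b"), c("a", "a", "a", "b")),
                     spec)
  expect_equal(unname(sc$scores_raw[, 1]), c(2, 3))
  expect_equal(unname(sc$scores_std[, 1]), c(-1, 1))
  # all-OOV message gets the corpus mean and a flag
  sc2 <- score_corpus(est, list(c("a", "a"), c("a", "b"), c("zzz")), spec)
  expect_true(sc2$flagged_empty[3])
  expect_equal(unname(sc2$scores_raw[3, 1]),
               mean(sc2$scores_raw[1:2, 1]))
  # per-dimension moments after standardization (population convention)
  set.seed(6)
  msgs <- lapply(1:40, function(i) sample(c("a", "b"), 10, replace = TRUE))
  sc3 <- score_corpus(est, msgs, spec)
  expect_equal(mean(sc3$scores_std[, 1]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(sc3$scores_std[, 1]^2)), 1, tolerance = 1e-9)
  # affine rescaling of raw scores leaves standardized scores unchanged
  est_resc <- est; est_resc$W <- 10 * est$W + 0  # homogeneous rescale
  sc4 <- score_corpus(est_resc, msgs, spec)
  expect_equal(sc4$scores_std, sc3$scores_std, tolerance = 1e-9)
  # constant scores are a configuration error naming the dimension
  expect_error(score_corpus(est, list(c("a"), c("a")), spec), "d")
})
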