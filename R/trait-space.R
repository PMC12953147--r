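#' Define a trait space
#'
#' A trait space fixes the ordered set of continuous psychological or
#' demographic dimensions a model is conditioned on (e.g. the Big Five, or a
#' depression + age pair), together with the population mean and standard
#' deviation of each dimension in raw units. Profiles built in this space are
#' always expressed in standardized units (SDs from the population mean).
#'
#' @param names Character vector of dimension labels, e.g.
#'   `c("openness","conscientiousness","extraversion","agreeableness","neuroticism")`.
#' @param mu Numeric vector of per-dimension population means (raw units).
#'   Default 0 for already-standardized scores.
#' @param sigma Numeric vector of per-dimension population SDs (raw units),
#'   all strictly positive. Default 1.
#' @return An object of class `trait_spec` with fields `names`, `t`, `mu`,
#'   `sigma`.
#' @examples
#' spec <- trait_spec(c("depression", "age"))
#' spec$t
#' @export
trait_spec <- function(names, mu = rep(0, length(names)),
                       sigma = rep(1, length(names))) {
  names <- as.character(names)
  if (length(names) < 1L) {
    stop("a trait space needs at least one dimension", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("trait dimension names must be unique", call. = FALSE)
  }
  mu <- as.numeric(mu)
  sigma <- as.numeric(sigma)
  if (length(mu) != length(names) || length(sigma) != length(names)) {
    stop("mu and sigma must match the number of dimensions", call. = FALSE)
  }
  if (!all(is.finite(mu)) || !all(is.finite(sigma))) {
    stop("mu and sigma must be finite", call. = FALSE)
  }
  if (any(sigma <= 0)) {
    stop("all sigma must be strictly positive", call. = FALSE)
  }
  structure(
    list(names = names, t = length(names), mu = mu, sigma = sigma),
    class = "trait_spec"
  )
}

#' @export
print.trait_spec <- function(x, ...) {
  cat("Trait space with", x$t, "dimension(s):\n")
  for (i in seq_len(x$t)) {
    cat(sprintf("  [%d] %s (mu = %g, sigma = %g)\n",
                i - 1L, x$names[i], x$mu[i], x$sigma[i]))
  }
  invisible(x)
}

# Operating range of standardized scores. The adapter is trained on scores
# roughly in [-3, 3]; anything beyond +/-5 SD is far out of distribution and
# is clamped at profile construction.
.trait_clamp <- 5

#' Construct a trait profile
#'
#' A trait profile is a vector of standardized scores (SDs from the
#' population mean), one per dimension of its trait space. Scores are clamped
#' to the operating range \eqn{[-5, 5]}.
#'
#' @param spec A [trait_spec()].
#' @param scores Numeric vector of standardized scores, length `spec$t`.
#' @return An object of class `trait_profile` with fields `spec` and `scores`.
#' @examples
#' spec <- trait_spec(letters[1:5])
#' trait_profile(spec, c(0, 0, 3, 0, 0))
#' @export
trait_profile <- function(spec, scores) {
  stopifnot(inherits(spec, "trait_spec"))
  scores <- as.numeric(scores)
  if (length(scores) != spec$t) {
    stop(sprintf("expected %d scores, got %d", spec$t, length(scores)),
         call. = FALSE)
  }
  if (!all(is.finite(scores))) {
    stop("trait scores must be finite", call. = FALSE)
  }
  scores <- pmin(pmax(scores, -.trait_clamp), .trait_clamp)
  names(scores) <- spec$names
  structure(list(spec = spec, scores = scores), class = "trait_profile")
}

#' @export
print.trait_profile <- function(x, ...) {
  cat("Trait profile:",
      paste(sprintf("%s=%g", x$spec$names, x$scores), collapse = ", "), "\n")
  invisible(x)
}

#' Build a single-focal-dimension input vector
#'
#' Constructs the standardized input profile that places level `k` (in SD
#' units) on one focal dimension and the population mean (0) everywhere else:
#' e.g. focusing the third of five dimensions gives `(0, 0, k, 0, 0)`.
#'
#' @param spec A [trait_spec()].
#' @param focal_index 0-based index of the focal dimension.
#' @param k Level on the focal dimension, in SDs from the mean (typically in
#'   \eqn{[-3, 3]}).
#' @return A [trait_profile()].
#' @examples
#' spec <- trait_spec(c("O", "C", "E", "A", "N"))
#' build_input_vector(spec, 2, 3)  # high extraversion
#' @export
build_input_vector <- function(spec, focal_index, k) {
  stopifnot(inherits(spec, "trait_spec"))
  if (length(focal_index) != 1L || is.na(focal_index) ||
      focal_index != trunc(focal_index) ||
      focal_index < 0 || focal_index >= spec$t) {
    stop(sprintf("focal_index must be a 0-based integer in [0, %d]",
                 spec$t - 1L), call. = FALSE)
  }
  if (length(k) != 1L || !is.finite(k)) {
    stop("k must be a single finite number", call. = FALSE)
  }
  scores <- rep(0, spec$t)
  scores[focal_index + 1L] <- k
  trait_profile(spec, scores)
}

#' Combine several focal dimensions into one profile
#'
#' Places a level on each of several distinct dimensions at once, e.g.
#' `{0: +3, 2: -3}` over five dimensions gives `(3, 0, -3, 0, 0)` — high on
#' the first trait and low on the third simultaneously. Unassigned
#' dimensions stay at the population mean.
#'
#' @param spec A [trait_spec()].
#' @param assignments Named list or named numeric vector mapping 0-based
#'   dimension indices (as names) to levels `k`, e.g. `list("0" = 3, "2" = -3)`.
#'   May be empty (mean profile).
#' @return A [trait_profile()].
#' @export
combine_profiles <- function(spec, assignments = list()) {
  stopifnot(inherits(spec, "trait_spec"))
  if (length(assignments) == 0L) {
    return(trait_profile(spec, rep(0, spec$t)))
  }
  idx_chr <- names(assignments)
  if (is.null(idx_chr) || any(!nzchar(idx_chr))) {
    stop("assignments must be named by 0-based dimension index", call. = FALSE)
  }
  idx <- suppressWarnings(as.integer(idx_chr))
  if (any(is.na(idx)) || any(idx < 0) || any(idx >= spec$t)) {
    stop("assignment indices must be 0-based integers within the trait space",
         call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop("duplicate dimension index in assignments", call. = FALSE)
  }
  ks <- vapply(assignments, function(v) as.numeric(v)[1L], numeric(1))
  if (!all(is.finite(ks))) stop("levels must be finite", call. = FALSE)
  scores <- rep(0, spec$t)
  scores[idx + 1L] <- ks
  trait_profile(spec, scores)
}

#' Standardize raw trait scores
#'
#' Maps raw scores to standardized units: entry i becomes
#' \eqn{(raw_i - \mu_i)/\sigma_i} with the population constants of the trait
#' space, so the population mean maps to 0 and one raw SD to 1.
#'
#' @param spec A [trait_spec()] carrying `mu` and `sigma`.
#' @param raw_scores Numeric vector of raw scores, length `spec$t`.
#' @return A [trait_profile()] in standardized units.
#' @export
standardize_traits <- function(spec, raw_scores) {
  stopifnot(inherits(spec, "trait_spec"))
  raw_scores <- as.numeric(raw_scores)
  if (length(raw_scores) != spec$t) {
    stop("raw_scores length must match the trait space", call. = FALSE)
  }
  trait_profile(spec, (raw_scores - spec$mu) / spec$sigma)
}

#' De-standardize a trait profile back to raw units
#'
#' Inverse of [standardize_traits()]: raw_i = mu_i + z_i * sigma_i.
#'
#' @param profile A [trait_profile()].
#' @return Numeric vector of raw scores.
#' @export
destandardize_traits <- function(profile) {
  stopifnot(inherits(profile, "trait_profile"))
  unname(profile$spec$mu + profile$scores * profile$spec$sigma)
}

#' A point on the interpersonal circumplex
#'
#' The interpersonal circumplex organizes interpersonal traits on two axes,
#' warmth and dominance, obtained by rotating the extraversion and
#' agreeableness axes by an angle alpha (22.5 degrees in the standard
#' parameterization).
#'
#' @param warmth Warmth coordinate (standardized units).
#' @param dominance Dominance coordinate (standardized units).
#' @param alpha_degrees Rotation angle in degrees, in \eqn{[0, 90)}.
#' @return An object of class `circumplex_point`.
#' @export
circumplex_point <- function(warmth, dominance, alpha_degrees = 22.5) {
  if (!is.finite(warmth) || !is.finite(dominance)) {
    stop("warmth and dominance must be finite", call. = FALSE)
  }
  if (!is.finite(alpha_degrees) || alpha_degrees < 0 || alpha_degrees >= 90) {
    stop("alpha_degrees must lie in [0, 90)", call. = FALSE)
  }
  structure(list(warmth = as.numeric(warmth),
                 dominance = as.numeric(dominance),
                 alpha_degrees = as.numeric(alpha_degrees)),
            class = "circumplex_point")
}

#' Rotate circumplex coordinates into trait coordinates
#'
#' Maps a (warmth, dominance) position to (extraversion, agreeableness)
#' scores via the rotation
#' \deqn{ext = \cos\alpha \cdot warmth - \sin\alpha \cdot dominance}
#' \deqn{agr = \sin\alpha \cdot warmth + \cos\alpha \cdot dominance}
#' The rotation is orthonormal, so Euclidean norms are preserved.
#'
#' @param point A [circumplex_point()].
#' @return Named numeric vector `c(ext = ..., agr = ...)`.
#' @examples
#' circumplex_to_traits(circumplex_point(3, 0))
#' @export
circumplex_to_traits <- function(point) {
  stopifnot(inherits(point, "circumplex_point"))
  a <- point$alpha_degrees * pi / 180
  c(ext = cos(a) * point$warmth - sin(a) * point$dominance,
    agr = sin(a) * point$warmth + cos(a) * point$dominance)
}

#' Rotate trait coordinates back onto the circumplex
#'
#' Inverse of [circumplex_to_traits()]: recovers the (warmth, dominance)
#' position whose rotation gives the supplied extraversion and agreeableness
#' scores.
#'
#' @param ext Extraversion score.
#' @param agr Agreeableness score.
#' @param alpha_degrees Rotation angle in degrees, in \eqn{[0, 90)}.
#' @return A [circumplex_point()].
#' @export
traits_to_circumplex <- function(ext, agr, alpha_degrees = 22.5) {
  if (!is.finite(ext) || !is.finite(agr)) {
    stop("ext and agr must be finite", call. = FALSE)
  }
  if (!is.finite(alpha_degrees) || alpha_degrees < 0 || alpha_degrees >= 90) {
    stop("alpha_degrees must lie in [0, 90)", call. = FALSE)
  }
  a <- alpha_degrees * pi / 180
  # inverse rotation (transpose of the forward rotation matrix)
  circumplex_point(warmth = cos(a) * ext + sin(a) * agr,
                   dominance = -sin(a) * ext + cos(a) * agr,
                   alpha_degrees = alpha_degrees)
}
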