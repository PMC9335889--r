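# Personalized decision boundaries from labeled real-life decisions.
#
# The single classification feature is the decision angle v. Correct
# decisions (no unexpected-grasp feedback) train one Gaussian per target;
# each adjacent pair of targets forms a 2-class Naive Bayes problem whose
# decision boundary is the angle where the two (prior-weighted) class
# densities are equal. Unexpected decisions are held out to verify the
# adapted boundaries: a "correction" is an unexpected decision whose angle
# classifies to the intended target under the new boundaries.

#' Fit per-target Gaussian angle models
#'
#' For each target, the mean and sample standard deviation (n - 1
#' denominator) of the decision angles of its correct decisions, with the
#' empirical prior. A standard-deviation floor avoids degenerate spikes.
#'
#' @param training Data frame of labeled decisions (see
#'   [extract_labeled_decisions()]); only rows with `unexpected == FALSE`
#'   and a closing/opening executed target 1--4 are used, keyed by
#'   `executed_target`.
#' @param sigma_floor Minimum standard deviation in degrees (default 0.5).
#' @return Data frame with one row per target: `target, mu, sigma, n,
#'   prior`. Targets with fewer than 2 decisions get `NA` model parameters.
#' @export
fit_angle_models <- function(training, sigma_floor = 0.5) {
  if (!is.null(training$unexpected)) {
    training <- training[!training$unexpected, , drop = FALSE]
  }
  n_tot <- nrow(training)
  out <- do.call(rbind, lapply(1:4, function(k) {
    v <- training$v[training$executed_target == k]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n >= 2) {
      data.frame(target = k, mu = mean(v),
                 sigma = max(stats::sd(v), sigma_floor),
                 n = n, prior = n / n_tot)
    } else {
      data.frame(target = k, mu = NA_real_, sigma = NA_real_, n = n,
                 prior = if (n_tot) n / n_tot else NA_real_)
    }
  }))
  out
}

#' Equal-density boundary between two Gaussian angle classes
#'
#' Solves `pi_i N(v; mu_i, sigma_i) = pi_j N(v; mu_j, sigma_j)`, a quadratic
#' in `v`. With equal sigmas and equal priors this reduces to the midpoint
#' of the means (the closed form behind the symmetric default boundaries).
#' When the quadratic has no real root inside `(mu_i, mu_j)` -- a
#' pathological variance ratio -- the midpoint is returned with a warning.
#' The result is clamped to the open interval `(mu_i, mu_j)`.
#'
#' @param mu_i,sigma_i Mean/SD (degrees) of the lower class (`mu_i < mu_j`).
#' @param mu_j,sigma_j Mean/SD of the upper class.
#' @param prior_i,prior_j Class priors (default equal).
#' @return Boundary angle in degrees; attribute `fallback` is `TRUE` when
#'   the midpoint fallback was used.
#' @export
equal_density_boundary <- function(mu_i, sigma_i, mu_j, sigma_j,
                                   prior_i = 0.5, prior_j = 0.5) {
  if (!(mu_i < mu_j)) amo_config_error("equal_density_boundary needs mu_i < mu_j")
  midpoint <- (mu_i + mu_j) / 2
  if (sigma_i == sigma_j) {
    # linear case: equal variances
    b <- midpoint + sigma_i^2 * log(prior_i / prior_j) / (mu_j - mu_i)
  } else {
    a <- 1 / (2 * sigma_j^2) - 1 / (2 * sigma_i^2)
    bb <- mu_i / sigma_i^2 - mu_j / sigma_j^2
    cc <- mu_j^2 / (2 * sigma_j^2) - mu_i^2 / (2 * sigma_i^2) -
      log((prior_j * sigma_i) / (prior_i * sigma_j))
    disc <- bb^2 - 4 * a * cc
    roots <- if (disc >= 0) (-bb + c(-1, 1) * sqrt(disc)) / (2 * a) else numeric(0)
    inside <- roots[roots > mu_i & roots < mu_j]
    if (length(inside)) {
      b <- inside[1]
    } else {
      warning("no equal-density root between the class means; using midpoint")
      b <- structure(midpoint, fallback = TRUE)
      return(b)
    }
  }
  eps <- 1e-9 * (mu_j - mu_i)
  b <- min(max(b, mu_i + eps), mu_j - eps)
  attr(b, "fallback") <- FALSE
  b
}

#' Adapt the decision boundaries from correct decisions
#'
#' Fits the per-target angle models and computes the three adjacent-pair
#' equal-density boundaries. A pair with an unfittable class (fewer than 2
#' training decisions) keeps its default boundary and is flagged; if the
#' resulting triple violates the ordering invariant `0 < b12 < b23 < b34 <
#' 90`, the defaults are returned with every pair flagged.
#'
#' @param training Labeled decisions (training partition).
#' @param defaults Fallback [decision_boundaries()].
#' @param priors_mode `"equal"` (default; the boundary is where the class
#'   *densities* are equal) or `"empirical"` (posterior-weighted by
#'   training counts).
#' @param sigma_floor Passed to [fit_angle_models()].
#' @return A [decision_boundaries()] object with attributes `fallback`
#'   (logical, one per pair) and `models` (the fitted model table).
#' @export
adapt_boundaries <- function(training, defaults = default_boundaries(),
                             priors_mode = c("equal", "empirical"),
                             sigma_floor = 0.5) {
  priors_mode <- match.arg(priors_mode)
  models <- fit_angle_models(training, sigma_floor = sigma_floor)
  def <- c(defaults$b12, defaults$b23, defaults$b34)
  b <- def
  fallback <- rep(TRUE, 3)
  for (p in 1:3) {
    mi <- models[p, ]; mj <- models[p + 1, ]
    if (is.na(mi$mu) || is.na(mj$mu) || !(mi$mu < mj$mu)) next
    pr <- if (priors_mode == "equal") c(0.5, 0.5) else {
      tot <- mi$n + mj$n
      c(mi$n, mj$n) / tot
    }
    bp <- equal_density_boundary(mi$mu, mi$sigma, mj$mu, mj$sigma,
                                 prior_i = pr[1], prior_j = pr[2])
    fallback[p] <- isTRUE(attr(bp, "fallback"))
    b[p] <- as.numeric(bp)
  }
  if (!(b[1] > 0 && b[3] < 90 && all(diff(b) > 0))) {
    warning("adapted boundaries violate ordering; falling back to defaults")
    b <- def
    fallback <- rep(TRUE, 3)
  }
  out <- decision_boundaries(b[1], b[2], b[3])
  attr(out, "fallback") <- fallback
  attr(out, "models") <- models
  out
}

#' Verify boundaries against the unexpected decisions
#'
#' @param b A [decision_boundaries()] object.
#' @param verification Labeled decisions with `v` and `intended_target`
#'   (normally the `unexpected == TRUE` partition).
#' @return An `adaptation_result`: the boundaries, `n_feedback` (number of
#'   unexpected decisions) and `n_corrected` (how many classify to their
#'   intended target under `b`).
#' @export
verify_boundaries <- function(b, verification) {
  stopifnot(inherits(b, "decision_boundaries"))
  n_fb <- nrow(verification)
  n_corr <- if (n_fb) {
    sum(classify_target(verification$v, b) == verification$intended_target,
        na.rm = TRUE)
  } else 0L
  structure(
    list(boundaries = b, n_feedback = n_fb, n_corrected = as.integer(n_corr)),
    class = "adaptation_result"
  )
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf(
    "<adaptation_result> boundaries %.1f/%.1f/%.1f deg; %d feedback, %d corrected\n",
    x$boundaries$b12, x$boundaries$b23, x$boundaries$b34,
    x$n_feedback, x$n_corrected))
  invisible(x)
}
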