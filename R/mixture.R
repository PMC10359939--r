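# Two-component Gaussian mixture for hit-threshold estimation, fitted by
# EM. One component captures the inactive background (survival fractions
# near 1), the other the extreme responses.

#' Fit the two-component background/active Gaussian mixture
#'
#' Univariate EM fit with a deterministic, anchored initialization: the
#' background component starts at the anchor (1 for survival fractions,
#' 0 for z scores) with weight 0.9 and the sample sd; the active
#' component starts at the 5th percentile of the data with weight 0.1.
#' Iteration stops when the log-likelihood improves by less than 1e-6 or
#' after 500 iterations; the log-likelihood trace is retained and is
#' non-decreasing. If a component degenerates (sd below 1e-6 or weight
#' below 1e-3) the fit falls back to a single background Gaussian with a
#' warning.
#'
#' @param values numeric readouts (>= 20 values).
#' @param seed integer seed; the default initialization is deterministic,
#'   the seed exists so alternative stochastic initializations stay
#'   reproducible.
#' @param anchor location of the inactive background (default 1, the
#'   survival-fraction scale; use 0 for z scores).
#' @param patientId,concentrationNM optional provenance recorded in the
#'   fit.
#' @return A \linkS4class{MixtureFit}; its \code{threshold} slot is NA
#'   until \code{\link{activityThreshold}} (or the screen driver) sets it.
#' @examples
#' set.seed(1)
#' fit <- fitBackgroundMixture(c(rnorm(1800, 1, 0.05), rnorm(200, 0.3, 0.1)))
#' backgroundMean(fit)
#' @export
fitBackgroundMixture <- function(values, seed = 1L, anchor = 1,
                                 patientId = NA_character_,
                                 concentrationNM = NA_real_) {
  values <- as.numeric(values)
  if (length(values) < 20L)
    stop("mixture fitting requires at least 20 values")
  .withSeed(seed, {
    s0 <- stats::sd(values)
    if (!is.finite(s0) || s0 == 0) s0 <- max(1e-3, abs(anchor) * 1e-3)
    w <- c(0.9, 0.1)
    mu <- c(anchor, .percentile(values, 5))
    sigma <- c(s0, s0)
    trace <- numeric(0)
    fallback <- FALSE
    ll <- -Inf
    for (iter in seq_len(500L)) {
      d1 <- w[1L] * stats::dnorm(values, mu[1L], sigma[1L])
      d2 <- w[2L] * stats::dnorm(values, mu[2L], sigma[2L])
      tot <- d1 + d2
      tot[tot < 1e-300] <- 1e-300
      newll <- sum(log(tot))
      trace <- c(trace, newll)
      if (is.finite(ll) && newll - ll < 1e-6) { ll <- newll; break }
      ll <- newll
      r <- d1 / tot
      n1 <- sum(r); n2 <- length(values) - n1
      w <- c(n1, n2) / length(values)
      mu <- c(sum(r * values) / n1, sum((1 - r) * values) / n2)
      sigma <- c(sqrt(sum(r * (values - mu[1L])^2) / n1),
                 sqrt(sum((1 - r) * (values - mu[2L])^2) / n2))
      if (any(!is.finite(sigma)) || any(sigma < 1e-6) || any(w < 1e-3)) {
        fallback <- TRUE
        break
      }
    }
    if (fallback) {
      warning("degenerate two-component fit; falling back to a single ",
              "background Gaussian")
      mu <- rep(mean(values), 2L)
      sigma <- rep(max(stats::sd(values), 1e-8), 2L)
      w <- c(1, 0)
      d <- stats::dnorm(values, mu[1L], sigma[1L])
      d[d < 1e-300] <- 1e-300
      trace <- sum(log(d))  # trace restarts: a different (1-component) model
    }
    bg <- which.min(abs(mu - anchor))
    new("MixtureFit", patientId = as.character(patientId),
        concentrationNM = as.numeric(concentrationNM),
        weights = w, means = mu, sds = sigma,
        backgroundIndex = as.integer(bg), loglik = trace[length(trace)],
        loglikTrace = trace, threshold = NA_real_, fallback = fallback)
  })
}

#' Data-driven activity threshold from a mixture fit
#'
#' The threshold is the analytic quantile of the fitted background
#' Gaussian at the requested percentile:
#' \eqn{\mu_{bg} + z(p/100)\,\sigma_{bg}}. The default 0.01 percentile
#' (lower-tail probability 1e-4) marks responses far enough below the
#' background to call a compound active at that concentration.
#'
#' @param fit a \linkS4class{MixtureFit}.
#' @param hitPercentile percentile of the background distribution in
#'   (0, 100) (default 0.01).
#' @return The threshold on the readout scale.
#' @examples
#' set.seed(1)
#' fit <- fitBackgroundMixture(rnorm(2000, 1, 0.05))
#' activityThreshold(fit)  # near 1 - 3.719 * 0.05
#' @export
activityThreshold <- function(fit, hitPercentile = 0.01) {
  stopifnot(is(fit, "MixtureFit"))
  if (hitPercentile <= 0 || hitPercentile >= 100)
    stop("hitPercentile must lie in (0, 100)")
  sbg <- backgroundSd(fit)
  if (sbg <= 0) {
    warning("background sd is zero; threshold equals the background mean")
    return(backgroundMean(fit))
  }
  backgroundMean(fit) + stats::qnorm(hitPercentile / 100) * sbg
}
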