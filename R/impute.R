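#' Impute missing accelerometer samples
#'
#' Occasional sensor breakdowns leave gaps in one sensor of a pair (in the
#' original recordings about 0.8% of samples). Gaps are filled with the
#' mean of `n_imputations` stochastic draws from a chained local-regression
#' model: each missing sample is predicted from a +/-0.5 s window of the
#' same channel (local linear trend in time) together with the synchronous
#' channels of the other sensor of the same joint, and a residual-noise
#' draw is added per imputation. Observed samples are never touched, and
#' the procedure is deterministic for a fixed seed.
#'
#' A joint with 20% or more of its samples missing in either sensor is not
#' imputable; it is flagged untestable (condition class
#' `untestable_joint_error`) and callers exclude it from scoring, mirroring
#' the exclusion of joints that could not be tested.
#'
#' @param trace a [sensor_pair_trace()].
#' @param n_imputations number of stochastic draws averaged per gap.
#' @param seed integer seed for the residual draws.
#' @param window_s half-width of the regression window in seconds.
#' @return a [sensor_pair_trace()] with gaps filled and missing masks
#'   cleared (original masks kept in attribute `"imputed_mask"`).
#' @export
impute_missing <- function(trace, n_imputations = 50, seed = 1,
                           window_s = 0.5) {
  stopifnot(inherits(trace, "assess_trace"))
  for (sensor in c("proximal", "distal")) {
    frac <- mean(trace[[paste0("missing_", sensor)]])
    if (frac >= 0.2) {
      stop(structure(
        class = c("untestable_joint_error", "error", "condition"),
        list(message = paste0(
               "joint ", trace$joint, ": ", round(100 * frac, 1),
               "% of ", sensor, " samples missing (>= 20%); ",
               "joint flagged untestable"),
             call = NULL, joint = trace$joint)))
    }
  }
  if (!any(trace$missing_proximal) && !any(trace$missing_distal)) {
    return(trace)
  }
  rng <- local_rng(seed)
  n <- nrow(trace$proximal)
  t <- seq(0, by = 1 / trace$sampling_rate, length.out = n)
  win <- max(2L, round(window_s * trace$sampling_rate))
  out <- trace
  for (sensor in c("proximal", "distal")) {
    miss <- trace[[paste0("missing_", sensor)]]
    if (!any(miss)) next
    other <- out[[setdiff(c("proximal", "distal"), sensor)]]
    m <- trace[[sensor]]
    for (ax in 1:3) {
      y <- m[, ax]
      y[miss] <- NA_real_
      # initial fill so the chained pass always has complete covariates
      y0 <- stats::approx(t[!miss], y[!miss], xout = t, rule = 2)$y
      for (i in which(miss)) {
        lo <- max(1L, i - win); hi <- min(n, i + win)
        rows <- setdiff(lo:hi, which(miss))
        if (length(rows) < 4L) {
          m[i, ax] <- y0[i]
          next
        }
        X <- cbind(1, t[rows] - t[i], other[rows, , drop = FALSE])
        fit <- stats::lm.fit(X, y[rows])
        sigma <- sqrt(sum(fit$residuals^2) /
                        max(1L, length(rows) - ncol(X)))
        xi <- c(1, 0, other[i, ])
        pred <- sum(xi * ifelse(is.na(fit$coefficients), 0,
                                fit$coefficients))
        draws <- pred + rng$rnorm(n_imputations, 0, sigma)
        m[i, ax] <- mean(draws)
      }
    }
    out[[sensor]] <- m
  }
  imputed <- list(proximal = trace$missing_proximal,
                  distal = trace$missing_distal)
  out$missing_proximal <- rep(FALSE, n)
  out$missing_distal <- rep(FALSE, n)
  out$missing_fraction <- 0
  attr(out, "imputed_mask") <- imputed
  out
}
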