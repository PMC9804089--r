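#' Intraclass correlation ICC(2,1)
#'
#' Single-measure two-way random-effects intraclass correlation under
#' absolute agreement (Shrout & Fleiss ICC(2,1)), the standard model for
#' test-retest designs where occasions are a random facet. Mean squares
#' come from the two-way ANOVA `score ~ subject + occasion` (fitted with
#' [stats::aov()]):
#'
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#'
#' with `n` subjects and `k` occasions. Variance components are returned
#' alongside: between-subject `sigma2_subject = (MS_R - MS_E)/k`, trial
#' (occasion) `sigma2_t = (MS_C - MS_E)/n`, and residual `sigma2_e = MS_E`.
#' ANOVA component estimates can come out negative in small samples; they
#' are reported as estimated, and [sem_mdc()] requires the caller to
#' truncate at zero explicitly.
#'
#' @param scores numeric matrix or data frame, `n` subjects x `k >= 2`
#'   occasions, no missing cells (exclude incomplete subjects first).
#' @return list with `icc`, `ms` (MSR, MSC, MSE), `sigma2_subject`,
#'   `sigma2_t`, `sigma2_e`, `n_subjects`, `k`.
#' @examples
#' icc_2_1(cbind(test = c(1, 2, 4, 6), retest = c(2, 3, 4, 5)))$icc
#' @export
icc_2_1 <- function(scores) {
  m <- as.matrix(scores)
  if (anyNA(m)) {
    stop("scores contain missing cells; drop incomplete subjects first",
         call. = FALSE)
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L) {
    stop("need at least 3 subjects and 2 occasions", call. = FALSE)
  }
  if (stats::var(as.vector(m)) == 0) {
    stop("zero total variance: ICC undefined", call. = FALSE)
  }
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(n), times = k)),
                  occasion = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + occasion, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  list(icc = unname(icc),
       ms = c(MSR = unname(msr), MSC = unname(msc), MSE = unname(mse)),
       sigma2_subject = unname((msr - mse) / k),
       sigma2_t = unname((msc - mse) / n),
       sigma2_e = unname(mse),
       n_subjects = n, k = k)
}

#' Standard error of measurement and minimal detectable change
#'
#' Absolute-reliability indices from the two-way ANOVA variance
#' components: `SEM = sqrt(sigma2_t + sigma2_e)` (trial plus residual
#' random error) and `MDC95 = 1.96 * sqrt(2) * SEM`, the smallest change
#' between two measurements interpretable as real at 95% confidence.
#'
#' @param sigma2_t trial (occasion) variance component, >= 0.
#' @param sigma2_e residual error variance component, >= 0. Negative ANOVA
#'   estimates must be truncated to 0 by the caller (see
#'   [truncate_components()]), which keeps the truncation explicit.
#' @return named numeric: `sem`, `mdc95`.
#' @examples
#' sem_mdc(0.02, 0.02)  # sem 0.2, mdc95 0.554
#' @export
sem_mdc <- function(sigma2_t, sigma2_e) {
  if (sigma2_t < 0 || sigma2_e < 0) {
    stop("negative variance component; truncate ANOVA estimates at 0 ",
         "explicitly before computing SEM (see truncate_components())",
         call. = FALSE)
  }
  sem <- sqrt(sigma2_t + sigma2_e)
  c(sem = sem, mdc95 = 1.96 * sqrt(2) * sem)
}

#' @rdname sem_mdc
#' @param components numeric vector of variance-component estimates.
#' @export
truncate_components <- function(components) {
  if (any(components < 0)) {
    warning("negative variance-component estimate(s) truncated to 0: ",
            paste(signif(components[components < 0], 3), collapse = ", "),
            call. = FALSE)
  }
  pmax(components, 0)
}

#' MDC as a percentage of the grand mean
#'
#' Expresses the minimal detectable change relative to the grand mean of
#' the test and retest occasion means (their average), as an integer
#' percentage for reporting.
#'
#' @param mean_test,mean_retest occasion means of the score.
#' @param mdc95 minimal detectable change.
#' @return integer percentage `100 * mdc95 / grand_mean`.
#' @examples
#' mdc_percent_grand_mean(2.55, 2.47, 0.63)  # 25
#' @export
mdc_percent_grand_mean <- function(mean_test, mean_retest, mdc95) {
  grand <- (mean_test + mean_retest) / 2
  if (!is.finite(grand) || grand <= 0) {
    stop("grand mean must be positive", call. = FALSE)
  }
  as.integer(round(100 * mdc95 / grand))
}

#' Fraction of participants able to improve by the MDC
#'
#' A participant can show measurable improvement when their score can drop
#' by the MDC without crossing 0, the best possible score; i.e. when
#' `score - mdc95 >= 0`. Reports the fraction and count, a ceiling-effect
#' check on the score's responsiveness.
#'
#' @param scores baseline (test-occasion) scores, >= 0.
#' @param mdc95 minimal detectable change.
#' @return list with `fraction`, `count`, `n`, `percent` (integer).
#' @export
improvable_fraction <- function(scores, mdc95) {
  scores <- scores[is.finite(scores)]
  if (!length(scores)) stop("no scores provided", call. = FALSE)
  if (any(scores < 0)) {
    stop("scores must be >= 0 (0 is the best possible score)", call. = FALSE)
  }
  count <- sum(scores - mdc95 >= 0)
  list(fraction = count / length(scores), count = count,
       n = length(scores),
       percent = as.integer(round(100 * count / length(scores))))
}
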