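#' Rank correlations with two-tailed p values
#'
#' `spearman_rho()` computes Spearman's rho as the Pearson correlation of
#' midranks; `kendall_tau_b()` computes Kendall's tau-b,
#' `\(C - D\) / sqrt((n0 - n1)(n0 - n2))`, with the tie terms `n1`, `n2`
#' over tied groups in either margin — the tie-corrected variant suited to
#' ordinal comparators (SCALE, GMFCS, therapist counts) where ties are the
#' rule. Missing pairs are dropped pairwise. Two-tailed p values come from
#' [stats::cor.test()] with the matching method.
#'
#' @param x,y paired numeric vectors.
#' @return object of class `correlation_result`: list with `coefficient`,
#'   `p`, `n`, `method`, `band` (magnitude label, see
#'   [classify_correlation()]).
#' @examples
#' kendall_tau_b(c(1, 2, 3, 4), c(1, 3, 2, 4))$coefficient  # 2/3
#' @export
spearman_rho <- function(x, y) {
  d <- complete_pairs(x, y)
  rho <- stats::cor(rank(d$x), rank(d$y))
  p <- suppressWarnings(
    stats::cor.test(d$x, d$y, method = "spearman", exact = FALSE)$p.value)
  correlation_result(rho, p, nrow(d), "spearman")
}

#' @rdname spearman_rho
#' @export
kendall_tau_b <- function(x, y) {
  d <- complete_pairs(x, y)
  n <- nrow(d)
  conc <- disc <- 0
  for (i in seq_len(n - 1L)) {
    dx <- d$x[(i + 1L):n] - d$x[i]
    dy <- d$y[(i + 1L):n] - d$y[i]
    s <- sign(dx) * sign(dy)
    conc <- conc + sum(s > 0)
    disc <- disc + sum(s < 0)
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_term(d$x); n2 <- tie_term(d$y)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) {
    stop("zero variance in a margin: tau-b undefined", call. = FALSE)
  }
  tau <- (conc - disc) / denom
  p <- suppressWarnings(
    stats::cor.test(d$x, d$y, method = "kendall", exact = FALSE)$p.value)
  correlation_result(tau, p, n, "kendall_tau_b")
}

complete_pairs <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  d <- data.frame(x = x[keep], y = y[keep])
  if (nrow(d) < 4L) {
    stop("need at least 4 complete pairs", call. = FALSE)
  }
  if (stats::sd(d$x) == 0 || stats::sd(d$y) == 0) {
    stop("zero variance in x or y: correlation undefined", call. = FALSE)
  }
  d
}

correlation_result <- function(coefficient, p, n, method) {
  structure(
    list(coefficient = unname(coefficient), p = unname(p), n = n,
         method = method, band = classify_correlation(coefficient)),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<%s> r = %.2f (%s), p = %.3g, n = %d\n",
              x$method, x$coefficient, x$band, x$p, x$n))
  invisible(x)
}

#' Interpretation bands for correlations and ICCs
#'
#' Correlation magnitudes are labelled negligible (0.00-0.29), low
#' (0.30-0.49), moderate (0.50-0.69), high (0.70-0.89) or very high
#' (>= 0.90). ICCs are labelled poor (< 0.50), moderate (0.50-0.75), good
#' (0.75-0.90) or excellent (> 0.90); when a CI is supplied the bands of
#' its bounds are reported too, since reliability is judged on the ICC
#' together with its CI.
#'
#' @param r correlation coefficient, `|r| <= 1`.
#' @return band label string.
#' @examples
#' classify_correlation(0.56)  # "moderate"
#' classify_icc(0.86)$band     # "good"
#' @export
classify_correlation <- function(r) {
  stopifnot(is.finite(r), abs(r) <= 1)
  a <- abs(r)
  if (a < 0.30) "negligible"
  else if (a < 0.50) "low"
  else if (a < 0.70) "moderate"
  else if (a < 0.90) "high"
  else "very high"
}

#' @rdname classify_correlation
#' @param icc intraclass correlation in \[0, 1\].
#' @param ci optional `(lo, hi)` confidence bounds.
#' @export
classify_icc <- function(icc, ci = NULL) {
  stopifnot(is.finite(icc), icc >= 0, icc <= 1)
  band1 <- function(v) {
    if (v < 0.50) "poor"
    else if (v < 0.75) "moderate"
    else if (v < 0.90) "good"
    else "excellent"
  }
  out <- list(band = band1(icc))
  if (!is.null(ci)) {
    out$ci_bands <- c(lo = band1(max(0, ci[1])), hi = band1(min(1, ci[2])))
  }
  out
}

#' Smallest correlation detectable at given power
#'
#' Power analysis of the two-sided test of zero correlation via the Fisher
#' z transformation with small-sample bias term: the noncentrality is
#' `sqrt(n - 3) * (atanh(r) + r / (2 (n - 1)))`, and power is
#' `pnorm(ncp - z[1 - alpha/2]) + pnorm(-ncp - z[1 - alpha/2])`. Returns
#' the smallest `|r|` reaching the target power, rounded to two decimals.
#'
#' @param n sample size (>= 4).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return minimal detectable correlation, 2 decimals.
#' @examples
#' min_detectable_r(20)  # 0.58
#' @export
min_detectable_r <- function(n, alpha = 0.05, power = 0.80) {
  stopifnot(n >= 4, alpha > 0, alpha < 1, power > 0, power < 1)
  za <- stats::qnorm(1 - alpha / 2)
  pow <- function(r) {
    ncp <- sqrt(n - 3) * (atanh(r) + r / (2 * (n - 1)))
    stats::pnorm(ncp - za) + stats::pnorm(-ncp - za)
  }
  if (pow(0.999999) < power) {
    stop("target power unreachable at n = ", n, call. = FALSE)
  }
  r <- stats::uniroot(function(r) pow(r) - power, c(1e-6, 0.999999),
                      tol = 1e-9)$root
  round(r, 2)
}

#' Concurrent-validity correlation table
#'
#' Correlates the two game outcomes with the clinical comparators:
#' Spearman's rho for the leg and total summary scores against the
#' matching SCALE / GMFCS / therapist summaries, producing the standard
#' 5-row (SCALE x accuracy, SCALE x IMS, GMFCS x accuracy, GMFCS x IMS,
#' therapist x IMS) by 3-column (more affected, less affected, total)
#' layout. Joints excluded from the game are excluded from the comparator
#' summaries too before correlating. Cells with fewer than 4 complete
#' pairs are `NA`.
#'
#' @param summaries output of [summary_score_table()] (test occasion).
#' @param ratings ratings data frame (participant_id, occasion, side,
#'   joint, scale, gmfcs, therapist_count), as emitted by
#'   [simulate_cohorts()]; joints excluded from scoring should already be
#'   removed.
#' @param side_maps named list of [affected_side_map()] per participant.
#' @return data frame with comparator, outcome, summary, rho, p, n, band.
#' @export
concurrent_validity_table <- function(summaries, ratings,
                                      side_maps = list()) {
  ratings <- ratings[ratings$occasion == "test", ]
  summaries <- summaries[summaries$occasion == "test", ]
  leg_label <- function(pid, side) {
    sm <- side_maps[[pid]]
    if (is.null(sm)) sm <- affected_side_map("left")
    unname(sm[side])
  }
  ratings$leg <- mapply(leg_label, ratings$participant_id, ratings$side)
  agg <- function(var, fun = mean) {
    per <- lapply(split(ratings, ratings$participant_id), function(d) {
      data.frame(
        participant_id = d$participant_id[1],
        more = fun(d[[var]][d$leg == "more_affected"]),
        less = fun(d[[var]][d$leg == "less_affected"]),
        total = fun(d[[var]]))
    })
    do.call(rbind, per)
  }
  comp <- list(
    scale = agg("scale"),
    gmfcs = agg("gmfcs"),
    therapist = agg("therapist_count"))
  rows <- list(
    c("scale", "accuracy"), c("scale", "ims"),
    c("gmfcs", "accuracy"), c("gmfcs", "ims"),
    c("therapist", "ims"))
  out <- list()
  for (rw in rows) {
    comparator <- rw[1]; outcome <- rw[2]
    for (col in c("more", "less", "total")) {
      game_col <- paste0(outcome, "_", col)
      c_tab <- comp[[comparator]]
      m <- merge(summaries[c("participant_id", game_col)],
                 c_tab[c("participant_id", col)], by = "participant_id")
      res <- tryCatch(spearman_rho(m[[game_col]], m[[col]]),
                      error = function(e) NULL)
      out[[length(out) + 1L]] <- data.frame(
        comparator = comparator, outcome = outcome, summary = col,
        rho = if (is.null(res)) NA_real_ else res$coefficient,
        p = if (is.null(res)) NA_real_ else res$p,
        n = nrow(m),
        band = if (is.null(res)) NA_character_ else res$band)
    }
  }
  do.call(rbind, out)
}

#' Per-joint concurrent validity (tau-b)
#'
#' Kendall tau-b between a per-joint game score and a per-joint comparator
#' rating, for each of the six joints.
#'
#' @param joint_scores per-joint score table from [score_cohort()] (test
#'   occasion), `excluded` rows dropped.
#' @param ratings ratings table as in [concurrent_validity_table()].
#' @param score game score column (`"accuracy"` or `"ims"`).
#' @param rating comparator column (`"scale"` or `"therapist_count"`).
#' @return data frame with side, joint, tau, p, n.
#' @export
joint_validity_table <- function(joint_scores, ratings, score = "ims",
                                 rating = "therapist_count") {
  joint_scores <- joint_scores[joint_scores$occasion == "test" &
                                 !isTRUE_vec(joint_scores$excluded), ]
  ratings <- ratings[ratings$occasion == "test", ]
  m <- merge(joint_scores, ratings,
             by = c("participant_id", "occasion", "side", "joint"))
  out <- list()
  for (s in c("left", "right")) {
    for (j in c("hip", "knee", "ankle")) {
      d <- m[m$side == s & m$joint == j, ]
      res <- tryCatch(kendall_tau_b(d[[score]], d[[rating]]),
                      error = function(e) NULL)
      out[[length(out) + 1L]] <- data.frame(
        side = s, joint = j,
        tau = if (is.null(res)) NA_real_ else res$coefficient,
        p = if (is.null(res)) NA_real_ else res$p,
        n = nrow(d))
    }
  }
  do.call(rbind, out)
}
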