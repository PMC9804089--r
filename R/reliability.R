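#' Full test-retest reliability analysis of one score
#'
#' Computes everything the reliability battery reports for one summary
#' score: ICC(2,1) with a BCa bootstrap CI (subjects resampled), the
#' trial and residual variance components (negative ANOVA estimates
#' truncated to zero with a warning), SEM and MDC95, the MDC as a
#' percentage of the grand mean, the fraction of participants able to
#' improve by the MDC without crossing 0, and the Wilcoxon signed-rank
#' test for a systematic test-retest shift. Subjects with a missing
#' occasion are excluded listwise.
#'
#' @param scores n x 2 matrix or data frame (columns test, retest).
#' @param B bootstrap replicates for the ICC CI.
#' @param level CI level.
#' @param seed integer seed.
#' @return object of class `reliability_result`.
#' @export
reliability_analysis <- function(scores, B = 1000, level = 0.95, seed = 1) {
  m <- as.matrix(scores)
  stopifnot(ncol(m) == 2L)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  fit <- icc_2_1(m)
  ci <- bca_ci(m, function(d) icc_2_1(d)$icc, B = B, level = level,
               seed = seed)
  outside <- fit$icc < ci$lo || fit$icc > ci$hi
  if (outside) {
    warning("ICC point estimate lies outside its BCa interval ",
            "(possible with strong bias correction at small n)",
            call. = FALSE)
  }
  comp <- truncate_components(c(fit$sigma2_t, fit$sigma2_e))
  sm <- sem_mdc(comp[1], comp[2])
  means <- colMeans(m)
  mdc_pct <- mdc_percent_grand_mean(means[1], means[2], sm[["mdc95"]])
  # scores marginally below 0 (possible for the involuntary-movement
  # score) are already at the theoretical best and cannot improve; clamp
  # for the ceiling analysis without changing any count
  improv <- improvable_fraction(pmax(m[, 1], 0), sm[["mdc95"]])
  wil <- wilcoxon_signed_rank(m[, 1], m[, 2])
  structure(
    list(icc = fit$icc, icc_ci = c(lo = ci$lo, hi = ci$hi),
         icc_band = classify_icc(min(1, max(0, fit$icc)),
                                 c(ci$lo, ci$hi)),
         ci_outside_flag = outside,
         sigma2_subject = fit$sigma2_subject,
         sigma2_t = comp[1], sigma2_e = comp[2],
         sem = sm[["sem"]], mdc95 = sm[["mdc95"]],
         mdc_pct_grand_mean = mdc_pct,
         mean_test = unname(means[1]), mean_retest = unname(means[2]),
         improvable = improv,
         wilcoxon_p = wil$p,
         n_subjects = nrow(m), n_boot = B),
    class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> n = %d subjects, %d bootstrap reps\n",
              x$n_subjects, x$n_boot))
  cat(sprintf("  ICC(2,1) = %.2f (%.2f-%.2f), %s\n", x$icc,
              x$icc_ci[["lo"]], x$icc_ci[["hi"]], x$icc_band$band))
  cat(sprintf("  SEM = %.3f, MDC95 = %.2f (%d%% of grand mean)\n",
              x$sem, x$mdc95, x$mdc_pct_grand_mean))
  cat(sprintf("  Wilcoxon test-retest p = %.2f; improvable: %d/%d (%d%%)\n",
              x$wilcoxon_p, x$improvable$count, x$improvable$n,
              x$improvable$percent))
  invisible(x)
}

#' Reliability table over the six summary scores
#'
#' Runs [reliability_analysis()] for each of the six summary scores
#' (accuracy and involuntary movement x more-affected / less-affected /
#' total), matching test and retest rows per participant.
#'
#' @param summaries output of [summary_score_table()] containing both
#'   occasions.
#' @param B,level,seed passed to [reliability_analysis()].
#' @return data frame with one row per score: mean_test, mean_retest,
#'   wilcoxon_p, icc, ci bounds, sem, mdc95, mdc_pct, improvable counts.
#' @export
reliability_table <- function(summaries, B = 1000, level = 0.95, seed = 1) {
  cols <- c("accuracy_more", "ims_more", "accuracy_less", "ims_less",
            "accuracy_total", "ims_total")
  test <- summaries[summaries$occasion == "test", ]
  retest <- summaries[summaries$occasion == "retest", ]
  m <- merge(test, retest, by = "participant_id",
             suffixes = c("_t1", "_t2"))
  rows <- lapply(cols, function(col) {
    sc <- cbind(m[[paste0(col, "_t1")]], m[[paste0(col, "_t2")]])
    r <- reliability_analysis(sc, B = B, level = level, seed = seed)
    data.frame(score = col, n = r$n_subjects,
               mean_test = r$mean_test, mean_retest = r$mean_retest,
               wilcoxon_p = r$wilcoxon_p, icc = r$icc,
               icc_lo = r$icc_ci[["lo"]], icc_hi = r$icc_ci[["hi"]],
               band = r$icc_band$band, sem = r$sem, mdc95 = r$mdc95,
               mdc_pct = r$mdc_pct_grand_mean,
               improvable_pct = r$improvable$percent)
  })
  do.call(rbind, rows)
}
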