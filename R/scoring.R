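#' Estimate a joint angle from a proximal/distal sensor pair
#'
#' Movements in the game are slow, seated, single-joint movements, so each
#' accelerometer is treated as a quasi-static gravity sensor. Acceleration
#' channels are low-pass filtered (4th-order Butterworth, 1.5 Hz cutoff,
#' applied forward and backward for zero phase), the sagittal inclination
#' of each sensor is `atan2(a_x, -a_z)` in degrees, and the joint angle is
#' the distal inclination minus the proximal (reference) inclination, so
#' that whole-segment compensatory motion that moves both sensors together
#' cancels out.
#'
#' Samples where the filtered total acceleration of either sensor stays
#' below 0.3 g are unreliable for inclination; they are flagged in the
#' `low_g` attribute and a warning is emitted.
#'
#' @param trace a [sensor_pair_trace()] with gaps already imputed
#'   (see [impute_missing()]).
#' @param lowpass_hz filter cutoff in Hz (`NA` disables filtering).
#' @return object of class `angle_trace`: list with `joint`, `angles`
#'   (degrees), `sampling_rate`.
#' @export
estimate_joint_angle <- function(trace, lowpass_hz = 1.5) {
  stopifnot(inherits(trace, "assess_trace"))
  if (any(trace$missing_proximal) || any(trace$missing_distal)) {
    stop("trace still contains missing samples; run impute_missing() first",
         call. = FALSE)
  }
  filt <- function(m) {
    if (is.na(lowpass_hz)) return(m)
    ny <- trace$sampling_rate / 2
    if (lowpass_hz >= ny) return(m)
    bf <- signal::butter(4, lowpass_hz / ny, type = "low")
    apply(m, 2, function(col) signal::filtfilt(bf, col))
  }
  p <- filt(trace$proximal)
  d <- filt(trace$distal)
  low_g <- sqrt(rowSums(p^2)) < 0.3 | sqrt(rowSums(d^2)) < 0.3
  if (mean(low_g) > 0.02) {
    warning("joint ", trace$joint, ": ", round(100 * mean(low_g), 1),
            "% of samples have near-zero total acceleration (< 0.3 g); ",
            "inclination estimates there are unreliable", call. = FALSE)
  }
  incl <- function(m) atan2(m[, "x"], -m[, "z"]) * 180 / pi
  ang <- incl(d) - incl(p)
  # principal value: a hip/knee/ankle angle never legitimately wraps
  ang <- ((ang + 180) %% 360) - 180
  structure(
    list(joint = trace$joint, angles = ang,
         sampling_rate = trace$sampling_rate),
    class = "angle_trace", low_g = low_g
  )
}

#' Angular joint speed
#'
#' First time derivative of the joint angle, degrees/second, by forward
#' differences with the last value repeated so speeds align sample-wise
#' with angles.
#'
#' @param angle an `angle_trace` (or numeric vector of angles in degrees,
#'   with `sampling_rate` given).
#' @param sampling_rate Hz; taken from the trace when `angle` is an
#'   `angle_trace`.
#' @return numeric vector of speeds, same length as the angles.
#' @export
angular_speed <- function(angle, sampling_rate = NULL) {
  if (inherits(angle, "angle_trace")) {
    sampling_rate <- angle$sampling_rate
    angle <- angle$angles
  }
  stopifnot(is.numeric(angle), all(is.finite(angle)),
            is.numeric(sampling_rate))
  if (length(angle) < 2L) return(rep(0, length(angle)))
  v <- diff(angle) * sampling_rate
  c(v, v[length(v)])
}

#' Tracking error of the avatar against the target path
#'
#' Root-mean-square error between the avatar position steered by the
#' participant and the target path over the 30 s test phase, in normalized
#' screen units. The accommodation phase never enters the error.
#'
#' @param avatar normalized avatar positions over the test phase.
#' @param path an [target_path()] (or numeric vector of target positions of
#'   the same length).
#' @return RMSE in screen units (>= 0).
#' @export
tracking_error <- function(avatar, path) {
  target <- if (inherits(path, "assess_path")) path$positions else path
  if (length(avatar) != length(target)) {
    stop("avatar and target path differ in length after alignment (",
         length(avatar), " vs ", length(target), ")", call. = FALSE)
  }
  sqrt(mean((avatar - target)^2))
}

#' Movement metric of a non-target joint
#'
#' Summarizes how much a non-target joint moved during the test phase:
#' the mean absolute angular speed in degrees/second. Joints that should
#' stay still score near the resting fidget level; involuntary co-movement
#' raises the metric.
#'
#' @param speeds angular speeds (deg/s) over the test phase.
#' @return mean absolute speed, deg/s.
#' @export
movement_metric <- function(speeds) {
  stopifnot(is.numeric(speeds), length(speeds) > 0L)
  mean(abs(speeds))
}

test_phase_index <- function(session) {
  t <- trace_times(session)
  t >= session$accommodation_duration - 1e-9
}

#' Raw per-session measurements
#'
#' Runs the measurement chain for one session: imputes gaps per joint,
#' estimates angles and speeds, and returns the tracking error of the
#' target joint plus the movement metric of every non-target joint
#' (keyed relative to the target, e.g. `"contra_knee"`). Joints flagged
#' untestable (>= 20% missing) are reported in `excluded`.
#'
#' @param session a [game_session()].
#' @param seed seed for the imputation draws.
#' @param lowpass_hz low-pass cutoff passed to [estimate_joint_angle()].
#' @return list with `error`, `metrics` (named numeric), `context`
#'   (target joint name), `target_joint`, `excluded` (character joint ids),
#'   `participant_id`, `occasion`.
#' @export
session_metrics <- function(session, seed = 1, lowpass_hz = 1.5) {
  stopifnot(inherits(session, "game_session"))
  in_test <- test_phase_index(session)
  metrics <- numeric(0)
  excluded <- character(0)
  target_ok <- TRUE
  for (j in all_joints()) {
    tr <- tryCatch(
      impute_missing(session$traces[[j]], seed = seed),
      untestable_joint_error = function(e) e
    )
    if (inherits(tr, "untestable_joint_error")) {
      excluded <- c(excluded, j)
      if (j == session$target_joint) target_ok <- FALSE
      next
    }
    ang <- estimate_joint_angle(tr, lowpass_hz = lowpass_hz)
    if (j != session$target_joint) {
      sp <- angular_speed(ang)[in_test]
      metrics[relative_joint(j, session$target_joint)] <- movement_metric(sp)
    }
  }
  err <- if (target_ok) tracking_error(session$avatar, session$path) else NA_real_
  list(
    participant_id = session$participant_id, occasion = session$occasion,
    target_joint = session$target_joint,
    context = joint_name(session$target_joint),
    error = err, metrics = metrics, excluded = excluded
  )
}

#' Adult reference statistics
#'
#' The raw game measurements are standardized against a cohort of
#' neurologically intact adults representing movement mastery. For each
#' target-joint context (hip, knee, ankle; left and right targets pooled by
#' mirroring) the reference holds the mean and SD (denominator n-1) of the
#' adult tracking error, and per non-target joint (relative to the target)
#' the mean and SD of the adult movement metric.
#'
#' @param metrics_list list of [session_metrics()] results from the adult
#'   cohort.
#' @return object of class `reference_stats`.
#' @export
build_reference <- function(metrics_list) {
  contexts <- c("hip", "knee", "ankle")
  by_ctx <- split(metrics_list,
                  vapply(metrics_list, `[[`, character(1), "context"))
  if (!all(contexts %in% names(by_ctx))) {
    stop("adult cohort must cover all three target-joint contexts; missing: ",
         paste(setdiff(contexts, names(by_ctx)), collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(vapply(metrics_list, `[[`, character(1), "participant_id"))
  ref <- lapply(by_ctx[contexts], function(ms) {
    errs <- vapply(ms, `[[`, numeric(1), "error")
    errs <- errs[is.finite(errs)]
    if (length(errs) < 3L) {
      stop("need at least 3 adults per target-joint context", call. = FALSE)
    }
    rels <- sort(unique(unlist(lapply(ms, function(m) names(m$metrics)))))
    movement <- do.call(rbind, lapply(rels, function(r) {
      v <- unlist(lapply(ms, function(m) m$metrics[r]))
      v <- v[is.finite(v)]
      data.frame(rel_joint = r, mu = mean(v), sd = stats::sd(v),
                 n = length(v))
    }))
    out <- list(mu_err = mean(errs), sd_err = stats::sd(errs),
                n_err = length(errs), movement = movement)
    if (out$sd_err <= 0 || any(movement$sd <= 0)) {
      stop("degenerate reference: zero adult SD in some cell (identical ",
           "adults cannot define a standardization scale)", call. = FALSE)
    }
    out
  })
  structure(list(contexts = ref, n_adults = length(ids)),
            class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat("<reference_stats> adult cohort n =", x$n_adults, "\n")
  for (ctx in names(x$contexts)) {
    c_ <- x$contexts[[ctx]]
    cat(sprintf("  %-5s error mu=%.4f sd=%.4f; %d movement cells\n",
                ctx, c_$mu_err, c_$sd_err, nrow(c_$movement)))
  }
  invisible(x)
}

#' Write / read reference statistics as JSON
#' @param ref a `reference_stats` object.
#' @param path JSON file path.
#' @return `read_reference()` returns a `reference_stats` object.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "reference_stats"))
  jsonlite::write_json(unclass(ref), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$contexts <- lapply(x$contexts, function(c_) {
    c_$movement <- as.data.frame(c_$movement)
    c_
  })
  structure(x, class = "reference_stats")
}

#' Accuracy score
#'
#' The tracking error expressed in adult SD units: `error / sd_adult` for
#' the matching target-joint context. The score is standardized to the
#' adult SD but not centred, so 0 means a perfect trace and larger values
#' mean worse accuracy. Set `centered = TRUE` for the centred variant
#' `(error - mu_adult) / sd_adult`.
#'
#' @param error tracking error from [tracking_error()].
#' @param ref a `reference_stats` object.
#' @param context `"hip"`, `"knee"` or `"ankle"`.
#' @param centered centre at the adult mean before scaling.
#' @return score in adult SD units.
#' @export
accuracy_score <- function(error, ref, context, centered = FALSE) {
  stopifnot(inherits(ref, "reference_stats"))
  c_ <- ref$contexts[[match.arg(context, c("hip", "knee", "ankle"))]]
  if (c_$sd_err <= 0) stop("degenerate reference: sd_err <= 0", call. = FALSE)
  if (centered) (error - c_$mu_err) / c_$sd_err else error / c_$sd_err
}

#' Involuntary movement score
#'
#' The average standardized excess movement of the five non-target joints:
#' mean over joints of `(metric - mu_adult) / sd_adult`, in adult SD units.
#' 0 means adult-like stillness of the non-target joints; the score is not
#' clipped, so values below 0 (stiller than the average adult) can occur.
#'
#' @param metrics named numeric vector of movement metrics keyed by
#'   relative joint (as produced by [session_metrics()]).
#' @param ref a `reference_stats` object.
#' @param context target-joint context.
#' @return score in adult SD units.
#' @export
involuntary_movement_score <- function(metrics, ref, context) {
  stopifnot(inherits(ref, "reference_stats"))
  c_ <- ref$contexts[[match.arg(context, c("hip", "knee", "ankle"))]]
  mov <- c_$movement
  idx <- match(names(metrics), mov$rel_joint)
  if (anyNA(idx)) {
    stop("reference has no cell for joint(s): ",
         paste(names(metrics)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (any(mov$sd[idx] <= 0)) {
    stop("degenerate reference: zero movement SD", call. = FALSE)
  }
  mean((metrics - mov$mu[idx]) / mov$sd[idx])
}

#' Score one session against the adult reference
#'
#' @param session a [game_session()].
#' @param ref a `reference_stats` object.
#' @param seed imputation seed.
#' @param centered_accuracy use the centred accuracy variant.
#' @param lowpass_hz low-pass cutoff passed to [estimate_joint_angle()];
#'   must match the cutoff the reference was built with.
#' @return one-row data frame: participant_id, occasion, side, joint,
#'   accuracy, ims, excluded (TRUE when the target joint was untestable).
#' @export
score_session <- function(session, ref, seed = 1, centered_accuracy = FALSE,
                          lowpass_hz = 1.5) {
  m <- session_metrics(session, seed = seed, lowpass_hz = lowpass_hz)
  excluded <- session$target_joint %in% m$excluded
  acc <- ims <- NA_real_
  if (!excluded) {
    acc <- accuracy_score(m$error, ref, m$context,
                          centered = centered_accuracy)
    ims <- involuntary_movement_score(m$metrics, ref, m$context)
  }
  data.frame(
    participant_id = m$participant_id, occasion = m$occasion,
    side = joint_side(session$target_joint),
    joint = joint_name(session$target_joint),
    accuracy = acc, ims = ims, excluded = excluded
  )
}

#' Summarize per-joint scores into leg and total means
#'
#' Computes the summary scores used in all downstream analyses: the mean
#' over the joints of the more-affected leg, of the less-affected leg, and
#' over all testable joints. Excluded joints (e.g. ROM below 10 degrees, or
#' untestable sensor data) are dropped from every mean; if all joints of a
#' leg are excluded that summary is `NA`.
#'
#' @param joint_scores data frame with columns `side`, `joint`, and a score
#'   column; rows with `excluded == TRUE` or `NA` scores are dropped.
#' @param side_map an [affected_side_map()].
#' @param score column name to summarize (`"accuracy"` or `"ims"`).
#' @return named numeric: `more_affected`, `less_affected`, `total`.
#' @export
summarize_scores <- function(joint_scores, side_map, score = "accuracy") {
  stopifnot(score %in% names(joint_scores))
  keep <- !isTRUE_vec(joint_scores$excluded) & is.finite(joint_scores[[score]])
  d <- joint_scores[keep, ]
  if (!nrow(d)) {
    stop("no testable joints: cannot form any summary score", call. = FALSE)
  }
  leg <- function(label) {
    sides <- names(side_map)[side_map == label]
    v <- d[[score]][d$side %in% sides]
    if (!length(v)) NA_real_ else mean(v)
  }
  c(more_affected = leg("more_affected"),
    less_affected = leg("less_affected"),
    total = mean(d[[score]]))
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & x
}

#' Score a set of sessions and build the per-participant score table
#'
#' @param sessions list of [game_session()] objects.
#' @param ref a `reference_stats` object.
#' @param seed imputation seed.
#' @param centered_accuracy use the centred accuracy variant.
#' @return data frame of per-joint scores (one row per session).
#' @export
score_cohort <- function(sessions, ref, seed = 1,
                         centered_accuracy = FALSE, lowpass_hz = 1.5) {
  do.call(rbind, lapply(sessions, score_session, ref = ref, seed = seed,
                        centered_accuracy = centered_accuracy,
                        lowpass_hz = lowpass_hz))
}

#' Summary-score table for a scored cohort
#'
#' Collapses a per-joint score table into one row per participant and
#' occasion with the more-affected, less-affected and total means of both
#' scores.
#'
#' @param joint_scores output of [score_cohort()].
#' @param side_maps named list of [affected_side_map()] per participant id;
#'   participants not listed default to `"left"` more affected.
#' @return data frame: participant_id, occasion, then
#'   `accuracy_more/less/total` and `ims_more/less/total`.
#' @export
summary_score_table <- function(joint_scores, side_maps = list()) {
  keys <- unique(joint_scores[c("participant_id", "occasion")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    pid <- keys$participant_id[i]; occ <- keys$occasion[i]
    d <- joint_scores[joint_scores$participant_id == pid &
                        joint_scores$occasion == occ, ]
    sm <- side_maps[[pid]]
    if (is.null(sm)) sm <- affected_side_map("left")
    a <- summarize_scores(d, sm, "accuracy")
    m <- summarize_scores(d, sm, "ims")
    data.frame(participant_id = pid, occasion = occ,
               accuracy_more = a[["more_affected"]],
               accuracy_less = a[["less_affected"]],
               accuracy_total = a[["total"]],
               ims_more = m[["more_affected"]],
               ims_less = m[["less_affected"]],
               ims_total = m[["total"]])
  })
  do.call(rbind, rows)
}
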