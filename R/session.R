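#' Joint calibration record
#'
#' Before each trial the game is calibrated to the participant's maximum
#' active range of motion (ROM) of the target joint; during play only the
#' central `usable_fraction` (default 90%) of that ROM is used. Joints with
#' an active ROM below 10 degrees cannot be tested and are rejected.
#'
#' @param joint target joint id (see [joint_id()]).
#' @param angle_min,angle_max active ROM limits in degrees.
#' @param usable_fraction fraction of the ROM used by the game, in (0, 1].
#' @return an object of class `assess_calibration`.
#' @export
calibration <- function(joint, angle_min, angle_max, usable_fraction = 0.9) {
  assert_joint_id(joint)
  stopifnot(is.numeric(angle_min), is.numeric(angle_max),
            is.numeric(usable_fraction), length(usable_fraction) == 1L)
  if (!(usable_fraction > 0 && usable_fraction <= 1)) {
    stop("usable_fraction must be in (0, 1]", call. = FALSE)
  }
  if (angle_max - angle_min < 10) {
    stop("active ROM of joint ", joint, " is ", angle_max - angle_min,
         " degrees; joints with an active ROM below 10 degrees cannot be ",
         "tested", call. = FALSE)
  }
  structure(
    list(joint = joint, angle_min = angle_min, angle_max = angle_max,
         usable_fraction = usable_fraction),
    class = "assess_calibration"
  )
}

#' Target path of one game trial
#'
#' The star-studded target trajectory the avatar has to follow during the
#' 30 s test phase: a smooth curve of normalized screen heights in \[0, 1\]
#' (0 = bottom of the screen) containing both upward and downward segments.
#'
#' @param time_s sample times in seconds, starting at 0.
#' @param positions normalized screen heights in \[0, 1\], same length as
#'   `time_s`.
#' @param star_times times (s) at which stars sit on the path.
#' @return an object of class `assess_path` with fields `time_s`,
#'   `positions`, `star_times`, `duration` and `sampling_rate`.
#' @export
target_path <- function(time_s, positions, star_times = numeric()) {
  stopifnot(length(time_s) == length(positions), length(time_s) >= 3L)
  if (any(!is.finite(positions)) || min(positions) < 0 || max(positions) > 1) {
    stop("path positions must be finite and within [0, 1]", call. = FALSE)
  }
  d <- diff(positions)
  if (!(any(d > 0) && any(d < 0))) {
    stop("target path must contain both upward and downward curves",
         call. = FALSE)
  }
  structure(
    list(time_s = time_s, positions = positions, star_times = star_times,
         duration = max(time_s) - min(time_s),
         sampling_rate = 1 / stats::median(diff(time_s))),
    class = "assess_path"
  )
}

#' Proximal/distal accelerometer pair for one joint
#'
#' Each joint is instrumented with two 3-axis accelerometers, one proximal
#' (the reference sensor) and one distal of the joint, so that the joint
#' angle can be computed as a difference of segment inclinations and
#' whole-body compensatory movement cancels out.
#'
#' @param joint joint id.
#' @param proximal,distal numeric n x 3 matrices (columns x, y, z) of
#'   acceleration in g units.
#' @param sampling_rate sampling rate in Hz.
#' @param missing_proximal,missing_distal logical vectors of length n
#'   flagging samples lost to sensor dropouts (whole sensor missing).
#' @return an object of class `assess_trace`.
#' @export
sensor_pair_trace <- function(joint, proximal, distal, sampling_rate,
                              missing_proximal = NULL, missing_distal = NULL) {
  assert_joint_id(joint)
  proximal <- as.matrix(proximal); distal <- as.matrix(distal)
  if (ncol(proximal) != 3L || ncol(distal) != 3L) {
    stop("sensor traces must have 3 axis columns (x, y, z)", call. = FALSE)
  }
  n <- nrow(proximal)
  if (nrow(distal) != n) {
    stop("proximal and distal traces of joint ", joint,
         " differ in length (", n, " vs ", nrow(distal), ")", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be > 0", call. = FALSE)
  }
  if (is.null(missing_proximal)) missing_proximal <- rep(FALSE, n)
  if (is.null(missing_distal)) missing_distal <- rep(FALSE, n)
  stopifnot(length(missing_proximal) == n, length(missing_distal) == n)
  frac <- mean(missing_proximal | missing_distal)
  if (frac >= 1) {
    stop("all samples of joint ", joint, " are flagged missing", call. = FALSE)
  }
  colnames(proximal) <- colnames(distal) <- c("x", "y", "z")
  structure(
    list(joint = joint, proximal = proximal, distal = distal,
         sampling_rate = sampling_rate,
         missing_proximal = as.logical(missing_proximal),
         missing_distal = as.logical(missing_distal),
         missing_fraction = frac),
    class = "assess_trace"
  )
}

#' One assessment-game trial
#'
#' A `game_session` bundles everything recorded during one trial of the
#' game: the selected target joint and its ROM calibration, the target
#' path, the avatar trajectory actually steered by the participant during
#' the test phase, and the six sensor-pair traces covering the 25 s
#' accommodation phase plus the 30 s test phase.
#'
#' @param participant_id participant identifier string.
#' @param occasion `"test"` or `"retest"`.
#' @param target_joint joint id of the trial's target joint.
#' @param calibration an [calibration()] object for the target joint.
#' @param path an [target_path()] object.
#' @param traces named list of six [sensor_pair_trace()] objects, one per
#'   joint id.
#' @param avatar normalized avatar positions over the test phase, same
#'   length as `path$positions`.
#' @param accommodation_duration accommodation-phase length in seconds.
#' @return an object of class `game_session`.
#' @export
game_session <- function(participant_id, occasion, target_joint, calibration,
                         path, traces, avatar, accommodation_duration = 25) {
  occasion <- match.arg(occasion, c("test", "retest"))
  assert_joint_id(target_joint)
  stopifnot(inherits(calibration, "assess_calibration"),
            inherits(path, "assess_path"))
  missing_joints <- setdiff(all_joints(), names(traces))
  if (length(missing_joints)) {
    stop("session is missing sensor pair(s) for joint(s): ",
         paste(missing_joints, collapse = ", "), call. = FALSE)
  }
  for (j in names(traces)) {
    if (!inherits(traces[[j]], "assess_trace") || traces[[j]]$joint != j) {
      stop("trace list entry ", j, " is not a sensor pair trace for ", j,
           call. = FALSE)
    }
  }
  if (calibration$joint != target_joint) {
    stop("calibration is for ", calibration$joint,
         " but target joint is ", target_joint, call. = FALSE)
  }
  if (length(avatar) != length(path$positions)) {
    stop("avatar trace length (", length(avatar),
         ") does not match path length (", length(path$positions), ")",
         call. = FALSE)
  }
  if (any(!is.finite(avatar)) || min(avatar) < 0 || max(avatar) > 1) {
    stop("avatar positions must be finite and within [0, 1]", call. = FALSE)
  }
  rate <- traces[[target_joint]]$sampling_rate
  n_expected <- round((accommodation_duration + path$duration) * rate) + 1L
  for (j in all_joints()) {
    if (nrow(traces[[j]]$proximal) != n_expected) {
      stop("trace for ", j, " has ", nrow(traces[[j]]$proximal),
           " samples but accommodation + test phases require ", n_expected,
           call. = FALSE)
    }
  }
  structure(
    list(participant_id = as.character(participant_id), occasion = occasion,
         target_joint = target_joint, calibration = calibration, path = path,
         traces = traces, avatar = avatar,
         accommodation_duration = accommodation_duration,
         sampling_rate = rate),
    class = "game_session"
  )
}

#' @export
print.game_session <- function(x, ...) {
  cat("<game_session>", x$participant_id, "/", x$occasion,
      "| target:", x$target_joint, "\n")
  cat("  phases:", x$accommodation_duration, "s accommodation +",
      x$path$duration, "s test @", x$sampling_rate, "Hz\n")
  fr <- vapply(x$traces, function(tr) tr$missing_fraction, numeric(1))
  cat("  missing fraction:", sprintf("%.2f%%", 100 * mean(fr)), "\n")
  invisible(x)
}

#' Encode the therapist's involuntary-movement rating
#'
#' During the game a therapist notes which types of involuntary movements
#' occurred at least once: mirror movements, trunk movements, or movements
#' in any other joint. One point is given per observed type, so a fully
#' selective performance scores 0 and a performance showing all three types
#' scores 3.
#'
#' @param observed_types character vector (a set, no duplicates) drawn from
#'   `"mirror"`, `"trunk"`, `"other_joint"`.
#' @return integer count 0-3.
#' @examples
#' encode_therapist_rating(c("mirror", "trunk"))   # 2
#' encode_therapist_rating(character())            # 0
#' @export
encode_therapist_rating <- function(observed_types) {
  valid <- c("mirror", "trunk", "other_joint")
  observed_types <- as.character(observed_types)
  bad <- setdiff(observed_types, valid)
  if (length(bad)) {
    stop("unknown involuntary movement type(s): ",
         paste(bad, collapse = ", "), " (expected subset of ",
         paste(valid, collapse = ", "), ")", call. = FALSE)
  }
  if (anyDuplicated(observed_types)) {
    stop("observed_types must be a set (no duplicates)", call. = FALSE)
  }
  length(observed_types)
}

trace_times <- function(session) {
  n <- nrow(session$traces[[1L]]$proximal)
  seq(0, by = 1 / session$sampling_rate, length.out = n)
}

#' Write / read a game session
#'
#' A session is stored as a directory holding a JSON metadata document
#' (`session.json`), the sensor traces in long format (`traces.csv`:
#' `time_s, side, joint, sensor, axis, value_g, missing`), and the target
#' path and avatar trajectory (`path.csv`, `avatar.csv`: `time_s,
#' position`). The representation is plain text and language neutral;
#' write -> read round-trips a session exactly up to float formatting.
#'
#' @param session a [game_session()].
#' @param path directory to write to (created if needed) / read from.
#' @return `read_session()` returns a [game_session()];
#'   `write_session()` returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "game_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    participant_id = session$participant_id,
    occasion = session$occasion,
    target_joint = session$target_joint,
    calibration = session$calibration[c("joint", "angle_min", "angle_max",
                                        "usable_fraction")],
    accommodation_duration = session$accommodation_duration,
    test_duration = session$path$duration,
    sampling_rate = session$sampling_rate,
    star_times = session$path$star_times
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  t <- trace_times(session)
  rows <- lapply(all_joints(), function(j) {
    tr <- session$traces[[j]]
    side <- joint_side(j); name <- joint_name(j)
    do.call(rbind, lapply(c("proximal", "distal"), function(sensor) {
      m <- tr[[sensor]]
      miss <- tr[[paste0("missing_", sensor)]]
      data.frame(
        time_s = rep(t, 3L), side = side, joint = name, sensor = sensor,
        axis = rep(c("x", "y", "z"), each = length(t)),
        value_g = c(m[, "x"], m[, "y"], m[, "z"]),
        missing = rep(as.integer(miss), 3L)
      )
    }))
  })
  utils::write.csv(do.call(rbind, rows), file.path(path, "traces.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(time_s = session$path$time_s,
               position = session$path$positions),
    file.path(path, "path.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(time_s = session$path$time_s, position = session$avatar),
    file.path(path, "avatar.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "session.json")
  if (!file.exists(meta_file)) {
    stop("no session.json found in ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (field in c("participant_id", "occasion", "target_joint",
                  "calibration", "accommodation_duration", "test_duration",
                  "sampling_rate")) {
    if (is.null(meta[[field]])) {
      stop("session.json is missing required field '", field, "'",
           call. = FALSE)
    }
  }
  traces_df <- utils::read.csv(file.path(path, "traces.csv"),
                               stringsAsFactors = FALSE)
  need <- c("time_s", "side", "joint", "sensor", "axis", "value_g", "missing")
  if (!all(need %in% names(traces_df))) {
    stop("traces.csv is missing column(s): ",
         paste(setdiff(need, names(traces_df)), collapse = ", "),
         call. = FALSE)
  }
  traces <- list()
  for (j in all_joints()) {
    sub <- traces_df[traces_df$side == joint_side(j) &
                       traces_df$joint == joint_name(j), ]
    if (!nrow(sub)) {
      stop("traces.csv contains no samples for joint ", j, call. = FALSE)
    }
    get_sensor <- function(sensor) {
      s <- sub[sub$sensor == sensor, ]
      s <- s[order(match(s$axis, c("x", "y", "z")), s$time_s), ]
      n <- nrow(s) / 3L
      if (n != floor(n)) {
        stop("traces.csv: joint ", j, " sensor ", sensor,
             " does not have 3 complete axis series", call. = FALSE)
      }
      list(values = matrix(s$value_g, ncol = 3L,
                           dimnames = list(NULL, c("x", "y", "z"))),
           missing = as.logical(s$missing[seq_len(n)]))
    }
    p <- get_sensor("proximal"); d <- get_sensor("distal")
    traces[[j]] <- sensor_pair_trace(
      j, p$values, d$values, meta$sampling_rate,
      missing_proximal = p$missing, missing_distal = d$missing)
  }
  path_df <- utils::read.csv(file.path(path, "path.csv"))
  avatar_df <- utils::read.csv(file.path(path, "avatar.csv"))
  tp <- target_path(path_df$time_s, path_df$position,
                    star_times = as.numeric(unlist(meta$star_times)))
  cal <- calibration(meta$calibration$joint, meta$calibration$angle_min,
                     meta$calibration$angle_max,
                     meta$calibration$usable_fraction)
  game_session(meta$participant_id, meta$occasion, meta$target_joint,
               cal, tp, traces, avatar_df$position,
               accommodation_duration = meta$accommodation_duration)
}
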