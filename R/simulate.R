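#' Simulation configuration
#'
#' Defines the synthetic study: an adult reference cohort, neurologically
#' intact control children, and patients with impaired selective control.
#' Group sizes default to the study design (31 adults, 31 control children,
#' 20 patients). Each participant carries latent impairment parameters:
#'
#' * `sigma_track` — SD of the tracking error of the target joint, in
#'   normalized screen units. Drawn log-normally around group medians
#'   (`adult_track`, `patient_track`); control children interpolate from
#'   `child_track` at age 6 down to the adult level at 18.
#' * `lag` — visuomotor reaction delay in seconds.
#' * coupling gains `c_j` (one per joint, unitless, >= 0) — fraction of the
#'   target joint's excursion leaking into joint `j` when `j` is a
#'   non-target joint. Mirror coupling (contralateral homologue) acts at
#'   full weight, ipsilateral adjacent joints at `w_adjacent`, remaining
#'   joints at `w_other`. Control children's gains decay log-linearly with
#'   age (maturation of selective control). Patients additionally carry a
#'   per-person `severity` factor (log-normal, SD `severity_sdlog`)
#'   multiplying all coupling gains (and, with exponent 1/2, the tracking
#'   noise), reproducing the large between-patient heterogeneity of a
#'   clinical rehabilitation cohort.
#' * `fidget_scale` — resting angular-speed SD in deg/s; adults fidget
#'   too, which gives the reference cells nonzero SDs.
#' * `trunk` — latent trunk involvement; visible to the simulated
#'   therapist but not to the six joint sensors.
#'
#' `occasion_noise` is the SD (on the log scale) of the multiplicative
#' perturbation applied to `sigma_track` and the coupling gains on the
#' retest occasion, producing realistic test-retest variability.
#'
#' @param n_adults,n_controls,n_patients cohort sizes.
#' @param seed integer master seed.
#' @param sampling_rate sensor sampling rate, Hz.
#' @param duration,accommodation_duration test / accommodation phase
#'   lengths in seconds.
#' @param adult_track,child_track,patient_track median tracking-noise SD
#'   (screen units) for adults, 6-year-old controls, patients.
#' @param track_sdlog log-scale spread of `sigma_track` across children.
#' @param adult_track_sdlog log-scale spread of `sigma_track` across the
#'   adult reference cohort; ages 18-50 span a wide range of gaming and
#'   tracking skill, and this heterogeneity sets the width of the
#'   standardization denominator.
#' @param adult_couple,child_couple,patient_couple median coupling gains.
#' @param couple_sdlog log-scale spread of coupling gains across joints
#'   within a person.
#' @param severity_sdlog log-scale spread of the per-person severity
#'   factor of patients.
#' @param maturation_rate exponential decay rate (per year) of control
#'   children's coupling and tracking noise with age.
#' @param more_affected_factor multiplier on coupling gains of the
#'   more-affected side of patients.
#' @param w_adjacent,w_other coupling weights of ipsilateral adjacent and
#'   remaining non-target joints (mirror weight is 1).
#' @param fidget_sd median resting angular-speed SD, deg/s.
#' @param fidget_sdlog log-scale spread of `fidget_scale`.
#' @param sensor_noise accelerometer white-noise SD, g.
#' @param missing_rate expected fraction of samples lost per sensor.
#' @param occasion_noise test-retest log-scale perturbation SD.
#' @param n_occasions occasions for patients (1 = test only, 2 adds a
#'   retest); adults and controls are measured once.
#' @param rating_noise log-scale SD of the noise applied to the latent
#'   impairment before SCALE/GMFCS thresholding; clinical scales measure a
#'   related but distinct construct (strength, gross function), so their
#'   agreement with the game scores is deliberately imperfect.
#' @param therapist_jitter log-scale SD of the per-trial jitter on the
#'   involuntary-movement drivers seen by the simulated therapist.
#' @param scale_thresholds,gmfcs_thresholds,therapist_threshold thresholds
#'   applied to latent impairment when deriving the synthetic clinical
#'   ratings (see [simulate_cohorts()]).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(
    n_adults = 31, n_controls = 31, n_patients = 20, seed = 1,
    sampling_rate = 50, duration = 30, accommodation_duration = 25,
    adult_track = 0.030, child_track = 0.040, patient_track = 0.055,
    track_sdlog = 0.35, adult_track_sdlog = 0.75,
    adult_couple = 0.005, child_couple = 0.05, patient_couple = 0.09,
    couple_sdlog = 0.25, severity_sdlog = 0.32, maturation_rate = 0.16,
    more_affected_factor = 1.5,
    w_adjacent = 0.6, w_other = 0.3,
    fidget_sd = 1.0, fidget_sdlog = 0.03,
    sensor_noise = 0.02, missing_rate = 0.008,
    occasion_noise = 0.18, n_occasions = 2,
    rating_noise = 1.0, therapist_jitter = 0.8,
    scale_thresholds = c(normal = 0.05, impaired = 0.245),
    gmfcs_thresholds = c(0.073, 0.11, 0.224, 0.62),
    therapist_threshold = 0.11) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_adults >= 3, cfg$n_controls >= 0, cfg$n_patients >= 0,
            cfg$sampling_rate > 0, cfg$duration > 0,
            all(unlist(cfg[c("adult_track", "child_track", "patient_track",
                             "track_sdlog", "couple_sdlog", "fidget_sd",
                             "sensor_noise", "missing_rate",
                             "occasion_noise")]) >= 0),
            cfg$n_occasions %in% 1:2)
  class(cfg) <- "simulation_config"
  cfg
}

nominal_rom <- function(joint) {
  switch(joint_name(joint),
         hip = c(-10, 60), knee = c(0, 80), ankle = c(-30, 25))
}

# weight of joint j's coupling gain during a trial targeting `target`:
# 1 for the mirror (contralateral homologous) joint, w_adjacent for
# ipsilateral neighbours, w_other for the rest
trial_weight <- function(j, target, cfg) {
  rel <- relative_joint(j, target)
  if (rel == "target") return(0)
  if (rel == paste0("contra_", joint_name(target))) return(1)
  adjacent <- list(hip = "knee", knee = c("hip", "ankle"), ankle = "knee")
  if (startsWith(rel, "ipsi_") &&
      joint_name(j) %in% adjacent[[joint_name(target)]]) {
    return(cfg$w_adjacent)
  }
  cfg$w_other
}

#' Draw the latent impairment parameters of one cohort
#'
#' @param config a [simulation_config()].
#' @return data frame, one row per participant, with group, age, side
#'   labelling and all latent parameters (coupling gains in columns
#'   `c_<joint id>`).
#' @export
draw_latents <- function(config) {
  cfg <- config
  rng <- local_rng(cfg$seed)
  groups <- rep(c("adult", "control", "patient"),
                c(cfg$n_adults, cfg$n_controls, cfg$n_patients))
  n <- length(groups)
  ids <- sprintf("%s%02d", substr(groups, 1, 1),
                 stats::ave(seq_len(n), groups, FUN = seq_along))
  age <- numeric(n); track_med <- numeric(n); couple_med <- numeric(n)
  for (i in seq_len(n)) {
    age[i] <- switch(groups[i],
                     adult = rng$runif(1, 18, 50),
                     control = rng$runif(1, 6, 18),
                     patient = rng$runif(1, 8, 17.5))
    decay <- exp(-cfg$maturation_rate * (age[i] - 6))
    track_med[i] <- switch(groups[i],
      adult = cfg$adult_track,
      control = cfg$adult_track + (cfg$child_track - cfg$adult_track) * decay,
      patient = cfg$patient_track)
    couple_med[i] <- switch(groups[i],
      adult = cfg$adult_couple,
      control = cfg$adult_couple +
        (cfg$child_couple - cfg$adult_couple) * decay,
      patient = cfg$patient_couple)
  }
  severity <- ifelse(groups == "patient",
                     rng$rlnorm(n, 0, cfg$severity_sdlog), 1)
  couple_med <- couple_med * severity
  track_med <- track_med * sqrt(severity)
  sigma_track <- rng$rlnorm(n, log(track_med),
                            ifelse(groups == "adult",
                                   cfg$adult_track_sdlog, cfg$track_sdlog))
  lag <- rng$runif(n, 0.01, 0.08)
  fidget_scale <- rng$rlnorm(n, log(cfg$fidget_sd), cfg$fidget_sdlog)
  trunk <- rng$rlnorm(n, log(couple_med), cfg$couple_sdlog)
  more_affected <- ifelse(rng$runif(n) < 0.5, "left", "right")
  lat <- data.frame(participant_id = ids, group = groups, age = age,
                    severity = severity, sigma_track = sigma_track,
                    lag = lag, fidget_scale = fidget_scale, trunk = trunk,
                    more_affected = more_affected,
                    stringsAsFactors = FALSE)
  for (j in all_joints()) {
    side_factor <- ifelse(groups == "patient" &
                            joint_side(j) == more_affected,
                          cfg$more_affected_factor, 1)
    lat[[paste0("c_", j)]] <-
      rng$rlnorm(n, log(couple_med * side_factor), cfg$couple_sdlog)
  }
  lat
}

# smooth unit-SD noise: white noise low-pass filtered and rescaled
smooth_noise <- function(n, rate, cutoff_hz, rng) {
  x <- rng$rnorm(n)
  ny <- rate / 2
  if (cutoff_hz < ny) {
    bf <- signal::butter(2, cutoff_hz / ny, type = "low")
    x <- signal::filtfilt(bf, x)
  }
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Simulate one game session
#'
#' The target-joint angle is the inverse screen map of the target path
#' delayed by the participant's lag plus smoothed tracking noise of SD
#' `sigma_track`, clipped to the usable ROM; the avatar trace is the
#' forward map of that angle (so with zero noise and lag the avatar
#' reproduces the path exactly). Every non-target joint moves with its
#' coupling gain times the target excursion (full weight for the mirror
#' joint, reduced for adjacent/other joints, mirrored in sign for the
#' contralateral side) plus resting fidget noise. Angles are converted to
#' proximal/distal accelerometer readings through a pure-gravity sensor
#' model (proximal sensor static, distal inclined by the joint angle) with
#' additive white noise, and samples are dropped in short bursts at the
#' configured missing rate.
#'
#' @param latent one row of [draw_latents()] (list or 1-row data frame).
#' @param target_joint joint id of the trial's target.
#' @param path an [target_path()] for the test phase.
#' @param seed integer seed for this session's noise.
#' @param config a [simulation_config()].
#' @param occasion `"test"` or `"retest"`.
#' @return a [game_session()].
#' @export
simulate_session <- function(latent, target_joint, path, seed, config,
                             occasion = "test") {
  cfg <- config
  latent <- as.list(latent)
  rng <- local_rng(seed)
  rate <- cfg$sampling_rate
  n_test <- length(path$positions)
  n_acc <- round(cfg$accommodation_duration * rate)
  n <- n_acc + n_test

  rom <- nominal_rom(target_joint)
  rom_jitter <- rng$runif(2, 0.95, 1.05)
  mapping <- calibrate_rom(rom[1] * rom_jitter[1], rom[2] * rom_jitter[2],
                           joint = target_joint)

  # accommodation-phase target: a second generated path of the same
  # family, over-generated and truncated (a very short segment need not
  # contain both an upward and a downward curve itself)
  acc_path <- generate_target_path(
    duration = max(cfg$accommodation_duration, 15), n_curves = 3,
    seed = rng$derive_seed(), sampling_rate = rate)
  target_screen <- c(acc_path$positions[seq_len(n_acc)], path$positions)

  lag_k <- round(latent$lag * rate)
  followed <- if (lag_k > 0) {
    c(rep(target_screen[1], lag_k), target_screen[seq_len(n - lag_k)])
  } else target_screen
  noise <- smooth_noise(n, rate, 1.0, rng) * latent$sigma_track
  avatar_screen <- pmin(1, pmax(0, followed + noise))
  angle_target <- map_screen_to_angle(avatar_screen, mapping)
  avatar_full <- map_angle_to_screen(angle_target, mapping)
  # involuntary coupling follows the intended (path-following) movement,
  # not the tracking noise: mirror movements mirror the voluntary drive
  angle_intent <- map_screen_to_angle(pmin(1, pmax(0, followed)), mapping)
  excursion <- angle_intent - mean(angle_intent)

  angles <- list()
  for (j in all_joints()) {
    if (j == target_joint) {
      angles[[j]] <- angle_target
      next
    }
    w <- trial_weight(j, target_joint, cfg)
    gain <- latent[[paste0("c_", j)]] * w
    fidget_speed <- smooth_noise(n, rate, 2.0, rng) * latent$fidget_scale
    fidget_angle <- cumsum(fidget_speed) / rate
    fidget_angle <- fidget_angle - mean(fidget_angle)
    angles[[j]] <- gain * excursion + fidget_angle
  }

  traces <- list()
  for (j in all_joints()) {
    prox_incl <- rep(0, n)
    dist_incl <- prox_incl + angles[[j]]
    to_accel <- function(incl_deg) {
      th <- incl_deg * pi / 180
      cbind(x = sin(th), y = rep(0, n), z = -cos(th)) +
        matrix(rng$rnorm(3 * n, 0, cfg$sensor_noise), ncol = 3)
    }
    prox <- to_accel(prox_incl)
    dist <- to_accel(dist_incl)
    drop_mask <- function() {
      miss <- rep(FALSE, n)
      if (cfg$missing_rate > 0) {
        n_events <- rng$rbinom(1, n, cfg$missing_rate / 3)
        if (n_events > 0) {
          starts <- rng$sample(n, n_events)
          for (s in starts) {
            len <- 1 + rng$rbinom(1, 8, 0.25)
            miss[s:min(n, s + len - 1)] <- TRUE
          }
        }
      }
      miss
    }
    traces[[j]] <- sensor_pair_trace(
      j, prox, dist, rate,
      missing_proximal = drop_mask(), missing_distal = drop_mask())
  }

  game_session(
    participant_id = latent$participant_id %||% "sim",
    occasion = occasion, target_joint = target_joint,
    calibration = mapping$calibration, path = path, traces = traces,
    avatar = avatar_full[(n_acc + 1):n],
    accommodation_duration = cfg$accommodation_duration
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

perturb_latent <- function(latent, occasion_noise, rng) {
  out <- as.list(latent)
  jit <- function(x) x * rng$rlnorm(length(x), 0, occasion_noise)
  out$sigma_track <- jit(out$sigma_track)
  for (j in all_joints()) {
    key <- paste0("c_", j)
    out[[key]] <- jit(out[[key]])
  }
  out
}

#' Simulate a full study dataset
#'
#' Generates sessions for all six target joints for every participant
#' (adults and controls once, patients for `n_occasions` occasions),
#' retains the drawn latent truth, and derives synthetic clinical ratings
#' by thresholding the latent impairment:
#'
#' * SCALE per joint: 2 (normal) below `scale_thresholds["normal"]`,
#'   1 (impaired) below `scale_thresholds["impaired"]`, else 0 (unable),
#'   applied to the joint's coupling gain after log-normal `rating_noise`.
#' * GMFCS: level I-V by thresholding the participant's mean coupling gain
#'   (after `rating_noise`) at `gmfcs_thresholds`.
#' * therapist involuntary-movement count per session: one point per type
#'   (mirror / other joint / trunk) whose jittered latent driver exceeds
#'   `therapist_threshold`.
#'
#' @param config a [simulation_config()].
#' @param keep_sessions keep the generated [game_session()] objects in the
#'   result (set `FALSE` to retain only scores-by-products and truth when
#'   sessions are scored on the fly by the caller).
#' @param session_callback optional function called as
#'   `f(session, latent_row)` on each generated session; when supplied
#'   with `keep_sessions = FALSE`, sessions are processed one by one
#'   without accumulating in memory.
#' @return list with `participants` (latent truth incl. group, age, side
#'   map), `sessions` (named list, possibly empty), `ratings` (per
#'   participant/occasion/joint SCALE + GMFCS + therapist counts), and
#'   `config`.
#' @export
simulate_cohorts <- function(config, keep_sessions = TRUE,
                             session_callback = NULL) {
  cfg <- config
  lat <- draw_latents(cfg)
  rng <- local_rng(cfg$seed + 1)
  sessions <- list()
  ratings <- list()
  for (i in seq_len(nrow(lat))) {
    row <- lat[i, ]
    # clinical ratings are assessed once per participant: SCALE per joint
    # and GMFCS threshold a noisy view of the latent impairment
    # person-level rating bias (strength, cooperation) shared across the
    # six SCALE items, plus item-level noise
    scale_bias <- rng$rlnorm(1, 0, cfg$rating_noise)
    scale_j <- vapply(all_joints(), function(j) {
      scale_from_latent(row[[paste0("c_", j)]] * scale_bias *
                          rng$rlnorm(1, 0, cfg$rating_noise / 2),
                        cfg$scale_thresholds)
    }, integer(1))
    gmfcs_i <- gmfcs_from_latent(
      row, cfg$gmfcs_thresholds, rng$rlnorm(1, 0, cfg$rating_noise))
    occs <- if (row$group == "patient" && cfg$n_occasions == 2) {
      c("test", "retest")
    } else "test"
    for (occ in occs) {
      eff <- if (occ == "retest") {
        perturb_latent(row, cfg$occasion_noise, rng)
      } else as.list(row)
      for (tj in all_joints()) {
        path <- generate_target_path(duration = cfg$duration, n_curves = 3,
                                     seed = rng$derive_seed(),
                                     sampling_rate = cfg$sampling_rate)
        ses <- simulate_session(eff, tj, path, seed = rng$derive_seed(),
                                config = cfg, occasion = occ)
        key <- paste(row$participant_id, occ, tj, sep = ".")
        if (!is.null(session_callback)) session_callback(ses, row)
        if (keep_sessions) sessions[[key]] <- ses

        # therapist rating of this trial
        mirror_j <- contralateral_joint(tj)
        adjacent <- list(hip = "knee", knee = c("hip", "ankle"),
                         ankle = "knee")
        adj_ids <- vapply(adjacent[[joint_name(tj)]], function(nm)
          joint_id(joint_side(tj), nm), character(1))
        jit <- function(x) x * rng$rlnorm(1, 0, cfg$therapist_jitter)
        types <- character(0)
        if (jit(eff[[paste0("c_", mirror_j)]]) > cfg$therapist_threshold) {
          types <- c(types, "mirror")
        }
        adj_gain <- max(vapply(adj_ids, function(a)
          eff[[paste0("c_", a)]] * cfg$w_adjacent, numeric(1)))
        if (jit(adj_gain) > cfg$therapist_threshold) {
          types <- c(types, "other_joint")
        }
        if (jit(row$trunk) > cfg$therapist_threshold) {
          types <- c(types, "trunk")
        }
        ratings[[key]] <- data.frame(
          participant_id = row$participant_id, occasion = occ,
          side = joint_side(tj), joint = joint_name(tj),
          scale = scale_j[[tj]],
          gmfcs = gmfcs_i,
          therapist_count = encode_therapist_rating(types),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(participants = lat, sessions = sessions,
       ratings = do.call(rbind, ratings), config = cfg)
}

scale_from_latent <- function(c_joint, thresholds) {
  if (c_joint < thresholds[["normal"]]) 2L
  else if (c_joint < thresholds[["impaired"]]) 1L
  else 0L
}

gmfcs_from_latent <- function(latent_row, thresholds, noise = 1) {
  u <- mean(unlist(latent_row[paste0("c_", all_joints())])) * noise
  as.integer(findInterval(u, thresholds) + 1L)
}
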