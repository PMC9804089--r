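#' Calibrate the angle-to-screen mapping from a joint's active ROM
#'
#' The game maps joint angle to vertical avatar position. Only the central
#' `usable_fraction` (default 90%) of the participant's maximum active ROM
#' is used, with a symmetric margin on either side: the usable span is
#' `usable_fraction * (angle_max - angle_min)` centred on the ROM midpoint,
#' and its endpoints map to screen positions 0 and 1. Angles outside the
#' usable range clamp to the screen edges. Joints with a ROM below 10
#' degrees cannot be calibrated.
#'
#' @param angle_min,angle_max active ROM limits in degrees
#'   (`angle_max > angle_min`).
#' @param usable_fraction fraction of the ROM used, in (0, 1].
#' @return an object of class `screen_mapping` with fields `angle_lo`,
#'   `angle_hi` (usable endpoints, degrees), `slope` and `offset` of the
#'   affine angle -> screen map, plus the underlying [calibration()].
#' @examples
#' m <- calibrate_rom(0, 50)
#' m$angle_lo  # 2.5
#' m$angle_hi  # 47.5
#' map_angle_to_screen(25, m)  # 0.5
#' @export
calibrate_rom <- function(angle_min, angle_max, usable_fraction = 0.9,
                          joint = "left_knee") {
  if (angle_max <= angle_min) {
    stop("angle_max must exceed angle_min", call. = FALSE)
  }
  cal <- calibration(joint, angle_min, angle_max, usable_fraction)
  rom <- angle_max - angle_min
  mid <- (angle_min + angle_max) / 2
  half_span <- usable_fraction * rom / 2
  angle_lo <- mid - half_span
  angle_hi <- mid + half_span
  slope <- 1 / (angle_hi - angle_lo)
  structure(
    list(calibration = cal, angle_lo = angle_lo, angle_hi = angle_hi,
         slope = slope, offset = -slope * angle_lo),
    class = "screen_mapping"
  )
}

#' @rdname calibrate_rom
#' @param angle joint angle(s) in degrees.
#' @param mapping a `screen_mapping` from [calibrate_rom()].
#' @export
map_angle_to_screen <- function(angle, mapping) {
  stopifnot(inherits(mapping, "screen_mapping"))
  pmin(1, pmax(0, mapping$slope * angle + mapping$offset))
}

#' @rdname calibrate_rom
#' @param position normalized screen position(s) in \[0, 1\].
#' @export
map_screen_to_angle <- function(position, mapping) {
  stopifnot(inherits(mapping, "screen_mapping"))
  position <- pmin(1, pmax(0, position))
  (position - mapping$offset) / mapping$slope
}

#' Generate a target path of upward and downward curves
#'
#' Builds the star trajectory for the 30 s test phase as a random-phase sum
#' of sinusoids (periods between 3 and 10 s), affinely rescaled into
#' \[0.05, 0.95\] so the avatar never has to pin the screen edges. The
#' result is smooth, contains both rising and falling segments, and is
#' deterministic for a fixed seed. Star times are evenly spaced along the
#' path.
#'
#' @param duration test-phase duration in seconds.
#' @param n_curves number of sinusoid components (>= 2 so that the path has
#'   both an upward and a downward curve).
#' @param seed integer seed; the same seed always yields the same path.
#' @param sampling_rate sampling rate in Hz.
#' @param star_interval_s spacing of stars along the path in seconds.
#' @return an [target_path()] object.
#' @export
generate_target_path <- function(duration = 30, n_curves = 3, seed = 1,
                                 sampling_rate = 50, star_interval_s = 2) {
  if (n_curves < 2) {
    stop("n_curves must be >= 2: a path with fewer components cannot ",
         "contain both an upward and a downward curve", call. = FALSE)
  }
  stopifnot(duration > 0, sampling_rate > 0)
  rng <- local_rng(seed)
  periods <- rng$runif(n_curves, 3, 10)
  phases <- rng$runif(n_curves, 0, 2 * pi)
  amps <- rng$runif(n_curves, 0.5, 1)
  t <- seq(0, duration, by = 1 / sampling_rate)
  y <- rowSums(vapply(seq_len(n_curves), function(k) {
    amps[k] * sin(2 * pi * t / periods[k] + phases[k])
  }, numeric(length(t))))
  # rescale into [0.05, 0.95]; clamp guards float round-off at the edges
  y <- 0.05 + 0.9 * (y - min(y)) / (max(y) - min(y))
  y <- pmin(0.95, pmax(0.05, y))
  star_times <- seq(star_interval_s, duration, by = star_interval_s)
  target_path(t, y, star_times = star_times)
}

# Self-contained RNG stream: draws do not disturb (or depend on) the
# global .Random.seed, so every generator is deterministic per seed even
# when interleaved with other stochastic code.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  draw <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      assign(".Random.seed", env$state, globalenv())
      out <- fn(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, globalenv())
      }
      out
    }
  }
  list(runif = draw(stats::runif), rnorm = draw(stats::rnorm),
       rlnorm = draw(stats::rlnorm), sample = draw(base::sample),
       rbinom = draw(stats::rbinom),
       derive_seed = draw(function() sample.int(.Machine$integer.max, 1L)))
}
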