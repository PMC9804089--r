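test_that("therapist rating encodes the number of observed movement types", {
  expect_identical(
    encode_therapist_rating(c("mirror", "trunk", "other_joint")), 3L)
  expect_identical(encode_therapist_rating(character()), 0L)
  expect_identical(encode_therapist_rating(c("mirror", "trunk")), 2L)
  expect_error(encode_therapist_rating("head"), "unknown involuntary")
  expect_error(encode_therapist_rating(c("mirror", "mirror")), "duplicates")
})

test_that("joint id helpers and relative-joint mapping behave anatomically", {
  expect_length(all_joints(), 6L)
  expect_identical(contralateral_joint("left_knee"), "right_knee")
  expect_identical(relative_joint("left_hip", "left_knee"), "ipsi_hip")
  expect_identical(relative_joint("right_knee", "left_knee"), "contra_knee")
  expect_identical(relative_joint("left_knee", "left_knee"), "target")
  expect_error(joint_id("left", "elbow"))
  sm <- affected_side_map("right")
  expect_identical(unname(sm["right"]), "more_affected")
  expect_identical(unname(sm["left"]), "less_affected")
})

test_that("calibration rejects untestable ROMs and bad fractions", {
  expect_error(calibration("left_knee", 0, 9), "below 10 degrees")
  expect_error(calibration("left_knee", 0, 50, usable_fraction = 0),
               "usable_fraction")
  cal <- calibration("left_knee", 0, 50)
  expect_equal(cal$usable_fraction, 0.9)
})

test_that("target path enforces range and up/down curves", {
  t <- seq(0, 10, 0.1)
  expect_error(target_path(t, rep(0.5, length(t))), "upward and downward")
  expect_error(target_path(t, seq(0, 1.2, length.out = length(t))),
               "within \\[0, 1\\]")
  p <- target_path(t, 0.5 + 0.4 * sin(t))
  expect_equal(p$duration, 10)
})

test_that("game_session validates trace completeness and avatar range", {
  s <- make_perfect_session()
  expect_s3_class(s, "game_session")
  traces5 <- s$traces[-1]
  expect_error(
    game_session("p", "test", "left_knee", s$calibration, s$path, traces5,
                 s$avatar, s$accommodation_duration),
    names(s$traces)[1])
  bad_avatar <- s$avatar
  bad_avatar[3] <- 1.4
  expect_error(
    game_session("p", "test", "left_knee", s$calibration, s$path, s$traces,
                 bad_avatar, s$accommodation_duration),
    "avatar positions")
})

test_that("session write -> read round-trips losslessly", {
  cfg <- tiny_config(missing_rate = 0.01)
  lat <- draw_latents(cfg)
  for (seed in c(3, 17)) {
    path <- generate_target_path(duration = cfg$duration, seed = seed,
                                 sampling_rate = cfg$sampling_rate)
    s <- simulate_session(as.list(lat[nrow(lat), ]), "right_ankle", path,
                          seed = seed, config = cfg)
    dir <- file.path(tempdir(), paste0("ses", seed))
    write_session(s, dir)
    s2 <- read_session(dir)
    expect_identical(s2$participant_id, s$participant_id)
    expect_identical(s2$occasion, s$occasion)
    expect_identical(s2$target_joint, s$target_joint)
    expect_equal(s2$calibration, s$calibration)
    expect_equal(s2$path$positions, s$path$positions, tolerance = 1e-12)
    expect_equal(s2$avatar, s$avatar, tolerance = 1e-12)
    for (j in all_joints()) {
      expect_equal(s2$traces[[j]]$proximal, s$traces[[j]]$proximal,
                   tolerance = 1e-12)
      expect_identical(s2$traces[[j]]$missing_distal,
                       s$traces[[j]]$missing_distal)
    }
    unlink(dir, recursive = TRUE)
  }
})

test_that("reading a session with a missing sensor pair names the joint", {
  s <- make_perfect_session()
  dir <- file.path(tempdir(), "broken")
  write_session(s, dir)
  tr <- utils::read.csv(file.path(dir, "traces.csv"))
  tr <- tr[!(tr$side == "right" & tr$joint == "hip"), ]
  utils::write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
  expect_error(read_session(dir), "right_hip")
  file.remove(file.path(dir, "session.json"))
  expect_error(read_session(dir), "session.json")
  unlink(dir, recursive = TRUE)
})

test_that("masked samples survive the round-trip unfilled", {
  cfg <- tiny_config(missing_rate = 0.008)
  lat <- draw_latents(cfg)
  path <- generate_target_path(duration = cfg$duration, seed = 4,
                               sampling_rate = cfg$sampling_rate)
  s <- simulate_session(as.list(lat[1, ]), "left_hip", path, seed = 9,
                        config = cfg)
  total_missing <- sum(vapply(s$traces, function(tr)
    sum(tr$missing_proximal) + sum(tr$missing_distal), numeric(1)))
  expect_gt(total_missing, 0)
  dir <- file.path(tempdir(), "masked")
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_identical(
    lapply(s2$traces, `[[`, "missing_distal"),
    lapply(s$traces, `[[`, "missing_distal"))
  unlink(dir, recursive = TRUE)
})
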