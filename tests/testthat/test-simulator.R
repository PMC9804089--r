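noiseless_latent <- function(cfg, coupling = 0) {
  lat <- as.list(draw_latents(cfg)[1, ])
  lat$sigma_track <- 0
  lat$lag <- 0
  for (j in all_joints()) lat[[paste0("c_", j)]] <- coupling
  lat
}

test_that("a zero-noise session reproduces the target path exactly", {
  cfg <- tiny_config(sensor_noise = 0, missing_rate = 0)
  lat <- noiseless_latent(cfg)
  path <- generate_target_path(duration = cfg$duration, seed = 8,
                               sampling_rate = cfg$sampling_rate)
  s <- simulate_session(lat, "left_knee", path, seed = 2, config = cfg)
  expect_equal(s$avatar, path$positions, tolerance = 1e-12)
  expect_equal(tracking_error(s$avatar, s$path), 0, tolerance = 1e-12)
  # non-target joints carry fidget only
  m <- session_metrics(s)
  expect_lt(max(m$metrics), 3 * lat$fidget_scale)
})

test_that("sessions are deterministic per seed", {
  cfg <- tiny_config()
  lat <- as.list(draw_latents(cfg)[2, ])
  path <- generate_target_path(duration = cfg$duration, seed = 1,
                               sampling_rate = cfg$sampling_rate)
  s1 <- simulate_session(lat, "right_hip", path, seed = 42, config = cfg)
  s2 <- simulate_session(lat, "right_hip", path, seed = 42, config = cfg)
  s3 <- simulate_session(lat, "right_hip", path, seed = 43, config = cfg)
  expect_identical(s1$traces$left_knee$distal, s2$traces$left_knee$distal)
  expect_identical(s1$avatar, s2$avatar)
  expect_false(identical(s1$traces$left_knee$distal,
                         s3$traces$left_knee$distal))
})

test_that("raising one contralateral coupling gain raises that joint's metric", {
  cfg <- tiny_config(sensor_noise = 0, missing_rate = 0)
  path <- generate_target_path(duration = cfg$duration, seed = 3,
                               sampling_rate = cfg$sampling_rate)
  lat0 <- noiseless_latent(cfg, coupling = 0)
  lat2 <- lat0
  lat2$c_right_hip <- 2.0        # mirror joint of a left-hip trial
  s0 <- simulate_session(lat0, "left_hip", path, seed = 5, config = cfg)
  s2 <- simulate_session(lat2, "left_hip", path, seed = 5, config = cfg)
  m0 <- session_metrics(s0)$metrics
  m2 <- session_metrics(s2)$metrics
  expect_gt(m2[["contra_hip"]], 2 * m0[["contra_hip"]])
  expect_equal(m2[["contra_knee"]], m0[["contra_knee"]], tolerance = 0.2)
})

test_that("all generated sessions satisfy the session invariants", {
  st <- tiny_study()
  expect_true(all(vapply(st$sim$sessions, inherits, TRUE, "game_session")))
  s <- st$sim$sessions[[1]]
  expect_identical(sort(names(s$traces)), sort(all_joints()))
  expect_true(all(s$avatar >= 0 & s$avatar <= 1))
})

test_that("latent truth is retained and groups have ordered impairment", {
  st <- tiny_study()
  lat <- st$latents
  expect_identical(nrow(lat), 18L)
  cj <- rowMeans(lat[paste0("c_", all_joints())])
  expect_lt(mean(cj[lat$group == "adult"]), mean(cj[lat$group == "control"]))
  expect_lt(mean(cj[lat$group == "control"]),
            mean(cj[lat$group == "patient"]))
  expect_true(all(lat$age[lat$group == "adult"] >= 18))
  expect_true(all(lat$age[lat$group != "adult"] <= 18))
})

test_that("control children's coupling declines with age (maturation)", {
  cfg <- simulation_config(n_adults = 3, n_controls = 200, n_patients = 0,
                           seed = 77)
  lat <- draw_latents(cfg)
  ctl <- lat[lat$group == "control", ]
  cj <- rowMeans(ctl[paste0("c_", all_joints())])
  expect_lt(stats::cor(ctl$age, cj, method = "spearman"), -0.3)
})

test_that("synthetic ratings are valid and track latent impairment", {
  st <- tiny_study()
  r <- st$sim$ratings
  expect_true(all(r$scale %in% 0:2))
  expect_true(all(r$gmfcs %in% 1:5))
  expect_true(all(r$therapist_count %in% 0:3))
  # ratings are stable across occasions for SCALE and GMFCS
  key <- paste(r$participant_id, r$side, r$joint)
  split_scale <- split(r$scale, key)
  expect_true(all(vapply(split_scale, function(v) length(unique(v)) == 1,
                         TRUE)))
})

test_that("scoring adults against their own reference centres the IMS at 0", {
  st <- tiny_study()
  lat <- st$latents
  adult_ids <- lat$participant_id[lat$group == "adult"]
  adult <- st$scores[st$scores$participant_id %in% adult_ids, ]
  expect_lt(abs(mean(adult$ims)), 0.1)
})

test_that("test-retest scores are near-identical when occasion noise is zero", {
  # full-length sessions: at 50 Hz with the 30 s test phase, residual
  # within-occasion noise is small relative to between-patient spread
  cfg <- simulation_config(n_adults = 6, n_controls = 0, n_patients = 8,
                           seed = 55, occasion_noise = 0)
  sim <- simulate_cohorts(cfg)
  lat <- sim$participants
  adult_ids <- lat$participant_id[lat$group == "adult"]
  ms <- lapply(sim$sessions, session_metrics, seed = 1)
  ref <- build_reference(
    ms[vapply(ms, function(m) m$participant_id %in% adult_ids, TRUE)])
  scores <- score_cohort(sim$sessions, ref, seed = 1)
  su <- summary_score_table(scores)
  pat <- su[su$participant_id %in%
              lat$participant_id[lat$group == "patient"], ]
  m <- merge(pat[pat$occasion == "test", ],
             pat[pat$occasion == "retest", ], by = "participant_id")
  icc <- icc_2_1(cbind(m$accuracy_total.x, m$accuracy_total.y))$icc
  expect_gte(icc, 0.99)
})
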