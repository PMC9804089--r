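gravity_mat <- function(incl_deg, noise = 0) {
  th <- incl_deg * pi / 180
  m <- cbind(x = sin(th), y = rep(0, length(th)), z = -cos(th))
  if (noise > 0) m <- m + matrix(stats::rnorm(3 * length(th), 0, noise),
                                 ncol = 3)
  m
}

test_that("aligned sensors give zero angle; tilt gives the tilt", {
  n <- 200
  still <- rep(0, n)
  tr0 <- sensor_pair_trace("left_knee", gravity_mat(still),
                           gravity_mat(still), 25)
  a0 <- estimate_joint_angle(tr0)
  expect_equal(a0$angles, rep(0, n), tolerance = 1e-9)

  tr30 <- sensor_pair_trace("left_knee", gravity_mat(still),
                            gravity_mat(rep(30, n)), 25)
  expect_equal(estimate_joint_angle(tr30)$angles, rep(30, n),
               tolerance = 1e-6)
})

test_that("identical proximal and distal motion cancels (compensation)", {
  wiggle <- 20 * sin((1:300) / 15) + 10
  tr <- sensor_pair_trace("right_hip", gravity_mat(wiggle),
                          gravity_mat(wiggle), 25)
  expect_equal(estimate_joint_angle(tr)$angles, rep(0, 300),
               tolerance = 1e-8)
})

test_that("a common inclination bias of both sensors leaves the angle unchanged", {
  base <- 25 * sin((1:300) / 20)
  tr <- sensor_pair_trace("left_ankle", gravity_mat(rep(0, 300)),
                          gravity_mat(base), 25)
  tr_biased <- sensor_pair_trace("left_ankle", gravity_mat(rep(15, 300)),
                                 gravity_mat(base + 15), 25)
  expect_equal(estimate_joint_angle(tr_biased)$angles,
               estimate_joint_angle(tr)$angles, tolerance = 1e-6)
})

test_that("near-zero total acceleration triggers a warning", {
  n <- 200
  prox <- gravity_mat(rep(0, n))
  dist <- gravity_mat(rep(0, n)) * 0.1   # sustained < 0.3 g
  tr <- sensor_pair_trace("left_hip", prox, dist, 25)
  expect_warning(estimate_joint_angle(tr), "near-zero total acceleration")
})

test_that("angular speed is the forward difference in deg/s", {
  expect_equal(angular_speed(rep(5, 50), sampling_rate = 50), rep(0, 50))
  ramp <- seq(0, 10, by = 0.2)   # 10 deg/s when sampled at 50 Hz
  v <- angular_speed(ramp, sampling_rate = 50)
  expect_equal(v, rep(10, length(ramp)), tolerance = 1e-9)
  a <- cumsum(stats::rnorm(100))
  expect_equal(angular_speed(-a, 25), -angular_speed(a, 25))
  expect_length(angular_speed(a, 25), 100)
})

test_that("tracking error is the RMSE over the test phase", {
  p <- generate_target_path(duration = 10, seed = 2, sampling_rate = 25)
  expect_equal(tracking_error(p$positions, p), 0)
  expect_equal(tracking_error(p$positions + 0.04, p), 0.04,
               tolerance = 1e-9)
  # mirrored avatar around 0.5: RMSE = 2 x RMS deviation of the path
  sym <- 0.5 + 0.3 * sin(seq(0, 6 * pi, length.out = 200))
  sym_path <- target_path(seq(0, 7.96, by = 0.04), sym)
  expect_equal(tracking_error(1 - sym, sym_path),
               2 * sqrt(mean((sym - 0.5)^2)), tolerance = 1e-12)
  expect_error(tracking_error(p$positions[-1], p), "differ in length")
})

test_that("movement metric of a sinusoid matches the mean-|cos| value", {
  rate <- 200
  f <- 0.5; A <- 12
  t <- seq(0, 20, by = 1 / rate)
  speeds <- angular_speed(A * sin(2 * pi * f * t), rate)
  expect_equal(movement_metric(speeds), (2 / pi) * A * 2 * pi * f,
               tolerance = 0.01)
  expect_equal(movement_metric(rep(0, 10)), 0)
  expect_equal(movement_metric(c(-5, 5, -5, 5)), 5)
})

test_that("accuracy and involuntary-movement scores standardize correctly", {
  ref <- make_toy_reference(sd_err = 0.04, mu_err = 0.05, mu_m = 5, sd_m = 1)
  expect_equal(accuracy_score(0, ref, "knee"), 0)
  expect_equal(accuracy_score(0.10, ref, "knee"), 2.5)
  expect_equal(accuracy_score(0.10, ref, "knee", centered = TRUE), 1.25)

  mv <- ref$contexts$knee$movement
  m <- stats::setNames(mv$mu, mv$rel_joint)        # all at the adult mean
  expect_equal(involuntary_movement_score(m, ref, "knee"), 0)
  m2 <- m; m2[1] <- m2[1] + 2 * mv$sd[1]           # one joint at mu + 2 sd
  expect_equal(involuntary_movement_score(m2, ref, "knee"), 0.4)
  m3 <- stats::setNames(mv$mu + mv$sd, mv$rel_joint)
  expect_equal(involuntary_movement_score(m3, ref, "knee"), 1.0)
})

test_that("reference building uses sample statistics and rejects degeneracy", {
  mk <- function(id, ctx, err, bump = 0) {
    rels <- setdiff(as.vector(outer(c("ipsi", "contra"),
                                    c("hip", "knee", "ankle"),
                                    paste, sep = "_")),
                    paste0("ipsi_", ctx))
    list(participant_id = id, occasion = "test", excluded = character(),
         context = ctx, error = err,
         metrics = stats::setNames(rep(4 + bump, 5), sort(rels)))
  }
  ms <- list()
  for (ctx in c("hip", "knee", "ankle")) {
    ms <- c(ms, list(mk("a1", ctx, 0.04, 0), mk("a2", ctx, 0.05, 1),
                     mk("a3", ctx, 0.06, 2)))
  }
  ref <- build_reference(ms)
  expect_equal(ref$contexts$knee$mu_err, 0.05)
  expect_equal(ref$contexts$knee$sd_err, stats::sd(c(0.04, 0.05, 0.06)))
  expect_equal(ref$contexts$hip$movement$mu, rep(5, 5))
  expect_equal(ref$contexts$hip$movement$sd, rep(1, 5))
  expect_equal(ref$n_adults, 3)

  identical_adults <- unlist(lapply(c("hip", "knee", "ankle"), function(ctx)
    list(mk("a1", ctx, 0.05), mk("a2", ctx, 0.05), mk("a3", ctx, 0.05))),
    recursive = FALSE)
  expect_error(build_reference(identical_adults), "degenerate")
  expect_error(build_reference(identical_adults[1:3]),
               "all three target-joint")
})

test_that("reference JSON round-trips", {
  ref <- make_toy_reference()
  f <- tempfile(fileext = ".json")
  write_reference(ref, f)
  ref2 <- read_reference(f)
  expect_equal(ref2$contexts$knee$mu_err, ref$contexts$knee$mu_err)
  expect_equal(ref2$contexts$ankle$movement$sd,
               ref$contexts$ankle$movement$sd)
  file.remove(f)
})

test_that("summaries average testable joints per leg and in total", {
  d <- data.frame(
    side = rep(c("left", "right"), each = 3),
    joint = rep(c("hip", "knee", "ankle"), 2),
    accuracy = c(2, 3, 4, 1, 1, 1),
    excluded = FALSE)
  s <- summarize_scores(d, affected_side_map("left"), "accuracy")
  expect_equal(unname(s), c(3, 1, 2))

  # constant scores propagate to all summaries
  d$accuracy <- 1.7
  expect_equal(unname(summarize_scores(d, affected_side_map("right"),
                                       "accuracy")),
               rep(1.7, 3))

  # an excluded ankle drops out of its leg mean only
  d$accuracy <- c(2, 3, 4, 1, 1, 1)
  d$excluded <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  s <- summarize_scores(d, affected_side_map("left"), "accuracy")
  expect_equal(unname(s[1]), 2.5)
  expect_equal(unname(s[2]), 1)
  # a fully excluded leg yields NA for that leg
  d$excluded <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  s <- summarize_scores(d, affected_side_map("left"), "accuracy")
  expect_true(is.na(s[["more_affected"]]))
  expect_equal(unname(s[["total"]]), 1)
  d$excluded <- TRUE
  expect_error(summarize_scores(d, affected_side_map("left"), "accuracy"),
               "no testable joints")
})

test_that("scoring a perfect session yields accuracy 0", {
  s <- make_perfect_session()
  ref <- make_toy_reference()
  row <- score_session(s, ref)
  expect_equal(row$accuracy, 0)
  expect_false(row$excluded)
})

test_that("an untestable joint is excluded without touching the others", {
  s <- make_perfect_session()
  # knock out 25% of the right hip distal sensor
  tr <- s$traces$right_hip
  n <- nrow(tr$distal)
  miss <- seq_len(n) <= 0.25 * n
  s$traces$right_hip <- sensor_pair_trace(
    "right_hip", tr$proximal, tr$distal, tr$sampling_rate,
    missing_distal = miss)
  m <- session_metrics(s)
  m_clean <- session_metrics(make_perfect_session())
  expect_identical(m$excluded, "right_hip")
  expect_false("contra_hip" %in% names(m$metrics))
  common <- intersect(names(m$metrics), names(m_clean$metrics))
  expect_equal(m$metrics[common], m_clean$metrics[common])
  expect_equal(m$error, m_clean$error)
})
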