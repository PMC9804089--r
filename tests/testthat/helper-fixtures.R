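# Shared fixtures, built in code at test time.

# A small hand-made session: target left_knee, perfect tracking, all other
# joints static. rate/durations kept small so unit tests stay fast.
make_perfect_session <- function(rate = 25, duration = 10, accommodation = 4,
                                 sigma_sensor = 0, participant = "p1",
                                 occasion = "test") {
  path <- generate_target_path(duration = duration, n_curves = 3, seed = 5,
                               sampling_rate = rate)
  mapping <- calibrate_rom(0, 80, joint = "left_knee")
  n_acc <- round(accommodation * rate)
  n <- n_acc + length(path$positions)
  screen <- c(rep(path$positions[1], n_acc), path$positions)
  angle <- map_screen_to_angle(screen, mapping)
  gravity <- function(incl_deg) {
    th <- incl_deg * pi / 180
    m <- cbind(x = sin(th), y = rep(0, length(th)), z = -cos(th))
    if (sigma_sensor > 0) m <- m + matrix(stats::rnorm(3 * length(th), 0,
                                                       sigma_sensor),
                                          ncol = 3)
    m
  }
  still <- rep(0, n)
  traces <- list()
  for (j in all_joints()) {
    a <- if (j == "left_knee") angle else still
    traces[[j]] <- sensor_pair_trace(j, gravity(still), gravity(a), rate)
  }
  game_session(participant, occasion, "left_knee", mapping$calibration,
               path, traces, avatar = path$positions,
               accommodation_duration = accommodation)
}

# Hand-built reference with round numbers, for score arithmetic tests.
make_toy_reference <- function(sd_err = 0.04, mu_err = 0.05,
                               mu_m = 5, sd_m = 1) {
  ctx <- function(target) {
    rels <- setdiff(as.vector(outer(c("ipsi", "contra"),
                                    c("hip", "knee", "ankle"), paste,
                                    sep = "_")),
                    paste0("ipsi_", target))
    list(mu_err = mu_err, sd_err = sd_err, n_err = 10,
         movement = data.frame(rel_joint = sort(rels), mu = mu_m, sd = sd_m,
                               n = 10))
  }
  structure(list(contexts = list(hip = ctx("hip"), knee = ctx("knee"),
                                 ankle = ctx("ankle")),
                 n_adults = 10),
            class = "reference_stats")
}

# One small simulated study, cached across test files. occasion_noise = 0
# so test-retest agreement is limited only by sensor/fidget noise.
.fixture_env <- new.env(parent = emptyenv())

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_adults = 6, n_controls = 6, n_patients = 6, seed = 101,
         sampling_rate = 25, duration = 12, accommodation_duration = 5,
         occasion_noise = 0),
    list(...))
  do.call(simulation_config, args)
}

tiny_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- tiny_config()
    sim <- simulate_cohorts(cfg)
    lat <- sim$participants
    adult_ids <- lat$participant_id[lat$group == "adult"]
    ms <- lapply(sim$sessions, session_metrics, seed = 1)
    ref <- build_reference(
      ms[vapply(ms, function(m) m$participant_id %in% adult_ids, TRUE)])
    scores <- score_cohort(sim$sessions, ref, seed = 1)
    side_maps <- stats::setNames(
      lapply(lat$more_affected, affected_side_map), lat$participant_id)
    summaries <- summary_score_table(scores, side_maps)
    summaries$group <- lat$group[match(summaries$participant_id,
                                       lat$participant_id)]
    .fixture_env$study <- list(config = cfg, sim = sim, ref = ref,
                               scores = scores, summaries = summaries,
                               side_maps = side_maps, latents = lat)
  }
  .fixture_env$study
}
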