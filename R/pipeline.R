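#' Run the full simulate -> score -> analyze pipeline
#'
#' One-command orchestration of the whole toolkit: simulates the
#' configured cohorts, builds the adult reference, scores the control and
#' patient sessions, and runs the discriminative-validity ANCOVA, the
#' concurrent-validity correlation tables and the test-retest reliability
#' battery. All outputs are written as CSV/JSON under `out_dir` together
#' with a machine-readable run manifest (seed, settings, stage timings,
#' warnings); the whole bundle is a pure function of (config, seed).
#'
#' @param config a [simulation_config()] (or path to a YAML file of
#'   arguments understood by it).
#' @param out_dir output directory.
#' @param boot_n bootstrap replicates for reliability CIs.
#' @param ancova_b bootstrap replicates for the ANCOVA.
#' @param design_points ANCOVA age design points.
#' @return invisibly, a list with all in-memory results (`reference`,
#'   `joint_scores`, `summaries`, `validity`, `joint_validity`,
#'   `reliability`, `ancova`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, boot_n = 1000, ancova_b = 2000,
                         design_points = c(9.5, 12.5, 15.5)) {
  if (is.character(config)) {
    config <- do.call(simulation_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   boot_n = boot_n, ancova_b = ancova_b,
                   design_points = design_points,
                   r_version = as.character(getRversion()),
                   warnings = character(0), stages = list())
  note <- function(msg) {
    manifest$warnings <<- c(manifest$warnings, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- withCallingHandlers(expr, warning = function(w) {
      manifest$warnings <<- c(manifest$warnings,
                              paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<-
      list(seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  sim <- stage("simulate", simulate_cohorts(config))
  lat <- sim$participants
  groups <- stats::setNames(lat$group, lat$participant_id)
  side_maps <- stats::setNames(
    lapply(lat$more_affected, affected_side_map), lat$participant_id)

  adult_ids <- lat$participant_id[lat$group == "adult"]
  adult_sessions <- Filter(function(s) s$participant_id %in% adult_ids,
                           sim$sessions)
  ref <- stage("reference", build_reference(
    lapply(adult_sessions, session_metrics, seed = config$seed)))
  write_reference(ref, file.path(out_dir, "reference.json"))

  child_sessions <- Filter(function(s) !(s$participant_id %in% adult_ids),
                           sim$sessions)
  joint_scores <- stage("score",
                        score_cohort(child_sessions, ref,
                                     seed = config$seed))
  summaries <- summary_score_table(joint_scores, side_maps)
  summaries$group <- unname(groups[summaries$participant_id])
  utils::write.csv(joint_scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(summaries, file.path(out_dir, "summary_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$ratings, file.path(out_dir, "ratings.csv"),
                   row.names = FALSE)
  utils::write.csv(lat, file.path(out_dir, "latent_truth.csv"),
                   row.names = FALSE)

  results <- list(reference = ref, joint_scores = joint_scores,
                  summaries = summaries)

  if (config$n_patients == 0) {
    note("n_patients = 0: validity and discriminative stages skipped")
  } else {
    pat <- summaries[summaries$group == "patient" &
                       summaries$occasion == "test", ]
    ctl <- summaries[summaries$group == "control" &
                       summaries$occasion == "test", ]
    ages <- stats::setNames(lat$age, lat$participant_id)
    if (nrow(ctl)) {
      anc <- stage("discriminative", lapply(
        c(accuracy = "accuracy_total", ims = "ims_total"),
        function(col) robust_ancova(
          ages[pat$participant_id], pat[[col]],
          ages[ctl$participant_id], ctl[[col]],
          design_points = design_points, B = ancova_b,
          seed = config$seed)))
      for (nm in names(anc)) {
        utils::write.csv(as.data.frame(anc[[nm]]),
                         file.path(out_dir, paste0("ancova_", nm, ".csv")),
                         row.names = FALSE)
      }
      results$ancova <- anc
    }
    pat_ratings <- sim$ratings[sim$ratings$participant_id %in%
                                 pat$participant_id, ]
    validity <- stage("validity", concurrent_validity_table(
      pat, pat_ratings, side_maps))
    joint_validity <- stage("joint_validity", joint_validity_table(
      joint_scores[joint_scores$participant_id %in% pat$participant_id, ],
      pat_ratings))
    utils::write.csv(validity, file.path(out_dir, "validity.csv"),
                     row.names = FALSE)
    utils::write.csv(joint_validity,
                     file.path(out_dir, "joint_validity.csv"),
                     row.names = FALSE)
    results$validity <- validity
    results$joint_validity <- joint_validity
    if (config$n_occasions == 2) {
      pat_sum <- summaries[summaries$group == "patient", ]
      rel <- stage("reliability", reliability_table(
        pat_sum, B = boot_n, seed = config$seed))
      utils::write.csv(rel, file.path(out_dir, "reliability.csv"),
                       row.names = FALSE)
      results$reliability <- rel
    }
  }

  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Per-child clinical report
#'
#' Renders, for one participant, each joint's accuracy and involuntary
#' movement score in adult SD units together with the percentile of that
#' score among simulated control children of approximately the same age
#' (within `age_window` years). Excluded joints are listed with the
#' reason. The output mirrors the joint-level clinical summary a therapist
#' would use to personalize therapy.
#'
#' @param joint_scores per-joint score rows of the child (one occasion).
#' @param control_scores per-joint score table of the control cohort.
#' @param control_ages named vector of control ages (years).
#' @param child_age the child's age in years.
#' @param age_window half-width of the age-matching window, years.
#' @return data frame: side, joint, accuracy, ims, percentile columns,
#'   status; printed as a small text report via `print()`.
#' @export
render_child_report <- function(joint_scores, control_scores, control_ages,
                                child_age, age_window = 2) {
  stopifnot(nrow(joint_scores) >= 1L)
  in_window <- names(control_ages)[abs(control_ages - child_age) <=
                                     age_window]
  ctl <- control_scores[control_scores$participant_id %in% in_window &
                          !isTRUE_vec(control_scores$excluded), ]
  pct <- function(score, side, joint) {
    v <- ctl[[score]][ctl$side == side & ctl$joint == joint]
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    100 * mean(v < joint_scores[[score]][joint_scores$side == side &
                                           joint_scores$joint == joint]) +
      50 * mean(v == joint_scores[[score]][joint_scores$side == side &
                                             joint_scores$joint == joint])
  }
  rows <- lapply(seq_len(nrow(joint_scores)), function(i) {
    r <- joint_scores[i, ]
    if (isTRUE_vec(r$excluded)) {
      return(data.frame(side = r$side, joint = r$joint,
                        accuracy = NA_real_, ims = NA_real_,
                        accuracy_pctile = NA_real_, ims_pctile = NA_real_,
                        status = "excluded: joint untestable (ROM < 10 deg or sensor dropout)"))
    }
    data.frame(side = r$side, joint = r$joint,
               accuracy = r$accuracy, ims = r$ims,
               accuracy_pctile = pct("accuracy", r$side, r$joint),
               ims_pctile = pct("ims", r$side, r$joint),
               status = if (length(in_window)) "ok" else
                 "no age-matched controls in window; percentile omitted")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("child_report", "data.frame")
  attr(out, "child_age") <- child_age
  attr(out, "n_controls") <- length(in_window)
  out
}

#' @export
print.child_report <- function(x, ...) {
  cat(sprintf(
    "Joint-level game report (age %.1f y, %d age-matched controls)\n",
    attr(x, "child_age"), attr(x, "n_controls")))
  cat("scores in adult SD units (0 = adult-like mastery; larger = worse)\n")
  for (i in seq_len(nrow(x))) {
    if (startsWith(x$status[i], "excluded")) {
      cat(sprintf("  %-5s %-5s  %s\n", x$side[i], x$joint[i], x$status[i]))
    } else {
      cat(sprintf(
        "  %-5s %-5s  accuracy %5.2f (pctile %3.0f)  involuntary %5.2f (pctile %3.0f)\n",
        x$side[i], x$joint[i], x$accuracy[i], x$accuracy_pctile[i],
        x$ims[i], x$ims_pctile[i]))
    }
  }
  invisible(x)
}
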