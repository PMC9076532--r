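#' Run the full analysis pipeline on one synthetic session
#'
#' Generates a session, builds the trial table with engagement labels,
#' computes streak statistics, runs the sliding baseline decoder and the
#' session-inclusion check, selects matched engaged/disengaged trial sets,
#' detects place fields in both states, cross-tabulates them, and runs the
#' engagement-split, speed-matched and streak-onset decoding protocols.
#' Deterministic given `(cfg, seed)`.
#'
#' @param cfg a [gen_config()] object
#' @param seed integer seed (default `cfg$seed`)
#' @param n_shuffles shuffle count for place-field nulls (1000 for
#'   quantitative use; reduce for quick runs)
#' @param streak_shuffles permutations for the streak control
#' @param run_speed_match,run_streak_onset stage toggles
#' @return list of class `pg_report` with the tables described above
#' @export
run_pipeline <- function(cfg, seed = cfg$seed, n_shuffles = 1000,
                         streak_shuffles = 1000, run_speed_match = TRUE,
                         run_streak_onset = TRUE) {
  gen <- generate_session(cfg, seed)
  session <- gen$session
  truth <- gen$truth

  trials <- build_trial_table(session)
  usable <- trials$trial[!trials$excluded]
  labels <- trials$engagement[!trials$excluded]

  streaks <- streak_stats(trials$engagement, streak_shuffles)

  sliding <- tryCatch(sliding_decoder(session, usable),
                      error = function(e) NULL)
  sliding_err <- if (is.null(sliding)) rep(NA_real_, length(usable)) else
    sliding$error_cm
  inclusion <- session_inclusion(trials[!trials$excluded, ], sliding_err)

  eng <- usable[labels == "engaged"]
  dis <- usable[labels == "disengaged"]

  report <- list(config = cfg, seed = seed, session = session,
                 truth = truth, trials = trials, streaks = streaks,
                 sliding = sliding, inclusion = inclusion)

  set.seed(substream_seed(seed, 20))
  if (length(eng) && length(dis)) {
    matched <- match_trials(eng, dis)
    fields <- tryCatch({
      fe <- place_field_table(session, matched$engaged, n_shuffles,
                              state = "engaged")
      fd <- place_field_table(session, matched$disengaged, n_shuffles,
                              state = "disengaged")
      list(e = fe, d = fd)
    }, error = function(e) structure(list(message = conditionMessage(e)),
                                     class = "pg_skipped"))
    report$matched <- matched
    if (!inherits(fields, "pg_skipped")) {
      report$fields_engaged <- fields$e
      report$fields_disengaged <- fields$d
      report$field_comparison <- compare_fields(fields$e, fields$d,
                                                cfg$n_cells,
                                                cfg$n_spatial_bins)
      report$fraction_with_fields <- c(
        engaged = nrow(fields$e) / cfg$n_cells,
        disengaged = nrow(fields$d) / cfg$n_cells)
    } else {
      report$fields_engaged <- fields
    }
  }

  set.seed(substream_seed(seed, 21))
  report$engagement_decoding <- tryCatch(
    engagement_decoder(session, usable, labels),
    error = function(e) structure(list(message = conditionMessage(e)),
                                  class = "pg_skipped"))

  if (run_speed_match) {
    set.seed(substream_seed(seed, 22))
    report$speed_matched_decoding <- tryCatch(
      speed_matched_decoding(session, usable, labels),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "pg_skipped"))
  }

  if (run_streak_onset) {
    report$streak_onset <- streak_onset_decoder(session, trials$engagement)
    if (!is.null(report$fields_engaged) && nrow(report$fields_engaged))
      report$selectivity_onset <- selectivity_timecourse(
        session, trials$engagement, report$fields_engaged)
  }

  class(report) <- "pg_report"
  report
}

#' Write a session (and optional ground truth) to an HDF5 container
#'
#' Layout: `/behavior` (position, speed, lick, reward, trial_index,
#' trial_type), `/activity` (cells x frames matrix), `/truth` (tuning
#' curves and statuses, if given), `/meta` (frame_rate, track geometry,
#' and the generator config as a JSON string attribute). Requires the
#' `rhdf5` package.
#'
#' @param session a `pg_session`
#' @param path output file
#' @param truth optional `pg_truth`
#' @export
write_session_h5 <- function(session, path, truth = NULL) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("write_session_h5 requires the rhdf5 package")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  h5w <- rhdf5::h5write
  for (g in c("behavior", "activity", "truth", "meta"))
    rhdf5::h5createGroup(path, g)
  h5w(session$position, path, "behavior/position")
  h5w(session$speed, path, "behavior/speed")
  h5w(as.integer(session$lick), path, "behavior/lick")
  h5w(as.integer(session$reward), path, "behavior/reward")
  h5w(session$trial_index, path, "behavior/trial_index")
  h5w(session$trial_type, path, "behavior/trial_type")
  rhdf5::h5createDataset(path, "activity/deconvolved",
                         dims = dim(session$activity),
                         chunk = c(nrow(session$activity),
                                   min(ncol(session$activity), 1024L)))
  h5w(session$activity, path, "activity/deconvolved")
  if (!is.null(truth)) {
    h5w(truth$status, path, "truth/status")
    h5w(truth$engaged_curve, path, "truth/engaged_curve")
    h5w(truth$disengaged_curve, path, "truth/disengaged_curve")
    h5w(truth$states, path, "truth/states")
  }
  h5w(session$frame_rate, path, "meta/frame_rate")
  h5w(session$track_length, path, "meta/track_length")
  h5w(session$n_spatial_bins, path, "meta/n_spatial_bins")
  cfg <- session$config
  cfg$engagement_markov <- as.vector(cfg$engagement_markov)
  h5w(as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)),
      path, "meta/config_json")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a session written by [write_session_h5()]
#'
#' @param path HDF5 file
#' @return list with `session` (class `pg_session`) and `truth` (NULL if
#'   absent)
#' @export
read_session_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("read_session_h5 requires the rhdf5 package")
  h5r <- function(name) rhdf5::h5read(path, name)
  cfgl <- jsonlite::fromJSON(h5r("meta/config_json"))
  cfgl$engagement_markov <- matrix(cfgl$engagement_markov, 2, 2)
  cfg <- do.call(gen_config, cfgl[names(cfgl) %in% names(formals(gen_config))])
  session <- structure(list(
    frame_rate = as.numeric(h5r("meta/frame_rate")),
    track_length = as.numeric(h5r("meta/track_length")),
    n_spatial_bins = as.integer(h5r("meta/n_spatial_bins")),
    position = as.numeric(h5r("behavior/position")),
    speed = as.numeric(h5r("behavior/speed")),
    lick = as.logical(h5r("behavior/lick")),
    reward = as.logical(h5r("behavior/reward")),
    trial_index = as.integer(h5r("behavior/trial_index")),
    trial_type = as.character(h5r("behavior/trial_type")),
    activity = as.matrix(h5r("activity/deconvolved")),
    config = cfg
  ), class = "pg_session")
  truth <- NULL
  contents <- rhdf5::h5ls(path)
  if (any(contents$group == "/truth" & contents$name == "status")) {
    truth <- structure(list(
      status = as.character(h5r("truth/status")),
      engaged_curve = as.matrix(h5r("truth/engaged_curve")),
      disengaged_curve = as.matrix(h5r("truth/disengaged_curve")),
      states = as.character(h5r("truth/states"))
    ), class = "pg_truth")
  }
  rhdf5::h5closeAll()
  list(session = session, truth = truth)
}
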