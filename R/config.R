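#' Configuration for the synthetic session generator
#'
#' Builds and validates the full parameter set of the synthetic-session
#' generator. Defaults describe a trained mouse on a 2-m virtual track that
#' repeats in a circular topology, with a 20-cm reward zone (1/10 of the
#' track) starting at 140 cm, interleaved standard/probe/crutch trials, and
#' a two-state (engaged/disengaged) Markov chain over trials whose high
#' self-transition probabilities produce engagement streaks.
#'
#' Place-code degradation on disengaged trials is parameterized by the
#' fraction of tuned cells that lose their field (default 0.52), the
#' fraction of untuned cells that gain one (default 0.25), the fraction of
#' surviving fields that remap to a new location (default 0.5), and a
#' variance inflation factor for trial-to-trial amplitude noise.
#'
#' @param n_trials number of laps/trials in the session
#' @param n_cells number of simulated cells
#' @param frame_rate imaging frame rate, Hz
#' @param track_length track circumference, cm
#' @param n_spatial_bins number of spatial bins (bin width must divide the
#'   track exactly)
#' @param reward_zone_start,reward_zone_length true reward zone geometry, cm
#' @param p_probe,p_crutch per-trial probabilities of probe and crutch
#'   trials (remainder standard)
#' @param engagement_markov 2x2 row-stochastic transition matrix over
#'   (engaged, disengaged) trial states
#' @param place_cell_fraction fraction of cells with a place field on
#'   engaged trials
#' @param field_width_sd wrapped-Gaussian tuning curve s.d., cm
#' @param field_amplitude peak tuning amplitude, activity units
#' @param baseline_rate floor activity level, activity units
#' @param trial_amplitude_cv coefficient of variation of the lognormal
#'   per-cell, per-trial amplitude factor (reliability knob)
#' @param disengaged_field_loss fraction of engaged-tuned cells whose field
#'   disappears on disengaged trials
#' @param disengaged_field_gain fraction of engaged-untuned cells that gain
#'   a field on disengaged trials
#' @param disengaged_remap_fraction fraction of surviving fields that move
#'   to a uniformly random new center on disengaged trials
#' @param disengaged_noise_scale variance inflation (>= 1) applied to the
#'   amplitude factor and additive noise on disengaged trials
#' @param engaged_slowdown_depth relative speed dip (0..1) in the 20 cm
#'   before the reward zone on engaged trials; disengaged trials run at a
#'   position-independent mean speed
#' @param base_speed mean running speed, cm/s
#' @param speed_noise_sd frame-to-frame speed jitter s.d., cm/s
#' @param lick_rate_engaged,lick_rate_disengaged expected non-consumption
#'   licks per trial in each state
#' @param lick_concentration_engaged s.d. (cm) of engaged lick placement
#'   around the reward-zone start
#' @param consume_p_disengaged probability that a disengaged (satiated)
#'   mouse emits a consumption lick bout after reward delivery; engaged
#'   trials always consume
#' @param noise_rate mean of the additive nonnegative (exponential)
#'   activity noise, activity units per frame
#' @param seed default RNG seed used by [generate_session()]
#' @return a validated list of class `gen_config`
#' @export
gen_config <- function(n_trials = 90,
                       n_cells = 100,
                       frame_rate = 30,
                       track_length = 200,
                       n_spatial_bins = 40,
                       reward_zone_start = 140,
                       reward_zone_length = 20,
                       p_probe = 0.1,
                       p_crutch = 0.15,
                       engagement_markov = matrix(c(0.95, 0.05,
                                                    0.10, 0.90),
                                                  2, 2, byrow = TRUE),
                       place_cell_fraction = 0.5,
                       field_width_sd = 10,
                       field_amplitude = 1,
                       baseline_rate = 0.02,
                       trial_amplitude_cv = 0.3,
                       disengaged_field_loss = 0.52,
                       disengaged_field_gain = 0.25,
                       disengaged_remap_fraction = 0.5,
                       disengaged_noise_scale = 3,
                       engaged_slowdown_depth = 0.5,
                       base_speed = 20,
                       speed_noise_sd = 1.5,
                       lick_rate_engaged = 10,
                       lick_rate_disengaged = 1,
                       lick_concentration_engaged = 10,
                       consume_p_disengaged = 0.25,
                       noise_rate = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_trials = as.integer(n_trials), n_cells = as.integer(n_cells),
    frame_rate = frame_rate, track_length = track_length,
    n_spatial_bins = as.integer(n_spatial_bins),
    reward_zone_start = reward_zone_start,
    reward_zone_length = reward_zone_length,
    p_probe = p_probe, p_crutch = p_crutch,
    engagement_markov = engagement_markov,
    place_cell_fraction = place_cell_fraction,
    field_width_sd = field_width_sd,
    field_amplitude = field_amplitude,
    baseline_rate = baseline_rate,
    trial_amplitude_cv = trial_amplitude_cv,
    disengaged_field_loss = disengaged_field_loss,
    disengaged_field_gain = disengaged_field_gain,
    disengaged_remap_fraction = disengaged_remap_fraction,
    disengaged_noise_scale = disengaged_noise_scale,
    engaged_slowdown_depth = engaged_slowdown_depth,
    base_speed = base_speed, speed_noise_sd = speed_noise_sd,
    lick_rate_engaged = lick_rate_engaged,
    lick_rate_disengaged = lick_rate_disengaged,
    lick_concentration_engaged = lick_concentration_engaged,
    consume_p_disengaged = consume_p_disengaged,
    noise_rate = noise_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "gen_config"
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks every invariant of the configuration and stops with a message
#' listing all violated fields.
#'
#' @param cfg a `gen_config` list
#' @return `cfg`, invisibly, if valid
#' @export
validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, field) if (!isTRUE(ok)) bad <<- c(bad, field)

  chk(cfg$n_trials >= 1, "n_trials")
  chk(cfg$n_cells >= 1, "n_cells")
  chk(cfg$frame_rate > 0, "frame_rate")
  chk(cfg$track_length > 0, "track_length")
  chk(cfg$n_spatial_bins >= 1, "n_spatial_bins")
  # bin width must tile the track exactly
  bw <- cfg$track_length / cfg$n_spatial_bins
  chk(abs(cfg$n_spatial_bins * bw - cfg$track_length) < 1e-9, "n_spatial_bins")
  chk(cfg$reward_zone_start >= 0 &&
        cfg$reward_zone_start + cfg$reward_zone_length <= cfg$track_length,
      "reward_zone")
  for (f in c("p_probe", "p_crutch", "place_cell_fraction",
              "disengaged_field_loss", "disengaged_field_gain",
              "disengaged_remap_fraction", "engaged_slowdown_depth",
              "consume_p_disengaged"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f)
  chk(cfg$p_probe + cfg$p_crutch <= 1, "p_probe+p_crutch")
  m <- cfg$engagement_markov
  chk(is.matrix(m) && all(dim(m) == c(2, 2)) && all(m >= 0) &&
        all(abs(rowSums(m) - 1) < 1e-12), "engagement_markov")
  chk(cfg$disengaged_noise_scale >= 1, "disengaged_noise_scale")
  chk(cfg$trial_amplitude_cv >= 0, "trial_amplitude_cv")
  chk(cfg$field_width_sd > 0, "field_width_sd")
  chk(cfg$field_amplitude >= 0, "field_amplitude")
  chk(cfg$base_speed > 0, "base_speed")
  chk(cfg$lick_rate_engaged >= 0 && cfg$lick_rate_disengaged >= 0,
      "lick_rates")

  if (length(bad))
    stop("invalid generator configuration; violated fields: ",
         paste(unique(bad), collapse = ", "))
  invisible(cfg)
}

# Bin width in cm
bin_width <- function(cfg) cfg$track_length / cfg$n_spatial_bins
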