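#' Sample a per-trial engagement state sequence
#'
#' Trials alternate between an engaged and a disengaged behavioral state
#' according to a two-state Markov chain, starting engaged. With the default
#' self-transition probabilities (>= 0.9) the sequence exhibits streaks of
#' consecutive same-state trials, mimicking the blocks of disengagement seen
#' late in real sessions.
#'
#' @param cfg a [gen_config()] object
#' @param n_trials number of trials (defaults to `cfg$n_trials`)
#' @return character vector of "engaged"/"disengaged", length `n_trials`
#' @export
generate_engagement_sequence <- function(cfg, n_trials = cfg$n_trials) {
  validate_config(cfg)
  m <- cfg$engagement_markov
  states <- character(n_trials)
  s <- 1L  # start engaged
  for (t in seq_len(n_trials)) {
    states[t] <- c("engaged", "disengaged")[s]
    s <- if (stats::runif(1) < m[s, 1]) 1L else 2L
  }
  states
}

# Draw per-trial types with the configured probe/crutch probabilities.
assign_trial_types <- function(cfg, n_trials = cfg$n_trials) {
  p <- c(standard = 1 - cfg$p_probe - cfg$p_crutch,
         probe = cfg$p_probe, crutch = cfg$p_crutch)
  sample(names(p), n_trials, replace = TRUE, prob = p)
}

# Position-dependent speed multiplier. Engaged trials slow down in the
# 20 cm before the reward zone (flat dip of relative depth `depth`, with
# 5-cm cosine ramps on either side); disengaged trials run flat.
speed_profile_factor <- function(pos, state, cfg) {
  depth <- if (state == "engaged") cfg$engaged_slowdown_depth else 0
  if (depth == 0) return(rep(1, length(pos)))
  s <- cfg$reward_zone_start
  L <- cfg$track_length
  ramp <- 5
  w <- numeric(length(pos))
  d0 <- (pos - (s - 20)) %% L            # distance past dip start
  inside <- d0 >= 0 & d0 < 20
  w[inside] <- 1
  # entry ramp: [s - 20 - ramp, s - 20)
  din <- ((s - 20) - pos) %% L
  on_in <- din > 0 & din <= ramp
  w[on_in] <- 0.5 * (1 + cos(pi * din[on_in] / ramp))
  # exit ramp: [s, s + ramp)
  dout <- (pos - s) %% L
  on_out <- dout >= 0 & dout < ramp
  w[on_out] <- 0.5 * (1 + cos(pi * dout[on_out] / ramp))
  1 - depth * w
}

#' Generate per-frame position and speed for every trial
#'
#' Speed is generated first and position integrated from it at the frame
#' rate, so the number of frames per trial varies with the speed profile
#' (engaged trials are longer because of the pre-reward slowdown). Each
#' trial starts at position 0 and ends just before completing one lap; the
#' track wraps at `track_length`.
#'
#' @param cfg a [gen_config()] object
#' @param states per-trial engagement states
#' @return data.frame with columns `trial_index`, `position`, `speed`
#' @export
generate_trajectory <- function(cfg, states) {
  stopifnot(length(states) >= 1)
  fr <- cfg$frame_rate
  L <- cfg$track_length
  out <- vector("list", length(states))
  for (tr in seq_along(states)) {
    tf <- stats::rlnorm(1, -0.5 * log(1 + 0.1^2), sqrt(log(1 + 0.1^2)))
    pos <- numeric(0)
    spd <- numeric(0)
    p <- 0
    repeat {
      v <- cfg$base_speed * tf *
        speed_profile_factor(p, states[tr], cfg) +
        stats::rnorm(1, 0, cfg$speed_noise_sd)
      v <- max(v, 1)  # always make forward progress
      pos <- c(pos, p)
      spd <- c(spd, v)
      p <- p + v / fr
      if (p >= L) break
    }
    out[[tr]] <- data.frame(trial_index = tr, position = pos, speed = spd)
  }
  do.call(rbind, out)
}

#' Generate licks and rewards for every trial
#'
#' Engaged trials place around `lick_rate_engaged` licks at positions drawn
#' from a wrapped normal centered on the reward-zone start; disengaged
#' trials place around `lick_rate_disengaged` licks uniformly on the track.
#' Rewards follow the task rules: on standard trials the first lick inside
#' the true reward zone triggers the (single) reward; crutch trials are
#' rewarded at zone entry regardless of licking; probe trials are never
#' rewarded. After each reward a short burst of consumption licks is placed
#' inside the zone so that downstream consumption-lick exclusion is
#' exercised.
#'
#' @param cfg a [gen_config()] object
#' @param states per-trial engagement states
#' @param types per-trial types ("standard"/"probe"/"crutch")
#' @param traj trajectory data.frame from [generate_trajectory()]
#' @return list with per-frame logical vectors `lick` and `reward`
#' @export
generate_licks <- function(cfg, states, types, traj) {
  n_frames <- nrow(traj)
  lick <- logical(n_frames)
  reward <- logical(n_frames)
  zs <- cfg$reward_zone_start
  ze <- zs + cfg$reward_zone_length
  for (tr in seq_along(states)) {
    idx <- which(traj$trial_index == tr)
    pos <- traj$position[idx]
    if (states[tr] == "engaged") {
      n <- stats::rpois(1, cfg$lick_rate_engaged)
      lp <- wrap_pos(stats::rnorm(n, zs, cfg$lick_concentration_engaged),
                     cfg$track_length)
    } else {
      n <- stats::rpois(1, cfg$lick_rate_disengaged)
      lp <- stats::runif(n, 0, cfg$track_length)
    }
    lf <- pmax(findInterval(lp, pos), 1L)
    lick[idx[lf]] <- TRUE

    # reward per task rules; at most one per trial
    rframe <- NA_integer_
    if (types[tr] == "standard") {
      zone_licks <- which(lick[idx] & pos >= zs & pos < ze)
      if (length(zone_licks)) rframe <- zone_licks[1]
    } else if (types[tr] == "crutch") {
      entry <- which(pos >= zs & pos < ze)
      if (length(entry)) rframe <- entry[1]
    }
    if (!is.na(rframe)) {
      reward[idx[rframe]] <- TRUE
      # consumption burst inside the zone, at/after the reward frame;
      # satiated disengaged mice often ignore the reward
      consumes <- states[tr] == "engaged" ||
        stats::runif(1) < cfg$consume_p_disengaged
      post <- which(seq_along(idx) >= rframe & pos >= zs & pos < ze)
      if (consumes && length(post)) {
        nb <- min(length(post), 1 + stats::rpois(1, 3))
        lick[idx[sort(sample(post, nb))]] <- TRUE
      }
    }
  }
  list(lick = lick, reward = reward)
}

# Mean of the wrapped-Gaussian tuning curve over the track (used as the
# flat activity level of untuned cells so population rates stay comparable
# across states).
flat_level <- function(cfg) {
  cfg$baseline_rate +
    cfg$field_amplitude * cfg$field_width_sd * sqrt(2 * pi) / cfg$track_length
}

# Evaluate a wrapped-Gaussian tuning curve at positions (cm).
tuning_rate <- function(pos, center, cfg) {
  if (is.na(center)) return(rep(flat_level(cfg), length(pos)))
  d <- circ_dist(pos, center, cfg$track_length)
  cfg$baseline_rate +
    cfg$field_amplitude * exp(-d^2 / (2 * cfg$field_width_sd^2))
}

#' Draw the ground-truth population tuning structure
#'
#' A `place_cell_fraction` of cells get a wrapped-Gaussian place field at a
#' uniform location on engaged trials. On disengaged trials, a fraction
#' `disengaged_field_loss` of those tuned cells lose their field (flat
#' disengaged curve), a fraction `disengaged_remap_fraction` of the
#' survivors remap to a new uniform center, and the rest retain their field.
#' Among engaged-untuned cells, a fraction `disengaged_field_gain` gain a
#' field on disengaged trials.
#'
#' @param cfg a [gen_config()] object
#' @return list of class `pg_truth` with per-cell `status`
#'   (retained/lost/gained/remapped/untuned), field centers per state
#'   (NA = untuned), and tuning curves evaluated at the 40 bin centers
#' @export
make_ground_truth <- function(cfg) {
  n <- cfg$n_cells
  tuned <- rep(FALSE, n)
  tuned[sample(n, round(cfg$place_cell_fraction * n))] <- TRUE
  status <- character(n)
  center_e <- rep(NA_real_, n)
  center_d <- rep(NA_real_, n)

  for (i in which(tuned)) {
    center_e[i] <- stats::runif(1, 0, cfg$track_length)
    u <- stats::runif(1)
    if (u < cfg$disengaged_field_loss) {
      status[i] <- "lost"
    } else if (u < cfg$disengaged_field_loss +
               (1 - cfg$disengaged_field_loss) * cfg$disengaged_remap_fraction) {
      status[i] <- "remapped"
      center_d[i] <- stats::runif(1, 0, cfg$track_length)
    } else {
      status[i] <- "retained"
      center_d[i] <- center_e[i]
    }
  }
  for (i in which(!tuned)) {
    if (stats::runif(1) < cfg$disengaged_field_gain) {
      status[i] <- "gained"
      center_d[i] <- stats::runif(1, 0, cfg$track_length)
    } else {
      status[i] <- "untuned"
    }
  }

  bw <- bin_width(cfg)
  centers <- (seq_len(cfg$n_spatial_bins) - 0.5) * bw
  curve_e <- t(vapply(seq_len(n),
                      function(i) tuning_rate(centers, center_e[i], cfg),
                      numeric(cfg$n_spatial_bins)))
  curve_d <- t(vapply(seq_len(n),
                      function(i) tuning_rate(centers, center_d[i], cfg),
                      numeric(cfg$n_spatial_bins)))
  structure(list(status = status,
                 center_engaged = center_e,
                 center_disengaged = center_d,
                 engaged_curve = curve_e,
                 disengaged_curve = curve_d),
            class = "pg_truth")
}

#' Generate the cells-by-frames activity matrix
#'
#' Frame activity is the state-appropriate tuning curve evaluated at the
#' current position, scaled by a per-cell, per-trial lognormal amplitude
#' factor (mean 1, CV `trial_amplitude_cv`; variance inflated by
#' `disengaged_noise_scale` on disengaged trials), plus additive
#' exponential (nonnegative) noise.
#'
#' @param cfg a [gen_config()] object
#' @param truth a `pg_truth` object from [make_ground_truth()]
#' @param traj trajectory data.frame
#' @param states per-trial engagement states
#' @return nonnegative matrix, `n_cells` x `n_frames`
#' @export
generate_activity <- function(cfg, truth, traj, states) {
  n_cells <- cfg$n_cells
  n_frames <- nrow(traj)
  n_trials <- length(states)
  dis_frame <- states[traj$trial_index] == "disengaged"

  rate <- matrix(0, n_cells, n_frames)
  for (i in seq_len(n_cells)) {
    rate[i, !dis_frame] <- tuning_rate(traj$position[!dis_frame],
                                       truth$center_engaged[i], cfg)
    if (any(dis_frame))
      rate[i, dis_frame] <- tuning_rate(traj$position[dis_frame],
                                        truth$center_disengaged[i], cfg)
  }

  # lognormal amplitude factor per (cell, trial), mean 1
  cv <- rep(cfg$trial_amplitude_cv, n_trials)
  cv[states == "disengaged"] <- cv[states == "disengaged"] *
    sqrt(cfg$disengaged_noise_scale)
  sl <- sqrt(log(1 + cv^2))
  amp <- matrix(stats::rlnorm(n_cells * n_trials,
                              rep(-0.5 * sl^2, each = n_cells),
                              rep(sl, each = n_cells)),
                n_cells, n_trials)
  rate <- rate * amp[, traj$trial_index, drop = FALSE]

  noise_mean <- ifelse(dis_frame,
                       cfg$noise_rate * cfg$disengaged_noise_scale,
                       cfg$noise_rate)
  if (cfg$noise_rate > 0) {
    rate <- rate + matrix(stats::rexp(n_cells * n_frames,
                                      rate = 1 / rep(noise_mean, each = n_cells)),
                          n_cells, n_frames)
  }
  rate
}

#' Generate a complete synthetic session
#'
#' Orchestrates state sequence, trial types, trajectory, licks/rewards,
#' ground-truth tuning and activity generation. Each component draws from
#' an independent substream derived from `seed`, so the same `(cfg, seed)`
#' always yields a bit-identical session.
#'
#' @param cfg a [gen_config()] object
#' @param seed integer seed (defaults to `cfg$seed`)
#' @param states optional per-trial engagement states to impose instead of
#'   sampling the Markov chain (e.g. a fixed engaged/disengaged split)
#' @param types optional per-trial types to impose
#' @return list with `session` (class `pg_session`: per-frame behavior plus
#'   the activity matrix) and `truth` (class `pg_truth`, including the true
#'   per-trial states and types)
#' @export
generate_session <- function(cfg, seed = cfg$seed, states = NULL, types = NULL) {
  validate_config(cfg)

  set.seed(substream_seed(seed, 1))
  if (is.null(states)) states <- generate_engagement_sequence(cfg)
  stopifnot(length(states) == cfg$n_trials,
            all(states %in% c("engaged", "disengaged")))

  set.seed(substream_seed(seed, 2))
  if (is.null(types)) types <- assign_trial_types(cfg)
  stopifnot(length(types) == cfg$n_trials)

  set.seed(substream_seed(seed, 3))
  traj <- generate_trajectory(cfg, states)

  set.seed(substream_seed(seed, 4))
  lr <- generate_licks(cfg, states, types, traj)

  set.seed(substream_seed(seed, 5))
  truth <- make_ground_truth(cfg)

  set.seed(substream_seed(seed, 6))
  activity <- generate_activity(cfg, truth, traj, states)

  truth$states <- states
  truth$types <- types

  session <- structure(list(
    frame_rate = cfg$frame_rate,
    track_length = cfg$track_length,
    n_spatial_bins = cfg$n_spatial_bins,
    position = traj$position,
    speed = traj$speed,
    lick = lr$lick,
    reward = lr$reward,
    trial_index = traj$trial_index,
    trial_type = types,
    activity = activity,
    config = cfg
  ), class = "pg_session")

  list(session = session, truth = truth)
}
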