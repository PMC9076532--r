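test_that("engagement Markov chain has the stated limiting behavior", {
  set.seed(1)
  # absorbing chain: start engaged, stay engaged
  cfg <- gen_config(engagement_markov = diag(2))
  expect_true(all(generate_engagement_sequence(cfg, 200) == "engaged"))

  # symmetric chain: stationary distribution is 1/2
  cfg <- gen_config(engagement_markov = matrix(0.5, 2, 2))
  s <- generate_engagement_sequence(cfg, 10000)
  expect_equal(mean(s == "engaged"), 0.5, tolerance = 0.05)

  # long-run empirical transition matrix converges to the generator matrix
  m <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  cfg <- gen_config(engagement_markov = m)
  s <- generate_engagement_sequence(cfg, 100000)
  si <- as.integer(s == "disengaged") + 1L
  emp <- prop.table(table(si[-length(si)], si[-1]), 1)
  expect_true(max(abs(emp - m)) < 0.01)
})

test_that("row-stochasticity of the engagement matrix is enforced", {
  expect_error(gen_config(engagement_markov = matrix(c(0.9, 0.2, 0.1, 0.9),
                                                     2, 2)),
               "engagement_markov")
})

test_that("trajectory realizes the engaged slowdown and one lap per trial", {
  cfg <- gen_config(engaged_slowdown_depth = 0.5, seed = 3)
  set.seed(3)
  states <- rep(c("engaged", "disengaged"), each = 25)
  traj <- generate_trajectory(cfg, states)

  # one lap per trial: every trial starts at 0 and stays inside the track
  expect_equal(length(unique(traj$trial_index)), 50)
  firsts <- !duplicated(traj$trial_index)
  expect_true(all(traj$position[firsts] == 0))
  expect_true(all(traj$position >= 0 & traj$position < cfg$track_length))
  # within a trial position is strictly increasing (no wrap mid-trial)
  expect_true(all(tapply(traj$position, traj$trial_index,
                         function(p) all(diff(p) > 0))))

  # engaged trials slow to about half the track-wide mean before the zone
  eng <- traj[states[traj$trial_index] == "engaged", ]
  dip <- eng$position >= cfg$reward_zone_start - 20 &
    eng$position < cfg$reward_zone_start
  profile_mean <- mean(tapply(eng$speed, floor(eng$position / 5), mean))
  expect_equal(mean(eng$speed[dip]) / profile_mean, 0.5, tolerance = 0.1)

  # disengaged trials have no dip
  dis <- traj[states[traj$trial_index] == "disengaged", ]
  dipd <- dis$position >= cfg$reward_zone_start - 20 &
    dis$position < cfg$reward_zone_start
  expect_equal(mean(dis$speed[dipd]) / mean(dis$speed), 1, tolerance = 0.1)
})

test_that("zero slowdown collapses the engaged/disengaged speed difference", {
  cfg <- gen_config(engaged_slowdown_depth = 0)
  set.seed(11)
  states <- rep(c("engaged", "disengaged"), each = 50)
  traj <- generate_trajectory(cfg, states)
  trial_means <- tapply(traj$speed, traj$trial_index, mean)
  eng <- trial_means[states == "engaged"]
  dis <- trial_means[states == "disengaged"]
  expect_gt(suppressWarnings(stats::ks.test(eng, dis)$p.value), 0.01)
})

test_that("licks and rewards follow the task rules", {
  gen <- small_session()
  s <- gen$session
  types <- gen$truth$types
  for (tr in seq_along(types)) {
    fr <- which(s$trial_index == tr)
    n_rew <- sum(s$reward[fr])
    expect_lte(n_rew, 1)
    if (types[tr] == "probe") expect_equal(n_rew, 0)
    if (types[tr] == "crutch") {
      expect_equal(n_rew, 1)
      # crutch reward fires at zone entry regardless of licking
      rf <- fr[which(s$reward[fr])]
      entry <- fr[which(s$position[fr] >= s$config$reward_zone_start)[1]]
      expect_equal(rf, entry)
    }
  }
})

test_that("a crutch trial with zero licks is still rewarded at zone entry", {
  cfg <- gen_config(n_trials = 6, n_cells = 2, lick_rate_engaged = 0,
                    lick_rate_disengaged = 0, p_probe = 0, p_crutch = 1)
  gen <- generate_session(cfg, seed = 1)
  s <- gen$session
  for (tr in 1:6) {
    fr <- which(s$trial_index == tr)
    expect_equal(sum(s$reward[fr]), 1)
    rf <- fr[which(s$reward[fr])]
    expect_gte(s$position[rf], cfg$reward_zone_start)
  }
})

test_that("lick-free trials propagate an undefined selectivity", {
  cfg <- gen_config(n_trials = 8, n_cells = 2, lick_rate_disengaged = 0,
                    p_probe = 1, p_crutch = 0)
  gen <- generate_session(cfg, seed = 2,
                          states = rep("disengaged", 8))
  tt <- build_trial_table(gen$session, classify = FALSE)
  expect_true(all(is.na(tt$lick_selectivity)))
  expect_true(all(tt$bins_with_licks == 0))
})

test_that("noiseless binned activity recovers the engaged tuning curve", {
  gen <- clean_session()
  s <- gen$session
  mm <- rate_map_average(bin_activity(s, 1:24, smooth_sd_cm = 1e-6))
  tuned <- which(!is.na(gen$truth$center_engaged))
  rel_err <- abs(mm[tuned, ] - gen$truth$engaged_curve[tuned, ]) /
    max(gen$truth$engaged_curve)
  # occupancy-discretization error only
  expect_lt(stats::median(rel_err), 0.01)
  expect_lt(max(rel_err), 0.05)
  # peak bins match ground-truth centers
  pk <- apply(mm[tuned, ], 1, which.max)
  true_bin <- floor(gen$truth$center_engaged[tuned] / 5) + 1
  expect_true(all(circ_dist(pk, true_bin, 40) <= 1))
})

test_that("a lost cell is position-independent on disengaged trials", {
  cfg <- gen_config(n_trials = 20, n_cells = 10, disengaged_field_loss = 1,
                    disengaged_field_gain = 0, place_cell_fraction = 1,
                    trial_amplitude_cv = 0, seed = 9)
  gen <- generate_session(cfg, seed = 9, states = rep("disengaged", 20))
  s <- gen$session
  rm_ <- bin_activity(s, 1:20, smooth_sd_cm = 1e-6)
  expect_true(all(gen$truth$status == "lost"))
  for (i in 1:5) {
    df <- data.frame(a = as.vector(rm_$map[i, , ]),
                     bin = factor(rep(1:40, each = 20)))
    p <- stats::anova(stats::lm(a ~ bin, df))$`Pr(>F)`[1]
    expect_gt(p, 0.01)
  }
})

test_that("full remapping draws new centers uniformly on the circle", {
  cfg <- gen_config(n_cells = 500, place_cell_fraction = 1,
                    disengaged_field_loss = 0, disengaged_field_gain = 0,
                    disengaged_remap_fraction = 1)
  set.seed(21)
  truth <- make_ground_truth(cfg)
  expect_true(all(truth$status == "remapped"))
  d <- circ_dist(truth$center_engaged, truth$center_disengaged, 200)
  counts <- table(cut(d, seq(0, 100, by = 10)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("sessions are bit-identical given (config, seed)", {
  cfg <- gen_config(n_trials = 10, n_cells = 5)
  a <- generate_session(cfg, seed = 123)
  b <- generate_session(cfg, seed = 123)
  expect_identical(a, b)
})

test_that("trial types are drawn with the configured probabilities", {
  cfg <- gen_config(p_probe = 0.1, p_crutch = 0.15)
  set.seed(4)
  types <- placegate:::assign_trial_types(cfg, 10000)
  expect_lt(abs(mean(types == "probe") - 0.10), 0.01)
  expect_lt(abs(mean(types == "crutch") - 0.15), 0.011)
})

test_that("disengaged decoding error grows with the noise scale", {
  errs <- sapply(c(1, 3, 8), function(ns) {
    mean(sapply(1:20, function(sd) {
      cfg <- gen_config(n_trials = 30, n_cells = 25,
                        disengaged_noise_scale = ns,
                        disengaged_field_loss = 0,
                        disengaged_field_gain = 0,
                        disengaged_remap_fraction = 0)
      gen <- generate_session(cfg, seed = 100 + sd,
                              states = rep(c("engaged", "disengaged"),
                                           c(15, 15)))
      model <- fit_template(gen$session, 1:15)
      mean(placegate:::.trial_errors(gen$session, model, 16:30),
           na.rm = TRUE)
    }))
  })
  expect_true(all(diff(errs) > 0))
})
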