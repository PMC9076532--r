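test_that("trials are segmented at position wraps with half-open bounds", {
  pos <- rep(seq(0, 199.9, by = 5), 3)
  tr <- segment_trials(pos, 30)
  expect_equal(nrow(tr), 3)
  expect_equal(tr$start_frame, c(1, 41, 81))
  expect_equal(tr$end_frame, c(41, 81, 121))
  # the 0.0-cm frame after a wrap belongs to the new trial
  expect_equal(pos[tr$start_frame], rep(0, 3))
  expect_error(segment_trials(seq(0, 100, by = 5), 30), "laps")

  # generator sessions are recovered exactly
  gen <- small_session()
  tt <- segment_trials(gen$session$position, 30)
  expect_equal(nrow(tt), gen$session$config$n_trials)
})

test_that("consumption licks are licks in the zone at/after the reward", {
  zone <- c(140, 160)
  pos <- c(90, 150, 155, 170)
  lick <- c(TRUE, TRUE, TRUE, FALSE)
  rew <- c(FALSE, TRUE, FALSE, FALSE)
  cons <- classify_licks(pos, lick, rew, zone)
  expect_equal(cons, c(FALSE, TRUE, TRUE, FALSE))

  # no reward (probe): nothing is consumption
  expect_equal(classify_licks(pos, lick, rep(FALSE, 4), zone),
               rep(FALSE, 4))

  # crutch rewarded at entry: later in-zone lick is consumption
  pos2 <- c(139, 141, 150)
  cons2 <- classify_licks(pos2, c(FALSE, FALSE, TRUE),
                          c(FALSE, TRUE, FALSE), zone)
  expect_equal(cons2, c(FALSE, FALSE, TRUE))
})

test_that("lick selectivity matches the zone-mass formula", {
  # all licks deep in the analysis zone: selectivity ~ 1
  expect_gt(lick_selectivity(rep(145, 5)), 0.99)
  # uniform licking: symmetry of the equal-length zones gives 0
  expect_equal(lick_selectivity(seq(1, 199, by = 2)), 0, tolerance = 1e-9)
  # no licks near either zone is still defined (smoothing leaks), but
  # zero licks anywhere is undefined
  expect_true(is.na(lick_selectivity(numeric(0))))
  # antisymmetry: swapping the two zones negates the value
  licks <- c(135, 142, 150, 20, 80)
  expect_equal(lick_selectivity(licks, 140),
               -lick_selectivity(licks, 40), tolerance = 1e-12)
  # bounded
  set.seed(8)
  for (k in 1:20) {
    v <- lick_selectivity(stats::runif(5, 0, 200))
    expect_true(is.na(v) || (v >= -1 && v <= 1))
  }
})

test_that("bins_with_licks counts occupied 5-cm bins", {
  expect_equal(bins_with_licks(numeric(0)), 0L)
  expect_equal(bins_with_licks(c(101, 101.5, 102, 103, 103.9, 101.1, 102.7)), 1L)
  expect_equal(bins_with_licks(c(2, 52, 102, 152)), 4L)
})

test_that("k-means engagement clustering separates and labels correctly", {
  # two perfectly separated point clouds in metric space
  set.seed(2)
  n <- 100
  sel <- c(stats::rnorm(n, 0.95, 0.01), stats::rnorm(n, -0.5, 0.01))
  bins <- c(stats::rnorm(n, 8, 0.1), stats::rnorm(n, 1, 0.1))
  cl <- cluster_engagement(sel, pmax(bins, 0))
  expect_equal(cl$label, rep(c("engaged", "disengaged"), each = n))
  expect_gt(mean(cl$silhouette > 0.9), 0.95)

  # duplicating every trial leaves labels unchanged for the duplicates
  cl2 <- cluster_engagement(rep(sel, 2), rep(pmax(bins, 0), 2))
  expect_equal(cl2$label[1:(2 * n)], cl2$label[(2 * n + 1):(4 * n)])

  # undefined-selectivity trials are labeled disengaged outside clustering
  cl3 <- cluster_engagement(c(sel, NA, NA), c(pmax(bins, 0), 0, 0))
  expect_equal(tail(cl3$label, 2), rep("disengaged", 2))
  expect_true(all(is.na(tail(cl3$silhouette, 2))))

  expect_error(cluster_engagement(rep(0.5, 10), rep(3, 10)), "degenerate")
})

test_that("trial exclusion implements duration and crutch-zone rules", {
  trials <- data.frame(trial = 1:3, duration_s = c(2.5, 30, 30),
                       type = c("standard", "crutch", "standard"))
  lp <- list(numeric(0), c(135, 150), c(20, 150))
  out <- exclude_trials(trials, lp)
  expect_true(out$excluded[1])
  expect_equal(out$exclude_reason[1], "duration")
  expect_true(out$excluded[2])
  expect_equal(out$exclude_reason[2], "crutch-zone-only")
  expect_false(out$excluded[3])

  # crutch trial with an out-of-zone lick is retained
  out2 <- exclude_trials(data.frame(trial = 1, duration_s = 30,
                                    type = "crutch"),
                         list(c(135, 90)))
  expect_false(out2$excluded[1])
})

test_that("streak statistics match hand enumeration and the shuffle law", {
  lab <- c("engaged", "engaged", "disengaged", "disengaged", "disengaged",
           "engaged")
  st <- streak_stats(lab, n_shuffles = 200)
  expect_equal(st$streak_hist, c("3" = 1L))
  expect_equal(st$transition_counts["engaged", "engaged"], 2)
  expect_equal(st$transition_counts["engaged", "disengaged"], 1)
  expect_equal(st$transition_counts["disengaged", "disengaged"], 2)
  expect_equal(st$transition_counts["disengaged", "engaged"], 1)
  expect_equal(rowSums(st$transition_matrix), c(engaged = 1, disengaged = 1))
  expect_equal(sum(st$streak_hist * as.integer(names(st$streak_hist))),
               sum(lab == "disengaged"))

  # all-engaged sequence
  st2 <- streak_stats(rep("engaged", 10), n_shuffles = 10)
  expect_equal(length(st2$streak_hist), 0L)
  expect_equal(st2$transition_matrix["engaged", "engaged"], 1)

  # shuffle control: exchangeability gives P(D->D) ~ (k-1)/(n-1)
  set.seed(6)
  lab3 <- rep(c("disengaged", "engaged"), c(8, 16))
  st3 <- streak_stats(lab3, n_shuffles = 2000)
  expect_equal(st3$shuffle_transition_matrix["disengaged", "disengaged"],
               7 / 23, tolerance = 0.03)
})

test_that("session inclusion applies the four criteria", {
  mk <- function(n, n_dis, ls = 0.9) {
    data.frame(trial = 1:n, lick_selectivity = ls,
               engagement = rep(c("engaged", "disengaged"),
                                c(n - n_dis, n_dis)))
  }
  good_err <- c(rep(NA, 20), rep(5, 40))
  ok <- session_inclusion(mk(60, 20), good_err)
  expect_true(ok$included)

  short <- session_inclusion(mk(40, 15), c(rep(NA, 20), rep(5, 20)))
  expect_false(short$included)
  expect_true("trial count" %in% short$reasons)

  few_dis <- session_inclusion(mk(60, 9), good_err)
  expect_false(few_dis$included)
  expect_true(few_dis$engaged_only)

  bad_ls <- session_inclusion(mk(60, 20, ls = 0.5), good_err)
  expect_true("lick selectivity" %in% bad_ls$reasons)

  bad_dec <- session_inclusion(mk(60, 20), rep(30, 60))
  expect_true("decoding quality" %in% bad_dec$reasons)
})

test_that("label recovery degrades gracefully as state separation shrinks", {
  # widening the engaged lick concentration toward uniform licking erases
  # the behavioral difference between the states
  acc <- sapply(c(10, 40, 120), function(conc) {
    mean(sapply(1:3, function(sd) {
      cfg <- gen_config(n_trials = 60, n_cells = 2,
                        lick_concentration_engaged = conc)
      gen <- generate_session(cfg, seed = 200 + sd,
                              states = rep(c("engaged", "disengaged"),
                                           c(40, 20)))
      tt <- build_trial_table(gen$session)
      mean(tt$engagement == gen$truth$states)
    }))
  })
  expect_true(all(diff(acc) <= 0.02))  # non-increasing up to small jitter
  expect_gt(acc[1], 0.9)
})
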