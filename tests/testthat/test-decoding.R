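# Brute-force evaluation of the Poisson naive-Bayes posterior, kept
# deliberately naive (products and scalar loops) as an independent oracle.
brute_posterior <- function(template, tau, a) {
  n_bins <- ncol(template)
  eps <- max(0.01 * mean(template), 1e-12)
  lik <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    f <- template[, b] + eps
    lik[b] <- prod(f^a) * exp(-tau * sum(f))
  }
  lik / sum(lik)
}

test_that("decode_frames matches the closed-form likelihood on a toy case", {
  # 1 cell, 2 bins, f = (2, 1), tau = 1, a = 3: likelihoods 8 e^-2 vs e^-1
  model <- structure(list(template = matrix(c(2, 1), 1, 2), tau = 1,
                          n_bins = 2), class = "pg_decoder")
  out <- decode_frames(model, matrix(3, 1, 1))
  expect_equal(out$map_bin, 1L)
  oracle <- brute_posterior(model$template, 1, 3)
  expect_equal(as.numeric(out$posterior), oracle, tolerance = 1e-9)

  # zero activity: posterior favors the bin with least expected activity
  out0 <- decode_frames(model, matrix(0, 1, 1))
  expect_equal(out0$map_bin, 2L)

  # uniform template: posterior uniform, MAP = lowest bin by the tie rule
  mu <- structure(list(template = matrix(1, 3, 5), tau = 1, n_bins = 5),
                  class = "pg_decoder")
  outu <- decode_frames(mu, matrix(c(1, 2, 0), 3, 1))
  expect_equal(as.numeric(outu$posterior), rep(0.2, 5), tolerance = 1e-12)
  expect_equal(outu$map_bin, 1L)
})

test_that("posteriors are normalized and stable for large activity", {
  set.seed(12)
  model <- structure(list(template = matrix(stats::rexp(50 * 40), 50, 40),
                          tau = 1 / 30, n_bins = 40), class = "pg_decoder")
  a <- matrix(stats::runif(50 * 20, 0, 1e4), 50, 20)
  out <- decode_frames(model, a)
  expect_true(all(is.finite(out$posterior)))
  expect_equal(rowSums(out$posterior), rep(1, 20), tolerance = 1e-9)
})

test_that("circular error and chance level have their closed forms", {
  expect_equal(circular_error(1, 21)$bins, 20)
  expect_equal(circular_error(1, 21)$cm, 100)
  expect_equal(circular_error(8, 8)$bins, 0)
  # brute-force min over the two arc directions
  expect_equal(circular_error(6, 40)$bins, 6)
  expect_equal(circular_error(6, 40)$cm, 30)
  expect_error(circular_error(0, 5), "out of range")

  expect_equal(chance_error(40)$bins, 10)
  expect_equal(chance_error(40)$cm, 50)
  # n = 4: distances {0,1,1,2}, mean 1
  expect_equal(chance_error(4)$bins, 1)
})

test_that("templates equal rate maps, with zeros floored only at decode", {
  gen <- clean_session()
  s <- gen$session
  model <- fit_template(s, 1:20)
  tuned <- which(!is.na(gen$truth$center_engaged))
  rel <- abs(model$template[tuned, ] - gen$truth$engaged_curve[tuned, ])
  # smoothing broadens the curve; compare after smoothing the truth
  sm_truth <- smooth_circular(gen$truth$engaged_curve[tuned, ], 2)
  expect_lt(max(abs(model$template[tuned, ] - sm_truth)) /
              max(sm_truth), 0.05)

  # single training trial: template equals that trial's rate map
  rm1 <- bin_activity(s, 3)
  m1 <- fit_template(s, 3)
  expect_equal(m1$template, rm1$map[, 1, ], tolerance = 1e-12)

  # a silent cell keeps an all-zero template row
  s2 <- s
  s2$activity[1, ] <- 0
  m2 <- fit_template(s2, 1:5)
  expect_equal(m2$template[1, ], rep(0, 40))
  expect_error(fit_template(s, integer(0)), "empty")
})

test_that("decoding error is invariant to joint circular rotation", {
  gen <- clean_session()
  s <- gen$session
  model <- fit_template(s, 1:12)
  e1 <- placegate:::.trial_errors(s, model, 13:24)
  k <- 11
  s_rot <- s
  s_rot$position <- (s$position + k * 5) %% 200
  model_rot <- fit_template(s_rot, 1:12)
  e2 <- placegate:::.trial_errors(s_rot, model_rot, 13:24)
  expect_equal(e1, e2, tolerance = 0.5)
})

test_that("sliding decoder needs a window plus one and flags early trials", {
  gen <- small_session()
  s <- gen$session
  expect_error(sliding_decoder(s, 1:20), "more than")
  sl <- sliding_decoder(s, 1:30)
  expect_true(all(is.na(sl$error_cm[1:20])))
  expect_true(all(!is.na(sl$error_cm[21:30])))
  # engaged, high-SNR trials decode well
  expect_lt(mean(sl$error_cm[21:30]), 10)
})

test_that("engagement decoder reproduces the degradation asymmetry", {
  gen <- small_session()
  s <- gen$session
  states <- gen$truth$states
  ed <- engagement_decoder(s, 1:45, states)
  expect_true(all(c("EE", "ED", "DE", "DD") %in% names(ed$errors)))
  expect_lt(ed$errors["EE"], 10)
  expect_gt(ed$errors["ED"], 1.5 * ed$errors["EE"])
  expect_lt(ed$errors["ED"], chance_error()$cm)
  expect_gt(ed$errors["DE"], ed$errors["EE"])
  expect_error(engagement_decoder(s, 1:12, rep("engaged", 12)),
               "disengaged")
})

test_that("no degradation means no decoder asymmetry", {
  errs <- t(sapply(1:8, function(sd) {
    cfg <- gen_config(n_trials = 44, n_cells = 25,
                      disengaged_field_loss = 0, disengaged_field_gain = 0,
                      disengaged_remap_fraction = 0,
                      disengaged_noise_scale = 1,
                      engaged_slowdown_depth = 0)
    gen <- generate_session(cfg, seed = 400 + sd,
                            states = rep(c("engaged", "disengaged"),
                                         c(22, 22)))
    engagement_decoder(gen$session, 1:44, gen$truth$states)$errors
  }))
  p <- compare_groups(errs[, "EE"], errs[, "ED"], paired = TRUE)$p_value
  expect_gt(p, 0.05)
  expect_lt(abs(mean(errs[, "EE"]) - mean(errs[, "ED"])), 2)
})

test_that("speed matching retains exactly matched per-bin speed counts", {
  gen <- small_session()
  s <- gen$session
  fa <- placegate:::.test_frames(s, 1:10)
  fb <- placegate:::.test_frames(s, 31:40)
  set.seed(31)
  plan <- speed_match(s, fa, fb)
  expect_equal(length(plan$keep_a), length(plan$keep_b))
  key <- function(fr) paste(floor(s$position[fr] / 2),
                            floor(s$speed[fr] / 5))
  expect_equal(sort(table(key(plan$keep_a))), sort(table(key(plan$keep_b))))
  expect_true(plan$usable)

  # identical sets: every frame retained, no empty bins
  plan2 <- speed_match(s, fa, fa)
  expect_equal(plan2$keep_a, sort(fa))
  expect_equal(plan2$n_empty_bins, 0)

  # disjoint speed distributions: unusable
  s3 <- s
  s3$speed[fb] <- s3$speed[fb] + 500
  plan3 <- speed_match(s3, fa, fb)
  expect_false(plan3$usable)
  expect_gt(plan3$n_empty_bins, 10)
})

test_that("overlap rule takes the per-cell minimum count", {
  s <- list(track_length = 200,
            position = c(rep(1, 5), rep(1, 3)),
            speed = rep(7, 8))
  plan <- speed_match(s, 1:5, 6:8)
  expect_equal(length(plan$keep_a), 3)
  expect_equal(plan$keep_b, 6:8)
})

test_that("streak detection and the onset decoder follow the criteria", {
  lab <- rep(c("engaged", "disengaged"), c(30, 12))
  q <- qualifying_streaks(lab)
  expect_equal(q$onset, 31)
  expect_equal(q$length, 12)
  # a 9-trial streak does not qualify
  expect_equal(nrow(qualifying_streaks(rep(c("engaged", "disengaged"),
                                           c(30, 9)))), 0)
  # preceding window must be at least 80% engaged
  lab2 <- c(rep(c("engaged", "disengaged"), 15), rep("disengaged", 10))
  expect_equal(nrow(qualifying_streaks(lab2)), 0)

  gen <- small_session()
  so <- streak_onset_decoder(gen$session, gen$truth$states)
  expect_equal(range(so$align), c(-20, 14))
  pre <- mean(so$error_cm[so$align < 0])
  post <- mean(so$error_cm[so$align >= 0 & so$align < 5])
  expect_gt(post, 2 * pre)  # error rises within five trials of onset
})

test_that("template matching decodes matched and scaled population vectors", {
  set.seed(14)
  template <- matrix(stats::rexp(30 * 40), 30, 40)
  model <- structure(list(template = template, tau = 1 / 30, n_bins = 40),
                     class = "pg_decoder")
  b <- 17
  expect_equal(template_match_decode(model, template[, b]), b)
  expect_equal(template_match_decode(model, 3 * template[, b]), b)
  expect_true(is.na(template_match_decode(model, numeric(30))))

  # Bayes and template matching agree on high-SNR synthetic data: both
  # decode near-perfectly, within 20% or half a spatial bin of each other
  gen <- highsnr_session()
  s <- gen$session
  m <- fit_template(s, 1:15)
  eb <- mean(placegate:::.trial_errors(s, m, 16:30), na.rm = TRUE)
  et <- mean(placegate:::.trial_errors(s, m, 16:30, decoder = "template"),
             na.rm = TRUE)
  expect_lt(eb, 10)
  expect_lt(et, 10)
  expect_lt(abs(eb - et), max(0.2 * max(eb, et), 2.5))
})
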