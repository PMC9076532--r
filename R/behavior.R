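#' Segment a session into trials at position wraps
#'
#' A new trial starts at each downward wrap of the (wrapped) position
#' trace; boundaries are half-open frame intervals, so the first frame at
#' or past 0 cm after a wrap belongs to the new trial.
#'
#' @param position per-frame wrapped position, cm
#' @param frame_rate Hz
#' @param trial_type optional per-trial type vector to attach
#' @param track_length cm
#' @return data.frame with `trial`, `start_frame`, `end_frame` (half-open),
#'   `duration_s` and `type`
#' @export
segment_trials <- function(position, frame_rate, trial_type = NULL,
                           track_length = 200) {
  wraps <- which(diff(position) < -track_length / 2)
  if (!length(wraps)) stop("no laps detected in position trace")
  starts <- c(1L, wraps + 1L)
  ends <- c(wraps + 1L, length(position) + 1L)  # half-open
  n <- length(starts)
  tt <- if (is.null(trial_type)) rep(NA_character_, n) else {
    stopifnot(length(trial_type) == n)
    trial_type
  }
  data.frame(trial = seq_len(n), start_frame = starts, end_frame = ends,
             duration_s = (ends - starts) / frame_rate, type = tt,
             stringsAsFactors = FALSE)
}

#' Classify each lick as consumption or non-consumption
#'
#' On rewarded trials, licks inside the true reward zone at or after the
#' reward frame are consumption licks (including the reward-triggering
#' lick) and are excluded from all lick metrics. All other licks,
#' including every lick on unrewarded trials, are non-consumption.
#'
#' @param position,lick,reward per-frame vectors for one trial
#' @param reward_zone `c(start, end)` of the true reward zone, cm
#' @return logical vector (same length as the trial): TRUE where the frame
#'   holds a consumption lick
#' @export
classify_licks <- function(position, lick, reward, reward_zone) {
  stopifnot(sum(reward) <= 1)
  cons <- logical(length(lick))
  rf <- which(reward)
  if (length(rf)) {
    in_zone <- position >= reward_zone[1] & position < reward_zone[2]
    cons <- lick & in_zone & seq_along(lick) >= rf
  }
  cons
}

# Smoothed circular lick profile on 2-cm bins (Gaussian s.d. 10 cm,
# truncated at 3 s.d. so licks far from a zone contribute no mass there).
lick_profile <- function(lick_positions, track_length = 200,
                         profile_bin = 2, smooth_sd_cm = 10) {
  nb <- round(track_length / profile_bin)
  counts <- tabulate(floor(lick_positions / profile_bin) + 1L, nbins = nb)
  drop(matrix(counts, 1) %*%
         t(circular_gaussian_matrix(nb, smooth_sd_cm / profile_bin,
                                    truncate_sd = 3)))
}

# Bin indices (2-cm profile bins) of a circular zone [from, from+len) cm.
zone_bins <- function(from, len, track_length = 200, profile_bin = 2) {
  nb <- round(track_length / profile_bin)
  first <- floor(wrap_pos(from, track_length) / profile_bin)
  (first + seq_len(round(len / profile_bin)) - 1L) %% nb + 1L
}

#' Lick selectivity of one trial
#'
#' Non-consumption licks are binned into 2-cm bins, circularly smoothed
#' (Gaussian s.d. 10 cm), and selectivity is
#' (reward-zone mass - opposite-zone mass) / (sum). The analysis reward
#' zone starts 10 cm before reward availability to include anticipatory
#' licking and spans 30 cm; the opposite zone is the same interval shifted
#' half a track. Returns NA when both zone masses are zero (no licks near
#' either zone).
#'
#' @param lick_positions positions (cm) of the trial's non-consumption licks
#' @param reward_zone_start cm where rewards become available
#' @param track_length cm
#' @return scalar in [-1, 1], or NA
#' @export
lick_selectivity <- function(lick_positions, reward_zone_start = 140,
                             track_length = 200) {
  prof <- lick_profile(lick_positions, track_length)
  rz <- zone_bins(reward_zone_start - 10, 30, track_length)
  oz <- zone_bins(reward_zone_start - 10 + track_length / 2, 30, track_length)
  a <- sum(prof[rz])
  b <- sum(prof[oz])
  if (a + b == 0) return(NA_real_)
  (a - b) / (a + b)
}

#' Number of 5-cm spatial bins with licks
#'
#' A lick-count proxy that is robust to burst licking: the number of 5-cm
#' bins containing at least one non-consumption lick.
#'
#' @param lick_positions positions (cm) of non-consumption licks
#' @param track_length cm
#' @param bin_cm spatial bin width, cm
#' @return integer count
#' @export
bins_with_licks <- function(lick_positions, track_length = 200, bin_cm = 5) {
  if (!length(lick_positions)) return(0L)
  length(unique(floor(wrap_pos(lick_positions, track_length) / bin_cm)))
}

# silhouette scores for a 2-cluster assignment on points in rows of x;
# squared Euclidean distance, the convention of MATLAB's silhouette()
silhouette2 <- function(x, cl) {
  d <- as.matrix(stats::dist(x))^2
  n <- nrow(x)
  vapply(seq_len(n), function(i) {
    own <- which(cl == cl[i]); own <- own[own != i]
    oth <- which(cl != cl[i])
    if (!length(own)) return(0)
    a <- mean(d[i, own]); b <- mean(d[i, oth])
    (b - a) / max(a, b)
  }, numeric(1))
}

#' Classify trials as engaged or disengaged by k-means on lick metrics
#'
#' Lick selectivity and bins-with-licks are z-scored across trials and
#' clustered with 2-means (deterministic seed, 10 restarts). The cluster
#' whose centroid has the larger coordinate sum in normalized space is
#' labeled engaged (ties broken by the lick-selectivity coordinate).
#' Trials with undefined selectivity (no non-consumption licks) cannot be
#' task-engaged and are labeled disengaged without entering the
#' clustering.
#'
#' @param selectivity per-trial lick selectivity (NA allowed)
#' @param n_lick_bins per-trial bins-with-licks counts
#' @param kmeans_seed,nstart determinism controls
#' @return list with per-trial `label`, `silhouette` (NA for trials
#'   outside the clustering) and `centroids` in normalized metric space
#' @export
cluster_engagement <- function(selectivity, n_lick_bins, kmeans_seed = 0,
                               nstart = 10) {
  stopifnot(length(selectivity) == length(n_lick_bins))
  ok <- !is.na(selectivity)
  if (sum(ok) < 2) stop("need at least 2 trials with defined lick metrics")
  z <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  x <- cbind(sel = z(selectivity[ok]), bins = z(n_lick_bins[ok]))
  if (all(apply(x, 2, function(col) length(unique(col)) == 1)))
    stop("degenerate clustering: all trials identical in metric space")
  old <- .Random.seed_save()
  set.seed(kmeans_seed)
  km <- stats::kmeans(x, centers = 2, nstart = nstart, iter.max = 100)
  .Random.seed_restore(old)
  sums <- rowSums(km$centers)
  engaged_cl <- if (abs(diff(sums)) < 1e-12) {
    which.max(km$centers[, "sel"])
  } else which.max(sums)
  label <- rep("disengaged", length(selectivity))
  label[ok][km$cluster == engaged_cl] <- "engaged"
  sil <- rep(NA_real_, length(selectivity))
  sil[ok] <- silhouette2(x, km$cluster)
  list(label = label, silhouette = sil, centroids = km$centers,
       engaged_cluster = engaged_cl)
}

# save/restore global RNG state so seeded sub-steps do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Flag trials excluded from analysis
#'
#' Excludes trials shorter than 3 s or longer than 60 s, crutch trials
#' whose non-consumption licks all fall inside the analysis reward zone
#' (licking only where reward is guaranteed carries no evidence of
#' engagement), and trials annotated as manually rewarded. Excluded trials
#' keep their metrics but are dropped from downstream analyses.
#'
#' @param trials trial table with `duration_s` and `type`
#' @param lick_positions list (per trial) of non-consumption lick
#'   positions, cm
#' @param reward_zone_start cm; the analysis zone is
#'   `[reward_zone_start - 10, reward_zone_start + 20)`
#' @param manual_reward optional logical per-trial annotation
#' @param track_length cm
#' @return `trials` with logical `excluded` and character `exclude_reason`
#' @export
exclude_trials <- function(trials, lick_positions, reward_zone_start = 140,
                           manual_reward = NULL, track_length = 200) {
  n <- nrow(trials)
  excluded <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  mark <- function(i, why) {
    excluded[i] <<- TRUE
    reason[i] <<- ifelse(is.na(reason[i]), why, paste(reason[i], why, sep = ";"))
  }
  bad_dur <- trials$duration_s < 3 | trials$duration_s > 60
  if (any(bad_dur)) mark(which(bad_dur), "duration")
  zone_only <- function(lp) {
    if (!length(lp)) return(FALSE)
    d <- wrap_pos(lp - (reward_zone_start - 10), track_length)
    all(d < 30)
  }
  crutch_bad <- trials$type == "crutch" &
    vapply(lick_positions, zone_only, logical(1))
  if (any(crutch_bad)) mark(which(crutch_bad), "crutch-zone-only")
  if (!is.null(manual_reward) && any(manual_reward))
    mark(which(manual_reward), "manual-reward")
  trials$excluded <- excluded
  trials$exclude_reason <- reason
  trials
}

#' Streak and transition statistics of engagement labels
#'
#' Decomposes the label sequence into maximal runs, reports the
#' disengaged streak-length histogram and the empirical 2x2 transition
#' matrix, and compares against a shuffle control: the same statistics on
#' uniform permutations of the label multiset (default 1,000), averaged.
#'
#' Transitions are counted circularly (the last trial transitions to the
#' first), so every trial contributes exactly one outgoing transition and
#' each row's count equals that state's trial count; under label
#' exchangeability the expected P(D to D) is then exactly (k-1)/(n-1) for
#' k disengaged of n trials. Streaks are maximal runs of the linear
#' sequence (no wrap).
#'
#' @param labels per-trial "engaged"/"disengaged" labels
#' @param n_shuffles permutations for the control
#' @return list with `streak_hist` (named disengaged-streak-length counts),
#'   `transition_counts`, `transition_matrix`, and shuffle-control means
#'   `shuffle_transition_matrix` and `shuffle_streak_hist`
#' @export
streak_stats <- function(labels, n_shuffles = 1000) {
  stopifnot(length(labels) >= 2)
  lv <- c("engaged", "disengaged")
  stopifnot(all(labels %in% lv))
  one <- function(lab) {
    r <- rle(lab)
    dls <- r$lengths[r$values == "disengaged"]
    hist <- tabulate(dls, nbins = length(lab))
    tc <- matrix(0, 2, 2, dimnames = list(from = lv, to = lv))
    nxt <- c(lab[-1], lab[1])  # circular closure
    for (i in seq_along(lab))
      tc[lab[i], nxt[i]] <- tc[lab[i], nxt[i]] + 1
    list(hist = hist, counts = tc)
  }
  obs <- one(labels)
  rs <- rowSums(obs$counts)
  tm <- obs$counts / ifelse(rs == 0, 1, rs)

  sh_tm <- matrix(0, 2, 2, dimnames = dimnames(obs$counts))
  sh_hist <- numeric(length(labels))
  for (s in seq_len(n_shuffles)) {
    p <- one(sample(labels))
    prs <- rowSums(p$counts)
    sh_tm <- sh_tm + p$counts / ifelse(prs == 0, 1, prs)
    sh_hist <- sh_hist + p$hist
  }
  hist_named <- function(h) {
    nz <- which(h > 0)
    stats::setNames(h[nz], nz)
  }
  list(streak_hist = hist_named(obs$hist),
       transition_counts = obs$counts,
       transition_matrix = tm,
       shuffle_transition_matrix = sh_tm / n_shuffles,
       shuffle_streak_hist = sh_hist / n_shuffles)
}

#' Session-level inclusion decision
#'
#' A session enters the main analysis when it has at least `min_trials`
#' trials, mean lick selectivity over trials with licks above `min_mean_ls`,
#' at least 20 trials whose sliding-decoder error is below 10 cm, and more
#' than ten trials of each engagement state. Sessions failing only the
#' disengaged-trial count are flagged `engaged_only` rather than rejected
#' outright.
#'
#' @param trials trial table with `lick_selectivity` and `engagement`
#' @param sliding_errors_cm per-trial mean decoding error from
#'   [sliding_decoder()] (NA for trials without a prediction)
#' @param min_trials,min_mean_ls thresholds
#' @return list(`included`, `engaged_only`, `reasons`)
#' @export
session_inclusion <- function(trials, sliding_errors_cm, min_trials = 50,
                              min_mean_ls = 0.7) {
  reasons <- character(0)
  if (nrow(trials) < min_trials) reasons <- c(reasons, "trial count")
  ls <- trials$lick_selectivity
  if (!any(!is.na(ls)) || mean(ls, na.rm = TRUE) <= min_mean_ls)
    reasons <- c(reasons, "lick selectivity")
  if (sum(sliding_errors_cm < 10, na.rm = TRUE) < 20)
    reasons <- c(reasons, "decoding quality")
  n_eng <- sum(trials$engagement == "engaged")
  n_dis <- sum(trials$engagement == "disengaged")
  if (n_eng <= 10) reasons <- c(reasons, "engaged count")
  engaged_only <- n_dis <= 10
  if (engaged_only) reasons <- c(reasons, "disengaged count")
  list(included = length(reasons) == 0,
       engaged_only = engaged_only && length(setdiff(reasons, "disengaged count")) == 0,
       reasons = reasons)
}

#' Build the full per-trial table for a session
#'
#' Segments trials, separates consumption from non-consumption licks,
#' computes lick selectivity, bins-with-licks, reward/correctness flags and
#' exclusion flags, and (optionally) the k-means engagement labels.
#'
#' A standard trial is correct when a lick in the true reward zone earned
#' the reward; probe and crutch trials are correct when at least one
#' non-consumption lick falls in the analysis reward zone (anticipatory
#' licking), a convention since correctness is only operationally defined
#' for rewarded trials.
#'
#' @param session a `pg_session`
#' @param classify run the engagement clustering (needs >= 2 trials with
#'   licks)
#' @param kmeans_seed seed for [cluster_engagement()]
#' @return data.frame, one row per trial, plus attribute `lick_positions`
#'   (list of per-trial non-consumption lick positions)
#' @export
build_trial_table <- function(session, classify = TRUE, kmeans_seed = 0) {
  cfg <- session$config
  zs <- cfg$reward_zone_start
  zone <- c(zs, zs + cfg$reward_zone_length)
  trials <- segment_trials(session$position, session$frame_rate,
                           session$trial_type, session$track_length)
  n <- nrow(trials)
  lick_pos <- vector("list", n)
  rewarded <- logical(n)
  correct <- logical(n)
  sel <- numeric(n)
  nbins <- integer(n)
  for (i in seq_len(n)) {
    fr <- trials$start_frame[i]:(trials$end_frame[i] - 1L)
    pos <- session$position[fr]
    lick <- session$lick[fr]
    rew <- session$reward[fr]
    cons <- classify_licks(pos, lick, rew, zone)
    # lick metrics count anticipatory licks plus the first lick after
    # reward availability (the first consumption lick); only the
    # subsequent consumption bout is excluded
    if (any(cons)) cons[which(cons)[1]] <- FALSE
    lp <- pos[lick & !cons]
    lick_pos[[i]] <- lp
    rewarded[i] <- any(rew)
    sel[i] <- lick_selectivity(lp, zs, session$track_length)
    nbins[i] <- bins_with_licks(lp, session$track_length)
    anticipatory <- any(wrap_pos(lp - (zs - 10), session$track_length) < 30)
    correct[i] <- switch(trials$type[i],
                         standard = rewarded[i],
                         probe = anticipatory,
                         crutch = anticipatory,
                         NA)
  }
  trials$rewarded <- rewarded
  trials$correct <- correct
  trials$lick_selectivity <- sel
  trials$bins_with_licks <- nbins
  trials <- exclude_trials(trials, lick_pos, zs,
                           track_length = session$track_length)
  if (classify) {
    cl <- cluster_engagement(sel, nbins, kmeans_seed = kmeans_seed)
    trials$engagement <- cl$label
    trials$silhouette <- cl$silhouette
  } else {
    trials$engagement <- NA_character_
    trials$silhouette <- NA_real_
  }
  attr(trials, "lick_positions") <- lick_pos
  trials
}
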