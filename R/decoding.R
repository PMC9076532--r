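#' Fit a Poisson naive-Bayes decoder template
#'
#' The template f_i(pos) is each cell's trial-averaged, spatially binned
#' and smoothed activity over the training trials (speed-filtered). A
#' small floor (1% of the grand-mean template value) is added at decode
#' time only, so reported templates are unmodified.
#'
#' @param session a `pg_session`
#' @param trials training trial indices
#' @param speed_threshold cm/s
#' @param frame_mask optional logical over session frames restricting
#'   which frames may enter the template (used by speed matching)
#' @return list of class `pg_decoder`: `template` (cells x bins), `tau`
#'   (frame duration, s), `n_bins`
#' @export
fit_template <- function(session, trials, speed_threshold = 5,
                         frame_mask = NULL) {
  if (!length(trials)) stop("empty training trial set")
  rm <- bin_activity(session, trials, speed_threshold,
                     frame_mask = frame_mask)
  structure(list(template = rate_map_average(rm),
                 tau = 1 / session$frame_rate,
                 n_bins = session$n_spatial_bins),
            class = "pg_decoder")
}

#' Decode position from population activity, frame by frame
#'
#' Implements the Poisson naive-Bayes rule with a uniform spatial prior:
#' the log posterior of bin `pos` given frame activity `a` is
#' `sum_i a_i log(f_i(pos) + eps) - tau * sum_i (f_i(pos) + eps)` up to a
#' constant. All computation is in the log domain with per-frame max
#' subtraction; MAP ties go to the lowest bin index.
#'
#' @param model a `pg_decoder`
#' @param activity cells x frames matrix of nonnegative activity
#' @return list with `posterior` (frames x bins, rows sum to 1),
#'   `map_bin` (per-frame MAP bin), `log_posterior` (unnormalized, frames
#'   x bins)
#' @export
decode_frames <- function(model, activity) {
  if (is.null(dim(activity))) activity <- matrix(activity, ncol = 1)
  if (nrow(activity) != nrow(model$template))
    stop("activity has ", nrow(activity), " cells but template has ",
         nrow(model$template))
  f <- model$template
  eps <- max(0.01 * mean(f), 1e-12)
  lf <- log(f + eps)
  # frames x bins
  ll <- crossprod(activity, lf) -
    matrix(model$tau * colSums(f + eps), ncol(activity), ncol(f),
           byrow = TRUE)
  post <- exp(ll - row_logsumexp(ll))
  post <- post / rowSums(post)
  list(posterior = post,
       map_bin = max.col(ll, ties.method = "first"),
       log_posterior = ll)
}

#' Circular decoding error
#'
#' Shortest-arc distance between true and decoded spatial bins; ranges
#' between 0 and n_bins/2 bins (0 and 100 cm on a 2-m track with 5-cm
#' bins).
#'
#' @param true_bin,decoded_bin bin indices in 1..n_bins (vectorized)
#' @param n_bins number of circular bins
#' @param bin_cm bin width for the cm-scale output
#' @return list(`bins`, `cm`)
#' @export
circular_error <- function(true_bin, decoded_bin, n_bins = 40, bin_cm = 5) {
  if (any(true_bin < 1 | true_bin > n_bins) ||
      any(decoded_bin < 1 | decoded_bin > n_bins))
    stop("bin index out of range 1..", n_bins)
  b <- circ_dist(true_bin, decoded_bin, n_bins)
  list(bins = b, cm = b * bin_cm)
}

#' Chance-level decoding error
#'
#' Expected circular error when the decoded bin is uniform random:
#' exactly n_bins / 4 bins for even n_bins (10 bins = 50 cm for 40 5-cm
#' bins).
#'
#' @param n_bins even number of circular bins
#' @param bin_cm bin width
#' @return list(`bins`, `cm`)
#' @export
chance_error <- function(n_bins = 40, bin_cm = 5) {
  stopifnot(n_bins %% 2 == 0)
  list(bins = n_bins / 4, cm = n_bins / 4 * bin_cm)
}

# Frames of given trials passing the speed filter (and optional mask).
.test_frames <- function(session, trials, speed_threshold = 5,
                         frame_mask = NULL) {
  ok <- session$trial_index %in% trials & session$speed >= speed_threshold
  if (!is.null(frame_mask)) ok <- ok & frame_mask
  which(ok)
}

# Mean circular decoding error (cm) per test trial.
.trial_errors <- function(session, model, test_trials, speed_threshold = 5,
                          frame_mask = NULL, decoder = c("bayes", "template")) {
  decoder <- match.arg(decoder)
  nb <- session$n_spatial_bins
  bw <- session$track_length / nb
  vapply(test_trials, function(tr) {
    fr <- .test_frames(session, tr, speed_threshold, frame_mask)
    if (!length(fr)) return(NA_real_)
    a <- session$activity[, fr, drop = FALSE]
    dec <- if (decoder == "bayes") decode_frames(model, a)$map_bin
           else template_match_decode(model, a)
    true_bin <- pmin(floor(session$position[fr] / bw), nb - 1L) + 1L
    keep <- !is.na(dec)
    if (!any(keep)) return(NA_real_)
    mean(circular_error(true_bin[keep], dec[keep], nb, bw)$cm)
  }, numeric(1))
}

#' Sliding-window baseline decoder
#'
#' Trains on a sliding window of `window` usable trials and tests on the
#' immediately following trial; used as an imaging-quality criterion
#' (sessions need at least 20 trials with error below 10 cm).
#'
#' @param session a `pg_session`
#' @param trials ordered usable trial indices
#' @param window training window length in trials
#' @param speed_threshold cm/s
#' @return data.frame (trial, error_cm); trials without a full preceding
#'   window get NA
#' @export
sliding_decoder <- function(session, trials, window = 20,
                            speed_threshold = 5) {
  trials <- sort(trials)
  if (length(trials) < window + 1)
    stop("need more than ", window, " trials for the sliding decoder")
  err <- rep(NA_real_, length(trials))
  for (k in (window + 1):length(trials)) {
    model <- fit_template(session, trials[(k - window):(k - 1)],
                          speed_threshold)
    err[k] <- .trial_errors(session, model, trials[k], speed_threshold)
  }
  data.frame(trial = trials, error_cm = err)
}

# Non-overlapping blocks of `size` consecutive same-state trials,
# in temporal order; remainder trials are dropped.
.state_blocks <- function(trials, labels, state, size = 10) {
  idx <- trials[labels == state]
  nb <- floor(length(idx) / size)
  lapply(seq_len(nb), function(b) idx[(b - 1) * size + seq_len(size)])
}

#' Engagement-split decoding
#'
#' Trains the decoder on blocks of `train_block` consecutive trials of one
#' engagement state and tests on all other trials, accumulating the mean
#' trial-wise error for each train-state x test-state condition across
#' iterations.
#'
#' @param session a `pg_session`
#' @param trials usable trial indices
#' @param labels engagement labels aligned with `trials`
#' @param train_block training block size (default 10)
#' @param speed_threshold cm/s
#' @param decoder "bayes" (Poisson naive Bayes) or "template" (cosine
#'   template matching control)
#' @return list with `errors` (named vector: EE, ED, DE, DD mean error,
#'   cm; train state first) and `per_iteration` data.frame
#' @export
engagement_decoder <- function(session, trials, labels, train_block = 10,
                               speed_threshold = 5,
                               decoder = c("bayes", "template")) {
  decoder <- match.arg(decoder)
  stopifnot(length(trials) == length(labels))
  for (st in c("engaged", "disengaged"))
    if (sum(labels == st) <= train_block)
      stop("need more than ", train_block, " ", st, " trials")
  rows <- list()
  for (st in c("engaged", "disengaged")) {
    for (blk in .state_blocks(trials, labels, st, train_block)) {
      model <- fit_template(session, blk, speed_threshold)
      held <- setdiff(trials, blk)
      e <- .trial_errors(session, model, held, speed_threshold,
                         decoder = decoder)
      hl <- labels[match(held, trials)]
      for (ts in c("engaged", "disengaged")) {
        v <- e[hl == ts]
        if (any(!is.na(v)))
          rows[[length(rows) + 1]] <- data.frame(
            train = st, test = ts, error_cm = mean(v, na.rm = TRUE))
      }
    }
  }
  it <- do.call(rbind, rows)
  key <- c(engaged = "E", disengaged = "D")
  cond <- paste0(key[it$train], key[it$test])
  errs <- tapply(it$error_cm, cond, mean)
  list(errors = errs[intersect(c("EE", "ED", "DE", "DD"), names(errs))],
       per_iteration = it)
}

#' Speed-matched frame subsampling plan
#'
#' Discretizes running speed into 5 cm/s bins within each 2-cm spatial
#' bin, takes the per-(spatial, speed)-bin overlap min(count_A, count_B)
#' as the target, and subsamples that many frames from each set uniformly
#' without replacement. Spatial bins with no overlapping frames are
#' counted; a plan with more than `max_empty` empty spatial bins is
#' flagged unusable.
#'
#' @param session a `pg_session`
#' @param frames_a,frames_b frame index vectors of the two trial sets
#'   (typically already speed-filtered)
#' @param spatial_bin_cm,speed_bin width of the matching bins
#' @param max_empty maximum tolerated empty spatial bins (default 10)
#' @return list of class `pg_speedmatch`: `keep_a`, `keep_b` (retained
#'   frame indices), `n_empty_bins`, `usable`
#' @export
speed_match <- function(session, frames_a, frames_b, spatial_bin_cm = 2,
                        speed_bin = 5, max_empty = 10) {
  ns <- ceiling(session$track_length / spatial_bin_cm)
  cell_of <- function(fr) {
    sb <- pmin(floor(session$position[fr] / spatial_bin_cm), ns - 1L)
    vb <- floor(session$speed[fr] / speed_bin)
    paste(sb, vb)
  }
  ca <- cell_of(frames_a)
  cb <- cell_of(frames_b)
  keep_a <- integer(0)
  keep_b <- integer(0)
  spatial_hit <- logical(ns)
  for (cell in intersect(unique(ca), unique(cb))) {
    ia <- frames_a[ca == cell]
    ib <- frames_b[cb == cell]
    k <- min(length(ia), length(ib))
    keep_a <- c(keep_a, if (length(ia) == k) ia else sample(ia, k))
    keep_b <- c(keep_b, if (length(ib) == k) ib else sample(ib, k))
    spatial_hit[as.integer(strsplit(cell, " ")[[1]][1]) + 1L] <- TRUE
  }
  n_empty <- sum(!spatial_hit)
  structure(list(keep_a = sort(keep_a), keep_b = sort(keep_b),
                 n_empty_bins = n_empty, usable = n_empty <= max_empty),
            class = "pg_speedmatch")
}

#' Engagement-split decoding on speed-matched frames
#'
#' For every ordered pair of 10-trial blocks (same or opposite engagement
#' state), frames of the two blocks are speed-matched, the template is fit
#' on the training block's retained frames only, and testing uses the
#' partner block's retained frames. Unusable pairs (too many empty
#' spatial bins) are excluded from the condition means.
#'
#' @inheritParams engagement_decoder
#' @return list with `errors` (EE/ED/DE/DD means, cm), `per_iteration`,
#'   and `n_unusable_pairs`
#' @export
speed_matched_decoding <- function(session, trials, labels,
                                   train_block = 10, speed_threshold = 5) {
  stopifnot(length(trials) == length(labels))
  blocks <- c(lapply(.state_blocks(trials, labels, "engaged", train_block),
                     function(b) list(state = "engaged", trials = b)),
              lapply(.state_blocks(trials, labels, "disengaged", train_block),
                     function(b) list(state = "disengaged", trials = b)))
  if (length(blocks) < 2) stop("not enough trial blocks for speed matching")
  rows <- list()
  n_unusable <- 0
  for (i in seq_along(blocks)) for (j in seq_along(blocks)) {
    if (i >= j) next
    A <- blocks[[i]]; B <- blocks[[j]]
    fa <- .test_frames(session, A$trials, speed_threshold)
    fb <- .test_frames(session, B$trials, speed_threshold)
    plan <- speed_match(session, fa, fb)
    if (!plan$usable) { n_unusable <- n_unusable + 1; next }
    mask_a <- mask_b <- logical(length(session$position))
    mask_a[plan$keep_a] <- TRUE
    mask_b[plan$keep_b] <- TRUE
    run <- function(tr_blk, te_blk, tr_mask, te_mask) {
      model <- fit_template(session, tr_blk$trials, speed_threshold,
                            frame_mask = tr_mask)
      e <- .trial_errors(session, model, te_blk$trials, speed_threshold,
                         frame_mask = te_mask)
      if (any(!is.na(e)))
        rows[[length(rows) + 1]] <<- data.frame(
          train = tr_blk$state, test = te_blk$state,
          error_cm = mean(e, na.rm = TRUE))
    }
    run(A, B, mask_a, mask_b)
    run(B, A, mask_b, mask_a)
  }
  if (!length(rows)) stop("all speed-matched block pairs were unusable")
  it <- do.call(rbind, rows)
  key <- c(engaged = "E", disengaged = "D")
  cond <- paste0(key[it$train], key[it$test])
  errs <- tapply(it$error_cm, cond, mean)
  list(errors = errs[intersect(c("EE", "ED", "DE", "DD"), names(errs))],
       per_iteration = it, n_unusable_pairs = n_unusable)
}

#' Find qualifying disengagement streaks
#'
#' A qualifying streak is a maximal run of at least `min_len` consecutive
#' disengaged trials whose preceding `pre_window` trials are at least
#' `pre_frac` engaged (and fully inside the session).
#'
#' @param labels per-trial engagement labels (session order)
#' @param min_len minimum streak length (default 10)
#' @param pre_window preceding window length (default 30)
#' @param pre_frac minimum engaged fraction in the window (default 0.8)
#' @return data.frame (onset, length); zero rows when none qualify
#' @export
qualifying_streaks <- function(labels, min_len = 10, pre_window = 30,
                               pre_frac = 0.8) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in which(r$values == "disengaged" & r$lengths >= min_len)) {
    onset <- starts[k]
    if (onset - pre_window < 1) next
    pre <- labels[(onset - pre_window):(onset - 1)]
    if (mean(pre == "engaged") >= pre_frac)
      out[[length(out) + 1]] <- data.frame(onset = onset,
                                           length = r$lengths[k])
  }
  if (!length(out)) data.frame(onset = integer(0), length = integer(0))
  else do.call(rbind, out)
}

#' Decoding error aligned to disengagement onset
#'
#' For each qualifying streak, the decoder is trained on trials 21-30
#' before the streak (the first ten of the preceding 30-trial window) and
#' tested on the 20 subsequent pre-onset trials and then the streak's
#' disengaged trials. Errors are aligned to the first disengaged trial
#' (offset 0) and averaged across streaks.
#'
#' @param session a `pg_session`
#' @param labels per-trial engagement labels (session order)
#' @param speed_threshold cm/s
#' @param min_streak,pre_window,pre_frac streak qualification parameters
#' @return data.frame (align, error_cm, n_streaks); zero rows (with
#'   attribute `flagged = "no qualifying streak"`) when none qualify
#' @export
streak_onset_decoder <- function(session, labels, speed_threshold = 5,
                                 min_streak = 10, pre_window = 30,
                                 pre_frac = 0.8) {
  streaks <- qualifying_streaks(labels, min_streak, pre_window, pre_frac)
  if (!nrow(streaks)) {
    out <- data.frame(align = integer(0), error_cm = numeric(0),
                      n_streaks = integer(0))
    attr(out, "flagged") <- "no qualifying streak"
    return(out)
  }
  acc <- list()
  for (s in seq_len(nrow(streaks))) {
    onset <- streaks$onset[s]
    train <- (onset - 30):(onset - 21)
    test <- c((onset - 20):(onset - 1),
              onset:(onset + streaks$length[s] - 1))
    model <- fit_template(session, train, speed_threshold)
    e <- .trial_errors(session, model, test, speed_threshold)
    acc[[s]] <- data.frame(align = test - onset, error_cm = e)
  }
  df <- do.call(rbind, acc)
  agg <- stats::aggregate(error_cm ~ align, df, mean, na.rm = TRUE)
  cnt <- stats::aggregate(error_cm ~ align, df,
                          function(v) sum(!is.na(v)))
  data.frame(align = agg$align, error_cm = agg$error_cm,
             n_streaks = cnt$error_cm)
}

#' Template-matching (cosine similarity) decoder
#'
#' Control decoder without the Poisson assumption: each frame's population
#' vector is compared to the template column of every spatial bin by
#' cosine similarity, and the best-matching bin is decoded (ties to the
#' lowest bin). Frames with a zero population vector are undefined and
#' returned as NA.
#'
#' @param model a `pg_decoder`
#' @param activity cells x frames matrix
#' @return per-frame decoded bin (NA for zero frames)
#' @export
template_match_decode <- function(model, activity) {
  if (is.null(dim(activity))) activity <- matrix(activity, ncol = 1)
  f <- model$template
  eps <- max(0.01 * mean(f), 1e-12)
  fe <- f + eps
  cn <- sqrt(colSums(fe^2))
  if (any(cn == 0)) stop("template has an all-zero column after flooring")
  an <- sqrt(colSums(activity^2))
  sim <- crossprod(activity, fe) / outer(an, cn)  # frames x bins
  out <- max.col(sim, ties.method = "first")
  out[an == 0] <- NA_integer_
  out
}
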