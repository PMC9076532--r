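# ---- internal binning workhorses ------------------------------------------

# Per-(trial, bin) mean activity from a frames x cells matrix.
# grp assigns each frame to (trial_rank - 1) * nb + bin, or 0 to drop it.
# Returns a (n_trials * nb) x n_cells matrix with NA where occupancy is 0.
.group_means <- function(tA, grp, n_groups) {
  keep <- grp > 0
  sums <- rowsum(tA[keep, , drop = FALSE], grp[keep])
  counts <- tabulate(grp[keep], nbins = n_groups)
  full <- matrix(NA_real_, n_groups, ncol(tA))
  gi <- as.integer(rownames(sums))
  full[gi, ] <- sums / counts[gi]
  full
}

# Trial-averaged (over occupied trials), circularly smoothed map per cell.
# Fast path used by the shuffle null: pools per-trial bin means.
.trialavg_map <- function(tA, grp, n_trials, nb, smooth_sd_bins) {
  means <- .group_means(tA, grp, n_trials * nb)
  binidx <- rep(seq_len(nb), n_trials)
  occ <- !is.na(means[, 1])
  sums <- rowsum(ifelse(is.na(means), 0, means), binidx)
  nocc <- tabulate(binidx[occ], nbins = nb)
  m <- t(sums / ifelse(nocc == 0, NA, nocc))   # cells x nb
  # fill any never-occupied bin from circular neighbors before smoothing
  if (anyNA(m)) m <- t(apply(m, 1, .fill_circular))
  smooth_circular(m, smooth_sd_bins)
}

# Fill NA entries of a circular profile by linear interpolation between
# the nearest occupied neighbors.
.fill_circular <- function(v) {
  n <- length(v)
  if (!anyNA(v)) return(v)
  ok <- which(!is.na(v))
  if (!length(ok)) return(v)
  for (i in which(is.na(v))) {
    dl <- (i - ok) %% n   # distance to occupied bin going backwards
    dr <- (ok - i) %% n
    l <- ok[which.min(dl)]; r <- ok[which.min(dr)]
    wl <- min(dl); wr <- min(dr)
    v[i] <- (v[l] * wr + v[r] * wl) / (wl + wr)
  }
  v
}

#' Spatially binned, smoothed per-trial rate maps
#'
#' For each cell and selected trial, frames with running speed below
#' `speed_threshold` are dropped, activity is averaged in 5-cm spatial
#' bins, zero-occupancy bins are interpolated from circular neighbors (and
#' flagged), and the per-trial profile is circularly smoothed with a
#' Gaussian of s.d. `smooth_sd_cm`.
#'
#' @param session a `pg_session`
#' @param trials integer trial indices to include
#' @param speed_threshold cm/s; frames slower than this are excluded
#' @param smooth_sd_cm smoothing s.d. in cm (default 10)
#' @param frame_mask optional logical over all session frames; frames with
#'   FALSE are excluded in addition to the speed filter (used for
#'   speed-matched subsampling)
#' @return list of class `pg_ratemap`: `map` (cells x trials x bins array),
#'   `occupancy` (trials x bins frame counts), `trials`, `empty_trials`
#'   (trials with no retained frames; their map slices are NA),
#'   `interpolated` (trials x bins logical)
#' @export
bin_activity <- function(session, trials, speed_threshold = 5,
                         smooth_sd_cm = 10, frame_mask = NULL) {
  stopifnot(length(trials) >= 1)
  nb <- session$n_spatial_bins
  bw <- session$track_length / nb
  n_cells <- nrow(session$activity)

  in_set <- session$trial_index %in% trials
  rank <- match(session$trial_index, trials)
  bin <- pmin(floor(session$position / bw), nb - 1L) + 1L
  ok <- in_set & session$speed >= speed_threshold
  if (!is.null(frame_mask)) ok <- ok & frame_mask
  grp <- ifelse(ok, (rank - 1L) * nb + bin, 0L)
  grp[is.na(grp)] <- 0L

  means <- .group_means(t(session$activity), grp, length(trials) * nb)
  occupancy <- matrix(tabulate(grp[grp > 0], nbins = length(trials) * nb),
                      length(trials), nb, byrow = TRUE)
  empty_trials <- trials[rowSums(occupancy) == 0]

  map <- array(NA_real_, c(n_cells, length(trials), nb))
  interpolated <- occupancy == 0 & rowSums(occupancy) > 0
  km <- circular_gaussian_matrix(nb, smooth_sd_cm / bw)
  for (tr in seq_along(trials)) {
    if (trials[tr] %in% empty_trials) next
    rows <- (tr - 1L) * nb + seq_len(nb)
    m <- t(means[rows, , drop = FALSE])           # cells x nb
    if (anyNA(m)) m <- t(apply(m, 1, .fill_circular))
    map[, tr, ] <- m %*% t(km)
  }
  structure(list(map = map, occupancy = occupancy, trials = trials,
                 empty_trials = empty_trials, interpolated = interpolated,
                 smooth_sd_cm = smooth_sd_cm, bin_width = bw),
            class = "pg_ratemap")
}

#' Trial-averaged rate map
#'
#' @param rm a `pg_ratemap`
#' @return cells x bins matrix, averaging over trials with retained frames
#' @export
rate_map_average <- function(rm) {
  apply(rm$map, c(1, 3), mean, na.rm = TRUE)
}

#' Shuffle null for place-field detection
#'
#' Builds surrogate rate maps in which the position-activity relationship
#' is destroyed while temporal autocorrelation is preserved: on each
#' surrogate the behavioral series (position, speed, trial identity) is
#' circularly shifted relative to the activity by a uniform random number
#' of at least `min_shift` frames, cut into 6 equal chunks whose order is
#' randomly permuted, and the trial-averaged smoothed map is rebuilt. The
#' per-cell, per-bin threshold is the 99th percentile across surrogates.
#'
#' @param session a `pg_session`
#' @param trials trial indices defining the tested map
#' @param n_shuffles number of surrogates (100 for screening, 1000 for
#'   quantitative comparisons)
#' @param speed_threshold cm/s
#' @param smooth_sd_cm smoothing s.d., cm
#' @param min_shift minimum circular shift, frames
#' @param percentile threshold percentile (default 99)
#' @param n_chunks chunks whose order is permuted (default 6)
#' @return list of class `pg_null`: `threshold` (cells x bins),
#'   `n_shuffles`
#' @export
shuffle_null <- function(session, trials, n_shuffles = 100,
                         speed_threshold = 5, smooth_sd_cm = 10,
                         min_shift = 500, percentile = 99, n_chunks = 6) {
  frames <- which(session$trial_index %in% trials)
  T_ <- length(frames)
  if (T_ <= 2 * min_shift)
    stop("trial set too short for a >=", min_shift, "-frame circular shift")
  nb <- session$n_spatial_bins
  bw <- session$track_length / nb
  n_trials <- length(trials)

  tA <- t(session$activity[, frames, drop = FALSE])
  pos <- session$position[frames]
  spd <- session$speed[frames]
  rank <- match(session$trial_index[frames], trials)
  chunk_starts <- floor(seq(0, T_, length.out = n_chunks + 1))[-(n_chunks + 1)] + 1
  chunk_ends <- c(chunk_starts[-1] - 1, T_)

  sdb <- smooth_sd_cm / bw
  out <- matrix(NA_real_, n_shuffles, nrow(session$activity) * nb)
  for (s in seq_len(n_shuffles)) {
    shift <- sample(min_shift:(T_ - min_shift), 1)
    idx <- ((seq_len(T_) - 1 + shift) %% T_) + 1
    perm <- sample(n_chunks)
    idx <- idx[unlist(lapply(perm, function(c) chunk_starts[c]:chunk_ends[c]),
                      use.names = FALSE)]
    p <- pos[idx]; v <- spd[idx]; r <- rank[idx]
    b <- pmin(floor(p / bw), nb - 1L) + 1L
    g <- ifelse(v >= speed_threshold, (r - 1L) * nb + b, 0L)
    out[s, ] <- as.vector(.trialavg_map(tA, g, n_trials, nb, sdb))
  }
  thr <- matrix(apply(out, 2, stats::quantile, probs = percentile / 100,
                      names = FALSE),
                nrow(session$activity), nb)
  structure(list(threshold = thr, n_shuffles = n_shuffles,
                 percentile = percentile), class = "pg_null")
}

# Maximal circularly contiguous runs of TRUE in a logical vector.
# Returns data.frame(start, len) with 1-based starts.
.circular_runs <- function(x) {
  n <- length(x)
  if (all(x)) return(data.frame(start = 1L, len = n))
  if (!any(x)) return(data.frame(start = integer(0), len = integer(0)))
  # rotate so the vector starts on a FALSE, then use rle
  off <- which(!x)[1] - 1L
  xr <- x[((seq_len(n) - 1L + off) %% n) + 1L]
  r <- rle(xr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = ((starts[keep] - 1L + off) %% n) + 1L,
             len = r$lengths[keep])
}

#' Detect significant place fields
#'
#' A candidate field is a maximal circularly contiguous run of at least
#' `min_bins` bins where the trial-averaged map exceeds the per-bin shuffle
#' threshold. If several candidates exist, only the one containing the
#' cell's highest supra-threshold peak is kept (one field per cell).
#'
#' @param mean_map cells x bins trial-averaged map
#' @param null a `pg_null` from [shuffle_null()]
#' @param min_bins minimum field extent in bins (default 3 = 15 cm)
#' @return data.frame with one row per cell that has a field: `cell`,
#'   `span_start`, `span_len`, `peak_bin`
#' @export
detect_fields <- function(mean_map, null, min_bins = 3) {
  stopifnot(all(dim(mean_map) == dim(null$threshold)))
  nb <- ncol(mean_map)
  res <- lapply(seq_len(nrow(mean_map)), function(i) {
    sig <- mean_map[i, ] > null$threshold[i, ]
    runs <- .circular_runs(sig)
    runs <- runs[runs$len >= min_bins, , drop = FALSE]
    if (!nrow(runs)) return(NULL)
    span_bins <- function(s, l) ((s - 1L + seq_len(l) - 1L) %% nb) + 1L
    # keep the run containing the global supra-threshold peak
    peak <- which(sig)[which.max(mean_map[i, sig])]
    hit <- vapply(seq_len(nrow(runs)),
                  function(r) peak %in% span_bins(runs$start[r], runs$len[r]),
                  logical(1))
    r <- if (any(hit)) which(hit)[1] else {
      which.max(vapply(seq_len(nrow(runs)), function(r) {
        max(mean_map[i, span_bins(runs$start[r], runs$len[r])])
      }, numeric(1)))
    }
    sb <- span_bins(runs$start[r], runs$len[r])
    data.frame(cell = i, span_start = runs$start[r], span_len = runs$len[r],
               peak_bin = sb[which.max(mean_map[i, sb])])
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(cell = integer(0), span_start = integer(0),
                      span_len = integer(0), peak_bin = integer(0))
  out
}

# bins covered by a field span, circular
field_bins <- function(span_start, span_len, nb) {
  ((span_start - 1L + seq_len(span_len) - 1L) %% nb) + 1L
}

#' Select matched engaged and disengaged trial sets
#'
#' Takes the smaller engagement class in full and selects equally many
#' trials from the larger class that are closest in time (trial index) to
#' the median trial of the smaller class; distance ties go to the earlier
#' trial.
#'
#' @param engaged,disengaged integer trial indices per class
#' @return list with `engaged` and `disengaged` index vectors of equal
#'   length (each sorted)
#' @export
match_trials <- function(engaged, disengaged) {
  if (!length(engaged) || !length(disengaged))
    stop("both engagement classes must be non-empty")
  pick <- function(from, anchor, k) {
    ord <- order(abs(from - anchor), from)
    sort(from[ord[seq_len(k)]])
  }
  if (length(engaged) >= length(disengaged)) {
    anchor <- stats::median(disengaged)
    list(engaged = pick(engaged, anchor, length(disengaged)),
         disengaged = sort(disengaged))
  } else {
    anchor <- stats::median(engaged)
    list(engaged = sort(engaged),
         disengaged = pick(disengaged, anchor, length(engaged)))
  }
}

#' Trial-to-trial reliability of a cell's spatial tuning
#'
#' Mean Pearson correlation over all unordered pairs of the cell's
#' per-trial binned activity vectors. Pairs where either vector is
#' constant (zero variance) are skipped and counted.
#'
#' @param trial_maps trials x bins matrix for one cell
#' @return list(`reliability`, `n_pairs`, `n_skipped`); reliability is NA
#'   when no usable pair exists
#' @export
field_reliability <- function(trial_maps) {
  tm <- trial_maps[stats::complete.cases(trial_maps), , drop = FALSE]
  n <- nrow(tm)
  if (n < 2) return(list(reliability = NA_real_, n_pairs = 0, n_skipped = 0))
  sds <- apply(tm, 1, stats::sd)
  usable <- sds > 0
  rs <- numeric(0)
  skipped <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (usable[i] && usable[j]) {
      rs <- c(rs, stats::cor(tm[i, ], tm[j, ]))
    } else skipped <- skipped + 1
  }
  list(reliability = if (length(rs)) mean(rs) else NA_real_,
       n_pairs = length(rs), n_skipped = skipped)
}

#' Place-field selectivity
#'
#' In-field and out-of-field activity are each normalized by their number
#' of bins; selectivity is (in - out) / (in + out), ranging from -1 (all
#' activity out of field) to 1 (all activity in field).
#'
#' @param map_vec bins-long activity profile (trial-averaged, or a single
#'   trial's map)
#' @param span_bins bin indices of the field
#' @return scalar in [-1, 1]; NA when total activity is zero
#' @export
field_selectivity <- function(map_vec, span_bins) {
  nb <- length(map_vec)
  if (length(span_bins) >= nb)
    stop("field span covers the whole track; selectivity undefined")
  if (!length(span_bins)) stop("empty field span")
  a_in <- mean(map_vec[span_bins])
  a_out <- mean(map_vec[-span_bins])
  if (a_in + a_out == 0) return(NA_real_)
  (a_in - a_out) / (a_in + a_out)
}

#' Full place-field table for one trial set
#'
#' Bins activity, builds the shuffle null, detects fields, and attaches
#' per-field reliability and selectivity.
#'
#' @param session a `pg_session`
#' @param trials trial indices (e.g. a matched engaged set)
#' @param n_shuffles surrogates for the null
#' @param speed_threshold cm/s
#' @param state optional label stored in the result
#' @return data.frame (cell, span_start, span_len, peak_bin, reliability,
#'   selectivity, state) with attribute `ratemap`
#' @export
place_field_table <- function(session, trials, n_shuffles = 1000,
                              speed_threshold = 5, state = NA_character_) {
  rm <- bin_activity(session, trials, speed_threshold)
  mm <- rate_map_average(rm)
  null <- shuffle_null(session, trials, n_shuffles, speed_threshold)
  pf <- detect_fields(mm, null)
  nb <- session$n_spatial_bins
  if (nrow(pf)) {
    pf$reliability <- vapply(seq_len(nrow(pf)), function(r) {
      field_reliability(rm$map[pf$cell[r], , ])$reliability
    }, numeric(1))
    pf$selectivity <- vapply(seq_len(nrow(pf)), function(r) {
      field_selectivity(mm[pf$cell[r], ],
                        field_bins(pf$span_start[r], pf$span_len[r], nb))
    }, numeric(1))
  } else {
    pf$reliability <- numeric(0)
    pf$selectivity <- numeric(0)
  }
  pf$state <- rep(state, nrow(pf))
  attr(pf, "ratemap") <- rm
  attr(pf, "mean_map") <- mm
  pf
}

#' Cross-tabulate place fields between engagement states
#'
#' For every cell, reports whether it has a field in both states, lost it
#' on disengagement, gained one, or has none in either state. For "both"
#' cells the circular peak distance is reported, and fields closer than
#' `similar_bins` count as "similar location".
#'
#' @param fields_engaged,fields_disengaged field tables from
#'   [place_field_table()] on matched trial sets
#' @param n_cells total number of cells
#' @param n_bins spatial bins
#' @param similar_bins peak-distance threshold for "similar location"
#'   (default 4 bins = 20 cm)
#' @return list with per-cell `status`, `peak_distance_bins` (NA unless
#'   both), and summary `fractions` (lost = among cells with engaged
#'   fields; gained = among cells without engaged fields; similar = among
#'   both-state cells)
#' @export
compare_fields <- function(fields_engaged, fields_disengaged, n_cells,
                           n_bins = 40, similar_bins = 4) {
  has_e <- logical(n_cells); has_e[fields_engaged$cell] <- TRUE
  has_d <- logical(n_cells); has_d[fields_disengaged$cell] <- TRUE
  status <- rep("neither", n_cells)
  status[has_e & has_d] <- "both"
  status[has_e & !has_d] <- "lost"
  status[!has_e & has_d] <- "gained"
  pk <- function(tbl) {
    v <- rep(NA_real_, n_cells)
    v[tbl$cell] <- tbl$peak_bin
    v
  }
  pd <- rep(NA_real_, n_cells)
  b <- status == "both"
  pd[b] <- circ_dist(pk(fields_engaged)[b], pk(fields_disengaged)[b], n_bins)
  fractions <- c(
    lost = if (any(has_e)) mean(status[has_e] == "lost") else NA,
    gained = if (any(!has_e)) mean(status[!has_e] == "gained") else NA,
    similar = if (any(b)) mean(pd[b] <= similar_bins) else NA
  )
  list(status = status, peak_distance_bins = pd, fractions = fractions)
}

#' Cell ordering and normalized raster for sequence plots
#'
#' Keeps cells whose frame-activity standard deviation exceeds the
#' `sd_percentile`-th percentile across cells, and sorts them by the
#' location of their most active spatial bin on the reference trials
#' (ties broken by cell index).
#'
#' @param session a `pg_session`
#' @param trials reference trials (typically correct standard trials)
#' @param sd_percentile s.d. inclusion percentile (default 30)
#' @param saturate upper/lower percentile saturation of the normalized
#'   raster (default 0.02)
#' @return list(`order` cell indices sorted by peak bin, `peak_bin`,
#'   `raster` cells-in-order x bins normalized to [0, 1])
#' @export
sort_sequence <- function(session, trials, sd_percentile = 30,
                          saturate = 0.02) {
  sds <- apply(session$activity, 1, stats::sd)
  keep <- which(sds > stats::quantile(sds, sd_percentile / 100))
  if (!length(keep)) stop("no cell passes the s.d. filter")
  mm <- rate_map_average(bin_activity(session, trials))
  peak <- apply(mm[keep, , drop = FALSE], 1, which.max)
  ord <- keep[order(peak, keep)]
  rast <- t(apply(mm[ord, , drop = FALSE], 1, function(v) {
    lo <- stats::quantile(v, saturate, names = FALSE)
    hi <- stats::quantile(v, 1 - saturate, names = FALSE)
    if (hi <= lo) return(rep(0, length(v)))
    pmin(pmax((v - lo) / (hi - lo), 0), 1)
  }))
  list(order = ord, peak_bin = peak[order(peak, keep)], raster = rast)
}

#' Field selectivity around disengagement onsets
#'
#' For cells with engaged place fields, the engaged field mask is frozen
#' and per-trial selectivity is computed on trials aligned to the first
#' trial of each qualifying disengaged streak (see
#' [qualifying_streaks()]), from `pre` trials before onset through the
#' streak.
#'
#' @param session a `pg_session`
#' @param labels per-trial engagement labels
#' @param fields_engaged field table computed on engaged trials
#' @param pre aligned trials before onset (default 20)
#' @param min_streak,pre_window,pre_frac streak qualification parameters
#' @return data.frame (align, mean_selectivity, n_cells) where `align` is
#'   the trial offset from streak onset (0 = first disengaged trial);
#'   averaged over cells and qualifying streaks
#' @export
selectivity_timecourse <- function(session, labels, fields_engaged,
                                   pre = 20, min_streak = 10,
                                   pre_window = 30, pre_frac = 0.8) {
  streaks <- qualifying_streaks(labels, min_streak, pre_window, pre_frac)
  if (!nrow(streaks))
    return(data.frame(align = integer(0), mean_selectivity = numeric(0),
                      n_cells = integer(0)))
  nb <- session$n_spatial_bins
  acc <- list()
  for (s in seq_len(nrow(streaks))) {
    onset <- streaks$onset[s]
    rng <- (onset - pre):(onset + streaks$length[s] - 1)
    rng <- rng[rng >= 1 & rng <= max(session$trial_index)]
    rm <- bin_activity(session, rng)
    for (k in seq_along(rng)) {
      vals <- vapply(seq_len(nrow(fields_engaged)), function(r) {
        v <- rm$map[fields_engaged$cell[r], k, ]
        if (anyNA(v)) return(NA_real_)
        field_selectivity(v, field_bins(fields_engaged$span_start[r],
                                        fields_engaged$span_len[r], nb))
      }, numeric(1))
      acc[[length(acc) + 1]] <- data.frame(align = rng[k] - onset,
                                           sel = mean(vals, na.rm = TRUE),
                                           n = sum(!is.na(vals)))
    }
  }
  df <- do.call(rbind, acc)
  out <- stats::aggregate(cbind(sel, n) ~ align, df, mean)
  data.frame(align = out$align, mean_selectivity = out$sel,
             n_cells = out$n)
}
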