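#' Circular distance between positions on a wrapped track
#'
#' @param a,b positions (same units as `circumference`)
#' @param circumference track length (or number of bins for bin-indexed input)
#' @return shortest arc distance, in the same units
#' @keywords internal
circ_dist <- function(a, b, circumference) {
  d <- abs(a - b) %% circumference
  pmin(d, circumference - d)
}

#' Wrap positions into [0, circumference)
#' @keywords internal
wrap_pos <- function(x, circumference) {
  x %% circumference
}

# Circulant smoothing matrix for a wrapped Gaussian kernel on n bins.
# sd is in bins. Kernel is normalized so that smoothing preserves the mean.
# truncate_sd cuts the kernel support (common practice; makes "no mass
# near the zone" an attainable state for the lick metrics).
circular_gaussian_matrix <- function(n, sd, truncate_sd = Inf) {
  stopifnot(n >= 1, sd > 0)
  # circular offsets between bins
  off <- outer(seq_len(n), seq_len(n), function(i, j) {
    d <- abs(i - j)
    pmin(d, n - d)
  })
  k <- exp(-off^2 / (2 * sd^2))
  k[off > truncate_sd * sd] <- 0
  sweep(k, 1, rowSums(k), "/")
}

#' Circular Gaussian smoothing of binned profiles
#'
#' Smooths each row of `x` (profiles over circular bins) with a wrapped
#' Gaussian kernel. The kernel is normalized, so constant profiles are
#' preserved exactly and total mass is conserved.
#'
#' @param x numeric vector of length `n_bins`, or a matrix with profiles in
#'   rows
#' @param sd_bins kernel standard deviation in bins
#' @return object of the same shape as `x`
#' @export
smooth_circular <- function(x, sd_bins) {
  if (is.null(dim(x))) {
    n <- length(x)
    drop(matrix(x, 1) %*% t(circular_gaussian_matrix(n, sd_bins)))
  } else {
    x %*% t(circular_gaussian_matrix(ncol(x), sd_bins))
  }
}

# Derive an independent substream seed (< 2^31) from a base seed and a
# component index; used so each generator component can be regenerated
# in isolation.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 10007) %% 2147483587L)
}

# log-sum-exp along rows of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Two-group Wilcoxon comparison
#'
#' Thin wrapper for the nonparametric comparisons used in summary reports:
#' paired (signed-rank) or unpaired (rank-sum), two-sided.
#'
#' @param x,y numeric vectors; equal length required when `paired = TRUE`
#' @param paired logical
#' @return list with `statistic` and `p_value`
#' @export
compare_groups <- function(x, y, paired = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("compare_groups needs at least 2 observations per group")
  if (paired && length(x) != length(y))
    stop("paired comparison requires equal-length samples")
  if (paired && all(x == y)) {
    # signed-rank statistic is degenerate when every pair is tied: no effect
    return(list(statistic = 0, p_value = 1))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, paired = paired, exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
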