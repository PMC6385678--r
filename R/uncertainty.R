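#' Flux autocorrelation time by bootstrap significance
#'
#' For each lag up to `max_lag`, the lag-l autocorrelation of the series is
#' bootstrapped (resampling the lag-l pairs with replacement, `n_boot`
#' datasets); a lag is significant when its two-sided `(1 - conf)`
#' percentile interval excludes zero.  The returned block length is one
#' more than the largest significant lag (values a distance l apart being
#' correlated means a decorrelating block must span l + 1 values), so a
#' series with no significant lag gets `t_c = 1` and a perfectly paired
#' series gets `t_c = 2`.  Per-lag significance, no multiplicity
#' correction.
#'
#' @param x numeric series (per-iteration flux values).
#' @param n_boot bootstrap datasets per lag.
#' @param conf confidence level.
#' @param max_lag maximum lag tested; defaults to `length(x) / 10`, capped
#'   at 100.
#' @param seed integer seed.
#' @return Integer block length `t_c >= 1`.
#' @export
flux_autocorr_tc <- function(x, n_boot = 1000, conf = 0.95, max_lag = NULL,
                             seed = 1L) {
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(floor(n / 10), 100L)
  max_lag <- max(1L, as.integer(max_lag))
  if (n < 2 * max_lag + 2) stop("series too short for the requested max_lag")
  if (sd(x) == 0) stop("zero-variance series: correlation time undefined")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.substream(seed, 0L, salt = 11L))
  alpha <- (1 - conf) / 2
  max_sig <- 0L
  for (lag in seq_len(max_lag)) {
    u <- x[seq_len(n - lag)]
    v <- x[seq_len(n - lag) + lag]
    m <- length(u)
    idx <- matrix(sample.int(m, m * n_boot, replace = TRUE), nrow = n_boot)
    U <- matrix(u[idx], nrow = n_boot)
    V <- matrix(v[idx], nrow = n_boot)
    mu <- rowMeans(U); mv <- rowMeans(V)
    su <- sqrt(rowMeans(U^2) - mu^2)
    sv <- sqrt(rowMeans(V^2) - mv^2)
    r <- (rowMeans(U * V) - mu * mv) / (su * sv)
    r <- r[is.finite(r)]
    if (length(r) < n_boot / 2) next
    ci <- quantile(r, c(alpha, 1 - alpha), names = FALSE)
    if (ci[1] > 0 || ci[2] < 0) max_sig <- as.integer(lag)
  }
  max_sig + 1L
}

#' Blocked-bootstrap confidence interval for a series mean
#'
#' Averages the series over non-overlapping blocks of length `t_c`
#' (trailing partial block dropped), then bootstraps the block means
#' (`n_boot` datasets drawn with replacement) and reports the percentile
#' interval of the mean.
#'
#' @param x numeric series.
#' @param t_c block length (from [flux_autocorr_tc()]).
#' @param n_boot number of bootstrap datasets.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return An object of class `bootstrap_result`: list with `point`, `lo`,
#'   `hi`, `conf`, `n_boot`, `t_c`, `seed`.
#' @export
blocked_bootstrap_ci <- function(x, t_c = 1L, n_boot = 1000, conf = 0.95,
                                 seed = 1L) {
  n <- length(x)
  t_c <- max(1L, as.integer(t_c))
  nb <- n %/% t_c
  if (nb < 2) stop("fewer than 2 blocks: series too short for t_c")
  bm <- colMeans(matrix(x[seq_len(nb * t_c)], nrow = t_c))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.substream(seed, 0L, salt = 13L))
  idx <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = n_boot)
  means <- rowMeans(matrix(bm[idx], nrow = n_boot))
  alpha <- (1 - conf) / 2
  ci <- quantile(means, c(alpha, 1 - alpha), names = FALSE)
  structure(list(point = mean(bm), lo = ci[1], hi = ci[2], conf = conf,
                 n_boot = n_boot, t_c = t_c, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%.5g  [%.5g, %.5g]  (%.0f%% blocked bootstrap, t_c = %d, %d datasets)\n",
              x$point, x$lo, x$hi, 100 * x$conf, x$t_c, x$n_boot))
  invisible(x)
}

#' Number of statistically independent events
#'
#' Bootstraps the per-iteration arrival counts: the block length is the
#' correlation time of the arrival series (1 if the series has zero
#' variance or no significant lag) and the effective independent count is
#' the total number of arrivals divided by the block length, with a
#' percentile CI from resampled block sums.
#'
#' @param arrivals non-negative per-iteration arrival counts.
#' @param n_boot bootstrap datasets.
#' @param conf confidence level.
#' @param seed integer seed.
#' @param t_c optional block length override.
#' @return A list with `count` (effective independent events), `total`
#'   (raw arrivals), `lo`, `hi`, `t_c`.
#' @export
independent_event_count <- function(arrivals, n_boot = 1000, conf = 0.95,
                                    seed = 1L, t_c = NULL) {
  if (any(arrivals < 0)) stop("arrival counts must be non-negative")
  if (sum(arrivals) == 0)
    return(list(count = 0, total = 0, lo = 0, hi = 0, t_c = 1L))
  if (is.null(t_c)) {
    t_c <- tryCatch(flux_autocorr_tc(arrivals, n_boot = n_boot, conf = conf,
                                     seed = seed),
                    error = function(e) 1L)
  }
  t_c <- max(1L, as.integer(t_c))
  n <- length(arrivals)
  nb <- n %/% t_c
  if (nb < 2) stop("fewer than 2 blocks for the event bootstrap")
  bs <- colSums(matrix(arrivals[seq_len(nb * t_c)], nrow = t_c))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.substream(seed, 0L, salt = 17L))
  idx <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = n_boot)
  totals <- rowSums(matrix(bs[idx], nrow = n_boot)) / t_c
  alpha <- (1 - conf) / 2
  ci <- quantile(totals, c(alpha, 1 - alpha), names = FALSE)
  list(count = sum(bs) / t_c, total = sum(arrivals), lo = ci[1], hi = ci[2],
       t_c = t_c)
}

#' Delta-method confidence interval for a ratio
#'
#' First-order error propagation for `num / den`: relative variances add,
#' so the relative half-width of the ratio is the quadrature sum of the
#' input relative half-widths.  Used for the productive-collision
#' percentage, whose numerator and denominator fluxes are bootstrapped
#' separately.
#'
#' @param num,den `bootstrap_result` objects; the denominator interval must
#'   not straddle zero.
#' @return A `bootstrap_result` for the ratio.
#' @export
ratio_ci <- function(num, den) {
  if (den$point == 0 || den$lo <= 0 && den$hi >= 0)
    stop("denominator interval straddles zero: ratio undefined")
  point <- num$point / den$point
  rn <- (num$hi - num$lo) / 2 / abs(num$point)
  rd <- (den$hi - den$lo) / 2 / abs(den$point)
  rel <- sqrt(rn^2 + rd^2)
  structure(list(point = point, lo = point * (1 - rel),
                 hi = point * (1 + rel), conf = num$conf,
                 n_boot = num$n_boot, t_c = NA_integer_, seed = num$seed),
            class = "bootstrap_result")
}
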