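#' Time-domain HRV indices of an RRI window
#'
#' @param rri numeric vector of R-R intervals (ms), at least 2.
#' @param sd_type `"population"` (divide by n, the default used by the
#'   monitoring vector) or `"sample"` (divide by n - 1).
#' @param nn_threshold threshold (ms) for the NN50 count; a pair of
#'   adjacent intervals counts when its absolute difference is strictly
#'   greater than this.
#' @return named numeric vector `(meanNN, SDNN, RMSSD, NN50)` in ms
#'   (NN50 a count).
#' @examples
#' time_domain_indices(c(1000, 1020, 1040))
#' @export
time_domain_indices <- function(rri, sd_type = c("population", "sample"),
                                nn_threshold = 50) {
  sd_type <- match.arg(sd_type)
  n <- length(rri)
  if (n < 2L) stop("insufficient data: need at least 2 RRIs")
  m <- mean(rri)
  ss <- sum((rri - m)^2)
  sdnn <- sqrt(ss / if (sd_type == "population") n else n - 1L)
  d <- diff(rri)
  c(meanNN = m,
    SDNN = sdnn,
    RMSSD = sqrt(mean(d^2)),
    NN50 = sum(abs(d) > nn_threshold))
}

#' Resample a tachogram to a uniform rate by cubic spline
#'
#' Interpolates the (beat time, interval) tachogram with a cubic spline
#' and samples it on a uniform grid inside the knot range (no
#' extrapolation).
#'
#' @param t_beat_s beat times (s), strictly increasing, at least 4 knots.
#' @param rri_ms intervals (ms).
#' @param rate sampling rate in Hz (default 4).
#' @return object of class `resampled_series`: `values` (ms), `rate`,
#'   `t0` (time of the first sample).
#' @export
resample_tachogram <- function(t_beat_s, rri_ms, rate = 4) {
  if (length(t_beat_s) < 4L)
    stop("insufficient data: cubic spline needs at least 4 knots")
  if (any(diff(t_beat_s) <= 0)) stop("beat times must be increasing")
  f <- stats::splinefun(t_beat_s, rri_ms, method = "fmm")
  grid <- seq(t_beat_s[1L], t_beat_s[length(t_beat_s)], by = 1 / rate)
  structure(list(values = f(grid), rate = rate, t0 = grid[1L]),
            class = "resampled_series")
}

#' Autoregressive power spectral density of a resampled series
#'
#' Removes the mean, fits an AR model of fixed order (Burg by default,
#' Yule-Walker as an alternative), and evaluates the one-sided parametric
#' PSD on a dense uniform frequency grid over `[0, rate/2]`. A constant
#' series yields an identically zero density.
#'
#' @param series a [resample_tachogram()] result, or a numeric vector
#'   (then `rate` must be given).
#' @param order AR model order (default 40).
#' @param rate sampling rate in Hz when `series` is a bare vector.
#' @param n_freq number of grid points (default 1024).
#' @param method `"burg"` or `"yule-walker"`.
#' @return object of class `psd_estimate`: `freqs` (Hz), `density`
#'   (ms^2/Hz, one-sided), `ar_order`, `rate`.
#' @export
ar_psd <- function(series, order = 40, rate = NULL, n_freq = 1024,
                   method = c("burg", "yule-walker")) {
  method <- match.arg(method)
  if (inherits(series, "resampled_series")) {
    x <- series$values
    rate <- series$rate
  } else {
    x <- as.numeric(series)
    if (is.null(rate)) stop("rate must be supplied for a bare vector")
  }
  n <- length(x)
  if (n <= order)
    stop("insufficient data: series length must exceed the AR order")
  freqs <- seq(0, rate / 2, length.out = n_freq)
  x <- x - mean(x)
  if (stats::var(x) < 1e-20) {
    dens <- rep(0, n_freq)
  } else {
    fit <- if (method == "burg") {
      stats::ar.burg(x, aic = FALSE, order.max = order, demean = FALSE)
    } else {
      stats::ar.yw(x, aic = FALSE, order.max = order, demean = FALSE)
    }
    a <- fit$ar
    # one-sided AR spectrum: 2 * s2 / (rate * |1 - sum_k a_k e^{-i 2 pi k f / rate}|^2)
    ek <- psd_basis(rate, n_freq, order)
    denom <- Mod(1 - as.vector(ek %*% a))^2
    dens <- 2 * fit$var.pred / rate / denom
  }
  structure(list(freqs = freqs, density = dens, ar_order = order,
                 rate = rate, method = method),
            class = "psd_estimate")
}

# complex exponential grid of the AR transfer function; constant for a
# given (rate, grid size, order), so cached across the many window fits
.psd_cache <- new.env(parent = emptyenv())
psd_basis <- function(rate, n_freq, order) {
  key <- paste(rate, n_freq, order, sep = "|")
  if (is.null(.psd_cache[[key]])) {
    freqs <- seq(0, rate / 2, length.out = n_freq)
    .psd_cache[[key]] <- exp(-2i * pi * outer(freqs / rate, seq_len(order)))
  }
  .psd_cache[[key]]
}

# trapezoid integral of the density over [lo, hi], with linear
# interpolation at the band edges
band_power <- function(psd, lo, hi) {
  f <- psd$freqs
  d <- psd$density
  if (lo < f[1L] || hi > f[length(f)])
    stop("band [", lo, ", ", hi, "] outside the PSD grid")
  inside <- f > lo & f < hi
  edge <- stats::approx(f, d, c(lo, hi), ties = "ordered")$y
  xs <- c(lo, f[inside], hi)
  ys <- c(edge[1L], d[inside], edge[2L])
  sum(diff(xs) * (head(ys, -1L) + tail(ys, -1L)) / 2)
}

#' Frequency-domain band powers from a PSD estimate
#'
#' Integrates the PSD over the low-frequency (0.04-0.15 Hz) and
#' high-frequency (0.15-0.4 Hz) bands and a total-power band
#' (0-0.4 Hz by default), by the trapezoid rule with interpolated band
#' edges. When `HF` is zero the ratio is reported as the configurable
#' sentinel cap rather than Inf.
#'
#' @param psd an [ar_psd()] result; the grid must cover `[0, 0.4]` Hz.
#' @param lf_band,hf_band,tp_band frequency bands in Hz.
#' @param lfhf_cap sentinel value returned for LF/HF when HF is zero
#'   (also caps the ratio).
#' @return named numeric vector `(TP, LF, HF, LF_HF)`, powers in ms^2.
#' @export
band_powers <- function(psd, lf_band = c(0.04, 0.15),
                        hf_band = c(0.15, 0.4), tp_band = c(0, 0.4),
                        lfhf_cap = 1e6) {
  lf <- band_power(psd, lf_band[1L], lf_band[2L])
  hf <- band_power(psd, hf_band[1L], hf_band[2L])
  tp <- band_power(psd, tp_band[1L], tp_band[2L])
  ratio <- if (hf <= 0) lfhf_cap else min(lf / hf, lfhf_cap)
  c(TP = tp, LF = lf, HF = hf, LF_HF = ratio)
}

#' Extract the eight-component HRV index vector from a window
#'
#' Assembles, in fixed order, the four time-domain indices (meanNN, SDNN,
#' RMSSD, NN50) and the four frequency-domain indices (TP, LF, HF, LF/HF)
#' obtained by cubic-spline resampling of the tachogram followed by an
#' AR power spectrum.
#'
#' @param t_beat_s,rri_ms the windowed tachogram (accepted beats only).
#' @param rate resampling rate (Hz).
#' @param ar_order AR model order.
#' @param tp_mode `"psd_band"` (total power as the PSD integral over
#'   `tp_band`) or `"variance"` (time-domain population variance of the
#'   windowed intervals).
#' @param sd_type,nn_threshold passed to [time_domain_indices()].
#' @param lf_band,hf_band,tp_band,lfhf_cap passed to [band_powers()].
#' @param method AR estimation method, see [ar_psd()].
#' @param n_freq PSD grid size.
#' @return named numeric vector of length 8 in the order
#'   `meanNN, SDNN, RMSSD, NN50, TP, LF, HF, LF_HF`.
#' @export
extract_hrv_vector <- function(t_beat_s, rri_ms, rate = 4, ar_order = 40,
                               tp_mode = c("psd_band", "variance"),
                               sd_type = "population", nn_threshold = 50,
                               lf_band = c(0.04, 0.15),
                               hf_band = c(0.15, 0.4),
                               tp_band = c(0, 0.4), lfhf_cap = 1e6,
                               method = "burg", n_freq = 1024) {
  tp_mode <- match.arg(tp_mode)
  td <- time_domain_indices(rri_ms, sd_type = sd_type,
                            nn_threshold = nn_threshold)
  rs <- resample_tachogram(t_beat_s, rri_ms, rate = rate)
  psd <- ar_psd(rs, order = ar_order, method = method, n_freq = n_freq)
  fd <- band_powers(psd, lf_band = lf_band, hf_band = hf_band,
                    tp_band = tp_band, lfhf_cap = lfhf_cap)
  if (tp_mode == "variance")
    fd[["TP"]] <- mean((rri_ms - mean(rri_ms))^2)
  out <- c(td, fd)
  names(out) <- hrv_index_names
  out
}
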