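#' Configuration of the synthetic interictal RRI generator
#'
#' The generator emulates the band structure HRV analysis assumes: an
#' instantaneous R-R interval composed of a baseline plus a
#' low-frequency oscillation (vasomotor/baroreflex band, default 0.10 Hz),
#' a high-frequency oscillation (respiratory sinus arrhythmia band,
#' default 0.25 Hz), and white Gaussian beat-to-beat noise. Defaults give
#' a resting adult tachogram (baseline 900 ms, oscillation amplitudes
#' 35/25 ms, noise SD 15 ms).
#'
#' @param duration stream duration (s).
#' @param mean_rr baseline interval (ms).
#' @param lf_amp,lf_freq low-frequency amplitude (ms) and frequency (Hz).
#' @param hf_amp,hf_freq high-frequency amplitude (ms) and frequency (Hz).
#' @param noise_sd beat-to-beat Gaussian noise SD (ms).
#' @param miss_rate,ectopic_rate default artifact probabilities per beat
#'   for [inject_artifacts()].
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(duration = 600, mean_rr = 900,
                             lf_amp = 35, lf_freq = 0.10,
                             hf_amp = 25, hf_freq = 0.25,
                             noise_sd = 15, miss_rate = 0.01,
                             ectopic_rate = 0.005, seed) {
  stopifnot(duration > 0, mean_rr > 0, lf_amp >= 0, hf_amp >= 0,
            noise_sd >= 0, miss_rate >= 0, miss_rate < 1,
            ectopic_rate >= 0, ectopic_rate < 1)
  if (missing(seed)) stop("seed is required")
  structure(list(duration = duration, mean_rr = mean_rr,
                 lf_amp = lf_amp, lf_freq = lf_freq,
                 hf_amp = hf_amp, hf_freq = hf_freq,
                 noise_sd = noise_sd, miss_rate = miss_rate,
                 ectopic_rate = ectopic_rate, seed = as.integer(seed)),
            class = "generator_config")
}

#' Specification of an injected preictal anomaly
#'
#' Within `[t_onset, t_onset + duration)` the generator parameters are
#' shifted multiplicatively and the two oscillation amplitudes are mixed
#' by a rotation, altering both the location and the correlation
#' structure of the HRV index vector (what a PCA residual monitor is
#' built to notice). Defaults are the package's frozen reference effect
#' size for end-to-end validation.
#'
#' @param t_onset anomaly start (s).
#' @param duration anomaly length (s), positive.
#' @param mean_shift,lf_shift,hf_shift,noise_shift multiplicative shifts
#'   of the corresponding [generator_config()] parameters, positive.
#' @param rotation amplitude-mixing strength in `[0, 1]`; 0 keeps the
#'   bands separate, 1 swaps them.
#' @return an `anomaly_spec` list.
#' @export
anomaly_spec <- function(t_onset, duration, mean_shift = 0.88,
                         lf_shift = 2.2, hf_shift = 0.35,
                         noise_shift = 1.8, rotation = 0.6) {
  stopifnot(duration > 0, mean_shift > 0, lf_shift > 0, hf_shift > 0,
            noise_shift > 0, rotation >= 0, rotation <= 1)
  structure(list(t_onset = t_onset, duration = duration,
                 mean_shift = mean_shift, lf_shift = lf_shift,
                 hf_shift = hf_shift, noise_shift = noise_shift,
                 rotation = rotation),
            class = "anomaly_spec")
}

# core beat-by-beat regenerator; anomalies is a list of anomaly_spec
generate_stream_core <- function(config, anomalies = list()) {
  withr::with_seed(config$seed, {
    phi <- stats::runif(2, 0, 2 * pi)
    cap <- as.integer(ceiling(config$duration * 1000 / config$mean_rr * 1.5)
                      + 16L)
    # unit-variance innovations pre-drawn per beat index, so streams that
    # share a seed are beat-for-beat identical until their parameters
    # first diverge
    eps <- stats::rnorm(cap)
    tt <- numeric(cap)
    rr <- numeric(cap)
    t <- 0
    k <- 0L
    w1 <- 2 * pi * config$lf_freq
    w2 <- 2 * pi * config$hf_freq
    while (t < config$duration) {
      mean_rr <- config$mean_rr
      a1 <- config$lf_amp
      a2 <- config$hf_amp
      nsd <- config$noise_sd
      for (an in anomalies) {
        if (t >= an$t_onset && t < an$t_onset + an$duration) {
          th <- an$rotation * pi / 2
          sa1 <- an$lf_shift * config$lf_amp
          sa2 <- an$hf_shift * config$hf_amp
          a1 <- cos(th) * sa1 + sin(th) * sa2
          a2 <- cos(th) * sa2 + sin(th) * sa1
          mean_rr <- config$mean_rr * an$mean_shift
          nsd <- config$noise_sd * an$noise_shift
        }
      }
      k <- k + 1L
      if (k > cap) {
        cap <- 2L * cap
        eps <- c(eps, stats::rnorm(cap - length(eps)))
        length(tt) <- cap
        length(rr) <- cap
      }
      x <- mean_rr + a1 * sin(w1 * t + phi[1L]) + a2 * sin(w2 * t + phi[2L]) +
        nsd * eps[k]
      x <- max(x, 250)          # physiological floor
      t <- t + x / 1000
      tt[k] <- t
      rr[k] <- x
    }
    rri_records(tt[seq_len(k)], rr[seq_len(k)])
  })
}

#' Generate a clean synthetic interictal RRI stream
#'
#' @param config a [generator_config()].
#' @return an [rri_records()] table, with the config attached as
#'   attribute `config` (used by [inject_preictal()]).
#' @export
generate_interictal <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  out <- generate_stream_core(config)
  attr(out, "config") <- config
  attr(out, "anomalies") <- list()
  out
}

#' Inject a preictal anomaly into a generated stream
#'
#' Re-emits the stream from its stored configuration and seed with the
#' anomaly's parameter shifts active inside its window; beats before the
#' window are bit-identical to the input. The truth interval accumulates
#' on the `anomalies` attribute (see [anomaly_intervals()]).
#'
#' @param stream a stream from [generate_interictal()] (or a previous
#'   [inject_preictal()] call).
#' @param spec an [anomaly_spec()]; the window must lie inside the stream.
#' @return the modified stream.
#' @export
inject_preictal <- function(stream, spec) {
  config <- attr(stream, "config")
  if (is.null(config))
    stop("stream carries no generator config; was it generated here?")
  stopifnot(inherits(spec, "anomaly_spec"))
  if (spec$t_onset < 0 || spec$t_onset + spec$duration > config$duration)
    stop("anomaly window outside the stream")
  anomalies <- c(attr(stream, "anomalies"), list(spec))
  out <- generate_stream_core(config, anomalies)
  attr(out, "config") <- config
  attr(out, "anomalies") <- anomalies
  out
}

#' Ground-truth anomaly intervals of a synthetic stream
#'
#' @param stream a stream from [inject_preictal()].
#' @return data.frame `t_start_s, t_end_s`, one row per injected anomaly.
#' @export
anomaly_intervals <- function(stream) {
  an <- attr(stream, "anomalies")
  if (is.null(an)) an <- list()
  data.frame(
    t_start_s = vapply(an, `[[`, 0, "t_onset"),
    t_end_s = vapply(an, function(a) a$t_onset + a$duration, 0))
}

#' Corrupt a stream with missed-beat and ectopic artifacts
#'
#' A missed beat merges two consecutive intervals into one (a high
#' outlier for the stream cleaner to split back); an ectopic event splits
#' one interval into a short/long pair (a low outlier). Ground truth is
#' returned for recovery scoring. Beat times are recomputed as the
#' cumulative interval sum.
#'
#' @param stream an [rri_records()] table.
#' @param miss_rate,ectopic_rate per-beat probabilities (defaults from the
#'   stream's config when present).
#' @param seed integer seed.
#' @return list with `records` (the corrupted stream) and `truth`
#'   (data.frame `type, index, t_s`: type `miss` or `ectopic`, `index` the
#'   corrupted output row, `t_s` its beat time).
#' @export
inject_artifacts <- function(stream, miss_rate = NULL, ectopic_rate = NULL,
                             seed) {
  config <- attr(stream, "config")
  if (is.null(miss_rate))
    miss_rate <- if (!is.null(config)) config$miss_rate else 0
  if (is.null(ectopic_rate))
    ectopic_rate <- if (!is.null(config)) config$ectopic_rate else 0
  stopifnot(miss_rate >= 0, ectopic_rate >= 0,
            miss_rate + ectopic_rate < 1)
  if (missing(seed)) stop("seed is required")
  withr::with_seed(seed, {
    rri <- stream$rri_ms
    n <- length(rri)
    u <- stats::runif(n)
    fr <- stats::runif(n, 0.30, 0.40)
    out <- numeric(0)
    type <- character(0)
    idx <- integer(0)
    i <- 1L
    while (i <= n) {
      if (u[i] < miss_rate && i < n) {
        out <- c(out, rri[i] + rri[i + 1L])
        type <- c(type, "miss")
        idx <- c(idx, length(out))
        i <- i + 2L
      } else if (u[i] < miss_rate + ectopic_rate) {
        out <- c(out, rri[i] * fr[i], rri[i] * (1 - fr[i]))
        type <- c(type, "ectopic")
        idx <- c(idx, length(out) - 1L)
        i <- i + 1L
      } else {
        out <- c(out, rri[i])
        i <- i + 1L
      }
    }
    t0 <- stream$t_beat_s[1L] - stream$rri_ms[1L] / 1000
    tt <- t0 + cumsum(out) / 1000
    list(records = rri_records(tt, out),
         truth = data.frame(type = type, index = idx, t_s = tt[idx],
                            stringsAsFactors = FALSE))
  })
}

#' Direct simulator of interictal HRV index vectors
#'
#' Draws eight-component HRV index vectors from a stationary multivariate
#' Gaussian whose correlation structure mimics resting interictal
#' recordings: a dominant overall-variability factor (SDNN, RMSSD, NN50,
#' TP, LF, HF move together), a sympathovagal-balance factor (LF and
#' LF/HF against HF and RMSSD), and a heart-rate-level factor (meanNN).
#' Used to exercise the MSPC layer with many independent vectors, which a
#' sliding window over one tachogram cannot provide.
#'
#' @param n number of vectors.
#' @param seed integer seed.
#' @return numeric matrix `n x 8`, columns in [extract_hrv_matrix()]
#'   order.
#' @export
simulate_hrv_vectors <- function(n, seed) {
  if (missing(seed)) stop("seed is required")
  b <- rbind(  # factor loadings: overall variability, balance, HR level
    meanNN = c(0.20,  0.10,  0.90),
    SDNN   = c(0.90,  0.10,  0.20),
    RMSSD  = c(0.80, -0.40,  0.30),
    NN50   = c(0.70, -0.30,  0.20),
    TP     = c(0.90,  0.10,  0.10),
    LF     = c(0.80,  0.40,  0.00),
    HF     = c(0.80, -0.45,  0.20),
    LF_HF  = c(0.00,  0.80, -0.10)
  )
  corr <- b %*% t(b)
  diag(corr) <- 1
  s <- c(60, 15, 12, 25, 900, 350, 300, 0.6)
  mu <- c(900, 55, 38, 70, 2600, 1000, 750, 1.5)
  sig <- diag(s) %*% corr %*% diag(s)
  withr::with_seed(seed, {
    x <- MASS::mvrnorm(n, mu = mu, Sigma = sig)
  })
  colnames(x) <- hrv_index_names
  x
}

#' Generate an on-disk synthetic cohort
#'
#' Writes one RRI stream and one label file per subject plus a JSON
#' manifest. Each subject's seed is derived from the cohort seed, so the
#' dataset is byte-identical across runs. When anomalies are injected,
#' each anomaly's end is labeled as a seizure onset (the preictal change
#' precedes the seizure), and interictal intervals are the remaining time
#' at least `interictal_margin_s` from every onset.
#'
#' @param configs list of [generator_config()], one per subject.
#' @param anomalies list (same length) of lists of [anomaly_spec()];
#'   `NULL` for a clean cohort.
#' @param dir output directory (created if needed).
#' @param interictal_margin_s margin used for interictal labeling (s).
#' @return the manifest (also written to `manifest.json`): per-subject
#'   files, seeds, durations, and the total interictal hours.
#' @export
generate_cohort <- function(configs, anomalies = NULL, dir,
                            interictal_margin_s = 1800) {
  stopifnot(is.list(configs))
  n <- length(configs)
  if (is.null(anomalies)) anomalies <- rep(list(list()), n)
  stopifnot(length(anomalies) == n)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- vector("list", n)
  total_ii_s <- 0
  for (i in seq_len(n)) {
    cfg <- configs[[i]]
    stream <- generate_interictal(cfg)
    for (an in anomalies[[i]]) stream <- inject_preictal(stream, an)
    onsets <- vapply(anomalies[[i]],
                     function(a) a$t_onset + a$duration, 0)
    ii <- interictal_complement(cfg$duration, onsets, interictal_margin_s)
    tl <- labeled_timeline(onsets = onsets, interictal = ii,
                           interictal_margin_s = interictal_margin_s)
    rri_file <- file.path(dir, sprintf("subject_%02d_rri.csv", i))
    lab_file <- file.path(dir, sprintf("subject_%02d_labels.csv", i))
    write_rri(stream, rri_file)
    write_labels(tl, lab_file)
    total_ii_s <- total_ii_s + sum(ii$end_s - ii$start_s)
    subjects[[i]] <- list(id = sprintf("subject_%02d", i),
                          rri_file = basename(rri_file),
                          label_file = basename(lab_file),
                          seed = cfg$seed, duration_s = cfg$duration,
                          n_anomalies = length(anomalies[[i]]))
  }
  manifest <- list(n_subjects = n, subjects = subjects,
                   total_interictal_h = total_ii_s / 3600,
                   interictal_margin_s = interictal_margin_s)
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(dir, "manifest.json"))
  invisible(manifest)
}

# interictal time inside [0, duration] at least margin from every onset
interictal_complement <- function(duration, onsets, margin) {
  if (length(onsets) == 0L)
    return(data.frame(start_s = 0, end_s = duration))
  cuts <- sort(c(0, duration,
                 pmax(pmin(c(onsets - margin, onsets + margin), duration), 0)))
  out <- NULL
  for (k in seq_len(length(cuts) - 1L)) {
    s <- cuts[k]; e <- cuts[k + 1L]
    if (e - s <= 0) next
    mid <- (s + e) / 2
    if (all(abs(mid - onsets) >= margin))
      out <- rbind(out, data.frame(start_s = s, end_s = e))
  }
  if (is.null(out)) data.frame(start_s = numeric(0), end_s = numeric(0))
  else merge_intervals(out)
}
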