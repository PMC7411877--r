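# Independent reference implementations used as oracles. These are kept
# deliberately naive and separate from the package's code paths.

# --- stream cleaning: recompute the buffer from scratch at every beat ----
# buffer = longest suffix of accepted intervals with sum <= span seconds
naive_clean_stream <- function(rri, span = 180, warmup_s = 30,
                               n_sigma = 4, constant_tol = 0.2) {
  accepted <- numeric(0)
  out_rri <- numeric(0)
  out_flag <- character(0)
  n_out <- 0L
  suffix_buffer <- function(a) {
    s <- 0
    k <- length(a)
    while (k >= 1 && s + a[k] <= span * 1000) {
      s <- s + a[k]
      k <- k - 1
    }
    if (k == length(a)) k <- length(a) - 1  # keep at least one
    a[(k + 1):length(a)]
  }
  for (x in rri) {
    buf <- if (length(accepted)) suffix_buffer(accepted) else numeric(0)
    if (sum(buf) / 1000 < warmup_s || length(buf) < 2) {
      accepted <- c(accepted, x)
      out_rri <- c(out_rri, x)
      out_flag <- c(out_flag, "measured")
      next
    }
    med <- sort(buf)[c(ceiling(length(buf) / 2),
                       floor(length(buf) / 2) + 1)]
    med <- mean(med)
    sigma <- 1.4826 * {
      d <- sort(abs(buf - med))
      mean(d[c(ceiling(length(d) / 2), floor(length(d) / 2) + 1)])
    }
    cls <- if (sigma == 0) {
      if (abs(x - med) <= constant_tol * med) "normal"
      else if (x < med) "low" else "high"
    } else if (x <= med - n_sigma * sigma) "low"
    else if (x >= med + n_sigma * sigma) "high"
    else "normal"
    if (cls == "normal") {
      accepted <- c(accepted, x)
      out_rri <- c(out_rri, x)
      out_flag <- c(out_flag, "measured")
    } else if (cls == "low") {
      n_out <- n_out + 1L
      out_rri <- c(out_rri, x)
      out_flag <- c(out_flag, "removed")
    } else {
      n_out <- n_out + 1L
      nn <- round(x / med)
      repl <- if (nn <= 1) x else rep(x / nn, nn)
      accepted <- c(accepted, repl)
      out_rri <- c(out_rri, repl)
      out_flag <- c(out_flag, rep("corrected", length(repl)))
    }
  }
  list(rri = out_rri, flag = out_flag, outliers = n_out)
}

# --- MSPC: brute-force matrix-product evaluation ------------------------
brute_q <- function(model, x) {
  xs <- (x - model$center) / model$scale
  v <- model$loadings
  p <- length(xs)
  as.numeric(t(xs) %*% (diag(p) - v %*% t(v)) %*% xs)
}

brute_t2 <- function(model, x) {
  xs <- (x - model$center) / model$scale
  v <- model$loadings
  as.numeric(t(xs) %*% v %*% diag(1 / model$sigma^2, length(model$sigma)) %*%
               t(v) %*% xs)
}

# random model with exactly orthonormal loadings
rand_orthonormal_model <- function(p = 8, r = 6, seed = 1) {
  withr::with_seed(seed, {
    v <- qr.Q(qr(matrix(rnorm(p * r), p, r)))
    structure(list(center = rnorm(p, 1000, 100),
                   scale = runif(p, 0.5, 3),
                   loadings = v,
                   sigma = sort(runif(r, 0.5, 2), decreasing = TRUE),
                   cl_Q = NA_real_, cl_T2 = NA_real_, alpha = NA_real_,
                   n_components = r,
                   var_explained = NA_real_,
                   index_names = paste0("x", seq_len(p)), n_train = NA),
              class = "mspc_model")
  })
}

# --- HRV: independently scripted reference computation ------------------
ref_burg <- function(x, p) {
  n <- length(x)
  f <- x
  b <- x
  a <- numeric(0)
  e <- sum(x^2) / n
  for (m in 1:p) {
    ff <- f[(m + 1):n]
    bb <- b[m:(n - 1)]
    k <- -2 * sum(ff * bb) / (sum(ff^2) + sum(bb^2))
    a <- c(a + k * rev(a), k)
    e <- e * (1 - k^2)
    fn <- ff + k * bb
    bn <- bb + k * ff
    f <- c(rep(NA_real_, m), fn)
    b <- c(rep(NA_real_, m), bn)
  }
  list(ar = -a, var = e)
}

ref_trapz <- function(x, y) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1]) * (y[i] + y[i - 1]) / 2
  s
}

ref_band <- function(f, d, lo, hi) {
  sel <- f > lo & f < hi
  dlo <- approx(f, d, lo)$y
  dhi <- approx(f, d, hi)$y
  ref_trapz(c(lo, f[sel], hi), c(dlo, d[sel], dhi))
}

ref_hrv_vector <- function(t, r, rate = 4, order = 40, n_freq = 1024) {
  n <- length(r)
  m <- sum(r) / n
  sdnn <- sqrt(sum((r - m)^2) / n)
  dd <- r[-1] - r[-n]
  rmssd <- sqrt(sum(dd^2) / (n - 1))
  nn50 <- sum(abs(dd) > 50)
  grid <- seq(t[1], t[n], by = 1 / rate)
  y <- spline(t, r, xout = grid, method = "fmm")$y
  y <- y - mean(y)
  fit <- ref_burg(y, order)
  freqs <- seq(0, rate / 2, length.out = n_freq)
  dens <- sapply(freqs, function(fr) {
    a_sum <- sum(fit$ar * exp(-2i * pi * seq_along(fit$ar) * fr / rate))
    2 * fit$var / rate / Mod(1 - a_sum)^2
  })
  lf <- ref_band(freqs, dens, 0.04, 0.15)
  hf <- ref_band(freqs, dens, 0.15, 0.4)
  tp <- ref_band(freqs, dens, 0, 0.4)
  c(meanNN = m, SDNN = sdnn, RMSSD = rmssd, NN50 = nn50,
    TP = tp, LF = lf, HF = hf, LF_HF = lf / hf)
}

# --- shared fixtures ----------------------------------------------------
two_tone_stream <- function(duration = 400, mean_rr = 1000, lf_amp = 0,
                            hf_amp = 0, noise_sd = 0, seed = 101) {
  generate_interictal(generator_config(
    duration = duration, mean_rr = mean_rr, lf_amp = lf_amp,
    hf_amp = hf_amp, noise_sd = noise_sd, seed = seed))
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "hrvmspc")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", name)
  path
}
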