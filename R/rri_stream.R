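#' Create a beat-to-beat RRI record table
#'
#' The basic container used throughout the package: one row per heartbeat,
#' with the elapsed time of the beat since stream start (seconds), the
#' R-R interval that ended at that beat (milliseconds), and a quality flag.
#'
#' @param t_beat_s elapsed beat times in seconds, strictly increasing.
#' @param rri_ms positive R-R intervals in milliseconds.
#' @param flag per-beat quality flag, one of `"measured"`, `"corrected"`,
#'   `"removed"`.
#' @return a `data.frame` with columns `t_beat_s`, `rri_ms`, `flag`.
#' @export
rri_records <- function(t_beat_s, rri_ms, flag = "measured") {
  if (length(t_beat_s) != length(rri_ms))
    stop("t_beat_s and rri_ms must have equal length")
  if (any(rri_ms <= 0)) stop("all rri_ms must be positive")
  if (length(t_beat_s) > 1L && any(diff(t_beat_s) <= 0))
    stop("t_beat_s must be strictly increasing")
  flag <- rep_len(as.character(flag), length(rri_ms))
  bad <- setdiff(unique(flag), c("measured", "corrected", "removed"))
  if (length(bad)) stop("unknown flag: ", paste(bad, collapse = ", "))
  data.frame(t_beat_s = as.numeric(t_beat_s),
             rri_ms = as.numeric(rri_ms),
             flag = flag,
             stringsAsFactors = FALSE)
}

#' Robust outlier statistics of an RRI buffer
#'
#' Median, median absolute deviation (MAD), the robust standard deviation
#' `sigma = 1.4826 * MAD`, and the acceptance bounds `median +/- 4 sigma`
#' used to screen each incoming interval against the recent buffer.
#'
#' @param rri numeric vector of buffered R-R intervals (ms), at least 2.
#' @param n_sigma half-width of the acceptance band in robust SD units.
#' @return an object of class `outlier_stats` with fields `median`, `mad`,
#'   `sigma`, `lower`, `upper`.
#' @examples
#' compute_outlier_stats(c(800, 900, 1000, 1100, 1200))
#' @export
compute_outlier_stats <- function(rri, n_sigma = 4) {
  if (length(rri) < 2L)
    stop("insufficient data: need at least 2 buffered RRIs")
  med <- stats::median(rri)
  mad_ <- stats::median(abs(rri - med))
  sigma <- 1.4826 * mad_
  structure(list(median = med, mad = mad_, sigma = sigma,
                 lower = med - n_sigma * sigma,
                 upper = med + n_sigma * sigma,
                 n_sigma = n_sigma),
            class = "outlier_stats")
}

#' @export
print.outlier_stats <- function(x, ...) {
  cat(sprintf("RRI outlier stats: median %.1f ms, MAD %.1f ms, sigma %.2f ms\n",
              x$median, x$mad, x$sigma))
  cat(sprintf("  acceptance band (median +/- %g sigma): [%.2f, %.2f] ms\n",
              x$n_sigma, x$lower, x$upper))
  invisible(x)
}

#' Classify an incoming RRI against buffer statistics
#'
#' An interval strictly inside `(lower, upper)` is normal; values at or
#' beyond a bound take the adjacent outlier class. When the buffer is
#' constant (`sigma = 0`) the band degenerates, so intervals within
#' `constant_tol` (fractional) of the median are accepted and anything
#' else is classified by sign.
#'
#' @param stats an [compute_outlier_stats()] result.
#' @param rri numeric vector of candidate intervals (ms).
#' @param constant_tol fractional tolerance used when `sigma = 0`.
#' @return character vector in `{"normal","low_outlier","high_outlier"}`.
#' @export
classify_rri <- function(stats, rri, constant_tol = 0.2) {
  stopifnot(inherits(stats, "outlier_stats"))
  if (stats$sigma == 0) {
    dev <- rri - stats$median
    out <- ifelse(abs(dev) <= constant_tol * stats$median, "normal",
                  ifelse(dev < 0, "low_outlier", "high_outlier"))
    return(out)
  }
  ifelse(rri <= stats$lower, "low_outlier",
         ifelse(rri >= stats$upper, "high_outlier", "normal"))
}

#' Split a long interval into estimated missed beats
#'
#' A high outlier is assumed to be `N` merged beats where
#' `N = round(rri / median_rri)`; it is replaced by `N` equal intervals of
#' `rri / N` ms so that summed beat time is conserved exactly. If rounding
#' gives `N <= 1` the interval is kept as a single corrected beat.
#'
#' @param rri the outlying interval (ms).
#' @param median_rri the buffer median (ms), positive.
#' @return numeric vector of replacement intervals (ms), flagged
#'   `corrected` by the caller.
#' @examples
#' correct_high_outlier(1900, 1000)  # two beats of 950 ms
#' @export
correct_high_outlier <- function(rri, median_rri) {
  if (median_rri <= 0) stop("median_rri must be positive")
  n <- round(rri / median_rri)
  if (n <= 1) return(rri)
  rep(rri / n, n)
}

#' Clean an RRI stream with a rolling robust buffer
#'
#' Replays the stream beat by beat against a first-in-first-out buffer of
#' the most recent ~`span` seconds of accepted intervals. Once the buffer
#' holds at least `warmup_s` seconds, each incoming interval is screened
#' against the buffer's `median +/- 4 sigma` band (the buffer excludes the
#' candidate itself): low outliers are removed, high outliers are replaced
#' by the estimated number of missed beats via [correct_high_outlier()],
#' and accepted (measured or corrected) intervals enter the buffer.
#' Beat times in the output are the cumulative sum of accepted intervals,
#' so corrections conserve elapsed time and removals shorten it.
#'
#' @param records an [rri_records()] table, time-ordered.
#' @param span buffer span in seconds (default 180).
#' @param warmup_s outlier testing is skipped until the buffer covers this
#'   many seconds; earlier beats pass through flagged `measured`.
#' @param n_sigma acceptance band half-width (robust SDs).
#' @param constant_tol degenerate-buffer tolerance, see [classify_rri()].
#' @return a list with `records` (the cleaned table: accepted beats with
#'   recomputed cumulative `t_beat_s`, plus `removed` rows retained for
#'   audit with their original interval), and `report`, a failure report
#'   list `(total, outliers, failure_rate_pct)` counting screened input
#'   beats that fell outside the acceptance band.
#' @seealso [accepted_records()] to drop the `removed` audit rows.
#' @export
process_stream <- function(records, span = 180, warmup_s = 30,
                           n_sigma = 4, constant_tol = 0.2) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  report <- list(total = n, outliers = 0L, failure_rate_pct = 0)
  if (n == 0L) {
    return(list(records = rri_records(numeric(0), numeric(0), character(0)),
                report = report))
  }
  if (n > 1L && any(diff(records$t_beat_s) <= 0))
    stop("records must be strictly time-ordered")
  span_ms <- span * 1000
  t0 <- records$t_beat_s[1L] - records$rri_ms[1L] / 1000

  buf <- numeric(0)
  buf_sum <- 0
  cap <- 2L * n
  out_rri <- numeric(cap)
  out_flag <- character(cap)
  m <- 0L
  n_out <- 0L
  push <- function(vals, flags) {
    k <- length(vals)
    if (m + k > cap) {  # grow
      cap <<- max(2L * cap, m + k)
      length(out_rri) <<- cap
      length(out_flag) <<- cap
    }
    out_rri[(m + 1L):(m + k)] <<- vals
    out_flag[(m + 1L):(m + k)] <<- flags
    m <<- m + k
  }
  accept <- function(vals) {
    buf <<- c(buf, vals)
    buf_sum <<- buf_sum + sum(vals)
    while (buf_sum > span_ms && length(buf) > 1L) {
      buf_sum <<- buf_sum - buf[1L]
      buf <<- buf[-1L]
    }
  }

  for (i in seq_len(n)) {
    rri <- records$rri_ms[i]
    if (buf_sum / 1000 < warmup_s || length(buf) < 2L) {
      push(rri, "measured")
      accept(rri)
      next
    }
    st <- compute_outlier_stats(buf, n_sigma = n_sigma)
    cls <- classify_rri(st, rri, constant_tol = constant_tol)
    if (cls == "normal") {
      push(rri, "measured")
      accept(rri)
    } else if (cls == "low_outlier") {
      n_out <- n_out + 1L
      push(rri, "removed")
    } else {
      n_out <- n_out + 1L
      repl <- correct_high_outlier(rri, st$median)
      push(repl, rep("corrected", length(repl)))
      accept(repl)
    }
  }

  out_rri <- out_rri[seq_len(m)]
  out_flag <- out_flag[seq_len(m)]
  keep <- out_flag != "removed"
  t_beat <- numeric(m)
  t_beat[keep] <- t0 + cumsum(out_rri[keep]) / 1000
  if (any(!keep)) {   # removed rows carry the elapsed time at occurrence
    last_t <- c(t0, t_beat[keep])
    t_beat[!keep] <- last_t[findInterval(which(!keep), which(keep)) + 1L]
  }
  report$outliers <- n_out
  report$failure_rate_pct <- if (n > 0) 100 * n_out / n else 0

  out <- data.frame(t_beat_s = t_beat, rri_ms = out_rri, flag = out_flag,
                    stringsAsFactors = FALSE)
  list(records = out, report = report)
}

#' Keep only beats usable for HRV analysis
#'
#' @param records a cleaned record table from [process_stream()].
#' @return the rows whose flag is `measured` or `corrected`.
#' @export
accepted_records <- function(records) {
  records[records$flag != "removed", , drop = FALSE]
}

#' Read / write RRI streams as delimited text
#'
#' Files have a header and columns `t_beat_s, rri_ms` (plus `flag` when
#' present), one beat per line.
#'
#' @param path file path.
#' @param records an [rri_records()] table.
#' @return `read_rri` returns an [rri_records()] table.
#' @export
read_rri <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t_beat_s", "rri_ms") %in% names(df)))
    stop("RRI file must have columns t_beat_s, rri_ms")
  flag <- if ("flag" %in% names(df)) df$flag else "measured"
  rri_records(df$t_beat_s, df$rri_ms, flag)
}

#' @rdname read_rri
#' @export
write_rri <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a failure report as JSON
#'
#' @param report the `report` element of a [process_stream()] result.
#' @param path file path.
#' @export
write_failure_report <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}
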