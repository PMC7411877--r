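merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  iv <- iv[order(iv$start_s), , drop = FALSE]
  if (any(iv$end_s <= iv$start_s)) stop("intervals must have start < end")
  out_s <- iv$start_s[1L]
  out_e <- iv$end_s[1L]
  if (nrow(iv) > 1L) {
    for (i in 2L:nrow(iv)) {
      k <- length(out_s)
      if (iv$start_s[i] <= out_e[k]) {
        out_e[k] <- max(out_e[k], iv$end_s[i])
      } else {
        out_s <- c(out_s, iv$start_s[i])
        out_e <- c(out_e, iv$end_s[i])
      }
    }
  }
  data.frame(start_s = out_s, end_s = out_e)
}

as_intervals <- function(x) {
  if (is.null(x)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  if (is.matrix(x)) x <- data.frame(start_s = x[, 1L], end_s = x[, 2L])
  stopifnot(is.data.frame(x), all(c("start_s", "end_s") %in% names(x)))
  x
}

#' Assemble a labeled study timeline
#'
#' Seizure onsets, interictal intervals, and exclusion intervals
#' (e.g. nocturnal periods, naps, ectopy-contaminated or noisy-EEG
#' segments) on a common clock. All intervals are half-open
#' `[start, end)`, non-negative, and merged within each list. Interictal
#' intervals must lie at least `interictal_margin_s` (30 min by default)
#' from every seizure onset.
#'
#' @param onsets seizure onset times (s).
#' @param interictal interictal intervals: data.frame or 2-column matrix
#'   of `start_s, end_s`.
#' @param exclusions exclusion intervals, optionally with a `tag` column.
#' @param interictal_margin_s minimum distance of interictal time from any
#'   onset (s).
#' @return object of class `labeled_timeline`.
#' @export
labeled_timeline <- function(onsets = numeric(0), interictal = NULL,
                             exclusions = NULL,
                             interictal_margin_s = 1800) {
  onsets <- sort(as.numeric(onsets))
  ii <- merge_intervals(as_intervals(interictal))
  ex_raw <- as_intervals(exclusions)
  tag <- if (!is.null(exclusions) && "tag" %in% names(ex_raw)) ex_raw$tag
         else rep_len("unspecified", nrow(ex_raw))
  ex <- ex_raw[order(ex_raw$start_s), c("start_s", "end_s"), drop = FALSE]
  ex$tag <- tag[order(ex_raw$start_s)]
  if (any(c(ii$start_s, ex$start_s, onsets) < 0))
    stop("times must be non-negative")
  for (o in onsets) {
    viol <- ii$end_s > o - interictal_margin_s &
            ii$start_s < o + interictal_margin_s
    if (any(viol))
      stop("interictal interval within ", interictal_margin_s,
           " s of the onset at ", o, " s")
  }
  structure(list(seizure_onsets = onsets, interictal_intervals = ii,
                 exclusion_intervals = ex,
                 interictal_margin_s = interictal_margin_s),
            class = "labeled_timeline")
}

#' Read / write timeline label files
#'
#' Delimited text with columns `kind` (`onset`, `interictal`,
#' `exclusion`), `start_s`, `end_s` (empty for onsets), `tag`.
#'
#' @param path file path.
#' @param timeline a [labeled_timeline()].
#' @export
write_labels <- function(timeline, path) {
  stopifnot(inherits(timeline, "labeled_timeline"))
  rows <- rbind(
    if (length(timeline$seizure_onsets))
      data.frame(kind = "onset", start_s = timeline$seizure_onsets,
                 end_s = NA_real_, tag = ""),
    if (nrow(timeline$interictal_intervals))
      data.frame(kind = "interictal",
                 start_s = timeline$interictal_intervals$start_s,
                 end_s = timeline$interictal_intervals$end_s, tag = ""),
    if (nrow(timeline$exclusion_intervals))
      data.frame(kind = "exclusion",
                 start_s = timeline$exclusion_intervals$start_s,
                 end_s = timeline$exclusion_intervals$end_s,
                 tag = timeline$exclusion_intervals$tag))
  if (is.null(rows))
    rows <- data.frame(kind = character(0), start_s = numeric(0),
                       end_s = numeric(0), tag = character(0))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ex <- df[df$kind == "exclusion", , drop = FALSE]
  labeled_timeline(
    onsets = df$start_s[df$kind == "onset"],
    interictal = df[df$kind == "interictal", c("start_s", "end_s")],
    exclusions = if (nrow(ex))
      data.frame(start_s = ex$start_s, end_s = ex$end_s, tag = ex$tag))
}

#' Drop or clip data falling in exclusion intervals
#'
#' Beat tables (column `t_beat_s`) lose every beat inside an exclusion
#' interval; episode tables (columns `t_start_s`, `t_end_s`) are clipped
#' at exclusion edges, split when an exclusion falls inside an episode,
#' and dropped when fully covered.
#'
#' @param x a beat or episode data.frame.
#' @param timeline a [labeled_timeline()].
#' @return the filtered data.frame.
#' @export
apply_exclusions <- function(x, timeline) {
  stopifnot(inherits(timeline, "labeled_timeline"))
  ex <- timeline$exclusion_intervals
  if (nrow(ex) == 0L) return(x)
  if ("t_beat_s" %in% names(x)) {
    drop <- rep(FALSE, nrow(x))
    for (i in seq_len(nrow(ex)))
      drop <- drop | (x$t_beat_s >= ex$start_s[i] & x$t_beat_s < ex$end_s[i])
    return(x[!drop, , drop = FALSE])
  }
  if (all(c("t_start_s", "t_end_s") %in% names(x))) {
    pieces <- lapply(seq_len(nrow(x)), function(i) {
      segs <- data.frame(s = x$t_start_s[i], e = x$t_end_s[i])
      for (j in seq_len(nrow(ex))) {
        new <- list()
        for (k in seq_len(nrow(segs))) {
          s <- segs$s[k]; e <- segs$e[k]
          if (ex$end_s[j] <= s || ex$start_s[j] >= e) {
            new[[length(new) + 1L]] <- c(s, e)
          } else {
            if (s < ex$start_s[j])
              new[[length(new) + 1L]] <- c(s, ex$start_s[j])
            if (e > ex$end_s[j])
              new[[length(new) + 1L]] <- c(ex$end_s[j], e)
          }
        }
        segs <- if (length(new))
          data.frame(s = vapply(new, `[`, 0, 1L),
                     e = vapply(new, `[`, 0, 2L))
        else data.frame(s = numeric(0), e = numeric(0))
      }
      if (nrow(segs) == 0L) return(NULL)
      out <- x[rep(i, nrow(segs)), , drop = FALSE]
      out$t_start_s <- segs$s
      out$t_end_s <- segs$e
      out
    })
    out <- do.call(rbind, pieces)
    if (is.null(out)) out <- x[0L, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  stop("x must have t_beat_s or t_start_s/t_end_s columns")
}

#' Sensitivity within a prediction horizon
#'
#' A seizure counts as predicted when some alarm episode overlaps the
#' half-open horizon window `[onset - horizon, onset)`; any nonempty
#' intersection counts, and multiple episodes before one seizure count
#' once.
#'
#' @param episodes episode data.frame with `t_start_s`, `t_end_s`.
#' @param onsets seizure onset times (s), at least one.
#' @param horizon prediction horizon (s), default 900 (15 min).
#' @return list with `sensitivity` (fraction), `hits` (logical per
#'   seizure), `n_predicted`, `n_seizures`.
#' @export
sensitivity_at_horizon <- function(episodes, onsets, horizon = 900) {
  if (length(onsets) == 0L)
    stop("sensitivity undefined: no seizure onsets supplied")
  onsets <- sort(onsets)
  hits <- vapply(onsets, function(o) {
    any(episodes$t_start_s < o & episodes$t_end_s > o - horizon)
  }, logical(1L))
  list(sensitivity = mean(hits), hits = hits,
       n_predicted = sum(hits), n_seizures = length(onsets))
}

#' Sensitivity from a per-seizure alarm interval table
#'
#' Convenience wrapper for tables of alarm intervals expressed relative to
#' each seizure's onset (onset at 0 s, preictal times negative). Rows with
#' missing `start_s` mark seizures for which the statistic never exceeded
#' its control limit.
#'
#' @param tbl data.frame with columns `seizure_id`, `statistic`,
#'   `start_s`, `end_s`.
#' @param statistic which statistic's rows to score (e.g. `"Q"`).
#' @param horizon prediction horizon (s).
#' @return as [sensitivity_at_horizon()], with seizures ordered by id.
#' @export
sensitivity_from_alarm_table <- function(tbl, statistic, horizon = 900) {
  ids <- sort(unique(tbl$seizure_id))
  rows <- tbl[tbl$statistic == statistic & !is.na(tbl$start_s), ,
              drop = FALSE]
  hits <- vapply(ids, function(id) {
    ep <- rows[rows$seizure_id == id, , drop = FALSE]
    nrow(ep) > 0L &&
      any(ep$start_s < 0 & ep$end_s > -horizon)
  }, logical(1L))
  list(sensitivity = mean(hits), hits = stats::setNames(hits, ids),
       n_predicted = sum(hits), n_seizures = length(ids))
}

#' False positives per hour of interictal time
#'
#' Counts alarm episode onsets falling inside (half-open) interictal
#' intervals and divides by the total interictal duration in hours.
#'
#' @param episodes episode data.frame with `t_start_s`.
#' @param interictal interictal intervals (data.frame/matrix
#'   `start_s, end_s`, or a [labeled_timeline()]).
#' @return rate in 1/h.
#' @export
false_positive_rate <- function(episodes, interictal) {
  if (inherits(interictal, "labeled_timeline"))
    interictal <- interictal$interictal_intervals
  iv <- merge_intervals(as_intervals(interictal))
  hours <- sum(iv$end_s - iv$start_s) / 3600
  if (hours <= 0) stop("zero interictal duration")
  inside <- vapply(episodes$t_start_s, function(t) {
    any(t >= iv$start_s & t < iv$end_s)
  }, logical(1L))
  sum(inside) / hours
}

#' Exact one-sided sign test
#'
#' Exact binomial tail probability of observing at least (direction
#' `"greater"`) or at most (`"less"`) the given number of successes under
#' a chance success probability.
#'
#' @param successes observed successes.
#' @param n number of trials.
#' @param chance success probability under the null (default 0.5).
#' @param direction `"greater"` or `"less"`.
#' @return the exact p-value.
#' @examples
#' sign_test_one_sided(12, 14)  # 106/16384
#' @export
sign_test_one_sided <- function(successes, n, chance = 0.5,
                                direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (successes < 0 || successes > n)
    stop("successes must be between 0 and n")
  if (direction == "greater") {
    stats::pbinom(successes - 1, n, chance, lower.tail = FALSE)
  } else {
    stats::pbinom(successes, n, chance)
  }
}

#' Compare two groups of false-positive rates
#'
#' Two-sample t-test (Welch by default) of per-subject rates, e.g.
#' patients against healthy controls. Degenerate zero-variance data are
#' handled: identical groups give p = 1.
#'
#' @param group_a,group_b numeric vectors of per-subject rates, each of
#'   length at least 2.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return the two-sided p-value.
#' @export
compare_fp_rates <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("both groups need at least 2 values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    return(if (mean(group_a) == mean(group_b)) 1 else 0)
  }
  stats::t.test(group_a, group_b, var.equal = var_equal)$p.value
}

#' Bland-Altman agreement of paired RRI measurements
#'
#' @param reference,device aligned paired measurements (ms), equal length
#'   of at least 2.
#' @return list with `bias` (mean of reference - device), `loa`
#'   (bias +/- 1.96 SD of the differences), `sd`, `n`.
#' @export
bland_altman <- function(reference, device) {
  if (length(reference) != length(device))
    stop("sequences must have equal length")
  if (length(reference) < 2L) stop("need at least 2 pairs")
  d <- reference - device
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa = c(lower = bias - 1.96 * s,
                            upper = bias + 1.96 * s),
       sd = s, n = length(d))
}

#' Summarize per-subject RRI measurement failure rates
#'
#' Per-subject failure percentage (outliers / total * 100, reported
#' rounded to one decimal as in device summaries), with the mean (two
#' decimals) and population standard deviation (divisor n) of the rounded
#' rates.
#'
#' @param total per-subject total RRI counts, positive.
#' @param outliers per-subject outlier counts.
#' @return list with `rate_pct` (rounded per-subject rates), `mean_pct`,
#'   `sd_pct`, and the unrounded `rate_raw`.
#' @export
failure_rate_summary <- function(total, outliers) {
  if (length(total) != length(outliers))
    stop("total and outliers must have equal length")
  if (any(total <= 0)) stop("totals must be positive")
  raw <- 100 * outliers / total
  rates <- round(raw, 1)
  m <- mean(rates)
  list(rate_pct = rates,
       mean_pct = round(m, 2),
       sd_pct = round(sqrt(mean((rates - m)^2)), 2),
       rate_raw = raw)
}
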