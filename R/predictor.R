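#' Initial state of the alarm state machine
#'
#' @param tau accumulated persistence time (s).
#' @param status `"interictal"` or `"preictal"`.
#' @param t_now stream time (s).
#' @return a `predictor_state` list.
#' @export
predictor_state <- function(tau = 0, status = c("interictal", "preictal"),
                            t_now = 0) {
  status <- match.arg(status)
  structure(list(tau = tau, status = status, t_now = t_now),
            class = "predictor_state")
}

exceedance <- function(Q, T2, model, mode) {
  switch(mode,
         q = Q > model$cl_Q,
         t2 = T2 > model$cl_T2,
         either = Q > model$cl_Q || T2 > model$cl_T2)
}

#' One step of the alarm state machine
#'
#' Per incoming beat, the persistence counter `tau` accumulates the beat's
#' interval (seconds) while the monitored condition pushes toward a state
#' change -- exceedance while interictal, or recovery while preictal --
#' and resets to zero otherwise. When `tau` reaches `persistence` seconds
#' the patient status toggles and `tau` resets, so isolated excursions
#' shorter than the persistence window never raise (or clear) a warning.
#'
#' Equality with a control limit counts as non-exceedance. Recovery is by
#' default the logical negation of exceedance (under `mode = "either"`,
#' both statistics at or below their limits); `recovery = "literal"`
#' instead clears when either statistic alone is at or below its limit.
#'
#' @param state a [predictor_state()].
#' @param y_s elapsed time carried by this observation (s); the R-R
#'   interval itself at per-beat cadence.
#' @param Q,T2 the monitoring statistics at this beat.
#' @param model a tuned [fit_mspc()] model (control limits set).
#' @param mode which statistic raises alarms: `"q"`, `"t2"`, or
#'   `"either"`.
#' @param persistence required continuous time (s) before toggling
#'   (default 10).
#' @param recovery `"negation"` (default) or `"literal"`, see above.
#' @return the new `predictor_state`, with attribute `toggled` set to
#'   `TRUE` when the status changed at this step.
#' @export
predictor_step <- function(state, y_s, Q, T2, model,
                           mode = c("q", "t2", "either"), persistence = 10,
                           recovery = c("negation", "literal")) {
  mode <- match.arg(mode)
  recovery <- match.arg(recovery)
  stopifnot(inherits(state, "predictor_state"))
  if (mode %in% c("q", "either") && is.na(model$cl_Q))
    stop("control limits not tuned; call tune_control_limits() first")
  if (mode %in% c("t2", "either") && is.na(model$cl_T2))
    stop("control limits not tuned; call tune_control_limits() first")
  if (y_s <= 0) stop("y_s must be positive")

  ex <- exceedance(Q, T2, model, mode)
  rec <- if (recovery == "negation" || mode != "either") !ex
         else (Q <= model$cl_Q || T2 <= model$cl_T2)

  grow <- (ex && state$status == "interictal") ||
          (rec && state$status == "preictal")
  tau <- if (grow) state$tau + y_s else 0
  status <- state$status
  toggled <- FALSE
  if (tau >= persistence) {
    status <- if (status == "interictal") "preictal" else "interictal"
    tau <- 0
    toggled <- TRUE
  }
  out <- predictor_state(tau = tau, status = status,
                         t_now = state$t_now + y_s)
  attr(out, "toggled") <- toggled
  out
}

#' Run the alarm state machine over a monitored stream
#'
#' Folds [predictor_step()] over a time-ordered stream of monitoring
#' statistics and collects alarm episodes: an episode opens when the
#' status toggles interictal to preictal and closes at the next toggle
#' back (or at stream end).
#'
#' @param stats data.frame with columns `t_eval` (s), `y_s` (elapsed
#'   seconds carried by each row), `Q`, `T2`.
#' @param model a tuned [fit_mspc()] model.
#' @param init optional [predictor_state()] carried over from a previous
#'   segment (streaming use).
#' @inheritParams predictor_step
#' @return list with `trace` (data.frame `t_eval, tau, status`),
#'   `episodes` (data.frame `t_start_s, t_end_s, statistic`), and `state`
#'   (the final state, for resumption).
#' @export
run_predictor <- function(stats, model, mode = c("q", "t2", "either"),
                          persistence = 10,
                          recovery = c("negation", "literal"),
                          init = NULL) {
  mode <- match.arg(mode)
  recovery <- match.arg(recovery)
  need <- c("t_eval", "y_s", "Q", "T2")
  if (!all(need %in% names(stats)))
    stop("stats must have columns ", paste(need, collapse = ", "))
  if (nrow(stats) > 1L && any(diff(stats$t_eval) <= 0))
    stop("stats must be strictly time-ordered")
  state <- if (is.null(init)) predictor_state() else init
  n <- nrow(stats)
  tau_tr <- numeric(n)
  st_tr <- character(n)
  starts <- numeric(0)
  ends <- numeric(0)
  open <- state$status == "preictal"
  if (open) starts <- state$t_now
  for (i in seq_len(n)) {
    state <- predictor_step(state, stats$y_s[i], stats$Q[i], stats$T2[i],
                            model, mode = mode, persistence = persistence,
                            recovery = recovery)
    if (isTRUE(attr(state, "toggled"))) {
      if (state$status == "preictal") {
        starts <- c(starts, stats$t_eval[i])
        open <- TRUE
      } else {
        ends <- c(ends, stats$t_eval[i])
        open <- FALSE
      }
    }
    tau_tr[i] <- state$tau
    st_tr[i] <- state$status
  }
  if (open && n > 0L) ends <- c(ends, stats$t_eval[n])
  label <- c(q = "Q", t2 = "T2", either = "either")[[mode]]
  episodes <- data.frame(t_start_s = starts, t_end_s = ends,
                         statistic = rep_len(label, length(starts)),
                         stringsAsFactors = FALSE)
  list(trace = data.frame(t_eval = stats$t_eval, tau = tau_tr,
                          status = st_tr, stringsAsFactors = FALSE),
       episodes = episodes, state = state)
}
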