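#' Trial-wise value and prediction-error traces
#'
#' Replays a session deterministically through the delta-rule update with a
#' subject's point-estimate parameters (posterior means by default),
#' recording the value of both options at decision time and the prediction
#' error at outcome time.  Neutral trials keep the fixed value difference
#' 0.4 and generate no prediction error; omitted trials carry the values
#' forward and have no prediction error.
#'
#' @param params_point a [subject_params()] object (typically posterior
#'   means).
#' @param session a behavioural session aligned with `schedule`.
#' @param schedule the [build_schedule()] object.
#' @param value_signal `"chosen"` (value of the chosen option, default) or
#'   `"difference"` (chosen minus unchosen) for the decision-time value
#'   column.
#' @return a list of class `rlddm_traces`: `values` (per trial: `q_high`,
#'   `q_low`, `value_decision`, plus identifiers) and `pe` (per non-omitted
#'   reward/loss trial: `pe`, `sign` - zero prediction errors are assigned
#'   to the positive category).
#' @examples
#' sched <- build_schedule(1, n_per_type = 5)
#' pars <- subject_params("RLDDM_bspow", alpha = .3, nu = 3, bb = 1.2,
#'                        bp = -.2, t_nd = .35)
#' sess <- simulate_subject(pars, sched, 3)
#' tr <- compute_traces(pars, sess, sched)
#' head(tr$values)
#' @export
compute_traces <- function(params_point, session, schedule,
                           value_signal = c("chosen", "difference")) {
  value_signal <- match.arg(value_signal)
  stopifnot(inherits(params_point, "subject_params"))
  if (nrow(session) != nrow(schedule))
    stop("session and schedule must be aligned trial-for-trial")
  alpha <- params_point$alpha
  n <- nrow(schedule)
  Qu <- c(reward = 0, neutral = NA, loss = 0)
  Ql <- c(reward = 0, neutral = NA, loss = 0)
  q_high <- q_low <- value_dec <- pe <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ty <- as.character(schedule$trial_type[i])
    ch <- as.character(session$choice[i])
    if (ty == "neutral") {
      # fixed difference, centred on zero: never updated
      q_high[i] <- 0.4; q_low[i] <- 0
    } else {
      q_high[i] <- Qu[ty]; q_low[i] <- Ql[ty]
    }
    if (ch != "omitted") {
      q_c <- if (ch == "better") q_high[i] else q_low[i]
      q_u <- if (ch == "better") q_low[i] else q_high[i]
      value_dec[i] <- if (value_signal == "chosen") q_c else q_c - q_u
      if (ty != "neutral") {
        r <- session$reinforcement[i]
        pe[i] <- r - q_c
        if (ch == "better") Qu[ty] <- Qu[ty] + alpha * (r - Qu[ty])
        else Ql[ty] <- Ql[ty] + alpha * (r - Ql[ty])
      }
    }
  }
  sid <- as.character(session$subject_id[1])
  values <- data.frame(subject_id = sid, trial = schedule$trial,
                       trial_type = schedule$trial_type,
                       within_type_index = schedule$within_type_index,
                       q_high = q_high, q_low = q_low,
                       value_decision = value_dec)
  keep <- !is.na(pe)
  pe_df <- data.frame(subject_id = sid, trial = schedule$trial[keep],
                      trial_type = droplevels(schedule$trial_type[keep]),
                      within_type_index = schedule$within_type_index[keep],
                      pe = pe[keep],
                      sign = factor(ifelse(pe[keep] >= 0, "positive",
                                           "negative"),
                                    levels = c("positive", "negative")))
  structure(list(values = values, pe = pe_df, value_signal = value_signal),
            class = "rlddm_traces")
}

#' Detrend value traces against the control-group mean
#'
#' Subtracts the control group's per-trial mean value estimate from every
#' subject's trace (including, for checks, the controls themselves), which
#' removes the bias imposed on the value time courses by the shared
#' quasi-randomized trial sequence and contingencies.
#'
#' @param patient_traces list of `rlddm_traces` (or a single one) to
#'   detrend.
#' @param control_traces list of `rlddm_traces` from the control group.
#' @return the traces with `q_high`, `q_low` and `value_decision` replaced
#'   by their detrended counterparts (a single object if a single object
#'   was supplied).
#' @export
detrend_values <- function(patient_traces, control_traces) {
  single <- inherits(patient_traces, "rlddm_traces")
  if (single) patient_traces <- list(patient_traces)
  if (inherits(control_traces, "rlddm_traces"))
    control_traces <- list(control_traces)
  if (!length(control_traces)) stop("control group must be non-empty")
  ctrl <- do.call(rbind, lapply(control_traces, `[[`, "values"))
  cm <- aggregate(cbind(q_high, q_low, value_decision) ~
                    trial_type + within_type_index, ctrl, mean,
                  na.action = stats::na.pass, na.rm = TRUE)
  out <- lapply(patient_traces, function(tr) {
    v <- tr$values
    i <- match(paste(v$trial_type, v$within_type_index),
               paste(cm$trial_type, cm$within_type_index))
    if (anyNA(i)) stop("control traces do not cover all trials")
    v$q_high <- v$q_high - cm$q_high[i]
    v$q_low <- v$q_low - cm$q_low[i]
    v$value_decision <- v$value_decision - cm$value_decision[i]
    tr$values <- v
    tr$detrended <- TRUE
    tr
  })
  if (single) out[[1]] else out
}

#' Section means of value and prediction-error traces
#'
#' Means per subject over the full task and the task sections (within-type
#' trials 1-20, 21-40, 41-60 by default): four value means (reward/loss x
#' high/low option) and four prediction-error means (positive/negative x
#' reward/loss).  Empty cells (e.g. no negative prediction errors within a
#' section) propagate as `NA`, never zero.
#'
#' @param traces an `rlddm_traces` object.
#' @param sections named list of within-type index ranges.
#' @return data frame: `subject_id`, `section`, `measure`, `mean`.
#' @export
section_means <- function(traces,
                          sections = list(full = 1:60, s1 = 1:20,
                                          s2 = 21:40, s3 = 41:60)) {
  stopifnot(inherits(traces, "rlddm_traces"))
  v <- traces$values; p <- traces$pe
  sid <- v$subject_id[1]
  rows <- list()
  for (sec in names(sections)) {
    rng <- sections[[sec]]
    for (ty in c("reward", "loss")) {
      vv <- v[v$trial_type == ty & v$within_type_index %in% rng, ]
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sid, section = sec,
        measure = paste("value", ty, c("high", "low"), sep = "_"),
        mean = c(mean_or_na(vv$q_high), mean_or_na(vv$q_low)))
      pp <- p[p$trial_type == ty & p$within_type_index %in% rng, ]
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sid, section = sec,
        measure = paste("pe", ty, c("positive", "negative"), sep = "_"),
        mean = c(mean_or_na(pp$pe[pp$sign == "positive"]),
                 mean_or_na(pp$pe[pp$sign == "negative"])))
    }
  }
  do.call(rbind, rows)
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else mean(x)
}

#' Export parametric-modulator event tables
#'
#' Builds per-subject event tables in the conventional neuroimaging events
#' layout (`onset_s`, `duration_s`, `event_type`, `modulator`): decision-time
#' events carry the value signal of that trial and outcome-time events the
#' prediction error, both raw (uncentred).  Onsets are reconstructed from
#' the session timeline: each trial presents its stimuli, the response
#' arrives after `rt` (the full response window for omissions), the jittered
#' inter-stimulus interval from the schedule separates response and
#' feedback, and a fixed feedback (1 s) plus inter-trial (1.5 s) period
#' precedes the next trial.
#'
#' @param session a behavioural session.
#' @param traces the subject's `rlddm_traces`.
#' @param schedule the [build_schedule()] object (provides the ISI record).
#' @param dir if non-`NULL`, write one tab-separated file per signal
#'   (`<subject>_value_events.tsv`, `<subject>_pe_events.tsv`) into `dir`.
#' @param rt_max response window (s), used as the duration of omissions.
#' @return invisibly, a list with the `value` and `pe` event data frames
#'   (and `paths` when written).
#' @export
export_modulators <- function(session, traces, schedule, dir = NULL,
                              rt_max = 3) {
  stopifnot(inherits(traces, "rlddm_traces"))
  n <- nrow(session)
  rt_eff <- ifelse(is.na(session$rt), rt_max, session$rt)
  feedback_dur <- 1; iti <- 1.5
  onset_decision <- cumsum(c(0, (rt_eff + schedule$isi_s + feedback_dur +
                                   iti)[-n]))
  onset_outcome <- onset_decision + rt_eff + schedule$isi_s
  ok <- session$choice != "omitted"
  v <- traces$values
  value_events <- data.frame(
    onset_s = onset_decision[ok], duration_s = session$rt[ok],
    event_type = paste0("decision_", session$trial_type[ok]),
    modulator = v$value_decision[ok])
  pe_i <- match(traces$pe$trial, session$trial)
  pe_events <- data.frame(
    onset_s = onset_outcome[pe_i], duration_s = feedback_dur,
    event_type = paste0("outcome_", traces$pe$trial_type),
    modulator = traces$pe$pe)
  out <- list(value = value_events, pe = pe_events)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sid <- as.character(session$subject_id[1])
    paths <- c(value = file.path(dir, paste0(sid, "_value_events.tsv")),
               pe = file.path(dir, paste0(sid, "_pe_events.tsv")))
    write.table(value_events, paths["value"], sep = "\t", row.names = FALSE,
                quote = FALSE)
    write.table(pe_events, paths["pe"], sep = "\t", row.names = FALSE,
                quote = FALSE)
    out$paths <- paths
  }
  invisible(out)
}
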