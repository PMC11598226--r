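# Time-variant posture evaluation: a debounced state machine over the
# per-frame label stream. The current confirmed pose persists until a
# different label has been seen for count_step1 consecutive samples; on
# confirmation the old segment is closed and a transition event records
# the elapsed gap (TD). UNKNOWN frames extend the gap between segments and
# never count toward a candidate.
#
# Counters tick per sample (1/6 s by default), not per hardware clock;
# clock_ticks() converts a duration to 100 MHz clock ticks for display
# parity with the accelerator's 8-bit counters (which saturate at 255 —
# not reproduced here, counters are unbounded).

#' Evaluator state for streaming posture timing
#'
#' @param count_step1 Debounce threshold: consecutive samples a new label
#'   must persist before a posture change is confirmed. Default 3 samples
#'   (0.5 s at the 1/6 s period), matching the 3-deep learning FIFO. With
#'   `count_step1 = 1` the evaluator degenerates to edge detection.
#' @param sample_period Sampling period in seconds; a frame at time `t`
#'   covers `[t, t + sample_period)`, so a closed segment ends one period
#'   after its last frame.
#' @return An `eval_state`.
#' @export
eval_state <- function(count_step1 = 3L, sample_period = 1 / 6) {
  if (!is_count(count_step1) || count_step1 < 1)
    somno_stop("count_step1 must be an integer >= 1", "somno_config_error")
  if (!is_number(sample_period) || sample_period <= 0)
    somno_stop("sample_period must be > 0", "somno_config_error")
  structure(
    list(
      pose_current = "UNKNOWN",   # P_C: confirmed pose
      pose_past = "UNKNOWN",      # P_p: previously confirmed pose
      count_1 = 0L,               # dwell samples of the confirmed pose
      count = 0L,                 # consecutive samples of the pending candidate
      count_step1 = as.integer(count_step1),
      sample_period = sample_period,
      seg_start = NA_real_,
      seg_end = NA_real_,         # end of the covered span so far
      pending_label = NA_character_,
      pending_start = NA_real_,
      last_t = -Inf
    ),
    class = "eval_state"
  )
}

empty_events <- function() {
  data.frame(kind = character(0), label = character(0),
             from = character(0), to = character(0),
             start = numeric(0), end = numeric(0), duration = numeric(0),
             stringsAsFactors = FALSE)
}

segment_event <- function(label, start, end) {
  data.frame(kind = "SEGMENT", label = label, from = NA_character_,
             to = NA_character_, start = start, end = end,
             duration = end - start, stringsAsFactors = FALSE)
}

transition_event <- function(from, to, start, end) {
  data.frame(kind = "TRANSITION", label = NA_character_, from = from,
             to = to, start = start, end = end, duration = end - start,
             stringsAsFactors = FALSE)
}

#' Advance the evaluator by one labelled frame
#'
#' Feeds the label of the frame at time `t` (strictly increasing). A label
#' equal to the confirmed pose extends its segment and dwell counter. A
#' different posture label becomes (or extends) the pending candidate;
#' once it has persisted `count_step1` consecutive samples it is
#' confirmed: the old segment is emitted, plus a TRANSITION whose duration
#' (TD) spans the gap from the old segment's end to the new segment's
#' start. `UNKNOWN` labels reset the candidate and extend the gap only.
#'
#' @param state An [eval_state()].
#' @param label Posture label for this frame (`"UNKNOWN"` allowed).
#' @param t Frame timestamp in seconds.
#' @return List with the updated `state` and an `events` data frame
#'   (zero or more rows: kind, label, from, to, start, end, duration).
#' @export
eval_step <- function(state, label, t) {
  if (!inherits(state, "eval_state"))
    somno_stop("not an eval_state", "somno_config_error")
  if (!is.character(label) || length(label) != 1L || is.na(label))
    somno_stop("label must be a single posture string", "somno_data_error")
  label <- as.character(label)  # drop any names so comparisons are on value
  if (!is_number(t) || t <= state$last_t)
    somno_stop(sprintf("timestamps must be strictly increasing (got %s after %s)",
                       format(t), format(state$last_t)), "somno_data_error")
  state$last_t <- t
  events <- empty_events()
  period <- state$sample_period

  if (identical(label, state$pose_current) && state$pose_current != "UNKNOWN") {
    # same posture: dwell counter ticks, segment span extends
    state$count_1 <- state$count_1 + 1L
    state$seg_end <- t + period
    state$count <- 0L
    state$pending_label <- NA_character_
    return(list(state = state, events = events))
  }

  if (identical(label, "UNKNOWN")) {
    # gap frame: no candidate survives a gap
    state$count <- 0L
    state$pending_label <- NA_character_
    return(list(state = state, events = events))
  }

  # a (new or continuing) candidate posture
  if (identical(label, state$pending_label)) {
    state$count <- state$count + 1L
  } else {
    state$pending_label <- label
    state$pending_start <- t
    state$count <- 1L
  }

  if (state$count >= state$count_step1) {
    # confirmed: close the old segment, record the transition over the gap
    if (state$pose_current != "UNKNOWN") {
      events <- rbind(
        segment_event(state$pose_current, state$seg_start, state$seg_end),
        # clamp: a zero gap can round a hair below seg_end on the time grid
        transition_event(state$pose_current, label,
                         state$seg_end, max(state$pending_start, state$seg_end))
      )
    }
    state$pose_past <- state$pose_current
    state$pose_current <- label
    state$seg_start <- state$pending_start
    state$seg_end <- t + period
    state$count_1 <- state$count
    state$count <- 0L
    state$pending_label <- NA_character_
  }
  list(state = state, events = events)
}

#' Signed difference of two pose timestamps
#'
#' The accelerator computes posture period differences with a two's
#' complement adder; in software this is plain signed subtraction.
#'
#' @param t_a,t_b Times in seconds.
#' @return `t_a - t_b`.
#' @export
pose_period_difference <- function(t_a, t_b) {
  t_a - t_b
}

#' Close the evaluator at end of stream
#'
#' Emits the still-open segment for the confirmed pose, closed at `t_end`
#' (default: one period past the last frame). An unconfirmed pending
#' candidate is dropped. A state with no confirmed pose yields no events.
#'
#' @param state An [eval_state()].
#' @param t_end End-of-stream time in seconds.
#' @return Events data frame.
#' @export
eval_finalize <- function(state, t_end = NULL) {
  if (!inherits(state, "eval_state"))
    somno_stop("not an eval_state", "somno_config_error")
  if (state$pose_current == "UNKNOWN") return(empty_events())
  if (is.null(t_end)) t_end <- state$seg_end
  segment_event(state$pose_current, state$seg_start, max(t_end, state$seg_start))
}

#' Evaluate a whole label sequence
#'
#' Convenience driver: runs [eval_step()] over uniformly sampled labels
#' and finalizes.
#'
#' @param labels Character vector of per-frame labels.
#' @param t Frame times; defaults to `(0, 1, 2, ...) * sample_period`.
#' @param count_step1,sample_period Passed to [eval_state()].
#' @return Events data frame in emission order.
#' @export
evaluate_labels <- function(labels, t = NULL, count_step1 = 3L,
                            sample_period = 1 / 6) {
  state <- eval_state(count_step1, sample_period)
  if (is.null(t)) t <- (seq_along(labels) - 1) * sample_period
  if (length(t) != length(labels))
    somno_stop("labels and t must have equal length", "somno_data_error")
  events <- empty_events()
  for (i in seq_along(labels)) {
    res <- eval_step(state, labels[i], t[i])
    state <- res$state
    if (nrow(res$events)) events <- rbind(events, res$events)
  }
  rbind(events, eval_finalize(state))
}

#' Duration in hardware clock ticks
#'
#' Display parity with the accelerator's counters: `ticks = duration *
#' clock_hz` at the 100 MHz device clock.
#'
#' @param duration_s Duration in seconds.
#' @param clock_hz Device clock frequency (default 1e8).
#' @export
clock_ticks <- function(duration_s, clock_hz = 100e6) {
  duration_s * clock_hz
}
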