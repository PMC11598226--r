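# End-to-end orchestration: stream -> fusion -> learn-or-classify dispatch
# -> adaptive evaluation -> event log. The hardware's concurrent
# processing elements become sequential per-frame stages; at 6 frames/s
# there is no throughput constraint to honour.

#' Run configuration for the monitoring pipeline
#'
#' @param mode One of `"simulate"` (generate a stream from a scenario and
#'   monitor it, reporting accuracy against the schedule), `"learn"`
#'   (stability-gated posture learning into a subject profile) or
#'   `"monitor"` (classification plus adaptive timing over an existing
#'   stream).
#' @param scenario A [scenario()] (required for `simulate`; optional
#'   ground truth otherwise).
#' @param stream A stream data frame (required for `learn`/`monitor`
#'   unless `scenario` is given, in which case it is generated).
#' @param subject_id Subject identifier (required for `learn`).
#' @param store A [profile_store()]; defaults to an empty store in learn
#'   mode. In monitor mode a `subject_id` without a stored profile is an
#'   error.
#' @param geometry A [geometry()].
#' @param table Truth-table override, a [posture_truth_table()].
#' @param count_step1 Debounce threshold in samples (default 3).
#' @param strict Strict full-pattern classification in monitor mode
#'   (default `FALSE`: early-exit, like the hardware).
#' @param seed RNG seed used when simulating.
#' @return A validated `run_config`.
#' @export
run_config <- function(mode = c("simulate", "learn", "monitor"),
                       scenario = NULL, stream = NULL, subject_id = NULL,
                       store = NULL, geometry = somnoposture::geometry(),
                       table = posture_truth_table(), count_step1 = 3L,
                       strict = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(scenario))
    somno_stop("simulate mode needs a scenario", "somno_config_error")
  if (mode %in% c("learn", "monitor") && is.null(stream) && is.null(scenario))
    somno_stop(sprintf("%s mode needs a stream or a scenario", mode),
               "somno_config_error")
  if (mode == "learn" && is.null(subject_id))
    somno_stop("learn mode needs a subject_id", "somno_config_error")
  if (!is_flag(strict))
    somno_stop("strict must be TRUE or FALSE", "somno_config_error")
  if (!is_count(count_step1) || count_step1 < 1)
    somno_stop("count_step1 must be an integer >= 1", "somno_config_error")
  if (!is.null(scenario) && !inherits(scenario, "somno_scenario"))
    somno_stop("scenario must be a somno_scenario", "somno_config_error")
  structure(
    list(mode = mode, scenario = scenario, stream = stream,
         subject_id = subject_id, store = store,
         geometry = as_geometry(geometry), table = table,
         count_step1 = as.integer(count_step1), strict = strict, seed = seed),
    class = "run_config"
  )
}

#' Run the full pipeline
#'
#' Per frame: the fusion word is formed; PIR = 0 frames idle (the wait
#' gate). In learn mode stable words are registered in the subject's
#' profile. In simulate/monitor mode each occupied word is classified
#' (profile patterns can resolve adaptive labels that the standard table
#' cannot) and streamed through the debounced evaluator, yielding posture
#' SEGMENT and TRANSITION events.
#'
#' @param config A [run_config()].
#' @return List with `events` (data frame), `summary` (list: frames,
#'   occupied frames, per-label segment counts and dwell, transition
#'   count, and — when a scenario supplies ground truth — segment label
#'   accuracy), `store` (learn mode) and the processed `stream`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    somno_stop("run_pipeline needs a run_config", "somno_config_error")
  geometry <- config$geometry
  scenario <- config$scenario
  stream <- config$stream
  if (is.null(stream)) {
    if (!is.null(config$seed)) {
      scenario$seed <- config$seed
    }
    stream <- generate_stream(scenario)
  }
  check_stream(stream)
  period <- if (!is.null(scenario)) scenario$sample_period
            else if (nrow(stream) > 1) stats::median(diff(stream$t)) else 1 / 6
  fused <- fuse_stream(stream, geometry)
  n_frames <- nrow(fused)
  n_occupied <- sum(fused$pir == 1L)

  if (config$mode == "learn") {
    store <- config$store %||% profile_store()
    res <- match_or_create_subject(store, config$subject_id)
    store <- res$store
    lr <- learn_words(fused, res$profile, config$table)
    store$subjects[[config$subject_id]] <- lr$profile
    summary <- list(frames = n_frames, occupied_frames = n_occupied,
                    stable_words = lr$n_stable,
                    learned_labels = names(lr$profile$learned),
                    adaptive_slots = names(lr$profile$adaptive))
    return(list(events = empty_events(), summary = summary, store = store,
                stream = stream))
  }

  # monitor / simulate: classify then evaluate
  profile <- NULL
  if (!is.null(config$subject_id)) {
    store <- config$store
    if (is.null(store) || !config$subject_id %in% names(store$subjects))
      somno_stop(sprintf("no stored profile for subject %s", config$subject_id),
                 "somno_data_error")
    profile <- store$subjects[[config$subject_id]]
  }
  tree <- build_tree(config$table)
  labels <- character(n_frames)
  for (i in seq_len(n_frames)) {
    w <- fusion_word(fused$word[i], pir = fused$pir[i], t = fused$t[i])
    lab <- classify(w, tree, strict = config$strict)
    if (lab == "UNKNOWN" && !is.null(profile)) {
      pats <- c(profile$learned, profile$adaptive)
      hit <- names(pats)[pats == fused$word[i]]
      if (length(hit)) lab <- hit[1]
    }
    labels[i] <- lab
  }
  events <- evaluate_labels(labels, t = fused$t,
                            count_step1 = config$count_step1,
                            sample_period = period)
  summary <- summarize_events(events, n_frames, n_occupied)
  if (!is.null(scenario)) {
    rec <- schedule_recovery(scenario, events)
    summary$segments_expected <- rec$expected
    summary$segments_recovered <- rec$recovered
    summary$segment_accuracy_pct <- if (rec$expected > 0)
      accuracy(rec$recovered, rec$expected) else NA_real_
  }
  list(events = events, summary = summary, store = config$store,
       stream = stream)
}

summarize_events <- function(events, n_frames, n_occupied) {
  segs <- events[events$kind == "SEGMENT", , drop = FALSE]
  dwell <- if (nrow(segs)) tapply(segs$duration, segs$label, sum) else numeric(0)
  list(
    frames = n_frames,
    occupied_frames = n_occupied,
    segment_count = nrow(segs),
    transition_count = sum(events$kind == "TRANSITION"),
    segment_counts = if (nrow(segs)) table(segs$label) else table(character(0)),
    dwell_s = dwell
  )
}

#' Compare emitted segments against a scenario's schedule
#'
#' Position-wise label match between the scenario's posture segments
#' (gaps, `OFF_BED` and `UNDEFINED` excluded) and the emitted SEGMENT
#' events, plus the largest absolute boundary error in seconds.
#'
#' @param scenario A [scenario()].
#' @param events Events from [run_pipeline()] / [evaluate_labels()].
#' @return List: `expected`, `recovered` (labels matching in order and
#'   position), `order_exact` (all labels match), and
#'   `max_boundary_error_s`.
#' @export
schedule_recovery <- function(scenario, events) {
  truth <- scenario$schedule
  truth <- truth[truth$label %in% STANDARD_POSTURES, , drop = FALSE]
  segs <- events[events$kind == "SEGMENT", , drop = FALSE]
  n <- nrow(truth)
  m <- nrow(segs)
  k <- min(n, m)
  matched <- if (k > 0) sum(truth$label[seq_len(k)] == segs$label[seq_len(k)]) else 0L
  berr <- 0
  if (k > 0) {
    berr <- max(abs(truth$start[seq_len(k)] - segs$start[seq_len(k)]),
                abs(truth$end[seq_len(k)] - segs$end[seq_len(k)]))
  }
  list(expected = n, recovered = as.integer(matched),
       order_exact = (n == m) && matched == n,
       max_boundary_error_s = berr)
}

check_stream <- function(stream) {
  if (!is.data.frame(stream))
    somno_stop("stream must be a data frame", "somno_data_error")
  miss <- setdiff(STREAM_COLS, names(stream))
  if (length(miss))
    somno_stop(sprintf("stream is missing columns: %s",
                       paste(miss, collapse = ", ")), "somno_data_error")
  if (nrow(stream) > 1 && any(diff(stream$t) <= 0))
    somno_stop(sprintf("stream timestamps must be strictly increasing (first violation at row %d)",
                       which(diff(stream$t) <= 0)[1] + 1L), "somno_data_error")
  bad <- which(!stats::complete.cases(stream[, STREAM_COLS]))
  if (length(bad))
    somno_stop(sprintf("malformed stream rows (missing values) at line(s): %s",
                       paste(utils::head(bad, 5), collapse = ", ")),
               "somno_data_error")
  invisible(stream)
}

#' Read / write sensor streams as CSV
#'
#' The stream dialect has header `t,pir,d_HR,d_HL,d_AR,d_AL,d_RL,d_LL`
#' with distances in metres. Numeric fields round-trip losslessly at
#' 15 significant digits. A header-only file reads as an empty stream;
#' missing columns or non-monotone timestamps are rejected with the
#' offending row reported.
#'
#' @param path CSV file path.
#' @return `read_stream` returns the stream data frame.
#' @export
read_stream <- function(path) {
  if (!file.exists(path))
    somno_stop(sprintf("stream file not found: %s", path), "somno_data_error")
  stream <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_stream(stream)
  stream
}

#' @rdname read_stream
#' @param stream Stream data frame to write.
#' @export
write_stream <- function(stream, path) {
  check_stream(stream)
  out <- stream[, STREAM_COLS, drop = FALSE]
  for (col in c("t", DIST_COLS))
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write posture events as JSON lines
#'
#' One JSON object per line (`kind`, `label` or `from`/`to`, `start`,
#' `end`, `duration`), plus an optional human-readable log mirroring the
#' accelerator's display: past posture, current posture, TD.
#'
#' @param events Events data frame.
#' @param path Output path for the JSONL.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    e <- as.list(events[i, ])
    e <- e[!vapply(e, function(x) is.na(x) && !is.numeric(x), logical(1))]
    writeLines(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_events
#' @return `format_event_log` returns one display line per event.
#' @export
format_event_log <- function(events) {
  vapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    if (e$kind == "SEGMENT")
      sprintf("POSTURE %s  start %.2f s  end %.2f s  dwell %.2f s",
              e$label, e$start, e$end, e$duration)
    else
      sprintf("PAST %s  CURRENT %s  TD %.2f s",
              e$from, e$to, e$duration)
  }, character(1))
}
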