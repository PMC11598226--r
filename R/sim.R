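# Synthetic sensor-scene simulator.
#
# Emulates six overhead ultrasonic channels watching a bed from above plus
# a PIR occupancy flag, sampled every 1/6 s. A scheduled posture sets which
# channels see a raised echo surface; Gaussian noise on the distances
# stands in for measurement error. The generator exists so that every
# downstream stage (fusion, classification, learning, timing) is testable
# without hardware.

SCHEDULE_LABELS <- c(STANDARD_POSTURES, "OFF_BED", "UNDEFINED")

#' Scenario: a posture schedule plus sampling and noise parameters
#'
#' @param schedule Data frame with columns `label`, `start`, `end`
#'   (seconds). Segments must be sorted, non-overlapping and of
#'   non-negative duration; labels are the eight standard postures,
#'   `OFF_BED` or `UNDEFINED`. Segment intervals are half-open
#'   `[start, end)` so adjacent segments never double-sample a boundary
#'   instant. Sampling instants not covered by any segment behave as
#'   `OFF_BED`.
#' @param sample_period Sampling period in seconds (default 1/6).
#' @param noise_sd Standard deviation of additive Gaussian distance noise,
#'   metres (default 0.02; use 0 for noise-free streams).
#' @param seed Integer RNG seed making the stream reproducible; `NULL`
#'   draws from the session RNG.
#' @param geometry A [geometry()].
#' @return A `somno_scenario` object.
#' @examples
#' sc <- scenario(data.frame(label = "LLP", start = 0, end = 10), noise_sd = 0)
#' nrow(generate_stream(sc))  # 60 frames at 1/6 s
#' @export
scenario <- function(schedule,
                     sample_period = 1 / 6,
                     noise_sd = 0.02,
                     seed = NULL,
                     geometry = somnoposture::geometry()) {
  schedule <- as.data.frame(schedule, stringsAsFactors = FALSE)
  need <- c("label", "start", "end")
  if (!all(need %in% names(schedule)))
    somno_stop("schedule needs columns label, start, end", "somno_config_error")
  schedule <- schedule[, need]
  if (nrow(schedule) > 0) {
    if (!all(schedule$label %in% SCHEDULE_LABELS))
      somno_stop(sprintf("unknown schedule label(s): %s",
                         paste(setdiff(schedule$label, SCHEDULE_LABELS), collapse = ", ")),
                 "somno_config_error")
    if (any(!is.finite(schedule$start)) || any(!is.finite(schedule$end)))
      somno_stop("schedule times must be finite", "somno_config_error")
    if (any(schedule$end < schedule$start))
      somno_stop("schedule segments must have non-negative duration", "somno_config_error")
    if (is.unsorted(schedule$start))
      somno_stop("schedule segments must be sorted by start", "somno_config_error")
    if (nrow(schedule) > 1 &&
        any(schedule$start[-1] < schedule$end[-nrow(schedule)]))
      somno_stop("schedule segments must not overlap", "somno_config_error")
  }
  if (!is_number(sample_period) || sample_period <= 0)
    somno_stop("sample_period must be > 0", "somno_config_error")
  if (!is_number(noise_sd) || noise_sd < 0)
    somno_stop("noise_sd must be >= 0", "somno_config_error")
  if (!is.null(seed) && !is_count(seed))
    somno_stop("seed must be a non-negative integer", "somno_config_error")
  structure(
    list(schedule = schedule, sample_period = sample_period,
         noise_sd = noise_sd, seed = seed, geometry = as_geometry(geometry)),
    class = "somno_scenario"
  )
}

#' @export
print.somno_scenario <- function(x, ...) {
  cat(sprintf("<somno_scenario> %d segment(s), period %.4g s, noise sd %.3g m, seed %s\n",
              nrow(x$schedule), x$sample_period, x$noise_sd,
              if (is.null(x$seed)) "none" else x$seed))
  if (nrow(x$schedule)) print.data.frame(x$schedule, row.names = FALSE)
  invisible(x)
}

#' Ideal channel distances for a posture
#'
#' Maps a posture label to the six noise-free echo distances. A channel
#' whose truth-table bit is 1 has a body part under it and reads
#' `sensor_height - body_elevation`; a 0 channel reads the bare bed at
#' `sensor_height`. Supine don't-care head bits are emitted as 1 (the head
#' is physically present; the classifier's don't-care mask is what ignores
#' it). `OFF_BED` reads the bare bed on all channels, and `UNDEFINED` (a
#' body mid-roll or between sensors) emits the all-zeros pattern, i.e. bed
#' height everywhere but with the PIR still asserted.
#'
#' @param label A standard posture, `"OFF_BED"` or `"UNDEFINED"`.
#' @param geometry A [geometry()].
#' @param table Truth table supplying the bit patterns.
#' @return Named numeric vector of six distances in metres, channel order.
#' @examples
#' posture_to_distances("LLP")  # 2.40 2.15 2.40 2.15 2.40 2.15
#' @export
posture_to_distances <- function(label, geometry = somnoposture::geometry(),
                                 table = posture_truth_table()) {
  geometry <- as_geometry(geometry)
  h <- geometry$sensor_height
  if (!is.character(label) || length(label) != 1L || !label %in% SCHEDULE_LABELS)
    somno_stop(sprintf("unknown posture label: %s", paste(label, collapse = ",")),
               "somno_config_error")
  if (label %in% c("OFF_BED", "UNDEFINED"))
    return(stats::setNames(rep(h, 6L), SENSOR_CHANNELS))
  pat <- table$pattern[table$label == label]
  if (length(pat) != 1L)
    somno_stop(sprintf("label %s has no truth-table row", label), "somno_config_error")
  bits <- strsplit(pat, "")[[1]]
  bits[bits == "X"] <- "1"  # don't-care positions: body part physically present
  d <- ifelse(bits == "1", h - geometry$body_elevation, h)
  stats::setNames(d, SENSOR_CHANNELS)
}

#' Round-trip echo time for a target distance
#'
#' Inverse of the time-of-flight range equation: an echo from a surface at
#' distance `d` returns after `2 d / speed` seconds. Composes with
#' [tof_to_distance()] to the identity.
#'
#' @param d Distance in metres (>= 0), vectorised.
#' @param speed Speed of sound in m/s (default 340).
#' @return Time of flight in seconds.
#' @export
echo_from_distance <- function(d, speed = 340) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0))
    somno_stop("distance must be finite and >= 0", "somno_data_error")
  if (!is_number(speed) || speed <= 0)
    somno_stop("speed must be > 0", "somno_config_error")
  2 * d / speed
}

# active schedule label at instant t (half-open segments); OFF_BED in gaps
label_at <- function(schedule, t) {
  if (nrow(schedule) == 0) return("OFF_BED")
  hit <- which(schedule$start <= t & t < schedule$end)
  if (length(hit) == 0) "OFF_BED" else schedule$label[hit[1]]
}

#' Generate a synthetic sensor stream from a scenario
#'
#' Samples the schedule at `t = start + k * sample_period` for
#' `k = 0, 1, ...` over the half-open span `[first start, last end)`, so a
#' duration `D` yields `floor(D / period)` frames. Each frame carries the
#' active posture's ideal distances plus i.i.d. Gaussian noise, and
#' `pir = 0` exactly during `OFF_BED` (including schedule gaps). With the
#' scenario's seed set, the stream is bit-identical across calls.
#'
#' @param scenario A [scenario()].
#' @return A data frame with columns `t, pir, d_HR, d_HL, d_AR, d_AL,
#'   d_RL, d_LL` (distances in metres); zero rows for an empty schedule.
#' @export
generate_stream <- function(scenario) {
  if (!inherits(scenario, "somno_scenario"))
    somno_stop("generate_stream needs a somno_scenario", "somno_config_error")
  sched <- scenario$schedule
  empty <- stats::setNames(
    as.data.frame(matrix(numeric(0), ncol = 8L)), STREAM_COLS)
  if (nrow(sched) == 0) return(empty)
  t0 <- sched$start[1]
  t1 <- sched$end[nrow(sched)]
  n <- floor((t1 - t0) / scenario$sample_period + 1e-9)
  if (n <= 0) return(empty)
  t <- t0 + (seq_len(n) - 1L) * scenario$sample_period
  labels <- vapply(t, function(ti) label_at(sched, ti), character(1))
  ideal <- t(vapply(labels, posture_to_distances, numeric(6),
                    geometry = scenario$geometry))
  noise <- with_seed(scenario$seed, {
    matrix(stats::rnorm(n * 6L, sd = scenario$noise_sd), nrow = n)
  })
  d <- ideal + noise
  d[d < 0] <- 0  # echoes cannot report negative range
  out <- data.frame(t = t, pir = as.integer(labels != "OFF_BED"), d)
  names(out) <- STREAM_COLS
  rownames(out) <- NULL
  out
}

#' Random multi-segment scenario over the standard postures
#'
#' Builds a contiguous schedule of `n_segments` back-to-back segments, each
#' a standard posture different from its neighbour, with durations drawn
#' uniformly from `duration_range`. Used for randomized schedule-recovery
#' checks.
#'
#' @param n_segments Number of posture segments.
#' @param seed RNG seed (also becomes the scenario's noise seed).
#' @param duration_range Length-2 numeric, segment duration bounds in
#'   seconds.
#' @param noise_sd,sample_period,geometry Passed to [scenario()].
#' @return A `somno_scenario`.
#' @export
random_scenario <- function(n_segments = 30, seed = NULL,
                            duration_range = c(5, 15),
                            noise_sd = 0.02, sample_period = 1 / 6,
                            geometry = somnoposture::geometry()) {
  if (!is_count(n_segments) || n_segments < 1)
    somno_stop("n_segments must be a positive integer", "somno_config_error")
  sched <- with_seed(seed, {
    labels <- character(n_segments)
    labels[1] <- sample(STANDARD_POSTURES, 1L)
    for (i in seq_len(n_segments)[-1])
      labels[i] <- sample(setdiff(STANDARD_POSTURES, labels[i - 1]), 1L)
    dur <- stats::runif(n_segments, duration_range[1], duration_range[2])
    # snap durations to whole sample periods so ground truth is unambiguous
    dur <- pmax(1, round(dur / sample_period)) * sample_period
    ends <- cumsum(dur)
    data.frame(label = labels, start = c(0, ends[-n_segments]), end = ends,
               stringsAsFactors = FALSE)
  })
  scenario(sched, sample_period = sample_period, noise_sd = noise_sd,
           seed = seed, geometry = geometry)
}

#' Read / write scenario files
#'
#' Scenario files are YAML (`.yml`/`.yaml`) or JSON with keys `schedule`
#' (list of `label`/`start`/`end`), `sample_period`, `noise_sd`, `seed`
#' and `geometry`.
#'
#' @param path File path; the extension selects the format.
#' @return `read_scenario` returns a `somno_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path))
    somno_stop(sprintf("scenario file not found: %s", path), "somno_config_error")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(raw$schedule))
    somno_stop("scenario file has no schedule", "somno_config_error")
  sched <- raw$schedule
  if (!is.data.frame(sched))
    sched <- do.call(rbind, lapply(sched, function(s)
      data.frame(label = s$label, start = s$start, end = s$end,
                 stringsAsFactors = FALSE)))
  args <- list(schedule = sched)
  for (k in c("sample_period", "noise_sd", "seed"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  if (!is.null(raw$geometry)) args$geometry <- as_geometry(raw$geometry)
  do.call(scenario, args)
}

#' @rdname read_scenario
#' @param scenario A `somno_scenario` to serialise.
#' @export
write_scenario <- function(scenario, path) {
  x <- list(
    schedule = lapply(seq_len(nrow(scenario$schedule)), function(i)
      as.list(scenario$schedule[i, ])),
    sample_period = scenario$sample_period,
    noise_sd = scenario$noise_sd,
    seed = scenario$seed,
    geometry = unclass(scenario$geometry)
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path, precision = 17)  # full double precision round-trip
  else
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}
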