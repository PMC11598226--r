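# Sensor fusion: time-of-flight to distance, range validation, and
# thresholding the six channels into a presence word gated by the PIR flag.

#' Convert echo time of flight to distance
#'
#' The range equation for a pulsed ultrasonic sensor: the pulse travels to
#' the target and back, so `distance = speed * tof / 2`.
#'
#' @param tof Round-trip time of flight in seconds (>= 0), vectorised.
#' @param speed Speed of sound in m/s (default 340).
#' @return Distance in metres.
#' @examples
#' tof_to_distance(0.01)  # 1.7 m
#' @export
tof_to_distance <- function(tof, speed = 340) {
  if (!is.numeric(tof) || any(!is.finite(tof)) || any(tof < 0))
    somno_stop("time of flight must be finite and >= 0", "somno_data_error")
  if (!is_number(speed) || speed <= 0)
    somno_stop("speed must be > 0", "somno_config_error")
  speed * tof / 2
}

#' Validate distances against the trusted echo range
#'
#' Readings outside the inclusive `[min, max]` window (default 0.3--2.7 m)
#' are noise-prone and are flagged rather than rejected: downstream they
#' count as "no body part present" so a streaming system tolerates
#' dropouts.
#'
#' @param d Numeric vector of distances in metres (finite).
#' @param geometry A [geometry()] supplying `valid_range`.
#' @return List with `d` (unchanged) and `valid` (logical vector).
#' @export
validate_range <- function(d, geometry = somnoposture::geometry()) {
  geometry <- as_geometry(geometry)
  if (!is.numeric(d) || any(!is.finite(d)))
    somno_stop("distances must be finite numbers", "somno_data_error")
  list(d = d, valid = d >= geometry$valid_range[1] & d <= geometry$valid_range[2])
}

#' Threshold one sensor frame into a fusion word
#'
#' A channel's presence bit is 1 iff its distance is inside the valid
#' range and at most `sensor_height - presence_margin`: the echo surface
#' is measurably closer than the bare bed. When the PIR flag is 0 the bed
#' is unoccupied, and the word is emitted all-zero with attribute
#' `occupied = FALSE`; its bits are meaningless and downstream stages
#' treat the frame as idle.
#'
#' @param frame A list or one-row data frame with `pir` and the six
#'   distance columns `d_HR, d_HL, d_AR, d_AL, d_RL, d_LL` (metres), plus
#'   optional `t`.
#' @param geometry A [geometry()].
#' @return A `fusion_word` with attribute `occupied`.
#' @examples
#' frame_to_word(list(t = 0, pir = 1,
#'   d_HR = 2.4, d_HL = 2.15, d_AR = 2.4, d_AL = 2.15, d_RL = 2.4, d_LL = 2.15))
#' @export
frame_to_word <- function(frame, geometry = somnoposture::geometry()) {
  geometry <- as_geometry(geometry)
  frame <- as.list(frame)
  if (!all(DIST_COLS %in% names(frame)))
    somno_stop(sprintf("frame must carry the six distance fields %s",
                       paste(DIST_COLS, collapse = ", ")), "somno_data_error")
  d <- unlist(frame[DIST_COLS], use.names = FALSE)
  if (length(d) != 6L)
    somno_stop("frame must have exactly six distances", "somno_data_error")
  pir <- frame$pir
  if (is.null(pir) || !pir %in% c(0, 1))
    somno_stop("frame must carry a 0/1 pir flag", "somno_data_error")
  t <- if (is.null(frame$t)) NA_real_ else frame$t
  if (pir == 0) {
    w <- fusion_word(rep(0L, 6L), pir = 0L, t = t)
    attr(w, "occupied") <- FALSE
    return(w)
  }
  vr <- validate_range(d, geometry)
  bits <- as.integer(vr$valid & d <= geometry$sensor_height - geometry$presence_margin)
  w <- fusion_word(bits, pir = 1L, t = t)
  attr(w, "occupied") <- TRUE
  w
}

#' Fuse a whole sensor stream into words
#'
#' Applies [frame_to_word()] to every row of a stream table.
#'
#' @param stream Data frame in the stream dialect
#'   (`t, pir, d_HR, ..., d_LL`).
#' @param geometry A [geometry()].
#' @return Data frame with columns `t`, `pir`, `word` (6-character bit
#'   string, H_R first).
#' @export
fuse_stream <- function(stream, geometry = somnoposture::geometry()) {
  geometry <- as_geometry(geometry)
  if (!all(STREAM_COLS %in% names(stream)))
    somno_stop(sprintf("stream is missing columns: %s",
                       paste(setdiff(STREAM_COLS, names(stream)), collapse = ", ")),
               "somno_data_error")
  n <- nrow(stream)
  words <- character(n)
  for (i in seq_len(n))
    words[i] <- word_string(frame_to_word(stream[i, ], geometry))
  data.frame(t = stream$t, pir = as.integer(stream$pir), word = words,
             stringsAsFactors = FALSE)
}
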