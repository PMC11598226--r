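#' Sensor-array geometry
#'
#' Describes the overhead mounting of the six ultrasonic sensors relative to
#' the bed plane. The defaults reproduce a ceiling array 2.4 m above the
#' bed with a usable echo range of 0.3--2.7 m and roughly 47 cm of bed
#' covered per sensor.
#'
#' A body part under a sensor raises the echo surface by `body_elevation`
#' metres, so an occupied channel reads `sensor_height - body_elevation`.
#' The fusion stage declares presence when the distance drops below
#' `sensor_height - presence_margin`; the margin therefore has to sit
#' strictly between the measurement noise scale and the body elevation.
#'
#' @param sensor_height Height of the sensor plane above the bed, metres.
#' @param body_elevation How much a body part raises the echo surface, metres.
#' @param presence_margin Presence threshold margin (delta), metres.
#' @param valid_range Length-2 numeric, inclusive `[min, max]` of trusted
#'   echo distances in metres; readings outside are flagged invalid.
#' @param per_sensor_coverage Bed length covered per sensor, metres
#'   (informational only).
#' @return An object of class `somno_geometry`.
#' @examples
#' g <- geometry()
#' g$sensor_height - g$body_elevation  # occupied-channel distance, 2.15 m
#' @export
geometry <- function(sensor_height = 2.4,
                     body_elevation = 0.25,
                     presence_margin = 0.15,
                     valid_range = c(0.3, 2.7),
                     per_sensor_coverage = 0.47) {
  for (v in list(sensor_height, body_elevation, presence_margin, per_sensor_coverage))
    if (!is_number(v) || v <= 0)
      somno_stop("geometry fields must be positive finite numbers", "somno_config_error")
  if (!is.numeric(valid_range) || length(valid_range) != 2L || any(!is.finite(valid_range)))
    somno_stop("valid_range must be two finite numbers", "somno_config_error")
  valid_range <- as.numeric(valid_range)
  if (valid_range[1] >= valid_range[2])
    somno_stop("valid_range must satisfy min < max", "somno_config_error")
  if (presence_margin >= body_elevation)
    somno_stop("presence_margin must be smaller than body_elevation", "somno_config_error")
  if (sensor_height <= valid_range[1] || sensor_height > valid_range[2])
    somno_stop("sensor_height must lie inside the valid echo range", "somno_config_error")
  structure(
    list(
      sensor_height = sensor_height,
      body_elevation = body_elevation,
      presence_margin = presence_margin,
      valid_range = valid_range,
      per_sensor_coverage = per_sensor_coverage
    ),
    class = "somno_geometry"
  )
}

#' @export
print.somno_geometry <- function(x, ...) {
  cat(sprintf(
    "<somno_geometry> height %.2f m, body elevation %.2f m, margin %.2f m, valid [%.2f, %.2f] m\n",
    x$sensor_height, x$body_elevation, x$presence_margin,
    x$valid_range[1], x$valid_range[2]
  ))
  invisible(x)
}

as_geometry <- function(x) {
  if (inherits(x, "somno_geometry")) return(x)
  if (is.null(x)) return(geometry())
  if (is.list(x)) return(do.call(geometry, x))
  somno_stop("cannot interpret geometry", "somno_config_error")
}
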