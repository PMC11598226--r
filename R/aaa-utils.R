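#' Fixed channel order of the sensor array
#'
#' Head-right, head-left, abdomen-right, abdomen-left, leg-right, leg-left.
#' Every 6-bit word and every distance vector in the package follows this
#' order.
#' @export
SENSOR_CHANNELS <- c("H_R", "H_L", "A_R", "A_L", "R_L", "L_L")

#' The eight standard posture labels
#'
#' Right/left yearner, left/right fetal, right/left lateral, supine, frog.
#' @export
STANDARD_POSTURES <- c("RY", "LY", "LF", "RF", "RLP", "LLP", "SP", "FP")

#' Adaptive posture slot names New_1 ... New_8
#' @export
ADAPTIVE_SLOTS <- paste0("New_", 1:8)

# stream CSV distance column names, aligned with SENSOR_CHANNELS
DIST_COLS <- c("d_HR", "d_HL", "d_AR", "d_AL", "d_RL", "d_LL")
STREAM_COLS <- c("t", "pir", DIST_COLS)

# classed errors so the CLI can map config vs data problems to exit codes
somno_stop <- function(msg, class = "somno_error", call. = FALSE) {
  stop(structure(
    class = c(class, "somno_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_count <- function(x) is_number(x) && x >= 0 && x == floor(x)

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream; a NULL seed leaves the RNG alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is_count(seed)) somno_stop("seed must be a non-negative integer", "somno_config_error")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
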