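# Accuracy / error-rate metrics and the pipelined-accelerator latency
# model.

#' Classification accuracy in percent
#'
#' `100 * n_correct / n_total`. Note that 29 of 30 correct predictions is
#' 96.67%, the arithmetic value — this function always reports the exact
#' quotient.
#'
#' @param n_correct Number of correct predictions (0..n_total).
#' @param n_total Total predictions (>= 1).
#' @return Accuracy in percent.
#' @examples
#' accuracy(29, 30)  # 96.6667
#' @export
accuracy <- function(n_correct, n_total) {
  if (!is_count(n_total) || n_total < 1)
    somno_stop("n_total must be an integer >= 1", "somno_data_error")
  if (!is_count(n_correct) || n_correct > n_total)
    somno_stop("n_correct must be an integer in 0..n_total", "somno_data_error")
  100 * n_correct / n_total
}

#' Error rate as the complement of accuracy
#'
#' Applied on the percent scale: `100 - accuracy`. The complement
#' invariant `accuracy + error_rate == 100` holds exactly.
#'
#' @param acc Accuracy in percent (0..100).
#' @return Error rate in percent.
#' @export
error_rate <- function(acc) {
  if (!is.numeric(acc) || any(!is.finite(acc)) || any(acc < 0) || any(acc > 100))
    somno_stop("accuracy must be in [0, 100] percent", "somno_data_error")
  100 - acc
}

#' Latency of a pipelined accelerator
#'
#' For a pipeline of `stages` stages at clock period `tclk_ns`, one
#' iteration takes `stages * tclk_ns` and `iterations` back-to-back
#' iterations take `(iterations + stages - 1) * tclk_ns` (the pipeline
#' fills once). The accelerator's figures — 8 stages at 10 ns, 30
#' iterations — give 80 ns per iteration and 370 ns total.
#'
#' @param stages Pipeline stages S (>= 1).
#' @param tclk_ns Clock period in nanoseconds (> 0).
#' @param iterations Iteration count N (>= 1).
#' @return List with `per_iteration_ns` and `total_ns`.
#' @examples
#' pipeline_latency(stages = 8, tclk_ns = 10, iterations = 30)
#' @export
pipeline_latency <- function(stages = 8L, tclk_ns = 10, iterations = 30L) {
  if (!is_count(stages) || stages < 1)
    somno_stop("stages must be an integer >= 1", "somno_config_error")
  if (!is_number(tclk_ns) || tclk_ns <= 0)
    somno_stop("tclk_ns must be > 0", "somno_config_error")
  if (!is_count(iterations) || iterations < 1)
    somno_stop("iterations must be an integer >= 1", "somno_config_error")
  list(
    per_iteration_ns = stages * tclk_ns,
    total_ns = (iterations + stages - 1) * tclk_ns
  )
}
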