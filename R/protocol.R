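#' Square current-step stimulation protocol
#'
#' Describes the family of square current injections delivered in one
#' current-clamp session: an ordered set of step amplitudes, the timing of the
#' step within each sweep, and the sampling rate. The default protocol is ten
#' steps from -300 pA to +600 pA in 100 pA increments, digitized at 10 kHz,
#' with a 200 ms pre-step baseline, a 500 ms step and a 200 ms tail.
#'
#' @param currents_pA ordered numeric vector of step amplitudes (pA),
#'   strictly increasing.
#' @param baseline_ms pre-step baseline duration (ms).
#' @param step_ms current step duration (ms).
#' @param post_ms post-step duration (ms).
#' @param sampling_rate_hz digitization rate (Hz).
#' @return An object of class `step_protocol`.
#' @examples
#' p <- step_protocol()
#' p$currents_pA
#' @export
step_protocol <- function(currents_pA = seq(-300, 600, by = 100),
                          baseline_ms = 200, step_ms = 500, post_ms = 200,
                          sampling_rate_hz = 10000) {
  if (length(currents_pA) < 1 || anyNA(currents_pA))
    stop("currents_pA must be a non-empty numeric vector without NA")
  if (length(currents_pA) > 1 && any(diff(currents_pA) <= 0))
    stop("currents_pA must be strictly increasing")
  if (!is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be positive")
  if (baseline_ms < 0 || post_ms < 0 || step_ms <= 0)
    stop("durations must be non-negative and step_ms positive")
  structure(
    list(currents_pA = as.numeric(currents_pA),
         baseline_ms = baseline_ms, step_ms = step_ms, post_ms = post_ms,
         sampling_rate_hz = sampling_rate_hz),
    class = "step_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat("Current-step protocol:", length(x$currents_pA), "sweeps,",
      min(x$currents_pA), "to", max(x$currents_pA), "pA\n")
  cat(sprintf("  baseline %g ms | step %g ms | post %g ms | %g kHz\n",
              x$baseline_ms, x$step_ms, x$post_ms, x$sampling_rate_hz / 1000))
  invisible(x)
}

# sample interval in ms
protocol_dt_ms <- function(protocol) 1000 / protocol$sampling_rate_hz

# sample counts for the three epochs and the whole sweep
protocol_samples <- function(protocol) {
  dt <- protocol_dt_ms(protocol)
  n_base <- round(protocol$baseline_ms / dt)
  n_step <- round(protocol$step_ms / dt)
  n_post <- round(protocol$post_ms / dt)
  list(n_base = n_base, n_step = n_step, n_post = n_post,
       n_total = n_base + n_step + n_post)
}

# [start, end] sample indices (1-based, inclusive) of the step epoch
protocol_step_window <- function(protocol) {
  ns <- protocol_samples(protocol)
  c(ns$n_base + 1L, ns$n_base + ns$n_step)
}
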