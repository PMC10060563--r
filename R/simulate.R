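#' Simulate one current-clamp recording from a model neuron
#'
#' Integrates a leaky integrate-and-fire neuron through every step of a
#' [step_protocol()] using the exact exponential update at the protocol
#' sampling interval (threshold crossings located in continuous time, so
#' inter-spike intervals follow the closed form exactly) and returns the
#' sweep family as a `recording`, the same container the feature extractors
#' consume. Spikes are rendered as a stereotyped 2 ms waveform
#' peaking at +30 mV so that waveform-based measures (amplitude, half-width,
#' threshold voltage) are defined on simulated data. Ground truth (true
#' passive parameters, analytic rheobase, integrator spike times) travels
#' with the recording.
#'
#' @param params a [neuron_params()] object.
#' @param protocol a [step_protocol()] object. The step must fit in the sweep.
#' @param seed optional integer seed for the measurement-noise draw.
#' @param cell_id,animal_id identifiers carried into downstream tables.
#' @return An object of class `recording`: a list with `sweeps` (matrix,
#'   one column per current step, voltage in mV), `protocol`, `cell_id`,
#'   `animal_id` and `ground_truth` (list: `params`, `rheobase_pA`, `tau_ms`,
#'   `spike_times_ms`, `spike_counts_step`).
#' @examples
#' rec <- simulate_neuron(neuron_params(), step_protocol())
#' dim(rec$sweeps)
#' @export
simulate_neuron <- function(params, protocol, seed = NULL,
                            cell_id = "cell", animal_id = "animal") {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "step_protocol"))
  ns <- protocol_samples(protocol)
  if (ns$n_step < 1 || ns$n_total < ns$n_step)
    stop("step does not fit in the sweep")
  if (!is.null(seed)) set.seed(seed)
  sim <- lif_integrate(protocol$currents_pA,
                       params$rm_mohm, params$cm_pf, params$el_mv,
                       params$vth_mv, params$vreset_mv, params$tref_ms,
                       params$noise_sd_mv,
                       ns$n_base, ns$n_step, ns$n_post,
                       protocol_dt_ms(protocol))
  win_ms <- c(protocol$baseline_ms, protocol$baseline_ms + protocol$step_ms)
  counts <- vapply(sim$spike_times_ms, function(st)
    sum(st > win_ms[1] & st <= win_ms[2]), integer(1))
  structure(
    list(sweeps = sim$sweeps, protocol = protocol,
         cell_id = cell_id, animal_id = animal_id,
         ground_truth = list(params = params,
                             rheobase_pA = lif_rheobase_pA(params),
                             tau_ms = lif_tau_ms(params),
                             spike_times_ms = sim$spike_times_ms,
                             spike_counts_step = counts)),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Current-clamp recording %s (animal %s): %d sweeps x %d samples\n",
              x$cell_id, x$animal_id, ncol(x$sweeps), nrow(x$sweeps)))
  print(x$protocol)
  invisible(x)
}
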