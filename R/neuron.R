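#' Leaky integrate-and-fire neuron parameters
#'
#' Parameter set for the leaky integrate-and-fire (LIF) model neuron used by
#' the cohort simulator. The passive parameters map one-to-one onto the
#' measured quantities downstream: `rm_mohm` is the true input resistance,
#' `rm_mohm * cm_pf / 1000` the true membrane time constant (ms), `el_mv` the
#' true resting potential, and `1000 * (vth_mv - el_mv) / rm_mohm` the
#' analytic rheobase (pA).
#'
#' @param rm_mohm membrane resistance (MOhm), > 0.
#' @param cm_pf membrane capacitance (pF), > 0.
#' @param el_mv resting (leak reversal) potential (mV).
#' @param vth_mv spike threshold voltage (mV), must exceed `vreset_mv`.
#' @param vreset_mv post-spike reset potential (mV).
#' @param tref_ms absolute refractory period (ms), >= 0. Values below the 2 ms
#'   pasted-spike waveform are honoured as 2 ms effective dead time.
#' @param noise_sd_mv per-sample Gaussian measurement noise added to the
#'   recorded voltage (mV), >= 0. The noise does not enter the dynamics, so
#'   ground-truth spike times are independent of the noise draw.
#' @return An object of class `neuron_params`.
#' @examples
#' np <- neuron_params(rm_mohm = 100)
#' lif_rheobase_pA(np)  # 200 pA
#' @export
neuron_params <- function(rm_mohm = 100, cm_pf = 100, el_mv = -70,
                          vth_mv = -50, vreset_mv = -65, tref_ms = 2,
                          noise_sd_mv = 0) {
  if (!is.finite(rm_mohm) || rm_mohm <= 0) stop("rm_mohm must be > 0")
  if (!is.finite(cm_pf) || cm_pf <= 0) stop("cm_pf must be > 0")
  if (!is.finite(vth_mv) || !is.finite(vreset_mv) || vreset_mv >= vth_mv)
    stop("vreset_mv must be below vth_mv")
  if (tref_ms < 0) stop("tref_ms must be >= 0")
  if (noise_sd_mv < 0) stop("noise_sd_mv must be >= 0")
  structure(
    list(rm_mohm = rm_mohm, cm_pf = cm_pf, el_mv = el_mv, vth_mv = vth_mv,
         vreset_mv = vreset_mv, tref_ms = tref_ms, noise_sd_mv = noise_sd_mv),
    class = "neuron_params")
}

#' Analytic LIF rheobase
#'
#' Minimum sustained current that drives the steady-state membrane voltage
#' `E_L + I * R_m` to threshold: `I = 1000 * (V_th - E_L) / R_m` in pA.
#'
#' @param params a [neuron_params()] object.
#' @return Rheobase in pA.
#' @export
lif_rheobase_pA <- function(params) {
  1000 * (params$vth_mv - params$el_mv) / params$rm_mohm
}

#' Analytic LIF membrane time constant
#'
#' @param params a [neuron_params()] object.
#' @return `R_m * C_m` in ms.
#' @export
lif_tau_ms <- function(params) params$rm_mohm * params$cm_pf / 1000
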