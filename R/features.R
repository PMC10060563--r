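#' Detect action potentials in a voltage sweep
#'
#' A spike is an upward crossing of `v_cross` (default -20 mV) at which the
#' immediately preceding dV/dt exceeds `dvdt_min` (default 20 V/s), with a
#' lockout of `lockout_ms` after each accepted event. Times are reported at
#' the sample where the dV/dt criterion is evaluated, in seconds from sweep
#' start. Input is assumed already low-pass filtered at acquisition; no
#' additional filtering is applied.
#'
#' @param sweep numeric voltage trace (mV).
#' @param protocol the [step_protocol()] the sweep was acquired under (sets
#'   the sample interval and the step window).
#' @param v_cross voltage crossing criterion (mV).
#' @param dvdt_min slope criterion (V/s, equivalently mV/ms).
#' @param lockout_ms dead time after an accepted spike (ms).
#' @return Numeric vector of spike times (s).
#' @export
detect_spikes <- function(sweep, protocol, v_cross = -20, dvdt_min = 20,
                          lockout_ms = 2) {
  if (length(sweep) == 0) stop("empty sweep")
  if (anyNA(sweep)) stop("sweep contains NA")
  dt_ms <- protocol_dt_ms(protocol)
  n <- length(sweep)
  if (n < 2) return(numeric(0))
  ge <- sweep >= v_cross
  cand <- which(ge[-1L] & !ge[-n]) + 1L           # upward crossings of v_cross
  cand <- cand[(sweep[cand] - sweep[cand - 1L]) / dt_ms > dvdt_min]
  if (length(cand) == 0) return(numeric(0))
  # report at the dV/dt-criterion sample (the one before the crossing)
  t_ms <- (cand - 2) * dt_ms
  keep <- logical(length(t_ms))
  last <- -Inf
  for (k in seq_along(t_ms)) {
    if (t_ms[k] - last >= lockout_ms) {
      keep[k] <- TRUE
      last <- t_ms[k]
    }
  }
  t_ms[keep] / 1000
}

#' Input-output (f-I) curve of a recording
#'
#' Counts spikes inside the current-step window of every sweep and converts
#' counts to firing rates (count / step duration). This is the input-output
#' relationship from which rheobase is estimated.
#'
#' @param rec a `recording`.
#' @param ... spike-criterion settings passed to [detect_spikes()].
#' @return An object of class `fi_curve`: a data.frame with columns
#'   `current_pA`, `n_spikes`, `rate_hz`.
#' @export
compute_fi_curve <- function(rec, ...) {
  stopifnot(inherits(rec, "recording"))
  step_s <- rec$protocol$step_ms / 1000
  win_s <- c(rec$protocol$baseline_ms,
             rec$protocol$baseline_ms + rec$protocol$step_ms) / 1000
  counts <- vapply(seq_len(ncol(rec$sweeps)), function(j) {
    st <- detect_spikes(rec$sweeps[, j], rec$protocol, ...)
    sum(st > win_s[1] & st <= win_s[2])
  }, integer(1))
  out <- data.frame(current_pA = rec$protocol$currents_pA,
                    n_spikes = counts,
                    rate_hz = counts / step_s)
  attr(out, "step_s") <- step_s
  class(out) <- c("fi_curve", "data.frame")
  out
}

#' Rheobase from the f-I curve via a monotone spline
#'
#' Estimates the minimum current eliciting a single action potential by
#' fitting a monotone shape-preserving cubic spline (Hyman-filtered Hermite
#' interpolant on an isotonic fit of the counts) to spike count versus
#' injected current over the non-negative currents, and locating the smallest
#' current at which the spline reaches a count of one by search on a 1 pA
#' grid. The estimate is constrained to the half-open interval
#' (largest zero-count current, smallest spiking current].
#'
#' @param fi an `fi_curve` from [compute_fi_curve()].
#' @param grid_pA root-search grid resolution (pA).
#' @return A list with `rheobase_pA` (NA when no sweep spikes), `flag`
#'   (`"ok"`, `"no_spikes"` or `"all_spiking"`), and `bracket_pA`.
#' @export
estimate_rheobase <- function(fi, grid_pA = 1) {
  stopifnot(inherits(fi, "fi_curve"))
  nn <- fi$current_pA >= 0
  cur <- fi$current_pA[nn]
  cnt <- fi$n_spikes[nn]
  if (length(cur) < 2)
    stop("need at least two non-negative current steps")
  if (all(cnt == 0))
    return(list(rheobase_pA = NA_real_, flag = "no_spikes",
                bracket_pA = c(NA_real_, NA_real_)))
  if (all(cnt > 0))
    return(list(rheobase_pA = min(cur), flag = "all_spiking",
                bracket_pA = c(NA_real_, min(cur))))
  iso <- isoreg(cur, cnt)$yf
  lo <- max(cur[iso < 1])            # largest current the spline leaves below 1
  hi <- min(cur[iso >= 1])
  f <- splinefun(cur, iso, method = "hyman")
  grid <- seq(min(cur), max(cur), by = grid_pA)
  idx <- which(f(grid) >= 1)[1]
  est <- grid[idx]
  est <- min(max(est, lo + grid_pA), hi)   # enforce (lo, hi]
  list(rheobase_pA = est, flag = "ok", bracket_pA = c(lo, hi))
}

#' Input resistance from the hyperpolarizing step
#'
#' Input resistance is the steady-state voltage deflection divided by the
#' injected current, R_in = dV/I, computed from the sweep at `current_pA`
#' (default -300 pA): dV is the mean voltage over the last `window_ms` of the
#' step minus the mean over the `window_ms` immediately preceding the step.
#' With dV in mV and I in pA, R_in(MOhm) = 1000 * dV/I.
#'
#' @param rec a `recording`.
#' @param current_pA amplitude of the hyperpolarizing sweep to use (pA).
#' @param window_ms averaging-window length (ms).
#' @return A list with `rin_mohm`, `delta_v_mv` and `flags` (character;
#'   `"spikes_in_rin_sweep"` if any spike fell inside the step window,
#'   `"implausible_rin"` when the deflection is zero).
#' @export
compute_input_resistance <- function(rec, current_pA = -300,
                                     window_ms = 100) {
  stopifnot(inherits(rec, "recording"))
  j <- which(abs(rec$protocol$currents_pA - current_pA) < 1e-9)
  if (length(j) != 1)
    stop(sprintf("protocol has no %g pA sweep", current_pA))
  ns <- protocol_samples(rec$protocol)
  nw <- round(window_ms / protocol_dt_ms(rec$protocol))
  nw <- min(nw, ns$n_base, ns$n_step)
  v <- rec$sweeps[, j]
  base_win <- (ns$n_base - nw + 1):ns$n_base
  step_end <- ns$n_base + ns$n_step
  step_win <- (step_end - nw + 1):step_end
  dv <- mean(v[step_win]) - mean(v[base_win])
  rin <- 1000 * dv / current_pA
  flags <- character(0)
  st <- detect_spikes(v, rec$protocol)
  win_s <- c(rec$protocol$baseline_ms,
             rec$protocol$baseline_ms + rec$protocol$step_ms) / 1000
  if (any(st > win_s[1] & st <= win_s[2]))
    flags <- c(flags, "spikes_in_rin_sweep")
  if (dv == 0) flags <- c(flags, "implausible_rin")
  list(rin_mohm = rin, delta_v_mv = dv, flags = flags)
}

#' Passive-membrane and action-potential waveform features
#'
#' Resting membrane potential (RMP) is the mean pre-step baseline voltage
#' across all sweeps. The membrane time constant is obtained from a
#' single-exponential fit ([stats::SSasymp]) to the first `tau_fit_ms` of the
#' -300 pA step onset. Action-potential features are averaged over the first
#' (up to) three spikes of the lowest suprathreshold sweep: threshold voltage
#' is the voltage where dV/dt first exceeds `dvdt_min` before the peak,
#' amplitude is peak minus threshold voltage, and half-width is the duration
#' at half amplitude (linear interpolation at the two crossings).
#'
#' @param rec a `recording`.
#' @param tau_current_pA sweep used for the exponential fit (pA).
#' @param tau_fit_ms fit-window length from step onset (ms).
#' @param dvdt_min slope criterion shared with spike detection (V/s).
#' @return A list with `rmp_mv`, `tau_ms`, `ap_amp_mv`, `ap_halfwidth_ms`,
#'   `ap_thr_mv` and `flags`. AP fields are NA when no sweep spikes.
#' @export
compute_passive_and_ap_features <- function(rec, tau_current_pA = -300,
                                            tau_fit_ms = 200,
                                            dvdt_min = 20) {
  stopifnot(inherits(rec, "recording"))
  ns <- protocol_samples(rec$protocol)
  dt_ms <- protocol_dt_ms(rec$protocol)
  flags <- character(0)

  rmp <- mean(rec$sweeps[seq_len(ns$n_base), , drop = FALSE])

  tau <- NA_real_
  j <- which(abs(rec$protocol$currents_pA - tau_current_pA) < 1e-9)
  if (length(j) == 1) {
    nfit <- min(round(tau_fit_ms / dt_ms), ns$n_step)
    idx <- ns$n_base + seq_len(nfit)
    df <- data.frame(t_ms = (seq_len(nfit) - 1) * dt_ms,
                     v = rec$sweeps[idx, j])
    fit <- tryCatch(nls(v ~ SSasymp(t_ms, Asym, R0, lrc), data = df),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      tau <- exp(-coef(fit)[["lrc"]])
    } else {
      # nls declines on (near-)noiseless exponentials; fall back to the
      # log-linear fit with the asymptote taken from the step steady state
      step_end <- ns$n_base + ns$n_step
      vinf <- mean(rec$sweeps[(step_end - min(1000, ns$n_step) + 1):step_end, j])
      y <- (df$v - vinf) * sign(df$v[1] - vinf)
      keep <- y > max(y) * 0.02
      if (sum(keep) >= 5) {
        sl <- coef(lm(log(y[keep]) ~ df$t_ms[keep]))[[2]]
        if (is.finite(sl) && sl < 0) tau <- -1 / sl
      }
      if (!is.finite(tau)) flags <- c(flags, "tau_fit_failed")
    }
  } else flags <- c(flags, "tau_sweep_missing")

  amp <- hw <- thr <- NA_real_
  counts <- vapply(seq_len(ncol(rec$sweeps)), function(j) {
    st <- detect_spikes(rec$sweeps[, j], rec$protocol, dvdt_min = dvdt_min)
    length(st)
  }, integer(1))
  if (any(counts > 0)) {
    j <- which(counts > 0)[1]
    v <- rec$sweeps[, j]
    st_s <- detect_spikes(v, rec$protocol, dvdt_min = dvdt_min)
    st_idx <- round(st_s * 1000 / dt_ms) + 1L
    st_idx <- head(st_idx, 3)
    per <- vapply(st_idx, function(i0) {
      i1 <- min(i0 + round(2.5 / dt_ms), length(v))
      pk <- i0 - 1L + which.max(v[i0:i1])
      back <- max(i0 - round(1 / dt_ms), 2L)
      seg <- back:pk
      dv <- diff(v)[seg - 1L] / dt_ms          # slope into each sample
      ti <- seg[which(dv > dvdt_min)[1]]
      if (is.na(ti)) return(c(NA_real_, NA_real_, NA_real_))
      thr_v <- v[ti - 1L]
      a <- v[pk] - thr_v
      half <- thr_v + a / 2
      up <- ti - 1L + which(v[ti:pk] >= half)[1]
      dn_rel <- which(v[pk:min(pk + round(5 / dt_ms), length(v))] < half)[1]
      if (is.na(up) || is.na(dn_rel)) return(c(a, NA_real_, thr_v))
      dn <- pk + dn_rel - 1L
      # linear interpolation at the half-amplitude crossings
      f_up <- (half - v[up - 1L]) / (v[up] - v[up - 1L])
      f_dn <- (v[dn - 1L] - half) / (v[dn - 1L] - v[dn])
      w <- ((dn - 1L + f_dn) - (up - 1L + f_up)) * dt_ms
      c(a, w, thr_v)
    }, numeric(3))
    amp <- mean(per[1, ], na.rm = TRUE)
    hw <- mean(per[2, ], na.rm = TRUE)
    thr <- mean(per[3, ], na.rm = TRUE)
  } else flags <- c(flags, "no_spikes_for_ap")

  list(rmp_mv = rmp, tau_ms = tau, ap_amp_mv = amp, ap_halfwidth_ms = hw,
       ap_thr_mv = thr, flags = flags)
}

#' Extract all excitability features from one recording
#'
#' Runs spike detection, the f-I curve, spline rheobase, input resistance and
#' (optionally) the passive/AP measures, and assembles a `cell_features`
#' object with quality-control flags. A cell passes QC when both rheobase and
#' input resistance are defined; QC failures are excluded from the composite
#' scores downstream.
#'
#' @param rec a `recording`.
#' @param ap_features compute passive-membrane and AP waveform measures
#'   (disable for large simulation sweeps where only the excitability
#'   composite is needed).
#' @param ... spike-criterion settings passed to [detect_spikes()].
#' @return An object of class `cell_features`.
#' @export
extract_cell_features <- function(rec, ap_features = TRUE, ...) {
  if (!inherits(rec, "recording"))
    stop("not a recording object")
  if (ncol(rec$sweeps) != length(rec$protocol$currents_pA))
    stop(sprintf("recording %s: %d sweeps but %d protocol currents",
                 rec$cell_id, ncol(rec$sweeps),
                 length(rec$protocol$currents_pA)))
  fi <- compute_fi_curve(rec, ...)
  rb <- estimate_rheobase(fi)
  rin <- compute_input_resistance(rec)
  flags <- c(if (rb$flag != "ok") paste0("rheobase_", rb$flag), rin$flags)
  pa <- if (ap_features) compute_passive_and_ap_features(rec)
        else list(rmp_mv = NA_real_, tau_ms = NA_real_, ap_amp_mv = NA_real_,
                  ap_halfwidth_ms = NA_real_, ap_thr_mv = NA_real_,
                  flags = character(0))
  flags <- c(flags, pa$flags)
  i200 <- which(abs(fi$current_pA - 200) < 1e-9)
  qc_pass <- is.finite(rb$rheobase_pA) && is.finite(rin$rin_mohm) &&
    !("implausible_rin" %in% flags)
  structure(
    list(cell_id = rec$cell_id, animal_id = rec$animal_id,
         rheobase_pA = rb$rheobase_pA, rin_mohm = rin$rin_mohm,
         delta_v_mv = rin$delta_v_mv, rmp_mv = pa$rmp_mv, tau_ms = pa$tau_ms,
         ap_amp_mv = pa$ap_amp_mv, ap_halfwidth_ms = pa$ap_halfwidth_ms,
         ap_thr_mv = pa$ap_thr_mv, fi = fi,
         n_spikes_at_200pA = if (length(i200)) fi$n_spikes[i200] else NA_integer_,
         qc_flags = flags, qc_pass = qc_pass),
    class = "cell_features")
}

#' @export
print.cell_features <- function(x, ...) {
  cat(sprintf("Cell %s (animal %s): rheobase %.0f pA, Rin %.1f MOhm, RMP %.1f mV\n",
              x$cell_id, x$animal_id, x$rheobase_pA, x$rin_mohm, x$rmp_mv))
  if (length(x$qc_flags)) cat("  flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate per-cell features
#'
#' @param features a list of `cell_features` objects.
#' @return A data.frame with one row per cell (the per-cell features CSV
#'   schema: identifiers, rheobase, Rin, passive and AP measures, spike count
#'   at +200 pA, QC outcome).
#' @export
features_table <- function(features) {
  rows <- lapply(features, function(f) {
    stopifnot(inherits(f, "cell_features"))
    data.frame(cell_id = f$cell_id, animal_id = f$animal_id,
               rheobase_pA = f$rheobase_pA, rin_MOhm = f$rin_mohm,
               delta_v_mV = f$delta_v_mv, rmp_mV = f$rmp_mv,
               tau_ms = f$tau_ms, ap_amp_mV = f$ap_amp_mv,
               ap_halfwidth_ms = f$ap_halfwidth_ms,
               ap_thr_mV = f$ap_thr_mv,
               n_spikes_at_200pA = f$n_spikes_at_200pA,
               qc_pass = f$qc_pass,
               qc_flags = paste(f$qc_flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
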