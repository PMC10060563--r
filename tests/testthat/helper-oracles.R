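# Independent oracles used across the suite. These re-derive expected values
# from first principles (closed forms, per-sample brute force, textbook
# formulas) and never call the code paths they check.

# Closed-form LIF spike count inside a step of `step_ms` at current I (pA).
# First spike at t1 = tau*ln(IR/(IR - (Vth - EL))) from rest; subsequent
# inter-spike interval = dead + tau*ln((EL + IR - Vreset)/(EL + IR - Vth)),
# dead = max(tref, 2 ms) because the pasted waveform occupies 2 ms.
oracle_isi_count <- function(params, i_pa, step_ms) {
  ir <- i_pa * params$rm_mohm * 1e-3          # steady-state drive in mV
  gap <- params$vth_mv - params$el_mv
  if (ir <= gap) return(0L)
  tau <- params$rm_mohm * params$cm_pf / 1000
  t1 <- tau * log(ir / (ir - gap))
  dead <- max(params$tref_ms, 2)
  isi <- dead + tau * log((params$el_mv + ir - params$vreset_mv) /
                            (params$el_mv + ir - params$vth_mv))
  if (t1 > step_ms) return(0L)
  as.integer(floor((step_ms - t1) / isi) + 1)
}

# Literal per-sample implementation of the spike criterion: upward crossing
# of v_cross whose preceding-sample slope exceeds dvdt_min, 2 ms lockout,
# time reported at the slope-criterion sample. O(n) scan, no vectorization.
oracle_brute_spikes <- function(v, dt_ms, v_cross = -20, dvdt_min = 20,
                                lockout_ms = 2) {
  times <- numeric(0)
  last <- -Inf
  for (i in 2:length(v)) {
    if (v[i] >= v_cross && v[i - 1] < v_cross) {
      slope <- (v[i] - v[i - 1]) / dt_ms
      t_ms <- (i - 2) * dt_ms
      if (slope > dvdt_min && t_ms - last >= lockout_ms) {
        times <- c(times, t_ms)
        last <- t_ms
      }
    }
  }
  times / 1000
}

# Textbook Pearson correlation, slope and intercept.
oracle_pearson <- function(x, y) {
  sx <- x - mean(x); sy <- y - mean(y)
  r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  slope <- sum(sx * sy) / sum(sx^2)
  list(r = r, slope = slope, intercept = mean(y) - slope * mean(x))
}

# Hand-built voltage trace with the stereotyped spike waveform pasted at
# given times (ms): linear rise vth -> +30 mV over 0.5 ms then linear decay
# to vreset over 1.5 ms, on a flat baseline.
make_pasted_trace <- function(spike_ms, n = 10000, dt_ms = 0.1,
                              baseline = -70, vth = -50, vreset = -65) {
  v <- rep(baseline, n)
  n_wave <- round(2 / dt_ms); n_rise <- round(0.5 / dt_ms)
  wave <- c(vth + (30 - vth) * (0:n_rise) / n_rise,
            30 + (vreset - 30) * (1:(n_wave - n_rise - 1)) /
              (n_wave - n_rise))
  for (t in spike_ms) {
    k0 <- round(t / dt_ms) + 1
    idx <- k0:(k0 + length(wave) - 1)
    v[idx] <- wave
  }
  v
}

# Classical balanced two-way ANOVA sums of squares from cell means.
oracle_twoway_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  gm <- mean(y)
  ss_a <- sum(tapply(y, a, length) * (tapply(y, a, mean) - gm)^2)
  ss_b <- sum(tapply(y, b, length) * (tapply(y, b, mean) - gm)^2)
  cellm <- tapply(y, list(a, b), mean)
  celln <- tapply(y, list(a, b), length)
  am <- tapply(y, a, mean); bm <- tapply(y, b, mean)
  ss_ab <- 0
  for (i in seq_len(nlevels(a))) for (j in seq_len(nlevels(b)))
    ss_ab <- ss_ab + celln[i, j] *
      (cellm[i, j] - am[i] - bm[j] + gm)^2
  ss_err <- 0
  for (i in seq_len(nlevels(a))) for (j in seq_len(nlevels(b))) {
    yy <- y[a == levels(a)[i] & b == levels(b)[j]]
    ss_err <- ss_err + sum((yy - mean(yy))^2)
  }
  list(ss_a = unname(ss_a), ss_b = unname(ss_b), ss_ab = unname(ss_ab),
       ss_err = unname(ss_err))
}

# Split-plot (one between, one within factor) SS partition from scratch.
oracle_rm_ss <- function(y, g, w, s) {
  g <- factor(g); w <- factor(w); s <- factor(s)
  gm <- mean(y)
  n_w <- nlevels(w)
  subj_mean <- tapply(y, s, mean)
  subj_g <- tapply(as.character(g), s, function(x) x[1])
  ss_between_subj <- n_w * sum((subj_mean - gm)^2)
  g_mean <- tapply(y, g, mean)
  n_per_g <- tapply(y, g, length)
  ss_g <- sum(n_per_g * (g_mean[names(n_per_g)] - gm)^2)
  ss_subj_within_g <- ss_between_subj - ss_g
  w_mean <- tapply(y, w, mean)
  n_per_w <- tapply(y, w, length)
  ss_w <- sum(n_per_w * (w_mean - gm)^2)
  cellm <- tapply(y, list(g, w), mean)
  celln <- tapply(y, list(g, w), length)
  ss_gw <- 0
  for (i in seq_len(nlevels(g))) for (j in seq_len(n_w))
    ss_gw <- ss_gw + celln[i, j] *
      (cellm[i, j] - g_mean[i] - w_mean[j] + gm)^2
  ss_total <- sum((y - gm)^2)
  ss_resid <- ss_total - ss_g - ss_subj_within_g - ss_w - ss_gw
  list(ss_g = unname(ss_g), ss_subj = unname(ss_subj_within_g),
       ss_w = unname(ss_w), ss_gw = unname(ss_gw), ss_resid = unname(ss_resid),
       df_g = nlevels(g) - 1, df_subj = nlevels(s) - nlevels(g),
       df_w = n_w - 1, df_gw = (nlevels(g) - 1) * (n_w - 1),
       df_resid = (nlevels(s) - nlevels(g)) * (n_w - 1))
}

# Noise-free generator settings: all biological/measurement variability off,
# so every quantity is determined by the group means.
noiseless_config <- function(...) {
  cohort_config(depression_sd = 0, rm_animal_cv = 0, rm_cell_cv = 0,
                vth_animal_sd = 0, vth_cell_sd = 0, cm_cell_cv = 0,
                noise_sd_mv = 0, behavior_sd_s = 0, pwt_sd_g = 1e-3, ...)
}
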