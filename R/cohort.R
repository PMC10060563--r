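#' Synthetic cohort configuration
#'
#' Parameters for the synthetic cohort generator: a 2 x 2 design of surgery
#' (spared nerve injury, SNI, vs sham) by housing (standard housing, SH, vs
#' extended environmental enrichment, ExEE), a per-animal latent
#' depression-like score that couples behaviour and neuronal excitability,
#' and a full current-clamp recording session per cell.
#'
#' Each animal `a` in group `g` receives a latent depression score
#' `d_a = depression_mean[g] + N(0, depression_sd)`. Behaviour follows the
#' latent score (less grooming, more immobility when depressed); cell
#' parameters follow it through `coupling`: membrane resistance rises by
#' `coupling * rm_shift_frac * d_a` (fraction) and threshold voltage falls by
#' `coupling * vth_shift_mv * d_a` (mV), so depressed animals carry
#' hyperexcitable cells (higher R_in, lower rheobase). With `coupling = 0`
#' the excitability of a cell is unrelated to behaviour and the true
#' animal-level correlation is zero. The defaults put the SNI-SH group at
#' +30% R_m and -3 mV threshold relative to sham-SH, with SNI-ExEE almost at
#' sham level (the enrichment-rescue pattern), and give a model-implied
#' animal-level resilience-excitability correlation of about -0.8.
#'
#' @param n_animals_per_group animals per design cell (>= 2).
#' @param groups data.frame with columns `surgery` and `housing` defining the
#'   design cells.
#' @param cells_per_animal integer range (length 1 or 2) of recorded cells
#'   per animal.
#' @param depression_mean named numeric, latent group means, names
#'   `"surgery-housing"`.
#' @param depression_sd animal-level latent sd.
#' @param coupling latent depression-to-excitability coupling (0 = none).
#' @param rm_mohm,cm_pf,el_mv,vth_mv,vreset_mv,tref_ms baseline LIF
#'   parameters (see [neuron_params()]).
#' @param rm_shift_frac fractional R_m increase per unit latent score.
#' @param vth_shift_mv threshold decrease (mV) per unit latent score.
#' @param rm_animal_cv,rm_cell_cv animal- and cell-level R_m variability
#'   (coefficients of variation).
#' @param vth_animal_sd,vth_cell_sd animal- and cell-level threshold
#'   variability (mV).
#' @param cm_cell_cv cell-level capacitance variability.
#' @param noise_sd_mv recording measurement noise (mV per sample).
#' @param splash_mean_s,tst_mean_s,fst_mean_s behavioural group-centre
#'   scores (s) at zero latent depression.
#' @param splash_slope_s grooming-time decrease per unit latent score (s).
#' @param immobility_slope_s immobility increase per unit latent score (s).
#' @param behavior_sd_s behavioural residual sd (s).
#' @param splash_max_s,immobility_max_s test durations used as clamps (s).
#' @param pwt_contra_g,pwt_sham_ipsi_g contralateral / sham ipsilateral
#'   paw-withdrawal thresholds (g).
#' @param pwt_sni_sh_ipsi_g,pwt_sni_exee_ipsi_g post-injury plateau of the
#'   ipsilateral threshold in SNI-SH and SNI-ExEE animals (g).
#' @param pwt_sd_g measurement sd of a single von Frey reading (g).
#' @param pwt_timepoints_day von Frey session days relative to surgery.
#' @param protocol the [step_protocol()] delivered to every cell.
#' @param seed integer root seed; a config plus its seed fully determines
#'   the cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_animals_per_group = 4,
                          groups = data.frame(
                            surgery = c("sham", "sham", "SNI", "SNI"),
                            housing = c("SH", "ExEE", "SH", "ExEE")),
                          cells_per_animal = c(3, 8),
                          depression_mean = c("sham-SH" = 0, "sham-ExEE" = 0,
                                              "SNI-SH" = 1, "SNI-ExEE" = 0.2),
                          depression_sd = 0.3,
                          coupling = 1,
                          rm_mohm = 100, cm_pf = 100, el_mv = -70,
                          vth_mv = -50, vreset_mv = -65, tref_ms = 2,
                          rm_shift_frac = 0.30, vth_shift_mv = 3,
                          rm_animal_cv = 0.05, rm_cell_cv = 0.10,
                          vth_animal_sd = 0.5, vth_cell_sd = 1,
                          cm_cell_cv = 0.05,
                          noise_sd_mv = 0.3,
                          splash_mean_s = 120, tst_mean_s = 150,
                          fst_mean_s = 180,
                          splash_slope_s = 50, immobility_slope_s = 50,
                          behavior_sd_s = 25,
                          splash_max_s = 300, immobility_max_s = 360,
                          pwt_contra_g = 4.5, pwt_sham_ipsi_g = 4.5,
                          pwt_sni_sh_ipsi_g = 1.8, pwt_sni_exee_ipsi_g = 3.2,
                          pwt_sd_g = 0.3,
                          pwt_timepoints_day = c(-1, 7, 21, 42, 56),
                          protocol = step_protocol(),
                          seed = 1) {
  if (!is.numeric(n_animals_per_group) || n_animals_per_group < 2)
    stop("n_animals_per_group must be >= 2 (z-scores are undefined otherwise)")
  stopifnot(is.data.frame(groups),
            all(c("surgery", "housing") %in% names(groups)))
  if (length(cells_per_animal) == 1)
    cells_per_animal <- rep(cells_per_animal, 2)
  if (cells_per_animal[1] < 1 || cells_per_animal[2] < cells_per_animal[1])
    stop("cells_per_animal must be a positive range")
  glab <- paste(groups$surgery, groups$housing, sep = "-")
  if (!all(glab %in% names(depression_mean)))
    stop("depression_mean must name every group 'surgery-housing'")
  if (depression_sd < 0 || behavior_sd_s < 0 || pwt_sd_g < 0)
    stop("all sds must be >= 0")
  stopifnot(inherits(protocol, "step_protocol"))
  structure(
    list(n_animals_per_group = as.integer(n_animals_per_group),
         groups = groups, cells_per_animal = as.integer(cells_per_animal),
         depression_mean = depression_mean, depression_sd = depression_sd,
         coupling = coupling,
         rm_mohm = rm_mohm, cm_pf = cm_pf, el_mv = el_mv, vth_mv = vth_mv,
         vreset_mv = vreset_mv, tref_ms = tref_ms,
         rm_shift_frac = rm_shift_frac, vth_shift_mv = vth_shift_mv,
         rm_animal_cv = rm_animal_cv, rm_cell_cv = rm_cell_cv,
         vth_animal_sd = vth_animal_sd, vth_cell_sd = vth_cell_sd,
         cm_cell_cv = cm_cell_cv, noise_sd_mv = noise_sd_mv,
         splash_mean_s = splash_mean_s, tst_mean_s = tst_mean_s,
         fst_mean_s = fst_mean_s, splash_slope_s = splash_slope_s,
         immobility_slope_s = immobility_slope_s,
         behavior_sd_s = behavior_sd_s, splash_max_s = splash_max_s,
         immobility_max_s = immobility_max_s,
         pwt_contra_g = pwt_contra_g, pwt_sham_ipsi_g = pwt_sham_ipsi_g,
         pwt_sni_sh_ipsi_g = pwt_sni_sh_ipsi_g,
         pwt_sni_exee_ipsi_g = pwt_sni_exee_ipsi_g, pwt_sd_g = pwt_sd_g,
         pwt_timepoints_day = pwt_timepoints_day,
         protocol = protocol, seed = as.integer(seed)),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Cohort config: %d groups x %d animals, %d-%d cells/animal, coupling %g, seed %d\n",
              nrow(x$groups), x$n_animals_per_group,
              x$cells_per_animal[1], x$cells_per_animal[2],
              x$coupling, x$seed))
  invisible(x)
}

# fraction of the injury-induced PWT drop still expressed on a given day
pwt_injury_fraction <- function(day) ifelse(day <= 0, 0, 1 - exp(-day / 5))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a complete synthetic cohort
#'
#' Draws the per-animal latent depression scores, generates the behavioural
#' tables (splash grooming, tail-suspension and forced-swim immobility, von
#' Frey six-measure paw-withdrawal thresholds over the time course) and
#' simulates one full current-clamp session per cell with [simulate_neuron()].
#' Ground truth for every downstream quantity travels with the cohort.
#'
#' The root seed deterministically spawns independent sub-streams for
#' (1) animal latents and behaviour, (2) cell parameters and (3) per-cell
#' recording noise, so changing the number of recorded cells never reshuffles
#' the behavioural draws.
#'
#' @param config a [cohort_config()].
#' @param recordings simulate the voltage traces (set `FALSE` to get only
#'   behaviour plus ground truth, e.g. for behavioural-only analyses).
#' @return A list of class `cohort`:
#'   `behavior` (final-timepoint table, one row per animal, the behavioural
#'   CSV schema), `pwt_timecourse` (per-animal per-day six-measure paw
#'   means), `recordings` (list, animal_id -> list of `recording`), and
#'   `ground_truth` (per-animal latents, true cell parameters, true composite
#'   scores and the true animal-level correlation).
#' @export
simulate_cohort <- function(config, recordings = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n_groups <- nrow(cfg$groups)
  n_animals <- n_groups * cfg$n_animals_per_group
  if (n_animals < 2) stop("fewer than 2 animals: composites undefined")

  set.seed(cfg$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  ## stage 1: animal latents + behaviour -----------------------------------
  set.seed(stage_seeds[1])
  surgery <- rep(cfg$groups$surgery, each = cfg$n_animals_per_group)
  housing <- rep(cfg$groups$housing, each = cfg$n_animals_per_group)
  glab <- paste(surgery, housing, sep = "-")
  animal_id <- sprintf("%s_a%02d", gsub("-", "_", glab),
                       rep(seq_len(cfg$n_animals_per_group), times = n_groups))
  d <- cfg$depression_mean[glab] + rnorm(n_animals, 0, cfg$depression_sd)
  names(d) <- animal_id

  splash <- clamp(cfg$splash_mean_s - cfg$splash_slope_s * d +
                    rnorm(n_animals, 0, cfg$behavior_sd_s), 0, cfg$splash_max_s)
  tst <- clamp(cfg$tst_mean_s + cfg$immobility_slope_s * d +
                 rnorm(n_animals, 0, cfg$behavior_sd_s), 0, cfg$immobility_max_s)
  fst <- clamp(cfg$fst_mean_s + cfg$immobility_slope_s * d +
                 rnorm(n_animals, 0, cfg$behavior_sd_s), 0, cfg$immobility_max_s)

  ipsi_final <- ifelse(surgery == "sham", cfg$pwt_sham_ipsi_g,
                       ifelse(housing == "SH", cfg$pwt_sni_sh_ipsi_g,
                              cfg$pwt_sni_exee_ipsi_g))
  days <- cfg$pwt_timepoints_day
  tc_rows <- list()
  final_ipsi <- matrix(NA_real_, n_animals, 6)
  final_contra <- matrix(NA_real_, n_animals, 6)
  for (ti in seq_along(days)) {
    day <- days[ti]
    mu_ipsi <- cfg$pwt_sham_ipsi_g +
      (ipsi_final - cfg$pwt_sham_ipsi_g) * pwt_injury_fraction(day)
    m_ipsi <- matrix(rnorm(n_animals * 6, rep(mu_ipsi, 6), cfg$pwt_sd_g),
                     n_animals, 6)
    m_contra <- matrix(rnorm(n_animals * 6, cfg$pwt_contra_g, cfg$pwt_sd_g),
                       n_animals, 6)
    m_ipsi <- clamp(m_ipsi, 0.1, Inf)
    m_contra <- clamp(m_contra, 0.1, Inf)
    tc_rows[[ti]] <- data.frame(animal_id = animal_id, surgery = surgery,
                                housing = housing, timepoint_day = day,
                                pwt_ipsi_g = rowMeans(m_ipsi),
                                pwt_contra_g = rowMeans(m_contra),
                                stringsAsFactors = FALSE)
    if (ti == length(days)) {
      final_ipsi <- m_ipsi
      final_contra <- m_contra
    }
  }
  pwt_timecourse <- do.call(rbind, tc_rows)

  behavior <- data.frame(animal_id = animal_id, surgery = surgery,
                         housing = housing,
                         splash_s = splash, tst_s = tst, fst_s = fst,
                         stringsAsFactors = FALSE)
  colnames(final_ipsi) <- sprintf("pwt_ipsi_%d_g", 1:6)
  colnames(final_contra) <- sprintf("pwt_contra_%d_g", 1:6)
  behavior <- cbind(behavior, final_ipsi, final_contra,
                    timepoint_day = days[length(days)])
  rownames(behavior) <- NULL

  ## stage 2: cell parameters ----------------------------------------------
  set.seed(stage_seeds[2])
  n_cells <- if (cfg$cells_per_animal[1] == cfg$cells_per_animal[2])
    rep(cfg$cells_per_animal[1], n_animals)
  else
    sample(cfg$cells_per_animal[1]:cfg$cells_per_animal[2], n_animals,
           replace = TRUE)
  rm_animal <- cfg$rm_mohm * (1 + cfg$coupling * cfg$rm_shift_frac * d) *
    (1 + rnorm(n_animals, 0, cfg$rm_animal_cv))
  vth_animal <- cfg$vth_mv - cfg$coupling * cfg$vth_shift_mv * d +
    rnorm(n_animals, 0, cfg$vth_animal_sd)
  cell_params <- list()
  for (a in seq_len(n_animals)) {
    ps <- vector("list", n_cells[a])
    for (k in seq_len(n_cells[a])) {
      rm_k <- max(rm_animal[a] * (1 + rnorm(1, 0, cfg$rm_cell_cv)),
                  0.2 * cfg$rm_mohm)
      vth_k <- max(vth_animal[a] + rnorm(1, 0, cfg$vth_cell_sd),
                   cfg$vreset_mv + 2)
      cm_k <- max(cfg$cm_pf * (1 + rnorm(1, 0, cfg$cm_cell_cv)),
                  0.2 * cfg$cm_pf)
      ps[[k]] <- neuron_params(rm_mohm = rm_k, cm_pf = cm_k,
                               el_mv = cfg$el_mv, vth_mv = vth_k,
                               vreset_mv = cfg$vreset_mv,
                               tref_ms = cfg$tref_ms,
                               noise_sd_mv = cfg$noise_sd_mv)
    }
    cell_params[[animal_id[a]]] <- ps
  }

  ## stage 3: recordings ----------------------------------------------------
  set.seed(stage_seeds[3])
  cell_seeds <- sample.int(.Machine$integer.max - 1L, sum(n_cells))
  recs <- NULL
  if (recordings) {
    recs <- setNames(vector("list", n_animals), animal_id)
    ci <- 0L
    for (a in seq_len(n_animals)) {
      rl <- vector("list", n_cells[a])
      for (k in seq_len(n_cells[a])) {
        ci <- ci + 1L
        rl[[k]] <- simulate_neuron(cell_params[[animal_id[a]]][[k]],
                                   cfg$protocol, seed = cell_seeds[ci],
                                   cell_id = sprintf("%s_c%02d", animal_id[a], k),
                                   animal_id = animal_id[a])
      }
      recs[[animal_id[a]]] <- rl
    }
  }

  ## ground truth ------------------------------------------------------------
  true_rm <- unlist(lapply(cell_params, function(ps)
    vapply(ps, function(p) p$rm_mohm, numeric(1))))
  true_rheo <- unlist(lapply(cell_params, function(ps)
    vapply(ps, lif_rheobase_pA, numeric(1))))
  cell_animal <- rep(animal_id, times = n_cells)
  ze <- (zscore(true_rm) - zscore(true_rheo)) / 2
  true_excit <- tapply(ze, factor(cell_animal, levels = animal_id), mean)
  true_res <- (zscore(splash) - zscore(tst) - zscore(fst)) / 3
  true_r <- if (sd(true_excit) > 0 && sd(true_res) > 0)
    cor(true_excit, true_res) else NA_real_

  ground_truth <- list(
    per_animal = data.frame(animal_id = animal_id, surgery = surgery,
                            housing = housing, d = as.numeric(d),
                            n_cells = n_cells,
                            true_excitability = as.numeric(true_excit),
                            true_resilience = as.numeric(true_res),
                            stringsAsFactors = FALSE),
    cell_params = cell_params,
    true_r = true_r)

  structure(list(behavior = behavior, pwt_timecourse = pwt_timecourse,
                 recordings = recs, ground_truth = ground_truth,
                 config = cfg),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d animals, %d cells, true animal-level r = %.3f\n",
              nrow(x$behavior), sum(x$ground_truth$per_animal$n_cells),
              x$ground_truth$true_r))
  invisible(x)
}
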