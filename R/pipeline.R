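#' End-to-end run configuration
#'
#' Bundles everything a full pipeline run needs: the cohort generator
#' settings, the screening and composite settings, and the post-hoc method
#' for the group statistics. A `run_config` plus its seed reproduces every
#' output file byte for byte.
#'
#' @param cohort a [cohort_config()].
#' @param alpha significance threshold for screening and post-hoc reporting.
#' @param var_equal pooled-variance t-test in the von Frey screen.
#' @param posthoc_method post-hoc adjustment for the two-way ANOVAs.
#' @param cor_method correlation coefficient for the resilience analysis.
#' @param pool pooling level for the excitability composite.
#' @param ap_features extract passive/AP waveform features (slower).
#' @param seed root seed; overrides `cohort$seed` so one number controls
#'   the whole run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), alpha = 0.05,
                       var_equal = FALSE,
                       posthoc_method = c("tukey", "holm_sidak", "bky_fdr"),
                       cor_method = c("pearson", "spearman"),
                       pool = c("cells", "animal_means"),
                       ap_features = TRUE,
                       seed = cohort$seed) {
  stopifnot(inherits(cohort, "cohort_config"))
  posthoc_method <- match.arg(posthoc_method)
  cor_method <- match.arg(cor_method)
  pool <- match.arg(pool)
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, alpha = alpha, var_equal = var_equal,
                 posthoc_method = posthoc_method, cor_method = cor_method,
                 pool = pool, ap_features = ap_features,
                 seed = as.integer(seed)),
            class = "run_config")
}

run_config_to_list <- function(config) {
  ch <- unclass(config$cohort)
  ch$groups <- as.list(ch$groups)
  ch$protocol <- unclass(ch$protocol)
  ch$depression_mean <- as.list(ch$depression_mean)
  list(cohort = ch, alpha = config$alpha, var_equal = config$var_equal,
       posthoc_method = config$posthoc_method,
       cor_method = config$cor_method, pool = config$pool,
       ap_features = config$ap_features, seed = config$seed)
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(run_config_to_list(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  ch <- x$cohort
  cohort <- cohort_config(
    n_animals_per_group = ch$n_animals_per_group,
    groups = as.data.frame(ch$groups, stringsAsFactors = FALSE),
    cells_per_animal = unlist(ch$cells_per_animal),
    depression_mean = unlist(ch$depression_mean),
    depression_sd = ch$depression_sd, coupling = ch$coupling,
    rm_mohm = ch$rm_mohm, cm_pf = ch$cm_pf, el_mv = ch$el_mv,
    vth_mv = ch$vth_mv, vreset_mv = ch$vreset_mv, tref_ms = ch$tref_ms,
    rm_shift_frac = ch$rm_shift_frac, vth_shift_mv = ch$vth_shift_mv,
    rm_animal_cv = ch$rm_animal_cv, rm_cell_cv = ch$rm_cell_cv,
    vth_animal_sd = ch$vth_animal_sd, vth_cell_sd = ch$vth_cell_sd,
    cm_cell_cv = ch$cm_cell_cv, noise_sd_mv = ch$noise_sd_mv,
    splash_mean_s = ch$splash_mean_s, tst_mean_s = ch$tst_mean_s,
    fst_mean_s = ch$fst_mean_s, splash_slope_s = ch$splash_slope_s,
    immobility_slope_s = ch$immobility_slope_s,
    behavior_sd_s = ch$behavior_sd_s, splash_max_s = ch$splash_max_s,
    immobility_max_s = ch$immobility_max_s,
    pwt_contra_g = ch$pwt_contra_g, pwt_sham_ipsi_g = ch$pwt_sham_ipsi_g,
    pwt_sni_sh_ipsi_g = ch$pwt_sni_sh_ipsi_g,
    pwt_sni_exee_ipsi_g = ch$pwt_sni_exee_ipsi_g, pwt_sd_g = ch$pwt_sd_g,
    pwt_timepoints_day = unlist(ch$pwt_timepoints_day),
    protocol = step_protocol(currents_pA = unlist(ch$protocol$currents_pA),
                             baseline_ms = ch$protocol$baseline_ms,
                             step_ms = ch$protocol$step_ms,
                             post_ms = ch$protocol$post_ms,
                             sampling_rate_hz = ch$protocol$sampling_rate_hz),
    seed = ch$seed)
  run_config(cohort = cohort, alpha = x$alpha, var_equal = x$var_equal,
             posthoc_method = x$posthoc_method, cor_method = x$cor_method,
             pool = x$pool, ap_features = x$ap_features, seed = x$seed)
}

#' Simulate and analyse one cohort in memory
#'
#' Convenience wrapper for simulation studies: simulates a cohort, extracts
#' per-cell features from every recording, builds the resilience and
#' excitability composites and returns their animal-level correlation,
#' without writing any files. Passive/AP features are skipped by default
#' since the composites only need input resistance and rheobase.
#'
#' @param config a [cohort_config()].
#' @param pool,method composite pooling and correlation settings (see
#'   [excitability_scores()] and [correlate_resilience_excitability()]).
#' @param screen apply the von Frey inclusion screen before the composites.
#' @param ap_features also extract passive/AP waveform features.
#' @return A list with `correlation` (a `correlation_result`), `features`
#'   (per-cell data.frame), `resilience`, `excitability` and `cohort`.
#' @export
analyze_cohort <- function(config, pool = "cells", method = "pearson",
                           screen = FALSE, ap_features = FALSE) {
  cohort <- simulate_cohort(config)
  behavior <- if (screen) {
    s <- screen_behavior(cohort$behavior)
    s[s$included, ]
  } else cohort$behavior
  feats <- features_table(lapply(unlist(cohort$recordings, recursive = FALSE),
                                 extract_cell_features,
                                 ap_features = ap_features))
  res <- resilience_scores(behavior)
  exc <- excitability_scores(feats[feats$animal_id %in% res$animal_id, ],
                             pool = pool)
  list(correlation = correlate_resilience_excitability(res, exc,
                                                       method = method),
       features = feats, resilience = res, excitability = exc,
       cohort = cohort)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis chain on a synthetic cohort
#'
#' One-command end-to-end run: simulate the cohort, write the raw bundle,
#' screen the behavioural table (von Frey inclusion), extract per-cell
#' excitability features, build the resilience and excitability composites
#' and their animal-level correlation, and run the group-statistics battery
#' (two-way ANOVAs with the configured post-hoc on each depression-like
#' readout, a repeated-measures ANOVA on the paw-withdrawal time course, and
#' a final-day two-way ANOVA on the ipsilateral threshold). Every exclusion
#' is logged with its reason in the summary.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; created if needed.
#' @return Invisibly, a list with the in-memory results: `cohort`,
#'   `screened`, `features` (data.frame), `correlation`
#'   (`correlation_result`), `stats` (list of `anova_result` / post-hoc
#'   tables), plus the paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- stage("simulate", simulate_cohort(config$cohort))
  stage("write-cohort", write_cohort(cohort, out_dir))

  screened <- stage("screen",
                    screen_behavior(cohort$behavior, alpha = config$alpha,
                                    var_equal = config$var_equal))
  write_behavior_table(screened, file.path(out_dir, "behavior_screened.csv"))

  feats <- stage("features", {
    fl <- lapply(unlist(cohort$recordings, recursive = FALSE),
                 extract_cell_features, ap_features = config$ap_features)
    features_table(fl)
  })
  write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)

  correlation <- stage("correlate", {
    res <- resilience_scores(screened[screened$included, ])
    exc <- excitability_scores(
      feats[feats$animal_id %in% res$animal_id, ], pool = config$pool)
    correlate_resilience_excitability(res, exc, method = config$cor_method)
  })
  jsonlite::write_json(
    list(slope = correlation$slope, intercept = correlation$intercept,
         r = correlation$correlation_r, r2 = correlation$r_squared,
         p = correlation$p_value, n = correlation$n_animals,
         method = correlation$method),
    file.path(out_dir, "correlation.json"), auto_unbox = TRUE, digits = NA)
  write.csv(correlation$per_animal,
            file.path(out_dir, "composites.csv"), row.names = FALSE)

  stats_out <- stage("stats", {
    out <- list()
    for (oc in c("splash_s", "tst_s", "fst_s")) {
      ar <- two_way_anova(screened[screened$included, ], oc)
      out[[oc]] <- list(anova = ar,
                        posthoc = posthoc(ar, method = config$posthoc_method,
                                          alpha = config$alpha))
    }
    tc <- cohort$pwt_timecourse
    tc$group <- paste(tc$surgery, tc$housing, sep = "-")
    out$pwt_rm <- rm_two_way_anova(tc, "pwt_ipsi_g", between = "group",
                                   within = "timepoint_day")
    final_day <- max(tc$timepoint_day)
    out$pwt_final <- two_way_anova(tc[tc$timepoint_day == final_day, ],
                                   "pwt_ipsi_g")
    out
  })
  stats_json <- lapply(stats_out, function(x) {
    if (inherits(x, "anova_result")) list(effects = x$effects,
                                          cell_means = x$cell_means)
    else list(effects = x$anova$effects, cell_means = x$anova$cell_means,
              posthoc = x$posthoc)
  })
  jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  write_run_config(config, file.path(out_dir, "run_config.yaml"))
  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(pipeline_summary_lines(config, cohort, screened, feats,
                                    correlation, stats_out), summary_path)

  invisible(list(cohort = cohort, screened = screened, features = feats,
                 correlation = correlation, stats = stats_out,
                 out_dir = out_dir))
}

pipeline_summary_lines <- function(config, cohort, screened, feats,
                                   correlation, stats_out) {
  gl <- paste(screened$surgery, screened$housing, sep = "-")
  lines <- c(
    "Synthetic-cohort excitability/resilience pipeline run",
    sprintf("seed: %d | animals: %d | cells: %d", config$seed,
            nrow(screened), nrow(feats)),
    "",
    "== von Frey screening ==",
    sprintf("included %d / %d animals", sum(screened$included),
            nrow(screened)),
    sprintf("  %s: %s", screened$animal_id, screened$reason),
    "",
    "== cell QC ==",
    sprintf("QC-passing cells: %d / %d", sum(feats$qc_pass), nrow(feats)),
    if (any(!feats$qc_pass))
      sprintf("  excluded %s: %s", feats$cell_id[!feats$qc_pass],
              feats$qc_flags[!feats$qc_pass]),
    "",
    "== group means +/- SEM (behaviour, included animals) ==")
  for (oc in c("splash_s", "tst_s", "fst_s")) {
    v <- screened[[oc]][screened$included]
    g <- gl[screened$included]
    ag <- aggregate(v, list(group = g), function(x)
      sprintf("%.1f +/- %.1f s", mean(x), sd(x) / sqrt(length(x))))
    lines <- c(lines, sprintf("%s: %s", oc,
                              paste(ag$group, ag$x, sep = " ",
                                    collapse = " | ")))
  }
  lines <- c(lines, "",
             "== resilience ~ excitability ==",
             sprintf("r = %.3f (r^2 = %.3f), p = %.4g, n = %d, slope = %.3f",
                     correlation$correlation_r, correlation$r_squared,
                     correlation$p_value, correlation$n_animals,
                     correlation$slope),
             "",
             "== ANOVA battery ==")
  for (nm in names(stats_out)) {
    x <- stats_out[[nm]]
    ar <- if (inherits(x, "anova_result")) x else x$anova
    for (i in seq_len(nrow(ar$effects)))
      lines <- c(lines, sprintf(
        "%s | %s: F(%g,%g) = %.4g, p = %.4g", nm, ar$effects$effect[i],
        ar$effects$df1[i], ar$effects$df2[i], ar$effects$F[i],
        ar$effects$p[i]))
    if (!inherits(x, "anova_result")) {
      ph <- x$posthoc
      for (i in seq_len(nrow(ph)))
        lines <- c(lines, sprintf("%s |   %s: p_adj = %.4g (%s)", nm,
                                  ph$comparison[i], ph$p_adj[i],
                                  ph$method[i]))
    }
  }
  c(lines, "", "== config ==",
    yaml::as.yaml(run_config_to_list(config)))
}
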