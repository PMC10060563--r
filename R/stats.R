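#' Unpaired two-sample t-test
#'
#' Two-sided unpaired t-test, pooled-variance (Student) by default so that
#' the degrees of freedom follow the `nA + nB - 2` reporting convention;
#' Welch optional. When the pooled variance is zero and the means are equal
#' the statistic is undefined and `t = 0, p = 1` is returned with a flag.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return A list with `t`, `df`, `p_value`, `mean_diff`, `method`, `flag`.
#' @export
unpaired_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 observations per group")
  if (anyNA(a) || anyNA(b)) stop("NA in input")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1,
                  mean_diff = 0, method = "student",
                  flag = "zero_variance_equal_means"))
    return(list(t = Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2, p_value = 0,
                mean_diff = mean(a) - mean(b), method = "student",
                flag = "zero_variance"))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(a) - mean(b),
       method = if (var_equal) "student" else "welch", flag = NA_character_)
}

# factor-cell means +/- sem used in every ANOVA report
cell_mean_table <- function(y, cell) {
  ag <- aggregate(y, list(cell = cell), function(v)
    c(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v)))
  data.frame(cell = ag$cell, mean = ag$x[, "mean"], sem = ag$x[, "sem"],
             n = ag$x[, "n"], stringsAsFactors = FALSE)
}

#' Two-way between-subjects ANOVA
#'
#' Fits `outcome ~ factor_a * factor_b` with sum-to-zero contrasts and
#' reports Type-II sums of squares (via [car::Anova]), which reduce to the
#' classical decomposition for balanced designs while remaining well defined
#' for the unbalanced group sizes typical of animal cohorts. When the
#' within-cell variance is exactly zero the F ratios are degenerate: effects
#' with positive sums of squares are reported as `Inf` and flagged, effects
#' with zero sums of squares as `F = 0, p = 1`.
#'
#' @param table data.frame with one row per observation.
#' @param outcome name of the outcome column.
#' @param factor_a,factor_b names of the two factor columns (e.g. surgery
#'   and housing).
#' @return An object of class `anova_result`: `effects` (effect, df1, df2,
#'   F, p), `cell_means`, the fitted `lm` in `fit`, and `flags`.
#' @export
two_way_anova <- function(table, outcome, factor_a = "surgery",
                          factor_b = "housing") {
  for (cl in c(outcome, factor_a, factor_b))
    if (!cl %in% names(table)) stop("missing column: ", cl)
  d <- data.frame(y = table[[outcome]],
                  A = factor(table[[factor_a]]),
                  B = factor(table[[factor_b]]))
  if (anyNA(d)) stop("NA in outcome or factors")
  tab <- table(d$A, d$B)
  if (any(tab == 0))
    stop("empty design cell(s): ",
         paste(outer(rownames(tab), colnames(tab), paste, sep = ":")[tab == 0],
               collapse = ", "))
  if (any(tab < 2))
    stop("each design cell needs >= 2 observations")
  fit <- lm(y ~ A * B, data = d,
            contrasts = list(A = "contr.sum", B = "contr.sum"))
  flags <- character(0)
  rss <- sum(residuals(fit)^2)
  df2 <- fit$df.residual
  if (rss < 1e-12) {
    # zero within-cell variance: compute effect SS directly, guard the ratios
    aa <- tryCatch(suppressWarnings(car::Anova(fit, type = 2)),
                   error = function(e) NULL)
    ss <- if (!is.null(aa)) aa[c("A", "B", "A:B"), "Sum Sq"]
          else {
            a0 <- suppressWarnings(anova(fit))  # classical SS fallback
            a0[c("A", "B", "A:B"), "Sum Sq"]
          }
    Fv <- ifelse(ss < 1e-12, 0, Inf)
    pv <- ifelse(ss < 1e-12, 1, 0)
    df1 <- c(nlevels(d$A) - 1, nlevels(d$B) - 1,
             (nlevels(d$A) - 1) * (nlevels(d$B) - 1))
    flags <- "zero_residual_variance"
    eff <- data.frame(effect = c(factor_a, factor_b, "interaction"),
                      df1 = df1, df2 = df2, F = Fv, p = pv)
  } else {
    aa <- car::Anova(fit, type = 2)
    idx <- match(c("A", "B", "A:B"), rownames(aa))
    eff <- data.frame(effect = c(factor_a, factor_b, "interaction"),
                      df1 = aa$Df[idx], df2 = df2,
                      F = aa$`F value`[idx], p = aa$`Pr(>F)`[idx])
  }
  rownames(eff) <- NULL
  structure(list(effects = eff,
                 cell_means = cell_mean_table(d$y, interaction(d$A, d$B,
                                                               sep = ":")),
                 fit = fit, data = d,
                 factor_a = factor_a, factor_b = factor_b,
                 outcome = outcome, flags = flags),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Two-way ANOVA on", x$outcome, "\n")
  print(x$effects, digits = 4)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Two-way repeated-measures ANOVA
#'
#' Univariate mixed ANOVA with one between-subjects factor (group) and one
#' within-subjects factor (time), subject as the repeated unit:
#' `aov(y ~ group * time + Error(subject))`. Subjects with incomplete time
#' series are dropped listwise with a warning. Effects whose sums of squares
#' are exactly zero are reported as `F = 0, p = 1`. No sphericity correction
#' is applied by default.
#'
#' @param table data.frame, one row per subject x timepoint.
#' @param outcome outcome column name.
#' @param between between-subjects factor column.
#' @param within within-subjects (time) factor column.
#' @param subject subject-id column.
#' @return An `anova_result` with effects `between`, `within` and
#'   `interaction`, plus `dropped_subjects`.
#' @export
rm_two_way_anova <- function(table, outcome, between = "surgery",
                             within = "timepoint_day",
                             subject = "animal_id") {
  for (cl in c(outcome, between, within, subject))
    if (!cl %in% names(table)) stop("missing column: ", cl)
  d <- data.frame(y = table[[outcome]],
                  G = factor(table[[between]]),
                  W = factor(table[[within]]),
                  S = factor(table[[subject]]))
  if (anyNA(d$y)) {
    drop_na <- !is.na(d$y)
    d <- d[drop_na, ]
  }
  counts <- table(d$S)
  n_levels <- nlevels(d$W)
  incomplete <- names(counts)[counts < n_levels]
  if (length(incomplete)) {
    warning("subject(s) with incomplete series dropped: ",
            paste(incomplete, collapse = ", "))
    d <- d[!d$S %in% incomplete, ]
    d$S <- droplevels(d$S)
  }
  if (nlevels(d$S) < 2) stop("need at least 2 complete subjects")
  fit <- aov(y ~ G * W + Error(S), data = d)
  sm <- summary(fit)
  rows <- do.call(rbind, lapply(sm, function(st) {
    df <- as.data.frame(st[[1]])
    df$term <- trimws(rownames(df))
    df
  }))
  get_eff <- function(term, resid_term_df) {
    r <- rows[rows$term == term, , drop = FALSE]
    if (nrow(r) != 1) stop("could not locate term ", term)
    r
  }
  resid_rows <- rows[rows$term == "Residuals", , drop = FALSE]
  # stratum 1 residuals test G; stratum 2 residuals test W and G:W
  eff <- lapply(c("G", "W", "G:W"), function(tm) {
    r <- get_eff(tm)
    resid <- if (tm == "G") resid_rows[1, ] else resid_rows[2, ]
    ss <- r$`Sum Sq`
    Fv <- if (ss < 1e-12) 0 else if (resid$`Sum Sq` < 1e-12) Inf
          else (ss / r$Df) / (resid$`Sum Sq` / resid$Df)
    pv <- if (ss < 1e-12) 1 else if (resid$`Sum Sq` < 1e-12) 0
          else pf(Fv, r$Df, resid$Df, lower.tail = FALSE)
    data.frame(effect = c(G = between, W = within, `G:W` = "interaction")[tm],
               df1 = r$Df, df2 = resid$Df, F = Fv, p = pv)
  })
  eff <- do.call(rbind, eff)
  rownames(eff) <- NULL
  structure(list(effects = eff,
                 cell_means = cell_mean_table(d$y, interaction(d$G, d$W,
                                                               sep = ":")),
                 fit = fit, data = d, factor_a = between, factor_b = within,
                 outcome = outcome, flags = character(0),
                 dropped_subjects = incomplete),
            class = "anova_result")
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak: with the p-values in ascending order,
#' `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, made monotone by taking running
#' maxima and capped at 1.
#'
#' @param p numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
holm_sidak_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  adj[order(o)]
}

#' Benjamini-Krieger-Yekutieli two-stage FDR adjustment
#'
#' Two-stage linear step-up procedure: stage one applies Benjamini-Hochberg
#' at level `alpha / (1 + alpha)` to estimate the number of true null
#' hypotheses `m0 = m - r1`; stage two rescales the Benjamini-Hochberg
#' adjusted values by `(m0 / m) * (1 + alpha)`. The returned values are
#' specific to `alpha`: rejection at level `alpha` corresponds to
#' `adjusted <= alpha`. The adaptive rescaling can push an adjusted value
#' below the raw p-value; [posthoc()] floors its reported values at the raw
#' p-value (after taking the rejection decision) so that reported adjusted
#' p-values are never smaller than unadjusted ones.
#'
#' @param p numeric vector of raw p-values.
#' @param alpha FDR level the adjustment is computed for.
#' @return Adjusted p-values in the input order.
#' @export
bky_adjust <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  bh <- p.adjust(p, "BH")
  r1 <- sum(bh <= alpha / (1 + alpha))
  m0 <- m - r1
  fac <- if (m0 == 0) 1 else m0 / m
  pmin(bh * fac * (1 + alpha), 1)
}

#' Post-hoc pairwise comparisons for a two-way design
#'
#' All pairwise comparisons between the design-cell means of a fitted
#' [two_way_anova()], using the pooled residual mean square and its degrees
#' of freedom. Adjustment methods: Tukey-Kramer (studentized range),
#' Holm-Sidak step-down, or the Benjamini-Krieger-Yekutieli two-stage FDR.
#' Reported adjusted p-values are floored at the raw p-value; rejection
#' decisions for the BKY method are taken before flooring (see
#' [bky_adjust()]).
#'
#' @param ar an `anova_result` from [two_way_anova()].
#' @param method adjustment method.
#' @param alpha level used for the BKY stage-one estimate and the `reject`
#'   column.
#' @return A data.frame with one row per comparison: `comparison`, `diff`,
#'   `se`, `t`, `df`, `p_raw`, `p_adj`, `reject`, `method`.
#' @export
posthoc <- function(ar, method = c("tukey", "holm_sidak", "bky_fdr"),
                    alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(ar, "anova_result"))
  if (is.null(ar$fit) || !inherits(ar$fit, "lm"))
    stop("posthoc requires a between-subjects two_way_anova fit")
  cm <- ar$cell_means
  k <- nrow(cm)
  mse <- sum(residuals(ar$fit)^2) / ar$fit$df.residual
  df <- ar$fit$df.residual
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    dif <- cm$mean[i] - cm$mean[j]
    se <- sqrt(mse * (1 / cm$n[i] + 1 / cm$n[j]))
    tv <- if (se == 0) { if (dif == 0) 0 else Inf * sign(dif) } else dif / se
    p_raw <- if (se == 0) { if (dif == 0) 1 else 0 }
             else 2 * pt(-abs(tv), df)
    data.frame(comparison = paste(cm$cell[i], "vs", cm$cell[j]),
               diff = dif, se = se, t = tv, df = df, p_raw = p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (method == "tukey") {
    qv <- abs(out$diff) / sqrt((mse / 2) * (1 / cm$n[pairs[1, ]] +
                                              1 / cm$n[pairs[2, ]]))
    p_adj <- ifelse(is.finite(qv), ptukey(qv, k, df, lower.tail = FALSE),
                    ifelse(out$diff == 0, 1, 0))
    reject <- p_adj <= alpha
  } else if (method == "holm_sidak") {
    p_adj <- holm_sidak_adjust(out$p_raw)
    reject <- p_adj <= alpha
  } else {
    p_adj <- bky_adjust(out$p_raw, alpha = alpha)
    reject <- p_adj <= alpha
  }
  out$p_adj <- pmax(p_adj, out$p_raw)
  out$reject <- reject
  out$method <- method
  out
}
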