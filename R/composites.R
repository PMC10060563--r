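#' Z-score a vector
#'
#' `(x - mean(x)) / sd(x)` with the sample standard deviation (denominator
#' n - 1). Constant input is rejected: a zero-variance measure carries no
#' ordering information and would silently zero a composite.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return Numeric vector with mean 0 and sample sd 1.
#' @examples
#' zscore(c(1, 2, 3))
#' @export
zscore <- function(x) {
  if (length(x) < 2) stop("need at least 2 values to z-score")
  if (anyNA(x)) stop("NA in input to zscore")
  s <- sd(x)
  if (s == 0) stop("zero variance: z-scores undefined")
  (x - mean(x)) / s
}

#' Behavioural resilience composite per animal
#'
#' Each depression-like readout is z-scored across all animals (groups
#' pooled), signed so that higher always means more resilient, and averaged:
#' `resilience = mean(z(splash grooming), -z(TST immobility),
#' -z(FST immobility))`. Grooming time falls and immobility rises with the
#' depression-like state, hence the signs.
#'
#' @param behavior behavioural table with columns `animal_id`, `splash_s`,
#'   `tst_s`, `fst_s`. Animals with a missing score are excluded with a
#'   warning.
#' @return A data.frame with `animal_id` and `resilience` (z-units).
#' @export
resilience_scores <- function(behavior) {
  need <- c("animal_id", "splash_s", "tst_s", "fst_s")
  miss <- setdiff(need, names(behavior))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ok <- complete.cases(behavior[, c("splash_s", "tst_s", "fst_s")])
  if (!all(ok))
    warning(sum(!ok), " animal(s) dropped from resilience: missing test score")
  b <- behavior[ok, ]
  if (nrow(b) < 2) stop("need at least 2 animals with complete scores")
  data.frame(animal_id = b$animal_id,
             resilience = (zscore(b$splash_s) - zscore(b$tst_s) -
                             zscore(b$fst_s)) / 3,
             stringsAsFactors = FALSE)
}

#' Neuronal excitability composite per animal
#'
#' Input resistance and rheobase are z-scored across all QC-passing cells
#' (groups pooled) and combined with signs such that higher always means more
#' excitable: `cell excitability = mean(z(R_in), -z(rheobase))`. Cell values
#' are then averaged within each animal to a grand average per animal.
#' Alternatively (`pool = "animal_means"`) the raw measures are first
#' averaged per animal and z-scored across animals.
#'
#' @param features per-cell features as returned by [features_table()] (or a
#'   list of `cell_features`). Cells failing QC are excluded; animals left
#'   with no QC-passing cell are dropped with a warning.
#' @param pool pooling level for the z-scores.
#' @return A data.frame with `animal_id`, `excitability` (z-units) and
#'   `n_cells`.
#' @export
excitability_scores <- function(features,
                                pool = c("cells", "animal_means")) {
  pool <- match.arg(pool)
  if (!is.data.frame(features)) features <- features_table(features)
  need <- c("animal_id", "rheobase_pA", "rin_MOhm", "qc_pass")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  all_animals <- unique(features$animal_id)
  f <- features[features$qc_pass & is.finite(features$rheobase_pA) &
                  is.finite(features$rin_MOhm), ]
  if (nrow(f) < 2) stop("need at least 2 QC-passing cells")
  dropped <- setdiff(all_animals, unique(f$animal_id))
  if (length(dropped))
    warning("animal(s) with no QC-passing cell dropped: ",
            paste(dropped, collapse = ", "))
  if (pool == "cells") {
    ze <- (zscore(f$rin_MOhm) - zscore(f$rheobase_pA)) / 2
    ag <- aggregate(ze, list(animal_id = f$animal_id), mean)
    n <- aggregate(ze, list(animal_id = f$animal_id), length)
    out <- data.frame(animal_id = ag$animal_id, excitability = ag$x,
                      n_cells = n$x, stringsAsFactors = FALSE)
  } else {
    rin_m <- aggregate(f$rin_MOhm, list(animal_id = f$animal_id), mean)
    rb_m <- aggregate(f$rheobase_pA, list(animal_id = f$animal_id), mean)
    n <- aggregate(f$rin_MOhm, list(animal_id = f$animal_id), length)
    out <- data.frame(animal_id = rin_m$animal_id,
                      excitability = (zscore(rin_m$x) - zscore(rb_m$x)) / 2,
                      n_cells = n$x, stringsAsFactors = FALSE)
  }
  # keep the input animal order
  out[order(match(out$animal_id, all_animals)), , drop = FALSE]
}

#' Correlate behavioural resilience with neuronal excitability
#'
#' Matches animals by id, fits the ordinary least-squares line of resilience
#' (y) on excitability (x) and reports the Pearson (or Spearman) correlation
#' with its two-sided p-value. This is the animal-level association between
#' the depression-like state and ACC neuronal excitability.
#'
#' @param resilience data.frame from [resilience_scores()].
#' @param excitability data.frame from [excitability_scores()].
#' @param method correlation coefficient.
#' @return An object of class `correlation_result`: `per_animal`
#'   (animal_id, resilience, excitability, n_cells), `slope`, `intercept`,
#'   `correlation_r`, `r_squared`, `p_value`, `n_animals`, `method`.
#' @export
correlate_resilience_excitability <- function(resilience, excitability,
                                              method = c("pearson",
                                                         "spearman")) {
  method <- match.arg(method)
  m <- merge(resilience, excitability, by = "animal_id", sort = FALSE)
  m <- m[order(m$animal_id), , drop = FALSE]
  rownames(m) <- NULL
  if (nrow(m) < 3) stop("need at least 3 matched animals")
  if (sd(m$resilience) == 0 || sd(m$excitability) == 0)
    stop("zero variance on one axis: correlation undefined")
  fit <- lm(resilience ~ excitability, data = m)
  ct <- suppressWarnings(cor.test(m$excitability, m$resilience,
                                  method = method))
  r <- unname(ct$estimate)
  structure(
    list(per_animal = m[, c("animal_id", "resilience", "excitability",
                            if ("n_cells" %in% names(m)) "n_cells")],
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         correlation_r = r, r_squared = r^2, p_value = ct$p.value,
         n_animals = nrow(m), method = method),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Resilience ~ excitability over %d animals (%s):\n",
              x$n_animals, x$method))
  cat(sprintf("  r = %.3f (r^2 = %.3f), p = %.4g\n",
              x$correlation_r, x$r_squared, x$p_value))
  cat(sprintf("  OLS line: y = %.3f x + %.3f\n", x$slope, x$intercept))
  invisible(x)
}
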