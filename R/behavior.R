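#' Summarize the six von Frey measures of one paw
#'
#' @param measures exactly six finite, positive paw-withdrawal thresholds (g).
#' @return Named numeric vector `c(mean = , sd = )` (sample sd).
#' @examples
#' summarize_pwt(c(2, 2, 2, 2, 2, 2))
#' @export
summarize_pwt <- function(measures) {
  if (length(measures) != 6)
    stop("exactly 6 measures per paw are required")
  if (!all(is.finite(measures)) || any(measures <= 0))
    stop("measures must be finite and positive")
  c(mean = mean(measures), sd = sd(measures))
}

#' Von Frey inclusion decision for one animal
#'
#' Applies the six-measure unpaired t-test inclusion criterion: the six
#' ipsilateral readings are compared with the six contralateral readings by a
#' two-sided unpaired t-test. An SNI animal is included when the test is
#' significant (`p < alpha`) and the ipsilateral mean is below the
#' contralateral mean (the injury direction); a sham animal is included when
#' the test is not significant (`p >= alpha`). When both paws have zero
#' variance and equal means the test statistic is undefined and the
#' comparison is treated as not significant.
#'
#' @param ipsi,contra six paw-withdrawal thresholds (g) per paw.
#' @param surgery `"SNI"` or `"sham"`.
#' @param alpha significance threshold.
#' @param var_equal pooled-variance (Student) t-test instead of Welch.
#' @return A list with `included` (logical), `p` and `reason`.
#' @export
vonfrey_inclusion <- function(ipsi, contra, surgery, alpha = 0.05,
                              var_equal = FALSE) {
  summarize_pwt(ipsi)
  summarize_pwt(contra)
  if (!surgery %in% c("SNI", "sham")) stop("surgery must be 'SNI' or 'sham'")
  mi <- mean(ipsi); mc <- mean(contra)
  if (sd(ipsi) == 0 && sd(contra) == 0) {
    # t undefined; equal means -> not significant by convention
    p <- if (mi == mc) 1 else 0
  } else {
    p <- t.test(ipsi, contra, var.equal = var_equal)$p.value
  }
  if (surgery == "SNI") {
    included <- p < alpha && mi < mc
    why <- if (included) "hypersensitive ipsi paw"
           else if (mi >= mc) "ipsi mean not below contra"
           else "no significant ipsi-contra difference"
  } else {
    included <- p >= alpha
    why <- if (included) "no ipsi-contra difference (as expected for sham)"
           else "unexpected ipsi-contra difference in sham"
  }
  list(included = included, p = p,
       reason = sprintf("%s: p=%.4g, ipsi=%.3g g, contra=%.3g g (%s)",
                        if (included) "included" else "excluded", p, mi, mc, why))
}

pwt_cols <- function(side) sprintf("pwt_%s_%d_g", side, 1:6)

behavior_schema_cols <- function() {
  c("animal_id", "surgery", "housing", "splash_s", "tst_s", "fst_s",
    pwt_cols("ipsi"), pwt_cols("contra"), "timepoint_day")
}

#' Screen a behavioural table with the von Frey inclusion criterion
#'
#' @param behavior a behavioural table (see [load_behavior_table()] for the
#'   schema).
#' @param alpha significance threshold for [vonfrey_inclusion()].
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return The table with `included` (logical) and `reason` (character)
#'   columns appended.
#' @export
screen_behavior <- function(behavior, alpha = 0.05, var_equal = FALSE) {
  need <- c("surgery", pwt_cols("ipsi"), pwt_cols("contra"))
  miss <- setdiff(need, names(behavior))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dec <- lapply(seq_len(nrow(behavior)), function(i) {
    vonfrey_inclusion(as.numeric(behavior[i, pwt_cols("ipsi")]),
                      as.numeric(behavior[i, pwt_cols("contra")]),
                      behavior$surgery[i], alpha = alpha,
                      var_equal = var_equal)
  })
  behavior$included <- vapply(dec, `[[`, logical(1), "included")
  behavior$reason <- vapply(dec, `[[`, character(1), "reason")
  behavior
}

#' Load and validate a behavioural CSV table
#'
#' Expects one row per animal with columns `animal_id`, `surgery`
#' (SNI/sham), `housing` (SH/EEE/ExEE), `splash_s`, `tst_s`, `fst_s`, six
#' ipsilateral and six contralateral von Frey columns
#' (`pwt_ipsi_1_g` ... `pwt_contra_6_g`) and `timepoint_day`. Schema
#' violations are reported with their row numbers. Durations are checked
#' against the test lengths (splash 300 s; tail suspension and forced swim
#' 360 s).
#'
#' @param path CSV file path.
#' @param splash_max_s,immobility_max_s test durations used for validation.
#' @return A validated data.frame.
#' @export
load_behavior_table <- function(path, splash_max_s = 300,
                                immobility_max_s = 360) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(behavior_schema_cols(), names(df))
  if (length(miss))
    stop("behavior table is missing columns: ", paste(miss, collapse = ", "))
  probs <- character(0)
  bad <- function(rows, what) {
    if (any(rows)) sprintf("rows %s: %s",
                           paste(which(rows), collapse = ","), what)
  }
  probs <- c(probs,
    bad(!df$surgery %in% c("SNI", "sham"), "unknown surgery label"),
    bad(!df$housing %in% c("SH", "EEE", "ExEE"), "unknown housing label"),
    bad(!is.finite(df$splash_s) | df$splash_s < 0 |
          df$splash_s > splash_max_s,
        sprintf("splash_s outside [0, %g]", splash_max_s)),
    bad(!is.finite(df$tst_s) | df$tst_s < 0 | df$tst_s > immobility_max_s,
        sprintf("tst_s outside [0, %g]", immobility_max_s)),
    bad(!is.finite(df$fst_s) | df$fst_s < 0 | df$fst_s > immobility_max_s,
        sprintf("fst_s outside [0, %g]", immobility_max_s)))
  for (cl in c(pwt_cols("ipsi"), pwt_cols("contra"))) {
    v <- df[[cl]]
    probs <- c(probs, bad(!is.finite(v) | v <= 0,
                          paste0(cl, " not finite and positive")))
  }
  probs <- probs[!vapply(probs, is.null, logical(1))]
  if (length(probs))
    stop("invalid behavior table:\n  ", paste(unlist(probs), collapse = "\n  "))
  df
}

#' Write a behavioural table to CSV
#'
#' @param behavior a behavioural data.frame.
#' @param path output file.
#' @export
write_behavior_table <- function(behavior, path) {
  write.csv(behavior, path, row.names = FALSE)
  invisible(path)
}
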