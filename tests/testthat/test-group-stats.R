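balanced_fixture <- function() {
  data.frame(surgery = rep(c("sham", "SNI"), each = 6),
             housing = rep(rep(c("SH", "ExEE"), each = 3), 2),
             y = c(3, 4, 5, 6, 7, 8, 10, 11, 12, 7, 8, 9))
}

test_that("two-way ANOVA F values match the hand-computed sums of squares on a balanced integer fixture", {
  d <- balanced_fixture()
  ar <- two_way_anova(d, "y")
  ss <- oracle_twoway_ss(d$y, d$surgery, d$housing)
  mse <- ss$ss_err / 8
  expect_equal(ar$effects$F[ar$effects$effect == "surgery"],
               ss$ss_a / mse, tolerance = 1e-8)
  expect_equal(ar$effects$F[ar$effects$effect == "housing"],
               ss$ss_b / mse, tolerance = 1e-8)
  expect_equal(ar$effects$F[ar$effects$effect == "interaction"],
               ss$ss_ab / mse, tolerance = 1e-8)
  expect_equal(ar$effects$df1, c(1, 1, 1))
  expect_equal(ar$effects$df2, c(8, 8, 8))
})

test_that("row order never changes the ANOVA statistics", {
  d <- balanced_fixture()
  set.seed(3)
  base <- two_way_anova(d, "y")$effects
  perm <- two_way_anova(d[sample(nrow(d)), ], "y")$effects
  expect_equal(perm, base)
})

test_that("zero within-cell variance with a pure main effect exercises the degenerate guard", {
  d <- data.frame(surgery = rep(c("sham", "SNI"), each = 4),
                  housing = rep(c("SH", "ExEE"), 4),
                  y = rep(c(1, 5), each = 4))
  ar <- two_way_anova(d, "y")
  expect_true("zero_residual_variance" %in% ar$flags)
  eff <- ar$effects
  expect_true(is.infinite(eff$F[eff$effect == "surgery"]))
  expect_equal(eff$F[eff$effect == "housing"], 0)
  expect_equal(eff$F[eff$effect == "interaction"], 0)
})

test_that("empty or underfilled design cells are rejected with an explicit message", {
  d <- balanced_fixture()
  expect_error(two_way_anova(d[!(d$surgery == "SNI" & d$housing == "SH"), ],
                             "y"), "empty design cell")
  d2 <- d[-c(1, 2), ]   # leaves one observation in sham:SH
  expect_error(two_way_anova(d2, "y"), ">= 2 observations")
})

test_that("repeated-measures ANOVA matches a from-scratch split-plot SS partition", {
  # 2 groups x 4 subjects x 3 times, small integers
  d <- expand.grid(animal_id = sprintf("s%d", 1:8),
                   timepoint_day = c(0, 7, 14))
  d$surgery <- ifelse(as.integer(sub("s", "", d$animal_id)) <= 4,
                      "sham", "SNI")
  set.seed(5)
  d$y <- c(2, 3, 4, 3, 5, 6, 7, 6,
           3, 4, 5, 4, 7, 8, 9, 8,
           4, 5, 6, 5, 9, 10, 11, 10)
  ar <- rm_two_way_anova(d, "y")
  o <- oracle_rm_ss(d$y, d$surgery, d$timepoint_day, d$animal_id)
  expect_equal(ar$effects$F[1], (o$ss_g / o$df_g) / (o$ss_subj / o$df_subj),
               tolerance = 1e-8)
  expect_equal(ar$effects$F[2], (o$ss_w / o$df_w) / (o$ss_resid / o$df_resid),
               tolerance = 1e-8)
  expect_equal(ar$effects$F[3],
               (o$ss_gw / o$df_gw) / (o$ss_resid / o$df_resid),
               tolerance = 1e-8)
  expect_equal(ar$effects$df1, c(o$df_g, o$df_w, o$df_gw))
  expect_equal(ar$effects$df2, c(o$df_subj, o$df_resid, o$df_resid))
})

test_that("constant data gives all-zero F and a pure group offset loads only the between effect", {
  d <- expand.grid(animal_id = sprintf("s%d", 1:8),
                   timepoint_day = c(0, 7, 14))
  d$surgery <- ifelse(as.integer(sub("s", "", d$animal_id)) <= 4,
                      "sham", "SNI")
  d$y <- 5
  expect_equal(rm_two_way_anova(d, "y")$effects$F, c(0, 0, 0))
  d$y <- ifelse(d$surgery == "SNI", 7, 2) +
    rep(c(-0.1, 0, 0.1, -0.05, 0.05, -0.1, 0, 0.1), 3)
  ar <- rm_two_way_anova(d, "y")
  eff <- ar$effects
  expect_gt(eff$F[eff$effect == "surgery"],
            10 * max(eff$F[eff$effect != "surgery"]))
})

test_that("subjects with incomplete time series are dropped with a warning", {
  d <- expand.grid(animal_id = sprintf("s%d", 1:6),
                   timepoint_day = c(0, 7))
  d$surgery <- ifelse(as.integer(sub("s", "", d$animal_id)) <= 3,
                      "sham", "SNI")
  set.seed(1); d$y <- rnorm(nrow(d))
  d <- d[!(d$animal_id == "s2" & d$timepoint_day == 7), ]
  expect_warning(ar <- rm_two_way_anova(d, "y"), "s2")
  expect_equal(ar$dropped_subjects, "s2")
})

test_that("Holm-Sidak and BKY adjustments match their hand oracles", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  # step-down Sidak by hand: 1 - (1 - p_(i))^(m - i + 1), monotone
  hs <- c(1 - (1 - 0.01)^4, 1 - (1 - 0.02)^3, 1 - (1 - 0.03)^2, 0.5)
  hs <- cummax(hs)
  expect_equal(holm_sidak_adjust(p), hs, tolerance = 1e-12)
  # BKY two-stage by hand: BH -> m0 estimate at alpha/(1+alpha) -> rescale
  bh <- p.adjust(p, "BH")                       # 0.04 0.04 0.04 0.50
  r1 <- sum(bh <= 0.05 / 1.05)                  # 3 rejections in stage one
  m0 <- length(p) - r1
  expect_equal(bky_adjust(p, alpha = 0.05),
               pmin(bh * (m0 / length(p)) * 1.05, 1), tolerance = 1e-12)
  expect_equal(bky_adjust(p, alpha = 0.05),
               c(0.0105, 0.0105, 0.0105, 0.13125), tolerance = 1e-12)
  # degenerate stage-one outcomes
  expect_equal(bky_adjust(rep(0.001, 4)), rep(0.00105, 4), tolerance = 1e-12)
  expect_equal(bky_adjust(c(0.2, 0.3, 0.5, 0.9)),
               p.adjust(c(0.2, 0.3, 0.5, 0.9), "BH") * 1.05,
               tolerance = 1e-12)
})

test_that("post-hoc tables report adjusted p >= raw p for all three methods", {
  set.seed(12)
  for (k in 1:5) {
    d <- data.frame(surgery = rep(c("sham", "SNI"), each = 8),
                    housing = rep(rep(c("SH", "ExEE"), each = 4), 2),
                    y = rnorm(16, rep(c(0, 1, 2, 0), each = 4)))
    ar <- two_way_anova(d, "y")
    for (m in c("tukey", "holm_sidak", "bky_fdr")) {
      ph <- posthoc(ar, method = m)
      expect_equal(nrow(ph), 6)
      expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
      expect_true(all(ph$p_adj >= 0 & ph$p_adj <= 1))
    }
  }
})

test_that("identical groups yield no post-hoc rejections", {
  d <- data.frame(surgery = rep(c("sham", "SNI"), each = 6),
                  housing = rep(rep(c("SH", "ExEE"), each = 3), 2),
                  y = rep(c(2, 3, 4), 4))
  ar <- two_way_anova(d, "y")
  for (m in c("tukey", "holm_sidak", "bky_fdr")) {
    ph <- posthoc(ar, method = m)
    expect_false(any(ph$reject))
    expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
  }
  expect_error(posthoc(ar, method = "bonferroni"), "arg")
})

test_that("the pooled t-test follows the textbook formula and df convention", {
  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  tt <- unpaired_t(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  expect_equal(tt$t, (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3)),
               tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 2 * pt(-abs(tt$t), 4), tolerance = 1e-12)
  # the n_A = 16 vs n_B = 14 design reports df = 28 under pooled Student
  set.seed(2)
  tt2 <- unpaired_t(rnorm(16), rnorm(14))
  expect_equal(tt2$df, 28)
  # degenerate: zero variance, equal means
  z <- unpaired_t(rep(2, 3), rep(2, 4))
  expect_equal(z$p_value, 1)
  expect_equal(z$flag, "zero_variance_equal_means")
})
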