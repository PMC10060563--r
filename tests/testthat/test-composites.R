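test_that("zscore centres and scales with the sample sd and rejects degenerate input", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore(c(5, 5, 5)), "zero variance")
  expect_error(zscore(3), "at least 2")
  set.seed(10)
  for (k in 1:10) {
    x <- rnorm(8)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(zscore(a * x + b), zscore(x), tolerance = 1e-12)
  }
})

test_that("resilience is the mean of the signed behavioural z-scores, pooled across groups", {
  b <- data.frame(animal_id = c("a", "b", "c"),
                  splash_s = c(10, 20, 30), tst_s = c(7, 6, 5),
                  fst_s = c(9, 7, 5))
  r <- resilience_scores(b)
  # animal b sits at the pooled mean of every test
  expect_equal(r$resilience[r$animal_id == "b"], 0)
  expect_equal(r$resilience,
               (zscore(b$splash_s) - zscore(b$tst_s) - zscore(b$fst_s)) / 3,
               tolerance = 1e-12)
  # z_splash = 1, z_tst = -1, z_fst = -1 gives resilience 1: animal c here
  expect_equal(r$resilience[r$animal_id == "c"], 1)
})

test_that("excitability rises with input resistance and falls with rheobase", {
  # one cell per animal so the animal composite IS the cell composite
  ft <- data.frame(animal_id = letters[1:6],
                   cell_id = paste0("c", 1:6),
                   rin_MOhm = c(130, 110, 120, 130, 140, 150),
                   rheobase_pA = c(170, 190, 180, 170, 160, 150),
                   qc_pass = TRUE)
  # cell a sits exactly at the pooled mean of both measures
  expect_equal(mean(ft$rin_MOhm), ft$rin_MOhm[1])
  expect_equal(mean(ft$rheobase_pA), ft$rheobase_pA[1])
  e0 <- excitability_scores(ft)
  expect_equal(e0$excitability[e0$animal_id == "a"], 0, tolerance = 1e-12)
  # raising one cell's Rin strictly raises its excitability,
  # raising its rheobase strictly lowers it
  up <- ft; up$rin_MOhm[1] <- up$rin_MOhm[1] + 30
  expect_gt(excitability_scores(up)$excitability[1], e0$excitability[1])
  dn <- ft; dn$rheobase_pA[1] <- dn$rheobase_pA[1] + 50
  expect_lt(excitability_scores(dn)$excitability[1], e0$excitability[1])
})

test_that("QC-failing cells are excluded and empty animals dropped with a warning", {
  ft <- data.frame(animal_id = c("a", "a", "b", "c"),
                   cell_id = paste0("c", 1:4),
                   rin_MOhm = c(100, 120, 140, 160),
                   rheobase_pA = c(200, 180, 160, 140),
                   qc_pass = c(TRUE, TRUE, TRUE, FALSE))
  expect_warning(e <- excitability_scores(ft), "no QC-passing cell")
  expect_equal(e$animal_id, c("a", "b"))
  expect_equal(e$n_cells, c(2, 1))
})

test_that("a noiseless coupled cohort separates every SNI-SH animal's excitability from sham-SH", {
  cfg <- noiseless_config(cells_per_animal = 3, seed = 2)
  co <- simulate_cohort(cfg, recordings = FALSE)
  gt <- co$ground_truth
  ft <- do.call(rbind, lapply(names(gt$cell_params), function(an) {
    ps <- gt$cell_params[[an]]
    data.frame(animal_id = an,
               rin_MOhm = vapply(ps, function(p) p$rm_mohm, numeric(1)),
               rheobase_pA = vapply(ps, lif_rheobase_pA, numeric(1)),
               qc_pass = TRUE)
  }))
  e <- excitability_scores(ft)
  sni_sh <- e$excitability[grep("^SNI_SH", e$animal_id)]
  sham_sh <- e$excitability[grep("^sham_SH", e$animal_id)]
  expect_gt(min(sni_sh), max(sham_sh))
})

test_that("the regression line and Pearson r match the textbook formulas", {
  # exact inverse line
  res <- data.frame(animal_id = letters[1:4], resilience = c(3, 2, 1, 0))
  exc <- data.frame(animal_id = letters[1:4], excitability = c(0, 1, 2, 3))
  cr <- correlate_resilience_excitability(res, exc)
  expect_equal(cr$correlation_r, -1)
  expect_equal(cr$slope, -1)
  expect_equal(cr$r_squared, 1)
  # symmetric V has zero correlation
  resv <- data.frame(animal_id = c("a", "b", "c"),
                     resilience = c(1, 0, 1))
  excv <- data.frame(animal_id = c("a", "b", "c"),
                     excitability = c(0, 1, 2))
  expect_equal(correlate_resilience_excitability(resv, excv)$correlation_r, 0)
  # random 16-animal cohort against the closed-form oracle
  set.seed(16)
  x <- rnorm(16); y <- -0.8 * x + rnorm(16, 0, 0.5)
  ids <- sprintf("m%02d", 1:16)
  cr2 <- correlate_resilience_excitability(
    data.frame(animal_id = ids, resilience = y),
    data.frame(animal_id = ids, excitability = x))
  o <- oracle_pearson(x, y)
  expect_equal(cr2$correlation_r, o$r, tolerance = 1e-12)
  expect_equal(cr2$slope, o$slope, tolerance = 1e-12)
  expect_equal(cr2$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(cr2$r_squared, o$r^2, tolerance = 1e-12)
})

test_that("the correlation is matched by animal id, not row order", {
  set.seed(8)
  ids <- sprintf("m%02d", 1:10)
  res <- data.frame(animal_id = ids, resilience = rnorm(10))
  exc <- data.frame(animal_id = ids, excitability = rnorm(10))
  base <- correlate_resilience_excitability(res, exc)
  shuf <- correlate_resilience_excitability(res[sample(10), ],
                                            exc[sample(10), ])
  expect_equal(shuf$correlation_r, base$correlation_r)
  expect_equal(shuf$slope, base$slope)
})

test_that("degenerate correlation inputs are rejected", {
  res <- data.frame(animal_id = c("a", "b"), resilience = c(1, 2))
  exc <- data.frame(animal_id = c("a", "b"), excitability = c(1, 2))
  expect_error(correlate_resilience_excitability(res, exc), "3 matched")
  res3 <- data.frame(animal_id = c("a", "b", "c"), resilience = c(1, 1, 1))
  exc3 <- data.frame(animal_id = c("a", "b", "c"), excitability = c(1, 2, 3))
  expect_error(correlate_resilience_excitability(res3, exc3),
               "zero variance")
})
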