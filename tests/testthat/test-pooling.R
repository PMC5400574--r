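test_that("per-study effect matches direct arithmetic and is antisymmetric", {
  abu <- raw_ff(2, 53, 5, 58, model = "homozygote")
  e <- study_effect(abu)
  expect_equal(e$or, (2 * 58) / (53 * 5), tolerance = 1e-12)  # 116/265
  expect_equal(e$or, 0.4377, tolerance = 1e-4)
  expect_equal(e$se, sqrt(1 / 2 + 1 / 53 + 1 / 5 + 1 / 58), tolerance = 1e-12)

  bal <- study_effect(raw_ff(10, 10, 10, 10))
  expect_equal(bal$log_or, 0)
  expect_equal(bal$se, sqrt(0.4), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    cells <- rpois(4, 30) + 1
    f <- raw_ff(cells[1], cells[2], cells[3], cells[4])
    t <- raw_ff(cells[3], cells[4], cells[1], cells[2])  # arms swapped
    expect_equal(study_effect(t)$log_or, -study_effect(f)$log_or)
    expect_equal(study_effect(t)$se, study_effect(f)$se)
  }
  expect_error(study_effect(raw_ff(0, 5, 3, 7)), "zero cell")
})

test_that("single-study pooling is the identity and duplicates are homogeneous", {
  abu <- raw_ff(2, 53, 5, 58, model = "homozygote")
  pooled <- pool_fixed_mh(list(abu))
  expect_equal(pooled$or, study_effect(abu)$or, tolerance = 1e-12)
  expect_equal(pooled$se, study_effect(abu)$se, tolerance = 1e-12)
  expect_equal(pooled$k, 1L)
  expect_equal(pooled$p_Q, 1)

  two <- pool_fixed_mh(list(raw_ff(10, 10, 10, 10), raw_ff(10, 10, 10, 10)))
  expect_equal(two$or, 1)
  expect_equal(two$Q, 0)
  expect_equal(two$I2, 0)
  expect_error(pool_fixed_mh(list()), "no informative studies")
})

test_that("inverse-variance pooling matches closed forms and a textbook oracle", {
  # antithetic pair: theta-hat = 0, Q = 2
  p <- pool_fixed_iv(eff_df(c(1, -1), c(1, 1)))
  expect_equal(p$log_or, 0)
  expect_equal(p$Q, 2)
  expect_equal(p$p_Q, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(p$p_Q, 0.1572992, tolerance = 1e-6)

  # equal weights reduce to the arithmetic mean
  th <- c(0.2, -0.5, 1.1)
  expect_equal(pool_fixed_iv(eff_df(th, rep(2, 3)))$log_or, mean(th),
               tolerance = 1e-12)

  # brute-force oracle on small sets: recompute every formula independently
  set.seed(42)
  for (i in 1:20) {
    k <- sample(1:3, 1)
    yi <- rnorm(k); sei <- runif(k, 0.3, 2)
    p <- pool_fixed_iv(eff_df(yi, sei))
    wi <- sei^-2
    mu <- sum(wi * yi) / sum(wi)
    expect_equal(p$log_or, mu, tolerance = 1e-12)
    expect_equal(p$se, sum(wi)^-0.5, tolerance = 1e-12)
    expect_equal(p$Q, sum(wi * (yi - mu)^2), tolerance = 1e-12)
    expect_equal(p$ci_low, exp(mu - qnorm(0.975) / sqrt(sum(wi))),
                 tolerance = 1e-12)
    expect_equal(p$p, 2 * pnorm(-abs(mu * sqrt(sum(wi)))), tolerance = 1e-12)
  }
})

test_that("DerSimonian-Laird estimates tau2 by moments and degenerates to fixed", {
  # hand algebra: Q = 2, df = 1, sum w = 2, sum w^2/sum w = 1 -> tau2 = 1
  p <- pool_random_dl(eff_df(c(1, -1), c(1, 1)))
  expect_equal(p$tau2, 1)
  expect_equal(p$log_or, 0)
  expect_error(pool_random_dl(eff_df(1, 1)), "at least 2")

  # homogeneous effects: tau2 = 0 and random == fixed IV exactly
  hom <- eff_df(c(0.1, 0.1, 0.1), c(0.5, 0.7, 0.9))
  r <- pool_random_dl(hom); f <- pool_fixed_iv(hom)
  expect_equal(r$tau2, 0)
  expect_equal(r$log_or, f$log_or, tolerance = 1e-12)
  expect_equal(r$se, f$se, tolerance = 1e-12)
})

test_that("heterogeneity-driven model selection uses strict thresholds", {
  expect_equal(select_model(0.286, 15.3), "FIXED_MH")
  expect_equal(select_model(0.002, 59.3), "RANDOM_DL")
  expect_equal(select_model(0.1, 50), "FIXED_MH")    # boundary: both strict
  expect_equal(select_model(0.099, 0), "RANDOM_DL")
  expect_equal(select_model(0.5, 50.1), "RANDOM_DL")
  expect_equal(select_model(0.5, 10, fixed = "IV"), "FIXED_IV")
})

test_that("pooled CI excludes 1 exactly when p < 0.05, and I2 stays in range", {
  set.seed(3)
  for (i in 1:30) {
    k <- sample(2:8, 1)
    p <- pool_fixed_iv(eff_df(rnorm(k, 0, 0.5), runif(k, 0.1, 1)))
    expect_true(p$I2 >= 0 && p$I2 <= 100)
    expect_true(p$tau2 >= 0)
    excludes_one <- p$ci_low > 1 || p$ci_high < 1
    expect_equal(excludes_one, p$p < 0.05)
  }
})

test_that("MH and IV pooled odds ratios agree closely on the packaged data", {
  tab <- rs1063192_studies()
  for (m in genetic_models()) {
    mh <- meta_analyze(tab, m, method = "fixed", fixed = "MH")
    iv <- meta_analyze(tab, m, method = "fixed", fixed = "IV")
    expect_lt(abs(mh$or - iv$or), 0.02)
  }
})

test_that("pooling agrees with an independent reference implementation", {
  library(metafor)
  tab <- rs1063192_studies()
  for (m in c("allele", "homozygote")) {
    ffs <- fourfold_tables(tab, m)$tables
    eff <- do.call(rbind, lapply(ffs, function(f)
      data.frame(yi = study_effect(f)$log_or, vi = study_effect(f)$se^2)))
    dl <- pool_random_dl(ffs)
    ref <- metafor::rma(yi, vi, data = eff, method = "DL")
    expect_equal(dl$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(dl$log_or, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(dl$se, ref$se, tolerance = 1e-8)
    expect_equal(dl$Q, ref$QE, tolerance = 1e-8)
    # MH point estimate against the reference (corrected counts, no further add)
    A <- vapply(ffs, function(f) f$a, numeric(1))
    B <- vapply(ffs, function(f) f$b, numeric(1))
    C <- vapply(ffs, function(f) f$c, numeric(1))
    D <- vapply(ffs, function(f) f$d, numeric(1))
    mh <- pool_fixed_mh(ffs)
    ref_mh <- metafor::rma.mh(ai = A, bi = B, ci = C, di = D,
                              measure = "OR", add = 0, to = "none",
                              correct = FALSE)
    expect_equal(mh$log_or, as.numeric(ref_mh$beta), tolerance = 1e-8)
    expect_equal(mh$se, ref_mh$se, tolerance = 1e-6)
  }
})

test_that("fixed-effect pooling recovers a simulated true odds ratio with near-nominal coverage", {
  reps <- 200
  hits <- 0
  errs <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- synthetic_config(k = 50, true_allele_or = 0.7, tau = 0,
                            n_case_law = c(1000L, 1000L),
                            n_ctrl_law = c(1000L, 1000L), seed = i)
    res <- meta_analyze(simulate_study_table(cfg), "allele", method = "fixed")
    errs[i] <- res$or - 0.7
    if (res$ci_low <= 0.7 && res$ci_high >= 0.7) hits <- hits + 1
  }
  expect_lt(abs(mean(errs)), 0.03)
  expect_gte(hits / reps, 0.92)
  expect_lte(hits / reps, 0.97)
})
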