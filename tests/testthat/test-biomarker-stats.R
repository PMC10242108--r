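test_that("fold enrichment follows the 2^-dCT closed forms", {
  expect_equal(fold_enrichment(25, 25), 1)
  expect_equal(fold_enrichment(26, 25), 0.5)
  expect_equal(fold_enrichment(15, 25), 1024)
  expect_error(fold_enrichment(NA, 25), "finite")
  # strictly decreasing in target Ct, increasing in reference Ct
  expect_true(all(diff(fold_enrichment(seq(20, 30, 0.5), 25)) < 0))
  expect_true(all(diff(fold_enrichment(25, seq(20, 30, 0.5))) > 0))
})

test_that("predictor scores multiply and are order-invariant", {
  folds <- c("hsa-miR-5096" = 70, "hsa-let-7i-3p" = 2, "hsa-miR-4311" = 3)
  expect_equal(predictor_score(folds, c("hsa-miR-5096", "hsa-let-7i-3p")),
               140)
  expect_equal(predictor_score(folds, c("hsa-let-7i-3p", "hsa-miR-5096")),
               140)
  expect_equal(predictor_score(folds, "P"), 420)
  expect_equal(predictor_score(c(a = 2, b = 3, c = 5), c("a", "b", "c")), 30)
  expect_error(predictor_score(folds[1:2], "P"), "hsa-miR-4311")
  expect_error(predictor_score(folds, c("hsa-miR-5096")), "at least two")
  # log-linearity property over random folds
  set.seed(4)
  for (i in 1:20) {
    f <- setNames(2^rnorm(4), letters[1:4])
    perm <- sample(4)
    expect_equal(predictor_score(f, letters[perm[1:3]]),
                 prod(f[letters[perm[1:3]]]))
    expect_equal(log(predictor_score(f, letters[1:4])),
                 sum(log(f)), tolerance = 1e-12)
  }
})

test_that("dichotomization is strict at the cut-off", {
  expect_equal(dichotomize(70, 70), "low")     # "> 70 vs <= 70"
  expect_equal(dichotomize(70.01, 70), "high")
  expect_equal(dichotomize(0, 5), "low")
  expect_equal(dichotomize(c(69, 70, 71), 70), c("low", "low", "high"))
})

test_that("ROC analysis equals the pairwise concordance oracle", {
  # separable scores
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))
  expect_equal(r$auc, 1)
  expect_lte(r$ci95[2], 1)
  # all-tied scores
  r2 <- roc_analysis(rep(5, 8), rep(c(0, 1), 4))
  expect_equal(r2$auc, 0.5)
  # random sets vs oracle, exactly
  set.seed(17)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    y <- c(0, 0, 1, 1, sample(0:1, n - 4, replace = TRUE))
    s <- sample(seq(0, 5, 0.5), n, replace = TRUE)   # with ties
    expect_equal(roc_analysis(s, y)$auc, oracle_auc(s, y))
  }
  expect_error(roc_analysis(1:4, rep(1, 4)), "each outcome class")
})

test_that("DeLong interval and test agree with the reference implementation", {
  set.seed(8)
  s <- c(rnorm(20, 1.2), rnorm(18))
  y <- rep(c(1, 0), c(20, 18))
  mine <- roc_analysis(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
  expect_equal(mine$ci95,
               as.numeric(pROC::ci.auc(ref, method = "delong"))[c(1, 3)],
               tolerance = 1e-9)
  # paired comparison
  s2 <- s + rnorm(38, sd = 2)
  mine2 <- roc_analysis(s2, y)
  cmp <- compare_auc(mine, mine2, paired = TRUE)
  ref2 <- pROC::roc(y, s2, quiet = TRUE)
  rtest <- pROC::roc.test(ref, ref2, method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, rtest$p.value, tolerance = 1e-9)
})

test_that("comparing a ROC with itself gives a null result", {
  r <- roc_analysis(c(1, 3, 2, 5, 4, 6), c(0, 0, 0, 1, 1, 1))
  cmp <- compare_auc(r, r, paired = TRUE)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$p_value, 1)
  expect_error(compare_auc(r, roc_analysis(1:6, rep(c(0, 1), 3)),
                           paired = TRUE), NA)
})

test_that("paired DeLong test detects an informative marker", {
  set.seed(9)
  hits <- 0
  for (i in 1:100) {
    y <- rep(c(1, 0), each = 50)
    informative <- y * 1.5 + rnorm(100)
    random <- rnorm(100)
    p <- compare_auc(roc_analysis(informative, y),
                     roc_analysis(random, y), paired = TRUE)$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("cut-off selection matches exhaustive search and declared ties", {
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  sel <- select_cutoff(r, "youden")
  expect_equal(sel$value, 1)                   # perfect separation
  expect_gt(sel$cutoff, 2); expect_lte(sel$cutoff, 3)
  set.seed(23)
  for (i in 1:20) {
    y <- c(0, 0, 1, 1, sample(0:1, 8, replace = TRUE))
    s <- sample(seq(0, 3, 0.25), 12, replace = TRUE)
    rr <- roc_analysis(s, y)
    for (m in c("youden", "liu")) {
      sel <- select_cutoff(rr, m)
      expect_equal(sel$value, oracle_best_cutoff(s, y, m), tolerance = 1e-12)
    }
  }
  expect_error(select_cutoff(roc_analysis(rep(1, 6), rep(c(0, 1), 3))),
               "degenerate")
})

test_that("cut-off recovery on separated simulated groups", {
  ct <- simulate_ct_table(12, effect_log2 = 4, noise_sd = 0.3, seed = 6)
  sc <- score_ct_table(ct)
  folds <- sc[["miR-sim"]]
  y <- as.integer(sc$group == "FDG_pos")
  if (max(folds[y == 0]) < min(folds[y == 1])) {
    cut <- select_cutoff(roc_analysis(folds, y), "youden")$cutoff
    expect_gt(cut, max(folds[y == 0]))
    expect_lte(cut, min(folds[y == 1]))
  }
})

test_that("Ct tables validate and score per sample", {
  ct <- simulate_ct_table(4, effect_log2 = 1, noise_sd = 0, seed = 2)
  sc <- score_ct_table(ct)
  expect_equal(nrow(sc), 8)
  expect_equal(unname(tapply(sc[["miR-sim"]], sc$group, mean)["FDG_pos"] /
                      tapply(sc[["miR-sim"]], sc$group, mean)["FDG_neg"]), 2)
  expect_error(read_ct_table(data.frame(sample_id = 1)), "lacks column")
  ct$ct_target[1] <- NA
  expect_message(read_ct_table(ct), "dropping 1")
})

test_that("simulated Ct effects land within analytic error", {
  ct <- simulate_ct_table(50, effect_log2 = 3, noise_sd = 0.5, seed = 13)
  sc <- score_ct_table(ct)
  lf <- log2(sc[["miR-sim"]])
  diff <- mean(lf[sc$group == "FDG_pos"]) - mean(lf[sc$group == "FDG_neg"])
  se <- 0.5 * sqrt(2) * sqrt(2 / 50)   # dCT noise sd * sqrt(2/n)
  expect_lt(abs(diff - 3), 3 * se)
  # zero effect, zero noise: identical folds
  ct0 <- simulate_ct_table(5, effect_log2 = 0, noise_sd = 0, seed = 3)
  s0 <- score_ct_table(ct0)
  expect_equal(unique(s0[["miR-sim"]]), 2^-5)
})

test_that("reference constants are exposed as documented", {
  expect_equal(unname(reference_cutoffs["hsa-miR-5096"]), 70)
  expect_setequal(names(predictor_presets), c("P1", "P2", "P3", "P"))
  expect_equal(sort(predictor_presets$P2),
               sort(c("hsa-miR-5096", "hsa-let-7i-3p")))
})
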