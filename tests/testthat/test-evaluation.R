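test_that("AUC-ROC matches hand values and the pair-counting oracle", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)  # all ties
  expect_equal(auc_roc(c(0.9, 0.4, 0.6, 0.1), c(1, 0, 1, 0)), 1)
  expect_equal(auc_roc(c(0.9, 0.4, 0.6, 0.1), c(0, 1, 0, 1)), 0)
  expect_warning(v <- auc_roc(c(0.1, 0.2), c(1, 1)), "single-class")
  expect_true(is.na(v))
  set.seed(73)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    scores <- round(runif(n), 1)              # coarse grid to force ties
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(auc_roc(scores, labels), auc_brute(scores, labels))
    # complement property
    expect_equal(auc_roc(scores, labels) + auc_roc(scores, 1 - labels), 1)
  }
})

test_that("AUC-ROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(79)
  scores <- runif(60); labels <- rbinom(60, 1, 0.3)
  expect_equal(auc_roc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))))
})

test_that("AUC-PR is step-interpolated average precision", {
  expect_equal(auc_pr(c(0.9, 0.8, 0.7), c(0, 1, 1)), (1 / 2 + 2 / 3) / 2)
  expect_equal(auc_pr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)  # perfect
  expect_equal(auc_pr(c(0.9, 0.1, 0.2), c(1, 0, 0)), 1)  # single pos first
  expect_warning(v <- auc_pr(c(0.5, 0.4), c(0, 0)), "no positives")
  expect_true(is.na(v))
})

bench <- generate_dti_benchmark(n_drugs = 25, n_targets = 12, seed = 83)
S_chem <- pairwise_similarity(bench$corpus, "lingosim")

test_that("repeated CV produces the full fold grid, deterministically", {
  cv <- cross_validate(bench$network, S_chem, bench$target_sim,
                       n_folds = 5, n_repeats = 5, seed = 9)
  expect_identical(nrow(tidy(cv)), 25L)
  expect_true(all(tidy(cv)$auc_roc >= 0 & tidy(cv)$auc_roc <= 1))
  expect_true(all(tidy(cv)$auc_pr >= 0 & tidy(cv)$auc_pr <= 1))
  # folds partition the drugs with near-equal sizes
  sizes <- tidy(cv)$n_test_drugs
  expect_true(all(sizes == 5L))            # 25 drugs split into 5 even folds
  expect_identical(sum(sizes[1:5]), 25L)
  cv2 <- cross_validate(bench$network, S_chem, bench$target_sim,
                        n_folds = 5, n_repeats = 5, seed = 9)
  expect_identical(tidy(cv), tidy(cv2))
  g <- glance(cv)
  expect_identical(g$n_folds, 25L)
  expect_true(g$sd_auc_roc_repeats <= g$sd_auc_roc + 1e-9 ||
                is.finite(g$sd_auc_roc_repeats))
  expect_error(cross_validate(bench$network, S_chem, bench$target_sim,
                              n_folds = 30), "folds")
})

test_that("CV leaves the caller's RNG stream untouched", {
  set.seed(101)
  before <- runif(1)
  set.seed(101)
  invisible(cross_validate(bench$network, S_chem, bench$target_sim,
                           n_folds = 5, n_repeats = 1, seed = 2))
  expect_identical(runif(1), before)
})

test_that("paired t-test handles identical, shifted and degenerate inputs", {
  cv <- cross_validate(bench$network, S_chem, bench$target_sim,
                       n_folds = 5, n_repeats = 2, seed = 4)
  same <- paired_ttest(cv, cv)
  expect_equal(same$statistic, 0)
  expect_false(same$significant)
  # constant nonzero difference is reported significant with a warning
  cv_shift <- cv
  cv_shift$folds$auc_roc <- cv$folds$auc_roc + 0.05
  expect_warning(res <- paired_ttest(cv_shift, cv), "degenerate")
  expect_true(res$significant)
  expect_equal(res$mean_diff, 0.05)
  # mismatched partitions are refused
  cv_other <- cross_validate(bench$network, S_chem, bench$target_sim,
                             n_folds = 5, n_repeats = 2, seed = 5)
  expect_error(paired_ttest(cv, cv_other), "matched seeds")
})

test_that("rejection rate under a known shift tracks the analytic power", {
  # fold scores ~ N(mu, sd): the paired test on 25 matched folds should
  # reject at roughly the power of a one-sample t-test on the differences
  set.seed(89)
  n <- 25; delta <- 0.02; sd_d <- 0.03
  nominal <- stats::power.t.test(n = n, delta = delta, sd = sd_d,
                                 type = "one.sample")$power
  template <- list(seed = 1L, n_folds = 5L, n_repeats = 5L)
  mk <- function(rocs) {
    structure(c(template,
                list(method = "m",
                     folds = tibble::tibble(repeat_ = rep(1:5, each = 5),
                                            fold = rep(1:5, 5),
                                            auc_roc = rocs,
                                            auc_pr = rocs))),
              class = "cv_result")
  }
  rejections <- replicate(300, {
    base <- rnorm(n, 0.8, 0.02)
    a <- mk(base + rnorm(n, delta, sd_d))
    b <- mk(base)
    paired_ttest(a, b)$significant
  })
  expect_lt(abs(mean(rejections) - nominal), 0.12)
})
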