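test_that("stratified partition covers degenerate and paper-sized cases", {
  # leave-one-out: every subset of size 1
  lab <- rep(c(-1, 1), each = 5)
  plan <- stratified_partition(lab, 10, seed = 1)
  expect_equal(sort(plan$fold), 1:10)

  # 17 + 17 subjects into 20 subsets: all assigned, none empty,
  # per-class subset sizes differ by at most one
  lab <- rep(c(-1, 1), each = 17)
  plan <- stratified_partition(lab, 20, seed = 3)
  expect_equal(nrow(plan), 34)
  counts <- table(factor(plan$fold, levels = 1:20))
  expect_true(all(counts >= 1))
  for (cls in c(-1, 1)) {
    per <- table(factor(plan$fold[plan$label == cls], levels = 1:20))
    expect_lte(max(per) - min(per), 1)
  }
})

test_that("fold plans are seed-deterministic", {
  lab <- rep(c(-1, 1), c(9, 12))
  expect_identical(stratified_partition(lab, 7, seed = 5),
                   stratified_partition(lab, 7, seed = 5))
  expect_false(identical(stratified_partition(lab, 7, seed = 5)$fold,
                         stratified_partition(lab, 7, seed = 6)$fold))
})

test_that("partition rejects impossible requests", {
  expect_error(stratified_partition(rep(c(-1, 1), 3), 7), "exceeds")
  expect_error(stratified_partition(rep(1, 6), 3), "both classes")
})

test_that("metric arithmetic matches hand arithmetic under both conventions", {
  # perfect classifier on 17 + 17
  perfect <- list(A_CC = 17, A_IC = 0, B_CC = 17, B_IC = 0)
  for (conv in c("standard", "as-printed")) {
    m <- compute_metrics(perfect, conv)
    expect_equal(c(m$accuracy, m$specificity, m$sensitivity), c(1, 1, 1))
  }
  # 29 of 34 correct
  m <- compute_metrics(list(A_CC = 14, A_IC = 3, B_CC = 15, B_IC = 2))
  expect_equal(m$accuracy, 29 / 34)
  # mixed-count example, both conventions by direct substitution
  cts <- list(A_CC = 10, A_IC = 7, B_CC = 15, B_IC = 2)
  std <- compute_metrics(cts, "standard")
  expect_equal(std$accuracy, 25 / 34)
  expect_equal(std$specificity, 10 / 17)
  expect_equal(std$sensitivity, 15 / 17)
  ap <- compute_metrics(cts, "as-printed")
  expect_equal(ap$specificity, 10 / 12)
  expect_equal(ap$sensitivity, 15 / 22)
})

test_that("zero denominators yield NA, never a silent zero", {
  m <- compute_metrics(list(A_CC = 0, A_IC = 0, B_CC = 3, B_IC = 1))
  expect_true(is.na(m$specificity))
  expect_equal(m$sensitivity, 3 / 4)
})

test_that("a test sample identical to a training sample gets its training prediction", {
  cohort <- tiny_cohort(seed = 31)
  fm <- tiny_fm(cohort)
  X <- fm$values
  lab <- fm$labels
  tr <- 1:14
  res <- run_fold(X[tr, ], lab[tr], X[c(15, 16, 3), ], lab[c(15, 16, 3)],
                  k_values = 5)
  # subject 3 appears in both training and test; its test prediction must
  # equal the training-side prediction of the fold's model
  art <- res$artifacts
  sel <- art$ranking$order[1:5]
  co_tr <- project(art$pca, X[tr, ])[, sel]
  train_pred <- predict(art$svms[[1]], co_tr)
  expect_identical(res$predictions$prediction[3], train_pred[3])
})

test_that("perfectly separated classes are classified without error at full k", {
  # disjoint intensity supports: huge effect, tiny noise
  cohort <- tiny_cohort(effect = 5, noise = 0.05, seed = 32)
  fm <- tiny_fm(cohort)
  res <- run_cv(fm, n_folds = 8, seed = 2)
  full_k <- max(res$metrics$k)
  expect_equal(res$metrics$accuracy[res$metrics$k == full_k], 1)
})

test_that("pooled counts equal the sum of per-fold counts", {
  cohort <- tiny_cohort(seed = 33)
  fm <- tiny_fm(cohort)
  res <- run_cv(fm, n_folds = 4, k_range = c(2, 5), seed = 9)
  for (kk in c(2, 5)) {
    p <- res$predictions[res$predictions$k == kk, ]
    per_fold <- lapply(split(p, p$fold), function(pf)
      sum(pf$truth == pf$prediction))
    expect_equal(sum(unlist(per_fold)),
                 res$metrics$n_correct[res$metrics$k == kk])
    expect_equal(res$metrics$n[res$metrics$k == kk], nrow(fm$values))
  }
})

test_that("training artifacts are unchanged when a test subject is removed", {
  cohort <- tiny_cohort(seed = 34)
  fm <- tiny_fm(cohort)
  X <- fm$values; lab <- fm$labels
  tr <- 1:12; te <- 13:16
  full <- run_fold(X[tr, ], lab[tr], X[te, ], lab[te], k_values = 4)
  dropped <- run_fold(X[tr, ], lab[tr], X[te[-2], ], lab[te[-2]], k_values = 4)
  expect_equal(full$artifacts$pca$eigenvalues, dropped$artifacts$pca$eigenvalues)
  expect_identical(full$artifacts$ranking$order, dropped$artifacts$ranking$order)
  expect_equal(full$artifacts$svms[[1]]$weights, dropped$artifacts$svms[[1]]$weights)
  expect_equal(full$predictions$prediction[-2], dropped$predictions$prediction)
})

test_that("folds short of the requested k fall back to all their components", {
  cohort <- tiny_cohort(n_a = 5, n_b = 5, grid = 8, radius = 2,
                        center = c(5, 5, 5), seed = 35)
  fm <- tiny_fm(cohort)
  # training folds have 8 subjects -> at most 7 components; ask for 9
  res <- run_cv(fm, n_folds = 5, k_range = c(3, 9), seed = 1)
  expect_true(all(res$fold_log$k_requested == 9))
  expect_true(all(res$fold_log$k_used <= 7))
  expect_equal(nrow(res$metrics), 2)
})

test_that("CV reruns with the same seed are bit-identical", {
  cohort <- tiny_cohort(seed = 36)
  fm <- tiny_fm(cohort)
  r1 <- run_cv(fm, n_folds = 4, k_range = 1:4, seed = 11)
  r2 <- run_cv(fm, n_folds = 4, k_range = 1:4, seed = 11)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("null cohorts with permuted labels classify at chance level", {
  # no-effect cohort; labels re-permuted per seed; terminal-k accuracy
  # must stay inside the 99% binomial band around 0.5 in >= 9 of 10 seeds
  in_band <- logical(10)
  for (s in 1:10) {
    cohort <- tiny_cohort(n_a = 10, n_b = 10, effect = 0, seed = 200 + s)
    fm <- tiny_fm(cohort)
    fm$labels <- withr::with_seed(300 + s, sample(fm$labels))
    k_max <- nrow(fm$values) - max(table(
      stratified_partition(fm$labels, 10, seed = s)$fold)) - 1
    res <- run_cv(fm, n_folds = 10, k_range = k_max, seed = s)
    acc <- res$metrics$accuracy
    in_band[s] <- acc >= 0.2 && acc <= 0.8  # 99% binomial band for n = 20
  }
  expect_gte(sum(in_band), 9)
})

test_that("mean CV accuracy is nondecreasing in the planted effect size", {
  accs <- sapply(c(0, 0.1, 0.3), function(eff) {
    mean(sapply(1:10, function(s) {
      cohort <- tiny_cohort(n_a = 8, n_b = 8, effect = eff, noise = 0.1,
                            seed = 400 + s)
      fm <- tiny_fm(cohort)
      res <- run_cv(fm, n_folds = 8, k_range = 10, seed = s)
      res$metrics$accuracy
    }))
  })
  expect_true(all(diff(accs) >= 0))
})

test_that("strong effects are recovered under both 20-fold and 10-fold schemes", {
  cohort <- generate_cohort(cohort_config(seed = 61))  # 17+17, effect 2*sd
  fm <- vectorize(smooth_cohort(cohort, 8))
  for (scheme in c(20, 10)) {
    res <- run_cv(fm, n_folds = scheme, cost = 1, seed = 3)
    expect_gte(res$best$accuracy, 0.9)
  }
})

test_that("tidy, glance and autoplot expose the metric curves", {
  cohort <- tiny_cohort(seed = 37)
  fm <- tiny_fm(cohort)
  res <- run_cv(fm, n_folds = 4, k_range = 1:6, seed = 2)
  td <- tidy(res)
  expect_equal(td$k, 1:6)
  expect_true(all(td$accuracy >= 0 & td$accuracy <= 1))
  g <- glance(res)
  expect_equal(g$accuracy, max(td$accuracy))
  expect_equal(g$best_k, td$k[which.max(td$accuracy)])
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
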