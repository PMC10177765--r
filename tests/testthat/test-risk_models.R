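mk_clinical <- function(n, labels, age = 60, sex = "male", smoking = "never") {
  out <- data.frame(sample_id = paste0("s", seq_len(n)),
                    risk_label = rep_len(labels, n),
                    age = rep_len(age, n), sex = rep_len(sex, n),
                    smoking = rep_len(smoking, n))
  class(out) <- c("clinical_table", "data.frame")
  out
}

test_that("feature assembly counts panel burden and encodes covariates", {
  pan <- mk_panel("1", c(100L, 300L), c(199L, 399L))
  cat1 <- mk_catalog(c("s1", "s1", "s1", "s1"), "1",
                     c(120L, 350L, 600L, 900L), n_samples = 3L)
  cl <- mk_clinical(3, c("high", "low", "low"),
                    smoking = c("current", "never", "unknown"))
  ft <- assemble_features(cat1, list(mibc = pan), cl, "mibc+risk")
  expect_equal(ft$hotspot_burden_mibc, c(2L, 0L, 0L))    # 2 of 4 inside panel
  expect_equal(ft$smoking_current, c(1L, 0L, 0L))
  expect_equal(ft$smoking_missing, c(0L, 0L, 1L))
  expect_equal(levels(ft$label), c("low", "high"))

  # brute-force burden check on random records
  set.seed(12)
  pos <- sample(1:1000, 20, replace = TRUE)
  cat2 <- mk_catalog(sample(paste0("s", 1:5), 20, replace = TRUE), "1", pos,
                     n_samples = 5L)
  cl5 <- mk_clinical(5, c("high", "low", "high", "low", "low"))
  ft2 <- assemble_features(cat2, list(nmibc = pan), cl5, "nmibc+risk")
  for (i in 1:5) {
    mine <- ft2$hotspot_burden_nmibc[ft2$sample_id == paste0("s", i)]
    p <- pos[cat2$records$sample_id == paste0("s", i)]
    expect_equal(mine, bf_count_in(p, 100, 199) + bf_count_in(p, 300, 399))
  }

  # risk_only omits burden; missing age rows dropped with a message
  cl5$age[2] <- NA
  expect_message(ft3 <- assemble_features(cat2, list(), cl5, "risk_only"),
                 "dropped 1")
  expect_false(any(grepl("burden", names(ft3))))
  expect_equal(nrow(ft3), 4L)
})

test_that("stratified split is deterministic, disjoint and label-balanced", {
  tbl <- data.frame(sample_id = paste0("s", 1:200),
                    label = factor(rep(c("low", "high"), each = 100),
                                   levels = c("low", "high")),
                    x = rnorm(200))
  sp <- split_train_test(tbl, 0.7, seed = 5)
  expect_equal(nrow(sp$train), 140L)
  expect_equal(nrow(sp$test), 60L)
  expect_equal(as.integer(table(sp$train$label)), c(70L, 70L))
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0L)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), tbl$sample_id)
  sp2 <- split_train_test(tbl, 0.7, seed = 5)
  expect_identical(sp$train$sample_id, sp2$train$sample_id)
  sp3 <- split_train_test(tbl, 0.7, seed = 6)
  expect_false(identical(sp$train$sample_id, sp3$train$sample_id))
  expect_error(split_train_test(tbl, 1.0, seed = 1), "empty test")
  expect_error(split_train_test(tbl[c(1, 101), ], 0.7, seed = 1), "at least 2")
})

test_that("roc_auc equals brute-force pairwise concordance and is rank-invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(13)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # ties likely
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_identical(roc_auc(s, y)$auc, bf_auc(s, y))
    expect_identical(roc_auc(qlogis(pmin(pmax(s, 0.01), 0.99)), y)$auc,
                     roc_auc(s, y)$auc)              # monotone transform
  }
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("roc points start at (0,0), end at (1,1) and are monotone", {
  set.seed(14)
  s <- runif(30); y <- rbinom(30, 1, 0.4)
  roc <- roc_auc(s, y)$roc_points
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("all three models separate a separable table and not a permuted one", {
  set.seed(15)
  n <- 400
  tbl <- data.frame(sample_id = paste0("s", 1:n),
                    label = factor(rep(c("low", "high"), each = n / 2),
                                   levels = c("low", "high")),
                    f1 = c(rnorm(n / 2, 0), rnorm(n / 2, 8)),
                    f2 = rnorm(n))
  sp <- split_train_test(tbl, 0.7, seed = 1)
  for (mt in c("logistic", "neural_net", "random_forest")) {
    rep_ <- fit_and_score(sp$train, sp$test, mt, seed = 1)
    expect_equal(rep_$auc, 1.0, tolerance = 1e-9)
  }
  # label permutation: AUC concentrates near 0.5
  tbl_null <- tbl
  set.seed(16)
  tbl_null$label <- sample(tbl_null$label)
  spn <- split_train_test(tbl_null, 0.7, seed = 1)
  for (mt in c("logistic", "random_forest")) {
    rep_ <- fit_and_score(spn$train, spn$test, mt, seed = 1)
    expect_gt(rep_$auc, 0.35)
    expect_lt(rep_$auc, 0.65)
  }
})

test_that("permutation importance ranks a label-equal feature first, noise last", {
  set.seed(17)
  n <- 300
  tbl <- data.frame(sample_id = paste0("s", 1:n),
                    label = factor(sample(c("low", "high"), n, replace = TRUE),
                                   levels = c("low", "high")),
                    noise = rnorm(n))
  tbl$oracle <- as.numeric(tbl$label == "high") + rnorm(n, sd = 0.05)
  sp <- split_train_test(tbl, 0.7, seed = 2)
  rf <- fit_and_score(sp$train, sp$test, "random_forest", seed = 2)
  imp <- variable_importance(rf, sp$test, n_perm = 10, seed = 2)
  expect_equal(names(imp)[1], "oracle")
  expect_lt(abs(imp[["noise"]]), 0.05)
})
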