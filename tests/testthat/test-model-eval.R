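test_that("the Gaussian kernel matches its closed form and kernlab", {
  expect_equal(gaussian_kernel(1:3, 1:3, sigma = 2), 1)
  # squared distance 2 sigma^2 gives exp(-1)
  sigma <- 1.5
  x <- c(sqrt(2 * sigma^2), 0)
  expect_equal(gaussian_kernel(x, c(0, 0), sigma), exp(-1))
  expect_error(gaussian_kernel(1:3, 1:2, 1), "dimension")
  expect_error(gaussian_kernel(1:3, 1:3, 0), "positive")

  set.seed(2)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(gaussian_kernel(a, b, 1.3), gaussian_kernel(b, a, 1.3))
  rbf <- kernlab::rbfdot(sigma = 1 / (2 * 1.3^2))
  expect_equal(gaussian_kernel(a, b, 1.3), as.numeric(rbf(a, b)))
})

test_that("kernel matrices are symmetric with unit diagonal", {
  set.seed(26)
  m <- matrix(rnorm(30), nrow = 6)
  K <- outer(seq_len(6), seq_len(6),
             Vectorize(function(i, j) gaussian_kernel(m[i, ], m[j, ], 2)))
  expect_equal(K, t(K))
  expect_equal(diag(K), rep(1, 6))
  expect_true(all(K > 0 & K <= 1))
})

test_that("both classifiers separate an easy toy set", {
  toy <- separable_toy(10, seed = 1)
  for (kind in c("svm", "rf")) {
    model <- train_classifier(toy, classifier = kind, seed = 1)
    pred <- predict(model, toy)
    expect_equal(unname(pred), toy$label, info = kind)
  }
  expect_error(train_classifier(dplyr::mutate(toy, label = 1L)),
               "both classes")
})

test_that("prediction validates features and preserves row mapping", {
  toy <- separable_toy(10, seed = 1)
  model <- train_classifier(toy, seed = 1)
  expect_error(predict(model, dplyr::select(toy, -x2)), "missing")
  expect_error(predict(model, dplyr::mutate(toy, x3 = 1)), "extra")
  expect_length(predict(model, toy[0, ]), 0)
  shuffled <- toy[sample(nrow(toy)), ]
  expect_equal(predict(model, shuffled)[toy$sample_id],
               predict(model, toy))
})

test_that("metrics follow the confusion-matrix formulas", {
  perfect <- compute_metrics(19, 0, 19, 0)
  expect_equal(unlist(perfect[c("sn", "sp", "acc", "mcc")]),
               c(sn = 1, sp = 1, acc = 1, mcc = 1))
  chance <- compute_metrics(5, 5, 5, 5)
  expect_equal(chance$acc, 0.5)
  expect_equal(chance$mcc, 0)
  expect_equal(compute_metrics(3, 0, 0, 2)$mcc, 0)  # degenerate denominator
  expect_error(compute_metrics(0, 0, 0, 0), "zero")
  expect_error(compute_metrics(-1, 0, 1, 0), "non-negative")
})

test_that("MCC and ACC are symmetric under class swap and bounded", {
  set.seed(17)
  for (i in 1:25) {
    cnt <- sample(0:30, 4, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    a <- compute_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    b <- compute_metrics(cnt[3], cnt[4], cnt[1], cnt[2])  # TP<->TN, FP<->FN
    expect_equal(a$mcc, b$mcc)
    expect_equal(a$acc, b$acc)
    expect_true(a$mcc >= -1 && a$mcc <= 1)
    # ACC = (SN * P + SP * N) / (P + N)
    P <- cnt[1] + cnt[4]; N <- cnt[3] + cnt[2]
    if (P > 0 && N > 0) {
      expect_equal(a$acc, (a$sn * P + a$sp * N) / (P + N))
    }
  }
})

test_that("stratified k-fold CV recovers separable structure", {
  toy <- separable_toy(10, seed = 1)
  cv <- k_fold_cv(toy, k = 10, seed = 1)
  expect_gte(cv$mean_accuracy, 0.9)
  expect_equal(nrow(cv$folds), 10)
  expect_equal(sum(cv$folds$tp + cv$folds$fp + cv$folds$tn + cv$folds$fn),
               nrow(toy))
  # fold assignment changes with the seed but the result does not
  cv2 <- k_fold_cv(toy, k = 10, seed = 99)
  expect_equal(cv2$mean_accuracy, cv$mean_accuracy)
  expect_error(k_fold_cv(toy, k = 11), "fewer than")
})

test_that("label-shuffled data scores near chance", {
  set.seed(4)
  toy <- separable_toy(15, seed = 4)
  toy$label <- sample(toy$label)
  cv <- k_fold_cv(toy, k = 10, seed = 4)
  expect_gte(cv$mean_accuracy, 0.3)
  expect_lte(cv$mean_accuracy, 0.7)
})

test_that("jackknife equals n-fold CV and pools every sample once", {
  toy <- separable_toy(6, seed = 2)
  jk <- jackknife_cv(toy, seed = 2)
  expect_equal(jk$tp + jk$fp + jk$tn + jk$fn, nrow(toy))
  expect_equal(jk$acc, 1)
  cvn <- k_fold_cv(toy, k = nrow(toy) / 2, seed = 2)  # balanced classes
  expect_equal(jk$acc, cvn$pooled$acc)
  expect_error(jackknife_cv(toy[c(1, 7), ]), "at least 3")
})

test_that("stratified splitting preserves class balance", {
  n <- 186
  ds <- tibble::tibble(sample_id = paste0("s", 1:n),
                       label = rep(c(1L, 0L), each = n / 2),
                       x = rnorm(n))
  sp <- train_test_split_stratified(ds, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 148)
  expect_equal(nrow(sp$test), 38)
  expect_equal(unname(table(sp$train$label)), c(74, 74), ignore_attr = TRUE)
  expect_equal(unname(table(sp$test$label)), c(19, 19), ignore_attr = TRUE)
  # disjoint partition recovering the original set
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), ds$sample_id)

  ten <- ds[c(1:5, 94:98), ]
  sp2 <- train_test_split_stratified(ten, 0.5, seed = 1)
  expect_equal(nrow(sp2$train), 4)
  expect_error(train_test_split_stratified(ds, 1.2), "between 0 and 1")
})

test_that("models persist and reload through the versioned container", {
  toy <- separable_toy(5, seed = 6)
  model <- train_classifier(toy, seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(predict(back, toy), predict(model, toy))
  saveRDS(list(x = 1), path)
  expect_error(load_model(path), "not a dbpmix model")
})

test_that("tidiers and autoplot methods return the documented shapes", {
  toy <- separable_toy(8, seed = 9)
  cv <- k_fold_cv(toy, k = 4, seed = 9)
  expect_equal(tidy(cv), cv$folds)
  g <- glance(cv)
  expect_equal(g$mean_accuracy, cv$mean_accuracy)
  ev <- compute_metrics(14, 3, 16, 5)
  expect_equal(tidy(ev)$metric, c("sn", "sp", "acc", "mcc"))
  expect_equal(glance(ev)$mcc, ev$mcc)
  model <- train_classifier(toy, seed = 9)
  expect_equal(nrow(tidy(model)), 2)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(autoplot(mrmd_rank(toy)), "ggplot")
  tab <- report_table(list(toy = list(cv = cv, test = ev)))
  expect_equal(tab$acc_pct, 78.95)
})
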