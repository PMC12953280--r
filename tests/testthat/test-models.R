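# Variance filter, per-set PCA, random forest CV, baselines, NNLS ensemble.

test_that("variance filter keeps exactly the features at or above threshold", {
  set.seed(2)
  X <- cbind(matrix(rnorm(30 * 7), 30), matrix(1, 30, 3))
  colnames(X) <- paste0("f", 1:10)
  flt <- variance_filter(X, 5e-4)
  expect_length(flt$keep, 7)
  expect_equal(colnames(flt$X), paste0("f", 1:7))
  # variance exactly at the threshold is kept (>= keep / < drop)
  x1 <- rep(c(-1, 1), 15)
  X2 <- cbind(at = x1, const = rep(2, 30))
  flt2 <- variance_filter(X2, threshold = var(x1))
  expect_equal(flt2$keep, "at")
  expect_error(variance_filter(X2[, 2, drop = FALSE], 5e-4), "every feature")
  # refitting is not needed to apply to new rows
  expect_equal(colnames(apply_variance_filter(flt, X)), flt$keep)
})

test_that("per-set PCA captures structure and transfers to unseen rows", {
  set.seed(3)
  n <- 20
  t_lat <- rnorm(n)
  line <- outer(t_lat, c(1, -2, 0.5, 3, 1))           # exactly 1-D in 5-D
  noise <- matrix(rnorm(n * 5, sd = 1), n, 5)
  mk <- function(M) {
    colnames(M) <- paste0("f", seq_len(ncol(M)))
    rownames(M) <- sprintf("P%02d", seq_len(nrow(M)))
    M
  }
  fs <- structure(list(pre = mk(line), post = mk(noise),
                       delta = mk(line - noise)), class = "feature_set")
  red <- fit_reduction(fs, variance_threshold = 1e-8, retain = 0.95)
  expect_equal(red$sets$pre$n_components, 1L)          # a line is one PC
  # back-projection reproduces the training block within retained variance
  pre_hat <- red$X[, "pre_PC1", drop = FALSE] %*% t(red$sets$pre$rotation)
  pre_hat <- sweep(pre_hat, 2, red$sets$pre$center, `+`)
  expect_equal(unname(pre_hat), unname(line), tolerance = 1e-8)
  # per-set independence: permuting post columns leaves pre block unchanged
  fs2 <- fs
  fs2$post <- fs$post[, c(3, 1, 2, 5, 4)]
  colnames(fs2$post) <- paste0("f", 1:5)
  red2 <- fit_reduction(fs2, variance_threshold = 1e-8, retain = 0.95)
  expect_equal(abs(red2$sets$pre$rotation), abs(red$sets$pre$rotation))
  # transform on unseen rows uses fitted centres/loadings only
  newfs <- structure(list(pre = mk(outer(rnorm(4), c(1, -2, 0.5, 3, 1))),
                          post = mk(matrix(rnorm(20), 4)),
                          delta = mk(matrix(rnorm(20), 4))),
                     class = "feature_set")
  Z <- predict(red, newfs)
  expect_equal(ncol(Z), sum(vapply(red$sets, `[[`, 1L, "n_components")))
})

test_that("random forest CV recovers a planted signal and is deterministic", {
  set.seed(4)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- X[, 3]
  tr <- 1:140; te <- 141:200
  fit <- fit_rf_cv(X[tr, ], y[tr], rf_spec(seed = 9))
  rho <- cor(predict(fit, X[te, ]), y[te], method = "spearman")
  expect_gte(rho, 0.9)
  fit2 <- fit_rf_cv(X[tr, ], y[tr], rf_spec(seed = 9))
  expect_identical(predict(fit, X[te, ]), predict(fit2, X[te, ]))
  expect_identical(fit$oof, fit2$oof)
  expect_error(fit_rf_cv(rbind(X, NA)[1:(n + 1), ], c(y, 1)), "NaN/NA")
})

test_that("pure-noise outcomes stay inside the permutation null band", {
  set.seed(6)
  n <- 100
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- rnorm(n)
  fit <- fit_rf_cv(X, y, rf_spec(n_trees = 50L, max_depth = c(3L, 0L),
                                 seed = 9))
  rho_obs <- cor(fit$oof, y, method = "spearman")
  null_rhos <- replicate(200, cor(fit$oof, sample(y), method = "spearman"))
  band <- quantile(null_rhos, c(0.025, 0.975))
  expect_gt(rho_obs, band[1] - 0.05)
  expect_lt(rho_obs, band[2] + 0.05)
})

test_that("clinical baselines use the declared feature sets", {
  co <- fixture_cohort()
  tab <- cohort_table(co)
  expect_equal(colnames(clinical_features(tab)),
               c("post_volume_mm3", "delta_volume_mm3"))
  X5 <- clinical_features(tab, with_subtype = TRUE)
  expect_equal(ncol(X5), 5)
  expect_true(all(rowSums(X5[, 3:5]) == 1))      # one-hot sums to one
  expect_error(clinical_features(data.frame(pre_volume_mm3 = 1,
                                            post_volume_mm3 = 2),
                                 with_subtype = TRUE), "subtype")
  bad <- tab; bad$post_volume_mm3[1] <- -5
  expect_error(clinical_features(bad), "nonnegative")
})

test_that("volume-linked outcomes are recovered by the volume-only model", {
  cfg <- synthetic_config(
    n_patients = 150, seed = 23,
    rcb_link = rcb_link(volume = 1,
                        subtype = c("TN" = 0, "ER+/HER2-" = 0, "HER2+" = 0),
                        texture = 0, node_rate = 0, noise_sd = 0.2))
  tab <- cohort_table(generate_cohort(cfg))
  tr <- 1:100; te <- 101:150
  fit <- clinical_model(tab[tr, ], tab$rcb_score[tr], spec = rf_spec(seed = 5))
  rho <- cor(predict(fit, clinical_features(tab[te, ])), tab$rcb_score[te],
             method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("subtype information improves the fit when subtype shifts RCB", {
  cfg <- synthetic_config(
    n_patients = 150, seed = 29,
    rcb_link = rcb_link(volume = 1,
                        subtype = c("TN" = -1.5, "ER+/HER2-" = 1.5,
                                    "HER2+" = 0),
                        texture = 0, node_rate = 0, noise_sd = 0.1))
  tab <- cohort_table(generate_cohort(cfg))
  spec <- rf_spec(seed = 5)
  m2 <- clinical_model(tab, tab$rcb_score, with_subtype = FALSE, spec = spec)
  m5 <- clinical_model(tab, tab$rcb_score, with_subtype = TRUE, spec = spec)
  mse2 <- mean((m2$oof - tab$rcb_score)^2)
  mse5 <- mean((m5$oof - tab$rcb_score)^2)
  expect_lt(mse5, mse2)
})

test_that("all-pCR cohorts yield a constant model without failure", {
  clin <- data.frame(patient_id = sprintf("P%02d", 1:10),
                     subtype = rep(c("TN", "ER+/HER2-"), 5),
                     pre_volume_mm3 = rep(1000, 10),
                     post_volume_mm3 = rep(0, 10))
  fit <- clinical_model(clin, rep(0, 10),
                        spec = rf_spec(n_trees = 50L, max_depth = 2L,
                                       cv_folds = 2L, criterion = "mse",
                                       seed = 1))
  expect_equal(max(abs(predict(fit, clinical_features(clin)))), 0,
               tolerance = 1e-8)
})

test_that("NNLS ensemble weights match a projected-gradient oracle", {
  set.seed(8)
  n <- 60
  y <- runif(n, 0, 4)
  # one base model equals the outcome, others are noise
  P1 <- cbind(a = y, b = rnorm(n), c = rnorm(n), d = rnorm(n))
  e1 <- fit_ensemble(P1, y)
  expect_equal(unname(e1$weights), nnls_oracle(P1, y), tolerance = 1e-3)
  expect_equal(unname(e1$weights["a"]), 1, tolerance = 1e-6)
  expect_equal(unname(e1$weights[c("b", "c", "d")]), rep(0, 3),
               tolerance = 1e-6)
  # outcome orthogonal to all base predictions -> all weights zero
  P2 <- cbind(a = rep(c(1, -1), n / 2), b = rep(c(1, 1, -1, -1), n / 4))
  y2 <- rep(0, n)
  e2 <- fit_ensemble(P2, y2)
  expect_equal(unname(e2$weights), c(0, 0))
  # duplicated useful model: the split between the copies is not unique,
  # but the total weight and the fitted values match the oracle's optimum
  P3 <- cbind(a = y + rnorm(n, sd = 0.1), b = rnorm(n))
  P3 <- cbind(P3, a2 = P3[, "a"])
  e3 <- fit_ensemble(P3, y)
  w_orc <- nnls_oracle(P3, y)
  expect_equal(unname(e3$weights["a"] + e3$weights["a2"]),
               w_orc[1] + w_orc[3], tolerance = 1e-3)
  expect_equal(unname(e3$weights["a"] + e3$weights["a2"]),
               unname(fit_ensemble(P3[, 1:2], y)$weights["a"]),
               tolerance = 1e-6)
  expect_equal(as.numeric(P3 %*% e3$weights), as.numeric(P3 %*% w_orc),
               tolerance = 1e-3)
  expect_equal(predict(e3, P3), as.numeric(P3 %*% e3$weights))
  expect_error(fit_ensemble(matrix(0, 10, 3), rnorm(10)), "degenerate")
})

test_that("ensemble training loss never exceeds the best base model's", {
  set.seed(10)
  for (i in 1:5) {
    n <- 40
    y <- runif(n, 0, 4)
    P <- sapply(1:4, function(j) pmax(0, y + rnorm(n, sd = j / 2)))
    colnames(P) <- paste0("m", 1:4)
    e <- fit_ensemble(P, y)
    loss_ens <- sum((P %*% e$weights - y)^2)
    loss_best <- min(colSums((P - y)^2))
    expect_lte(loss_ens, loss_best + 1e-8)
    expect_true(all(e$weights >= 0))
    expect_identical(e$intercept, 0)
  }
})

test_that("training-side transforms are independent of test rows", {
  set.seed(12)
  mk <- function(M) {
    colnames(M) <- paste0("f", seq_len(ncol(M)))
    rownames(M) <- sprintf("P%02d", seq_len(nrow(M)))
    M
  }
  fs_train <- structure(list(pre = mk(matrix(rnorm(80), 16)),
                             post = mk(matrix(rnorm(80), 16)),
                             delta = mk(matrix(rnorm(80), 16))),
                        class = "feature_set")
  red <- fit_reduction(fs_train, variance_threshold = 1e-8)
  test_a <- structure(lapply(fs_train, function(M)
    mk(matrix(rnorm(40), 8))), class = "feature_set")
  test_b <- structure(lapply(test_a, function(M) mk(M * 100)),
                      class = "feature_set")
  red_after_a <- fit_reduction(fs_train, variance_threshold = 1e-8)
  predict(red, test_a)
  predict(red, test_b)
  # fitted statistics unchanged by anything done to test rows
  expect_identical(red$sets, red_after_a$sets)
  Za <- predict(red, test_a)
  expect_identical(Za, predict(red, test_a))
})
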