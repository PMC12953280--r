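# Spearman, AUC, DeLong inference, cross-validated AUC, associations.

test_that("spearman correlation matches rank arithmetic", {
  expect_equal(spearman_eval(1:10, 1:10)$rho, 1)
  expect_equal(spearman_eval(1:10, 10:1)$rho, -1)
  # d^2 = 4 -> rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_eval(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))$rho, 0.8)
  expect_error(spearman_eval(rep(1, 5), 1:5), "constant")
  expect_error(spearman_eval(1:2, 1:2), "length")
})

test_that("roc_auc equals brute-force pair counting", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  set.seed(14)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    scores <- round(rnorm(n), sample(c(0, 1, 3), 1))   # induce ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels))
    # orientation flag and negation agree
    expect_equal(roc_auc(scores, labels, direction = "lower"),
                 roc_auc(-scores, labels))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC of a score and its negation sum to one without ties", {
  set.seed(15)
  for (i in 1:20) {
    scores <- rnorm(25)
    labels <- c(rep(1, 10), rep(0, 15))
    expect_equal(roc_auc(scores, labels) + roc_auc(-scores, labels), 1)
  }
})

test_that("DeLong structural components match hand-enumerated placements", {
  # positives {3, 5, 7}, negatives {2, 5, 9}
  scores <- c(3, 5, 7, 2, 5, 9)
  labels <- c(1, 1, 1, 0, 0, 0)
  comp <- deepRCB:::delong_components(scores, labels)
  expect_equal(comp$v10, c(1 / 3, 0.5, 2 / 3))   # per positive vs negatives
  expect_equal(comp$v01, c(1, 0.5, 0))           # per negative vs positives
  expect_equal(comp$auc, 0.5)
  expect_equal(comp$auc, brute_auc(scores, labels))
})

test_that("DeLong CI and paired test agree with the pROC implementation", {
  set.seed(16)
  n <- 60
  labels <- rbinom(n, 1, 0.4)
  labels[1:2] <- c(0, 1)
  a <- rnorm(n) + labels
  b <- rnorm(n) + 0.5 * labels
  d <- delong(a, b, labels = labels)
  ra <- pROC::roc(labels, a, direction = "<", quiet = TRUE)
  rb <- pROC::roc(labels, b, direction = "<", quiet = TRUE)
  expect_equal(d$auc, as.numeric(pROC::auc(ra)))
  expect_equal(unname(d$ci),
               as.numeric(pROC::ci.auc(ra, method = "delong"))[c(1, 3)],
               tolerance = 1e-8)
  expect_equal(d$p,
               pROC::roc.test(ra, rb, method = "delong")$p.value,
               tolerance = 1e-8)
  # identical scores: difference 0, p = 1
  same <- delong(a, a, labels = labels)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  # symmetry of the paired p-value
  expect_equal(delong(a, b, labels = labels)$p,
               delong(b, a, labels = labels)$p)
})

test_that("DeLong CI tracks a stratified bootstrap on a fixed set", {
  set.seed(17)
  n <- 100
  labels <- rep(c(0, 1), each = n / 2)
  scores <- rnorm(n) + 0.8 * labels
  d <- delong(scores, labels = labels)
  boot <- replicate(2000, {
    i0 <- sample(which(labels == 0), replace = TRUE)
    i1 <- sample(which(labels == 1), replace = TRUE)
    roc_auc(scores[c(i0, i1)], labels[c(i0, i1)])
  })
  bci <- quantile(boot, c(0.025, 0.975))
  expect_lt(max(abs(unname(d$ci) - unname(bci))), 0.03)
})

test_that("cross-validated AUC reduces to DeLong with one fold", {
  set.seed(18)
  labels <- rbinom(80, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- rnorm(80) + labels
  cv <- cv_auc_ci(list(scores), list(labels))
  d <- delong(scores, labels = labels)
  expect_equal(cv$cvauc, d$auc, tolerance = 1e-6)
  expect_equal(cv$ci, d$ci, tolerance = 1e-6)
})

test_that("degenerate and single-class folds are handled", {
  # perfect separation in every fold
  sc <- list(c(1, 2, 10, 11), c(0, 1, 9, 12))
  lb <- list(c(0, 0, 1, 1), c(0, 0, 1, 1))
  cv <- cv_auc_ci(sc, lb)
  expect_equal(cv$cvauc, 1)
  expect_true(all(cv$ci >= 0 & cv$ci <= 1))
  # a single-class fold is merged forward with a warning
  sc2 <- list(c(1, 2), c(0, 1, 9, 12))
  lb2 <- list(c(1, 1), c(0, 0, 1, 1))
  expect_warning(cv2 <- cv_auc_ci(sc2, lb2), "merged")
  expect_equal(length(cv2$fold_aucs), 1)
})

test_that("component associations detect planted relations", {
  set.seed(19)
  n <- 90
  pcs <- cbind(PC1 = rnorm(n), PC2 = rnorm(n))
  cov_df <- data.frame(volume = pcs[, "PC1"],
                       noise = rnorm(n),
                       group = rep(c("a", "b", "c"), each = n / 3))
  tab <- pc_association(pcs, cov_df)
  r11 <- tab[tab$component == "PC1" & tab$covariate == "volume", ]
  expect_equal(r11$statistic, 1)
  expect_true(r11$flag)
  # three groups with means 0/1/2 and sd 0.1: H over the 5% critical value
  pcs2 <- cbind(PC1 = rnorm(n, rep(c(0, 1, 2), each = n / 3), 0.1))
  tab2 <- pc_association(pcs2, cov_df["group"])
  expect_gt(tab2$statistic, 5.991)
  expect_lt(tab2$p, 0.05)
  # identical group distributions: H ~ 0, p ~ 1
  pcs3 <- cbind(PC1 = rep(c(-1, 0, 1), times = 3))
  grp3 <- data.frame(g = rep(c("a", "b", "c"), each = 3))
  tab3 <- pc_association(pcs3, grp3)
  expect_lt(tab3$statistic, 1e-8)
  expect_gt(tab3$p, 0.99)
  expect_warning(pc_association(pcs, data.frame(one = rep("x", n))),
                 "single level")
})

test_that("cohort comparison applies the declared test per variable type", {
  # 2x2 with counts ((10,0),(0,10)): chi-square p < 0.001
  a <- data.frame(cls = rep("x", 10))
  b <- data.frame(cls = rep("y", 10))
  out <- cohort_compare(a, b, types = c(cls = "categorical"))
  expect_lt(out$p, 0.001)
  # identical tables: maximal p for every variable
  t1 <- data.frame(age = c(40, 50, 60, 55, 45), grade = c("1", "2", "2", "3", "1"))
  out2 <- cohort_compare(t1, t1, types = c(age = "continuous",
                                           grade = "categorical"))
  expect_true(all(out2$p > 0.99))
  expect_equal(out2$test[out2$variable == "age"], "mann-whitney")
  # declared-normal variables use the t-test; nulls are not rejected often
  set.seed(20)
  rejections <- mean(replicate(200, {
    cohort_compare(data.frame(v = rnorm(50)), data.frame(v = rnorm(50)),
                   types = c(v = "normal"))$p < 0.05
  }))
  expect_lte(rejections, 0.10)
  # missing values are dropped per variable
  t2 <- data.frame(v = c(NA, 1, 2, 3))
  out3 <- cohort_compare(t2, t2, types = c(v = "continuous"))
  expect_equal(nrow(out3), 1)
})

test_that("evaluation report enforces endpoint consistency", {
  set.seed(21)
  n <- 40
  y <- c(rep(0, 12), runif(n - 12, 0.2, 4))
  outc <- data.frame(rcb_score = y, pcr = y == 0,
                     responder = classify_rcb(y) %in% c("RCB-0", "RCB-I"))
  preds <- list(volume = y + rnorm(n, sd = 0.7),
                deep = y + rnorm(n, sd = 0.9))
  rep_tab <- evaluation_report(preds, outc, reference = "volume")
  expect_equal(nrow(rep_tab), 2)
  expect_true(all(rep_tab$auc_pcr_lo <= rep_tab$auc_pcr))
  expect_true(all(rep_tab$auc_pcr <= rep_tab$auc_pcr_hi))
  expect_true(is.na(rep_tab$p_vs_ref_pcr[rep_tab$model == "volume"]))
  expect_false(is.na(rep_tab$p_vs_ref_pcr[rep_tab$model == "deep"]))
  expect_gt(rep_tab$auc_pcr[1], 0.5)   # lower predicted RCB indicates pCR
  bad <- outc
  bad$responder[1] <- FALSE            # pcr without responder
  bad$pcr[1] <- TRUE
  expect_error(evaluation_report(preds, bad), "implies responder")
})

test_that("paired DeLong test holds its nominal size under the null", {
  set.seed(22)
  reps <- 300
  pvals <- replicate(reps, {
    base <- rnorm(60)
    labels <- rbinom(60, 1, 0.5)
    a <- base + rnorm(60, sd = 0.5)
    b <- base + rnorm(60, sd = 0.5)
    if (length(unique(labels)) < 2) return(NA_real_)
    delong(a, b, labels = labels)$p
  })
  size <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gt(size, 0.02)
  expect_lt(size, 0.09)
})
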