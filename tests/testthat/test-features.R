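# Coarse-mask downsampling, deep-feature extraction, delta sets.

test_that("overlap fractions are counted exactly on the coarse grid", {
  act <- make_activation(array(0, dim = c(2, 2, 2, 3)), c(8, 8, 8),
                         c(16, 16, 16))
  g <- array(FALSE, dim = c(16, 16, 16))
  g[1:8, 1:8, 1:8] <- TRUE                       # exactly one coarse block
  cm <- downsample_mask(tumor_mask(g, c(1, 1, 1)), act)
  expect_equal(sum(cm$grid), 1)
  expect_true(cm$grid[1, 1, 1])
  expect_equal(cm$overlap_fraction[1, 1, 1], 1)
  expect_equal(max(cm$overlap_fraction[-1]), 0)
  # full-image mask selects everything with fraction 1
  full <- downsample_mask(tumor_mask(array(TRUE, dim = c(16, 16, 16)),
                                     c(1, 1, 1)), act)
  expect_true(all(full$grid))
  expect_equal(unique(as.numeric(full$overlap_fraction)), 1)
  # empty mask selects nothing
  none <- downsample_mask(tumor_mask(array(FALSE, dim = c(16, 16, 16)),
                                     c(1, 1, 1)), act)
  expect_false(any(none$grid))
  # partial overlap counted, threshold respected
  g2 <- array(FALSE, dim = c(16, 16, 16))
  g2[1:4, 1:8, 1:8] <- TRUE                      # half of block 1
  cmt <- downsample_mask(tumor_mask(g2, c(1, 1, 1)), act, threshold = 0.6)
  expect_equal(cmt$overlap_fraction[1, 1, 1], 0.5)
  expect_false(any(cmt$grid))
  expect_error(downsample_mask(tumor_mask(array(TRUE, dim = c(8, 8, 8)),
                                          c(1, 1, 1)), act), "geometry")
})

test_that("summary statistics over selected voxels match hand arithmetic", {
  vals <- array(0, dim = c(4, 1, 1, 2))
  vals[, 1, 1, 1] <- c(1, 2, 3, 4)
  vals[, 1, 1, 2] <- c(5, 5, 5, 5)
  act <- make_activation(vals, c(1, 1, 1), c(4, 1, 1))
  cm <- downsample_mask(tumor_mask(array(TRUE, dim = c(4, 1, 1)),
                                   c(1, 1, 1)), act)
  fv <- extract_features(act, cm)
  expect_equal(unname(fv["ch01_mean"]), 2.5)
  expect_equal(unname(fv["ch01_sd"]), sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))
  expect_equal(unname(fv["ch01_sd"]), 1.118034, tolerance = 1e-6)
  expect_equal(unname(fv["ch01_min"]), 1)
  expect_equal(unname(fv["ch01_max"]), 4)
  expect_equal(unname(fv["ch01_median"]), 2.5)
  # constant channel: all statistics equal the constant, sd 0
  expect_equal(unname(fv["ch02_mean"]), 5)
  expect_equal(unname(fv["ch02_sd"]), 0)
  expect_equal(unname(fv["ch02_min"]), 5)
  expect_equal(length(fv), 2 * 5)
})

test_that("histogram features are a normalized codebook usage", {
  idx <- array(3L, dim = c(2, 2, 1))
  attr(idx, "codebook_size") <- 8L
  act <- make_activation(array(0, dim = c(2, 2, 1, 2)), c(2, 2, 1),
                         c(4, 4, 1), codebook_indices = idx)
  cm <- downsample_mask(tumor_mask(array(TRUE, dim = c(4, 4, 1)),
                                   c(1, 1, 1)), act)
  h <- extract_features(act, cm, mode = "histogram")
  expect_equal(as.numeric(h), c(0, 0, 1, 0, 0, 0, 0, 0))
  # mixed indices still sum to one and stay nonnegative
  idx2 <- array(c(1L, 2L, 2L, 7L), dim = c(2, 2, 1))
  attr(idx2, "codebook_size") <- 8L
  act2 <- make_activation(array(0, dim = c(2, 2, 1, 2)), c(2, 2, 1),
                          c(4, 4, 1), codebook_indices = idx2)
  h2 <- extract_features(act2, cm, mode = "histogram")
  expect_equal(sum(h2), 1)
  expect_true(all(h2 >= 0))
  expect_error(extract_features(make_activation(array(0, c(2, 2, 1, 2)),
                                                c(2, 2, 1), c(4, 4, 1)),
                                cm, mode = "histogram"), "codebook")
})

test_that("empty-mask fallback selects the most suspicious coarse voxel", {
  vals <- array(seq_len(2 * 2 * 2 * 1), dim = c(2, 2, 2, 1))
  act <- make_activation(vals, c(2, 2, 2), c(4, 4, 4))
  empty <- downsample_mask(tumor_mask(array(FALSE, dim = c(4, 4, 4)),
                                      c(1, 1, 1)), act)
  prob <- array(0, dim = c(4, 4, 4))
  prob[3, 3, 1] <- 0.9                     # peak inside coarse voxel (2,2,1)
  fv <- extract_features(act, empty, prob = prob)
  expect_equal(attr(fv, "fallback"), "max_prob")
  expect_equal(unname(fv["ch01_mean"]), vals[2, 2, 1, 1])
  expect_equal(unname(fv["ch01_sd"]), 0)
  # degenerate probability map falls back to global pooling
  fg <- extract_features(act, empty, prob = array(0.2, dim = c(4, 4, 4)))
  expect_equal(attr(fg, "fallback"), "global")
  expect_equal(unname(fg["ch01_mean"]), mean(vals))
  expect_error(extract_features(act, empty, fallback = "none"), "empty")
})

test_that("delta features subtract post from pre and are antisymmetric", {
  mk <- function(v) structure(setNames(v, paste0("f", seq_along(v))),
                              class = "deep_features", exam_tag = "pre",
                              fallback = "none")
  pre <- mk(c(1, 2))
  post <- mk(c(0.5, 3))
  d <- delta_features(pre, post)
  expect_equal(as.numeric(d), c(0.5, -1))
  expect_equal(attr(d, "exam_tag"), "delta")
  expect_equal(as.numeric(delta_features(pre, pre)), c(0, 0))
  set.seed(5)
  for (i in 1:10) {
    a <- mk(rnorm(6)); b <- mk(rnorm(6))
    expect_equal(as.numeric(delta_features(a, b)),
                 -as.numeric(delta_features(b, a)))
  }
  bad <- structure(setNames(c(1, 2), c("g1", "g2")), class = "deep_features")
  expect_error(delta_features(pre, bad), "labels")
})

test_that("feature sets align patients and respect input order invariance", {
  mk <- function(v, tag) structure(setNames(v, paste0("f", seq_along(v))),
                                   class = "deep_features", exam_tag = tag,
                                   fallback = "none")
  ext <- list(P2 = list(pre = mk(1:3, "pre"), post = mk(c(1, 1, 1), "post")),
              P1 = list(pre = mk(4:6, "pre"), post = mk(c(2, 2, 2), "post")),
              P3 = list(pre = mk(7:9, "pre"), post = mk(c(0, 0, 0), "post")))
  fs <- build_feature_sets(ext)
  expect_equal(rownames(fs$pre), c("P1", "P2", "P3"))
  expect_equal(dim(fs$pre), c(3L, 3L))
  expect_equal(fs$delta, fs$pre - fs$post)
  expect_equal(unname(fs$pre["P1", ]), c(4, 5, 6))
  fs2 <- build_feature_sets(ext[c("P1", "P2", "P3")])
  expect_identical(fs, fs2)
  expect_error(build_feature_sets(ext[c(1, 1)]), "duplicated")
  one <- build_feature_sets(ext["P1"])
  expect_equal(nrow(one$pre), 1L)
})

test_that("coarse selection is equivariant under one-block shifts", {
  m <- seg_model("unet3d", base_width = 2, bottleneck_channels = 4,
                 target_post = 3, seed = 1)
  m$weights <- lapply(m$weights, function(w) w * 0)
  m$weights$b3 <- c(0.3, 0.6, 0.9, 1.2)
  exam <- fixture_cohort()$patients[[2]]$pre_exam
  pr <- seg_predict(m, exam)
  g <- array(FALSE, dim = dim(exam$volumes[[1]]))
  g[5:8, 5:8, 5:8] <- TRUE
  g_shift <- array(FALSE, dim = dim(g))
  g_shift[9:12, 5:8, 5:8] <- TRUE            # one coarse block along x
  sp <- exam$spacing
  cm <- downsample_mask(tumor_mask(g, sp), pr$bottleneck)
  cms <- downsample_mask(tumor_mask(g_shift, sp), pr$bottleneck)
  sel <- which(cm$grid, arr.ind = TRUE)
  sels <- which(cms$grid, arr.ind = TRUE)
  expect_equal(sels[, 1], sel[, 1] + 1L, ignore_attr = TRUE)
  expect_equal(sels[, 2:3], sel[, 2:3], ignore_attr = TRUE)
  # constant-weight features are invariant to where the mask sits
  f1 <- extract_features(pr$bottleneck, cm)
  f2 <- extract_features(pr$bottleneck, cms)
  expect_equal(as.numeric(f1), as.numeric(f2))
})

test_that("feature vector length follows the model contract", {
  exam <- fixture_cohort()$patients[[2]]$pre_exam
  mask <- fixture_cohort()$patients[[2]]$pre_mask
  for (arch in c("unet3d", "attn-unet2d", "vqed2d")) {
    m <- seg_model(arch, base_width = 2, bottleneck_channels = 6,
                   codebook_size = 10, target_post = 3, seed = 4)
    pr <- seg_predict(m, exam)
    cm <- downsample_mask(mask, pr$bottleneck)
    if (m$is_vector_quantized) {
      fv <- extract_features(pr$bottleneck, cm, mode = "histogram")
      expect_length(fv, m$codebook_size)
    } else {
      fv <- extract_features(pr$bottleneck, cm)
      expect_length(fv, m$bottleneck_channels * 5L)
    }
    expect_false(anyDuplicated(names(fv)) > 0)
  }
})
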