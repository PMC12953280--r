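# Segmentation layer: seeded constrained region growing for ground truth,
# and three desk-scale segmentation networks exposing their bottleneck
# through a common contract.

#' Bottleneck activation block
#'
#' The activations of the most down-sampled (bottleneck) layer of a
#' segmentation network on its coarse grid, together with the geometry that
#' maps coarse voxels to blocks of input voxels. For 2D architectures the
#' per-slice coarse grids are stacked along z (z downsample factor 1).
#'
#' @param activations 4D array `[xc, yc, zc, channels]`.
#' @param downsample integer(3) per-axis downsample factors.
#' @param input_shape integer(3) shape of the (unpadded) input grid.
#' @param codebook_indices optional integer array `[xc, yc, zc]` of nearest
#'   codebook entries (vector-quantized models only).
#' @return object of class `bottleneck_activation`.
#' @export
bottleneck_activation <- function(activations, downsample, input_shape,
                                  codebook_indices = NULL) {
  d <- dim(activations)
  stopifnot(length(d) == 4L, length(downsample) == 3L)
  if (any(d[1:3] * downsample < input_shape))
    stop("coarse grid times downsample factors must cover the input grid")
  structure(list(activations = activations,
                 downsample = as.integer(downsample),
                 input_shape = as.integer(input_shape),
                 codebook_indices = codebook_indices),
            class = "bottleneck_activation")
}

#' Construct a desk-scale segmentation network
#'
#' Three architectures satisfy the same contract — a prediction yields a
#' probability grid at input resolution plus a [bottleneck_activation()]:
#' \describe{
#'   \item{`unet3d`}{3D U-Net with two pooling levels (bottleneck downsample
#'     4 per axis) and skip connections; uses all six input series.}
#'   \item{`attn-unet2d`}{2D attention-gated U-Net processing axial slices
#'     (in-plane downsample 4); uses the pre-contrast, first and fifth
#'     post-contrast series.}
#'   \item{`vqed2d`}{2D vector-quantized encoder-decoder with a discrete
#'     codebook; the bottleneck additionally reports codebook indices.}
#' }
#'
#' @param arch one of `"unet3d"`, `"attn-unet2d"`, `"vqed2d"`.
#' @param base_width channels of the first convolution.
#' @param bottleneck_channels channels at the bottleneck layer.
#' @param codebook_size codebook entries (vector-quantized model only).
#' @param target_post post-contrast series count the model requires on input
#'   (apply [carry_forward()] first).
#' @param downsample in-plane bottleneck downsample factor of the 2D
#'   architectures (2 or 4; the 3D U-Net is fixed at 4 per axis). Shallower
#'   bottlenecks leave more coarse voxels inside small tumors.
#' @param seed seed for the weight initialization.
#' @return object of class `seg_model` holding the contract fields and the
#'   initialized weights.
#' @export
seg_model <- function(arch = c("unet3d", "attn-unet2d", "vqed2d"),
                      base_width = 8L, bottleneck_channels = 16L,
                      codebook_size = 16L, target_post = 5L,
                      downsample = 4L, seed = 1L) {
  arch <- match.arg(arch)
  if (!downsample %in% c(2L, 4L)) stop("downsample must be 2 or 4")
  input_series <- switch(arch,
    unet3d = seq_len(1L + target_post),
    `attn-unet2d` = c(1L, 2L, 1L + target_post),
    vqed2d = seq_len(1L + target_post))
  cin <- length(input_series)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  wts <- init_weights(arch, cin, base_width, bottleneck_channels,
                      codebook_size)
  structure(
    list(identifier = arch,
         dimensionality = if (arch == "unet3d") "3D" else "2D",
         required_input_series = list(pre = 1L, post = as.integer(target_post)),
         input_series = input_series,
         bottleneck_channels = as.integer(bottleneck_channels),
         downsample_factors = if (arch == "unet3d") c(4L, 4L, 4L)
                              else c(as.integer(downsample),
                                     as.integer(downsample), 1L),
         is_vector_quantized = arch == "vqed2d",
         codebook_size = if (arch == "vqed2d") as.integer(codebook_size)
                         else NULL,
         base_width = as.integer(base_width),
         weights = wts, seed = as.integer(seed), trained = FALSE),
    class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> %s (%s), %d bottleneck channels, downsample %s%s%s\n",
              x$identifier, x$dimensionality, x$bottleneck_channels,
              paste(x$downsample_factors, collapse = "x"),
              if (x$is_vector_quantized)
                sprintf(", codebook %d", x$codebook_size) else "",
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}

# Stack the series a model consumes into a channel-last input array,
# z-scored per volume, zero-padded to the pooling granularity.
#' @noRd
exam_to_input <- function(model, exam) {
  need <- model$required_input_series$post
  if (n_post(exam) != need)
    stop("contract violation: model requires ", need,
         " post-contrast series, examination has ", n_post(exam),
         " (apply carry_forward first)")
  vols <- exam$volumes[model$input_series]
  norm <- lapply(vols, function(v) {
    s <- sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  })
  d <- dim(norm[[1]])
  x <- array(0, dim = c(d, length(norm)))
  for (i in seq_along(norm)) x[, , , i] <- norm[[i]]
  pad_to_multiple(x, model$downsample_factors)
}

#' @noRd
model_forward <- function(model, x) {
  f <- model$downsample_factors
  switch(model$identifier,
    unet3d = fw_unet3d(model$weights, x),
    `attn-unet2d` = fw_attn(model$weights, x, f),
    vqed2d = fw_vqed(model$weights, x, f))
}

#' @noRd
model_backward <- function(model, cache, dlogits) {
  f <- model$downsample_factors
  switch(model$identifier,
    unet3d = bw_unet3d(model$weights, cache, dlogits),
    `attn-unet2d` = bw_attn(model$weights, cache, dlogits, f),
    vqed2d = bw_vqed(model$weights, cache, dlogits, f))
}

#' Predict a tumor segmentation and expose the bottleneck
#'
#' Runs the network on a (preprocessed, carry-forwarded) examination.
#' Prediction is deterministic given fixed weights and input.
#'
#' @param model a [seg_model()].
#' @param exam a [dce_series()] with the series count the model requires.
#' @param threshold probability threshold for the binary mask.
#' @return list with `prob` (3D array in `[0, 1]` at input resolution),
#'   `mask` (a [tumor_mask()] at `threshold`) and `bottleneck`
#'   (a [bottleneck_activation()]).
#' @export
seg_predict <- function(model, exam, threshold = 0.5) {
  stopifnot(inherits(model, "seg_model"), inherits(exam, "dce_series"))
  d0 <- dim(exam$volumes[[1]])
  x <- exam_to_input(model, exam)
  fw <- model_forward(model, x)
  prob <- sigmoid(fw$logits)[, , , 1, drop = TRUE]
  dim(prob) <- dim(x)[1:3]
  prob <- prob[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
  dim(prob) <- d0
  ci <- fw$codebook_indices
  if (!is.null(ci)) attr(ci, "codebook_size") <- model$codebook_size
  bt <- bottleneck_activation(fw$bottleneck, model$downsample_factors, d0,
                              codebook_indices = ci)
  list(prob = prob,
       mask = tumor_mask(prob >= threshold, exam$spacing, exam$origin),
       bottleneck = bt)
}

#' Train a segmentation network on paired examinations and masks
#'
#' Stochastic gradient training (Adam) of the network on one examination at
#' a time, minimizing positive-weighted binary cross-entropy plus soft Dice;
#' the vector-quantized model additionally receives codebook and commitment
#' updates via the straight-through estimator. Deterministic given the model
#' seed and input order.
#'
#' @param model a [seg_model()].
#' @param exams list of [dce_series()] (carry-forwarded to the required
#'   series count automatically).
#' @param masks list of [tumor_mask()] aligned with `exams`.
#' @param epochs full passes over the training exams.
#' @param lr Adam learning rate.
#' @param verbose print the mean loss per epoch.
#' @return the trained `seg_model` with a `history` element of per-epoch
#'   mean losses.
#' @export
seg_train <- function(model, exams, masks, epochs = 4L, lr = 3e-3,
                      verbose = FALSE) {
  stopifnot(inherits(model, "seg_model"), length(exams) == length(masks),
            length(exams) >= 1L)
  state <- adam_init(model$weights)
  history <- numeric(epochs)
  need <- model$required_input_series$post
  inputs <- lapply(exams, function(e)
    exam_to_input(model, carry_forward(e, need)))
  targets <- lapply(seq_along(masks), function(i) {
    y <- pad_to_multiple(masks[[i]]$grid + 0, model$downsample_factors)
    dim(y) <- c(dim(y), 1L)
    y
  })
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(derive_seed(model$seed, "train"))
  for (ep in seq_len(epochs)) {
    ord <- sample(seq_along(inputs))
    losses <- numeric(length(ord))
    for (i in seq_along(ord)) {
      x <- inputs[[ord[i]]]
      y <- targets[[ord[i]]]
      fw <- model_forward(model, x)
      lg <- seg_loss_grad(fw$logits, y)
      losses[i] <- lg$loss
      grads <- model_backward(model, fw$cache, lg$grad)
      upd <- adam_step(model$weights, grads, state, lr = lr)
      model$weights <- upd$weights
      state <- upd$state
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
  }
  model$trained <- TRUE
  model$history <- history
  model
}

#' Dice overlap between two masks
#'
#' `2|A n B| / (|A| + |B|)`, optionally restricted to a region of interest
#' (e.g., the symptomatic breast). When both masks are empty within the
#' region the score is 1 by convention, so complete-response cases are not
#' penalized.
#'
#' @param pred,truth [tumor_mask()] objects (or 3D logical arrays) on the
#'   same grid.
#' @param roi optional binary array restricting the comparison.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(pred, truth, roi = NULL) {
  a <- if (inherits(pred, "tumor_mask")) pred$grid else pred != 0
  b <- if (inherits(truth, "tumor_mask")) truth$grid else truth != 0
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(a))) stop("roi shape differs from masks")
    a <- a & roi
    b <- b & roi
  }
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

# Shift a 3D array by an integer offset, filling with `fill`.
#' @noRd
shift_fill <- function(x, off, fill) {
  d <- dim(x)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- off[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) { dst[[a]] <- (1 + s):d[a]; src[[a]] <- 1:(d[a] - s) }
    else        { dst[[a]] <- 1:(d[a] + s); src[[a]] <- (1 - s):d[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Seeded constrained region growing
#'
#' Semi-automatic ground-truth segmentation: starting from one or more seed
#' voxels, grows through 26-connected voxels whose relative enhancement on
#' the first post-contrast series, `(post1 - pre) / pre`, exceeds
#' `threshold`, constrained to a geodesic distance of at most
#' `max_radius_mm` from the nearest seed (chamfer propagation through the
#' admissible voxels). Lowering the threshold can only enlarge the mask.
#'
#' @param series a [dce_series()].
#' @param seeds integer matrix (n x 3) of voxel indices (1-based), or a
#'   length-3 vector for a single seed.
#' @param threshold relative-enhancement inclusion threshold.
#' @param max_radius_mm maximum geodesic distance from a seed (mm).
#' @return a [tumor_mask()]; empty (with a warning) if no seed lies in an
#'   enhancing voxel.
#' @export
region_grow <- function(series, seeds, threshold = 0.5, max_radius_mm = 60) {
  stopifnot(inherits(series, "dce_series"))
  if (is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1)
  d <- dim(series$volumes[[1]])
  if (any(seeds < 1) || any(seeds > matrix(d, nrow(seeds), 3, byrow = TRUE)))
    stop("seed outside the image grid")
  pre <- series$volumes[[1]]
  post1 <- series$volumes[[2]]
  enh <- (post1 - pre) / pmax(pre, .Machine$double.eps)
  admissible <- enh > threshold
  dist <- array(Inf, dim = d)
  seeded <- FALSE
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (admissible[s[1], s[2], s[3]]) {
      dist[s[1], s[2], s[3]] <- 0
      seeded <- TRUE
    }
  }
  if (!seeded) {
    warning("no seed lies in an enhancing voxel; returning empty mask")
    return(tumor_mask(array(FALSE, dim = d), series$spacing, series$origin))
  }
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  steps <- sqrt(colSums((t(offsets) * series$spacing)^2))
  repeat {
    updated <- FALSE
    for (o in seq_len(nrow(offsets))) {
      cand <- shift_fill(dist, offsets[o, ], Inf) + steps[o]
      better <- admissible & (cand < dist) & (cand <= max_radius_mm)
      if (any(better)) {
        dist[better] <- cand[better]
        updated <- TRUE
      }
    }
    if (!updated) break
  }
  tumor_mask(is.finite(dist), series$spacing, series$origin)
}
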