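# Deep-feature extraction: map the tumor mask to the bottleneck's coarse
# grid, aggregate channel activations (or codebook usage) over the selected
# coarse voxels, and assemble pre/post/delta feature sets per patient.

#' Downsample a tumor mask to a bottleneck coarse grid
#'
#' For every coarse voxel the exact fraction of its underlying input voxels
#' inside the tumor mask is counted (no interpolation); a coarse voxel is
#' selected when that fraction exceeds `threshold`. The default threshold 0
#' selects every coarse voxel containing any part of the segmentation.
#'
#' @param mask a [tumor_mask()] on the input grid.
#' @param geometry a [bottleneck_activation()] (or its geometry) whose
#'   coarse grid the mask is mapped onto.
#' @param threshold selection threshold on the overlap fraction, in `[0, 1)`.
#' @return object of class `coarse_mask`: logical `grid` plus the
#'   `overlap_fraction` array on the coarse grid.
#' @export
downsample_mask <- function(mask, geometry, threshold = 0) {
  stopifnot(inherits(mask, "tumor_mask"),
            inherits(geometry, "bottleneck_activation"))
  f <- geometry$downsample
  cshape <- dim(geometry$activations)[1:3]
  if (any(dim(mask$grid) != geometry$input_shape))
    stop("mask grid does not match the bottleneck input geometry")
  g <- mask$grid + 0
  padded <- array(0, dim = cshape * f)
  padded[seq_len(dim(g)[1]), seq_len(dim(g)[2]), seq_len(dim(g)[3])] <- g
  counts <- sum_pool3(padded, f)
  frac <- counts / prod(f)
  structure(list(grid = frac > threshold, overlap_fraction = frac,
                 threshold = threshold),
            class = "coarse_mask")
}

#' @export
print.coarse_mask <- function(x, ...) {
  cat(sprintf("<coarse_mask> %s coarse grid, %d voxels selected\n",
              paste(dim(x$grid), collapse = "x"), sum(x$grid)))
  invisible(x)
}

#' @noRd
population_sd <- function(v) sqrt(mean((v - mean(v))^2))

.summary_stats <- list(mean = mean, sd = population_sd, min = min,
                       max = max, median = median)

#' Extract a deep-feature vector from a bottleneck activation
#'
#' In `summary` mode the configured statistics (default mean, population
#' standard deviation, minimum, maximum, median) of every bottleneck channel
#' are computed over the selected coarse voxels, giving
#' `channels x statistics` features. In `histogram` mode (vector-quantized
#' models) the normalized frequency of each codebook index over the selected
#' voxels is returned, a nonnegative vector summing to 1.
#'
#' When the coarse mask is empty (e.g., radiological complete response after
#' therapy) and `fallback` is `"max_prob"`, the single coarse voxel with the
#' highest predicted tumor probability is selected instead; if the
#' probability map is degenerate (constant), global pooling over all coarse
#' voxels is used. The engaged fallback is recorded in attribute
#' `"fallback"`.
#'
#' @param act a [bottleneck_activation()].
#' @param cmask a [downsample_mask()] result.
#' @param mode `"summary"` or `"histogram"`.
#' @param statistics named list of summary functions (summary mode).
#' @param prob optional probability grid at input resolution, required for
#'   the empty-mask fallback.
#' @param fallback `"max_prob"` (default) or `"none"` (error on empty mask).
#' @param exam_tag tag stored on the vector: `"pre"`, `"post"` or `"delta"`.
#' @return named numeric vector of class `deep_features` with attributes
#'   `exam_tag` and `fallback`.
#' @export
extract_features <- function(act, cmask, mode = c("summary", "histogram"),
                             statistics = .summary_stats, prob = NULL,
                             fallback = c("max_prob", "none"),
                             exam_tag = "pre") {
  mode <- match.arg(mode)
  fallback <- match.arg(fallback)
  stopifnot(inherits(act, "bottleneck_activation"),
            inherits(cmask, "coarse_mask"))
  cshape <- dim(act$activations)[1:3]
  if (any(dim(cmask$grid) != cshape))
    stop("coarse mask geometry does not match the activation grid")
  sel <- cmask$grid
  used_fallback <- "none"
  if (!any(sel)) {
    if (fallback == "none")
      stop("empty coarse mask and fallback disabled")
    sel <- array(FALSE, dim = cshape)
    pc <- NULL
    if (!is.null(prob)) {
      f <- act$downsample
      padded <- array(0, dim = cshape * f)
      padded[seq_len(dim(prob)[1]), seq_len(dim(prob)[2]),
             seq_len(dim(prob)[3])] <- prob
      # max-pool the probability map onto the coarse grid
      dim(padded) <- c(f[1], cshape[1], f[2], cshape[2], f[3], cshape[3])
      padded <- aperm(padded, c(1, 3, 5, 2, 4, 6))
      dim(padded) <- c(prod(f), prod(cshape))
      pc <- apply(padded, 2, max)
      dim(pc) <- cshape
    }
    if (!is.null(pc) && diff(range(pc)) > 0) {
      sel[which.max(pc)] <- TRUE
      used_fallback <- "max_prob"
    } else {
      sel[] <- TRUE
      used_fallback <- "global"
    }
  }
  if (mode == "summary") {
    K <- dim(act$activations)[4]
    am <- matrix(act$activations, prod(cshape), K)[as.logical(sel), ,
                                                   drop = FALSE]
    vals <- numeric(0)
    labels <- character(0)
    for (ch in seq_len(K)) {
      v <- am[, ch]
      for (st in names(statistics)) {
        vals <- c(vals, statistics[[st]](v))
        labels <- c(labels, sprintf("ch%02d_%s", ch, st))
      }
    }
  } else {
    if (is.null(act$codebook_indices))
      stop("histogram mode requires codebook indices (vector-quantized model)")
    S <- max(attr(act$codebook_indices, "codebook_size") %||% 0,
             max(act$codebook_indices))
    idx <- act$codebook_indices[as.logical(sel)]
    vals <- tabulate(idx, nbins = S) / length(idx)
    labels <- sprintf("code%03d", seq_len(S))
  }
  structure(setNames(vals, labels), class = "deep_features",
            exam_tag = exam_tag, fallback = used_fallback)
}

#' Delta features: pre-treatment minus post-treatment
#'
#' @param pre,post `deep_features` vectors with identical labels.
#' @return `deep_features` vector tagged `"delta"` with values
#'   `pre - post` entrywise.
#' @export
delta_features <- function(pre, post) {
  if (!identical(names(pre), names(post)))
    stop("feature labels differ between pre and post vectors")
  structure(setNames(as.numeric(pre) - as.numeric(post), names(pre)),
            class = "deep_features", exam_tag = "delta",
            fallback = "none")
}

#' Assemble per-patient feature vectors into aligned matrices
#'
#' @param extractions named list (names = patient ids), each element a list
#'   with `pre` and `post` `deep_features` vectors sharing labels.
#' @return object of class `feature_set`: matrices `pre`, `post`, `delta`
#'   (patients x features, rows ordered by patient id, `delta = pre - post`).
#' @export
build_feature_sets <- function(extractions) {
  ids <- names(extractions)
  if (is.null(ids) || any(ids == "")) stop("extractions must be named by patient id")
  if (anyDuplicated(ids)) stop("duplicated patient id: ",
                               ids[duplicated(ids)][1])
  ord <- order(ids)
  ids <- ids[ord]
  extractions <- extractions[ord]
  labels <- names(extractions[[1]]$pre)
  pre <- t(vapply(extractions, function(e) {
    if (!identical(names(e$pre), labels)) stop("inconsistent feature labels")
    as.numeric(e$pre)
  }, numeric(length(labels))))
  post <- t(vapply(extractions, function(e) {
    if (!identical(names(e$post), labels)) stop("inconsistent feature labels")
    as.numeric(e$post)
  }, numeric(length(labels))))
  dimnames(pre) <- dimnames(post) <- list(ids, labels)
  delta <- pre - post
  structure(list(pre = pre, post = post, delta = delta),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d patients x %d features (pre/post/delta)\n",
              nrow(x$pre), ncol(x$pre)))
  invisible(x)
}
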