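#' Residual cancer burden index from pathology components
#'
#' Computes the continuous residual cancer burden (RCB) score from its
#' pathology components: the invasive cellularity fraction of the tumor bed,
#' the primary tumor-bed diameter term, the number of positive lymph nodes
#' and the diameter of the largest nodal metastasis,
#' \deqn{RCB = 1.4 (f_{inv} d_{prim})^{0.17} +
#'       [4 (1 - 0.75^{LN}) d_{met}]^{0.17}.}
#' The score is 0 exactly when there is no residual invasive primary tumor
#' and no positive node (pathological complete response), and is strictly
#' increasing in each component.
#'
#' @param f_inv invasive cellularity fraction in `[0, 1]`.
#' @param d_prim primary tumor-bed diameter term in mm (nonnegative).
#' @param n_pos_nodes number of positive lymph nodes (nonnegative integer).
#' @param d_met diameter of the largest nodal metastasis in mm (nonnegative).
#' @return Nonnegative RCB score (vectorized over the inputs).
#' @examples
#' rcb_index(0, 0, 0, 0)          # pCR -> 0
#' rcb_index(0.3, 25, 2, 6)
#' @export
rcb_index <- function(f_inv, d_prim, n_pos_nodes = 0, d_met = 0) {
  if (any(f_inv < 0) || any(f_inv > 1)) stop("f_inv must lie in [0, 1]")
  if (any(d_prim < 0) || any(d_met < 0) || any(n_pos_nodes < 0))
    stop("pathology measurements must be nonnegative")
  if (any(n_pos_nodes != round(n_pos_nodes)))
    stop("n_pos_nodes must be a whole number")
  prim <- 1.4 * (f_inv * d_prim)^0.17
  nodal <- (4 * (1 - 0.75^n_pos_nodes) * d_met)^0.17
  prim + nodal
}

# Upper class boundaries for RCB-I and RCB-II; ties go to the lower class.
.rcb_breaks <- c(rcb1 = 1.36, rcb2 = 3.28)

#' Classify an RCB score into the four response categories
#'
#' RCB-0 is score exactly 0 (pathological complete response); the remaining
#' classes partition the positive axis with half-open upper bounds:
#' RCB-I is `(0, 1.36]`, RCB-II is `(1.36, 3.28]`, RCB-III is `> 3.28`.
#' A score on a boundary is assigned to the lower class.
#'
#' @param score nonnegative numeric vector of RCB scores.
#' @return factor with levels `RCB-0`, `RCB-I`, `RCB-II`, `RCB-III`.
#' @export
classify_rcb <- function(score) {
  if (any(score < 0)) stop("RCB score must be nonnegative")
  cls <- ifelse(score == 0, "RCB-0",
         ifelse(score <= .rcb_breaks[["rcb1"]], "RCB-I",
         ifelse(score <= .rcb_breaks[["rcb2"]], "RCB-II", "RCB-III")))
  factor(cls, levels = c("RCB-0", "RCB-I", "RCB-II", "RCB-III"))
}

#' RCB outcome record
#'
#' Bundles the continuous score with its derived endpoints. `pcr` (score 0)
#' and `responder` (RCB-0 or RCB-I) are implied by the score, so the
#' invariants pcr => responder and pcr <=> score == 0 hold by construction.
#'
#' @param score nonnegative RCB score.
#' @return list with `score`, `rcb_class`, `pcr`, `responder`.
#' @export
rcb_outcome <- function(score) {
  cls <- classify_rcb(score)
  list(score = score, rcb_class = cls,
       pcr = score == 0,
       responder = cls %in% c("RCB-0", "RCB-I"))
}

#' Anterior-posterior breast landmarks
#'
#' World y-coordinates (mm) of the nipple and the intermammary cleft used by
#' the anterior-posterior crop. Under the package's axis convention anterior
#' means smaller y, so `nipple_y < intermammary_cleft_y`.
#'
#' @param nipple_y anterior-posterior world coordinate (mm) of the nipple.
#' @param intermammary_cleft_y world coordinate (mm) of the intermammary cleft.
#' @return object of class `breast_landmarks`.
#' @export
breast_landmarks <- function(nipple_y, intermammary_cleft_y) {
  if (!(nipple_y < intermammary_cleft_y))
    stop("nipple must be anterior (smaller y) of the intermammary cleft")
  structure(list(nipple_y = nipple_y,
                 intermammary_cleft_y = intermammary_cleft_y),
            class = "breast_landmarks")
}

#' Outcome-link coefficients for the synthetic cohort
#'
#' The generator turns the geometric/latent state of each synthetic patient
#' into pathology components and then into an RCB score via [rcb_index()].
#' `volume` scales the residual tumor diameter into the primary tumor-bed
#' term (0 fixes the tumor-bed term at `d_prim_fixed` so residual volume
#' carries no signal); `subtype` shifts the invasive-cellularity logit per
#' receptor subtype; `texture` is the logit coefficient of the standardized
#' latent texture amplitude; `node_rate` is the Poisson mean of positive
#' nodes; `noise_sd` is the logit-scale noise on cellularity.
#'
#' @param volume scale from residual diameter (mm) to tumor-bed term.
#' @param subtype named numeric(3) of logit shifts for TN, ER+/HER2-, HER2+.
#' @param texture logit coefficient on the standardized texture amplitude.
#' @param node_rate Poisson mean of positive nodes in non-pCR patients.
#' @param noise_sd standard deviation of the cellularity logit noise.
#' @param f_inv_base baseline invasive cellularity (as a fraction).
#' @param d_prim_fixed tumor-bed term (mm) used when `volume == 0`.
#' @return list of link parameters.
#' @export
rcb_link <- function(volume = 1,
                     subtype = c("TN" = -0.5, "ER+/HER2-" = 0.4, "HER2+" = -0.2),
                     texture = 0, node_rate = 0.4, noise_sd = 0.3,
                     f_inv_base = 0.4, d_prim_fixed = 20) {
  list(volume = volume, subtype = subtype, texture = texture,
       node_rate = node_rate, noise_sd = noise_sd,
       f_inv_base = f_inv_base, d_prim_fixed = d_prim_fixed)
}

#' Configuration of the synthetic DCE-MRI cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: paired
#' pre-treatment and post-treatment DCE-MRI examinations with enhancing
#' ellipsoidal tumors, per-subtype shrinkage under therapy, a latent
#' high-frequency texture signal inside the tumor, and an RCB outcome linked
#' to residual volume, subtype and texture.
#'
#' @param n_patients number of patients.
#' @param grid_shape integer(3) voxel grid shape.
#' @param voxel_spacing numeric(3) voxel spacing in mm.
#' @param n_post_contrast post-contrast series per examination (3 to 5).
#' @param tumor_radius_range range (mm) of the baseline tumor radius.
#' @param shrinkage_model per-subtype mean log shrinkage factor and its
#'   log-scale dispersion; shrinkage is capped at 1.
#' @param enhancement_kinetics per-tissue monoexponential uptake parameters
#'   `c(amplitude, rate)` over the contrast series.
#' @param texture_amplitude_range range of the latent texture amplitude
#'   (relative intensity modulation inside the tumor).
#' @param noise_sd additive Gaussian image noise (relative intensity).
#' @param pcr_fraction fraction of patients with zero residual tumor
#'   (empty post-treatment mask, RCB score 0).
#' @param subtype_probs marginal subtype distribution (TN, ER+/HER2-, HER2+).
#' @param rcb_link outcome link, see [rcb_link()].
#' @param series_shift_mm max magnitude of the integer-voxel translation
#'   applied independently to each post-contrast volume (0 = aligned).
#' @param seed integer seed; the same configuration yields a bit-identical
#'   cohort.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 60,
                             grid_shape = c(32L, 32L, 16L),
                             voxel_spacing = c(2, 2, 2),
                             n_post_contrast = 3L,
                             tumor_radius_range = c(4, 10),
                             shrinkage_model = list(
                               mean_log = c("TN" = -1.1, "ER+/HER2-" = -0.5,
                                            "HER2+" = -0.9),
                               sd_log = 0.4),
                             enhancement_kinetics = list(
                               tumor = c(amplitude = 1.2, rate = 0.8),
                               parenchyma = c(amplitude = 0.25, rate = 0.5)),
                             texture_amplitude_range = c(0, 0.3),
                             noise_sd = 0.02,
                             pcr_fraction = 0.25,
                             subtype_probs = c("TN" = 0.34,
                                               "ER+/HER2-" = 0.37,
                                               "HER2+" = 0.29),
                             rcb_link = deepRCB::rcb_link(),
                             series_shift_mm = 0,
                             seed = 1L) {
  if (n_patients < 1) stop("n_patients must be positive")
  if (length(grid_shape) != 3L || any(grid_shape <= 0))
    stop("grid_shape must be 3 positive integers")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("voxel_spacing must be 3 positive reals")
  if (!n_post_contrast %in% 3:5)
    stop("n_post_contrast must be 3, 4 or 5")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (pcr_fraction < 0 || pcr_fraction > 1)
    stop("pcr_fraction must lie in [0, 1]")
  structure(
    list(n_patients = as.integer(n_patients),
         grid_shape = as.integer(grid_shape),
         voxel_spacing = as.numeric(voxel_spacing),
         n_post_contrast = as.integer(n_post_contrast),
         tumor_radius_range = tumor_radius_range,
         shrinkage_model = shrinkage_model,
         enhancement_kinetics = enhancement_kinetics,
         texture_amplitude_range = texture_amplitude_range,
         noise_sd = noise_sd, pcr_fraction = pcr_fraction,
         subtype_probs = subtype_probs, rcb_link = rcb_link,
         series_shift_mm = series_shift_mm, seed = as.integer(seed)),
    class = "synthetic_config")
}

# Ellipsoid membership and normalized radial coordinate on the voxel grid.
#' @noRd
ellipsoid_rho <- function(shape, spacing, center, semi_axes) {
  cx <- (seq_len(shape[1]) - 1) * spacing[1]
  cy <- (seq_len(shape[2]) - 1) * spacing[2]
  cz <- (seq_len(shape[3]) - 1) * spacing[3]
  qx <- ((cx - center[1]) / semi_axes[1])^2
  qy <- ((cy - center[2]) / semi_axes[2])^2
  qz <- ((cz - center[3]) / semi_axes[3])^2
  sqrt(outer(outer(qx, qy, `+`), qz, `+`))
}

# Band-limited random texture field: white noise smoothed by repeated
# separable box blurs (correlation length ~2 voxels per pass), standardized
# to unit variance. Models intratumoral heterogeneity at a spatial scale
# the bottleneck's coarse grid can resolve, rather than voxel-level noise.
#' @noRd
texture_noise_field <- function(shape, passes = 3L) {
  x <- array(rnorm(prod(shape)), dim = shape)
  blur1 <- function(v, axis) {
    d <- dim(v)
    idx_lo <- idx_hi <- seq_len(d[axis])
    idx_lo <- pmax(idx_lo - 1L, 1L)
    idx_hi <- pmin(idx_hi + 1L, d[axis])
    pick <- function(i) switch(axis,
      v[i, , , drop = FALSE], v[, i, , drop = FALSE], v[, , i, drop = FALSE])
    out <- (pick(idx_lo) + pick(seq_len(d[axis])) + pick(idx_hi)) / 3
    array(out, dim = d)
  }
  for (p in seq_len(passes)) for (a in 1:3) x <- blur1(x, a)
  x / sd(x)
}

# Integer-voxel circular-free shift with zero fill.
#' @noRd
shift_volume <- function(vol, shift) {
  d <- dim(vol)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) { dst[[a]] <- (1 + s):d[a]; src[[a]] <- 1:(d[a] - s) }
    else        { dst[[a]] <- 1:(d[a] + s); src[[a]] <- (1 - s):d[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

# Build the examination volumes for one time series given the anatomy.
#' @noRd
build_exam <- function(cfg, tissue, tumor_rho, texture_field, texture_amp) {
  shape <- cfg$grid_shape
  kin <- cfg$enhancement_kinetics
  in_tumor <- tumor_rho <= 1
  base <- array(0.05, dim = shape)          # air
  base[tissue] <- 1.0                       # fibroglandular tissue
  base[in_tumor] <- 1.1 * (1 + texture_amp * texture_field[in_tumor])
  # smooth enhancement rim (uptake rises towards the tumor edge) modulated
  # by the latent texture: heterogeneous contrast uptake within the tumor
  amp <- array(0, dim = shape)
  amp[tissue] <- kin$parenchyma[["amplitude"]]
  amp[in_tumor] <- kin$tumor[["amplitude"]] *
    (0.9 + 0.3 * pmin(tumor_rho[in_tumor], 1)) *
    pmax(0, 1 + texture_amp * texture_field[in_tumor])
  rate <- array(0, dim = shape)
  rate[tissue] <- kin$parenchyma[["rate"]]
  rate[in_tumor] <- kin$tumor[["rate"]]
  vols <- vector("list", 1L + cfg$n_post_contrast)
  vols[[1]] <- base + array(rnorm(prod(shape), 0, cfg$noise_sd), dim = shape)
  for (t in seq_len(cfg$n_post_contrast)) {
    vol <- base * (1 + amp * (1 - exp(-rate * t))) +
      array(rnorm(prod(shape), 0, cfg$noise_sd), dim = shape)
    if (cfg$series_shift_mm > 0) {
      smax <- max(1, round(cfg$series_shift_mm / min(cfg$voxel_spacing)))
      vol <- shift_volume(vol, sample(-smax:smax, 3, replace = TRUE))
    }
    vols[[t + 1]] <- vol
  }
  dce_series(vols, cfg$voxel_spacing)
}

#' Generate a synthetic DCE-MRI cohort with RCB outcomes
#'
#' Each patient receives a pre-treatment and a post-treatment examination
#' (enhancing ellipsoidal tumor inside a fibroglandular slab, monoexponential
#' contrast uptake, optional high-frequency texture), ground-truth masks on
#' both grids, anterior-posterior landmarks, a clinical record (subtype,
#' mask-derived volumes) and an RCB outcome. The outcome is produced by
#' constructing pathology components from the residual tumor (diameter),
#' subtype and latent texture amplitude via the configured [rcb_link()] and
#' evaluating [rcb_index()], so pCR, class and score are mutually consistent
#' by construction. A `pcr_fraction` of patients has zero residual tumor and
#' an empty post-treatment mask.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_cohort`: a list with `patients` (each
#'   holding `pre_exam`, `post_exam`, `pre_mask`, `post_mask`, `landmarks`,
#'   `clinical`, `pathology`, `outcome`) and the `config`. The caller's RNG
#'   state is left untouched.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  shape <- config$grid_shape
  sp <- config$voxel_spacing
  extent <- shape * sp
  link <- config$rcb_link
  subtypes <- names(config$subtype_probs)

  # fibroglandular slab along the anterior-posterior axis
  y_front <- 0.10 * extent[2]
  y_back <- 0.85 * extent[2]
  ycoord <- (seq_len(shape[2]) - 1) * sp[2]
  tissue <- array(FALSE, dim = shape)
  tissue[, ycoord >= y_front & ycoord <= y_back, ] <- TRUE
  landmarks <- breast_landmarks(nipple_y = y_front,
                                intermammary_cleft_y = y_front + 0.3 * extent[2])

  tr <- config$texture_amplitude_range
  tex_mid <- mean(tr)
  tex_half <- max(diff(tr) / 2, .Machine$double.eps)

  patients <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    subtype <- sample(subtypes, 1, prob = config$subtype_probs)
    r_base <- runif(1, config$tumor_radius_range[1], config$tumor_radius_range[2])
    ax_mult <- runif(3, 0.85, 1.2)
    semi_pre <- r_base * ax_mult
    margin <- max(semi_pre) + 2
    center <- c(runif(1, margin, extent[1] - margin),
                runif(1, y_front + margin, y_back - margin),
                runif(1, margin, extent[3] - margin))
    shrink <- min(1, exp(rnorm(1, config$shrinkage_model$mean_log[[subtype]],
                               config$shrinkage_model$sd_log)))
    is_pcr <- runif(1) < config$pcr_fraction
    semi_post <- if (is_pcr) c(0, 0, 0) else semi_pre * shrink
    texture_amp <- runif(1, tr[1], tr[2])
    texture_field <- texture_noise_field(shape)

    rho_pre <- ellipsoid_rho(shape, sp, center, semi_pre)
    rho_post <- if (is_pcr) array(Inf, dim = shape)
                else ellipsoid_rho(shape, sp, center, semi_post)

    pre_exam <- build_exam(config, tissue, rho_pre, texture_field, texture_amp)
    post_exam <- build_exam(config, tissue, rho_post, texture_field, texture_amp)
    pre_mask <- tumor_mask(rho_pre <= 1, sp)
    post_mask <- tumor_mask(rho_post <= 1, sp)

    # pathology components from the latent state through the outcome link
    if (is_pcr) {
      path <- list(f_inv = 0, d_prim = 0, n_pos_nodes = 0L, d_met = 0)
    } else {
      d_res <- 2 * prod(semi_post)^(1 / 3)     # equivalent-sphere diameter, mm
      d_prim <- if (link$volume > 0) link$volume * d_res else link$d_prim_fixed
      lp <- qlogis(link$f_inv_base) + link$subtype[[subtype]] +
        link$texture * (texture_amp - tex_mid) / tex_half +
        rnorm(1, 0, link$noise_sd)
      n_nodes <- if (link$node_rate > 0) rpois(1, link$node_rate) else 0L
      d_met <- if (n_nodes > 0) runif(1, 3, 12) else 0
      path <- list(f_inv = plogis(lp), d_prim = d_prim,
                   n_pos_nodes = as.integer(n_nodes), d_met = d_met)
    }
    outcome <- rcb_outcome(rcb_index(path$f_inv, path$d_prim,
                                     path$n_pos_nodes, path$d_met))
    clinical <- list(patient_id = sprintf("P%03d", p), subtype = subtype,
                     pre_volume_mm3 = mask_volume(pre_mask),
                     post_volume_mm3 = mask_volume(post_mask))
    patients[[p]] <- list(pre_exam = pre_exam, post_exam = post_exam,
                          pre_mask = pre_mask, post_mask = post_mask,
                          landmarks = landmarks, clinical = clinical,
                          pathology = path, outcome = outcome,
                          texture_amp = texture_amp)
  }
  structure(list(patients = patients, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- cohort_table(x)
  cat(sprintf("<synthetic_cohort> %d patients, %.0f%% pCR, median RCB %.2f\n",
              nrow(tab), 100 * mean(tab$pcr), median(tab$rcb_score)))
  invisible(x)
}

#' Clinical and outcome table of a synthetic cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame with one row per patient: id, subtype, mask-derived
#'   volumes (mm^3), RCB score/class, pCR and responder flags, and the
#'   latent texture amplitude.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- lapply(cohort$patients, function(p) {
    data.frame(patient_id = p$clinical$patient_id,
               subtype = p$clinical$subtype,
               pre_volume_mm3 = p$clinical$pre_volume_mm3,
               post_volume_mm3 = p$clinical$post_volume_mm3,
               rcb_score = p$outcome$score,
               rcb_class = as.character(p$outcome$rcb_class),
               pcr = p$outcome$pcr,
               responder = p$outcome$responder,
               texture_amp = p$texture_amp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
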