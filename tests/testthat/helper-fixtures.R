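# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Small default-condition cohort shared across modules.
fixture_cohort <- function() {
  memo("cohort10", function()
    generate_cohort(synthetic_config(n_patients = 10, seed = 7)))
}

# A briefly trained 3D U-Net on the shared cohort.
fixture_trained_unet <- function() {
  memo("unet", function() {
    co <- fixture_cohort()
    m <- seg_model("unet3d", base_width = 4, bottleneck_channels = 8,
                   seed = 11)
    seg_train(m, lapply(co$patients[1:6], `[[`, "pre_exam"),
              lapply(co$patients[1:6], `[[`, "pre_mask"), epochs = 3)
  })
}

# Uniformly enhancing ellipsoid examination for region-growing tests:
# pre-contrast 1 inside tissue, first post-contrast doubled inside the
# ellipsoid(s) only.
make_ellipsoid_exam <- function(shape = c(48, 48, 32), spacing = c(1, 1, 1),
                                centers = matrix(c(24, 24, 16), 1),
                                semi_axes = matrix(c(10, 8, 6), 1)) {
  pre <- array(1, dim = shape)
  post <- array(1.1, dim = shape)
  inside <- array(FALSE, dim = shape)
  for (i in seq_len(nrow(centers))) {
    rho <- deepRCB:::ellipsoid_rho(shape, spacing, centers[i, ],
                                   semi_axes[i, ])
    inside <- inside | (rho <= 1)
  }
  post[inside] <- 2
  dce_series(list(pre, post, post, post), spacing)
}

# Manually constructed bottleneck activation block.
make_activation <- function(vals, downsample, input_shape,
                            codebook_indices = NULL) {
  bottleneck_activation(vals, downsample, input_shape,
                        codebook_indices = codebook_indices)
}
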