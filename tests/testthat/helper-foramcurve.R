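# Shared fixtures, all generated in code at test time.

# A tiny deterministic pair with all three labels present.
tiny_pair <- function(dim = c(4L, 4L, 4L), id = "tiny") {
  labels <- array(0L, dim)
  labels[2, 2, 2] <- 1L
  labels[2, 3, 2] <- 1L
  labels[3, 3, 3] <- 2L
  grey <- array(1000L, dim)
  grey[labels == 1L] <- 40000L
  grey[labels == 2L] <- 12000L
  volume_pair(id, grey, labels, voxel_size_um = 1.75)
}

# A generic (asymmetric) phantom for orientation/permutation properties.
asym_pair <- function(seed = 3) {
  generate_phantom(phantom_params(
    n_chambers = 3L, chamber_radius_vox = 4, trochospire_pitch = 1.5,
    volume_shape = c(20L, 24L, 28L), infill_fraction = 0.3,
    noise_sd = 500, seed = seed), "asym")
}

# Random label grid over the three classes.
random_labels <- function(dim = c(4L, 4L, 4L)) {
  array(sample(0:2, prod(dim), replace = TRUE), dim)
}

# Desk-scale separable training world: tiny shells in 16^3 volumes with
# well-separated class intensities. Used by the training tests and the
# learning-curve acceptance criteria.
separable_population <- function(n, split, seed, noise_sd = 300,
                                 infill_fraction = 0) {
  generate_population(population_spec(
    n_specimens = n, split = split,
    n_chambers = c(2L, 3L), chamber_radius_vox = c(3.5, 4.5),
    trochospire_pitch = c(0.3, 0.8), wall_thickness_vox = c(1.6, 2.0),
    infill_fraction = infill_fraction, noise_sd = noise_sd,
    volume_shape = c(16L, 16L, 16L), seed = seed))
}

# Minimal training configuration: 8^3 patches over 16^3 volumes, a
# 2-channel U-Net, and a learning rate raised to 0.1 so the tiny network
# converges within tens of epochs on a CPU.
tiny_config <- function(...) {
  args <- list(patch_size_vox = c(8L, 8L, 8L), target_scale_vox = NULL,
               stride_vox = 8L, batch_size = 8L, base_channels = 2L,
               learning_rate = 0.1, patience_epochs = 10L,
               max_epochs = 10L, seed = 7L)
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}

# Brute-force Dice oracle: direct transcription of the definition,
# independent of the package implementation.
dice_oracle <- function(x, xp, labels = c(1L, 2L)) {
  num <- 0
  for (lab in labels) num <- num + sum(x == lab & xp == lab)
  den <- sum(x %in% labels) + sum(xp %in% labels)
  if (den == 0) return(1)
  2 * num / den
}
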