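test_that("single-chamber phantom matches analytic sphere-shell volumes", {
  r_out <- 10; wall <- 3; r_in <- r_out - wall
  p <- phantom_params(n_chambers = 1L, trochospire_pitch = 0,
                      infill_fraction = 0, noise_sd = 0,
                      chamber_radius_vox = r_out,
                      wall_thickness_vox = wall,
                      volume_shape = c(32L, 32L, 32L), seed = 5)
  ph <- generate_phantom(p)
  internal <- sum(ph$labels == 2L)
  external <- sum(ph$labels == 1L)
  expect_lt(abs(internal - 4 / 3 * pi * r_in^3) / (4 / 3 * pi * r_in^3),
            0.05)
  expect_lt(abs(external - 4 / 3 * pi * (r_out^3 - r_in^3)) /
              (4 / 3 * pi * (r_out^3 - r_in^3)), 0.05)
})

test_that("phantoms are deterministic given the seed", {
  p <- phantom_params(seed = 42, noise_sd = 900)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$grey, b$grey)
  expect_identical(a$labels, b$labels)
  d <- generate_phantom(phantom_params(seed = 43, noise_sd = 900))
  expect_false(identical(a$grey, d$grey))
})

test_that("infill creates a bimodal intensity histogram inside the cavity", {
  p <- phantom_params(n_chambers = 1L, trochospire_pitch = 0,
                      infill_fraction = 0.5, noise_sd = 0,
                      chamber_radius_vox = 10, wall_thickness_vox = 2,
                      volume_shape = c(32L, 32L, 32L), seed = 1)
  ph <- generate_phantom(p)
  vals <- ph$grey[ph$labels == 2L]
  means <- p$intensity_means
  expect_setequal(unique(vals), c(means[["cavity"]], means[["infill"]]))
  frac <- mean(vals == means[["infill"]])
  expect_equal(frac, 0.5, tolerance = 0.01)
  # labels are unaffected: infill is an intensity phenomenon only
  p0 <- p; p0$infill_fraction <- 0
  expect_identical(generate_phantom(p0)$labels, ph$labels)
})

test_that("infill dial collapses the within-shell contrast", {
  base <- list(n_chambers = 2L, chamber_radius_vox = 6,
               wall_thickness_vox = 2, noise_sd = 0,
               volume_shape = c(32L, 32L, 32L), seed = 9)
  easy <- generate_phantom(do.call(phantom_params,
                                   c(base, infill_fraction = 0)))
  hard <- generate_phantom(do.call(phantom_params,
                                   c(base, infill_fraction = 0.95)))
  gap <- function(ph) abs(mean(ph$grey[ph$labels == 1L]) -
                            mean(ph$grey[ph$labels == 2L]))
  expect_gt(gap(easy), 4 * gap(hard))
})

test_that("labelled volumes scale as the cube of the voxel size", {
  # same physical geometry sampled at double the voxel size
  fine <- phantom_params(n_chambers = 2L, chamber_radius_vox = 8,
                         wall_thickness_vox = 2.4, trochospire_pitch = 1,
                         noise_sd = 0, volume_shape = c(48L, 48L, 48L),
                         voxel_size_um = 1, seed = 3)
  coarse <- phantom_params(n_chambers = 2L, chamber_radius_vox = 4,
                           wall_thickness_vox = 1.2,
                           trochospire_pitch = 0.5, noise_sd = 0,
                           volume_shape = c(24L, 24L, 24L),
                           voxel_size_um = 2, seed = 3)
  vf <- volumetric_traits(generate_phantom(fine))
  vc <- volumetric_traits(generate_phantom(coarse))
  expect_equal(vc$total_volume_um3, vf$total_volume_um3,
               tolerance = 0.1)
})

test_that("impossible geometry errors instead of clipping", {
  expect_error(generate_phantom(phantom_params(
    n_chambers = 8L, chamber_radius_vox = 6, spiral_growth_rate = 1.5,
    wall_thickness_vox = 3, volume_shape = c(16L, 16L, 16L))),
    "cannot fit")
})

test_that("intensity validation enforces the low-contrast-infill regime", {
  expect_error(phantom_params(intensity_means = c(
    background = 3000, wall = 42000, cavity = 12000, infill = 12000)),
    "infill")
  expect_error(phantom_params(intensity_means = c(
    background = 3000, wall = 10000, cavity = 12000, infill = 9000)),
    "brighter")
})

test_that("generate_population draws a reproducible disjoint split", {
  spec <- population_spec(n_specimens = 16L, split = c(8L, 3L, 5L),
                          volume_shape = c(16L, 16L, 16L),
                          chamber_radius_vox = c(3, 4.5),
                          n_chambers = c(2L, 3L), seed = 11)
  pop <- generate_population(spec)
  expect_length(pop$train, 8L)
  expect_length(pop$val, 3L)
  expect_length(pop$test, 5L)
  ids <- vapply(c(pop$train, pop$val, pop$test),
                function(p) p$specimen_id, "")
  expect_length(unique(ids), 16L)
  pop2 <- generate_population(spec)
  expect_identical(pop2$train[[1]]$grey, pop$train[[1]]$grey)
  spec2 <- spec; spec2$seed <- 12L
  pop3 <- generate_population(spec2)
  expect_false(identical(pop3$train[[1]]$grey, pop$train[[1]]$grey))
  expect_error(population_spec(n_specimens = 10L, split = c(5L, 3L, 5L)),
               "split")
})

test_that("degenerate parameter distributions give identical geometry", {
  spec <- population_spec(n_specimens = 3L, split = c(1L, 1L, 1L),
                          n_chambers = 2L, spiral_growth_rate = 1.2,
                          trochospire_pitch = 0.5,
                          wall_thickness_vox = 2, chamber_radius_vox = 4,
                          infill_fraction = 0.2, noise_sd = 0,
                          volume_shape = c(16L, 16L, 16L), seed = 4)
  pop <- generate_population(spec)
  expect_identical(pop$train[[1]]$labels, pop$val[[1]]$labels)
  expect_identical(pop$train[[1]]$grey, pop$test[[1]]$grey)
})
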