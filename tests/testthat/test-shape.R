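test_that("a solid labelled cube meshes to its exact volume", {
  arr <- array(0L, c(12L, 12L, 12L))
  arr[2:11, 2:11, 2:11] <- 1L
  m <- extract_mesh(arr, "external", voxel_size_um = 1)
  expect_equal(mesh_volume(m), 1000)  # 10^3 voxels, exact for cuberille
  expect_identical(mesh_components(m), 1L)
  m2 <- extract_mesh(arr, 1L, voxel_size_um = 2)
  expect_equal(mesh_volume(m2), 8000)
  expect_error(extract_mesh(arr, "internal", 1), "absent")
})

test_that("a hollow shell's wall surface has two boundary components", {
  ph <- generate_phantom(phantom_params(
    n_chambers = 1L, trochospire_pitch = 0, infill_fraction = 0,
    noise_sd = 0, chamber_radius_vox = 10, wall_thickness_vox = 3,
    volume_shape = c(32L, 32L, 32L), seed = 5))
  wall <- extract_mesh(ph, "external")
  expect_identical(mesh_components(wall), 2L)  # outer + inner surface
  expect_equal(mesh_volume(wall),
               sum(ph$labels == 1L) * ph$voxel_size_um^3)
  cavity <- extract_mesh(ph, "internal")
  expect_identical(mesh_components(cavity), 1L)
})

test_that("decimation respects the face budget and preserves volume", {
  arr <- array(0L, c(40L, 40L, 40L))
  cc <- 20.5; r <- 15
  for (z in 1:40) for (y in 1:40) for (x in 1:40)
    if ((z - cc)^2 + (y - cc)^2 + (x - cc)^2 <= r^2) arr[z, y, x] <- 1L
  m <- extract_mesh(arr, "external", 1)
  expect_gt(nrow(m$faces), 5000L)
  dec <- decimate_and_smooth(m, target_faces = 500L,
                             smoothing_iterations = 10L)
  expect_lte(nrow(dec$faces), 500L)
  expect_lt(abs(mesh_volume(dec) - mesh_volume(m)) / mesh_volume(m),
            0.05)
})

test_that("decimation is a no-op below target; zero iterations skip smoothing", {
  arr <- array(0L, c(8L, 8L, 8L))
  arr[3:6, 3:6, 3:6] <- 2L
  m <- extract_mesh(arr, "internal", 1)
  out <- decimate_and_smooth(m, target_faces = 10000L,
                             smoothing_iterations = 0L)
  expect_identical(out$vertices, m$vertices)
  expect_identical(nrow(out$faces), nrow(m$faces))
})

test_that("alignment recovers a known rotation + scale exactly", {
  ph <- generate_phantom(phantom_params(seed = 3))
  ma <- extract_mesh(ph, "external", specimen_id = "a")
  ma <- decimate_and_smooth(ma, 2000L, 5L)
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0, 0, 0, 1), 3, byrow = TRUE)
  mb <- surface_mesh(ma$vertices %*% R * 2.3 + 5, ma$faces,
                     "external", "b")
  al <- align_population(list(ma, mb), "a", samples_per_mesh = 600L)
  pa <- attr(al[[1]], "sample_points")
  pb <- attr(al[[2]], "sample_points")
  j <- foramcurve:::nn_index_cpp(pb, pa)
  expect_lt(mean(sqrt(rowSums((pb - pa[j, ])^2))), 1e-3)
  expect_error(align_population(list(ma), "zz"), "not found")
})

test_that("identical meshes align to identity and score zero", {
  ph <- generate_phantom(phantom_params(seed = 4))
  ma <- extract_mesh(ph, "external", specimen_id = "a")
  mb <- surface_mesh(ma$vertices, ma$faces, "external", "b")
  mc <- surface_mesh(ma$vertices, ma$faces, "external", "c")
  al <- align_population(list(ma, mb, mc), "a", samples_per_mesh = 300L)
  expect_equal(unname(attr(al[[2]], "sample_points")),
               unname(attr(al[[1]], "sample_points")), tolerance = 1e-9)
  sc <- kpca_scores(al, n_axes = 2L)
  expect_true(all(sc$scores == 0))
  expect_true(all(is.na(sc$variance_explained)))
})

test_that("kPCA variance fractions are valid and reduce axes with warning", {
  meshes <- lapply(1:4, function(i) {
    ph <- generate_phantom(phantom_params(
      seed = i, chamber_radius_vox = 3 + 0.4 * i))
    extract_mesh(ph, "external", specimen_id = sprintf("s%d", i))
  })
  al <- align_population(meshes, "s1", samples_per_mesh = 300L)
  expect_warning(sc <- kpca_scores(al, n_axes = 5L), "reducing")
  ve <- sc$variance_explained
  expect_length(ve, 3L)
  expect_true(all(diff(ve) <= 1e-12))  # non-increasing
  expect_lte(sum(ve), 1 + 1e-9)
  expect_identical(rownames(sc$scores), sprintf("s%d", 1:4))
})

test_that("OBJ meshes round-trip", {
  dir <- withr::local_tempdir()
  arr <- array(0L, c(6L, 6L, 6L))
  arr[2:5, 2:5, 2:5] <- 1L
  m <- extract_mesh(arr, "external", 1.75, "rt")
  path <- file.path(dir, "m.obj")
  write_mesh_obj(m, path)
  back <- read_mesh_obj(path, "external", "rt")
  expect_equal(back$vertices, unname(m$vertices))
  expect_identical(back$faces, m$faces)
  expect_equal(mesh_volume(back), mesh_volume(m))
})
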