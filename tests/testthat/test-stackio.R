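test_that("volume_pair enforces its invariants", {
  p <- tiny_pair()
  expect_s3_class(p, "volume_pair")
  expect_identical(dim(p$grey), dim(p$labels))

  g <- array(0L, c(4, 4, 4))
  expect_error(volume_pair("x", g, array(0L, c(4, 4, 3)), 1.75),
               "dimension mismatch.*4x4x4.*4x4x3")
  bad <- array(0L, c(4, 4, 4)); bad[1, 1, 1] <- 7L
  expect_error(volume_pair("x", g, bad, 1.75), "unknown label code.*7")
  expect_error(volume_pair("x", g, array(0L, c(4, 4, 4)), -1),
               "voxel_size_um")
  expect_error(volume_pair("x", g, array(0L, c(4, 4, 4)), 1.75,
                           orientation_tag = "abc"), "orientation")
})

test_that("an all-background pair counts 64 background voxels", {
  g <- array(1000L, c(4L, 4L, 4L))
  p <- volume_pair("empty", g, array(0L, c(4L, 4L, 4L)), 1.75)
  expect_equal(sum(p$labels == 0L), 64L)
  expect_equal(count_foreground_slices(p), 0L)
})

test_that("write_pair/read_pair round-trips voxel-identically", {
  dir <- withr::local_tempdir()
  gp <- file.path(dir, "g.tif"); lp <- file.path(dir, "l.tif")
  for (seed in 1:3) {
    ph <- generate_phantom(phantom_params(
      volume_shape = c(10L, 12L, 14L), n_chambers = 2L,
      chamber_radius_vox = 3, seed = seed), sprintf("ph%d", seed))
    write_pair(ph, gp, lp)
    back <- read_pair(gp, lp)
    expect_identical(back$grey, ph$grey)
    expect_identical(back$labels, ph$labels)
    expect_identical(back$specimen_id, ph$specimen_id)
    expect_equal(back$voxel_size_um, ph$voxel_size_um)
  }
})

test_that("page order is the depth axis: slice k round-trips to slice k", {
  dir <- withr::local_tempdir()
  vol <- array(0L, c(5L, 3L, 4L))
  for (z in 1:5) vol[z, , ] <- z * 100L + matrix(seq_len(12), 3, 4)
  path <- file.path(dir, "v.tif")
  tiff_write_stack(vol, path, bits = 16L)
  back <- tiff_read_stack(path)
  expect_identical(back$data, vol)
  expect_equal(back$bits, 16L)
  # single-slice volume -> one-page file
  one <- file.path(dir, "one.tif")
  tiff_write_stack(vol[1, , , drop = FALSE], one, bits = 8L)
  expect_identical(dim(tiff_read_stack(one)$data), c(1L, 3L, 4L))
})

test_that("label stacks preserve exactly the distinct codes present", {
  dir <- withr::local_tempdir()
  p <- tiny_pair()
  write_pair(p, file.path(dir, "g.tif"), file.path(dir, "l.tif"))
  lab <- tiff_read_stack(file.path(dir, "l.tif"))
  expect_equal(lab$bits, 8L)
  expect_identical(sort(unique(as.vector(lab$data))), c(0L, 1L, 2L))
})

test_that("read_pair rejects mismatched shapes and foreign label codes", {
  dir <- withr::local_tempdir()
  tiff_write_stack(array(5L, c(4L, 4L, 4L)), file.path(dir, "g.tif"), 16L)
  tiff_write_stack(array(0L, c(4L, 4L, 3L)), file.path(dir, "l.tif"), 8L)
  expect_error(read_pair(file.path(dir, "g.tif"), file.path(dir, "l.tif"),
                         1.75),
               "dimension mismatch.*4x4x4.*4x4x3")
  bad <- array(0L, c(4L, 4L, 4L)); bad[2, 2, 2] <- 9L
  tiff_write_stack(bad, file.path(dir, "l2.tif"), 8L)
  expect_error(read_pair(file.path(dir, "g.tif"), file.path(dir, "l2.tif"),
                         1.75),
               "unknown label code.*9")
})

test_that("written TIFFs parse identically under an independent reader", {
  # Python tifffile (pre-installed) as format oracle for our writer
  py <- Sys.which("python")
  expect_true(nzchar(py))
  dir <- withr::local_tempdir()
  ph <- generate_phantom(phantom_params(volume_shape = c(8L, 9L, 11L),
                                        n_chambers = 1L,
                                        chamber_radius_vox = 2.6,
                                        wall_thickness_vox = 1,
                                        seed = 2), "oracle")
  gp <- file.path(dir, "g.tif")
  write_pair(ph, gp, file.path(dir, "l.tif"))
  out <- system2(py, c("-c", shQuote(paste0(
    "import tifffile, sys; a = tifffile.imread('", gp, "'); ",
    "print(a.shape, a.dtype, int(a.sum()))"))), stdout = TRUE)
  expect_equal(out, sprintf("(8, 9, 11) uint16 %d", sum(ph$grey)))
})
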