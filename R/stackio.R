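#' @useDynLib foramcurve, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif coef cor lm glm anova quasibinomial sd var prcomp setNames aggregate complete.cases
#' @importFrom utils head read.csv write.csv
NULL

# Label convention shared by every module: background = 0, external calcite
# wall = 1, internal chamber space = 2. Volumes are integer arrays indexed
# (z, y, x); an "XY image" is a constant-z slice, i.e. vol[z, , ].
LABEL_BACKGROUND <- 0L
LABEL_EXTERNAL <- 1L
LABEL_INTERNAL <- 2L
LABEL_CODES <- c(LABEL_BACKGROUND, LABEL_EXTERNAL, LABEL_INTERNAL)

#' Labels used by the three-class segmentation convention
#'
#' Background is 0, external calcite wall 1, internal chamber space 2.
#' All volumes in the package are integer arrays indexed `(z, y, x)`.
#'
#' @return Named integer vector of the three label codes.
#' @export
#' @examples
#' foram_labels()
foram_labels <- function() {
  c(background = LABEL_BACKGROUND, external = LABEL_EXTERNAL,
    internal = LABEL_INTERNAL)
}

#' Construct a paired greyscale + label volume for one specimen
#'
#' A `volume_pair` holds one specimen's greyscale scan and its
#' three-label segmentation on the same `(z, y, x)` voxel grid, together
#' with the isotropic voxel edge length in micrometres and an orientation
#' tag naming the current axis order (see [orientations()]).
#'
#' @param specimen_id Character scalar identifying the specimen.
#' @param grey Numeric or integer 3D array, intensities in the 16-bit
#'   range `[0, 65535]`.
#' @param labels Integer 3D array over codes `{0, 1, 2}` with the same
#'   dimensions as `grey`.
#' @param voxel_size_um Positive scalar, isotropic voxel size in
#'   micrometres.
#' @param orientation_tag One of the six axis-order names; default
#'   `"xyz"` (canonical).
#' @return An object of class `volume_pair`.
#' @export
volume_pair <- function(specimen_id, grey, labels, voxel_size_um,
                        orientation_tag = "xyz") {
  stopifnot(is.character(specimen_id), length(specimen_id) == 1L)
  if (!is.array(grey) || length(dim(grey)) != 3L)
    stop("'grey' must be a 3D array")
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  if (!identical(dim(grey), dim(labels)))
    stop(sprintf(
      "dimension mismatch: grey is %s but labels is %s",
      paste(dim(grey), collapse = "x"), paste(dim(labels), collapse = "x")))
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), LABEL_CODES)
  if (length(bad) > 0L)
    stop(sprintf("unknown label code(s): %s (permitted: 0, 1, 2)",
                 paste(sort(bad), collapse = ", ")))
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("'voxel_size_um' must be a positive scalar")
  if (!orientation_tag %in% ORIENTATION_NAMES)
    stop(sprintf("unknown orientation tag '%s'", orientation_tag))
  structure(
    list(specimen_id = specimen_id, grey = grey, labels = labels,
         voxel_size_um = as.numeric(voxel_size_um),
         orientation_tag = orientation_tag),
    class = "volume_pair")
}

#' @export
print.volume_pair <- function(x, ...) {
  d <- dim(x$grey)
  tab <- tabulate(as.vector(x$labels) + 1L, nbins = 3L)
  cat(sprintf(
    "<volume_pair> %s  [%d x %d x %d] (z,y,x)  voxel %.4g um  orient %s\n",
    x$specimen_id, d[1], d[2], d[3], x$voxel_size_um, x$orientation_tag))
  cat(sprintf("  background %d | external %d | internal %d voxels\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Minimal baseline multipage TIFF I/O (uncompressed, single-channel).
## No TIFF package ships with this R installation, so the subset of the
## format the pipeline needs (grey 16-bit / label 8-bit multipage stacks,
## strip layout, either byte order on read) is implemented here directly.

.tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L)

#' Write a 3D volume as an uncompressed multipage TIFF
#'
#' Page `k` of the file is the XY slice at depth `z = k`. Data are written
#' little-endian, one strip per page, photometric BlackIsZero.
#'
#' @param vol 3D numeric/integer array indexed `(z, y, x)`.
#' @param path Output file path.
#' @param bits Bits per sample: 8 or 16.
#' @return Invisibly, `path`.
#' @export
tiff_write_stack <- function(vol, path, bits = 16L) {
  stopifnot(is.array(vol), length(dim(vol)) == 3L, bits %in% c(8L, 16L))
  d <- dim(vol)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  vmax <- 2^bits - 1
  v <- as.vector(vol)
  if (any(!is.finite(v)) || any(v < 0) || any(v > vmax))
    stop(sprintf("volume values outside the %d-bit range", bits))
  bytes <- bits %/% 8L
  page_bytes <- ny * nx * bytes
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  data_off <- 8 + (seq_len(nz) - 1) * page_bytes
  ifd_off <- 8 + nz * page_bytes + (seq_len(nz) - 1) * ifd_size
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  for (z in seq_len(nz)) {
    page <- as.integer(round(t(vol[z, , , drop = TRUE])))
    # t() turns the (y, x) slice column-major order into row-major scanlines
    writeBin(page, con, size = bytes, endian = "little")
  }
  wentry <- function(tag, type, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (type == .tiff_types[["SHORT"]]) {
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (z in seq_len(nz)) {
    writeBin(n_entries, con, size = 2, endian = "little")
    wentry(256L, 4L, nx)                 # ImageWidth
    wentry(257L, 4L, ny)                 # ImageLength
    wentry(258L, 3L, bits)               # BitsPerSample
    wentry(259L, 3L, 1L)                 # Compression: none
    wentry(262L, 3L, 1L)                 # Photometric: BlackIsZero
    wentry(273L, 4L, data_off[z])        # StripOffsets
    wentry(277L, 3L, 1L)                 # SamplesPerPixel
    wentry(278L, 4L, ny)                 # RowsPerStrip
    wentry(279L, 4L, page_bytes)         # StripByteCounts
    wentry(339L, 3L, 1L)                 # SampleFormat: unsigned int
    nxt <- if (z < nz) ifd_off[z + 1] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read an uncompressed multipage TIFF into a 3D volume
#'
#' Supports baseline single-channel uncompressed TIFFs (8-, 16- or 32-bit
#' unsigned integer samples, strip layout, either byte order). Page `k`
#' becomes the XY slice at depth `z = k`.
#'
#' @param path File path.
#' @return List with `data` (integer array indexed `(z, y, x)`) and
#'   `bits` (bits per sample).
#' @export
tiff_read_stack <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file (truncated header)")
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark)"))
  rd <- function(off, size, n = 1L) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = FALSE, endian = endian)
  }
  rd32 <- function(off, n = 1L) {  # unsigned 32-bit as double
    lo <- rd(off, 2L, 2L * n)
    idx <- seq_len(n) * 2L
    if (endian == "little") lo[idx - 1L] + 65536 * lo[idx]
    else 65536 * lo[idx - 1L] + lo[idx]
  }
  if (rd(2, 2) != 42L) stop("not a TIFF file (bad magic number)")
  ifd_off <- rd32(4)
  pages <- list()
  while (ifd_off != 0) {
    n_entries <- rd(ifd_off, 2)
    tags <- list()
    for (i in seq_len(n_entries)) {
      eoff <- ifd_off + 2 + (i - 1) * 12
      tag <- rd(eoff, 2); type <- rd(eoff + 2, 2); count <- rd32(eoff + 4)
      tsize <- c(1, 1, 2, 4)[type]
      if (is.na(tsize)) next
      voff <- if (count * tsize > 4) rd32(eoff + 8) else eoff + 8
      vals <- if (type == 4L) rd32(voff, count) else rd(voff, tsize, count)
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    nx <- g(256); ny <- g(257)
    bits <- g(258, 1L)[1]
    if (!is.null(g(259)) && g(259) != 1L)
      stop("compressed TIFF not supported (only baseline uncompressed)")
    if (!is.null(g(277)) && g(277) != 1L)
      stop("multi-sample TIFF not supported (single channel only)")
    if (!bits %in% c(8, 16, 32))
      stop(sprintf("unsupported bit depth: %d", bits))
    strip_off <- g(273); strip_cnt <- g(279)
    if (is.null(nx) || is.null(ny) || is.null(strip_off))
      stop("malformed TIFF: missing required tags")
    if (is.null(strip_cnt)) strip_cnt <- nx * ny * (bits %/% 8)
    bytes <- bits %/% 8
    vals <- unlist(lapply(seq_along(strip_off), function(s) {
      nvals <- strip_cnt[s] %/% bytes
      if (bytes == 4L) rd32(strip_off[s], nvals)
      else rd(strip_off[s], bytes, nvals)
    }))
    if (length(vals) != nx * ny)
      stop("malformed TIFF: strip data does not match page size")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = ny, byrow = TRUE)
    ifd_off <- rd32(ifd_off + 2 + n_entries * 12)
  }
  if (length(pages) == 0L) stop("TIFF contains no pages")
  dms <- unique(t(vapply(pages, dim, integer(2))))
  if (nrow(dms) != 1L) stop("TIFF pages differ in shape")
  ny <- dms[1, 1]; nx <- dms[1, 2]
  vol <- array(0L, dim = c(length(pages), ny, nx))
  for (z in seq_along(pages)) vol[z, , ] <- pages[[z]]
  list(data = vol, bits = as.integer(bits))
}

.sidecar_path <- function(grey_path) {
  paste0(sub("\\.tiff?$", "", grey_path, ignore.case = TRUE), ".meta.txt")
}

.write_sidecar <- function(path, fields) {
  writeLines(sprintf("%s: %s", names(fields), vapply(fields, format, "")),
             path)
}

.read_sidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):[[:space:]]*(.*)$", lines))
  out <- lapply(kv, function(m) trimws(m[3]))
  names(out) <- vapply(kv, function(m) trimws(m[2]), "")
  out
}

#' Read a paired greyscale + label stack from disk
#'
#' Both files must be multipage TIFFs of identical page count and page
#' shape. Label codes outside the `{0, 1, 2}` convention raise an error
#' naming the offending codes; they are never silently remapped. 8-bit
#' greyscale input is rescaled to the 16-bit range on read.
#'
#' @param grey_path Path to the greyscale stack (16-bit expected).
#' @param label_path Path to the label stack (8-bit expected).
#' @param voxel_size_um Isotropic voxel size in micrometres. If `NULL`,
#'   taken from the plain-text sidecar written by [write_pair()].
#' @param specimen_id Optional specimen identifier; defaults to the
#'   sidecar value or the greyscale file stem.
#' @return A [volume_pair()].
#' @export
read_pair <- function(grey_path, label_path, voxel_size_um = NULL,
                      specimen_id = NULL) {
  grey <- tiff_read_stack(grey_path)
  lab <- tiff_read_stack(label_path)
  if (!identical(dim(grey$data), dim(lab$data)))
    stop(sprintf(
      "dimension mismatch: grey stack is %s but label stack is %s",
      paste(dim(grey$data), collapse = "x"),
      paste(dim(lab$data), collapse = "x")))
  g <- grey$data
  if (grey$bits == 8L) g <- g * 257L  # normalize 8-bit grey to 16-bit range
  meta <- .read_sidecar(.sidecar_path(grey_path))
  if (is.null(voxel_size_um)) {
    if (is.null(meta$voxel_size_um))
      stop("voxel_size_um not given and no sidecar metadata found")
    voxel_size_um <- as.numeric(meta$voxel_size_um)
  }
  if (is.null(specimen_id)) {
    specimen_id <- if (!is.null(meta$specimen_id)) meta$specimen_id
      else sub("\\.tiff?$", "", basename(grey_path), ignore.case = TRUE)
  }
  orientation <- if (!is.null(meta$orientation_tag)) meta$orientation_tag
    else "xyz"
  volume_pair(specimen_id, g, lab$data, voxel_size_um, orientation)
}

#' Write a paired greyscale + label stack to disk
#'
#' Greyscale goes out as a 16-bit multipage TIFF, labels as 8-bit; page
#' `k` of each file is the XY slice at depth `k`. A plain-text sidecar
#' (`<grey stem>.meta.txt`) records `specimen_id`, `voxel_size_um` and
#' `orientation_tag`.
#'
#' @param pair A [volume_pair()].
#' @param grey_path,label_path Output paths.
#' @return Invisibly, a character vector of the files written.
#' @export
write_pair <- function(pair, grey_path, label_path) {
  stopifnot(inherits(pair, "volume_pair"))
  tiff_write_stack(pair$grey, grey_path, bits = 16L)
  tiff_write_stack(pair$labels, label_path, bits = 8L)
  sc <- .sidecar_path(grey_path)
  .write_sidecar(sc, list(specimen_id = pair$specimen_id,
                          voxel_size_um = pair$voxel_size_um,
                          orientation_tag = pair$orientation_tag))
  invisible(c(grey_path, label_path, sc))
}
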