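# Axis-order data augmentation: every specimen can be presented to the
# network in the six orderings of its three axes. The orientation name
# "abc" means: the new x axis shows the original axis a, the new y axis
# the original b, the new z axis the original c ("xyz" = identity).

ORIENTATION_NAMES <- c("xyz", "yzx", "zyx", "xzy", "yxz", "zxy")

.axis_dim <- c(x = 3L, y = 2L, z = 1L)  # arrays are indexed (z, y, x)

#' The six axis-order orientations
#'
#' @return Character vector of the six orientation names. The first,
#'   `"xyz"`, is the identity; the other five are the non-identity axis
#'   permutations used for data augmentation.
#' @export
orientations <- function() ORIENTATION_NAMES

#' Axis permutation realizing an orientation
#'
#' Returns the permutation `p` such that `aperm(vol, p)` applied to a
#' `(z, y, x)`-indexed array presents the volume in orientation `name`.
#'
#' @param name Orientation name.
#' @return Integer vector of length 3 for use with [aperm()].
#' @export
orientation_permutation <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% ORIENTATION_NAMES)
    stop(sprintf("unknown orientation name '%s'", as.character(name)[1]))
  letters3 <- strsplit(name, "")[[1]]
  # new dim order is (z, y, x) = letters 3, 2, 1 of the name
  unname(.axis_dim[letters3[c(3L, 2L, 1L)]])
}

#' Inverse of an orientation
#'
#' `reorient(reorient(p, o), orientation_inverse(o))` restores `p` for
#' every orientation `o`.
#'
#' @param name Orientation name.
#' @return The orientation name whose permutation inverts `name`'s.
#' @export
orientation_inverse <- function(name) {
  p <- orientation_permutation(name)
  inv <- order(p)
  for (cand in ORIENTATION_NAMES)
    if (identical(orientation_permutation(cand), inv)) return(cand)
  stop("internal error: orientation group not closed")  # unreachable
}

#' Reorient a volume pair into another axis order
#'
#' Both channels are permuted by the same axis permutation, so the voxel
#' multiset — and hence every per-label count and volumetric trait — is
#' unchanged. Three of the five non-identity axis permutations are
#' improper (mirror) transforms; with `proper = TRUE` one axis is
#' reversed after permuting so that every orientation is a proper
#' rotation (default off: plain axis reordering).
#'
#' @param pair A [volume_pair()].
#' @param name Target orientation name, interpreted relative to the
#'   canonical `"xyz"` frame.
#' @param proper Logical; reverse an axis after odd permutations so the
#'   transform has determinant +1.
#' @return The reoriented [volume_pair()] with its `orientation_tag` set.
#' @export
reorient <- function(pair, name, proper = FALSE) {
  stopifnot(inherits(pair, "volume_pair"))
  p <- orientation_permutation(name)
  g <- aperm(pair$grey, p)
  l <- aperm(pair$labels, p)
  if (proper && .perm_sign(p) < 0) {  # mirror -> flip new x to restore parity
    g <- g[, , dim(g)[3]:1, drop = FALSE]
    l <- l[, , dim(l)[3]:1, drop = FALSE]
  }
  volume_pair(pair$specimen_id, g, l, pair$voxel_size_um,
              orientation_tag = name)
}

.perm_sign <- function(p) {
  s <- 1L
  for (i in 1:2) for (j in (i + 1):3) if (p[i] > p[j]) s <- -s
  s
}

#' Augment a training set with all six axis orders
#'
#' Expands `N` canonical-orientation specimens into `6 N` pairs: the
#' originals first (in input order), then each non-identity orientation
#' in alphabetical name order, stable in specimen order. Feeding an
#' already augmented set (any non-`"xyz"` tag) is an error, preventing
#' accidental double augmentation.
#'
#' @param pairs List of [volume_pair()]s in canonical `"xyz"` orientation.
#' @param proper Passed to [reorient()].
#' @return List of `6 * length(pairs)` volume pairs.
#' @export
augment_set <- function(pairs, proper = FALSE) {
  stopifnot(is.list(pairs))
  if (length(pairs) == 0L) return(list())
  tags <- vapply(pairs, function(p) p$orientation_tag, "")
  if (any(tags != "xyz"))
    stop(sprintf(
      "input already augmented: found orientation tag(s) %s (expected all 'xyz')",
      paste(unique(tags[tags != "xyz"]), collapse = ", ")))
  extra <- sort(setdiff(ORIENTATION_NAMES, "xyz"))
  out <- pairs
  for (o in extra)
    out <- c(out, lapply(pairs, reorient, name = o, proper = proper))
  out
}

#' Count foreground XY slices of a volume pair
#'
#' The number of constant-z slices containing at least one non-background
#' label voxel — the per-stack quantity behind "number of foreground
#' images" accounting of augmented training sets.
#'
#' @param pair A [volume_pair()].
#' @return Integer count.
#' @export
count_foreground_slices <- function(pair) {
  stopifnot(inherits(pair, "volume_pair"))
  fg <- pair$labels != LABEL_BACKGROUND
  sum(apply(fg, 1L, any))
}
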