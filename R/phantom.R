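# Synthetic phantom generator. Stands in for the micro-CT scans and their
# manual segmentations: lenticular trochospiral multi-chamber shells with
# a bright calcite wall, a dark internal cavity partly filled by sediment
# whose density is close to that of the wall, Gaussian imaging noise, and
# specimen-to-specimen variation in size and shape across a population.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Parameters of a single synthetic shell phantom
#'
#' Chambers are spheres of geometrically growing radius placed along a
#' logarithmic spiral with an axial (trochospiral) rise; successive
#' chambers overlap so the cavity is connected. The wall is the set of
#' voxels inside the union of the outer chamber spheres but outside the
#' union of the cavity spheres (outer radius minus `wall_thickness_vox`).
#' A fraction of the cavity is "sediment infill": it keeps the internal
#' label (as a human annotator labels sediment-filled cavity internal)
#' but takes an intensity close to the wall's, which is what makes the
#' internal structure hard to segment at high infill.
#'
#' @param n_chambers Integer >= 1, number of chambers.
#' @param spiral_growth_rate Chamber-radius multiplier per chamber (> 1).
#' @param trochospire_pitch Axial rise per chamber, voxels (>= 0).
#' @param wall_thickness_vox Wall thickness in voxels (>= 1).
#' @param chamber_radius_vox Radius of the first (smallest) chamber,
#'   voxels.
#' @param angle_step_deg Angular advance per chamber along the spiral.
#' @param infill_fraction Fraction of cavity voxels filled with
#'   sediment-like material, in `[0, 1]`. Infill accumulates from the
#'   bottom of the volume upwards, as settled sediment does.
#' @param intensity_means Named numeric vector with entries `background`,
#'   `wall`, `cavity`, `infill` (16-bit intensity units). The wall must
#'   be brighter than the cavity, and the infill mean must sit close to
#'   the wall mean relative to the wall-cavity contrast.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (clamped to the 16-bit range).
#' @param volume_shape Integer triple `(nz, ny, nx)`.
#' @param voxel_size_um Isotropic voxel size, micrometres.
#' @param seed Integer seed; the phantom is deterministic given it.
#' @param max_infill_wall_contrast Upper bound on
#'   `|wall - infill| / (wall - cavity)`; guards the low-contrast-infill
#'   regime the generator exists to emulate.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(n_chambers = 6L,
                           spiral_growth_rate = 1.18,
                           trochospire_pitch = 1.2,
                           wall_thickness_vox = 2,
                           chamber_radius_vox = 3.5,
                           angle_step_deg = 80,
                           infill_fraction = 0.3,
                           intensity_means = c(background = 3000,
                                               wall = 42000,
                                               cavity = 12000,
                                               infill = 38000),
                           noise_sd = 800,
                           volume_shape = c(64L, 64L, 64L),
                           voxel_size_um = 1.75,
                           seed = 1L,
                           max_infill_wall_contrast = 0.35) {
  p <- list(n_chambers = as.integer(n_chambers),
            spiral_growth_rate = spiral_growth_rate,
            trochospire_pitch = trochospire_pitch,
            wall_thickness_vox = wall_thickness_vox,
            chamber_radius_vox = chamber_radius_vox,
            angle_step_deg = angle_step_deg,
            infill_fraction = infill_fraction,
            intensity_means = intensity_means,
            noise_sd = noise_sd,
            volume_shape = as.integer(volume_shape),
            voxel_size_um = voxel_size_um,
            seed = as.integer(seed),
            max_infill_wall_contrast = max_infill_wall_contrast)
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  stopifnot(p$n_chambers >= 1L, p$spiral_growth_rate > 1,
            p$trochospire_pitch >= 0, p$wall_thickness_vox >= 1,
            p$chamber_radius_vox > 0,
            p$infill_fraction >= 0, p$infill_fraction <= 1,
            p$noise_sd >= 0, length(p$volume_shape) == 3L,
            all(p$volume_shape >= 8L), p$voxel_size_um > 0)
  m <- p$intensity_means
  need <- c("background", "wall", "cavity", "infill")
  if (!all(need %in% names(m)))
    stop("intensity_means must name background, wall, cavity, infill")
  if (m[["wall"]] <= m[["cavity"]])
    stop("intensity_means: wall must be brighter than cavity")
  rel <- abs(m[["wall"]] - m[["infill"]]) / (m[["wall"]] - m[["cavity"]])
  if (rel > p$max_infill_wall_contrast)
    stop(sprintf(
      "intensity_means: infill-wall contrast (%.2f of wall-cavity) exceeds %.2f; infill must emulate sediment of near-calcite density",
      rel, p$max_infill_wall_contrast))
  invisible(p)
}

# Chamber centres and radii in voxel units, before fitting to the volume.
.phantom_geometry <- function(p) {
  i <- seq_len(p$n_chambers) - 1
  r <- p$chamber_radius_vox * p$spiral_growth_rate^i
  theta <- i * p$angle_step_deg * pi / 180
  # spiral radius proportional to chamber radius keeps successive
  # chambers overlapping at every growth rate
  a <- 0.9 * r
  cx <- a * cos(theta)
  cy <- a * sin(theta)
  cz <- p$trochospire_pitch * i
  centre <- cbind(z = cz - mean(range(cz)),
                  y = cy - mean(range(cy)),
                  x = cx - mean(range(cx)))
  list(centre = centre, radius = r)
}

#' Generate one synthetic specimen
#'
#' Builds the shell geometry, fits it inside the requested volume
#' (shrinking uniformly if needed — never clipping silently), rasterizes
#' wall and cavity labels, assigns per-class intensities with bottom-up
#' sediment infill, and adds Gaussian noise. Deterministic given
#' `params$seed`.
#'
#' @param params A [phantom_params()].
#' @param specimen_id Identifier for the resulting pair.
#' @return A [volume_pair()]; the attribute `"fitted_scale"` records the
#'   shrink factor applied to fit the volume (1 = untouched).
#' @export
generate_phantom <- function(params, specimen_id = "phantom") {
  validate_phantom_params(params)
  p <- params
  geom <- .phantom_geometry(p)
  shp <- p$volume_shape
  half <- (shp - 1) / 2
  margin <- 1.5
  ext <- vapply(1:3, function(ax)
    max(abs(geom$centre[, ax]) + geom$radius), 0)
  scale <- min(1, min((half - margin) / ext))
  if (scale < 1) {
    geom$centre <- geom$centre * scale
    geom$radius <- geom$radius * scale
  }
  if (min(geom$radius) <= p$wall_thickness_vox)
    stop(sprintf(
      "chambers cannot fit: smallest chamber radius %.2f vox does not exceed wall thickness %.2f vox after fitting (scale %.3f)",
      min(geom$radius), p$wall_thickness_vox, scale))
  nz <- shp[1]; ny <- shp[2]; nx <- shp[3]
  zc <- (seq_len(nz) - 1) - half[1]
  yc <- (seq_len(ny) - 1) - half[2]
  xc <- (seq_len(nx) - 1) - half[3]
  Z <- array(zc, dim = shp)
  Y <- array(rep(yc, each = nz), dim = shp)
  X <- array(rep(xc, each = nz * ny), dim = shp)
  outer_m <- array(FALSE, dim = shp)
  inner_m <- array(FALSE, dim = shp)
  for (k in seq_len(p$n_chambers)) {
    d2 <- (Z - geom$centre[k, "z"])^2 + (Y - geom$centre[k, "y"])^2 +
      (X - geom$centre[k, "x"])^2
    outer_m <- outer_m | (d2 <= geom$radius[k]^2)
    rin <- geom$radius[k] - p$wall_thickness_vox
    inner_m <- inner_m | (d2 <= rin^2)
  }
  labels <- array(LABEL_BACKGROUND, dim = shp)
  labels[outer_m & !inner_m] <- LABEL_EXTERNAL
  labels[inner_m] <- LABEL_INTERNAL
  m <- p$intensity_means
  grey <- array(m[["background"]], dim = shp)
  grey[labels == LABEL_EXTERNAL] <- m[["wall"]]
  grey[labels == LABEL_INTERNAL] <- m[["cavity"]]
  if (p$infill_fraction > 0) {
    idx <- which(labels == LABEL_INTERNAL)  # column-major: z fastest
    if (length(idx) > 0L) {
      zpos <- Z[idx]
      ord <- order(zpos, idx)  # fill from the bottom of the volume up
      k <- round(p$infill_fraction * length(idx))
      grey[idx[ord[seq_len(k)]]] <- m[["infill"]]
    }
  }
  grey <- .with_seed(p$seed, {
    if (p$noise_sd > 0) grey + rnorm(length(grey), sd = p$noise_sd)
    else grey
  })
  grey <- array(as.integer(pmin(65535, pmax(0, round(grey)))), dim = shp)
  out <- volume_pair(specimen_id, grey, labels, p$voxel_size_um)
  attr(out, "fitted_scale") <- scale
  out
}

#' Specification of a synthetic population
#'
#' Per-specimen phantom parameters are drawn independently from the
#' uniform ranges given here (a length-2 numeric for a range, a scalar
#' for a fixed value), emulating inter-specimen variation in size, shape
#' and degree of sediment infill. Defaults give a 50-specimen
#' population split 20 / 10 / 20 into training, validation and test
#' pools.
#'
#' @param n_specimens Total number of specimens.
#' @param split Integer triple `(n_train, n_val, n_test)`; must sum to
#'   `n_specimens`.
#' @param n_chambers Integer range for the chamber count.
#' @param spiral_growth_rate,trochospire_pitch,wall_thickness_vox,
#'   chamber_radius_vox,infill_fraction Ranges (or scalars) for the
#'   corresponding [phantom_params()] fields.
#' @param intensity_means,noise_sd,volume_shape,voxel_size_um Fixed
#'   acquisition-level settings shared by all specimens.
#' @param seed Population seed; specimen seeds are derived from it.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_specimens = 50L,
                            split = c(20L, 10L, 20L),
                            n_chambers = c(4L, 8L),
                            spiral_growth_rate = c(1.12, 1.24),
                            trochospire_pitch = c(0.6, 1.8),
                            wall_thickness_vox = c(1.5, 2.5),
                            chamber_radius_vox = c(2.8, 4.2),
                            infill_fraction = c(0.1, 0.5),
                            intensity_means = c(background = 3000,
                                                wall = 42000,
                                                cavity = 12000,
                                                infill = 38000),
                            noise_sd = 800,
                            volume_shape = c(64L, 64L, 64L),
                            voxel_size_um = 1.75,
                            seed = 1L) {
  split <- as.integer(split)
  if (length(split) != 3L || sum(split) != n_specimens)
    stop(sprintf(
      "split (%s) must be three integers summing to n_specimens (%d)",
      paste(split, collapse = ", "), n_specimens))
  structure(list(n_specimens = as.integer(n_specimens), split = split,
                 n_chambers = n_chambers,
                 spiral_growth_rate = spiral_growth_rate,
                 trochospire_pitch = trochospire_pitch,
                 wall_thickness_vox = wall_thickness_vox,
                 chamber_radius_vox = chamber_radius_vox,
                 infill_fraction = infill_fraction,
                 intensity_means = intensity_means, noise_sd = noise_sd,
                 volume_shape = as.integer(volume_shape),
                 voxel_size_um = voxel_size_um, seed = as.integer(seed)),
            class = "population_spec")
}

.draw_range <- function(rng, integer = FALSE) {
  if (length(rng) == 1L) return(rng)
  v <- runif(1, rng[1], rng[2])
  if (integer) as.integer(round(v)) else v
}

#' Generate a synthetic population with a train/validation/test split
#'
#' @param spec A [population_spec()].
#' @return List with elements `train`, `val`, `test` (lists of
#'   [volume_pair()]s) and `manifest` (data frame of specimen id, split
#'   and the drawn per-specimen parameters).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_specimens
  draws <- .with_seed(spec$seed, {
    lapply(seq_len(n), function(i) {
      list(n_chambers = .draw_range(spec$n_chambers, integer = TRUE),
           spiral_growth_rate = .draw_range(spec$spiral_growth_rate),
           trochospire_pitch = .draw_range(spec$trochospire_pitch),
           wall_thickness_vox = .draw_range(spec$wall_thickness_vox),
           chamber_radius_vox = .draw_range(spec$chamber_radius_vox),
           infill_fraction = .draw_range(spec$infill_fraction),
           seed = (spec$seed * 10007L + i * 131L) %% 2147483647L)
    })
  })
  ids <- sprintf("sp%03d", seq_len(n))
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draws[[i]]
    pp <- phantom_params(
      n_chambers = d$n_chambers,
      spiral_growth_rate = d$spiral_growth_rate,
      trochospire_pitch = d$trochospire_pitch,
      wall_thickness_vox = d$wall_thickness_vox,
      chamber_radius_vox = d$chamber_radius_vox,
      infill_fraction = d$infill_fraction,
      intensity_means = spec$intensity_means,
      noise_sd = spec$noise_sd,
      volume_shape = spec$volume_shape,
      voxel_size_um = spec$voxel_size_um,
      seed = d$seed)
    pairs[[i]] <- generate_phantom(pp, specimen_id = ids[i])
  }
  splits <- rep(c("train", "val", "test"), times = spec$split)
  manifest <- data.frame(
    specimen_id = ids, split = splits,
    n_chambers = vapply(draws, `[[`, 0L, "n_chambers"),
    spiral_growth_rate = vapply(draws, `[[`, 0, "spiral_growth_rate"),
    trochospire_pitch = vapply(draws, `[[`, 0, "trochospire_pitch"),
    wall_thickness_vox = vapply(draws, `[[`, 0, "wall_thickness_vox"),
    chamber_radius_vox = vapply(draws, `[[`, 0, "chamber_radius_vox"),
    infill_fraction = vapply(draws, `[[`, 0, "infill_fraction"),
    seed = vapply(draws, function(d) as.numeric(d$seed), 0))
  list(train = pairs[splits == "train"],
       val = pairs[splits == "val"],
       test = pairs[splits == "test"],
       manifest = manifest)
}
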