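# Orchestration of the experimental design and statistics: the
# training-set-size sweep crossed with augmentation, the early-stopping
# comparison, the Dice-versus-size GLM, manual-versus-network agreement
# regressions, and minimum-specimen determination.

#' Experimental design for the learning-curve sweep
#'
#' Defaults follow the full-scale design: training-set sizes 1, 2, 4, 8,
#' 16, 20 drawn from a 20-specimen pool, both an original and an
#' augmented arm, three replicate networks per cell, and a 0.95 accuracy
#' threshold for the minimum-specimen question. [desk_design()] scales
#' the sweep to sizes 1-2-4-8 on an 8-specimen pool.
#'
#' @param sizes Increasing integer vector of training-set sizes.
#' @param arms Character subset of `c("original", "augmented")`.
#' @param n_replicates Replicates per (size, arm) cell.
#' @param accuracy_threshold Dice threshold defining "accurate enough".
#' @param nesting If `TRUE` (default) smaller training sets are nested
#'   inside larger ones along one fixed seeded ordering of the pool;
#'   otherwise each size is sampled independently.
#' @param seed Design seed (pool ordering, per-cell training seeds).
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(sizes = c(1L, 2L, 4L, 8L, 16L, 20L),
                              arms = c("original", "augmented"),
                              n_replicates = 3L,
                              accuracy_threshold = 0.95,
                              nesting = TRUE,
                              seed = 1L) {
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) >= 1L, all(diff(sizes) > 0L), all(sizes >= 1L),
            accuracy_threshold > 0, accuracy_threshold < 1,
            n_replicates >= 1L)
  arms <- match.arg(arms, c("original", "augmented"), several.ok = TRUE)
  structure(list(sizes = sizes, arms = arms,
                 n_replicates = as.integer(n_replicates),
                 accuracy_threshold = accuracy_threshold,
                 nesting = isTRUE(nesting), seed = as.integer(seed)),
            class = "experiment_design")
}

#' @rdname experiment_design
#' @param ... Overrides passed to [experiment_design()].
#' @export
desk_design <- function(...) {
  args <- list(sizes = c(1L, 2L, 4L, 8L))
  override <- list(...)
  args[names(override)] <- override
  do.call(experiment_design, args)
}

#' Build the (unaugmented) training sets of the sweep
#'
#' @param pool List of [volume_pair()]s (the training pool).
#' @param design An [experiment_design()].
#' @return Named list, one element per size, each a list of pairs.
#'   With nesting on, `sets[["1"]]` is a prefix of `sets[["2"]]`, etc.
#' @export
build_training_sets <- function(pool, design) {
  stopifnot(inherits(design, "experiment_design"))
  if (max(design$sizes) > length(pool))
    stop(sprintf("largest training-set size (%d) exceeds pool size (%d)",
                 max(design$sizes), length(pool)))
  sets <- .with_seed(design$seed, {
    if (design$nesting) {
      ord <- sample.int(length(pool))
      lapply(design$sizes, function(s) pool[ord[seq_len(s)]])
    } else {
      lapply(design$sizes, function(s)
        pool[sample.int(length(pool), s)])
    }
  })
  names(sets) <- as.character(design$sizes)
  sets
}

#' Run the learning-curve experiment
#'
#' For every (size, arm) cell of the design, trains
#' `design$n_replicates` networks ([train_replicates()]; the augmented
#' arm expands its training set with [augment_set()] first), records
#' each replicate's best validation Dice, and keeps the median-accuracy
#' network for downstream trait extraction. Reproducible from the design
#' and config seeds.
#'
#' @param train_pool,val_pool Lists of [volume_pair()]s.
#' @param design An [experiment_design()].
#' @param cfg A [train_config()].
#' @param verbose Print per-cell progress.
#' @return Object of class `learning_curve_result` with `records` (one
#'   row per size x arm x replicate), `median_per_cell`, `median_models`
#'   (named `size_arm`), `failed_cells`, the design and config.
#' @export
run_learning_curve <- function(train_pool, val_pool, design, cfg,
                               verbose = FALSE) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(cfg, "train_config"))
  sets <- build_training_sets(train_pool, design)
  records <- list()
  median_models <- list()
  failed <- character(0)
  for (arm in design$arms) {
    for (s in design$sizes) {
      set_id <- sprintf("%d_%s", s, arm)
      pairs <- sets[[as.character(s)]]
      if (arm == "augmented") pairs <- augment_set(pairs)
      cell_cfg <- cfg
      cell_cfg$seed <- (design$seed * 7L + cfg$seed +
                        1009L * s + 31L * match(arm, design$arms)) %%
        2147483647L
      cell_cfg$n_replicates <- design$n_replicates
      res <- tryCatch(
        train_replicates(pairs, val_pool, cell_cfg,
                         training_set_id = set_id),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("cell %s failed: %s", set_id,
                        conditionMessage(res)))
        failed <- c(failed, set_id)
        next
      }
      if (verbose)
        message(sprintf("cell %-12s replicate Dice: %s", set_id,
                        paste(sprintf("%.4f", res$dices), collapse = " ")))
      records[[set_id]] <- data.frame(
        size = s, arm = arm, replicate = seq_along(res$dices),
        dice = res$dices, stringsAsFactors = FALSE)
      median_models[[set_id]] <- res$median_model
    }
  }
  if (length(records) == 0L) stop("all cells failed to train")
  records <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  med <- aggregate(dice ~ size + arm, data = records, FUN = median)
  names(med)[names(med) == "dice"] <- "median_dice"
  structure(list(records = records, median_per_cell = med,
                 median_models = median_models, failed_cells = failed,
                 design = design, config = cfg),
            class = "learning_curve_result")
}

#' @export
print.learning_curve_result <- function(x, ...) {
  cat("<learning_curve_result>\n")
  print(x$median_per_cell)
  invisible(x)
}

#' Fit the Dice-versus-size GLM
#'
#' Logit-link generalized linear model with quasibinomial error
#' structure for the per-replicate Dice scores, with predictors
#' `log2(size)`, arm, and their interaction. When the response is
#' degenerate (all Dice equal) a flagged zero-slope fit is returned
#' instead of an unstable one.
#'
#' @param result A `learning_curve_result`, or a data frame with
#'   columns `size`, `arm`, `dice`.
#' @return List with `coefficients`, `se`, `dispersion`, the `glm`
#'   object (`fit`), and `degenerate`.
#' @export
fit_dice_glm <- function(result) {
  rec <- if (inherits(result, "learning_curve_result")) result$records
    else result
  stopifnot(all(c("size", "arm", "dice") %in% names(rec)))
  if (length(unique(rec$arm)) < 2L)
    stop("both arms (original, augmented) are required for the GLM")
  if (length(unique(rec$size)) < 2L)
    stop("at least two training-set sizes are required for the GLM")
  rec$arm <- factor(rec$arm, levels = c("original", "augmented"))
  if (var(rec$dice) < 1e-12) {
    cf <- c("(Intercept)" = .logit(mean(rec$dice)),
            "log2(size)" = 0, "armaugmented" = 0,
            "log2(size):armaugmented" = 0)
    return(list(coefficients = cf, se = rep(NA_real_, 4),
                dispersion = 0, fit = NULL, degenerate = TRUE))
  }
  fit <- glm(dice ~ log2(size) * arm, family = quasibinomial("logit"),
             data = rec)
  sm <- summary(fit)
  list(coefficients = coef(fit), se = sm$coefficients[, "Std. Error"],
       dispersion = sm$dispersion, fit = fit, degenerate = FALSE)
}

.logit <- function(p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  log(p / (1 - p))
}

#' Compare early stopping against a full-length run
#'
#' For each training-set size, trains once with the configured patience
#' and once with patience equal to the epoch cap (a full run), using
#' identical seeds, and reports the paired best validation Dice values,
#' their squared correlation, and a one-way F-test for a difference
#' between the two stopping modes. Because early stopping returns the
#' running-maximum epoch, the pairs are exactly equal whenever the full
#' run's best epoch precedes `max_epochs - patience_epochs`.
#'
#' @param train_pool,val_pool Lists of [volume_pair()]s.
#' @param cfg A [train_config()] with `max_epochs > patience_epochs`.
#' @param sizes Training-set sizes (prefixes of the pool are used).
#' @return List with `pairs` (data frame: size, early, full,
#'   full_best_epoch), `r_squared`, `f_statistic`, `p_value`.
#' @export
compare_early_stopping <- function(train_pool, val_pool, cfg,
                                   sizes = c(1L, 2L, 4L)) {
  stopifnot(inherits(cfg, "train_config"),
            cfg$max_epochs > cfg$patience_epochs,
            max(sizes) <= length(train_pool))
  rows <- lapply(sizes, function(s) {
    pairs <- train_pool[seq_len(s)]
    scfg <- cfg
    scfg$seed <- (cfg$seed + 131L * s) %% 2147483647L
    early <- train(pairs, val_pool, scfg,
                   training_set_id = sprintf("%d_early", s))
    fcfg <- scfg
    fcfg$patience_epochs <- fcfg$max_epochs
    full <- train(pairs, val_pool, fcfg,
                  training_set_id = sprintf("%d_full", s))
    data.frame(size = s, early = early$best_val_dice,
               full = full$best_val_dice,
               early_epochs = length(early$history),
               full_best_epoch = full$best_epoch)
  })
  pairs <- do.call(rbind, rows)
  r2 <- if (all(pairs$early == pairs$full)) 1
    else if (var(pairs$early) == 0 || var(pairs$full) == 0) NA_real_
    else cor(pairs$early, pairs$full)^2
  long <- data.frame(dice = c(pairs$early, pairs$full),
                     mode = rep(c("early", "full"), each = nrow(pairs)))
  if (var(long$dice) < 1e-15) {
    fstat <- 0; pval <- 1
  } else {
    av <- anova(lm(dice ~ mode, data = long))
    fstat <- av[["F value"]][1]
    pval <- av[["Pr(>F)"]][1]
  }
  list(pairs = pairs, r_squared = r2, f_statistic = fstat,
       p_value = pval)
}

#' Manual-versus-network agreement regression
#'
#' Ordinary least squares of network-derived on manually derived trait
#' values, per training-set group (slope, intercept, R squared), plus a
#' pooled nested-model F-test for group-specific slopes (differences in
#' the degree of agreement across training sets). Groups whose manual
#' values are constant get a flagged `NA` R squared.
#'
#' @param manual,predicted Equal-length numeric vectors.
#' @param grouping Vector of training-set ids, one per observation (a
#'   single group if omitted).
#' @return List with `per_group` (data frame), `interaction_f`,
#'   `interaction_p` (`NA` with a single group).
#' @export
agreement_regression <- function(manual, predicted, grouping = NULL) {
  stopifnot(length(manual) == length(predicted))
  if (is.null(grouping)) grouping <- rep("all", length(manual))
  grouping <- as.character(grouping)
  keep <- complete.cases(manual, predicted)
  manual <- manual[keep]; predicted <- predicted[keep]
  grouping <- grouping[keep]
  groups <- unique(grouping)
  per <- lapply(groups, function(g) {
    m <- manual[grouping == g]
    p <- predicted[grouping == g]
    if (length(m) < 3L)
      stop(sprintf("group '%s' has fewer than 3 points", g))
    if (var(m) < 1e-24)
      return(data.frame(group = g, slope = NA_real_,
                        intercept = NA_real_, r_squared = NA_real_,
                        n = length(m), constant_manual = TRUE))
    fit <- lm(p ~ m)
    # suppressWarnings: summary.lm warns on exact (zero-residual) fits,
    # which are legitimate here (e.g. predicted == manual)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    data.frame(group = g, slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = r2, n = length(m),
               constant_manual = FALSE)
  })
  per <- do.call(rbind, per)
  fstat <- pval <- NA_real_
  if (length(groups) > 1L && !any(per$constant_manual)) {
    g <- factor(grouping)
    full <- lm(predicted ~ manual * g)
    red <- lm(predicted ~ manual + g)
    av <- anova(red, full)
    fstat <- av[["F"]][2]
    pval <- av[["Pr(>F)"]][2]
  }
  list(per_group = per, interaction_f = fstat, interaction_p = pval)
}

#' Smallest training-set size reaching an accuracy threshold
#'
#' @param result A `learning_curve_result`.
#' @param threshold Dice threshold; defaults to the design's
#'   `accuracy_threshold` (study value 0.95).
#' @return Named integer vector, one entry per arm: the smallest size
#'   whose median Dice meets the threshold, or `NA` if never reached.
#' @export
minimum_specimens <- function(result, threshold = NULL) {
  stopifnot(inherits(result, "learning_curve_result"))
  if (is.null(threshold)) threshold <- result$design$accuracy_threshold
  med <- result$median_per_cell
  out <- vapply(result$design$arms, function(a) {
    m <- med[med$arm == a, , drop = FALSE]
    m <- m[order(m$size), , drop = FALSE]
    hit <- which(m$median_dice >= threshold)
    if (length(hit) == 0L) NA_integer_ else as.integer(m$size[hit[1]])
  }, 0L)
  names(out) <- result$design$arms
  out
}

#' Manual-versus-predicted trait agreement on a test pool
#'
#' Applies each cell's median network to every test specimen and
#' regresses the network-derived trait on the manual one:
#' external-structure agreement uses external volume, internal-structure
#' agreement uses percentage calcite (the trait that depends on the
#' sediment-prone internal cavity). Returns one row per
#' (size, arm, structure).
#'
#' @param result A `learning_curve_result` with median models.
#' @param test_pool List of [volume_pair()]s.
#' @return Data frame with columns `size`, `arm`, `structure`,
#'   `r_squared`, `slope`, `n`.
#' @export
trait_agreement <- function(result, test_pool) {
  stopifnot(inherits(result, "learning_curve_result"),
            length(test_pool) >= 3L)
  manual <- lapply(test_pool, volumetric_traits)
  rows <- list()
  for (set_id in names(result$median_models)) {
    model <- result$median_models[[set_id]]
    parts <- strsplit(set_id, "_")[[1]]
    s <- as.integer(parts[1]); arm <- parts[2]
    pred <- lapply(test_pool, function(p) {
      lab <- predict(model, p)
      volumetric_traits(lab, p$voxel_size_um)
    })
    for (structure in c("external", "internal")) {
      if (structure == "external") {
        mv <- vapply(manual, `[[`, 0, "external_volume_um3")
        pv <- vapply(pred, `[[`, 0, "external_volume_um3")
      } else {
        mv <- vapply(manual, `[[`, 0, "percentage_calcite")
        pv <- vapply(pred, `[[`, 0, "percentage_calcite")
      }
      ok <- is.finite(mv) & is.finite(pv)
      reg <- if (sum(ok) >= 3L && var(mv[ok]) > 1e-24)
        agreement_regression(mv[ok], pv[ok])
      else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        size = s, arm = arm, structure = structure,
        r_squared = if (is.null(reg)) NA_real_
          else reg$per_group$r_squared[1],
        slope = if (is.null(reg)) NA_real_ else reg$per_group$slope[1],
        n = sum(ok))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
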