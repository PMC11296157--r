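make_pool <- function(n, seed = 11) {
  pop <- separable_population(n + 2, c(n, 1, 1), seed = seed)
  pop$train
}

test_that("build_training_sets nests prefixes and validates sizes", {
  pool <- make_pool(4)
  des <- desk_design(sizes = c(1L, 2L, 4L), seed = 5)
  sets <- build_training_sets(pool, des)
  expect_named(sets, c("1", "2", "4"))
  ids <- lapply(sets, function(s) vapply(s, function(p) p$specimen_id, ""))
  expect_identical(ids[["1"]], ids[["2"]][1])
  expect_identical(ids[["2"]], ids[["4"]][1:2])
  # reproducible ordering
  sets2 <- build_training_sets(pool, des)
  expect_identical(ids[["4"]],
                   vapply(sets2[["4"]], function(p) p$specimen_id, ""))
  expect_error(build_training_sets(pool, desk_design(sizes = c(1L, 8L))),
               "exceeds pool size")
  # augmented arm accounting: size 4 -> 24 stacks
  expect_length(augment_set(sets[["4"]]), 24L)
})

test_that("non-nested sampling draws each size independently", {
  pool <- make_pool(6)
  des <- desk_design(sizes = c(2L, 4L), nesting = FALSE, seed = 9)
  sets <- build_training_sets(pool, des)
  expect_length(sets[["2"]], 2L)
  expect_length(sets[["4"]], 4L)
})

test_that("the Dice GLM recovers known simulated coefficients", {
  # simulate records from a known logit-linear model with both arms
  set.seed(71)
  sizes <- rep(c(1, 2, 4, 8, 16), each = 24)
  arm <- rep(rep(c("original", "augmented"), each = 12), 5)
  b0 <- 0.4; b_size <- 0.35; b_arm <- 0.8; b_int <- -0.15
  eta <- b0 + b_size * log2(sizes) + b_arm * (arm == "augmented") +
    b_int * log2(sizes) * (arm == "augmented")
  mu <- 1 / (1 + exp(-eta))
  dice_sim <- pmin(pmax(mu + rnorm(length(mu), sd = 0.02), 0.01), 0.99)
  rec <- data.frame(size = sizes, arm = arm, dice = dice_sim)
  fit <- fit_dice_glm(rec)
  expect_false(fit$degenerate)
  truth <- c(b0, b_size, b_arm, b_int)
  for (k in 1:4)
    expect_lt(abs(fit$coefficients[k] - truth[k]), 2 * fit$se[k] + 1e-8)
})

test_that("degenerate and invalid GLM inputs are handled", {
  rec <- data.frame(size = rep(c(1, 2), each = 4),
                    arm = rep(c("original", "augmented"), 4),
                    dice = 0.9)
  fit <- fit_dice_glm(rec)
  expect_true(fit$degenerate)
  expect_identical(unname(fit$coefficients[2]), 0)
  expect_error(fit_dice_glm(data.frame(size = c(1, 2), arm = "original",
                                       dice = c(0.5, 0.6))),
               "both arms")
  expect_error(fit_dice_glm(data.frame(size = 1,
                                       arm = c("original", "augmented"),
                                       dice = c(0.5, 0.6))),
               "two training-set sizes")
})

test_that("agreement_regression nails exact relations and noise", {
  m <- c(1, 2, 3, 4, 5, 6)
  r <- agreement_regression(m, m, grouping = rep("g1", 6))
  expect_equal(r$per_group$slope, 1)
  expect_equal(r$per_group$r_squared, 1)
  r2 <- agreement_regression(m, 2 * m)
  expect_equal(r2$per_group$slope, 2)
  expect_equal(r2$per_group$r_squared, 1)
  # R^2 with known noise matches its analytic expectation within 2 SE:
  # for p = m + e, R^2 -> var(m) / (var(m) + sd^2)
  set.seed(5)
  n <- 4000
  mm <- rnorm(n, sd = 2)
  pp <- mm + rnorm(n, sd = 1)
  r3 <- agreement_regression(mm, pp)
  expected <- 4 / (4 + 1)
  se <- 2 * (1 - expected) / sqrt(n)  # delta-method scale, generous
  expect_lt(abs(r3$per_group$r_squared - expected), 4 * se)
  # constant manual values flag undefined fits
  r4 <- agreement_regression(rep(1, 5), rnorm(5))
  expect_true(is.na(r4$per_group$r_squared))
  expect_true(r4$per_group$constant_manual)
  expect_error(agreement_regression(1:2, 1:2), "fewer than 3")
})

test_that("grouped agreement detects differing slopes", {
  set.seed(8)
  m <- rep(1:10, 2)
  g <- rep(c("a", "b"), each = 10)
  p <- ifelse(g == "a", m, 3 * m) + rnorm(20, sd = 0.01)
  r <- agreement_regression(m, p, g)
  expect_equal(sort(round(r$per_group$slope)), c(1, 3))
  expect_lt(r$interaction_p, 1e-6)
})

test_that("minimum_specimens finds the threshold crossing", {
  fake <- structure(list(
    median_per_cell = data.frame(
      size = c(1, 2, 4, 8, 1, 2, 4, 8),
      arm = rep(c("original", "augmented"), each = 4),
      median_dice = c(0.90, 0.93, 0.94, 0.96, 0.96, 0.97, 0.98, 0.99)),
    design = desk_design(sizes = c(1L, 2L, 4L, 8L))),
    class = "learning_curve_result")
  out <- minimum_specimens(fake, threshold = 0.95)
  expect_identical(out[["original"]], 8L)
  expect_identical(out[["augmented"]], 1L)
  expect_true(is.na(minimum_specimens(fake, threshold = 0.999)[["original"]]))
})

test_that("a one-cell learning curve produces a consistent record", {
  pop <- separable_population(4, c(2, 1, 1), seed = 13)
  des <- desk_design(sizes = 2L, arms = "original", n_replicates = 1L,
                     seed = 3)
  cfg <- tiny_config(max_epochs = 2L, patience_epochs = 2L)
  res <- run_learning_curve(pop$train, pop$val, des, cfg)
  expect_identical(nrow(res$records), 1L)
  expect_identical(res$median_per_cell$median_dice, res$records$dice)
  expect_named(res$median_models, "2_original")
  ta <- trait_agreement(res, c(pop$test, pop$val, pop$train))
  expect_identical(nrow(ta), 2L)
  expect_setequal(ta$structure, c("external", "internal"))
})
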