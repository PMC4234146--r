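test_that("a single full-depth tree reproduces group means on a perfect split", {
  m <- cbind(split_asset = rep(c(1L, 0L), each = 4),
             other = rep(c(0L, 1L), 4))
  haz <- c(2, 2, 2, 2, 0, 0, 0, 0)
  x <- new_indicator_matrix(m)
  cfg <- forest_config(n_trees = 1, features_per_split = 2,
                       min_node_size = 1, bootstrap = FALSE, seed = 1)
  f <- fit_forest(x, haz, cfg)
  pred <- predict(f$model, data = f$data, num.threads = 1)$predictions
  expect_equal(pred, haz)
  # the structure is data-determined: another seed gives identical output
  f2 <- fit_forest(x, haz, forest_config(n_trees = 1,
                                         features_per_split = 2,
                                         min_node_size = 1,
                                         bootstrap = FALSE, seed = 999))
  pred2 <- predict(f2$model, data = f2$data, num.threads = 1)$predictions
  expect_equal(pred2, pred)
  # constant outcome is rejected
  expect_error(fit_forest(x, rep(1, 8), cfg), "constant")
  # a seed is mandatory
  expect_error(forest_config(n_trees = 10), "seed")
})

test_that("importance requires out-of-bag records and is seed-reproducible", {
  set.seed(21)
  m <- make_correlated_items(150, 5, loading = 0.4, seed = 21)
  haz <- m[, 1] + rnorm(150, 0, 0.5)
  x <- new_indicator_matrix(m)
  no_oob <- fit_forest(x, haz, forest_config(n_trees = 20, bootstrap = FALSE,
                                             seed = 2))
  expect_error(conditional_importance(no_oob), "out-of-bag")
  cfg <- forest_config(n_trees = 100, seed = 2, n_perm = 2)
  f <- fit_forest(x, haz, cfg)
  r1 <- conditional_importance(f)
  r2 <- conditional_importance(fit_forest(x, haz, cfg))
  expect_identical(r1, r2)
})

test_that("an informative asset outranks independent noise assets", {
  set.seed(77)
  n <- 400
  noise <- matrix(rbinom(n * 15, 1, 0.5), n, 15,
                  dimnames = list(NULL, sprintf("noise%02d", 1:15)))
  owner <- rbinom(n, 1, 0.5)
  haz <- ifelse(owner == 1, 1, -1) + rnorm(n, 0, 0.1)
  x <- new_indicator_matrix(cbind(informative = owner, noise))
  f <- fit_forest(x, haz, forest_config(n_trees = 150, seed = 77, n_perm = 2))
  ranking <- conditional_importance(f)
  expect_equal(ranking$indicator[1], "informative")
  expect_gt(ranking$importance[1], 10 * max(ranking$importance[-1]))
})

test_that("an indicator no tree splits on has exactly zero importance", {
  # y is a deterministic step in x1; a greedy variance split reaches purity
  # at the root, so x2 is never used by any tree
  n <- 60
  x1 <- rep(c(0L, 1L), n / 2)
  set.seed(5)
  x2 <- rbinom(n, 1, 0.5)
  haz <- ifelse(x1 == 1, 3, -3)
  x <- new_indicator_matrix(cbind(x1 = x1, x2 = x2))
  f <- fit_forest(x, haz, forest_config(n_trees = 50,
                                        features_per_split = 2,
                                        min_node_size = 1, seed = 9))
  ranking <- conditional_importance(f, conditional = FALSE)
  expect_identical(ranking$importance[ranking$indicator == "x2"], 0)
})

test_that("conditioning strips importance shared through correlation", {
  # two identical informative indicators: conditional importance of the
  # duplicated copy falls strictly below the marginal importance the same
  # indicator has in the single-copy design
  set.seed(13)
  n <- 500
  owner <- rbinom(n, 1, 0.5)
  others <- matrix(rbinom(n * 4, 1, 0.5), n, 4,
                   dimnames = list(NULL, sprintf("bg%d", 1:4)))
  haz <- owner * 1.5 + rnorm(n, 0, 0.4)

  single <- new_indicator_matrix(cbind(signal = owner, others))
  cfg <- forest_config(n_trees = 150, seed = 13, n_perm = 3)
  r_single <- conditional_importance(fit_forest(single, haz, cfg),
                                     conditional = FALSE)
  marginal <- r_single$importance[r_single$indicator == "signal"]

  dup <- new_indicator_matrix(cbind(signal = owner, signal_copy = owner,
                                    others))
  r_dup <- conditional_importance(fit_forest(dup, haz, cfg),
                                  conditional = TRUE)
  cond_signal <- r_dup$importance[r_dup$indicator == "signal"]
  cond_copy <- r_dup$importance[r_dup$indicator == "signal_copy"]
  expect_lt(cond_signal, marginal)
  expect_lt(cond_copy, marginal)
})

test_that("null-importance indicators center on zero across replicates", {
  imps <- vapply(1:20, function(s) {
    set.seed(100 + s)
    m <- matrix(rbinom(120 * 4, 1, 0.5), 120, 4,
                dimnames = list(NULL, c("inert", "a", "b", "c")))
    haz <- m[, "a"] - m[, "b"] + rnorm(120, 0, 0.5)
    f <- fit_forest(new_indicator_matrix(m), haz,
                    forest_config(n_trees = 60, seed = 100 + s, n_perm = 2))
    r <- conditional_importance(f)
    r$importance[r$indicator == "inert"]
  }, numeric(1))
  expect_lt(abs(mean(imps)), 2 * sd(imps) / sqrt(length(imps)))
})

test_that("asset selection honours fixed-k and the largest scree gap", {
  ranking <- tibble::tibble(
    indicator = sprintf("a%02d", 1:12),
    importance = c(10, 9, 8, 7, 6.5, 6, 5.5, 5, 0.5, 0.4, 0.3, 0.2),
    rank = 1:12)
  expect_equal(select_assets(ranking, "largest_gap"), sprintf("a%02d", 1:8))
  expect_equal(select_assets(ranking, "fixed_k", k = 8),
               sprintf("a%02d", 1:8))
  expect_equal(select_assets(ranking, "fixed_k", k = 3),
               c("a01", "a02", "a03"))
  expect_error(select_assets(ranking, "fixed_k", k = 0), "positive")
  expect_error(select_assets(ranking, "fixed_k", k = 13), "exceeds")
  # equal gaps: the earliest maximal gap wins
  flat <- tibble::tibble(indicator = c("p", "q", "r"),
                         importance = c(3, 2, 1), rank = 1:3)
  expect_equal(select_assets(flat, "largest_gap"), "p")
})

test_that("the summed asset score counts owned selected assets", {
  cohort <- make_test_cohort(
    3, assets = list(radio = c(1, 0, 1), tv = c(1, 0, 0),
                     fridge = c(1, 0, 1)))
  s <- asset_score(cohort, c("radio", "tv", "fridge"))
  expect_equal(unname(s), c(3L, 0L, 2L))
  expect_error(asset_score(cohort, c("radio", "yacht")), "yacht")
  cohort$radio[1] <- NA
  expect_error(asset_score(cohort, c("radio", "tv")), "radio")
  # monotone: granting an asset never lowers the score
  cohort2 <- make_test_cohort(
    3, assets = list(radio = c(0, 0, 1), tv = c(1, 0, 0)))
  before <- asset_score(cohort2, c("radio", "tv"))
  cohort2$radio <- c(1, 1, 1)
  after <- asset_score(cohort2, c("radio", "tv"))
  expect_true(all(after >= before))
})
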