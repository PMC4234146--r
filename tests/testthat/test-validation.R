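test_that("LOOCV error is zero for a perfectly linear score", {
  ch <- make_test_cohort(10, site = "A",
                         maternal_education_years = seq(0, 16,
                                                        length.out = 10))
  ch$haz <- 0.1 * ch$maternal_education_years - 2
  expect_equal(loocv_mse(ch, "education", refit_selection = FALSE),
               0, tolerance = 1e-20)
})

test_that("LOOCV without refit equals the hat-matrix PRESS closed form", {
  set.seed(42)
  n <- 60
  ch <- make_test_cohort(n, site = rep(c("A", "B", "C"), each = 20),
                         maternal_education_years = sample(0:16, n, TRUE))
  ch$haz <- -1 + 0.08 * ch$maternal_education_years +
    0.3 * (ch$site == "B") + rnorm(n, 0, 0.7)
  got <- loocv_mse(ch, "education", refit_selection = FALSE)
  X <- model.matrix(~ score + site,
                    data.frame(score = ch$maternal_education_years,
                               site = factor(ch$site)))
  want <- press_mse_oracle(ch$haz, X)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("LOOCV folds predict from the remaining observations", {
  # constant score: the model collapses to the intercept, so each fold
  # predicts the mean of the other outcomes; y = (0, 2, 4) gives MSE 6
  ch <- make_test_cohort(3, site = "A", haz = c(0, 2, 4),
                         maternal_education_years = 5)
  got <- suppressWarnings(loocv_mse(ch, "education",
                                    refit_selection = FALSE))
  expect_equal(got, 6)
})

test_that("k-fold with k = n reproduces leave-one-out", {
  set.seed(7)
  n <- 30
  ch <- make_test_cohort(n, site = rep(c("A", "B"), each = 15),
                         maternal_education_years = sample(0:16, n, TRUE))
  ch$haz <- -1.5 + 0.1 * ch$maternal_education_years + rnorm(n, 0, 0.5)
  expect_equal(kfold_mse(ch, "education", k = n, seed = 3,
                         refit_selection = FALSE),
               loocv_mse(ch, "education", refit_selection = FALSE),
               tolerance = 1e-12)
  expect_error(kfold_mse(ch, "education", k = n + 1), "exceed")
  expect_error(kfold_mse(ch, "education", k = 1), "at least 2")
})

test_that("adjusted R2 matches its formula and its boundary cases", {
  ch <- make_test_cohort(8, site = "A",
                         maternal_education_years = c(1, 3, 5, 7, 9, 11,
                                                      13, 15))
  ch$haz <- ch$maternal_education_years  # perfect fit, one site
  expect_equal(suppressWarnings(adjusted_r2(ch, ch$maternal_education_years)),
               1)

  # textbook-sized dataset against an independent closed-form computation
  set.seed(11)
  n <- 40
  ch2 <- make_test_cohort(n, site = rep(c("A", "B"), each = 20),
                          maternal_education_years = sample(0:16, n, TRUE))
  ch2$haz <- -1 + 0.05 * ch2$maternal_education_years + rnorm(n, 0, 0.8)
  score <- ch2$maternal_education_years
  got <- adjusted_r2(ch2, score)
  X <- model.matrix(~ score + site,
                    data.frame(score = score, site = factor(ch2$site)))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  res <- ch2$haz - H %*% ch2$haz
  r2 <- 1 - sum(res^2) / sum((ch2$haz - mean(ch2$haz))^2)
  p <- ncol(X) - 1
  want <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  expect_equal(got, want, tolerance = 1e-12)

  # independent score: adjusted R2 stays near zero at large n
  set.seed(12)
  n3 <- 800
  ch3 <- make_test_cohort(n3, site = rep(c("A", "B"), each = 400),
                          maternal_education_years = sample(0:16, n3, TRUE))
  ch3$haz <- rnorm(n3)
  expect_lt(abs(adjusted_r2(ch3, ch3$maternal_education_years)), 0.02)
})

test_that("the 25%-increase effect size is scale-free and recovers slopes", {
  n <- 20
  ch <- make_test_cohort(n, site = "A")
  score <- seq(0, 10, length.out = n)
  ch$haz <- 2 * (score / 10)  # HAZ = 2 x scaled score exactly
  es <- suppressWarnings(effect_size_25(ch, score))  # exact fit
  expect_equal(es$estimate, 0.5, tolerance = 1e-10)
  # invariant to affine transformation of the raw score
  es2 <- suppressWarnings(effect_size_25(ch, 5 * score + 3))
  expect_equal(es2$estimate, es$estimate, tolerance = 1e-10)
  expect_error(effect_size_25(ch, rep(1, n)), "zero")

  # parameter recovery: CI covers the generating value in >= 18/20 replicates
  cover <- vapply(1:20, function(s) {
    set.seed(400 + s)
    m <- 150
    chs <- make_test_cohort(m, site = rep(c("A", "B"), each = 75))
    sc <- runif(m)
    chs$haz <- -2 + 1.2 * sc + 0.3 * (chs$site == "B") + rnorm(m, 0, 0.8)
    ci <- effect_size_25(chs, sc, rescale = FALSE)$ci
    ci[1] <= 0.25 * 1.2 && 0.25 * 1.2 <= ci[2]
  }, logical(1))
  expect_gte(sum(cover), 18)

  # a score unrelated to HAZ: effect near zero, CI covers zero at the
  # nominal rate across replicates
  null_cover <- vapply(1:20, function(s) {
    set.seed(500 + s)
    chn <- make_test_cohort(300, site = rep(c("A", "B"), each = 150))
    chn$haz <- rnorm(300)
    esn <- effect_size_25(chn, runif(300), rescale = FALSE)
    esn$ci[1] <= 0 && 0 <= esn$ci[2]
  }, logical(1))
  expect_gte(sum(null_cover), 18)
})

test_that("income association flags construct validity", {
  set.seed(30)
  n <- 50
  ch <- make_test_cohort(n, site = rep(c("A", "B"), each = 25),
                         income_local = exp(runif(n, 2, 6)))
  ch$income_usd <- ch$income_local
  sc <- log1p(ch$income_usd)
  ia <- income_association(ch, sc)
  expect_equal(ia$pearson, 1)
  expect_equal(ia$spearman, 1)
  expect_equal(nrow(ia$site_means), 2)
  # permuted incomes de-correlate
  set.seed(9)
  ia2 <- income_association(ch, sample(sc))
  expect_lt(abs(ia2$pearson), 0.3)
  chz <- ch; chz$income_usd <- rep(0, n)
  expect_error(income_association(chz, sc), "zero")
})

test_that("compare_methods produces a well-formed comparison table", {
  g <- generate_cohort(generator_config(seed = 55, n_sites = 4,
                                        n_per_site = 60))
  ch <- g$cohort
  cmp <- compare_methods(
    ch, methods = c("education", "mpi"), cv = "kfold", k = 5, seed = 55)
  expect_s3_class(cmp, "method_comparison")
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$mse > 0))
  expect_true(all(cmp$ci_low <= cmp$effect_size_25 &
                    cmp$effect_size_25 <= cmp$ci_high))
  single <- compare_methods(ch, methods = "education", cv = "kfold",
                            k = 5, seed = 55)
  expect_equal(nrow(single), 1)
  md <- format_comparison_md(cmp)
  expect_length(md, 4)
})
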