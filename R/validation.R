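# Comparison framework: cross-validated prediction error of HAZ, adjusted
# R-squared with site indicators, scaled effect sizes per 25% of a measure's
# range, and the income construct-validity check.

# ---------------------------------------------------------------------------
# Scoring pipelines (refittable inside cross-validation folds)
# ---------------------------------------------------------------------------

#' Fit a wealth-scoring pipeline on a training cohort
#'
#' Returns the fitted artifacts for a method plus a scoring closure that can
#' be applied to held-out households on the training scale. This is the unit
#' that cross-validation refits inside each fold when `refit_selection` is
#' on: PCA loadings, the random-forest asset set and empirical income
#' octiles are then all derived from the training fold only.
#'
#' @param train a `wami_cohort`.
#' @param method one of `"education"`, `"pca"`, `"mpi"`, `"rf_assets"`,
#'   `"wami"`.
#' @param options list: `screen` (min_category_prop, alpha_drop_delta),
#'   `forest` (a [forest_config()]), `k_assets`, `assets` (fixed asset set,
#'   skips the forest), `octile` (`"fixed"` or `"empirical"`),
#'   `octile_cutoffs`, `mpi_cutoffs`, `ppr_threshold`, `indicators`.
#' @return A `scoring_pipeline`: list with `method`, `context`, and
#'   `score(cohort)`.
#' @export
fit_scoring <- function(train, method, options = list()) {
  ppr <- options$ppr_threshold %||% 2
  context <- list(ppr_threshold = ppr)

  screen_opts <- options$screen %||% list()
  screened <- function() {
    im <- indicator_matrix(train, indicators = options$indicators,
                           ppr_threshold = ppr)
    rep_ <- screen_indicators(
      im,
      min_category_prop = screen_opts$min_category_prop %||% 0.10,
      alpha_drop_delta = screen_opts$alpha_drop_delta %||% 0.01)
    keep_indicators(im, rep_)
  }

  if (method == "pca") {
    im <- screened()
    tet <- tetrachoric_matrix(im)
    context$pca <- pca_first_component(tet, im, anchor = options$anchor)
  } else if (method %in% c("rf_assets", "wami")) {
    if (!is.null(options$assets)) {
      context$assets <- options$assets
    } else {
      im <- screened()
      cfg <- options$forest %||% forest_config(seed = 20100101L)
      idx <- match(im$household_ids, train$household_id)
      forest <- fit_forest(im, train$haz[idx], cfg)
      ranking <- conditional_importance(forest)
      context$assets <- select_assets(ranking, mode = "fixed_k",
                                      k = options$k_assets %||% 8)
      context$ranking <- ranking
    }
    if (method == "wami") {
      context$octile_cutoffs <-
        if (identical(options$octile, "empirical")) {
          empirical_octile_cutoffs(train$income_usd)
        } else {
          options$octile_cutoffs %||% default_octile_cutoffs()
        }
    }
  } else if (method == "mpi") {
    context$mpi_cutoffs <- options$mpi_cutoffs
  } else if (method != "education") {
    stop("unknown method: ", method, call. = FALSE)
  }

  structure(list(
    method = method,
    context = context,
    score = function(cohort) compute_index(cohort, method, context)$score
  ), class = "scoring_pipeline")
}

# ---------------------------------------------------------------------------
# Cross-validated prediction error
# ---------------------------------------------------------------------------

#' Evaluation regression of HAZ on a score plus site indicators
#' @noRd
.haz_model <- function(haz, score, site, site_dummies = TRUE) {
  if (site_dummies && length(unique(site)) > 1) {
    stats::lm(haz ~ score + site,
              data = data.frame(haz = haz, score = score,
                                site = factor(site)))
  } else {
    stats::lm(haz ~ score, data = data.frame(haz = haz, score = score))
  }
}

.cv_mse <- function(cohort, method, fold_id, refit_selection, options,
                    context, site_dummies) {
  n <- nrow(cohort)
  if (!refit_selection) {
    pipeline <- if (!is.null(context)) {
      structure(list(method = method, context = context,
                     score = function(ch) {
                       compute_index(ch, method, context)$score
                     }),
                class = "scoring_pipeline")
    } else {
      fit_scoring(cohort, method, options)
    }
    all_scores <- pipeline$score(cohort)
  }
  errs <- rep(NA_real_, max(fold_id))
  skipped <- 0L
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    train <- cohort[!test, , drop = FALSE]
    train <- new_cohort(train, asset_names(cohort))
    if (site_dummies &&
        !all(cohort$site[test] %in% unique(train$site))) {
      skipped <- skipped + 1L
      next
    }
    if (refit_selection) {
      pipeline <- fit_scoring(train, method, options)
      s_train <- pipeline$score(train)
      test_cohort <- new_cohort(cohort[test, , drop = FALSE],
                                asset_names(cohort))
      s_test <- pipeline$score(test_cohort)
    } else {
      s_train <- all_scores[!test]
      s_test <- all_scores[test]
    }
    fit <- .haz_model(train$haz, s_train, train$site, site_dummies)
    newd <- data.frame(score = s_test)
    if (site_dummies && length(unique(train$site)) > 1) {
      newd$site <- factor(cohort$site[test], levels = levels(fit$model$site))
    }
    pred <- stats::predict(fit, newdata = newd)
    errs[f] <- mean((cohort$haz[test] - pred)^2)
  }
  if (skipped > 0) {
    warning(sprintf(
      "%d fold(s) skipped: held-out site absent from training data",
      skipped), call. = FALSE)
  }
  # weight folds by their size so LOOCV equals the mean squared error
  sizes <- tabulate(fold_id)
  ok <- !is.na(errs)
  sum(errs[ok] * sizes[ok]) / sum(sizes[ok])
}

#' Leave-one-out cross-validated MSE of HAZ prediction
#'
#' For each held-out household the scoring pipeline is (optionally) refitted
#' on the remaining households, a linear model HAZ ~ score + site indicators
#' is fitted on them, and the held-out HAZ is predicted; the mean squared
#' prediction error is returned. With `refit_selection = FALSE` and an
#' ordinary linear model this equals the PRESS statistic divided by n.
#'
#' @param cohort a `wami_cohort` with complete `haz`.
#' @param method index method name (see [compute_index()]).
#' @param refit_selection refit the full scoring pipeline inside each fold
#'   (asset selection, PCA loadings, empirical octiles). Default: on for
#'   `rf_assets` and `pca`, off otherwise. Computationally heavy at large n;
#'   see [kfold_mse()].
#' @param options pipeline options passed to [fit_scoring()].
#' @param context optional pre-fitted context (used when
#'   `refit_selection = FALSE`).
#' @param site_dummies include site indicator variables (default TRUE).
#' @return Mean squared prediction error (HAZ-units squared).
#' @export
loocv_mse <- function(cohort, method,
                      refit_selection = method %in% c("rf_assets", "pca"),
                      options = list(), context = NULL,
                      site_dummies = TRUE) {
  stopifnot(inherits(cohort, "wami_cohort"))
  n <- nrow(cohort)
  if (n < 3) stop("need at least 3 records", call. = FALSE)
  if (any(is.na(cohort$haz))) stop("haz must be complete", call. = FALSE)
  .cv_mse(cohort, method, seq_len(n), refit_selection, options, context,
          site_dummies)
}

#' K-fold cross-validated MSE of HAZ prediction
#'
#' Folds are assigned stratified by site from the seed; the refit contract
#' matches [loocv_mse()]. `k = n` reproduces leave-one-out exactly.
#'
#' @inheritParams loocv_mse
#' @param k number of folds (>= 2, <= n).
#' @param seed integer seed for the fold assignment.
#' @return Mean squared prediction error (HAZ-units squared).
#' @export
kfold_mse <- function(cohort, method, k = 10, seed = 1,
                      refit_selection = method %in% c("rf_assets", "pca"),
                      options = list(), context = NULL,
                      site_dummies = TRUE) {
  stopifnot(inherits(cohort, "wami_cohort"))
  n <- nrow(cohort)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k cannot exceed the number of records", call. = FALSE)
  if (any(is.na(cohort$haz))) stop("haz must be complete", call. = FALSE)
  fold_id <- integer(n)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  # shuffle within site, then deal folds round-robin across the grouped
  # order: sites stay balanced across folds and k = n gives singleton folds
  ord <- unlist(lapply(unique(cohort$site), function(s) {
    idx <- which(cohort$site == s)
    idx[sample.int(length(idx))]
  }))
  fold_id[ord] <- rep_len(seq_len(k), n)
  .cv_mse(cohort, method, fold_id, refit_selection, options, context,
          site_dummies)
}

# ---------------------------------------------------------------------------
# Explained variability and scaled effect size
# ---------------------------------------------------------------------------

#' Adjusted R-squared of HAZ on a wealth score with site indicators
#'
#' Ordinary least squares HAZ ~ score + site dummies (reference level:
#' first site code); returns 1 - (1 - R2)(n - 1)/(n - p - 1).
#'
#' @param cohort a `wami_cohort`.
#' @param scores per-household scores aligned with the cohort rows.
#' @param site_dummies include site indicators (default TRUE).
#' @return Adjusted R-squared (proportion, at most 1).
#' @export
adjusted_r2 <- function(cohort, scores, site_dummies = TRUE) {
  stopifnot(inherits(cohort, "wami_cohort"),
            length(scores) == nrow(cohort))
  fit <- .haz_model(cohort$haz, scores, cohort$site, site_dummies)
  if (any(is.na(stats::coef(fit))["score"])) {
    stop("score is collinear with the site indicators", call. = FALSE)
  }
  summary(fit)$adj.r.squared
}

#' Effect of a 25% increase in a wealth measure on HAZ
#'
#' Because the measures live on different scales, each score is min–max
#' rescaled to \[0, 1\] over the cohort before regression (a measure already
#' on the unit interval, like WAMI, can be used as-is with
#' `rescale = FALSE`). The reported effect is 0.25 times the slope of
#' HAZ ~ scaled score + site indicators, with a 95% CI and the slope's
#' p-value.
#'
#' @param cohort a `wami_cohort`.
#' @param scores per-household scores.
#' @param rescale min–max rescale the scores first (default TRUE).
#' @param site_dummies include site indicators (default TRUE).
#' @return List: `estimate` (HAZ change per 25% of range), `ci` (length 2),
#'   `p_value`, `slope`, `se`.
#' @export
effect_size_25 <- function(cohort, scores, rescale = TRUE,
                           site_dummies = TRUE) {
  stopifnot(inherits(cohort, "wami_cohort"),
            length(scores) == nrow(cohort))
  if (rescale) {
    rng <- range(scores)
    if (diff(rng) == 0) stop("score range is zero", call. = FALSE)
    scores <- (scores - rng[1]) / diff(rng)
  }
  fit <- .haz_model(cohort$haz, scores, cohort$site, site_dummies)
  sm <- summary(fit)$coefficients
  slope <- sm["score", "Estimate"]
  se <- sm["score", "Std. Error"]
  p <- sm["score", "Pr(>|t|)"]
  df <- fit$df.residual
  crit <- if (df < 100) stats::qt(0.975, df) else stats::qnorm(0.975)
  est <- 0.25 * slope
  list(estimate = est,
       ci = c(0.25 * (slope - crit * se), 0.25 * (slope + crit * se)),
       p_value = p, slope = slope, se = se)
}

# ---------------------------------------------------------------------------
# Income construct validity
# ---------------------------------------------------------------------------

#' Association between a wealth score and household income
#'
#' Construct-validity check: Pearson and Spearman correlation plus OLS slope
#' of the score on log(1 + income in USD), at household level and on site
#' means (site as the unit of analysis).
#'
#' @param cohort a `wami_cohort` with `income_usd`.
#' @param scores per-household scores.
#' @return List: `pearson`, `spearman`, `slope` (household level),
#'   `site_means` (tibble: site, mean_score, mean_income_usd),
#'   `site_pearson`.
#' @export
income_association <- function(cohort, scores) {
  stopifnot(inherits(cohort, "wami_cohort"),
            length(scores) == nrow(cohort))
  if (is.null(cohort$income_usd)) {
    stop("cohort has no income_usd column", call. = FALSE)
  }
  inc <- cohort$income_usd
  if (all(inc == 0, na.rm = TRUE)) stop("all incomes are zero",
                                        call. = FALSE)
  log_inc <- log1p(inc)
  sites <- sort(unique(cohort$site))
  site_means <- tibble::tibble(
    site = sites,
    mean_score = vapply(sites, function(s) mean(scores[cohort$site == s]),
                        numeric(1)),
    mean_income_usd = vapply(sites, function(s) mean(inc[cohort$site == s]),
                             numeric(1)))
  list(
    pearson = stats::cor(scores, log_inc),
    spearman = stats::cor(scores, log_inc, method = "spearman"),
    slope = unname(stats::coef(stats::lm(scores ~ log_inc))[2]),
    site_means = site_means,
    site_pearson = if (nrow(site_means) > 2) {
      stats::cor(site_means$mean_score, log1p(site_means$mean_income_usd))
    } else NA_real_
  )
}

# ---------------------------------------------------------------------------
# The comparison table
# ---------------------------------------------------------------------------

#' Compare wealth/SES measures in predicting child HAZ
#'
#' Produces one row per method: cross-validated MSE, adjusted R-squared,
#' the scaled 25%-increase effect size with CI and p-value, the income
#' association, and the number of input variables.
#'
#' @param cohort a `wami_cohort` with complete `haz` (and `income_usd` when
#'   income-dependent methods are requested).
#' @param methods methods to compare (default all five).
#' @param cv `"loocv"` or `"kfold"` (default `"kfold"` with `k` folds; the
#'   two give similar results, and k-fold keeps selection refits tractable).
#' @param k folds for `"kfold"` (default 10).
#' @param seed seed for fold assignment and the forest (default 1).
#' @param refit_selection refit selection pipelines inside folds (default
#'   TRUE for `pca`/`rf_assets`; a single logical applies to all methods).
#' @param options pipeline options (see [fit_scoring()]); the forest config
#'   defaults to [forest_config()] with this `seed`.
#' @return A `method_comparison` tibble: method, mse, adjusted_r2,
#'   effect_size_25, ci_low, ci_high, p_value, income_pearson, n_variables.
#' @export
compare_methods <- function(cohort,
                            methods = c("education", "pca", "mpi",
                                        "rf_assets", "wami"),
                            cv = c("kfold", "loocv"), k = 10, seed = 1,
                            refit_selection = NULL, options = list()) {
  cv <- match.arg(cv)
  stopifnot(inherits(cohort, "wami_cohort"))
  if (is.null(options$forest)) options$forest <- forest_config(seed = seed)

  rows <- lapply(methods, function(method) {
    pipeline <- fit_scoring(cohort, method, options)
    scores <- pipeline$score(cohort)
    refit <- refit_selection %||% (method %in% c("rf_assets", "pca"))
    mse <- if (cv == "loocv") {
      loocv_mse(cohort, method, refit_selection = refit, options = options,
                context = if (!refit) pipeline$context)
    } else {
      kfold_mse(cohort, method, k = k, seed = seed,
                refit_selection = refit, options = options,
                context = if (!refit) pipeline$context)
    }
    es <- effect_size_25(cohort, scores,
                         rescale = !identical(method, "wami"))
    inc <- if (!is.null(cohort$income_usd)) {
      income_association(cohort, scores)$pearson
    } else NA_real_
    n_vars <- switch(method,
                     education = 1L,
                     pca = length(pipeline$context$pca$loadings),
                     mpi = 14L,
                     rf_assets = length(pipeline$context$assets),
                     wami = length(pipeline$context$assets) + 4L)
    tibble::tibble(method = method, mse = mse,
                   adjusted_r2 = adjusted_r2(cohort, scores),
                   effect_size_25 = es$estimate,
                   ci_low = es$ci[1], ci_high = es$ci[2],
                   p_value = es$p_value,
                   income_pearson = inc,
                   n_variables = n_vars)
  })
  out <- do.call(rbind, rows)
  attr(out, "cv") <- cv
  attr(out, "k") <- if (cv == "kfold") k else nrow(cohort)
  attr(out, "seed") <- seed
  class(out) <- c("method_comparison", class(out))
  out
}

#' Render a method comparison as a Markdown table
#'
#' @param comparison a `method_comparison`.
#' @return Character vector of Markdown lines.
#' @export
format_comparison_md <- function(comparison) {
  hdr <- c(
    "| Method | CV MSE | Adjusted R2 | Effect size (95% CI) | p | Variables |",
    "|---|---|---|---|---|---|")
  rows <- vapply(seq_len(nrow(comparison)), function(i) {
    r <- comparison[i, ]
    sprintf("| %s | %.3f | %.2f%% | %.3f (%.3f-%.3f) | %.3g | %d |",
            r$method, r$mse, 100 * r$adjusted_r2, r$effect_size_25,
            r$ci_low, r$ci_high, r$p_value, r$n_variables)
  }, character(1))
  c(hdr, rows)
}
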