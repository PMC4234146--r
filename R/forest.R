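# Random-forest asset selection: regression forest of HAZ on binary
# indicators, conditional permutation importance, scree-gap / top-k
# selection, and the summed asset score.
#
# The forest itself is a standard bootstrap regression ensemble (fitted via
# ranger, with in-bag tracking so every tree's out-of-bag households are
# known). Conditional permutation importance permutes one indicator within
# strata defined by its correlated covariates, so importance shared through
# correlation alone is removed; the importance of indicator j is the mean
# over trees of the increase in out-of-bag squared error after permutation.

#' Forest configuration
#'
#' @param n_trees number of trees (default 500).
#' @param features_per_split candidate features per split; default
#'   `ceiling(p/3)` at fit time.
#' @param min_node_size minimum terminal node size (default 5).
#' @param bootstrap draw bootstrap resamples (default TRUE; required for
#'   out-of-bag importance).
#' @param seed integer seed; mandatory for reproducibility.
#' @param conditional_threshold minimum absolute phi coefficient for a
#'   covariate to enter an indicator's conditioning grid (default 0.2).
#' @param max_conditioning_vars cap on conditioning covariates, keeping the
#'   most associated, so strata stay populated (default 5, i.e. at most
#'   2^5 cells).
#' @param n_perm permutation replicates averaged per indicator (default 5).
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 500, features_per_split = NULL,
                          min_node_size = 5, bootstrap = TRUE, seed,
                          conditional_threshold = 0.2,
                          max_conditioning_vars = 5, n_perm = 5) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for reproducible forests", call. = FALSE)
  }
  stopifnot(n_trees >= 1, min_node_size >= 1, n_perm >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 features_per_split = features_per_split,
                 min_node_size = as.integer(min_node_size),
                 bootstrap = isTRUE(bootstrap),
                 seed = as.integer(seed),
                 conditional_threshold = conditional_threshold,
                 max_conditioning_vars = as.integer(max_conditioning_vars),
                 n_perm = as.integer(n_perm)),
            class = "forest_config")
}

#' Fit a regression forest of HAZ on binary indicators
#'
#' Variance-reduction splits on bootstrap resamples with out-of-bag record
#' tracking; deterministic given the config seed.
#'
#' @param x an `indicator_matrix`.
#' @param haz per-household outcome aligned with the rows of `x`; no
#'   missing values.
#' @param config a [forest_config()].
#' @return A `wami_forest`: the fitted ensemble plus the training data and
#'   config.
#' @export
fit_forest <- function(x, haz, config) {
  m <- .as_values(x)
  stopifnot(inherits(config, "forest_config"))
  if (length(haz) != nrow(m)) {
    stop("haz length must match the number of households", call. = FALSE)
  }
  if (any(is.na(haz))) stop("haz must not contain missing values",
                            call. = FALSE)
  if (stats::var(haz) == 0) {
    stop("haz is constant: no variance to explain", call. = FALSE)
  }
  mtry <- config$features_per_split %||% ceiling(ncol(m) / 3)
  df <- as.data.frame(m)
  fit <- ranger::ranger(
    x = df, y = haz,
    num.trees = config$n_trees,
    mtry = min(mtry, ncol(m)),
    min.node.size = config$min_node_size,
    replace = config$bootstrap,
    sample.fraction = 1,
    keep.inbag = TRUE,
    seed = config$seed,
    num.threads = 1
  )
  structure(list(model = fit, data = df, haz = haz,
                 indicator_names = colnames(m), config = config),
            class = "wami_forest")
}

#' @export
print.wami_forest <- function(x, ...) {
  cat(sprintf("<wami_forest> %d trees on %d households x %d indicators\n",
              x$config$n_trees, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Per-tree predictions as an n x n_trees matrix
#' @noRd
.all_tree_predictions <- function(forest, newdata) {
  stats::predict(forest$model, data = newdata, predict.all = TRUE,
                 num.threads = 1)$predictions
}

#' Conditioning strata for one indicator
#'
#' Covariates whose absolute phi coefficient (Pearson correlation of the
#' 0/1 columns) with the target indicator exceeds the threshold define the
#' permutation strata via cross-classification, capped at the most
#' associated `max_conditioning_vars` covariates.
#' @noRd
.conditioning_strata <- function(m, j, threshold, max_vars) {
  others <- setdiff(seq_len(ncol(m)), j)
  phi <- vapply(others, function(k) {
    if (stats::sd(m[, k]) == 0 || stats::sd(m[, j]) == 0) return(0)
    abs(stats::cor(m[, j], m[, k]))
  }, numeric(1))
  sel <- others[phi > threshold]
  if (length(sel) == 0) return(rep(1L, nrow(m)))
  if (length(sel) > max_vars) {
    sel <- sel[order(phi[match(sel, others)], decreasing = TRUE)][
      seq_len(max_vars)]
  }
  as.integer(interaction(as.data.frame(m[, sel, drop = FALSE]), drop = TRUE))
}

#' Permute a vector within strata
#' @noRd
.permute_within <- function(v, strata) {
  out <- v
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) > 1) out[idx] <- v[sample(idx)]
  }
  out
}

#' Conditional permutation importance of each indicator
#'
#' For each indicator, importance is the mean over trees of the out-of-bag
#' squared-error increase when the indicator is permuted — within strata of
#' its correlated covariates when `conditional = TRUE` (removing importance
#' that is due only to correlation), or freely otherwise. Averaged over
#' `config$n_perm` seeded permutation replicates.
#'
#' @param forest a `wami_forest` fitted with bootstrap resampling.
#' @param conditional permute within conditioning strata (default TRUE).
#' @return An `importance_ranking` tibble: `indicator`, `importance`
#'   (HAZ-units^2), `rank`, sorted by decreasing importance with ties broken
#'   by indicator name.
#' @export
conditional_importance <- function(forest, conditional = TRUE) {
  stopifnot(inherits(forest, "wami_forest"))
  cfg <- forest$config
  if (!cfg$bootstrap) {
    stop("no out-of-bag records: forest was fitted without bootstrap",
         call. = FALSE)
  }
  m <- as.matrix(forest$data)
  haz <- forest$haz
  inbag <- matrix(unlist(forest$model$inbag.counts), nrow = nrow(m))
  oob <- inbag == 0
  if (!any(oob)) stop("no out-of-bag records in any tree", call. = FALSE)
  tree_has_oob <- colSums(oob) > 0

  base_pred <- .all_tree_predictions(forest, forest$data)
  tree_mse <- function(pred) {
    vapply(which(tree_has_oob), function(t) {
      idx <- oob[, t]
      mean((haz[idx] - pred[idx, t])^2)
    }, numeric(1))
  }
  base_mse <- tree_mse(base_pred)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$seed + 1L)

  imp <- vapply(seq_len(ncol(m)), function(j) {
    strata <- if (conditional) {
      .conditioning_strata(m, j, cfg$conditional_threshold,
                           cfg$max_conditioning_vars)
    } else rep(1L, nrow(m))
    deltas <- vapply(seq_len(cfg$n_perm), function(r) {
      perm <- forest$data
      perm[[j]] <- .permute_within(m[, j], strata)
      pred <- .all_tree_predictions(forest, perm)
      mean(tree_mse(pred) - base_mse)
    }, numeric(1))
    mean(deltas)
  }, numeric(1))

  ord <- order(-imp, forest$indicator_names)
  out <- tibble::tibble(indicator = forest$indicator_names[ord],
                        importance = imp[ord],
                        rank = seq_along(imp))
  class(out) <- c("importance_ranking", class(out))
  out
}

#' Select priority assets from an importance ranking
#'
#' `fixed_k` keeps the top-`k` indicators (default 8). `largest_gap` mimics
#' scree-plot reading: the kept prefix ends just before the largest
#' consecutive drop in importance (earliest such gap on ties).
#'
#' @param ranking an `importance_ranking`.
#' @param mode `"fixed_k"` or `"largest_gap"`.
#' @param k number of assets for `fixed_k`.
#' @return Character vector of selected indicators, in rank order.
#' @export
select_assets <- function(ranking, mode = c("fixed_k", "largest_gap"),
                          k = 8) {
  mode <- match.arg(mode)
  if (nrow(ranking) == 0) stop("empty ranking", call. = FALSE)
  if (mode == "fixed_k") {
    if (k <= 0) stop("k must be positive", call. = FALSE)
    if (k > nrow(ranking)) stop("k exceeds the number of indicators",
                                call. = FALSE)
    return(ranking$indicator[seq_len(k)])
  }
  if (nrow(ranking) < 2) return(ranking$indicator)
  gaps <- -diff(ranking$importance)
  cut <- which.max(gaps)  # earliest maximal gap
  ranking$indicator[seq_len(cut)]
}

#' Summed asset score
#'
#' Unweighted count of selected assets owned: 0..k per household.
#'
#' @param cohort a `wami_cohort` (or an `indicator_matrix`).
#' @param assets character vector of selected asset indicators.
#' @param ppr_threshold crowding cutoff if `people_per_room` is among the
#'   selected indicators.
#' @return Integer scores named by household id.
#' @export
asset_score <- function(cohort, assets, ppr_threshold = 2) {
  if (inherits(cohort, "indicator_matrix")) {
    missing_ind <- setdiff(assets, cohort$indicator_names)
    if (length(missing_ind) > 0) {
      stop("missing indicator(s): ", paste(missing_ind, collapse = ", "),
           call. = FALSE)
    }
    v <- cohort$values[, assets, drop = FALSE]
    ids <- cohort$household_ids
  } else {
    stopifnot(inherits(cohort, "wami_cohort"))
    avail <- c(asset_names(cohort), "electricity", "people_per_room")
    missing_ind <- setdiff(assets, avail)
    if (length(missing_ind) > 0) {
      stop("missing indicator(s): ", paste(missing_ind, collapse = ", "),
           call. = FALSE)
    }
    v <- vapply(assets, function(a) {
      if (a == "people_per_room") {
        dichotomize_people_per_room(cohort$people_per_room, ppr_threshold)
      } else as.numeric(cohort[[a]])
    }, numeric(nrow(cohort)))
    v <- matrix(v, nrow = nrow(cohort),
                dimnames = list(NULL, assets))
    ids <- cohort$household_id
  }
  if (any(is.na(v))) {
    bad <- colnames(v)[colSums(is.na(v)) > 0]
    stop("missing values in indicator(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- as.integer(rowSums(v))
  names(out) <- ids
  out
}

#' Write an importance ranking to CSV
#' @param ranking an `importance_ranking`.
#' @param path output path.
#' @param selected optional selected asset set to flag.
#' @return `path`, invisibly.
#' @export
write_importance_csv <- function(ranking, path, selected = NULL) {
  df <- as.data.frame(ranking)
  df$selected <- df$indicator %in% (selected %||% character())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
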