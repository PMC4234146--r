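# Indicator screening: prevalence variation + Cronbach's alpha.

#' Dichotomize household crowding
#'
#' Codes people-per-room so that 1 means the less-crowded (asset-like) state,
#' keeping all indicators oriented "wealthier = 1".
#'
#' @param value non-negative people-per-room value(s).
#' @param threshold crowding cutoff; default 2 persons per room.
#' @return 1 if `value < threshold`, else 0 (`NA` propagates).
#' @examples
#' dichotomize_people_per_room(c(1.2, 2, 5.5))
#' @export
dichotomize_people_per_room <- function(value, threshold = 2) {
  if (any(value < 0, na.rm = TRUE)) {
    stop("people_per_room must be non-negative", call. = FALSE)
  }
  ifelse(is.na(value), NA_integer_, as.integer(value < threshold))
}

#' Assemble the households-by-indicators 0/1 matrix
#'
#' Combines a cohort's asset columns with electricity and the dichotomized
#' people-per-room indicator. Households with a missing value in any
#' requested indicator are ineligible and dropped with a warning.
#'
#' @param cohort a `wami_cohort`.
#' @param indicators indicator names to include; default all assets plus
#'   `"electricity"` and `"people_per_room"`.
#' @param ppr_threshold crowding cutoff passed to
#'   [dichotomize_people_per_room()].
#' @return An `indicator_matrix`: list with `values` (0/1 matrix),
#'   `indicator_names`, `household_ids`.
#' @export
indicator_matrix <- function(cohort, indicators = NULL, ppr_threshold = 2) {
  stopifnot(inherits(cohort, "wami_cohort"))
  if (is.null(indicators)) {
    indicators <- c(asset_names(cohort), "electricity", "people_per_room")
  }
  cols <- lapply(indicators, function(ind) {
    if (ind == "people_per_room") {
      dichotomize_people_per_room(cohort$people_per_room, ppr_threshold)
    } else if (ind %in% c(asset_names(cohort), "electricity",
                          "improved_water", "improved_sanitation")) {
      cohort[[ind]]
    } else {
      stop("unknown indicator: ", ind, call. = FALSE)
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- indicators
  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    warning(sprintf("%d household(s) with missing indicator data dropped",
                    sum(!complete)), call. = FALSE)
  }
  new_indicator_matrix(m[complete, , drop = FALSE],
                       household_ids = cohort$household_id[complete])
}

#' Construct an indicator matrix from a plain 0/1 matrix
#'
#' @param values households x indicators matrix with entries 0/1.
#' @param indicator_names,household_ids optional dimension names; defaults
#'   come from `dimnames(values)` or are generated.
#' @return An `indicator_matrix`.
#' @export
new_indicator_matrix <- function(values, indicator_names = colnames(values),
                                 household_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(indicator_names)) {
    indicator_names <- paste0("ind", seq_len(ncol(values)))
  }
  if (is.null(household_ids)) {
    household_ids <- paste0("hh", seq_len(nrow(values)))
  }
  if (!all(values %in% c(0, 1))) {
    stop("indicator matrix entries must be 0/1", call. = FALSE)
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(NULL, indicator_names)
  structure(list(values = values,
                 indicator_names = as.character(indicator_names),
                 household_ids = as.character(household_ids)),
            class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf("<indicator_matrix> %d households x %d indicators\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

.as_values <- function(x) {
  if (inherits(x, "indicator_matrix")) x$values else as.matrix(x)
}

#' Cronbach's coefficient alpha
#'
#' Internal-consistency reliability of a set of items:
#' \eqn{\alpha = k/(k-1) \, (1 - \sum_i s_i^2 / s_T^2)} where \eqn{s_i^2}
#' are item variances and \eqn{s_T^2} the variance of the row totals.
#'
#' @param x an `indicator_matrix` or numeric matrix (rows = households).
#' @return The alpha coefficient (at most 1; 1 exactly for identical items).
#' @export
cronbach_alpha <- function(x) {
  m <- .as_values(x)
  if (ncol(m) < 2) stop("alpha requires at least 2 indicators", call. = FALSE)
  if (nrow(m) < 2) stop("alpha requires at least 2 households", call. = FALSE)
  item_var <- apply(m, 2, stats::var)
  const <- item_var == 0
  if (any(const)) {
    stop("constant indicator(s): ",
         paste(colnames(m)[const], collapse = ", "), call. = FALSE)
  }
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  (k / (k - 1)) * (1 - sum(item_var) / total_var)
}

#' Alpha with each indicator deleted in turn
#'
#' @param x an `indicator_matrix` or numeric matrix with >= 3 columns.
#' @return Named vector: alpha of the matrix with that column removed.
#' @export
alpha_if_deleted <- function(x) {
  m <- .as_values(x)
  if (ncol(m) < 3) stop("alpha_if_deleted requires >= 3 indicators",
                        call. = FALSE)
  out <- vapply(seq_len(ncol(m)), function(j) {
    cronbach_alpha(m[, -j, drop = FALSE])
  }, numeric(1))
  names(out) <- colnames(m)
  out
}

#' Screen candidate indicators by variation and reliability
#'
#' Two passes. First, indicators with fewer than `min_category_prop` of
#' households in their rarer category are dropped (`low_variation`). Then
#' indicators are removed one at a time — always the one whose deletion
#' raises alpha the most, ties broken by name order — while the raise
#' exceeds `alpha_drop_delta` (`alpha_drop`).
#'
#' @param x an `indicator_matrix`.
#' @param min_category_prop minimum proportion in the rarer category
#'   (default 0.10); must be in (0, 0.5).
#' @param alpha_drop_delta minimum improvement in alpha that justifies
#'   dropping an indicator (default 0.01).
#' @return A `reliability_report`: list with `alpha_overall`,
#'   `alpha_if_deleted`, `prevalence`, `kept`, and `dropped`
#'   (data frame of indicator + reason).
#' @export
screen_indicators <- function(x, min_category_prop = 0.10,
                              alpha_drop_delta = 0.01) {
  stopifnot(inherits(x, "indicator_matrix"),
            min_category_prop > 0, min_category_prop < 0.5)
  m <- x$values
  prevalence <- colMeans(m)
  names(prevalence) <- colnames(m)

  minority <- pmin(prevalence, 1 - prevalence)
  low <- names(prevalence)[minority < min_category_prop]
  dropped <- data.frame(indicator = low,
                        reason = rep("low_variation", length(low)),
                        stringsAsFactors = FALSE)
  keep <- setdiff(colnames(m), low)
  if (length(keep) < 2) {
    stop("fewer than 2 indicators survive the low-variation screen",
         call. = FALSE)
  }

  cur <- m[, keep, drop = FALSE]
  repeat {
    alpha_now <- cronbach_alpha(cur)
    if (ncol(cur) < 3) break
    aid <- alpha_if_deleted(cur)
    gain <- aid - alpha_now
    if (max(gain) <= alpha_drop_delta) break
    # earliest name among ties at the maximal gain
    cand <- sort(names(gain)[gain == max(gain)])[1]
    dropped <- rbind(dropped, data.frame(indicator = cand,
                                         reason = "alpha_drop",
                                         stringsAsFactors = FALSE))
    cur <- cur[, setdiff(colnames(cur), cand), drop = FALSE]
  }

  kept <- colnames(cur)
  structure(list(
    alpha_overall = cronbach_alpha(cur),
    alpha_if_deleted = if (ncol(cur) >= 3) alpha_if_deleted(cur) else NULL,
    prevalence = prevalence,
    kept = kept,
    dropped = dropped
  ), class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> alpha = %.3f; %d kept, %d dropped\n",
              x$alpha_overall, length(x$kept), nrow(x$dropped)))
  if (nrow(x$dropped) > 0) {
    cat("dropped:\n")
    print(x$dropped, row.names = FALSE)
  }
  invisible(x)
}

#' Subset an indicator matrix to the kept indicators of a screening report
#'
#' @param x an `indicator_matrix`.
#' @param report a `reliability_report` (or character vector of names).
#' @return The restricted `indicator_matrix`, column order preserved.
#' @export
keep_indicators <- function(x, report) {
  keep <- if (inherits(report, "reliability_report")) report$kept else report
  sel <- intersect(x$indicator_names, keep)
  new_indicator_matrix(x$values[, sel, drop = FALSE],
                       indicator_names = sel,
                       household_ids = x$household_ids)
}
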