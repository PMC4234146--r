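# The four comparator wealth measures and the composite WAMI index.
#
# WAMI = (Water/sanitation + Assets + Maternal education + Income) / 32,
# each component scored 0..8:
#   water/sanitation: 4 points per improved source, summed (0, 4 or 8)
#   assets:           count of 8 selected assets owned
#   education:        completed years (0..16) divided by 2
#   income:           USD octile score 1..8 against fixed cutoffs

#' Maternal education as a continuous comparator
#'
#' Identity pass-through of completed years of schooling; the baseline
#' wealth measure against which the asset-based measures are compared.
#'
#' @param years non-negative years of completed schooling.
#' @return `years`, unchanged.
#' @export
education_measure <- function(years) {
  if (any(years < 0, na.rm = TRUE)) {
    stop("education years must be non-negative", call. = FALSE)
  }
  years
}

#' WAMI maternal-education component (0..8 points)
#'
#' Years of schooling on a 0–16 scale divided by 2; years above 16 are
#' capped so the component stays within its 0–8 bound.
#'
#' @param years non-negative years of completed schooling.
#' @return Points in \[0, 8\].
#' @export
education_score <- function(years) {
  if (any(years < 0, na.rm = TRUE)) {
    stop("education years must be non-negative", call. = FALSE)
  }
  pmin(years, 16) / 2
}

#' WAMI water/sanitation component (0, 4 or 8 points)
#'
#' 4 points for access to an improved water source and 4 for improved
#' sanitation, summed.
#'
#' @param improved_water,improved_sanitation 0/1 flags.
#' @return Points in \{0, 4, 8\}.
#' @export
water_sanitation_score <- function(improved_water, improved_sanitation) {
  if (any(is.na(improved_water)) || any(is.na(improved_sanitation))) {
    stop("improved_water and improved_sanitation must be non-missing",
         call. = FALSE)
  }
  if (!all(improved_water %in% 0:1) || !all(improved_sanitation %in% 0:1)) {
    stop("water/sanitation flags must be 0 or 1", call. = FALSE)
  }
  4 * improved_water + 4 * improved_sanitation
}

#' Default USD income octile cutoffs
#'
#' Upper bounds (inclusive) of the bins scored 1..7; incomes above the last
#' bound score 8. New cohorts can instead use empirical octiles via
#' [empirical_octile_cutoffs()].
#'
#' @return An `income_octile_cutoffs` object (7 strictly increasing upper
#'   bounds in USD).
#' @export
default_octile_cutoffs <- function() {
  income_octile_cutoffs(c(26, 47, 72, 106, 135, 200, 293))
}

#' Construct income octile cutoffs
#'
#' @param upper_bounds strictly increasing upper bounds (USD) for scores
#'   1..7; the 8th bin is unbounded above.
#' @return An `income_octile_cutoffs` object.
#' @export
income_octile_cutoffs <- function(upper_bounds) {
  upper_bounds <- as.numeric(upper_bounds)
  if (length(upper_bounds) != 7 || any(diff(upper_bounds) <= 0)) {
    stop("octile cutoffs must be 7 strictly increasing upper bounds",
         call. = FALSE)
  }
  structure(list(upper_bounds = upper_bounds),
            class = "income_octile_cutoffs")
}

#' Empirical income octiles of a cohort
#'
#' @param income_usd household incomes in USD.
#' @return An `income_octile_cutoffs` object from the sample's 1/8..7/8
#'   quantiles (rounded to 2 decimals).
#' @export
empirical_octile_cutoffs <- function(income_usd) {
  q <- stats::quantile(income_usd, probs = (1:7) / 8, na.rm = TRUE,
                       names = FALSE)
  q <- round(q, 2)
  if (any(diff(q) <= 0)) {
    stop("income distribution too concentrated for distinct octile cutoffs",
         call. = FALSE)
  }
  income_octile_cutoffs(q)
}

#' WAMI income component: octile score 1..8
#'
#' Incomes are rounded to 2 decimals (the cutoffs form a two-decimal USD
#' lattice) and assigned the first bin whose upper bound is >= income;
#' bin upper bounds are inclusive, so 26.00 scores 1 and 26.01 scores 2.
#'
#' @param income_usd non-negative income(s) in USD.
#' @param cutoffs an `income_octile_cutoffs`; default the fixed USD table.
#' @return Integer score(s) 1..8.
#' @examples
#' income_octile_score(c(26, 26.01, 100, 500))
#' @export
income_octile_score <- function(income_usd, cutoffs = default_octile_cutoffs()) {
  stopifnot(inherits(cutoffs, "income_octile_cutoffs"))
  if (any(is.na(income_usd))) stop("income must be non-missing",
                                   call. = FALSE)
  if (any(income_usd < 0)) stop("income must be non-negative", call. = FALSE)
  inc <- round(income_usd, 2)
  bounds <- c(cutoffs$upper_bounds, Inf)
  vapply(inc, function(v) which(bounds >= v)[1], integer(1))
}

#' WAMI components and composite score
#'
#' Computes the four WAMI components per household and the composite
#' `wami = total / 32`.
#'
#' @param cohort a `wami_cohort` with an `income_usd` column (see
#'   [add_income_usd()]).
#' @param assets the selected asset set (length 8 in the canonical index;
#'   any length k is accepted, the asset component then ranges 0..k).
#' @param cutoffs income octile cutoffs.
#' @param ppr_threshold crowding cutoff for a `people_per_room` asset.
#' @return A tibble: `household_id`, `site`, `water_san_score`,
#'   `asset_score`, `education_score`, `income_score`, `total`, `wami`.
#' @export
wami <- function(cohort, assets, cutoffs = default_octile_cutoffs(),
                 ppr_threshold = 2) {
  stopifnot(inherits(cohort, "wami_cohort"))
  if (is.null(cohort$income_usd)) {
    stop("cohort has no income_usd column; convert income first ",
         "(add_income_usd)", call. = FALSE)
  }
  for (f in c("improved_water", "improved_sanitation",
              "maternal_education_years", "income_usd")) {
    if (any(is.na(cohort[[f]]))) {
      stop("missing values in WAMI component input: ", f, call. = FALSE)
    }
  }
  ws <- water_sanitation_score(cohort$improved_water,
                               cohort$improved_sanitation)
  as_ <- unname(asset_score(cohort, assets, ppr_threshold = ppr_threshold))
  ed <- education_score(cohort$maternal_education_years)
  inc <- income_octile_score(cohort$income_usd, cutoffs)
  total <- ws + as_ + ed + inc
  tibble::tibble(household_id = cohort$household_id,
                 site = cohort$site,
                 water_san_score = ws,
                 asset_score = as.numeric(as_),
                 education_score = ed,
                 income_score = as.numeric(inc),
                 total = total,
                 wami = total / 32)
}

#' MPI deprivation cutoffs
#'
#' Household-level adaptation of the Multidimensional Poverty Index with
#' three equally weighted dimensions: education (maternal schooling below a
#' cutoff), health (any child has died), and living standard (no
#' electricity, unimproved water, unimproved sanitation, natural flooring,
#' solid cooking fuel, and ownership of at most one of seven listed assets).
#'
#' @param education_years schooling-deprivation cutoff: deprived when
#'   completed years are strictly below this (default 5).
#' @param assets exactly 7 asset indicator names for the asset-ownership
#'   deprivation.
#' @param asset_count_threshold deprived when owned count of the listed
#'   assets is <= this (default 1, i.e. "not more than one of seven").
#' @return An `mpi_cutoffs` object.
#' @export
mpi_cutoffs <- function(education_years = 5,
                        assets = c("radio", "tv", "mobile_phone", "fridge",
                                   "sewing_machine", "computer", "iron"),
                        asset_count_threshold = 1) {
  if (length(assets) != 7) {
    stop("the MPI asset list must have exactly 7 entries", call. = FALSE)
  }
  structure(list(education_years = education_years,
                 assets = assets,
                 asset_count_threshold = asset_count_threshold),
            class = "mpi_cutoffs")
}

#' MPI household wealth score
#'
#' Deprivation D is the equal-weight mean of the three dimension scores
#' (the living-standard dimension is itself the mean of its six
#' indicators); the returned score is wealth = 1 - D, so all measures in
#' the package point the same way (higher = wealthier).
#'
#' @param cohort a `wami_cohort`.
#' @param cutoffs an [mpi_cutoffs()].
#' @return Numeric scores in \[0, 1\] named by household id.
#' @export
mpi_wealth <- function(cohort, cutoffs = NULL) {
  stopifnot(inherits(cohort, "wami_cohort"))
  if (is.null(cutoffs)) {
    avail <- asset_names(cohort)
    defaults <- c("radio", "tv", "mobile_phone", "fridge",
                  "sewing_machine", "computer", "iron")
    use <- intersect(defaults, avail)
    if (length(use) < 7) use <- utils::head(unique(c(use, avail)), 7)
    cutoffs <- mpi_cutoffs(assets = use)
  }
  stopifnot(inherits(cutoffs, "mpi_cutoffs"))
  need <- c("maternal_education_years", "any_child_died", "electricity",
            "improved_water", "improved_sanitation", "natural_flooring",
            "solid_cooking_fuel")
  for (f in need) {
    if (any(is.na(cohort[[f]]))) {
      stop("missing values in MPI input field: ", f, call. = FALSE)
    }
  }
  owned <- asset_score(cohort, cutoffs$assets)
  edu_dep <- as.numeric(cohort$maternal_education_years <
                          cutoffs$education_years)
  health_dep <- as.numeric(cohort$any_child_died)
  living <- cbind(no_electricity = 1 - cohort$electricity,
                  unimproved_water = 1 - cohort$improved_water,
                  unimproved_sanitation = 1 - cohort$improved_sanitation,
                  natural_flooring = cohort$natural_flooring,
                  solid_cooking_fuel = cohort$solid_cooking_fuel,
                  few_assets = as.numeric(owned <=
                                            cutoffs$asset_count_threshold))
  deprivation <- (edu_dep + health_dep + rowMeans(living)) / 3
  out <- 1 - deprivation
  names(out) <- cohort$household_id
  out
}

#' Compute a per-household wealth/SES index by method
#'
#' Dispatch over the five measures. `pca`, `rf_assets` and `wami` need
#' fitted context: a `pca_wealth_index` for `pca`, a selected asset set for
#' `rf_assets` and `wami`.
#'
#' @param cohort a `wami_cohort`.
#' @param method one of `"education"`, `"pca"`, `"mpi"`, `"rf_assets"`,
#'   `"wami"`.
#' @param context list of fitted artifacts: `pca` (a `pca_wealth_index`),
#'   `assets` (character), optional `octile_cutoffs`, `mpi_cutoffs`,
#'   `ppr_threshold`.
#' @return A `wealth_index` tibble: `household_id`, `site`, `score`, with
#'   attributes `method` and `metadata`.
#' @export
compute_index <- function(cohort, method, context = list()) {
  stopifnot(inherits(cohort, "wami_cohort"))
  methods <- c("education", "pca", "mpi", "rf_assets", "wami")
  if (!is.character(method) || length(method) != 1 || !method %in% methods) {
    stop("unknown method; expected one of: ",
         paste(methods, collapse = ", "), call. = FALSE)
  }
  ppr <- context$ppr_threshold %||% 2
  meta <- list()
  score <- switch(
    method,
    education = education_measure(cohort$maternal_education_years),
    pca = {
      if (is.null(context$pca)) {
        stop("method 'pca' requires a fitted pca_wealth_index in ",
             "context$pca (run tetrachoric_matrix + pca_first_component)",
             call. = FALSE)
      }
      im <- indicator_matrix(cohort,
                             indicators = names(context$pca$loadings),
                             ppr_threshold = ppr)
      if (length(im$household_ids) != nrow(cohort)) {
        stop("households with missing indicators cannot be scored by pca",
             call. = FALSE)
      }
      meta$loadings <- context$pca$loadings
      unname(pca_score(context$pca, im))
    },
    mpi = unname(mpi_wealth(cohort, context$mpi_cutoffs)),
    rf_assets = {
      if (is.null(context$assets)) {
        stop("method 'rf_assets' requires a selected asset set in ",
             "context$assets (run fit_forest + conditional_importance + ",
             "select_assets)", call. = FALSE)
      }
      meta$assets <- context$assets
      as.numeric(asset_score(cohort, context$assets, ppr_threshold = ppr))
    },
    wami = {
      if (is.null(context$assets)) {
        stop("method 'wami' requires a selected asset set in ",
             "context$assets", call. = FALSE)
      }
      comp <- wami(cohort, context$assets,
                   cutoffs = context$octile_cutoffs %||%
                     default_octile_cutoffs(),
                   ppr_threshold = ppr)
      meta$components <- comp
      meta$assets <- context$assets
      comp$wami
    })
  out <- tibble::tibble(household_id = cohort$household_id,
                        site = cohort$site,
                        score = score)
  attr(out, "method") <- method
  attr(out, "metadata") <- meta
  class(out) <- c("wealth_index", class(out))
  out
}
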