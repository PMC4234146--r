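# Seeded synthetic multicountry cohort generator.
#
# Households carry a latent wealth factor w ~ N(site mean, site SD). Each
# binary indicator j is a probit dichotomization of
#   y_j = loading * w_std + sqrt(1 - loading^2) * noise,
# so the pairwise tetrachoric correlation between indicators is exactly
# loading^2 — tetrachoric recovery on generated data is a true
# parameter-recovery test. Education, income, water/sanitation, crowding and
# the MPI fields are drawn from wealth-linked models, and HAZ is linear in a
# scaled SES composite of the signal components plus Gaussian noise.

#' Default asset indicator names and target prevalences
#' @noRd
.default_assets <- c(
  iron = 0.55, mattress = 0.58, chair = 0.61, sofa = 0.35,
  cupboard = 0.45, table = 0.57, radio = 0.50, computer = 0.12,
  tv = 0.63, sewing_machine = 0.20, mobile_phone = 0.65, fridge = 0.31,
  bank_account = 0.31, separate_kitchen = 0.50
)

#' Synthetic cohort generator configuration
#'
#' Defaults emulate an eight-site, 100-households-per-site cross-sectional
#' survey: three poorer sites, three middle sites and two wealthier sites on
#' the latent-wealth scale; 14 binary assets plus electricity and a
#' people-per-room indicator (16 candidate indicators); wealth-linked
#' education, log-normal income in USD, site-level improved water and
#' sanitation coverage; and HAZ linear in a scaled WAMI-like SES composite
#' with site intercepts calibrated so roughly 42% of children are stunted.
#'
#' @param n_sites number of sites.
#' @param n_per_site households per site.
#' @param site_wealth_means,site_wealth_sds latent wealth location/scale per
#'   site (recycled to `n_sites`).
#' @param asset_prevalences named vector of target overall prevalences for
#'   the binary assets.
#' @param asset_loading loading of standardized latent wealth on each asset
#'   (pairwise tetrachoric correlation = `asset_loading^2`).
#' @param site_threshold_shift per-site shift added to every asset's probit
#'   threshold (site-varying prevalences beyond the wealth gradient).
#' @param electricity_prevalence,electricity_loading probit model for the
#'   electricity indicator.
#' @param ppr_log_mean,ppr_wealth_slope,ppr_log_sd log-normal model for
#'   people per room (decreasing in wealth).
#' @param edu_site_means,edu_wealth_slope,edu_sd maternal education model
#'   (years, clamped to 0..16 and rounded).
#' @param income_log_base,income_site_shift_scale,income_wealth_slope,income_log_sd
#'   log-normal USD income model; the site shift is
#'   `income_site_shift_scale` times the site's standardized wealth mean.
#' @param water_site_probs,sanitation_site_probs per-site coverage of
#'   improved water/sanitation.
#' @param child_died_intercept,child_died_slope logistic model for the
#'   any-child-died MPI indicator.
#' @param flooring_prevalence,fuel_prevalence,housing_loading probit models
#'   for natural flooring and solid cooking fuel (deprivations, decreasing
#'   in wealth).
#' @param signal_assets asset indicators entering the SES composite that
#'   drives HAZ.
#' @param n_signal_assets used when `signal_assets` is NULL: the first
#'   `n_signal_assets` assets become the signal set.
#' @param true_effect HAZ change per unit of the scaled (0..1) SES
#'   composite.
#' @param asset_effects optional named vector of additional direct HAZ
#'   effects per asset indicator.
#' @param wsh_effect additional direct HAZ effect of the mean of the two
#'   water/sanitation flags (independent signal beyond the composite).
#' @param haz_site_intercepts per-site HAZ intercepts.
#' @param haz_noise_sd residual HAZ standard deviation.
#' @param target_stunting stunting proportion targeted by
#'   [calibrate_stunting()].
#' @param seed mandatory integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_sites = 8, n_per_site = 100,
    site_wealth_means = c(-1.1, -0.8, -0.6, -0.1, 0.0, 0.2, 0.9, 1.1),
    site_wealth_sds = 0.8,
    asset_prevalences = .default_assets,
    asset_loading = 0.7,
    site_threshold_shift = 0,
    electricity_prevalence = 0.6, electricity_loading = 0.7,
    ppr_log_mean = 0.55, ppr_wealth_slope = 0.45, ppr_log_sd = 0.35,
    edu_site_means = c(3.3, 4.5, 5.3, 6.4, 6.6, 7.0, 7.8, 10.1),
    edu_wealth_slope = 1.2, edu_sd = 2.5,
    income_log_base = log(95), income_site_shift_scale = 0.6,
    income_wealth_slope = 0.55, income_log_sd = 0.6,
    water_site_probs = c(0.30, 0.70, 0.90, 0.95, 0.98, 0.98, 1.00, 1.00),
    sanitation_site_probs = c(0.05, 0.60, 0.75, 0.85, 0.90, 0.95, 1.00, 1.00),
    child_died_intercept = -1.2, child_died_slope = 0.4,
    flooring_prevalence = 0.45, fuel_prevalence = 0.55,
    housing_loading = 0.6,
    signal_assets = NULL, n_signal_assets = 8,
    true_effect = 1.5, asset_effects = NULL, wsh_effect = 0,
    haz_site_intercepts = c(-2.835, -2.735, -2.685, -2.585, -2.585,
                            -2.535, -2.435, -2.385),
    haz_noise_sd = 1.1,
    target_stunting = 0.42,
    seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory", call. = FALSE)
  }
  rec <- function(x) rep_len(x, n_sites)
  cfg <- list(
    n_sites = n_sites, n_per_site = n_per_site,
    site_codes = sprintf("S%02d", seq_len(n_sites)),
    site_wealth_means = rec(site_wealth_means),
    site_wealth_sds = rec(site_wealth_sds),
    asset_prevalences = asset_prevalences,
    asset_loading = asset_loading,
    site_threshold_shift = rec(site_threshold_shift),
    electricity_prevalence = electricity_prevalence,
    electricity_loading = electricity_loading,
    ppr_log_mean = ppr_log_mean, ppr_wealth_slope = ppr_wealth_slope,
    ppr_log_sd = ppr_log_sd,
    edu_site_means = rec(edu_site_means),
    edu_wealth_slope = edu_wealth_slope, edu_sd = edu_sd,
    income_log_base = income_log_base,
    income_site_shift_scale = income_site_shift_scale,
    income_wealth_slope = income_wealth_slope,
    income_log_sd = income_log_sd,
    water_site_probs = rec(water_site_probs),
    sanitation_site_probs = rec(sanitation_site_probs),
    child_died_intercept = child_died_intercept,
    child_died_slope = child_died_slope,
    flooring_prevalence = flooring_prevalence,
    fuel_prevalence = fuel_prevalence,
    housing_loading = housing_loading,
    signal_assets = signal_assets %||%
      names(asset_prevalences)[seq_len(min(n_signal_assets,
                                           length(asset_prevalences)))],
    true_effect = true_effect,
    asset_effects = asset_effects,
    wsh_effect = wsh_effect,
    haz_site_intercepts = rec(haz_site_intercepts),
    haz_noise_sd = haz_noise_sd,
    target_stunting = target_stunting,
    seed = as.integer(seed)
  )
  probs <- c(cfg$asset_prevalences, cfg$electricity_prevalence,
             cfg$water_site_probs, cfg$sanitation_site_probs,
             cfg$flooring_prevalence, cfg$fuel_prevalence)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$site_wealth_sds <= 0) || cfg$haz_noise_sd <= 0) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  if (abs(cfg$asset_loading) > 1) {
    stop("asset_loading must lie in [-1, 1]", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Population moments of the standardized latent wealth
#' @noRd
.wealth_moments <- function(config) {
  m <- mean(config$site_wealth_means)
  v <- mean((config$site_wealth_means - m)^2) +
    mean(config$site_wealth_sds^2)
  list(mean = m, sd = sqrt(v))
}

#' Model-implied overall prevalence of each binary asset
#'
#' Closed form under the probit latent-factor model, averaging over sites.
#'
#' @param config a [generator_config()].
#' @return Named vector of expected prevalences.
#' @export
expected_asset_prevalence <- function(config) {
  wm <- .wealth_moments(config)
  lam <- config$asset_loading
  a_s <- (config$site_wealth_means - wm$mean) / wm$sd  # site mean, std scale
  b_s <- config$site_wealth_sds / wm$sd
  res_sd_s <- sqrt(lam^2 * b_s^2 + 1 - lam^2)
  t_j <- stats::qnorm(1 - config$asset_prevalences)
  out <- vapply(seq_along(t_j), function(j) {
    mean(stats::pnorm((lam * a_s - (t_j[j] + config$site_threshold_shift)) /
                        res_sd_s))
  }, numeric(1))
  names(out) <- names(config$asset_prevalences)
  out
}

#' Probit indicator from standardized wealth
#' @noRd
.probit_indicator <- function(w_std, loading, threshold) {
  y <- loading * w_std +
    sqrt(1 - loading^2) * stats::rnorm(length(w_std))
  as.integer(y > threshold)
}

#' Generate a synthetic multicountry cohort
#'
#' Deterministic given `config$seed`. See [generator_config()] for the
#' generative model.
#'
#' @param config a [generator_config()].
#' @return List with `cohort` (a `wami_cohort`, incomes already in USD) and
#'   `truth` (latent wealth, the scaled SES composite, the signal asset
#'   set, and the generating effect sizes).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  K <- config$n_sites
  n <- K * config$n_per_site
  site_idx <- rep(seq_len(K), each = config$n_per_site)
  site <- config$site_codes[site_idx]

  w <- stats::rnorm(n, config$site_wealth_means[site_idx],
                    config$site_wealth_sds[site_idx])
  wm <- .wealth_moments(config)
  w_std <- (w - wm$mean) / wm$sd

  lam <- config$asset_loading
  assets <- sapply(names(config$asset_prevalences), function(a) {
    t_j <- stats::qnorm(1 - config$asset_prevalences[[a]]) +
      config$site_threshold_shift[site_idx]
    .probit_indicator(w_std, lam, t_j)
  })
  electricity <- .probit_indicator(
    w_std, config$electricity_loading,
    stats::qnorm(1 - config$electricity_prevalence))
  people_per_room <- exp(config$ppr_log_mean -
                           config$ppr_wealth_slope * w_std +
                           stats::rnorm(n, 0, config$ppr_log_sd))
  education <- pmin(16, pmax(0, round(
    config$edu_site_means[site_idx] + config$edu_wealth_slope * w_std +
      stats::rnorm(n, 0, config$edu_sd))))
  income_usd <- exp(config$income_log_base +
                      config$income_site_shift_scale *
                      (config$site_wealth_means[site_idx] - wm$mean) /
                      wm$sd +
                      config$income_wealth_slope * w_std +
                      stats::rnorm(n, 0, config$income_log_sd))
  income_usd <- round(income_usd, 2)
  improved_water <- stats::rbinom(n, 1, config$water_site_probs[site_idx])
  improved_sanitation <- stats::rbinom(
    n, 1, config$sanitation_site_probs[site_idx])
  any_child_died <- stats::rbinom(
    n, 1, stats::plogis(config$child_died_intercept -
                          config$child_died_slope * w_std))
  natural_flooring <- .probit_indicator(
    -w_std, config$housing_loading,
    stats::qnorm(1 - config$flooring_prevalence))
  solid_cooking_fuel <- .probit_indicator(
    -w_std, config$housing_loading,
    stats::qnorm(1 - config$fuel_prevalence))

  # scaled WAMI-like SES composite of the signal components
  sig <- config$signal_assets
  asset_comp <- if (length(sig) > 0) {
    8 * rowMeans(assets[, sig, drop = FALSE])
  } else rep(0, n)
  ses_total <- water_sanitation_score(improved_water, improved_sanitation) +
    asset_comp + education_score(education) +
    income_octile_score(income_usd)
  ses_scaled <- ses_total / 32

  haz <- config$haz_site_intercepts[site_idx] +
    config$true_effect * ses_scaled +
    config$wsh_effect * (improved_water + improved_sanitation) / 2 +
    stats::rnorm(n, 0, config$haz_noise_sd)
  if (!is.null(config$asset_effects)) {
    ae <- config$asset_effects
    miss <- setdiff(names(ae), colnames(assets))
    if (length(miss) > 0) stop("asset_effects for unknown asset(s): ",
                               paste(miss, collapse = ", "), call. = FALSE)
    haz <- haz + drop(assets[, names(ae), drop = FALSE] %*% ae)
  }

  rec <- tibble::tibble(
    household_id = sprintf("HH%04d", seq_len(n)),
    site = site,
    haz = haz,
    child_age_months = sample(24:60, n, replace = TRUE),
    child_sex = stats::rbinom(n, 1, 0.52),
    maternal_education_years = education,
    income_local = income_usd,
    currency = "USD",
    people_per_room = people_per_room,
    improved_water = improved_water,
    improved_sanitation = improved_sanitation,
    any_child_died = any_child_died,
    electricity = electricity,
    natural_flooring = natural_flooring,
    solid_cooking_fuel = solid_cooking_fuel,
    income_usd = income_usd
  )
  rec <- cbind(rec, tibble::as_tibble(assets))
  cohort <- new_cohort(rec, names(config$asset_prevalences),
                       provenance = sprintf(
                         "synthetic cohort (seed %d): %d sites x %d",
                         config$seed, K, config$n_per_site))
  truth <- list(latent_wealth = w_std,
                ses_scaled = ses_scaled,
                true_effect = config$true_effect,
                wsh_effect = config$wsh_effect,
                asset_effects = config$asset_effects,
                signal_assets = sig)
  list(cohort = cohort, truth = truth)
}

#' Calibrate HAZ intercepts to a target stunting proportion
#'
#' Simulates HAZ at a large n under the config, then shifts all site
#' intercepts by the constant that puts the simulated stunting proportion
#' on the target.
#'
#' @param config a [generator_config()].
#' @param n_sim households simulated for calibration (default 10000,
#'   rounded up to a multiple of the site count).
#' @return The config with shifted `haz_site_intercepts`.
#' @export
calibrate_stunting <- function(config, n_sim = 10000) {
  stopifnot(inherits(config, "generator_config"))
  target <- config$target_stunting
  if (target <= 0 || target >= 1) {
    stop("target stunting must lie strictly between 0 and 1 ",
         "(HAZ noise makes the boundaries unattainable)", call. = FALSE)
  }
  big <- config
  big$n_per_site <- ceiling(n_sim / config$n_sites)
  class(big) <- "generator_config"
  haz <- generate_cohort(big)$cohort$haz
  # stunting(shift) = mean(haz + shift < -2); exact on the simulated sample
  shift <- -2 - stats::quantile(haz, probs = target, names = FALSE,
                                type = 7)
  out <- config
  out$haz_site_intercepts <- config$haz_site_intercepts + shift
  out
}

#' Fixture cohort of 800 households with known exclusions
#'
#' A default synthetic cohort whose HAZ column is then modified so that
#' exactly one record has missing anthropometry and ten records have |HAZ|
#' beyond the filtering bound — the anthropometric filter retains exactly
#' 789 households.
#'
#' @param seed integer seed.
#' @param haz_abs_limit the filtering bound the extremes exceed (default 6).
#' @return A `wami_cohort` of 800 records.
#' @export
fixture_800 <- function(seed, haz_abs_limit = 6) {
  cfg <- generator_config(seed = seed)
  cohort <- generate_cohort(cfg)$cohort
  # ensure no accidental extremes before planting the known ones
  cohort$haz <- pmin(pmax(cohort$haz, -haz_abs_limit), haz_abs_limit)
  cohort$haz[1] <- NA_real_
  extremes <- (haz_abs_limit + c(0.5, 1.0, 1.5, 2.0, 2.5,
                                 0.7, 1.2, 1.7, 2.2, 2.7)) *
    rep(c(1, -1), each = 5)
  cohort$haz[2:11] <- extremes
  new_cohort(cohort, asset_names(cohort),
             provenance = c(attr(cohort, "provenance"),
                            "fixture: 1 missing HAZ, 10 extreme HAZ"))
}
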