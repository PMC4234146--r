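# Builders for small in-code fixtures.

# Minimal cohort with sensible defaults for every required field; any field
# can be overridden, and extra 0/1 asset columns supplied via `assets`
# (a named list or data.frame of columns).
make_test_cohort <- function(n = 6, site = "A", haz = NULL, assets = NULL,
                             ...) {
  overrides <- list(...)
  df <- tibble::tibble(
    household_id = sprintf("H%03d", seq_len(n)),
    site = rep_len(site, n),
    haz = haz %||% seq(-2, 1, length.out = n),
    child_age_months = rep_len(36L, n),
    child_sex = rep_len(c(0L, 1L), n),
    maternal_education_years = rep_len(c(0, 4, 8, 12, 16, 10), n),
    income_local = rep_len(c(10, 50, 90, 150, 250, 400), n),
    currency = "USD",
    people_per_room = rep_len(c(3, 2.5, 2, 1.5, 1, 0.8), n),
    improved_water = rep_len(c(0L, 1L), n),
    improved_sanitation = rep_len(c(0L, 0L, 1L), n),
    any_child_died = rep_len(0L, n),
    electricity = rep_len(c(0L, 1L), n),
    natural_flooring = rep_len(c(1L, 0L), n),
    solid_cooking_fuel = rep_len(c(1L, 1L, 0L), n)
  )
  for (f in names(overrides)) df[[f]] <- rep_len(overrides[[f]], n)
  asset_cols <- character()
  if (!is.null(assets)) {
    assets <- as.data.frame(assets)
    for (a in names(assets)) df[[a]] <- assets[[a]]
    asset_cols <- names(assets)
  }
  df$income_usd <- df$income_local
  new_cohort(df, asset_cols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Latent-factor binary matrix: k correlated items driven by one factor.
make_correlated_items <- function(n, k, loading = 0.7, prevalence = 0.5,
                                  seed = 1) {
  set.seed(seed)
  w <- stats::rnorm(n)
  m <- sapply(seq_len(k), function(j) {
    y <- loading * w + sqrt(1 - loading^2) * stats::rnorm(n)
    as.integer(y > stats::qnorm(1 - prevalence))
  })
  colnames(m) <- sprintf("item%02d", seq_len(k))
  m
}

# Independent oracle for Cronbach's alpha via the covariance matrix:
# alpha = k/(k-1) * (1 - tr(C)/sum(C)).
alpha_cov_oracle <- function(m) {
  C <- stats::cov(m)
  k <- ncol(m)
  (k / (k - 1)) * (1 - sum(diag(C)) / sum(C))
}

# Independent bivariate-normal upper-quadrant probability by Simpson's rule
# on a truncated grid (used by the tetrachoric grid-search oracle).
simpson_quadrant_prob <- function(t1, t2, rho, lim = 8, nstep = 2000) {
  x <- seq(max(t1, -lim), lim, length.out = nstep + 1)
  s <- sqrt(1 - rho^2)
  fx <- stats::dnorm(x) * stats::pnorm((rho * x - t2) / s)  # P(Y > t2 | x)
  h <- x[2] - x[1]
  w <- rep(c(4, 2), length.out = nstep - 1)
  h / 3 * (fx[1] + sum(w * fx[2:nstep]) + fx[nstep + 1])
}

# Grid-search tetrachoric oracle: maximize the multinomial likelihood of
# the 2x2 table over a rho grid, cell probabilities via Simpson quadrature.
tetrachoric_grid_oracle <- function(n11, n10, n01, n00,
                                    grid = seq(-0.99, 0.99, by = 0.001)) {
  N <- n11 + n10 + n01 + n00
  p1 <- (n11 + n10) / N
  p2 <- (n11 + n01) / N
  t1 <- stats::qnorm(1 - p1)
  t2 <- stats::qnorm(1 - p2)
  ll <- vapply(grid, function(r) {
    p11 <- simpson_quadrant_prob(t1, t2, r)
    p10 <- (1 - stats::pnorm(t1)) - p11
    p01 <- (1 - stats::pnorm(t2)) - p11
    p00 <- 1 - p11 - p10 - p01
    pr <- pmax(c(p11, p10, p01, p00), 1e-12)
    sum(c(n11, n10, n01, n00) * log(pr))
  }, numeric(1))
  grid[which.max(ll)]
}

# PRESS mean squared error via the hat matrix (closed form for OLS LOOCV).
press_mse_oracle <- function(y, X) {
  H <- X %*% solve(crossprod(X)) %*% t(X)
  r <- y - H %*% y
  mean((r / (1 - diag(H)))^2)
}
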