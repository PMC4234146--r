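# Tetrachoric correlation and first-principal-component wealth scoring.
#
# The tetrachoric correlation of two binary indicators is the correlation of
# the standard bivariate normal assumed to underlie them, estimated from the
# 2x2 cross-table by two-step maximum likelihood: thresholds fixed at the
# inverse-normal of the margins, rho by 1-D likelihood maximization.

#' Standard bivariate normal rectangle probability P(X <= h, Y <= k)
#'
#' Computed by 1-D quadrature of phi(x) * Phi((k - rho x)/sqrt(1 - rho^2)).
#' @param h,k upper limits (may be infinite).
#' @param rho correlation, |rho| < 1.
#' @return The probability.
#' @keywords internal
#' @export
pbinorm <- function(h, k, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (is.infinite(h) && h < 0) return(0)
  if (is.infinite(k) && k < 0) return(0)
  if (is.infinite(h)) return(stats::pnorm(k))
  if (is.infinite(k)) return(stats::pnorm(h))
  if (abs(rho) < 1e-12) return(stats::pnorm(h) * stats::pnorm(k))
  s <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((k - rho * x) / s)
  stats::integrate(f, -Inf, h, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Cell probabilities of the thresholded bivariate normal
#'
#' @param t1,t2 thresholds; indicator = 1 when the latent variable exceeds
#'   its threshold.
#' @param rho latent correlation.
#' @return Named vector `p11, p10, p01, p00` (clamped away from 0).
#' @keywords internal
#' @noRd
.tetra_cell_probs <- function(t1, t2, rho) {
  p00 <- pbinorm(t1, t2, rho)
  p0x <- stats::pnorm(t1)
  px0 <- stats::pnorm(t2)
  p01 <- p0x - p00            # x below threshold, y above
  p10 <- px0 - p00
  p11 <- 1 - p0x - px0 + p00
  pmax(c(p11 = p11, p10 = p10, p01 = p01, p00 = p00), 1e-12)
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Two-step maximum likelihood: thresholds from the margins, rho by
#' maximizing the multinomial likelihood over (-0.999, 0.999). Tables with a
#' zero cell receive a 0.5 continuity correction to every cell and the
#' estimate is flagged as a boundary case.
#'
#' @param n11,n10,n01,n00 cell counts: both indicators 1; first only;
#'   second only; neither.
#' @return List with `rho`, `thresholds` (length 2), and `boundary` flag.
#' @examples
#' tetrachoric_from_table(40, 10, 10, 40)$rho
#' @export
tetrachoric_from_table <- function(n11, n10, n01, n00) {
  n <- c(n11, n10, n01, n00)
  if (any(n < 0) || sum(n) < 1) stop("invalid counts", call. = FALSE)
  r1 <- n11 + n10  # margin of the first indicator = 1
  r0 <- n01 + n00
  c1 <- n11 + n01
  c0 <- n10 + n00
  if (r1 == 0 || r0 == 0 || c1 == 0 || c0 == 0) {
    stop("degenerate margin: one indicator is constant", call. = FALSE)
  }
  boundary <- any(n == 0)
  if (boundary) n <- n + 0.5
  N <- sum(n)
  p1 <- (n[1] + n[2]) / N  # P(first = 1)
  p2 <- (n[1] + n[3]) / N
  t1 <- stats::qnorm(1 - p1)
  t2 <- stats::qnorm(1 - p2)
  negll <- function(rho) {
    pr <- .tetra_cell_probs(t1, t2, rho)
    -sum(n * log(pr))
  }
  opt <- stats::optimize(negll, interval = c(-0.999, 0.999), tol = 1e-7)
  rho <- max(min(opt$minimum, 0.999), -0.999)
  list(rho = rho, thresholds = c(t1, t2), boundary = boundary)
}

#' Pairwise tetrachoric correlation matrix of an indicator set
#'
#' Estimates all pairwise tetrachoric correlations; if the assembled matrix
#' has an eigenvalue below `-psd_tol` it is replaced by its nearest positive
#' semidefinite correlation matrix (eigenvalue clipping, unit diagonal
#' restored) and `psd_adjusted` is set.
#'
#' @param x an `indicator_matrix` (screened).
#' @param psd_tol tolerance for negative eigenvalues before repair.
#' @return A `tetrachoric_matrix`: list with `rho` (symmetric matrix,
#'   unit diagonal), `thresholds` (per-indicator normal quantile of
#'   1 - prevalence), `psd_adjusted`, and `boundary` (logical matrix of
#'   clamped pairs).
#' @export
tetrachoric_matrix <- function(x, psd_tol = 1e-8) {
  m <- .as_values(x)
  p <- ncol(m)
  if (p < 2) stop("need at least 2 indicators", call. = FALSE)
  rho <- diag(1, p)
  boundary <- matrix(FALSE, p, p)
  dimnames(rho) <- dimnames(boundary) <- list(colnames(m), colnames(m))
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      a <- m[, i]; b <- m[, j]
      est <- tryCatch(
        tetrachoric_from_table(sum(a == 1 & b == 1), sum(a == 1 & b == 0),
                               sum(a == 0 & b == 1), sum(a == 0 & b == 0)),
        error = function(e) {
          stop(sprintf("tetrachoric estimation failed for pair (%s, %s): %s",
                       colnames(m)[i], colnames(m)[j], conditionMessage(e)),
               call. = FALSE)
        })
      rho[i, j] <- rho[j, i] <- est$rho
      boundary[i, j] <- boundary[j, i] <- est$boundary
    }
  }
  thresholds <- stats::qnorm(1 - colMeans(m))
  names(thresholds) <- colnames(m)
  psd_adjusted <- FALSE
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -psd_tol) {
    rho <- .nearest_psd_corr(rho)
    psd_adjusted <- TRUE
  }
  structure(list(rho = rho, thresholds = thresholds,
                 psd_adjusted = psd_adjusted, boundary = boundary),
            class = "tetrachoric_matrix")
}

#' Nearest positive semidefinite correlation matrix by eigenvalue clipping
#' @noRd
.nearest_psd_corr <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  out <- e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
  out <- stats::cov2cor(out)
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

#' @export
print.tetrachoric_matrix <- function(x, ...) {
  cat(sprintf("<tetrachoric_matrix> %d indicators%s\n", ncol(x$rho),
              if (x$psd_adjusted) " (PSD-repaired)" else ""))
  invisible(x)
}

#' First-principal-component wealth index
#'
#' Performs PCA on a (tetrachoric) correlation matrix and scores each
#' household by the leading eigenvector applied to its standardized
#' indicators: \eqn{\sum_j w_j (x_j - \bar x_j)/s_j}, the standardization
#' using sample prevalence mean and SD (Filmer–Pritchett convention).
#' Scores are standardized to mean 0, SD 1 over the cohort. The loading
#' sign is fixed so the anchor indicator loads positively.
#'
#' @param tet a `tetrachoric_matrix` (or plain correlation matrix).
#' @param x the `indicator_matrix` to score; columns must match `tet`.
#' @param anchor indicator name used to orient the component; default is the
#'   indicator most positively correlated with the rest (largest row sum of
#'   the correlation matrix).
#' @param multiplicity_tol relative eigengap below which the leading
#'   component is declared non-unique.
#' @return A `pca_wealth_index`: list with `loadings` (unit norm),
#'   `eigenvalue_share`, `scores` (named by household), `anchor`, and the
#'   standardization (`means`, `sds`) needed to score new households.
#' @export
pca_first_component <- function(tet, x, anchor = NULL,
                                multiplicity_tol = 1e-8) {
  rho <- if (inherits(tet, "tetrachoric_matrix")) tet$rho else as.matrix(tet)
  m <- .as_values(x)
  if (!identical(colnames(rho), colnames(m))) {
    stop("indicator matrix columns must match the correlation matrix",
         call. = FALSE)
  }
  e <- eigen(rho, symmetric = TRUE)
  gap <- (e$values[1] - e$values[2]) / max(e$values[1], .Machine$double.eps)
  if (gap < multiplicity_tol) {
    stop("leading eigenvalue is not unique; the first component is not ",
         "identified — choose an explicit anchor set of indicators or ",
         "inspect the correlation matrix", call. = FALSE)
  }
  loadings <- e$vectors[, 1]
  names(loadings) <- colnames(rho)
  if (is.null(anchor)) {
    anchor <- colnames(rho)[which.max(rowSums(rho))]
  }
  if (!anchor %in% colnames(rho)) {
    stop("anchor indicator not present: ", anchor, call. = FALSE)
  }
  if (loadings[anchor] < 0) loadings <- -loadings
  means <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant indicator(s) cannot be standardized: ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(m, 2, means, "-"), 2, sds, "/")
  raw <- drop(z %*% loadings)
  scores <- (raw - mean(raw)) / stats::sd(raw)
  names(scores) <- x$household_ids
  structure(list(loadings = loadings,
                 eigenvalue_share = e$values[1] / sum(e$values),
                 scores = scores,
                 anchor = anchor,
                 means = means, sds = sds,
                 score_center = mean(raw), score_scale = stats::sd(raw)),
            class = "pca_wealth_index")
}

#' Score new households with a fitted PCA wealth index
#'
#' Applies the training-cohort loadings and standardization, so held-out
#' households are scored on the training scale.
#'
#' @param index a `pca_wealth_index`.
#' @param x an `indicator_matrix` with the same indicators.
#' @return Numeric scores named by household id.
#' @export
pca_score <- function(index, x) {
  m <- .as_values(x)
  if (!identical(colnames(m), names(index$loadings))) {
    stop("indicator columns do not match the fitted index", call. = FALSE)
  }
  z <- sweep(sweep(m, 2, index$means, "-"), 2, index$sds, "/")
  raw <- drop(z %*% index$loadings)
  out <- (raw - index$score_center) / index$score_scale
  names(out) <- x$household_ids
  out
}

#' @export
print.pca_wealth_index <- function(x, ...) {
  cat(sprintf(
    "<pca_wealth_index> %d indicators, eigenvalue share %.1f%%, anchor '%s'\n",
    length(x$loadings), 100 * x$eigenvalue_share, x$anchor))
  invisible(x)
}

#' Write a square correlation matrix to CSV (header row and column)
#' @param tet a `tetrachoric_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tetrachoric_csv <- function(tet, path) {
  utils::write.csv(as.data.frame(tet$rho), path, row.names = TRUE)
  invisible(path)
}
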