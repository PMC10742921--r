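# Three levels of error: raw residuals (X - E), expected absolute residuals
# (EAR, the modeled RMS residual scale per cell), and standard errors (SE,
# the expected distance between a cell estimate and the unobserved true
# value).  EAR and SE are themselves summarized by 2-dimensional coordinate
# pairs so person/item error statistics can be recomputed on the fly from a
# bank without the calibration data.

.EAR_EPS <- 1e-12

#' Raw residual matrix
#'
#' @param X `data_matrix` or numeric matrix with `NA` missing cells.
#' @param E estimates matrix of the same shape.
#' @return `X - E` on observed cells, `NA` elsewhere.
#' @export
residual_matrix <- function(X, E) {
  vals <- as_values(X)
  stopifnot(all(dim(vals) == dim(E)))
  vals - E
}

# shared pipeline for Eq.-(11)-style decompositions: square, floor, log,
# 2-dimensional ALS, exponentiate, per-column degree-1 polyfit back onto the
# raw squares, floor, square root.
.decompose_scale <- function(sq_raw, seed, eps, tol, max_iter) {
  if (is.null(rownames(sq_raw)))
    rownames(sq_raw) <- paste0("p", seq_len(nrow(sq_raw)))
  if (is.null(colnames(sq_raw)))
    colnames(sq_raw) <- paste0("i", seq_len(ncol(sq_raw)))
  sq <- pmax(sq_raw, eps)
  L <- log(sq)
  obs_r <- rowSums(!is.na(L)); obs_c <- colSums(!is.na(L))
  if (any(obs_r < 3) || any(obs_c < 3))
    stop("need at least 3 observations per row and column to model the error scale")
  fit <- als_decompose(L, d = 2L, seed = seed, tol = tol, max_iter = max_iter)
  Lhat <- fitted(fit)
  Lhat_full <- matrix(NA_real_, nrow(L), ncol(L), dimnames = dimnames(L))
  Lhat_full[rownames(Lhat), colnames(Lhat)] <- Lhat
  M <- exp(pmin(Lhat_full, 700))
  out <- matrix(NA_real_, nrow(L), ncol(L), dimnames = dimnames(L))
  polyfit <- matrix(NA_real_, 2L, ncol(L),
                    dimnames = list(c("intercept", "slope"), colnames(L)))
  floors <- setNames(numeric(ncol(L)), colnames(L))
  for (j in seq_len(ncol(L))) {
    o <- which(!is.na(sq_raw[, j]) & is.finite(M[, j]))
    m <- M[o, j]
    cf <- c(mean(sq_raw[o, j]), 0)
    if (length(o) >= 3L && sd(m) > 0) {
      cf_lm <- coef(lm(sq_raw[o, j] ~ m))
      if (all(is.finite(cf_lm))) cf <- cf_lm
    }
    polyfit[, j] <- cf
    # the degree-1 fit can dip negative; floor it relative to the column's
    # own residual scale so standardized misfits stay bounded (exact-fit
    # columns still bottom out at eps)
    floors[j] <- max(eps, 0.05 * median(sq_raw[o, j]))
    out[, j] <- pmax(cf[1] + cf[2] * M[, j], floors[j])
  }
  list(values = sqrt(out), row_coords = fit$R, col_coords = fit$C,
       polyfit = polyfit, floors = floors)
}

#' Expected absolute residuals (EAR)
#'
#' Models the characteristic residual scale of every cell: squared residuals
#' are floored at `eps`, logged (turning the hard zero floor into an
#' unbounded interval metric and the row-by-column product into a sum,
#' absorbed by a second dimension), decomposed by ALS at dimensionality 2,
#' exponentiated, mapped back onto the raw squared residuals by a per-column
#' degree-1 polynomial fit, floored, and square-rooted.
#'
#' @param residuals signed residual matrix (`NA` where missing), at least 3
#'   observations per row and column.
#' @param seed seed for the 2-dimensional decomposition.
#' @param eps floor applied to squared residuals before the log (default
#'   `1e-12`); exact-fit cells give `EAR ~ sqrt(eps)`.
#' @param tol,max_iter passed to [als_decompose()].
#' @return `list(ear, row_coords (N x 2), col_coords (2 x I),
#'   polyfit (2 x I))`.
#' @export
estimate_ear <- function(residuals, seed = 1L, eps = .EAR_EPS,
                         tol = 1e-6, max_iter = 50L) {
  res <- .decompose_scale(residuals^2, seed, eps, tol, max_iter)
  list(ear = res$values, row_coords = res$row_coords,
       col_coords = res$col_coords, polyfit = res$polyfit,
       floors = res$floors)
}

#' Cell standard error from EAR, observation counts, and dimensionality
#'
#' `SE = 2 * ear * sqrt(d) / ((r - d) * (c - d))^(1/4)`, where `r` and `c`
#' count the observed cells in the row and column.  As `r -> d` or `c -> d`
#' the estimate interpolates the data exactly and its uncertainty diverges:
#' the function returns `+Inf` at `r = d` or `c = d`.  The
#' `"rc_minus_1"` variant replaces the denominator by
#' `((r - 1) * (c - 1))^(1/4)`.
#'
#' @param ear expected absolute residual(s), `> 0`.
#' @param r,c observed-cell counts (recycled against `ear`).
#' @param d dimensionality.
#' @param variant denominator convention; `"rc_minus_d"` is canonical.
#' @return standard error(s); error if `r < d` or `c < d`.
#' @export
standard_error <- function(ear, r, c, d, variant = c("rc_minus_d", "rc_minus_1")) {
  variant <- match.arg(variant)
  if (any(r < d) || any(c < d)) stop("invalid counts: r and c must be >= d")
  denom <- switch(variant,
                  rc_minus_d = ((r - d) * (c - d))^(1 / 4),
                  rc_minus_1 = ((r - 1) * (c - 1))^(1 / 4))
  out <- 2 * ear * sqrt(d) / denom
  out[denom == 0] <- Inf
  out
}

#' One-facet, one-dimension standard error
#'
#' With a single facet and a single dimension the cell standard-error formula
#' collapses to the classical form with `n - 1` in the denominator: a sample
#' of one value carries infinite uncertainty.
#'
#' @param ear residual scale (plays the role of the standard deviation).
#' @param n number of observations.
#' @return `ear / sqrt(n - 1)` (`+Inf` at `n = 1`).
#' @export
standard_error_1d <- function(ear, n) {
  out <- ear / sqrt(n - 1)
  out[n == 1] <- Inf
  out
}

#' Expected standard errors (ESE)
#'
#' Applies the same square/log/2-dimensional-ALS/polyfit/sqrt pipeline as
#' [estimate_ear()] to the SE matrix, yielding smooth expected standard
#' errors and a portable pair of 2-dimensional coordinates from which person
#' and item standard errors can be recomputed on the fly.  Infinite SE cells
#' are excluded from the fit and refilled from the coordinates.
#'
#' @param se standard-error matrix (`NA` where missing, `Inf` allowed).
#' @inheritParams estimate_ear
#' @return `list(ese, row_coords, col_coords, polyfit)`.
#' @export
estimate_ese <- function(se, seed = 1L, eps = .EAR_EPS,
                         tol = 1e-6, max_iter = 50L) {
  sq <- se^2
  sq[!is.finite(sq)] <- NA
  res <- .decompose_scale(sq, seed, eps, tol, max_iter)
  list(ese = res$values, row_coords = res$row_coords,
       col_coords = res$col_coords, polyfit = res$polyfit,
       floors = res$floors)
}

#' Cell misfit and person/item outfit
#'
#' Cell misfit standardizes each residual by its expected scale,
#' `(X - E) / EAR`; person and item outfit are the root mean square of the
#' cell misfits across a row or column.  A person is flagged interpretable
#' when outfit is below `threshold` (default 2.0); scores of persons with
#' larger outfit occupy an indeterminate location in the space and should be
#' set aside.
#'
#' @param X observations (`data_matrix` or matrix with `NA`).
#' @param E estimates matrix.
#' @param ear EAR matrix, `> 0` on observed cells.
#' @param threshold interpretability threshold on person outfit.
#' @return `list(cell, person_outfit, item_outfit, interpretable,
#'   frac_large)` where `frac_large` is the fraction of observed cells with
#'   `|misfit| > 2`.
#' @export
misfit <- function(X, E, ear, threshold = 2.0) {
  vals <- as_values(X)
  cell <- (vals - E) / ear
  person_outfit <- sqrt(rowMeans(cell^2, na.rm = TRUE))
  item_outfit <- sqrt(colMeans(cell^2, na.rm = TRUE))
  list(cell = cell,
       person_outfit = person_outfit,
       item_outfit = item_outfit,
       interpretable = person_outfit < threshold,
       frac_large = mean(abs(cell) > 2, na.rm = TRUE))
}

#' Full cell error model for a calibration
#'
#' Convenience wrapper chaining [residual_matrix()], [estimate_ear()], the
#' cell standard errors of [standard_error()] (with `r`, `c` counting
#' observed cells, so missingness is folded into the standard error), and
#' [estimate_ese()].
#'
#' @param X observations.
#' @param coords a [coordinate_set()].
#' @param seed seed for the two error decompositions.
#' @param se_variant passed to [standard_error()].
#' @param tol,max_iter passed to the internal decompositions.
#' @return object of class `noise_model` with elements `residuals`, `ear`,
#'   `se`, `ese`, `ear_coords`, `se_coords` (each a list with `row`, `col`,
#'   `polyfit`), `row_counts`, `col_counts`, `d`.
#' @export
estimate_noise_model <- function(X, coords, seed = 1L,
                                 se_variant = "rc_minus_d",
                                 tol = 1e-6, max_iter = 50L) {
  vals <- as_values(X)
  vals <- vals[rownames(coords$R), colnames(coords$C), drop = FALSE]
  E <- fitted(coords)
  res <- residual_matrix(vals, E)
  ear_fit <- estimate_ear(res, seed = seed, tol = tol, max_iter = max_iter)
  r_n <- rowSums(!is.na(vals))
  c_i <- colSums(!is.na(vals))
  d <- coords$dimensionality
  se <- standard_error(ear_fit$ear,
                       r = matrix(r_n, nrow(vals), ncol(vals)),
                       c = matrix(c_i, nrow(vals), ncol(vals), byrow = TRUE),
                       d = d, variant = se_variant)
  ese_fit <- estimate_ese(se, seed = seed + 1L, tol = tol, max_iter = max_iter)
  structure(list(residuals = res, ear = ear_fit$ear, se = se, ese = ese_fit$ese,
                 ear_coords = list(row = ear_fit$row_coords,
                                   col = ear_fit$col_coords,
                                   polyfit = ear_fit$polyfit,
                                   floors = ear_fit$floors),
                 se_coords = list(row = ese_fit$row_coords,
                                  col = ese_fit$col_coords,
                                  polyfit = ese_fit$polyfit,
                                  floors = ese_fit$floors),
                 row_counts = r_n, col_counts = c_i, d = d),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("noise_model: %d x %d cells, d = %d, median EAR %.3g, median SE %.3g\n",
              nrow(x$ear), ncol(x$ear), x$d,
              median(x$ear, na.rm = TRUE), median(x$se[is.finite(x$se)])))
  invisible(x)
}
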