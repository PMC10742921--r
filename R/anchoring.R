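# Age-anchored multistep calibration, common-item equating, and item drift.

#' Project out the age dimension
#'
#' Steps 1-2 of the age-anchored calibration: center the natural log of age
#' and scale it to unit norm, solve each column's age loading by least
#' squares over that column's observed cells, and return the residual
#' matrix.  By the normal equations every residual column is orthogonal to
#' the age vector over its observed cells.
#'
#' @param X pseudo-logit response matrix (`data_matrix` or matrix with `NA`).
#' @param ages positive ages in years, one per row.
#' @return `list(age_vector, loadings, residuals)`: the unit-norm centered
#'   log-age vector, the per-column loadings `C[1,]`, and `Res = X - E1`.
#' @export
age_residualize <- function(X, ages) {
  vals <- as_values(X)
  if (length(ages) != nrow(vals))
    stop("need one age per person (", nrow(vals), " persons)")
  bad <- !is.finite(ages) | ages <= 0
  if (any(bad))
    stop("missing or invalid age for persons: ",
         paste(rownames(vals)[bad], collapse = ", "))
  la <- log(ages)
  v <- la - mean(la)
  v <- v / sqrt(sum(v^2))
  obs <- !is.na(vals)
  vv <- colSums(v^2 * obs)
  vx <- colSums(v * ifelse(obs, vals, 0))
  c1 <- vx / vv
  list(age_vector = v, loadings = c1, residuals = vals - outer(v, c1))
}

#' Age-anchored multistep calibration
#'
#' Disentangles age from the construct dimensions by assigning age its own,
#' known coordinate before the residual factorization:
#'
#' 1. the natural log of age (equalizing age differences across the range) is
#'    centered and scaled to unit norm and installed as the first person
#'    coordinate `R[,1]`;
#' 2. each column's age loading `C[1,]` is solved by least squares over its
#'    observed cells, giving `E1` and the residual matrix `Res = X - E1`
#'    (each residual column is orthogonal to the age vector on its observed
#'    cells);
#' 3. ALS at `d_residual` decomposes `Res` into the remaining dimensions;
#' 4. the residual dimensions are appended to the age dimension;
#' 5. an anchored refinement (ALS iterations with the age dimension held
#'    fixed) absorbs the age variance the per-column solves of step 2 leak
#'    into the residual space, after which a final pass solves C from R and
#'    then R from C — the person coordinates are computed last so the person
#'    measures reflect the best attainable fit.
#'
#' Total dimensionality is `D = d_residual + 1`.  The raw log-age scale is
#' absorbed into `C[1,]`; the final free R pass re-estimates the age
#' coordinate, so the returned R is not orthonormal (it is the best-fit
#' solution given C).
#'
#' @param X pseudo-logit response matrix (`data_matrix` or matrix with `NA`).
#' @param ages positive ages in years, one per row of `X` (all required).
#' @param d_residual number of residual (non-age) dimensions, `>= 1`.
#' @param seed seed for the residual decomposition.
#' @param tol,max_iter convergence control for the ALS stages.
#' @param refine_iter iterations of the anchored refinement in step 5
#'   (default 25; set 0 for the literal single-pass finish).
#' @return [coordinate_set()] with `anchored_dims = 1`.
#' @export
age_anchored_calibration <- function(X, ages, d_residual, seed = 1L,
                                     tol = 1e-6, max_iter = 50L,
                                     refine_iter = 25L) {
  vals <- as_values(X)
  if (length(ages) != nrow(vals))
    stop("need one age per person (", nrow(vals), " persons)")
  bad <- !is.finite(ages) | ages <= 0
  if (any(bad))
    stop("missing or invalid age for persons: ",
         paste(rownames(vals)[bad], collapse = ", "))
  stopifnot(d_residual >= 1)

  # steps 1-2: unit-norm log-age dimension, per-column loadings, residuals
  ar <- age_residualize(vals, ages)
  v <- ar$age_vector
  Res <- ar$residuals

  # step 3: residual factorization
  fit2 <- als_decompose(Res, d_residual, seed = seed, tol = tol,
                        max_iter = max_iter)
  if (length(fit2$dropped_rows) || length(fit2$dropped_cols))
    stop("rows/columns with too few observations for the residual ",
         "factorization: ",
         paste(c(fit2$dropped_rows, fit2$dropped_cols), collapse = ", "))

  # step 4: merge age and residual dimensions
  R_pen <- cbind(v, fit2$R)
  colnames(R_pen) <- NULL
  d <- d_residual + 1L

  # step 5: anchored refinement, then C from R and R from C (persons last)
  C_init <- .solve_C(vals, R_pen)
  if (refine_iter > 0L) {
    ref <- .als_engine(vals, R_pen, C_init, 1L, integer(0),
                       tol, as.integer(refine_iter), TRUE)
    R_pen <- ref$R
  }
  C_fin <- .solve_C(vals, R_pen)
  R_fin <- .solve_R(vals, C_fin)
  dimnames(R_fin) <- list(rownames(vals), NULL)
  dimnames(C_fin) <- list(NULL, colnames(vals))
  coordinate_set(R_fin, C_fin, seed = seed, anchored_dims = 1L,
                 converged = fit2$converged, n_iter = fit2$n_iter,
                 rms_resid = sqrt(mean((vals - R_fin %*% C_fin)^2, na.rm = TRUE)))
}

# one least-squares pass for all columns / all rows (missing cells skipped)
.solve_C <- function(vals, R) {
  vapply(seq_len(ncol(vals)), function(i)
    solve_coordinates(vals[, i], R), numeric(ncol(R)))
}
.solve_R <- function(vals, C) {
  t(vapply(seq_len(nrow(vals)), function(n)
    solve_coordinates(vals[n, ], t(C)), numeric(nrow(C))))
}

#' Equate a new form to a reference item bank by common-item anchoring
#'
#' The C coordinates of the items the new form shares with the bank are held
#' fixed at their bank values; each person's coordinates on the new form are
#' then solved in a single least-squares pass from the common items alone,
#' and the remaining (new) item coordinates from those persons.  All persons
#' and items of both forms end up in one coordinate system; the fit of the
#' common-item estimates to the new form's observations certifies the link.
#'
#' @param reference_bank an [item_bank()].
#' @param X_B pseudo-logit response matrix of the new form.
#' @param common_ids item ids present in both (default: the intersection).
#' @param min_common minimum number of common items (default `2 * D`; the
#'   model minimum is `D + 1`).
#' @param outfit_warn warn if mean common-item outfit-like RMS residual
#'   exceeds this value (default 2).
#' @return `list(coords, fit)`: the Form-B [coordinate_set()] (common columns
#'   anchored) and a per-common-item fit report.
#' @export
equate_forms <- function(reference_bank, X_B, common_ids = NULL,
                         min_common = NULL, outfit_warn = 2) {
  stopifnot(inherits(reference_bank, "item_bank"))
  vals <- as_values(X_B)
  D <- reference_bank$dimensionality
  bank_ids <- colnames(reference_bank$C)
  if (is.null(common_ids)) common_ids <- intersect(colnames(vals), bank_ids)
  if (is.null(min_common)) min_common <- 2L * D
  if (!all(common_ids %in% bank_ids) || !all(common_ids %in% colnames(vals)))
    stop("common ids must be present in both the bank and the new form")
  if (length(common_ids) <= D)
    stop("under-identified link: need more than D = ", D, " common items, got ",
         length(common_ids))
  if (length(common_ids) < min_common)
    warning("fewer than ", min_common, " common items; the link may be noisy")

  C_common <- reference_bank$C[, common_ids, drop = FALSE]
  R_B <- t(vapply(seq_len(nrow(vals)), function(n)
    solve_coordinates(vals[n, common_ids], t(C_common)), numeric(D)))
  rownames(R_B) <- rownames(vals)

  C_B <- matrix(NA_real_, D, ncol(vals), dimnames = list(NULL, colnames(vals)))
  C_B[, common_ids] <- C_common
  new_ids <- setdiff(colnames(vals), common_ids)
  for (i in new_ids) C_B[, i] <- solve_coordinates(vals[, i], R_B)

  E_common <- R_B %*% C_common
  res <- vals[, common_ids, drop = FALSE] - E_common
  fit <- data.frame(item = common_ids,
                    rms_residual = sqrt(colMeans(res^2, na.rm = TRUE)),
                    n_obs = colSums(!is.na(res)))
  if (mean(fit$rms_residual) > outfit_warn)
    warning("equating may have failed: mean common-item RMS residual ",
            signif(mean(fit$rms_residual), 3))
  list(coords = coordinate_set(R_B, C_B, seed = reference_bank$provenance$seed,
                               anchored_cols = common_ids, converged = TRUE,
                               n_iter = 1L),
       fit = fit)
}

#' Item drift between two calibrations
#'
#' Compares item coordinates calibrated from two person groups in a common
#' frame (same anchors) — the multidimensional analogue of differential item
#' functioning.  Reported per item, per dimension, and pooled.
#'
#' @param C_group1,C_group2 D x I item coordinate matrices with column names.
#' @param shared_ids items to compare (default: the intersection).
#' @return `list(per_item, per_dimension, pooled)` of Pearson correlations.
#' @export
item_drift <- function(C_group1, C_group2, shared_ids = NULL) {
  if (is.null(shared_ids))
    shared_ids <- intersect(colnames(C_group1), colnames(C_group2))
  if (length(shared_ids) == 0) stop("no shared items")
  A <- C_group1[, shared_ids, drop = FALSE]
  B <- C_group2[, shared_ids, drop = FALSE]
  per_item <- vapply(shared_ids, function(i) cor(A[, i], B[, i]), 0)
  per_dim <- vapply(seq_len(nrow(A)), function(k) cor(A[k, ], B[k, ]), 0)
  list(per_item = per_item, per_dimension = per_dim,
       pooled = cor(as.vector(A), as.vector(B)))
}
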