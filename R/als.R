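#' Dot-product cell estimate
#'
#' The model estimate for a cell is the dot product of the person and item
#' coordinate vectors across dimensions.
#'
#' @param row_coords,col_coords numeric vectors of equal length D.
#' @return scalar estimate `sum(row_coords * col_coords)`.
#' @export
dot_estimate <- function(row_coords, col_coords) {
  if (length(row_coords) != length(col_coords))
    stop("dimension error: coordinate vectors have different lengths")
  sum(row_coords * col_coords)
}

#' Least-squares coordinate solve over non-missing cells
#'
#' Solves for one entity's D coordinates from its observed values and the
#' matching slices of the opposite coordinate matrix, using only non-missing
#' positions.  This is the single half-step of the alternating algorithm and
#' is also what equating and bank scoring use.
#'
#' @param observed numeric vector (length m) possibly containing `NA`.
#' @param basis numeric matrix whose rows align with `observed`: m x D (one
#'   basis row per observation).  A D x m matrix is transposed automatically.
#' @param mask optional logical vector marking the entries to use; default
#'   `!is.na(observed)`.
#' @return numeric vector of D coordinates (ordinary least squares; minimum
#'   norm with a warning reporting the condition number when the system is
#'   rank-deficient).
#' @export
solve_coordinates <- function(observed, basis, mask = NULL) {
  basis <- as.matrix(basis)
  if (nrow(basis) != length(observed) && ncol(basis) == length(observed))
    basis <- t(basis)
  if (nrow(basis) != length(observed))
    stop("basis rows must align with observed entries")
  if (is.null(mask)) mask <- !is.na(observed)
  y <- observed[mask]
  A <- basis[mask, , drop = FALSE]
  d <- ncol(A)
  if (length(y) <= d)
    stop("underdetermined: ", length(y), " observations for ", d, " dimensions")
  qa <- qr(A)
  if (qa$rank < d) {
    sv <- svd(A, nu = 0, nv = 0)$d
    kappa <- sv[1] / max(sv[length(sv)], .Machine$double.eps)
    warning(sprintf(
      "rank-deficient basis (rank %d < %d, condition %.3g); minimum-norm solution",
      qa$rank, d, kappa))
    return(drop(MASS::ginv(A) %*% y))
  }
  drop(qr.coef(qa, y))
}

#' Orthonormalize the columns of a coordinate matrix
#'
#' QR decomposition retaining only the orthonormal factor; the triangular
#' factor is re-absorbed by the next column half-iteration of the
#' alternation.  Column signs are fixed so the map is idempotent.
#'
#' @param R numeric matrix with full column rank.
#' @return matrix with orthonormal columns spanning the same column space.
#' @export
orthonormalize <- function(R) {
  R <- as.matrix(R)
  qa <- qr(R)
  if (qa$rank < ncol(R))
    stop("degenerate space: R is rank-deficient (rank ", qa$rank, " < ", ncol(R), ")")
  Q <- qr.Q(qa)
  s <- sign(diag(qr.R(qa)))
  s[s == 0] <- 1
  sweep(Q, 2L, s, `*`)
}

#' Coordinate set
#'
#' Holds the calibrated person coordinates R (N x D), item coordinates C
#' (D x I), and provenance: seed, anchors, convergence.  Unanchored R columns
#' are orthonormal at convergence; while R and C individually depend on the
#' random initialization, their product E = RC does not (the axis orientation
#' is arbitrary).
#'
#' @param R,C coordinate matrices.
#' @param seed integer seed used for initialization.
#' @param anchored_cols item ids whose C vectors were held fixed.
#' @param anchored_dims number of leading R dimensions held fixed.
#' @param converged,n_iter,rms_resid convergence metadata.
#' @param dropped_rows,dropped_cols entities excluded from calibration.
#' @return object of class `coordinate_set`.
#' @export
coordinate_set <- function(R, C, seed = NA_integer_, anchored_cols = character(0),
                           anchored_dims = 0L, converged = NA, n_iter = NA_integer_,
                           rms_resid = numeric(0), dropped_rows = character(0),
                           dropped_cols = character(0)) {
  stopifnot(ncol(R) == nrow(C))
  structure(list(R = R, C = C, dimensionality = ncol(R), seed = seed,
                 anchored_cols = anchored_cols, anchored_dims = anchored_dims,
                 converged = converged, n_iter = n_iter, rms_resid = rms_resid,
                 dropped_rows = dropped_rows, dropped_cols = dropped_cols),
            class = "coordinate_set")
}

#' @export
print.coordinate_set <- function(x, ...) {
  cat(sprintf("coordinate_set: %d persons x %d items, D = %d (%s, %d iterations)\n",
              nrow(x$R), ncol(x$C), x$dimensionality,
              if (isTRUE(x$converged)) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' @export
fitted.coordinate_set <- function(object, ...) object$R %*% object$C

#' Alternating least squares decomposition with missing data
#'
#' Factors an N x I matrix with missing cells as `X ~ RC` at dimensionality
#' `d`.  C is initialized with standard-normal draws from `seed`; rows of R
#' and columns of C are then updated in turn by ordinary least squares over
#' the non-missing cells only, with R re-orthonormalized by QR every
#' iteration.  No regularization is used anywhere.  Iteration stops when the
#' RMS change of the estimates over observed cells falls below `tol`.
#'
#' Rows or columns with `<= d` observed cells cannot be solved and are
#' excluded from calibration with a warning (their ids are recorded on the
#' result).  Anchors: `anchored_cols` holds the named columns of `C_init`
#' fixed (common-item equating); `R_anchor` fixes leading R dimensions (age
#' anchoring).
#'
#' @param X `data_matrix` or numeric matrix with `NA` missing cells.
#' @param d target dimensionality, `d < min(N, I)`.
#' @param seed integer seed for the `"random"` initialization of C (the
#'   product E is insensitive to it on well-fitting data; R and C
#'   individually are not).
#' @param init initialization of C: `"svd"` (default) uses the leading right
#'   singular vectors of the column-mean-imputed matrix — a deterministic
#'   spectral warm start that converges reliably even under blocked
#'   missingness; `"random"` draws standard-normal entries from `seed`,
#'   suited to multi-seed workflows that keep the best of several runs.
#' @param tol convergence tolerance on the RMS change of E (default `1e-6`).
#' @param max_iter maximum iterations (default 50; convergence typically
#'   needs fewer than 20 on well-conditioned data).
#' @param orthonormalize orthonormalize R each iteration (default TRUE).
#' @param C_init optional D x I initial C (required when `anchored_cols` is
#'   non-empty); unnamed columns are drawn from `seed`.
#' @param anchored_cols character ids of columns whose C vectors stay fixed.
#' @param R_anchor optional N x k matrix of fixed leading R dimensions.
#' @return [coordinate_set()] with convergence metadata; `converged = FALSE`
#'   flags the best iterate when `max_iter` is reached.
#' @export
als_decompose <- function(X, d, seed = 1L, init = c("svd", "random"),
                          tol = 1e-6, max_iter = 50L,
                          orthonormalize = TRUE, C_init = NULL,
                          anchored_cols = character(0), R_anchor = NULL) {
  init <- match.arg(init)
  vals <- as_values(X)
  if (is.null(rownames(vals))) rownames(vals) <- paste0("p", seq_len(nrow(vals)))
  if (is.null(colnames(vals))) colnames(vals) <- paste0("i", seq_len(ncol(vals)))
  all_rows <- rownames(vals); all_cols <- colnames(vals)
  k <- if (is.null(R_anchor)) 0L else ncol(as.matrix(R_anchor))
  if (d >= min(dim(vals))) stop("d must be smaller than min(N, I)")
  if (length(anchored_cols) && !all(anchored_cols %in% colnames(vals)))
    stop("unknown anchor ids: ",
         paste(setdiff(anchored_cols, colnames(vals)), collapse = ", "))

  # exclude unsolvable rows/columns (<= d observations)
  repeat {
    obs <- !is.na(vals)
    bad_r <- rowSums(obs) <= d
    bad_c <- colSums(obs) <= d
    if (!any(bad_r) && !any(bad_c)) break
    warning("excluding from calibration: ",
            paste(c(rownames(vals)[bad_r], colnames(vals)[bad_c]), collapse = ", "))
    vals <- vals[!bad_r, !bad_c, drop = FALSE]
    if (!is.null(R_anchor)) R_anchor <- as.matrix(R_anchor)[!bad_r, , drop = FALSE]
    if (!is.null(C_init)) C_init <- C_init[, !bad_c, drop = FALSE]
  }
  dropped_rows <- setdiff(all_rows, rownames(vals))
  dropped_cols <- setdiff(all_cols, colnames(vals))

  N <- nrow(vals); I <- ncol(vals)
  set.seed(seed)
  C0 <- if (init == "svd") {
    imp <- vals
    cm <- colMeans(vals, na.rm = TRUE)
    idx <- which(is.na(imp), arr.ind = TRUE)
    if (nrow(idx)) imp[idx] <- cm[idx[, 2L]]
    sv <- svd(imp, nu = 0, nv = d)
    t(sv$v) * sv$d[seq_len(d)]
  } else {
    matrix(rnorm(d * I), d, I)
  }
  if (!is.null(C_init)) {
    stopifnot(nrow(C_init) == d)
    keep <- intersect(colnames(C_init), colnames(vals))
    C0[, match(keep, colnames(vals))] <- C_init[, keep, drop = FALSE]
  }
  R0 <- matrix(rnorm(N * d), N, d)
  if (k > 0L) {
    stopifnot(nrow(R_anchor) == N, k <= d)
    R0[, seq_len(k)] <- as.matrix(R_anchor)
  }
  anchor_idx <- match(anchored_cols, colnames(vals)) - 1L

  fit <- .als_engine(vals, R0, C0, k, as.integer(anchor_idx),
                     tol, as.integer(max_iter), orthonormalize)
  R <- fit$R; C <- fit$C
  dimnames(R) <- list(rownames(vals), NULL)
  dimnames(C) <- list(NULL, colnames(vals))
  coordinate_set(R, C, seed = seed, anchored_cols = anchored_cols,
                 anchored_dims = k, converged = fit$converged,
                 n_iter = fit$n_iter, rms_resid = drop(fit$rms_resid),
                 dropped_rows = dropped_rows, dropped_cols = dropped_cols)
}
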