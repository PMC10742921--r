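# Dimensionality selection by cross-validated "objectivity":
# accuracy = holdout prediction of pseudo-missing cells,
# stability = agreement of person coordinates across item halves,
# objectivity = sqrt(accuracy * stability), maximized over d.

#' Holdout accuracy at a candidate dimensionality
#'
#' Hides a seeded random subset of the observed cells ("pseudo-missing"),
#' refits the decomposition at dimensionality `d`, and returns the Pearson
#' correlation between the hidden observations and their estimates.  The
#' hiding respects solvability: every row and column keeps more than `d`
#' observed cells.
#'
#' @param X `data_matrix` or numeric matrix with `NA` missing cells.
#' @param d candidate dimensionality.
#' @param fraction fraction of observed cells to hide (default 0.1, max 0.25).
#' @param seed seed controlling both the holdout draw and the refit.
#' @param ... passed to [als_decompose()].
#' @return correlation in `[-1, 1]`.
#' @export
accuracy <- function(X, d, fraction = 0.1, seed = 1L, ...) {
  stopifnot(fraction > 0, fraction <= 0.25)
  vals <- as_values(X)
  if (is.null(rownames(vals))) rownames(vals) <- paste0("p", seq_len(nrow(vals)))
  if (is.null(colnames(vals))) colnames(vals) <- paste0("i", seq_len(ncol(vals)))
  obs_idx <- which(!is.na(vals))
  n_hide <- floor(fraction * length(obs_idx))
  if (n_hide < 2L) stop("infeasible holdout: too few observed cells to hide")
  set.seed(seed + 211L)
  cand <- sample(obs_idx)
  rc <- rowSums(!is.na(vals)); cc <- colSums(!is.na(vals))
  ri <- ((cand - 1L) %% nrow(vals)) + 1L
  ci <- ((cand - 1L) %/% nrow(vals)) + 1L
  hide <- logical(length(cand)); taken <- 0L
  for (j in seq_along(cand)) {
    if (taken >= n_hide) break
    if (rc[ri[j]] > d + 1L && cc[ci[j]] > d + 1L) {
      hide[j] <- TRUE
      rc[ri[j]] <- rc[ri[j]] - 1L; cc[ci[j]] <- cc[ci[j]] - 1L
      taken <- taken + 1L
    }
  }
  if (taken < 2L) stop("infeasible holdout: hiding would break solvability")
  hidden <- cand[hide]
  train <- vals
  train[hidden] <- NA
  fit <- als_decompose(train, d, seed = seed, ...)
  E <- fitted(fit)
  # align in case rows/cols were dropped from the training fit
  E_full <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  E_full[rownames(E), colnames(E)] <- E
  ok <- is.finite(E_full[hidden])
  cor(vals[hidden][ok], E_full[hidden][ok])
}

#' Split-half stability of the person coordinates
#'
#' Splits the items into two non-overlapping halves (alternating columns),
#' calibrates R from each half at dimensionality `d`, aligns the second
#' solution to the first by orthogonal Procrustes rotation (independent runs
#' differ by an arbitrary rotation), and returns the Pearson correlation of
#' corresponding R entries.
#'
#' @inheritParams accuracy
#' @return correlation in `[-1, 1]`.
#' @export
stability <- function(X, d, seed = 1L, ...) {
  vals <- as_values(X)
  I <- ncol(vals)
  if (I < 2 * (d + 1)) stop("infeasible split: need I >= 2(d+1) columns")
  h1 <- seq(1L, I, by = 2L); h2 <- seq(2L, I, by = 2L)
  f1 <- als_decompose(vals[, h1, drop = FALSE], d, seed = seed, ...)
  f2 <- als_decompose(vals[, h2, drop = FALSE], d, seed = seed + 1L, ...)
  common <- intersect(rownames(f1$R), rownames(f2$R))
  R1 <- f1$R[common, , drop = FALSE]
  R2 <- f2$R[common, , drop = FALSE]
  R2a <- R2 %*% procrustes_rotation(R2, R1)
  cor(as.vector(R1), as.vector(R2a))
}

#' Orthogonal Procrustes rotation
#'
#' Rotation Q minimizing `||A Q - B||_F` (no scaling, no translation), used
#' to place independently calibrated coordinate sets in a common frame.
#'
#' @param A,B matrices of identical shape.
#' @return orthogonal rotation matrix Q.
#' @export
procrustes_rotation <- function(A, B) {
  s <- svd(crossprod(A, B))
  s$u %*% t(s$v)
}

#' Objectivity: root product of accuracy and stability
#'
#' Negative inputs are clamped to zero with a warning (the square root of a
#' negative product is undefined).
#'
#' @param accuracy,stability correlations.
#' @return `sqrt(accuracy * stability)`.
#' @export
objectivity <- function(accuracy, stability) {
  if (any(c(accuracy, stability) < 0, na.rm = TRUE)) {
    warning("negative accuracy/stability clamped to 0")
    accuracy <- pmax(accuracy, 0); stability <- pmax(stability, 0)
  }
  sqrt(accuracy * stability)
}

#' Search for the best dimensionality
#'
#' Evaluates accuracy, stability, and objectivity for each dimensionality in
#' `1..d_max` over `n_seeds` seeds, keeping the best seed per dimensionality,
#' and selects the dimensionality maximizing objectivity (ties go to the
#' smallest d).  The objectivity curve typically rises to a well-defined peak
#' at the true dimensionality and declines as overfitting erodes stability.
#'
#' @inheritParams accuracy
#' @param d_max largest dimensionality tried (`< min(N, I)/2`).
#' @param n_seeds seeds per dimensionality (default 5).
#' @param fraction pseudo-missing fraction for the accuracy holdout.
#' @return a `dim_report`: data frame `$report` with columns
#'   `d, accuracy, stability, objectivity, best_seed`, plus `best_d`,
#'   `pseudo_missing_fraction`, `seeds_tried`.
#' @export
best_dimensionality <- function(X, d_max = 10L, n_seeds = 5L, fraction = 0.1,
                                seed = 1L, ...) {
  vals <- as_values(X)
  if (d_max >= min(dim(vals)) / 2) stop("d_max must be below min(N, I)/2")
  seeds <- seed + seq_len(n_seeds) - 1L
  rows <- vector("list", d_max)
  for (d in seq_len(d_max)) {
    best <- NULL
    for (s in seeds) {
      acc <- accuracy(vals, d, fraction = fraction, seed = s, ...)
      sta <- stability(vals, d, seed = s, ...)
      obj <- suppressWarnings(objectivity(acc, sta))
      if (is.null(best) || isTRUE(obj > best$objectivity))
        best <- list(accuracy = acc, stability = sta, objectivity = obj, seed = s)
    }
    rows[[d]] <- data.frame(d = d, accuracy = best$accuracy,
                            stability = best$stability,
                            objectivity = best$objectivity,
                            best_seed = best$seed)
  }
  report <- do.call(rbind, rows)
  best_d <- report$d[which.max(report$objectivity)]  # which.max: first max = smallest d
  structure(list(report = report, best_d = best_d,
                 pseudo_missing_fraction = fraction, seeds_tried = seeds),
            class = "dim_report")
}

#' @export
print.dim_report <- function(x, ...) {
  cat("Dimensionality search (holdout fraction",
      x$pseudo_missing_fraction, ")\n")
  print(x$report, row.names = FALSE, digits = 3)
  cat("best d:", x$best_d, "\n")
  invisible(x)
}

#' Write a dimensionality report as CSV + JSON summary
#' @param x a `dim_report`.
#' @param csv_path,json_path output paths (either may be NULL).
#' @export
write_dim_report <- function(x, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(x$report, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(best_d = x$best_d,
                              pseudo_missing_fraction = x$pseudo_missing_fraction,
                              seeds_tried = x$seeds_tried,
                              report = x$report),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}
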