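# Construct coordinates, the linear 0-100 risk scale, classification, and
# scoring of new persons from an item bank.

#' Affine pseudo-logit-to-risk-scale transform
#'
#' Captures the complete map from a raw construct estimate to the reported
#' 0-100 scale: the variance-restoring semi-true rescale
#' `g * (x - center) + center` followed by the affine map
#' `slope * . + intercept`.  Persisting all four numbers in the bank makes
#' calibration and scoring reproduce identical values.
#'
#' @param semi_true_factor variance-restoring factor `g >= 1`.
#' @param center calibration mean of the construct estimates.
#' @param slope,intercept affine constants; `slope > 0` so a higher construct
#'   estimate always means a higher scale score.
#' @return object of class `scale_transform`.
#' @export
scale_transform <- function(semi_true_factor = 1, center = 0, slope = 1,
                            intercept = 0) {
  if (slope <= 0) stop("slope must be positive")
  structure(list(semi_true_factor = semi_true_factor, center = center,
                 slope = slope, intercept = intercept),
            class = "scale_transform")
}

apply_transform <- function(transform, estimates) {
  semi <- transform$semi_true_factor * (estimates - transform$center) + transform$center
  transform$slope * semi + transform$intercept
}

#' Construct (clinician) coordinates by regression on the person coordinates
#'
#' The person coordinates are, by construction, linearly independent
#' predictors; regressing the normalized construct ratings on them yields a
#' coordinate vector for the construct exactly as the column half-step of
#' the alternation does for an item.  With orthonormal R the coefficients
#' reduce to `t(R) %*% ratings`.
#'
#' @param R N x D person coordinate matrix.
#' @param ratings normalized (pseudo-logit) construct column; `NA` allowed,
#'   more than D persons must be rated.
#' @return `list(coords, fitted, residuals, rms_residual)`.
#' @export
construct_coordinates <- function(R, ratings) {
  stopifnot(nrow(R) == length(ratings))
  obs <- !is.na(ratings)
  if (sum(obs) <= ncol(R))
    stop("insufficient rated persons: need more than D = ", ncol(R))
  w <- solve_coordinates(ratings, R)
  fitted <- drop(R %*% w)
  res <- ratings - fitted
  list(coords = w, fitted = fitted, residuals = res,
       rms_residual = sqrt(mean(res[obs]^2)))
}

#' Map construct estimates to the 0-100 risk scale
#'
#' Applies the semi-true rescale ([semi_true_logits()]) and then an affine
#' map.  When `transform = "fit"` the affine constants are chosen so the 1st
#' and 99th percentiles of the calibration estimates land on 10 and 90 —
#' robust to tail outliers while keeping scores inside 0-100 without hard
#' clipping — and the fitted transform is returned for persistence.
#'
#' @param construct_estimates construct estimates in pseudo-logit units.
#' @param person_ses per-person standard errors (needed when fitting).
#' @param transform `"fit"` or a persisted [scale_transform()].
#' @param anchor_probs,anchor_values percentiles and their target scale
#'   values used when fitting (defaults `c(0.01, 0.99)` to `c(10, 90)`).
#' @return `list(drs, transform)`.
#' @export
drs_from_estimates <- function(construct_estimates, person_ses = NULL,
                               transform = "fit",
                               anchor_probs = c(0.01, 0.99),
                               anchor_values = c(10, 90)) {
  if (identical(transform, "fit")) {
    if (length(construct_estimates) < 10)
      stop("need at least 10 persons to fit the scale transform")
    if (is.null(person_ses)) stop("person_ses required to fit the transform")
    st <- semi_true_logits(construct_estimates, person_ses)
    q <- quantile(st$values, anchor_probs, names = FALSE)
    if (diff(q) <= 0) stop("degenerate estimate distribution; cannot fit scale")
    slope <- diff(anchor_values) / diff(q)
    intercept <- anchor_values[1] - slope * q[1]
    transform <- scale_transform(semi_true_factor = st$factor,
                                 center = st$center,
                                 slope = slope, intercept = intercept)
  } else if (!inherits(transform, "scale_transform")) {
    stop("transform must be 'fit' or a scale_transform")
  }
  list(drs = apply_transform(transform, construct_estimates),
       transform = transform)
}

#' Classify a scale score into risk categories
#'
#' Half-open intervals on the default cut scores 45/50/55:
#' `< 45` None, `[45, 50)` Low, `[50, 55)` Moderate, `>= 55` Severe.
#' Out-of-range scores clamp to the extreme categories.
#'
#' @param drs numeric scale score(s).
#' @param cut_scores strictly increasing boundaries (length 3).
#' @return factor with levels None/Low/Moderate/Severe.
#' @export
classify_drs <- function(drs, cut_scores = c(45, 50, 55)) {
  stopifnot(length(cut_scores) == 3, !is.unsorted(cut_scores, strictly = TRUE))
  labs <- c("None", "Low", "Moderate", "Severe")
  idx <- findInterval(drs, cut_scores) + 1L
  factor(labs[idx], levels = labs)
}

#' Per-person construct standard error by least-squares propagation
#'
#' For a person solved from item coordinates A (D x m) with per-cell standard
#' errors s, the coordinate covariance is
#' `V = (A A')^-1 A diag(s^2) A' (A A')^-1` and the construct-estimate
#' standard error is `sqrt(w' V w)` for construct coordinates w.
#'
#' @param C_items D x m item coordinates used for the solve.
#' @param cell_ses per-cell standard errors (length m).
#' @param w construct coordinate vector (length D).
#' @return scalar standard error (infinite if any cell SE is infinite).
#' @export
propagate_construct_se <- function(C_items, cell_ses, w) {
  if (any(!is.finite(cell_ses))) return(Inf)
  G <- tcrossprod(C_items)                      # A A'
  Gi <- tryCatch(solve(G), error = function(e) MASS::ginv(G))
  H <- Gi %*% C_items                           # (A A')^-1 A
  V <- H %*% (cell_ses^2 * t(H))
  sqrt(drop(t(w) %*% V %*% w))
}

#' Score one person from an item bank
#'
#' The scoring phase: the person's responses are matched against the bank,
#' converted to pseudo-logits with the banked metrics, and solved against
#' the banked item coordinates to give the person's coordinates in the
#' common space.  The dot product with the construct coordinates, passed
#' through the banked scale transform, is the reported 0-100 measure.  Age
#' is not required: the calibrated age loadings let the solve infer it
#' implicitly.  The error coordinates in the bank supply per-cell EAR (hence
#' outfit and the interpretability flag) and, via the cell standard-error
#' formula propagated through the construct solve and the scale slope, the
#' person's standard error in scale units.
#'
#' @param responses named numeric vector of raw responses by item id, or a
#'   two-column data frame `(item_id, response)`.
#' @param bank an [item_bank()].
#' @param construct name of the construct to score (default the first).
#' @param min_items soft floor on matched items (default `2 * D`; below it a
#'   warning is issued, at `<= D` scoring is impossible and errors).
#' @param misfit_threshold interpretability threshold on outfit (default 2).
#' @return object of class `person_score`: `drs`, `se_drs`, `outfit`,
#'   `category`, `interpretable`, `n_items_used`.
#' @export
score_person <- function(responses, bank, construct = NULL,
                         min_items = NULL, misfit_threshold = 2.0) {
  stopifnot(inherits(bank, "item_bank"))
  if (is.data.frame(responses)) {
    x <- as.numeric(responses[[2L]])
    names(x) <- as.character(responses[[1L]])
    responses <- x
  }
  D <- bank$dimensionality
  if (is.null(min_items)) min_items <- 2L * D
  if (is.null(construct)) construct <- names(bank$construct)[1L]
  w <- bank$construct[[construct]]
  if (is.null(w)) stop("unknown construct: ", construct)

  responses <- responses[!is.na(responses)]
  unknown <- setdiff(names(responses), bank$item_ids)
  if (length(unknown)) {
    warning("skipping unknown item ids: ", paste(unknown, collapse = ", "))
    responses <- responses[setdiff(names(responses), unknown)]
  }
  ids <- names(responses)
  n_used <- length(ids)
  if (n_used <= D)
    stop("insufficient data: ", n_used, " matched items for D = ", D)
  if (n_used < min_items)
    warning("only ", n_used, " matched items (recommended minimum ", min_items, ")")

  # raw -> pseudo-logit with the banked metric parameters
  xl <- vapply(ids, function(i)
    to_pseudologit(responses[[i]], bank$metrics[[i]])$values, 0)

  C_m <- bank$C[, ids, drop = FALSE]
  R_n <- solve_coordinates(xl, t(C_m))
  est <- dot_estimate(R_n, w)

  # residuals and banked-EAR outfit
  e_n <- drop(crossprod(C_m, R_n))
  res <- xl - e_n
  lr <- log(pmax(res^2, .EAR_EPS))
  ear_cc <- bank$ear_col_coords[, ids, drop = FALSE]
  r_ear <- solve_coordinates(lr, t(ear_cc))
  M <- exp(pmin(drop(crossprod(ear_cc, r_ear)), 700))
  pf <- bank$ear_polyfit[, ids, drop = FALSE]
  ear <- sqrt(pmax(pf[1L, ] + pf[2L, ] * M, bank$ear_floors[ids]))
  outfit <- sqrt(mean((res / ear)^2))

  # per-cell SE -> construct SE -> scale units
  cell_se <- standard_error(ear, r = n_used, c = bank$col_counts[ids], d = D)
  se_est <- propagate_construct_se(C_m, cell_se, w)
  tr <- bank$transform
  se_drs <- tr$slope * tr$semi_true_factor * se_est

  drs <- apply_transform(tr, est)
  structure(list(drs = drs, se_drs = se_drs, outfit = outfit,
                 category = as.character(classify_drs(drs, bank$cut_scores)),
                 interpretable = outfit < misfit_threshold,
                 n_items_used = n_used),
            class = "person_score")
}

#' @export
print.person_score <- function(x, ...) {
  cat(sprintf("DRS %.1f (SE %.2f), %s%s; outfit %.2f over %d items\n",
              x$drs, x$se_drs, x$category,
              if (x$interpretable) "" else " [NOT interpretable]",
              x$outfit, x$n_items_used))
  invisible(x)
}
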