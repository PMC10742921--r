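#' Column metric descriptors and the pseudo-logit transform
#'
#' Alternating least squares needs every column on one unbounded,
#' approximately linear metric.  Raw columns are therefore converted to
#' "pseudo-logits": each raw value is assigned a plausible log-odds (or
#' z-score) so that heterogeneous dichotomous, polytomous, interval and ratio
#' columns can share a single least-squares analysis.  The maps used are
#'
#' * `dichotomous` (values 0/1): plausible probabilities 0.25 / 0.75, so
#'   logits -1.0986 / +1.0986;
#' * `polytomous` (integers 0..K-1): plausible probability (k + 0.5)/K;
#' * `interval`: column z-score;
#' * `ratio` (hard floor at zero, e.g. response timings): z-score of the
#'   natural log, zeros clamped to half the smallest positive value.
#'
#' All maps are strictly increasing in the raw value and invertible once the
#' fitted `location`/`scale` parameters are stored.
#'
#' @param kind one of `"dichotomous"`, `"polytomous"`, `"interval"`, `"ratio"`.
#' @param n_categories number of categories (dichotomous implies 2).
#' @param location,scale standardization parameters fitted at calibration.
#' @return `column_metric()` returns an object of class `column_metric`.
#' @export
column_metric <- function(kind = c("dichotomous", "polytomous", "interval", "ratio"),
                          n_categories = NA_integer_,
                          location = NA_real_, scale = NA_real_) {
  kind <- match.arg(kind)
  if (kind == "dichotomous") n_categories <- 2L
  if (kind == "polytomous" && !is.na(n_categories) && n_categories < 2L)
    stop("polytomous metric needs at least 2 categories")
  if (!is.na(scale) && scale <= 0) stop("scale must be positive")
  structure(list(kind = kind, n_categories = as.integer(n_categories),
                 location = location, scale = scale),
            class = "column_metric")
}

#' @export
print.column_metric <- function(x, ...) {
  cat(sprintf("column_metric<%s>", x$kind))
  if (!is.na(x$n_categories)) cat(sprintf(" K=%d", x$n_categories))
  if (!is.na(x$location)) cat(sprintf(" loc=%.4g scale=%.4g", x$location, x$scale))
  cat("\n"); invisible(x)
}

.PROB_CLAMP <- 1e-6

#' @rdname column_metric
#' @param x raw column values (missing allowed).
#' @param metric a `column_metric`; its fitted parameters are filled in and
#'   returned for later inversion.
#' @return `to_pseudologit()` returns `list(values, metric)`; the values stay
#'   `NA` where the input was missing.  A zero-variance continuous column is
#'   an error (flagged degenerate upstream).
#' @export
to_pseudologit <- function(x, metric) {
  stopifnot(inherits(metric, "column_metric"))
  obs <- !is.na(x)
  out <- rep(NA_real_, length(x))
  v <- x[obs]
  switch(metric$kind,
    dichotomous = {
      if (!all(v %in% c(0, 1)))
        stop("dichotomous column contains values outside {0, 1}")
      out[obs] <- qlogis(ifelse(v == 1, 0.75, 0.25))
    },
    polytomous = {
      K <- metric$n_categories
      if (is.na(K)) K <- as.integer(max(v)) + 1L
      if (any(v != round(v)) || any(v < 0) || any(v > K - 1))
        stop("polytomous column contains categories outside 0..K-1")
      p <- pmin(pmax((v + 0.5) / K, .PROB_CLAMP), 1 - .PROB_CLAMP)
      out[obs] <- qlogis(p)
      metric$n_categories <- K
    },
    interval = {
      if (is.na(metric$location)) {
        metric$location <- mean(v); metric$scale <- sd(v)
        if (!is.finite(metric$scale) || metric$scale == 0)
          stop("degenerate column: zero variance")
      }
      out[obs] <- (v - metric$location) / metric$scale
    },
    ratio = {
      if (any(v < 0)) stop("ratio column contains negative values")
      if (any(v == 0)) {
        floor_at <- if (any(v > 0)) min(v[v > 0]) / 2 else 1e-6
        v[v == 0] <- floor_at
      }
      lv <- log(v)
      if (is.na(metric$location)) {
        metric$location <- mean(lv); metric$scale <- sd(lv)
        if (!is.finite(metric$scale) || metric$scale == 0)
          stop("degenerate column: zero variance")
      }
      out[obs] <- (lv - metric$location) / metric$scale
    })
  list(values = out, metric = metric)
}

#' @rdname column_metric
#' @return `from_pseudologit()` inverts the transform: exact for `interval`
#'   and `ratio` kinds; for categorical kinds it returns the expected
#'   probability (dichotomous) or expected continuous category `p*K - 0.5`
#'   (polytomous) via the inverse logit, input clamped to probabilities in
#'   `[1e-6, 1 - 1e-6]`.
#' @export
from_pseudologit <- function(x, metric) {
  stopifnot(inherits(metric, "column_metric"))
  switch(metric$kind,
    dichotomous = pmin(pmax(plogis(x), .PROB_CLAMP), 1 - .PROB_CLAMP),
    polytomous = {
      K <- metric$n_categories
      if (is.na(K)) stop("uncalibrated metric: n_categories unknown")
      p <- pmin(pmax(plogis(x), .PROB_CLAMP), 1 - .PROB_CLAMP)
      p * K - 0.5
    },
    interval = {
      if (is.na(metric$location)) stop("uncalibrated metric: no location/scale")
      x * metric$scale + metric$location
    },
    ratio = {
      if (is.na(metric$location)) stop("uncalibrated metric: no location/scale")
      exp(x * metric$scale + metric$location)
    })
}

#' Apply the pseudo-logit transform to every column of a matrix
#'
#' Zero-variance columns are flagged degenerate and dropped with a warning.
#'
#' @param x `data_matrix` or numeric matrix.
#' @param metrics named list of [column_metric()], one per column.
#' @return `list(values, metrics, dropped)`: the transformed matrix, the
#'   fitted metrics, and the ids of degenerate columns removed.
#' @export
pseudologit_matrix <- function(x, metrics) {
  vals <- as_values(x)
  ids <- colnames(vals)
  stopifnot(!is.null(ids), all(ids %in% names(metrics)))
  out <- vals
  fitted <- metrics
  dropped <- character(0)
  for (id in ids) {
    res <- tryCatch(to_pseudologit(vals[, id], metrics[[id]]), error = function(e) e)
    if (inherits(res, "error")) {
      if (grepl("degenerate", conditionMessage(res))) {
        dropped <- c(dropped, id); next
      }
      stop("column '", id, "': ", conditionMessage(res))
    }
    out[, id] <- res$values
    fitted[[id]] <- res$metric
  }
  if (length(dropped)) {
    warning("dropping degenerate zero-variance columns: ",
            paste(dropped, collapse = ", "))
    out <- out[, setdiff(ids, dropped), drop = FALSE]
    fitted <- fitted[setdiff(ids, dropped)]
  }
  list(values = out, metrics = fitted, dropped = dropped)
}

#' Read / write the column-metric sidecar
#'
#' JSON list of `{col_id, kind, n_categories, location, scale}` records.
#'
#' @param metrics named list of [column_metric()].
#' @param path file path.
#' @export
write_column_metrics <- function(metrics, path) {
  recs <- lapply(names(metrics), function(id) {
    m <- metrics[[id]]
    list(col_id = id, kind = m$kind, n_categories = m$n_categories,
         location = m$location, scale = m$scale)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_column_metrics
#' @export
read_column_metrics <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(recs, function(r) {
    column_metric(kind = r$kind,
                  n_categories = if (is.null(r$n_categories)) NA_integer_ else as.integer(r$n_categories),
                  location = if (is.null(r$location)) NA_real_ else as.numeric(r$location),
                  scale = if (is.null(r$scale)) NA_real_ else as.numeric(r$scale))
  })
  names(out) <- vapply(recs, function(r) r$col_id, "")
  out
}

#' Semi-true logit rescale
#'
#' Least-squares construct estimates are shrunk relative to the latent values
#' by measurement noise.  The semi-true rescale restores the lost variance by
#' the linear map `g * (x - mean(x)) + mean(x)` with
#' `g = sqrt(1 + RMSE^2 / var(x))`, `RMSE = sqrt(mean(se^2))`, so downstream
#' probabilities and logits are computed on an error-corrected scale.
#'
#' @param estimates construct estimates (pseudo-logit units).
#' @param person_ses per-person standard errors (same units, `>= 0`; non-finite
#'   values are excluded from the RMSE with a warning).
#' @return `list(values, factor, center)`; `factor` and `center` are persisted
#'   in the [scale_transform()] so the identical map can be re-applied at
#'   scoring time.
#' @export
semi_true_logits <- function(estimates, person_ses) {
  stopifnot(length(estimates) == length(person_ses), all(person_ses >= 0, na.rm = TRUE))
  ok <- is.finite(person_ses)
  if (!all(ok)) warning("excluding ", sum(!ok), " non-finite standard errors from RMSE")
  v <- var(estimates)
  if (!is.finite(v) || v == 0) stop("semi-true rescale undefined: zero variance estimates")
  rmse2 <- mean(person_ses[ok]^2)
  g <- sqrt(1 + rmse2 / v)
  ctr <- mean(estimates)
  list(values = g * (estimates - ctr) + ctr, factor = g, center = ctr)
}
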