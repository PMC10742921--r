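# End-to-end calibration, scoring, and equating entry points tying the
# modules together; these back the command-line tool in inst/cli.

.stop_cls <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Calibrate an instrument end to end
#'
#' Chains the full calibration phase: pseudo-logit conversion, (optionally
#' age-anchored) factorization, the cell error model, construct coordinates
#' from the ratings, per-person error propagation, the semi-true rescale and
#' 0-100 affine map, misfit flags, and item-bank assembly.
#'
#' @param X a [data_matrix()] carrying `col_metrics`, or an already
#'   pseudo-logit numeric matrix (then `metrics` must be supplied for the
#'   bank).
#' @param ages per-person ages in years; `NULL` disables age anchoring.
#' @param ratings raw construct ratings (integers `0..K-1`, `NA` allowed).
#' @param d_residual number of non-age dimensions; `NULL` runs
#'   [best_dimensionality()] on the age-residualized matrix.
#' @param seed master seed for this run.
#' @param metrics named [column_metric()] list when `X` is a plain matrix.
#' @param rating_categories K for the rating column (default: inferred).
#' @param cut_scores,misfit_threshold passed to the bank / flags.
#' @param d_max,n_seeds dimensionality-search settings when `d_residual` is
#'   NULL.
#' @param tol,max_iter,refine_iter ALS convergence control.
#' @return object of class `calibration`: `coords`, `noise`, `bank`, `drs`,
#'   `se_drs`, `outfit`, `interpretable`, `construct_fit`, `quality`,
#'   `dim_report` (when searched).
#' @export
calibrate <- function(X, ages = NULL, ratings = NULL, d_residual = NULL,
                      seed = 1L, metrics = NULL, rating_categories = NULL,
                      cut_scores = c(45, 50, 55), misfit_threshold = 2,
                      d_max = 10L, n_seeds = 5L,
                      tol = 1e-6, max_iter = 50L, refine_iter = 25L) {
  if (inherits(X, "data_matrix") && !is.null(X$col_metrics)) {
    pl <- pseudologit_matrix(X, X$col_metrics)
    XL <- pl$values; metrics <- pl$metrics
  } else {
    XL <- as_values(X)
    if (is.null(metrics))
      metrics <- setNames(
        lapply(colnames(XL), function(i)
          column_metric("interval", location = 0, scale = 1)),
        colnames(XL))
  }
  if (is.null(ratings)) .stop_cls("raschmf_input_error", "ratings are required to calibrate")

  dim_report <- NULL
  if (!is.null(ages)) {
    if (is.null(d_residual)) {
      Res <- age_residualize(XL, ages)$residuals
      dim_report <- best_dimensionality(Res, d_max = d_max, n_seeds = n_seeds,
                                        seed = seed, tol = tol, max_iter = max_iter)
      d_residual <- dim_report$best_d
    }
    coords <- age_anchored_calibration(XL, ages, d_residual, seed = seed,
                                       tol = tol, max_iter = max_iter,
                                       refine_iter = refine_iter)
  } else {
    if (is.null(d_residual)) {
      dim_report <- best_dimensionality(XL, d_max = d_max, n_seeds = n_seeds,
                                        seed = seed, tol = tol, max_iter = max_iter)
      d_residual <- dim_report$best_d
    }
    coords <- als_decompose(XL, d_residual, seed = seed, tol = tol,
                            max_iter = max_iter)
  }

  noise <- estimate_noise_model(XL, coords, seed = seed + 101L,
                                tol = tol, max_iter = max_iter)

  # normalized construct column (plausible-logit polytomous map)
  K <- rating_categories
  if (is.null(K)) K <- as.integer(max(ratings, na.rm = TRUE)) + 1L
  rmetric <- column_metric("polytomous", n_categories = K)
  rl_raw <- ratings[match(rownames(coords$R), rownames(XL))]
  rl <- to_pseudologit(rl_raw, rmetric)$values
  cfit <- construct_coordinates(coords$R, rl)
  w <- cfit$coords

  est <- drop(coords$R %*% w)
  person_se <- vapply(seq_len(nrow(coords$R)), function(n) {
    o <- which(!is.na(XL[rownames(coords$R)[n], colnames(coords$C)]))
    propagate_construct_se(coords$C[, o, drop = FALSE],
                           noise$se[n, o], w)
  }, 0)
  scale_fit <- drs_from_estimates(est, person_se, transform = "fit")
  tr <- scale_fit$transform
  se_drs <- tr$slope * tr$semi_true_factor * person_se

  fit <- misfit(XL[rownames(coords$R), colnames(coords$C), drop = FALSE],
                fitted(coords), noise$ear, threshold = misfit_threshold)

  bank <- build_item_bank(coords, noise, metrics,
                          construct_coords = list(construct = w),
                          transform = tr, cut_scores = cut_scores, seed = seed)
  quality <- quality_report(scale_fit$drs, se_drs,
                            item_outfit = fit$item_outfit)
  structure(list(coords = coords, noise = noise, bank = bank,
                 drs = scale_fit$drs, se_drs = se_drs,
                 outfit = fit$person_outfit,
                 interpretable = fit$interpretable,
                 construct_fit = cfit, quality = quality,
                 dim_report = dim_report, metrics = metrics, seed = seed),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %d persons, %d items, D = %d\n",
              nrow(x$coords$R), ncol(x$coords$C), x$coords$dimensionality))
  print(x$quality)
  cat(sprintf("  uninterpretable persons: %.1f%%\n",
              100 * mean(!x$interpretable)))
  invisible(x)
}

.read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      .stop_cls("raschmf_input_error", "config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  config
}

.need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    .stop_cls("raschmf_input_error", what, " file missing: ",
              if (is.null(path)) "(not given)" else path)
  path
}

#' Run the calibration phase from a configuration
#'
#' Configuration (list or YAML path): `data` (matrix CSV), `metrics` (sidecar
#' JSON), `age_col`, `rating_col` (columns of the CSV treated as age in
#' years / construct rating rather than items), `d_residual` (optional;
#' searched when absent), `seed`, `cut_scores`, `out_bank`, `out_report`.
#'
#' @param config list or path to a YAML file.
#' @param verbose log progress to stderr.
#' @return the [calibrate()] result, invisibly; writes the bank JSON and a
#'   quality-report JSON when output paths are configured.
#' @export
run_calibrate <- function(config, verbose = FALSE) {
  cfg <- .read_config(config)
  say <- function(...) if (verbose) message(...)
  dm <- read_data_matrix(.need_file(cfg$data, "data matrix"),
                         metrics_path = .need_file(cfg$metrics, "column metrics"))
  ages <- ratings <- NULL
  drop_cols <- character(0)
  if (!is.null(cfg$age_col)) {
    ages <- dm$values[, cfg$age_col]; drop_cols <- c(drop_cols, cfg$age_col)
  }
  if (!is.null(cfg$rating_col)) {
    ratings <- dm$values[, cfg$rating_col]; drop_cols <- c(drop_cols, cfg$rating_col)
  }
  items <- setdiff(dm$col_ids, drop_cols)
  X <- data_matrix(dm$values[, items, drop = FALSE],
                   col_metrics = dm$col_metrics[items])
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  say("calibrating ", nrow(X$values), " x ", ncol(X$values),
      " (seed ", seed, ")")
  cal <- calibrate(X, ages = ages, ratings = ratings,
                   d_residual = if (is.null(cfg$d_residual)) NULL
                                else as.integer(cfg$d_residual),
                   seed = seed,
                   cut_scores = if (is.null(cfg$cut_scores)) c(45, 50, 55)
                                else as.numeric(cfg$cut_scores),
                   tol = if (is.null(cfg$tol)) 1e-6 else as.numeric(cfg$tol),
                   max_iter = if (is.null(cfg$max_iter)) 50L
                              else as.integer(cfg$max_iter),
                   refine_iter = if (is.null(cfg$refine_iter)) 25L
                                 else as.integer(cfg$refine_iter))
  if (!isTRUE(cal$coords$converged))
    warning("calibration did not fully converge within the iteration cap")
  say("converged: ", cal$coords$converged, " after ", cal$coords$n_iter,
      " iterations; D = ", cal$coords$dimensionality)
  if (!is.null(cfg$out_bank)) write_item_bank(cal$bank, cfg$out_bank)
  if (!is.null(cfg$out_report))
    jsonlite::write_json(unclass(cal$quality), cfg$out_report,
                         auto_unbox = TRUE, digits = NA)
  invisible(cal)
}

#' Run the scoring phase from a configuration
#'
#' Configuration: `bank` (bank JSON), `responses` (CSV with columns
#' `item_id,response`), optional `construct`, `out` (score JSON).  An
#' uninterpretable score is still a successful run — the flag is data.
#'
#' @inheritParams run_calibrate
#' @return the [score_person()] result, invisibly.
#' @export
run_score <- function(config, verbose = FALSE) {
  cfg <- .read_config(config)
  bank <- read_item_bank(.need_file(cfg$bank, "item bank"))
  resp <- read.csv(.need_file(cfg$responses, "responses"),
                   stringsAsFactors = FALSE)
  score <- tryCatch(
    score_person(resp, bank, construct = cfg$construct),
    error = function(e) .stop_cls("raschmf_scoring_error", conditionMessage(e)))
  if (verbose) message("DRS ", round(score$drs, 1), " (", score$category, ")")
  if (!is.null(cfg$out))
    jsonlite::write_json(unclass(score), cfg$out, auto_unbox = TRUE, digits = NA)
  invisible(score)
}

#' Run the equating phase from a configuration
#'
#' Configuration: `bank` (reference bank JSON), `data` + `metrics` (new
#' form), optional `common_ids`, `out_bank`, `out_report` (link CSV).  The
#' new form's common columns are normalized with the banked metric
#' parameters so both forms share one pseudo-logit scale; its new columns
#' are fitted fresh.
#'
#' @inheritParams run_calibrate
#' @return `list(coords, fit, bank)` for the new form, invisibly.
#' @export
run_equate <- function(config, verbose = FALSE) {
  cfg <- .read_config(config)
  bank <- read_item_bank(.need_file(cfg$bank, "item bank"))
  dm <- read_data_matrix(.need_file(cfg$data, "data matrix"),
                         metrics_path = .need_file(cfg$metrics, "column metrics"))
  common <- if (!is.null(cfg$common_ids)) as.character(cfg$common_ids)
            else intersect(dm$col_ids, bank$item_ids)
  if (length(common) <= bank$dimensionality)
    .stop_cls("raschmf_equating_error",
              "too few common items: ", length(common), " for D = ",
              bank$dimensionality)
  metrics <- dm$col_metrics
  metrics[common] <- bank$metrics[common]
  pl <- pseudologit_matrix(dm, metrics)
  eq <- tryCatch(equate_forms(bank, pl$values, common_ids = common),
                 error = function(e) .stop_cls("raschmf_equating_error",
                                               conditionMessage(e)))
  if (verbose)
    message("equated ", length(common), " common items; mean RMS residual ",
            signif(mean(eq$fit$rms_residual), 3))
  noise_B <- estimate_noise_model(pl$values, eq$coords,
                                  seed = bank$provenance$seed + 7L)
  bank_B <- build_item_bank(eq$coords, noise_B, pl$metrics,
                            construct_coords = bank$construct,
                            transform = bank$transform,
                            cut_scores = bank$cut_scores,
                            seed = bank$provenance$seed)
  if (!is.null(cfg$out_bank)) write_item_bank(bank_B, cfg$out_bank)
  if (!is.null(cfg$out_report)) write.csv(eq$fit, cfg$out_report, row.names = FALSE)
  invisible(list(coords = eq$coords, fit = eq$fit, bank = bank_B))
}
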