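# Scale-quality statistics: RMSE / separation / reliability, Shannon entropy
# of ratings and binned measures, and ROC operating characteristics.

#' Reliability and separation of a set of measures
#'
#' `rmse = sqrt(mean(se^2))`; the error-disattenuated true spread is
#' `sd_true = sqrt(max(sd(measures)^2 - rmse^2, 0))`; separation is
#' `sd_true / rmse` and reliability is `separation^2 / (1 + separation^2)`
#' (the conventional Rasch conversion, comparable to Cronbach's alpha).
#'
#' @param measures person measures.
#' @param ses per-person standard errors (finite).
#' @return `list(rmse, separation, reliability)`; zero RMSE gives
#'   reliability 1 with infinite separation.
#' @export
reliability_stats <- function(measures, ses) {
  stopifnot(length(measures) >= 2, length(measures) == length(ses))
  if (any(!is.finite(ses))) stop("standard errors must be finite")
  rmse <- sqrt(mean(ses^2))
  if (rmse == 0) {
    warning("zero RMSE: separation is infinite")
    return(list(rmse = 0, separation = Inf, reliability = 1))
  }
  sd_true <- sqrt(max(sd(measures)^2 - rmse^2, 0))
  sep <- sd_true / rmse
  list(rmse = rmse, separation = sep,
       reliability = reliability_from_separation(sep))
}

#' @rdname reliability_stats
#' @param separation a separation statistic.
#' @export
reliability_from_separation <- function(separation) {
  ifelse(is.infinite(separation), 1, separation^2 / (1 + separation^2))
}

#' Shannon entropy of a discrete distribution, in bits
#'
#' `-sum(p * log2(p))` with the convention `0 * log2(0) = 0`.  Probabilities
#' not summing to one (within 1e-9) are renormalized with a warning.
#'
#' @param probabilities non-negative probabilities.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(probabilities) {
  if (any(probabilities < 0)) stop("negative probability")
  s <- sum(probabilities)
  if (abs(s - 1) > 1e-9) {
    warning("probabilities renormalized (sum = ", signif(s, 6), ")")
  }
  p <- probabilities / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy of measures binned into standard-error-sized units
#'
#' Partitions the scale range into `floor((max - min) / bin_width)` equal
#' bins (values beyond the last edge fall into the last bin), and reports
#' both the empirical entropy of the bin occupancy and the equiprobable
#' maximum `log2(n_bins)`.
#'
#' @param measures numeric scores.
#' @param bin_width bin width in score units (e.g. the median standard
#'   error), `> 0`.
#' @param range optional `c(min, max)`; default the observed range.
#' @return `list(n_bins, entropy, equiprobable_entropy)`; a degenerate range
#'   gives a single bin and zero entropy.
#' @export
binned_score_entropy <- function(measures, bin_width, range = NULL) {
  stopifnot(bin_width > 0)
  if (is.null(range)) range <- c(min(measures), max(measures))
  span <- diff(range)
  n_bins <- max(1L, as.integer(floor(span / bin_width)))
  if (n_bins == 1L)
    return(list(n_bins = 1L, entropy = 0, equiprobable_entropy = 0))
  edges <- range[1] + bin_width * seq_len(n_bins - 1L)
  idx <- findInterval(measures, edges) + 1L
  p <- tabulate(idx, nbins = n_bins) / max(length(measures), 1L)
  list(n_bins = n_bins,
       entropy = if (length(measures)) shannon_entropy(p) else NA_real_,
       equiprobable_entropy = log2(n_bins))
}

#' ROC curve, AUC, and operating-point metrics
#'
#' AUC by the trapezoidal rule over all score thresholds (via pROC, with
#' higher scores indicating the positive class), plus sensitivity,
#' specificity, and accuracy at a supplied cut (`score >= cut` is called
#' positive).
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1 or logical); both classes must be
#'   present.
#' @param cut operating cut point on the score scale.
#' @return `list(auc, sensitivity, specificity, accuracy, roc_points)` where
#'   `roc_points` is a data frame of (threshold, sensitivity, specificity).
#' @export
roc_metrics <- function(scores, labels, cut) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<",
                 levels = c(0, 1))
  pred <- scores >= cut
  pos <- labels == 1
  list(auc = as.numeric(pROC::auc(r)),
       sensitivity = mean(pred[pos]),
       specificity = mean(!pred[!pos]),
       accuracy = mean(pred == pos),
       roc_points = data.frame(threshold = r$thresholds,
                               sensitivity = r$sensitivities,
                               specificity = r$specificities))
}

#' Quality report for a calibrated scale
#'
#' Gathers the headline quality statistics in one list, mirroring how scale
#' quality is normally tabled: RMSE, separation, reliability, mean item
#' outfit, and the entropy of the binned score distribution.
#'
#' @param measures person scale scores.
#' @param ses per-person standard errors in scale units.
#' @param item_outfit per-item outfit vector.
#' @param bin_width width for the entropy binning; default the median SE.
#' @return object of class `quality_report`.
#' @export
quality_report <- function(measures, ses, item_outfit = NULL, bin_width = NULL) {
  ok <- is.finite(ses)
  rel <- reliability_stats(measures[ok], ses[ok])
  if (is.null(bin_width)) bin_width <- median(ses[ok])
  ent <- binned_score_entropy(measures, bin_width)
  structure(list(rmse = rel$rmse, separation = rel$separation,
                 reliability = rel$reliability,
                 mean_item_outfit = if (is.null(item_outfit)) NA_real_ else mean(item_outfit),
                 entropy_bits = ent$entropy, n_bins = ent$n_bins,
                 bin_width = bin_width),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Scale quality\n")
  cat(sprintf("  RMSE        %8.3f\n", x$rmse))
  cat(sprintf("  Separation  %8.3f\n", x$separation))
  cat(sprintf("  Reliability %8.3f\n", x$reliability))
  if (is.finite(x$mean_item_outfit))
    cat(sprintf("  Mean item outfit %5.3f\n", x$mean_item_outfit))
  cat(sprintf("  Entropy %.2f bits over %d bins of %.3g\n",
              x$entropy_bits, x$n_bins, x$bin_width))
  invisible(x)
}
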