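# The item bank: everything needed to score a new person without the
# calibration data — per-item estimate coordinates, the two error-coordinate
# pairs with their polyfit maps, column metrics, construct coordinates, the
# scale transform, and cut scores.

#' Assemble an item bank from calibration outputs
#'
#' @param coords [coordinate_set()] from calibration.
#' @param noise `noise_model` from [estimate_noise_model()].
#' @param metrics named list of fitted [column_metric()] descriptors.
#' @param construct_coords named list of construct coordinate vectors
#'   (each length D), or a single vector for one construct.
#' @param transform a [scale_transform()].
#' @param cut_scores strictly increasing category boundaries
#'   (default `c(45, 50, 55)`).
#' @param seed calibration seed recorded as provenance.
#' @return object of class `item_bank`.
#' @export
build_item_bank <- function(coords, noise, metrics, construct_coords,
                            transform, cut_scores = c(45, 50, 55),
                            seed = coords$seed) {
  D <- coords$dimensionality
  ids <- colnames(coords$C)
  if (!is.list(construct_coords)) construct_coords <- list(construct = construct_coords)
  for (w in construct_coords)
    if (length(w) != D) stop("assembly error: construct coordinates length ",
                             length(w), " != D = ", D)
  if (noise$d != D) stop("assembly error: noise model d = ", noise$d, " != D = ", D)
  if (!all(ids %in% names(metrics)))
    stop("assembly error: metrics missing for some items")
  if (is.unsorted(cut_scores, strictly = TRUE))
    stop("cut scores must be strictly increasing")
  structure(list(
    dimensionality = D,
    item_ids = ids,
    C = coords$C,
    ear_col_coords = noise$ear_coords$col,
    ear_polyfit = noise$ear_coords$polyfit,
    ear_floors = noise$ear_coords$floors,
    se_col_coords = noise$se_coords$col,
    se_polyfit = noise$se_coords$polyfit,
    col_counts = noise$col_counts[ids],
    metrics = metrics[ids],
    construct = construct_coords,
    transform = transform,
    cut_scores = cut_scores,
    provenance = list(seed = seed, calibrated = format(Sys.Date()),
                      software = as.character(utils::packageVersion("raschmf")),
                      schema = 1L)),
    class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("item_bank: %d items, D = %d, %d construct(s), cuts %s\n",
              length(x$item_ids), x$dimensionality, length(x$construct),
              paste(x$cut_scores, collapse = "/")))
  invisible(x)
}

#' Serialize / deserialize an item bank as a single JSON document
#'
#' @param bank an `item_bank`.
#' @param path file path.
#' @return `read_item_bank()` returns the reconstructed `item_bank`.
#' @export
write_item_bank <- function(bank, path) {
  obj <- list(
    schema = bank$provenance$schema,
    dimensionality = bank$dimensionality,
    item_ids = bank$item_ids,
    C = asplit_cols(bank$C),
    ear_col_coords = asplit_cols(bank$ear_col_coords),
    ear_polyfit = asplit_cols(bank$ear_polyfit),
    ear_floors = as.list(bank$ear_floors),
    se_col_coords = asplit_cols(bank$se_col_coords),
    se_polyfit = asplit_cols(bank$se_polyfit),
    col_counts = as.list(bank$col_counts),
    metrics = lapply(bank$metrics, unclass),
    construct = lapply(bank$construct, as.numeric),
    transform = unclass(bank$transform),
    cut_scores = bank$cut_scores,
    provenance = bank$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

asplit_cols <- function(m) {
  out <- lapply(seq_len(ncol(m)), function(j) as.numeric(m[, j]))
  names(out) <- colnames(m)
  out
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(x) {
    m <- do.call(cbind, as.list(x))
    m
  }
  metrics <- lapply(obj$metrics, function(m)
    column_metric(kind = m$kind,
                  n_categories = if (is.null(m$n_categories)) NA_integer_ else as.integer(m$n_categories),
                  location = if (is.null(m$location)) NA_real_ else as.numeric(m$location),
                  scale = if (is.null(m$scale)) NA_real_ else as.numeric(m$scale)))
  tr <- obj$transform
  structure(list(
    dimensionality = as.integer(obj$dimensionality),
    item_ids = obj$item_ids,
    C = rebuild(obj$C),
    ear_col_coords = rebuild(obj$ear_col_coords),
    ear_polyfit = rebuild(obj$ear_polyfit),
    ear_floors = unlist(obj$ear_floors),
    se_col_coords = rebuild(obj$se_col_coords),
    se_polyfit = rebuild(obj$se_polyfit),
    col_counts = unlist(obj$col_counts),
    metrics = metrics,
    construct = lapply(obj$construct, as.numeric),
    transform = scale_transform(semi_true_factor = tr$semi_true_factor,
                                center = tr$center, slope = tr$slope,
                                intercept = tr$intercept),
    cut_scores = as.numeric(obj$cut_scores),
    provenance = obj$provenance),
    class = "item_bank")
}
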