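#' Persons-by-items response matrix with missing cells
#'
#' A `data_matrix` wraps a numeric N x I matrix (NA = missing) together with
#' unique person/item identifiers and optional per-column metric descriptors.
#' Every row and every column must retain at least one observed cell.
#'
#' @param values numeric matrix, persons in rows, items in columns; `NA`
#'   marks missing cells.
#' @param row_ids,col_ids unique identifiers; default taken from `dimnames`.
#' @param col_metrics optional named list of [column_metric()] descriptors,
#'   one per column.
#' @return An object of class `data_matrix` with elements `values`,
#'   `row_ids`, `col_ids`, `col_metrics`.
#' @seealso [read_data_matrix()], [als_decompose()]
#' @export
data_matrix <- function(values, row_ids = rownames(values),
                        col_ids = colnames(values), col_metrics = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("data_matrix requires at least one row and one column")
  if (is.null(row_ids)) row_ids <- paste0("p", seq_len(nrow(values)))
  if (is.null(col_ids)) col_ids <- paste0("i", seq_len(ncol(values)))
  row_ids <- as.character(row_ids); col_ids <- as.character(col_ids)
  if (anyDuplicated(row_ids)) stop("row ids must be unique")
  if (anyDuplicated(col_ids)) stop("col ids must be unique")
  if (length(row_ids) != nrow(values) || length(col_ids) != ncol(values))
    stop("id lengths do not match matrix shape")
  obs <- !is.na(values)
  if (any(rowSums(obs) == 0L)) stop("every row must have at least one observed cell")
  if (any(colSums(obs) == 0L)) stop("every column must have at least one observed cell")
  dimnames(values) <- list(row_ids, col_ids)
  if (!is.null(col_metrics)) {
    if (is.null(names(col_metrics))) names(col_metrics) <- col_ids
    stopifnot(all(names(col_metrics) %in% col_ids))
  }
  structure(list(values = values, row_ids = row_ids, col_ids = col_ids,
                 col_metrics = col_metrics),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  obs <- !is.na(x$values)
  cat(sprintf("data_matrix: %d persons x %d items, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), 100 * (1 - mean(obs))))
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

#' Coerce to the plain value matrix of a data_matrix
#' @param x a `data_matrix` or numeric matrix.
#' @return numeric matrix with NA for missing cells.
#' @export
as_values <- function(x) {
  if (inherits(x, "data_matrix")) x$values else as.matrix(x)
}

#' Read / write a response matrix as CSV
#'
#' CSV layout: first column holds person ids, the header row holds item ids,
#' empty cells are missing.  Column metric descriptors travel in a JSON
#' sidecar (see [write_column_metrics()]).
#'
#' @param path CSV file path.
#' @param metrics_path optional path to a metric sidecar JSON.
#' @return [read_data_matrix()] returns a `data_matrix`;
#'   [write_data_matrix()] returns `path` invisibly.
#' @export
read_data_matrix <- function(path, metrics_path = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  metrics <- if (!is.null(metrics_path)) read_column_metrics(metrics_path)
  data_matrix(vals, col_metrics = metrics)
}

#' @rdname read_data_matrix
#' @param x a `data_matrix`.
#' @export
write_data_matrix <- function(x, path) {
  x <- if (inherits(x, "data_matrix")) x else data_matrix(x)
  df <- data.frame(person_id = x$row_ids, x$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
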