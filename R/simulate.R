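# Simulator of the assumed generative model: T = R_true C_true at a known
# dimensionality, heteroscedastic Gaussian noise with characteristic row and
# column scales, blocked or random missingness, and (in instrument mode)
# age-driven structure, dichotomous items paired with negatively loaded
# timing columns, and a discrete 0..K-1 construct rating.

#' Simulation specification
#'
#' Defaults mirror the calibration study's shape at desk scale: 300 persons
#' by 120 items, six true dimensions (a log-age dimension, a constant
#' "difficulty offset" dimension, and four latent dimensions), 25% blocked
#' missing data across three overlapping age forms, and moderate
#' heteroscedastic noise (`noise_base = 1` against a cell signal scale of
#' about `sqrt(true_d)`).
#'
#' @param n_persons,n_items,true_d matrix shape and true rank.
#' @param noise_base base Gaussian noise sd; a cell's noise sd is
#'   `noise_base * row_sd[n] * col_sd[i]`.
#' @param row_noise_spread,col_noise_spread lognormal sigma of the per-row /
#'   per-column noise multipliers.
#' @param missing_fraction target fraction of missing cells.
#' @param missing_pattern `"random"` or `"blocked"` (three overlapping
#'   age-form blocks).
#' @param age_blocks simulate the full instrument structure (ages, forms,
#'   dichotomous + timing items, rating column) in [simulate_instrument()].
#' @param frac_dichotomous fraction of items dichotomized at their median.
#' @param frac_timing fraction of items kept continuous as "timing" columns
#'   paired with (and loaded oppositely to) dichotomous items.
#' @param construct_weights construct projection weights (length `true_d`).
#' @param rating_categories number of discrete rating categories (default 11,
#'   a 0-10 scale).
#' @param rating_noise sd of the rating noise as a fraction of the
#'   projection sd.
#' @param seed default seed.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_persons = 300L, n_items = 120L, true_d = 6L,
                            noise_base = 1, row_noise_spread = 0.3,
                            col_noise_spread = 0.3, missing_fraction = 0.25,
                            missing_pattern = c("blocked", "random"),
                            age_blocks = TRUE, frac_dichotomous = 0.5,
                            frac_timing = 0.25, construct_weights = NULL,
                            rating_categories = 11L, rating_noise = 0.3,
                            seed = 1L) {
  missing_pattern <- match.arg(missing_pattern)
  stopifnot(true_d < min(n_persons, n_items), noise_base >= 0,
            missing_fraction >= 0, missing_fraction < 1,
            frac_dichotomous >= 0, frac_dichotomous <= 1,
            frac_timing >= 0, frac_timing <= 1)
  if (is.null(construct_weights))
    construct_weights <- c(0.2, 0, 1, 0.8, 0.6, -0.4, 0.5, 0.3,
                           rep(0.2, max(0, true_d - 8)))[seq_len(true_d)]
  stopifnot(length(construct_weights) == true_d)
  structure(list(n_persons = as.integer(n_persons), n_items = as.integer(n_items),
                 true_d = as.integer(true_d), noise_base = noise_base,
                 row_noise_spread = row_noise_spread,
                 col_noise_spread = col_noise_spread,
                 missing_fraction = missing_fraction,
                 missing_pattern = missing_pattern,
                 age_blocks = isTRUE(age_blocks),
                 frac_dichotomous = frac_dichotomous,
                 frac_timing = frac_timing,
                 construct_weights = construct_weights,
                 rating_categories = as.integer(rating_categories),
                 rating_noise = rating_noise, seed = as.integer(seed)),
            class = "simulation_spec")
}

# blocked missingness: three age groups, items split into all-form,
# adjacent-overlap, and form-specific categories sized to give ~25% missing.
.block_mask <- function(N, I, group) {
  cat_props <- c(all = 0.55, ct = 0.075, ta = 0.075, c = 0.10, t = 0.10, a = 0.10)
  n_cat <- round(cat_props * I)
  n_cat["all"] <- I - sum(n_cat[-1L])
  item_cat <- rep(names(n_cat), n_cat)[seq_len(I)]
  visible <- list(
    child = c("all", "ct", "c"),
    teen  = c("all", "ct", "ta", "t"),
    adult = c("all", "ta", "a"))
  mask <- matrix(FALSE, N, I)   # TRUE = observed
  for (g in names(visible))
    mask[group == g, item_cat %in% visible[[g]]] <- TRUE
  list(mask = mask, item_cat = item_cat)
}

.random_mask <- function(N, I, frac, true_d, max_tries = 50L) {
  for (try in seq_len(max_tries)) {
    mask <- matrix(runif(N * I) >= frac, N, I)
    if (all(rowSums(mask) > true_d + 1L) && all(colSums(mask) > true_d + 1L))
      return(mask)
  }
  stop("infeasible missing pattern after ", max_tries, " tries")
}

#' Simulate a model-conforming dataset with known truth
#'
#' Draws standard-normal `R_true` (N x D) and `C_true` (D x I), forms
#' `T = R_true C_true`, adds Gaussian noise with cell sd
#' `noise_base * row_sd[n] * col_sd[i]` (lognormal row/column multipliers:
#' every row and column has its own characteristic noise scale), and deletes
#' cells by the requested missing pattern.
#'
#' @param spec a [simulation_spec()].
#' @param seed overrides `spec$seed`.
#' @return `list(X, truth)` where `X` is a [data_matrix()] and `truth` holds
#'   `T`, `R_true`, `C_true`, `row_sds`, `col_sds`, `mask`, `noise`.
#' @export
simulate_dataset <- function(spec, seed = spec$seed) {
  set.seed(seed)
  N <- spec$n_persons; I <- spec$n_items; D <- spec$true_d
  R_true <- matrix(rnorm(N * D), N, D)
  C_true <- matrix(rnorm(D * I), D, I)
  T_mat <- R_true %*% C_true
  row_sds <- exp(rnorm(N, 0, spec$row_noise_spread))
  col_sds <- exp(rnorm(I, 0, spec$col_noise_spread))
  noise <- matrix(rnorm(N * I), N, I) * (spec$noise_base * outer(row_sds, col_sds))
  X <- T_mat + noise
  mask <- if (spec$missing_pattern == "blocked") {
    group <- sample(c("child", "teen", "adult"), N, replace = TRUE)
    .block_mask(N, I, group)$mask
  } else {
    .random_mask(N, I, spec$missing_fraction, D)
  }
  X[!mask] <- NA
  rownames(X) <- paste0("p", seq_len(N))
  colnames(X) <- paste0("i", seq_len(I))
  dimnames(T_mat) <- dimnames(X)
  list(X = data_matrix(X),
       truth = list(T = T_mat, R_true = R_true, C_true = C_true,
                    row_sds = row_sds, col_sds = col_sds, mask = mask,
                    noise = noise))
}

#' Simulate a full instrument: age forms, mixed metrics, construct rating
#'
#' Extends [simulate_dataset()] with the structure of an age-graded
#' screening instrument:
#'
#' * ages are drawn log-uniformly over 7-82 years and their centered,
#'   unit-norm log becomes the first true dimension;
#' * the second true dimension is a constant offset carrying per-item
#'   "difficulty"; remaining dimensions are standard normal;
#' * persons belong to child (< 10), teen (10-15), or adult (>= 16) forms;
#'   items are visible to all forms, to adjacent pairs, or to one form,
#'   yielding about 25% blocked missing data;
#' * a fraction of items is dichotomized at the item median; a fraction is
#'   kept continuous as positive "timing" columns whose loadings are the
#'   negated loadings of a paired dichotomous item (plus noise), so observed
#'   timing/response pairs correlate negatively;
#' * a discrete construct rating (0..K-1) is produced by adding noise to the
#'   projection `R_true %*% construct_weights` and cutting it at sample
#'   quantiles into K categories.
#'
#' @inheritParams simulate_dataset
#' @return `list(X, truth, ages, ratings, metrics)`; `truth` additionally
#'   holds `construct` (the noiseless projection), `group`, `item_kind`,
#'   `timing_pairs`.  `metrics` is the named [column_metric()] list matching
#'   the generated columns.
#' @export
simulate_instrument <- function(spec, seed = spec$seed) {
  stopifnot(spec$age_blocks)
  set.seed(seed)
  N <- spec$n_persons; I <- spec$n_items; D <- spec$true_d
  if (D < 3L) stop("instrument simulation needs true_d >= 3 (age + offset + latent)")

  ages <- exp(runif(N, log(7), log(82)))
  la <- log(ages)
  v <- la - mean(la); v <- v / sqrt(sum(v^2))
  R_true <- cbind(v, 1 / sqrt(N), matrix(rnorm(N * (D - 2L)), N, D - 2L))
  colnames(R_true) <- NULL
  group <- ifelse(ages < 10, "child", ifelse(ages < 16, "teen", "adult"))

  # item roles: timing columns pair with dichotomous columns
  n_tim <- round(spec$frac_timing * I)
  n_dich <- min(I - n_tim, max(n_tim, round(spec$frac_dichotomous * I)))
  item_kind <- rep("interval", I)
  dich_idx <- seq_len(n_dich)
  tim_idx <- if (n_tim > 0) n_dich + seq_len(n_tim) else integer(0)
  item_kind[dich_idx] <- "dichotomous"
  item_kind[tim_idx] <- "ratio"
  timing_pairs <- if (n_tim > 0) cbind(timing = tim_idx, dich = dich_idx[seq_len(n_tim)])

  C_true <- matrix(rnorm(D * I), D, I)
  C_true[1L, ] <- abs(C_true[1L, ]) * sqrt(N) / 3   # ability grows with log-age
  C_true[2L, ] <- rnorm(I, 0, 1) * sqrt(N)          # per-item difficulty offsets
  if (n_tim > 0)                                     # slower responses ~ lower ability
    for (j in seq_len(n_tim))
      C_true[, tim_idx[j]] <- -C_true[, dich_idx[j]] + rnorm(D, 0, 0.3)

  T_mat <- R_true %*% C_true
  row_sds <- exp(rnorm(N, 0, spec$row_noise_spread))
  col_sds <- exp(rnorm(I, 0, spec$col_noise_spread))
  noise <- matrix(rnorm(N * I), N, I) * (spec$noise_base * outer(row_sds, col_sds))
  latent <- T_mat + noise

  bm <- .block_mask(N, I, group)
  X <- latent
  metrics <- vector("list", I)
  for (i in seq_len(I)) {
    if (item_kind[i] == "dichotomous") {
      X[, i] <- as.numeric(latent[, i] > median(latent[, i]))
      metrics[[i]] <- column_metric("dichotomous")
    } else if (item_kind[i] == "ratio") {
      X[, i] <- exp(latent[, i] / sd(latent[, i]))
      metrics[[i]] <- column_metric("ratio")
    } else {
      metrics[[i]] <- column_metric("interval")
    }
  }
  X[!bm$mask] <- NA
  rownames(X) <- paste0("p", seq_len(N))
  colnames(X) <- paste0("i", seq_len(I))
  names(metrics) <- colnames(X)
  dimnames(T_mat) <- dimnames(X)

  proj <- drop(R_true %*% spec$construct_weights)
  K <- spec$rating_categories
  noisy <- proj + rnorm(N, 0, spec$rating_noise * sd(proj))
  edges <- quantile(noisy, probs = seq_len(K - 1L) / K, names = FALSE)
  ratings <- findInterval(noisy, edges)            # 0 .. K-1

  list(X = data_matrix(X, col_metrics = metrics),
       truth = list(T = T_mat, R_true = R_true, C_true = C_true,
                    row_sds = row_sds, col_sds = col_sds, mask = bm$mask,
                    construct = proj, group = group, item_kind = item_kind,
                    item_form = bm$item_cat, timing_pairs = timing_pairs),
       ages = ages, ratings = ratings, metrics = metrics)
}
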