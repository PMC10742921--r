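# End-to-end calibrate/score/equate entry points over files.

# the noise-free fixture is generated directly in pseudo-logit units, so its
# sidecar declares pre-standardized interval metrics (identity transform)
write_fixture_files <- function(sim, dir) {
  data_path <- file.path(dir, "matrix.csv")
  metrics_path <- file.path(dir, "metrics.json")
  df <- data.frame(person_id = sim$X$row_ids, age = sim$ages,
                   rating = sim$ratings, sim$X$values, check.names = FALSE)
  write.csv(df, data_path, row.names = FALSE, na = "")
  item_metrics <- setNames(
    lapply(sim$X$col_ids, function(i)
      column_metric("interval", location = 0, scale = 1)),
    sim$X$col_ids)
  metrics <- c(item_metrics,
               list(age = column_metric("ratio"),
                    rating = column_metric("polytomous", n_categories = 11)))
  write_column_metrics(metrics, metrics_path)
  list(data = data_path, metrics = metrics_path)
}

test_that("run_calibrate writes a bank that reproduces calibration scores", {
  dir <- withr::local_tempdir()
  sim <- nf_instrument()
  paths <- write_fixture_files(sim, dir)
  cfg <- list(data = paths$data, metrics = paths$metrics,
              age_col = "age", rating_col = "rating",
              d_residual = 5, seed = 2,
              tol = 1e-10, max_iter = 150, refine_iter = 60,
              out_bank = file.path(dir, "bank.json"),
              out_report = file.path(dir, "report.json"))
  cal <- run_calibrate(cfg)
  expect_true(file.exists(cfg$out_bank))
  expect_true(file.exists(cfg$out_report))
  bank <- read_item_bank(cfg$out_bank)
  X <- sim$X$values
  resp <- X[9, !is.na(X[9, ])]
  sc <- score_person(resp, bank)
  expect_equal(sc$drs, unname(cal$drs[9]), tolerance = 1e-6)
  rep_json <- jsonlite::read_json(cfg$out_report)
  expect_true(all(c("rmse", "separation", "reliability") %in% names(rep_json)))
})

test_that("run_calibrate reads its configuration from YAML", {
  dir <- withr::local_tempdir()
  sim <- nf_instrument()
  paths <- write_fixture_files(sim, dir)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(data = paths$data, metrics = paths$metrics,
                        age_col = "age", rating_col = "rating",
                        d_residual = 5, seed = 2), cfg_path)
  cal <- run_calibrate(cfg_path)
  expect_s3_class(cal, "calibration")
  expect_equal(cal$coords$dimensionality, 6L)
})

test_that("missing input files raise classed input errors naming the file", {
  dir <- withr::local_tempdir()
  sim <- nf_instrument()
  paths <- write_fixture_files(sim, dir)
  err <- tryCatch(
    run_calibrate(list(data = paths$data,
                       metrics = file.path(dir, "absent.json"))),
    raschmf_input_error = function(e) e)
  expect_s3_class(err, "raschmf_input_error")
  expect_match(conditionMessage(err), "absent.json")
})

test_that("run_score emits the six-field person record as JSON", {
  dir <- withr::local_tempdir()
  sim <- nf_instrument()
  paths <- write_fixture_files(sim, dir)
  bank_path <- file.path(dir, "bank.json")
  run_calibrate(list(data = paths$data, metrics = paths$metrics,
                     age_col = "age", rating_col = "rating",
                     d_residual = 5, seed = 2,
                     tol = 1e-10, max_iter = 150, refine_iter = 60,
                     out_bank = bank_path))
  X <- sim$X$values
  resp <- X[21, !is.na(X[21, ])]
  resp_path <- file.path(dir, "resp.csv")
  write.csv(data.frame(item_id = names(resp), response = unname(resp)),
            resp_path, row.names = FALSE)
  out_path <- file.path(dir, "score.json")
  sc <- run_score(list(bank = bank_path, responses = resp_path,
                       out = out_path))
  rec <- jsonlite::read_json(out_path)
  expect_setequal(names(rec), c("drs", "se_drs", "outfit", "category",
                                "interpretable", "n_items_used"))
  # subset of responses gives the same score on noise-free data
  half <- names(resp)[seq(1, length(resp), 2)]
  resp2_path <- file.path(dir, "resp2.csv")
  write.csv(data.frame(item_id = half, response = unname(resp[half])),
            resp2_path, row.names = FALSE)
  sc_half <- run_score(list(bank = bank_path, responses = resp2_path))
  expect_equal(sc_half$drs, sc$drs, tolerance = 1e-4)
  # too few responses is a scoring error
  resp3_path <- file.path(dir, "resp3.csv")
  write.csv(data.frame(item_id = names(resp)[1:5],
                       response = unname(resp[1:5])),
            resp3_path, row.names = FALSE)
  expect_error(run_score(list(bank = bank_path, responses = resp3_path)),
               class = "raschmf_scoring_error")
})

test_that("run_equate links an overlapping form and refuses a disjoint one", {
  dir <- withr::local_tempdir()
  sim <- nf_instrument()
  X <- sim$X$values
  idsA <- colnames(X)[1:56]; idsB <- colnames(X)[33:80]
  simA <- sim; simA$X <- data_matrix(X[, idsA])
  pathsA <- write_fixture_files(simA, dir)
  bank_path <- file.path(dir, "bankA.json")
  run_calibrate(list(data = pathsA$data, metrics = pathsA$metrics,
                     age_col = "age", rating_col = "rating",
                     d_residual = 5, seed = 2,
                     tol = 1e-10, max_iter = 150, refine_iter = 60,
                     out_bank = bank_path))
  # form B files
  dfB <- data.frame(person_id = rownames(X), X[, idsB], check.names = FALSE)
  dataB <- file.path(dir, "formB.csv")
  write.csv(dfB, dataB, row.names = FALSE, na = "")
  metricsB <- file.path(dir, "metricsB.json")
  mB <- setNames(lapply(idsB, function(i)
    column_metric("interval", location = 0, scale = 1)), idsB)
  write_column_metrics(mB, metricsB)
  out <- run_equate(list(bank = bank_path, data = dataB, metrics = metricsB,
                         out_bank = file.path(dir, "bankB.json"),
                         out_report = file.path(dir, "link.csv")))
  expect_lt(mean(out$fit$rms_residual), 1e-6)
  expect_true(file.exists(file.path(dir, "bankB.json")))
  link <- read.csv(file.path(dir, "link.csv"))
  expect_setequal(link$item, intersect(idsA, idsB))
  # disjoint form
  dfC <- dfB
  names(dfC)[-1] <- paste0("zz", seq_along(idsB))
  dataC <- file.path(dir, "formC.csv")
  write.csv(dfC, dataC, row.names = FALSE, na = "")
  metricsC <- file.path(dir, "metricsC.json")
  mC <- mB; names(mC) <- paste0("zz", seq_along(idsB))
  write_column_metrics(mC, metricsC)
  expect_error(run_equate(list(bank = bank_path, data = dataC,
                               metrics = metricsC)),
               class = "raschmf_equating_error")
})
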