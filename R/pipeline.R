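#' Run the full clock pipeline on one configuration
#'
#' Chains the stages in their canonical order -- detection-p masking, probe
#' missingness filter, sample missingness filter, cross-dataset probe
#' intersection, gold-standard construction, BMIQ calibration, kNN
#' imputation, clock training, prediction -- on either a simulated scenario
#' or user-supplied files, writing every intermediate artifact plus a
#' summary JSON to \code{out_dir}. All randomness flows from the single
#' top-level seed, so a rerun reproduces the summary byte for byte.
#'
#' @param config named list (or path to a YAML file) with optional entries:
#'   \describe{
#'     \item{seed}{top-level seed (default 1).}
#'     \item{simulate}{list of [simulate_dataset()] arguments; used when no
#'       input paths are given.}
#'     \item{input}{list with paths \code{beta}, \code{detp} (optional),
#'       \code{sheet}.}
#'     \item{train_fraction}{fraction of samples used for training
#'       (default 2/3; the split is seeded).}
#'     \item{detection_threshold, probe_max_missing, sample_max_missing,
#'       k, alpha, folds}{stage thresholds (defaults 0.001, 0.05, 0.05, 10,
#'       0.5, 10).}
#'     \item{normalize}{set \code{FALSE} to skip BMIQ calibration (the
#'       summary marks the stage skipped).}
#'   }
#' @param out_dir output directory (created if needed).
#' @return the summary list, invisibly written as \code{summary.json}.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("gestclock_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  thr <- list(detection = config$detection_threshold %||% 0.001,
              probe_max = config$probe_max_missing %||% 0.05,
              sample_max = config$sample_max_missing %||% 0.05,
              k = config$k %||% 10L,
              alpha = config$alpha %||% 0.5,
              folds = config$folds %||% 10L)
  do_norm <- config$normalize %||% TRUE
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = seed, stages = list())
  log_stage <- function(.stage, ...) {
    summary$stages[[.stage]] <<- list(...)
  }

  # stage: inputs
  if (!is.null(config$input)) {
    beta <- read_beta_matrix(config$input$beta)
    detp <- if (!is.null(config$input$detp))
      read_beta_matrix(config$input$detp, what = "detp") else NULL
    sheet <- read_sample_sheet(config$input$sheet)
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    sim <- do.call(simulate_dataset, sim_args)
    beta <- sim$beta; detp <- sim$detp; sheet <- sim$sheet
    write_beta_matrix(beta, file.path(out_dir, "simulated_beta.tsv"))
    utils::write.csv(sheet, file.path(out_dir, "sample_sheet.csv"),
                     row.names = FALSE)
  }
  log_stage("input", n_probes = nrow(beta), n_samples = ncol(beta))

  # stage: train/test split (seeded)
  frac <- config$train_fraction %||% (2 / 3)
  n <- ncol(beta)
  idx <- with_seed(seed + 1L, sample.int(n, round(frac * n)))
  train_ids <- colnames(beta)[sort(idx)]
  test_ids <- setdiff(colnames(beta), train_ids)
  log_stage("split", n_train = length(train_ids), n_test = length(test_ids))

  # stage: detection-p masking
  if (!is.null(detp)) {
    m <- mask_by_detection(beta, detp, threshold = thr$detection)
    beta <- m$beta
    log_stage("mask", n_masked = m$n_masked)
  } else log_stage("mask", skipped = TRUE)

  # stage: missingness filters, per dataset (probes first, then samples)
  qc_tr <- filter_missingness(beta[, train_ids, drop = FALSE],
                              thr$probe_max, thr$sample_max)
  qc_te <- filter_missingness(beta[, test_ids, drop = FALSE],
                              thr$probe_max, thr$sample_max)
  log_stage("qc_filter",
            train = list(probes = qc_tr$report$probes_retained,
                         samples = qc_tr$report$samples_retained),
            test = list(probes = qc_te$report$probes_retained,
                        samples = qc_te$report$samples_retained))

  # stage: probe intersection across datasets
  both <- intersect_probes(list(train = qc_tr$beta, test = qc_te$beta))
  log_stage("intersect", n_probes = nrow(both$train))

  # stage: gold standard + calibration
  if (isTRUE(do_norm)) {
    gold <- build_gold_standard(list(both$train))
    train_b <- calibrate_to_gold(both$train, gold)
    test_b <- calibrate_to_gold(both$test, gold)
    log_stage("normalize", n_probes = length(gold$probe_ids),
              gold_converged = gold$fit$converged)
  } else {
    gold <- NULL
    train_b <- both$train; test_b <- both$test
    log_stage("normalize", skipped = TRUE)
  }

  # stage: imputation
  train_b <- knn_impute(train_b, k = thr$k)
  test_b <- knn_impute(test_b, k = thr$k)
  log_stage("impute", k = thr$k)
  write_beta_matrix(train_b, file.path(out_dir, "train_beta.tsv"))
  write_beta_matrix(test_b, file.path(out_dir, "test_beta.tsv"))

  # stage: clock training
  tr_sheet <- sheet[match(colnames(train_b), sheet$sample_id), ]
  y <- unname(effective_ga(tr_sheet))
  clock <- ga_clock(t(train_b), y, alpha = thr$alpha, nfolds = thr$folds,
                    seed = seed + 2L, gold = gold)
  write_clock_model(clock, file.path(out_dir, "clock_model.csv"))
  log_stage("train", n_cpgs = length(clock$coefficients),
            lambda_min = clock$lambda_min)

  # stage: prediction + accuracy
  te_sheet <- sheet[match(colnames(test_b), sheet$sample_id), ]
  pred <- predict(clock, test_b, sheet = te_sheet)
  pred$ga_acceleration <- ga_acceleration(pred)
  utils::write.table(pred, file.path(out_dir, "predictions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  acc <- accuracy_metrics(pred)
  log_stage("predict", r = acc$r, median_abs_err = acc$median_abs_err,
            mean_abs_err = acc$mean_abs_err, n = acc$n)

  summary$accuracy <- acc
  summary$n_clock_cpgs <- length(clock$coefficients)
  summary$lambda_min <- clock$lambda_min
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary$out_dir <- out_dir
  invisible(summary)
}
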