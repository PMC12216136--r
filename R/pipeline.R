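#' Stratified train/validation/test split
#'
#' Shuffles within each class and allocates counts so that class
#' proportions are preserved within one sample per split; splits are
#' disjoint and exhaustive.
#'
#' @param table A [feature_table()].
#' @param fractions Numeric triple summing to 1 (train, validation, test).
#' @param seed Integer seed.
#' @return Named list of `feature_table`s: `train`, `val`, `test` (a split
#'   with fraction 0 is an empty slot of class `NULL`).
#' @export
stratified_split <- function(table, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(inherits(table, "feature_table"), length(fractions) == 3)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  y <- table$y
  if (any(tabulate(y, nlevels(y)) < 3) && all(fractions > 0))
    stop("each class needs at least 3 members for a three-way split")
  idx <- vector("list", 3)
  with_seed(seed, {
    for (cl in levels(y)) {
      rows <- sample(which(y == cl))
      n <- length(rows)
      n1 <- round(fractions[1] * n)
      n2 <- round(fractions[2] * n)
      n2 <- min(n2, n - n1)
      cuts <- c(rep(1L, n1), rep(2L, n2), rep(3L, n - n1 - n2))
      for (s in 1:3) idx[[s]] <- c(idx[[s]], rows[cuts == s])
    }
  })
  make <- function(rows) {
    if (!length(rows)) return(NULL)
    rows <- sort(rows)
    feature_table(table$x[rows, , drop = FALSE], table$y[rows], table$positive)
  }
  list(train = make(idx[[1]]), val = make(idx[[2]]), test = make(idx[[3]]))
}

#' Pipeline configuration
#'
#' Bundles the stage configurations for [run_pipeline()]. `data` is either
#' a [synth_spec()] (the table is generated) or a path to a CSV readable by
#' [read_feature_table()].
#'
#' @param data A `synth_spec` or a CSV path.
#' @param split Train/validation/test fractions (default 0.6/0.2/0.2).
#' @param seed Master seed; per-stage seeds are derived from it by stable
#'   hashing of the stage names.
#' @param fs_pop,fs_iter Population size / iteration budget of the
#'   feature-selection search.
#' @param tune_pop,tune_iter Budget of the hyperparameter search.
#' @param tune_epochs Training epochs per tuning candidate.
#' @param space A [hyperparam_space()].
#' @param train_cfg A [train_config()] for the final fit (learning rate,
#'   dropout and batch size are overridden by the tuned values).
#' @param out_dir Optional output directory for report/ledger/trace files.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(data = synth_spec(), split = c(0.6, 0.2, 0.2),
                            seed = 1L, fs_pop = 10L, fs_iter = 25L,
                            tune_pop = 4L, tune_iter = 3L, tune_epochs = 10L,
                            space = hyperparam_space(),
                            train_cfg = train_config(), out_dir = NULL) {
  structure(list(data = data, split = split, seed = as.integer(seed),
                 fs_pop = fs_pop, fs_iter = fs_iter, tune_pop = tune_pop,
                 tune_iter = tune_iter, tune_epochs = tune_epochs,
                 space = space, train_cfg = train_cfg, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Stages, in order: commit the input digest to a fresh ledger; fit the
#' Z-score normalizer on the training split only and apply it to all
#' splits; wrapper feature selection on the training split; hyperparameter
#' tuning on train/validation; final training on train+validation with the
#' tuned settings; macro-averaged evaluation on the held-out test split;
#' commit the report digest to the ledger. Test rows are never visible to
#' normalization, selection or tuning.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report`: `mask`, `tuned`, `report`
#'   (a `metrics_report` on the test split), `ledger`, `normalizer`,
#'   `timings`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  table <- stage("ingest", {
    if (inherits(config$data, "synth_spec")) generate_hd_like(config$data)$table
    else read_feature_table(config$data)
  })
  tick("ingest")

  led <- stage("ledger-commit-input", {
    payload <- paste(c(colnames(table$x), as.character(table$y),
                       format(table$x, digits = 17)), collapse = "\n")
    append_record(ledger_new(), payload)
  })
  tick("ledger_input")

  splits <- stage("split",
    stratified_split(table, config$split, derive_seed(config$seed, "split")))
  tick("split")

  norm <- stage("normalize", fit_normalizer(splits$train$x))
  ztr <- apply_zscore(splits$train$x, norm)
  zval <- if (!is.null(splits$val)) apply_zscore(splits$val$x, norm)
  zte <- if (!is.null(splits$test)) apply_zscore(splits$test$x, norm)
  tick("normalize")

  ztrain_tab <- feature_table(ztr, splits$train$y, table$positive)
  fs <- stage("select-features", {
    cfg <- shoa_config(pop_size = config$fs_pop, max_iter = config$fs_iter,
                       patience = 10L,
                       lower = rep(-4, ncol(ztr)), upper = rep(4, ncol(ztr)),
                       seed = derive_seed(config$seed, "fs"))
    select_features(ztrain_tab, cfg)
  })
  tick("feature_selection")

  mtr <- feature_table(ztr[, fs$mask, drop = FALSE], splits$train$y, table$positive)
  mval <- feature_table(zval[, fs$mask, drop = FALSE], splits$val$y, table$positive)
  tuned <- stage("tune", {
    cfg <- coa_config(pop_size = config$tune_pop, max_iter = config$tune_iter,
                      lower = rep(0, length(config$space$dims)),
                      upper = rep(1, length(config$space$dims)),
                      seed = derive_seed(config$seed, "tune"))
    tune_abigru(config$space, mtr, mval, cfg, epochs = config$tune_epochs)
  })
  tick("tuning")

  final <- stage("final-train", {
    xz <- rbind(ztr, zval)[, fs$mask, drop = FALSE]
    yy <- factor(c(as.character(splits$train$y), as.character(splits$val$y)),
                 levels = levels(table$y))
    hp <- tuned$params
    cfg <- train_config(learning_rate = hp$learning_rate %||% config$train_cfg$learning_rate,
                        epochs = config$train_cfg$epochs,
                        dropout = hp$dropout %||% config$train_cfg$dropout,
                        batch_size = hp$batch_size %||% config$train_cfg$batch_size,
                        seed = derive_seed(config$seed, "final-train"))
    model <- init_abigru(sum(fs$mask), hidden = hp$hidden_size %||% 8L,
                         classes = levels(table$y),
                         seed = derive_seed(config$seed, "init"))
    train_abigru(model, xz, yy, cfg)
  })
  tick("final_training")

  report <- stage("evaluate", {
    pred <- predict_abigru(final$model, zte[, fs$mask, drop = FALSE])
    macro_report(splits$test$y, pred$label)
  })
  tick("evaluate")

  led <- stage("ledger-commit-report",
    append_record(led, report_to_json(report)))
  tick("ledger_report")

  out <- structure(list(mask = fs$mask, tuned = tuned$params,
                        tuned_fitness = tuned$fitness, report = report,
                        ledger = led, normalizer = norm,
                        fs_trace = fs$trace, loss_history = final$loss_history,
                        model = final$model, timings = timings, config = config),
                   class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(out, config$out_dir)
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("== pipeline run ==\n")
  cat("selected features:", paste(names(x$mask)[x$mask], collapse = ", "), "\n")
  cat("tuned:", paste(sprintf("%s=%s", names(x$tuned),
                              vapply(x$tuned, function(v) format(v, digits = 4), "")),
                      collapse = ", "), "\n")
  print(x$report)
  print(x$ledger)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Report JSON + aligned text table, selection trace CSV, selected-feature
#' JSON, normalizer JSON and the ledger (JSON lines).
#'
#' @param run A `run_report`.
#' @param dir Output directory (created if needed).
#' @export
write_run_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  report_to_json(run$report, file.path(dir, "report.json"))
  df <- report_percent(run$report)
  writeLines(c("Classification report (%)",
               capture.output(print(format(df, nsmall = 2), row.names = FALSE))),
             file.path(dir, "report.txt"))
  write.csv(run$fs_trace, file.path(dir, "fs_trace.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(names(run$mask)[run$mask]),
             file.path(dir, "selected_features.json"))
  normalizer_to_json(run$normalizer, file.path(dir, "normalizer.json"))
  writeLines(jsonlite::toJSON(run$tuned, auto_unbox = TRUE, digits = NA),
             file.path(dir, "tuned_params.json"))
  write_ledger(run$ledger, file.path(dir, "ledger.jsonl"))
  invisible(dir)
}
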