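#' Pipeline configuration
#'
#' Assembles every stage setting in one object. Exactly one of `data_dir`
#' (a class-per-subdirectory image tree) or `fixture_spec` (a
#' [dataset_spec()] for the synthetic generator) provides the data. Every
#' random component receives a child seed derived deterministically from
#' `seed`, so a full run is reproducible end to end.
#'
#' @param data_dir Optional directory of labeled images.
#' @param fixture_spec Optional [dataset_spec()]; defaults to the full
#'   synthetic collection when `data_dir` is absent.
#' @param gabor List of preprocessing settings: `enabled`, `delta`,
#'   `orientations`, `gamma`, `bw` (see [gabor_denoise()]).
#' @param downscale Integer block-mean pooling factor applied after
#'   preprocessing (default 2; trades spatial detail for speed).
#' @param extractor An [extractor_config()].
#' @param hyper Classifier hyperparameters (see [train_classifier()]);
#'   defaults follow the stated settings: learning rate 0.01, dropout 0.5,
#'   batch size 5, 50 epochs, ReLU feature nonlinearity.
#' @param tune If `TRUE`, run [cssa_tune()] over `tune_space` before the
#'   final fit and use the tuned hyperparameters.
#' @param tune_space,tune_N,tune_T,tune_epochs Tuning space and optimizer
#'   budget; `tune_epochs` caps epochs during tuning runs (default 10) so
#'   the search stays cheap, while the final fit uses `hyper$epochs`.
#' @param fractions Stratified split fractions (must include `train` and
#'   `val`; a `test` entry is used for the final report, otherwise `val`
#'   doubles as the report split).
#' @param seed Master integer seed.
#' @param out_dir Optional directory for report artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir = NULL, fixture_spec = NULL,
                            gabor = list(), downscale = 2L,
                            extractor = extractor_config(),
                            hyper = list(), tune = FALSE,
                            tune_space = sparrowtex::tune_space(),
                            tune_N = 6L, tune_T = 4L, tune_epochs = 10L,
                            fractions = c(train = 0.6, val = 0.2,
                                          test = 0.2),
                            seed = 1L, out_dir = NULL) {
  if (is.null(data_dir) && is.null(fixture_spec)) {
    fixture_spec <- dataset_spec()
  }
  if (!is.null(data_dir) && !dir.exists(data_dir)) {
    abort(sprintf("Data directory does not exist: %s", data_dir))
  }
  gabor_defaults <- list(enabled = TRUE, delta = 4,
                         orientations = c(0, pi / 4, pi / 2, 3 * pi / 4),
                         gamma = 0.5, bw = 1)
  gabor <- utils::modifyList(gabor_defaults, gabor)
  if (!all(c("train", "val") %in% names(fractions))) {
    abort("`fractions` must name at least `train` and `val`.")
  }
  structure(list(data_dir = data_dir, fixture_spec = fixture_spec,
                 gabor = gabor, downscale = as.integer(downscale),
                 extractor = extractor, hyper = hyper, tune = tune,
                 tune_space = tune_space, tune_N = as.integer(tune_N),
                 tune_T = as.integer(tune_T),
                 tune_epochs = as.integer(tune_epochs),
                 fractions = fractions, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

preprocess_images <- function(manifest, config) {
  g <- config$gabor
  manifest$image <- purrr::map(manifest$image, function(img) {
    if (isTRUE(g$enabled)) {
      img <- gabor_denoise(img, delta = g$delta,
                           orientations = g$orientations,
                           gamma = g$gamma, bw = g$bw)
    }
    if (config$downscale > 1L) img <- downscale_image(img, config$downscale)
    img
  })
  manifest
}

#' Run the full classification pipeline
#'
#' Stages, in order: load or generate the labeled images; Gabor-bank
#' preprocessing; feature extraction through the MDConv stack; stratified
#' split; optional chaotic-sparrow-search hyperparameter tuning against
#' the validation error rate; final stacked-GRU fit; one-vs-rest metrics
#' on the held-out split. When `out_dir` is set, the confusion matrix,
#' metrics report (CSV + JSON), training history, per-sample predictions
#' and any tuned hyperparameters are written there.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: `confusion`, `report`
#'   (a [metrics_report()] tibble), `fit` (the `sgru_fit`), `tuned`
#'   (decoded best hyperparameters or `NULL`), `features`, `manifest`
#'   and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- if (!is.null(config$data_dir)) {
    read_image_dir(config$data_dir)
  } else {
    generate_dataset(config$fixture_spec)
  }
  manifest <- preprocess_images(manifest, config)

  ext_cfg <- config$extractor
  ext_cfg$seed <- derive_seed(config$seed, 2L)
  extractor <- init_extractor(ext_cfg)
  features <- extract_features(manifest$image, extractor)

  manifest <- stratified_split(manifest, config$fractions,
                               seed = derive_seed(config$seed, 1L))
  tr <- manifest$split == "train"
  va <- manifest$split == "val"
  te <- if ("test" %in% levels(manifest$split)) manifest$split == "test" else va
  y <- as.character(manifest$class)
  levels_y <- levels(manifest$class)

  tuned <- NULL
  hyper <- config$hyper
  if (isTRUE(config$tune)) {
    objective <- function(h) {
      h$epochs <- min(h$epochs %||% config$tune_epochs, config$tune_epochs)
      fit <- train_classifier(features[tr, , drop = FALSE],
                              factor(y[tr], levels = levels_y),
                              hyper = utils::modifyList(config$hyper, h),
                              seed = derive_seed(config$seed, 4L))
      pred <- predict(fit, features[va, , drop = FALSE])
      fitness_error_rate(pred$.pred_class, y[va])
    }
    ts <- cssa_tune(objective, space = config$tune_space,
                    N = config$tune_N, T = config$tune_T,
                    seed = derive_seed(config$seed, 5L))
    tuned <- ts$best
    hyper <- utils::modifyList(config$hyper, tuned)
  }

  fit <- train_classifier(features[tr, , drop = FALSE],
                          factor(y[tr], levels = levels_y),
                          features[va, , drop = FALSE],
                          factor(y[va], levels = levels_y),
                          hyper = hyper,
                          seed = derive_seed(config$seed, 3L))
  pred <- predict(fit, features[te, , drop = FALSE])
  cm <- build_confusion(y[te], pred$.pred_class, labels = levels_y)
  report <- metrics_report(cm)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(unclass(cm)),
                     file.path(config$out_dir, "confusion.csv"))
    write_metrics(report, file.path(config$out_dir, "metrics.csv"))
    write_metrics(report, file.path(config$out_dir, "metrics.json"))
    utils::write.csv(fit$history, file.path(config$out_dir, "history.csv"),
                     row.names = FALSE)
    preds_out <- dplyr::bind_cols(
      tibble::tibble(id = manifest$id[te], truth = y[te]), pred)
    utils::write.csv(preds_out,
                     file.path(config$out_dir, "predictions.csv"),
                     row.names = FALSE)
    if (!is.null(tuned)) {
      jsonlite::write_json(tuned, file.path(config$out_dir, "tuned.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  structure(list(confusion = cm, report = report, fit = fit, tuned = tuned,
                 features = features, manifest = manifest, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  avg <- x$report[x$report$class == "Average", ]
  cat(sprintf(
    "<pipeline_result> %d classes, %d images; macro accuracy %.2f%%, macro recall %.2f%%\n",
    nrow(x$confusion), nrow(x$manifest), avg$accuracy, avg$recall))
  invisible(x)
}

#' Per-class metrics of a pipeline run
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) x$report

#' One-row summary of a pipeline run
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  avg <- x$report[x$report$class == "Average", ]
  tibble::tibble(
    classes = nrow(x$confusion), images = nrow(x$manifest),
    overall_accuracy = overall_accuracy(x$confusion),
    macro_accuracy = avg$accuracy, macro_recall = avg$recall,
    macro_fscore = avg$fscore, tuned = !is.null(x$tuned)
  )
}
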