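#' Run configuration for the end-to-end pipelines
#'
#' One seeded configuration object shared by both pipelines; every output
#' artifact echoes it.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed for generation, splits, folds and training.
#' @param n_per_class synthetic instances per class.
#' @param classes list of [class_profile()]s (default: the seven products).
#' @param grid classifier grids ([default_grid()]).
#' @param families shape-classifier families to run.
#' @param arch CNN architecture: `"default"` (four-stage 32/64/128/256),
#'   `"search"` (all nine candidates), or a [cnn_architecture()].
#' @param train CNN [train_config()] (its seed is overridden by `seed`).
#' @param paper_mode compare CNN candidates on the test set (historical
#'   protocol) instead of a validation split.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("budvision_run_"), seed = 1L,
                       n_per_class = 30L, classes = default_class_profiles(),
                       grid = default_grid(),
                       families = c("knn", "mlp", "svm"),
                       arch = "default", train = train_config(),
                       paper_mode = FALSE) {
  train$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_per_class = as.integer(n_per_class), classes = classes,
                 grid = grid, families = families, arch = arch,
                 train = train, paper_mode = paper_mode),
            class = "run_config")
}

config_echo <- function(cfg) {
  list(seed = cfg$seed, n_per_class = cfg$n_per_class,
       classes = names(cfg$classes), families = cfg$families,
       folds = cfg$grid$folds,
       arch = if (is.character(cfg$arch)) cfg$arch else "custom",
       train = unclass(cfg$train), paper_mode = cfg$paper_mode)
}

result_json <- function(r) {
  list(family = r$family, params = r$params, cv_accuracy = r$cv_accuracy,
       train_accuracy = r$train_accuracy, test_accuracy = r$test_accuracy,
       train_accuracy_pct = r$train_accuracy_pct,
       test_accuracy_pct = r$test_accuracy_pct,
       confusion = as.data.frame.matrix(unclass(r$confusion)))
}

#' End-to-end morphological pipeline
#'
#' Synthetic gel plates -> denoising, Otsu segmentation, contour morphology
#' -> features.csv -> PCA scatter (PNG) -> grid-searched KNN/MLP/SVM for the
#' flowering-stage (2-class) and product-type (7-class) tasks. Writes
#' `features.csv`, `pca_scores.csv`, `pca_stage.png`, `pca_type.png` and
#' `shape_report.json` into `cfg$out_dir`; fully deterministic per seed.
#'
#' @param cfg a [run_config()].
#' @return The report, invisibly (also serialized as JSON).
#' @export
run_shape_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  times <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  ds <- make_benchmark_dataset(cfg$classes, cfg$n_per_class,
                               seed = cfg$seed, mode = "gel")
  times["generate_segment_features"] <- tic() - t0
  write_features_csv(ds, file.path(cfg$out_dir, "features.csv"))
  t0 <- tic()
  X <- feature_matrix(ds)
  z <- zscore(X)
  pca <- pca_explore(z$train, n_components = 2L)
  write.csv(data.frame(id = ds$features$id, pca$scores,
                       stage = ds$features$stage, type = ds$features$class),
            file.path(cfg$out_dir, "pca_scores.csv"), row.names = FALSE)
  for (lab in c("stage", "type")) {
    grDevices::png(file.path(cfg$out_dir, sprintf("pca_%s.png", lab)),
                   width = 640, height = 640)
    plot(pca, labels = if (lab == "stage") ds$features$stage else
      ds$features$class, main = sprintf("PCA scores by %s", lab))
    grDevices::dev.off()
  }
  times["pca"] <- tic() - t0
  report <- list(package_version = as.character(utils::packageVersion("budvision")),
                 config = config_echo(cfg),
                 pca_explained_pc12 = 100 * sum(pca$explained[1:2]),
                 tasks = list())
  for (task in c("stage", "type")) {
    t0 <- tic()
    labels <- if (task == "stage") ds$features$stage else ds$features$class
    res <- classify_features(X, labels, families = cfg$families,
                             grid = cfg$grid, seed = cfg$seed)
    report$tasks[[task]] <- lapply(res, result_json)
    times[paste0("classify_", task)] <- tic() - t0
  }
  report$wall_times_s <- as.list(round(times, 2))
  jsonlite::write_json(report, file.path(cfg$out_dir, "shape_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' End-to-end raw-image pipeline
#'
#' Synthetic phone plates -> finder-pattern detection, perspective
#' rectification, segmentation, colour crops -> bicubic 50 x 50 tensors ->
#' CNN training with RMSProp -> evaluation for both tasks. With
#' `cfg$arch = "search"` the nine candidate architectures are compared
#' first (validation split by default; test set under `paper_mode`).
#' Writes `cnn_report.json` and a model checkpoint (`cnn_model.rds` plus a
#' JSON architecture sidecar) into `cfg$out_dir`.
#'
#' @param cfg a [run_config()].
#' @return The report, invisibly.
#' @export
run_cnn_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  times <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  ds <- make_benchmark_dataset(cfg$classes, cfg$n_per_class,
                               seed = cfg$seed, mode = "phone")
  x <- crops_to_tensor(ds$crops)
  times["generate_rectify_crop"] <- tic() - t0
  report <- list(package_version = as.character(utils::packageVersion("budvision")),
                 config = config_echo(cfg), tasks = list())
  for (task in c("stage", "type")) {
    t0 <- tic()
    y <- if (task == "stage") ds$stage else ds$type
    sp <- split_dataset(y, train_frac = 0.9, seed = cfg$seed)
    xtr <- x[sp$train, , , , drop = FALSE]
    xte <- x[sp$test, , , , drop = FALSE]
    if (identical(cfg$arch, "search")) {
      se <- architecture_search(table_architectures(nlevels(y)),
                                xtr, y[sp$train], cfg$train,
                                test_x = xte, test_y = y[sp$test],
                                paper_mode = cfg$paper_mode)
      model <- se$model
      report$tasks[[task]]$candidates <- se$results
      report$tasks[[task]]$selected <- se$best
    } else {
      arch <- if (inherits(cfg$arch, "cnn_architecture")) cfg$arch else
        table_architectures(nlevels(y))[[2]]
      arch$n_classes <- nlevels(y)
      model <- train_cnn(arch, xtr, y[sp$train], cfg$train)
    }
    ev_tr <- evaluate_cnn(model, xtr, y[sp$train])
    ev_te <- evaluate_cnn(model, xte, y[sp$test])
    report$tasks[[task]]$train_accuracy <- ev_tr$accuracy
    report$tasks[[task]]$test_accuracy <- ev_te$accuracy
    report$tasks[[task]]$train_accuracy_pct <- ev_tr$accuracy_pct
    report$tasks[[task]]$test_accuracy_pct <- ev_te$accuracy_pct
    report$tasks[[task]]$confusion <-
      as.data.frame.matrix(unclass(ev_te$confusion))
    report$tasks[[task]]$final_train_curve <-
      model$curve[nrow(model$curve), ]
    if (task == "type") {
      saveRDS(model, file.path(cfg$out_dir, "cnn_model.rds"))
      jsonlite::write_json(unclass(model$arch),
                           file.path(cfg$out_dir, "cnn_model_arch.json"),
                           auto_unbox = TRUE)
    }
    times[paste0("cnn_", task)] <- tic() - t0
  }
  report$wall_times_s <- as.list(round(times, 2))
  jsonlite::write_json(report, file.path(cfg$out_dir, "cnn_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
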