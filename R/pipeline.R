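# End-to-end orchestration: images -> features -> pre-processing -> DUPLEX
# split -> LOOCV grid search -> test evaluation -> report files, plus a
# small command-line front end and simulation writers.

#' Run configuration
#'
#' @param preprocess_method One of `none`, `savgol`, `snv`, `minmax`,
#'   `area`, `baseline`.
#' @param savgol_window,savgol_degree Savitzky-Golay settings.
#' @param algorithms Algorithms to evaluate.
#' @param grids Named list of per-algorithm grids (defaults from
#'   [default_param_grid()]).
#' @param split_ratio Train : test ratio for the DUPLEX split.
#' @param response Label field to classify (`"type"` or `"species"`).
#' @param segmentation Settings from [segmentation_config()].
#' @param channel_weights Feature-extraction channel weights.
#' @param seed Seed recorded in the manifest (synthetic inputs only; the
#'   pipeline itself is deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(preprocess_method = "savgol", savgol_window = 33L,
                       savgol_degree = 2L,
                       algorithms = c("knn", "svm", "plsda", "kplsda", "lwplsc"),
                       grids = NULL, split_ratio = c(2, 1), response = "type",
                       segmentation = segmentation_config(),
                       channel_weights = c(0.2, 0.7, 0.1), seed = 42L) {
  if (is.null(grids))
    grids <- stats::setNames(lapply(algorithms, default_param_grid), algorithms)
  structure(list(preprocess_method = preprocess_method,
                 savgol_window = savgol_window, savgol_degree = savgol_degree,
                 algorithms = algorithms, grids = grids,
                 split_ratio = split_ratio, response = response,
                 segmentation = segmentation,
                 channel_weights = channel_weights, seed = seed),
            class = "run_config")
}

#' Extract features from a directory of rainbow photographs
#'
#' Segments every `.ppm`/`.pgm` image in `images_dir` and converts each
#' successfully extracted patch to a feature row. Failures are logged and
#' skipped; the run aborts only if no image succeeds.
#'
#' @param images_dir Directory of Netpbm images.
#' @param config A [run_config()].
#' @param out_csv Optional path for the feature CSV.
#' @param labels Optional data frame with columns `sample_id` (file name
#'   without extension), `species`, `type` to attach labels.
#' @param quiet Suppress per-image messages.
#' @return A `feature_matrix` (invisibly also written to `out_csv`).
#' @export
run_extract <- function(images_dir, config = run_config(), out_csv = NULL,
                        labels = NULL, quiet = FALSE) {
  files <- sort(list.files(images_dir, pattern = "\\.(ppm|pgm)$", full.names = TRUE))
  if (!length(files)) rc_error("invalid_input", "no readable images found")
  rows <- list(); ids <- character(0); failed <- character(0)
  for (f in files) {
    t0 <- proc.time()[3]
    res <- tryCatch({
      img <- read_pnm(f)
      patch <- extract_rainbow(img, config$segmentation)
      row_means(combine_channels(patch, config$channel_weights))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, basename(f))
      if (!quiet) message(sprintf("FAILED  %s: %s", basename(f), conditionMessage(res)))
      next
    }
    rows[[length(rows) + 1L]] <- res
    ids <- c(ids, sub("\\.(ppm|pgm)$", "", basename(f)))
    if (!quiet) message(sprintf("ok      %s (%.2fs)", basename(f), proc.time()[3] - t0))
  }
  if (!length(rows))
    rc_error("segmentation_failure",
             sprintf("all %d images failed segmentation", length(files)))
  X <- do.call(rbind, rows)
  sp <- ty <- NULL
  if (!is.null(labels)) {
    m <- match(ids, labels$sample_id)
    if ("species" %in% names(labels)) sp <- labels$species[m]
    if ("type" %in% names(labels)) ty <- labels$type[m]
  }
  fm <- feature_matrix(X, species = sp, type = ty, sample_id = ids)
  if (!is.null(out_csv)) write_feature_csv(fm, out_csv)
  if (length(failed) && !quiet)
    message(sprintf("%d/%d images failed: %s", length(failed), length(files),
                    paste(failed, collapse = ", ")))
  fm
}

#' Run the full classification experiment
#'
#' Executes the protocol in order: pre-processing, DUPLEX split, LOOCV grid
#' search per algorithm on the training set, refit with the selected
#' parameters, evaluation on the test set, and (optionally) report files:
#' `report.json`, a human-readable `report.txt` table, per-algorithm
#' accuracy-surface CSVs and a reproducibility manifest.
#'
#' @param fm A `feature_matrix` or path to a feature CSV.
#' @param config A [run_config()].
#' @param output_dir Optional directory for report files.
#' @param quiet Suppress progress messages.
#' @return List of class `experiment_report`: `split`, `results` (one entry
#'   per algorithm with `validation_accuracy`, `best_params`, `surface`,
#'   `test` evaluation), and `config`.
#' @export
run_experiment <- function(fm, config = run_config(), output_dir = NULL,
                           quiet = FALSE) {
  if (is.character(fm)) fm <- read_feature_csv(fm)
  y <- fm[[config$response]]
  if (is.null(y)) rc_error("labelling_error",
                           paste("feature matrix has no", config$response, "labels"))
  pp <- switch(config$preprocess_method,
               savgol = savgol_smooth(fm, config$savgol_window, config$savgol_degree),
               preprocess(fm, config$preprocess_method))
  split <- duplex_split(pp, config$split_ratio)
  train <- fm_subset(pp, split$train_idx)
  test <- fm_subset(pp, split$test_idx)
  results <- list()
  for (alg in config$algorithms) {
    t0 <- proc.time()[3]
    gs <- suppressWarnings(grid_search(train, alg, config$grids[[alg]],
                                       response = config$response))
    pred <- fit_predict_labels(alg, train$X, train[[config$response]],
                               test$X, gs$best_params)
    ev <- evaluate_predictions(test[[config$response]], pred,
                               classes = sort(unique(y)))
    results[[alg]] <- list(validation_accuracy = gs$best_accuracy,
                           best_params = gs$best_params,
                           surface = gs$surface, test = ev)
    if (!quiet)
      message(sprintf("%-7s validation %.1f%%  test %.1f%%  (%s) [%.1fs]",
                      alg, gs$best_accuracy, ev$overall,
                      paste(names(gs$best_params), unlist(gs$best_params),
                            sep = "=", collapse = ", "),
                      proc.time()[3] - t0))
  }
  report <- structure(list(split = split, results = results, config = config),
                      class = "experiment_report")
  if (!is.null(output_dir)) write_report_files(report, output_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(format_report_table(x), sep = "\n")
  invisible(x)
}

# Plain-text table in the style of the accuracy summary: validation, test
# overall, per-class, selected parameters. Rounded to one decimal at
# display only.
format_report_table <- function(report) {
  classes <- rownames(report$results[[1]]$test$confusion)
  hdr <- sprintf("%-8s %10s %8s %s %s", "method", "validation", "overall",
                 paste(sprintf("%12s", classes), collapse = " "), "parameters")
  lines <- vapply(names(report$results), function(alg) {
    r <- report$results[[alg]]
    sprintf("%-8s %9.1f%% %7.1f%% %s %s", alg, r$validation_accuracy,
            r$test$overall,
            paste(sprintf("%11.1f%%", r$test$per_class[classes]), collapse = " "),
            paste(names(r$best_params), unlist(r$best_params), sep = "=",
                  collapse = ", "))
  }, character(1))
  c(hdr, lines)
}

write_report_files <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  json <- lapply(report$results, function(r) {
    list(validation_accuracy = r$validation_accuracy,
         best_params = r$best_params,
         test_overall = r$test$overall,
         test_per_class = as.list(r$test$per_class),
         confusion = as.data.frame(unclass(r$test$confusion)))
  })
  jsonlite::write_json(list(results = json,
                            train_idx = report$split$train_idx,
                            test_idx = report$split$test_idx),
                       file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(format_report_table(report), file.path(output_dir, "report.txt"))
  for (alg in names(report$results))
    utils::write.csv(report$results[[alg]]$surface,
                     file.path(output_dir, paste0("surface_", alg, ".csv")),
                     row.names = FALSE)
  cfg_path <- file.path(output_dir, "config.json")
  cfg <- report$config
  cfg$grids <- lapply(cfg$grids, lapply, as.numeric)
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   package_version = as.character(utils::packageVersion("rainbowclass")),
                   r_version = R.version.string,
                   seed = report$config$seed,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(output_dir)
}

#' Write simulated rainbow photographs and ground truth to disk
#'
#' @param n Number of images.
#' @param dir Output directory (`imgNNN.ppm` plus `imgNNN_truth.json`).
#' @param base_spec A [scene_spec()]; image `i` uses `seed + i - 1`.
#' @param seed Base seed.
#' @return Character vector of image paths, invisibly.
#' @export
simulate_images <- function(n, dir, base_spec = scene_spec(), seed = 42L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n)
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$seed <- as.integer(seed + i - 1L)
    scene <- make_rainbow_image(sp)
    paths[i] <- file.path(dir, sprintf("img%03d.ppm", i))
    write_pnm(scene$image, paths[i])
    jsonlite::write_json(list(bbox = as.list(scene$bbox),
                              profile = scene$profile, seed = sp$seed),
                         file.path(dir, sprintf("img%03d_truth.json", i)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Write a simulated feature population to CSV
#'
#' @param path Output CSV.
#' @param spec A [population_spec()].
#' @param certify Passed to [make_feature_population()].
#' @return The `feature_matrix`, invisibly.
#' @export
simulate_features <- function(path, spec = population_spec(), certify = TRUE) {
  pop <- make_feature_population(spec, certify = certify)
  write_feature_csv(pop$fm, path)
  invisible(pop$fm)
}

#' Command-line entry point
#'
#' Subcommands (first argument), remaining arguments as `key=value`:
#' \describe{
#'   \item{simulate}{`what=features|images out=<path> n=<int> seed=<int>`}
#'   \item{extract}{`images=<dir> out=<csv>`}
#'   \item{train}{`features=<csv> algorithm=<plsda|kplsda> out=<json>` plus
#'     `n_lv=`, `sigma=`}
#'   \item{evaluate}{`features=<csv> out=<dir>` plus `algorithms=a,b,c`,
#'     `preprocess=<method>`}
#'   \item{report}{`dir=<dir>` (re-print a saved report table)}
#' }
#' A thin executable wrapper is installed under `exec/rainbowclass`.
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly, the result of the subcommand.
#' @export
rainbow_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop("usage: rainbowclass <simulate|extract|train|evaluate|report> key=value ...",
         call. = FALSE)
  cmd <- args[1L]
  kv <- strsplit(args[-1L], "=", fixed = TRUE)
  opts <- stats::setNames(lapply(kv, function(x) paste(x[-1L], collapse = "=")),
                          vapply(kv, `[[`, character(1), 1L))
  get_opt <- function(name, default = NULL) opts[[name]] %||% default
  res <- switch(cmd,
    simulate = {
      what <- get_opt("what", "features")
      seed <- as.integer(get_opt("seed", "42"))
      if (what == "features") {
        simulate_features(get_opt("out", "features.csv"),
                          population_spec(seed = seed))
      } else {
        simulate_images(as.integer(get_opt("n", "10")),
                        get_opt("out", "images"), seed = seed)
      }
    },
    extract = run_extract(get_opt("images"), run_config(),
                          out_csv = get_opt("out", "features.csv")),
    train = {
      fm <- read_feature_csv(get_opt("features"))
      alg <- get_opt("algorithm", "plsda")
      model <- switch(alg,
        plsda = pls_fit(fm, n_lv = as.integer(get_opt("n_lv", "2"))),
        kplsda = kpls_fit(fm, n_lv = as.integer(get_opt("n_lv", "2")),
                          sigma = as.numeric(get_opt("sigma", "1"))),
        stop("train supports algorithm=plsda|kplsda", call. = FALSE))
      save_model(model, get_opt("out", paste0(alg, "_model.json")))
      model
    },
    evaluate = {
      algs <- strsplit(get_opt("algorithms", "knn,svm,plsda,kplsda,lwplsc"), ",")[[1]]
      cfg <- run_config(preprocess_method = get_opt("preprocess", "savgol"),
                        algorithms = algs)
      run_experiment(get_opt("features"), cfg,
                     output_dir = get_opt("out", "results"))
    },
    report = {
      txt <- readLines(file.path(get_opt("dir", "results"), "report.txt"))
      cat(txt, sep = "\n")
      invisible(txt)
    },
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(res)
}
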