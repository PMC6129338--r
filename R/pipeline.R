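#' Pipeline orchestration
#'
#' Ties the three phases together — preprocessing, feature extraction
#' (texture + lesion area) and SVM classification — for batches of images,
#' and provides a self-contained synthetic experiment that generates a
#' balanced three-class dataset, trains the integrated classifier and
#' reports per-class recognition rates.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. All fields are
#' scalars, so a configuration round-trips losslessly through a flat
#' key=value file.
#'
#' @param median_window median-filter window (odd, px).
#' @param glcm_levels GLCM quantization levels.
#' @param glcm_log_base entropy log base (2 or `exp(1)`).
#' @param marker_threshold watershed basin depth, gray levels.
#' @param se_radius morphological cleanup disk radius, px.
#' @param C SVM penalty factor.
#' @param sigma SVM RBF width (`NA` = median heuristic).
#' @param seed master RNG seed; stage seeds are derived from it.
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(median_window = 3L,
                            glcm_levels = 64L,
                            glcm_log_base = 2,
                            marker_threshold = 10,
                            se_radius = 3L,
                            C = 50,
                            sigma = NA_real_,
                            seed = 1L) {
  cfg <- list(median_window = as.integer(median_window),
              glcm_levels = as.integer(glcm_levels),
              glcm_log_base = glcm_log_base,
              marker_threshold = marker_threshold,
              se_radius = as.integer(se_radius),
              C = C, sigma = sigma, seed = as.integer(seed))
  if (cfg$median_window < 3L || cfg$median_window %% 2L == 0L)
    stop("invalid `median_window`")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as a flat key=value file
#'
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(v) format(v, digits = 17), "")),
             path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) x[2]), vapply(kv, `[`, "", 1))
  pipeline_config(
    median_window = as.integer(vals$median_window),
    glcm_levels = as.integer(vals$glcm_levels),
    glcm_log_base = as.numeric(vals$glcm_log_base),
    marker_threshold = as.numeric(vals$marker_threshold),
    se_radius = as.integer(vals$se_radius),
    C = as.numeric(vals$C),
    sigma = if (identical(vals$sigma, "NA")) NA_real_ else as.numeric(vals$sigma),
    seed = as.integer(vals$seed))
}

#' Extract the full 11-dimensional feature vector from one image
#'
#' Runs preprocessing, per-segment GLCM statistics and lesion-area
#' segmentation, returning the classifier-ready vector.
#'
#' @param img colour array (or grayscale matrix; lesion colour clustering
#'   then works on intensity alone) in \[0, 255\].
#' @param cfg a [pipeline_config()].
#' @return list with `features` (length-11 vector), `pre` (preprocessing
#'   result), `lesion` (`lesion_segmentation`).
#' @export
extract_image_features <- function(img, cfg = pipeline_config()) {
  pre <- preprocess_image(img, window = cfg$median_window)
  gcfg <- glcm_config(levels = cfg$glcm_levels, log_base = cfg$glcm_log_base)
  tex <- features_for_segments(pre$gray_rotated, pre$segments, gcfg)
  lesion <- segment_lesion(pre$filtered,
                           marker_threshold = cfg$marker_threshold,
                           se_radius = cfg$se_radius)
  list(features = build_feature_vector(tex, lesion), pre = pre, lesion = lesion)
}

#' Run the pipeline over a batch of images
#'
#' Processes each image through preprocessing, feature extraction and
#' (when a model is supplied) classification. A failure on one image is
#' recorded in the manifest and does not abort the batch.
#'
#' @param images a list of in-memory images (matrices/arrays) and/or file
#'   paths; paths are read with [read_image()].
#' @param cfg a [pipeline_config()].
#' @param model optional `svm_model` for prediction.
#' @return an object of class `run_manifest`: data frame with one row per
#'   image (`input`, `status`, `predicted`, `area_fraction`, `error`) and
#'   the feature matrix in `attr(, "features")`.
#' @export
run_pipeline <- function(images, cfg = pipeline_config(), model = NULL) {
  if (!length(images)) stop("empty batch")
  n <- length(images)
  feats <- matrix(NA_real_, n, 11)
  status <- character(n); predicted <- rep(NA_character_, n)
  areafrac <- rep(NA_real_, n); errs <- rep(NA_character_, n)
  inputs <- vapply(seq_len(n), function(i)
    if (is.character(images[[i]])) images[[i]] else sprintf("<in-memory #%d>", i), "")
  for (i in seq_len(n)) {
    res <- tryCatch({
      img <- if (is.character(images[[i]])) read_image(images[[i]]) else images[[i]]
      ex <- extract_image_features(img, cfg)
      feats[i, ] <- ex$features
      areafrac[i] <- ex$lesion$area_fraction
      if (!is.null(model))
        predicted[i] <- svm_predict(model, matrix(ex$features, nrow = 1))$class
      "ok"
    }, error = function(e) {
      errs[i] <<- conditionMessage(e)
      "error"
    })
    status[i] <- res
  }
  out <- data.frame(input = inputs, status = status, predicted = predicted,
                    area_fraction = areafrac, error = errs,
                    stringsAsFactors = FALSE)
  attr(out, "features") <- feats
  attr(out, "config") <- cfg
  class(out) <- c("run_manifest", "data.frame")
  out
}

#' Self-contained synthetic recognition experiment
#'
#' Generates `n_per_class` synthetic images per disease class, splits each
#' class into `n_train` training and the remaining test images, extracts
#' the 11-dimensional texture + area feature vector from every image,
#' trains the integrated one-vs-one RBF SVM (plus the texture-only SVM1
#' and area-only SVM2 diagnostics), and reports per-class recognition
#' rates on the held-out test images.
#'
#' @param n_per_class images per class (default 30).
#' @param n_train training images per class (default 10; the rest test).
#' @param cfg a [pipeline_config()]; `cfg$seed` drives the generator.
#' @param verbose print progress.
#' @return list with `table` (per-class data frame: class, n_test,
#'   n_recognized, rate_pct), `overall_pct`, `svm1_overall_pct` (texture
#'   only), `svm2_overall_pct` (area only), `model`, `features`, `labels`,
#'   `split` (train/test indicator).
#' @export
end_to_end_experiment <- function(n_per_class = 30L, n_train = 10L,
                                  cfg = pipeline_config(), verbose = FALSE) {
  n_per_class <- as.integer(n_per_class)
  n_train <- as.integer(n_train)
  stopifnot(n_per_class >= 2L, n_train >= 1L, n_train < n_per_class)
  ds <- generate_dataset(n_per_class, seed = derive_seed(cfg$seed, 1L))
  n <- length(ds)
  labels <- vapply(ds, function(d) d$ground_truth$label, "")
  feats <- matrix(NA_real_, n, 11)
  for (i in seq_len(n)) {
    if (verbose) message(sprintf("image %d/%d (%s)", i, n, labels[i]))
    fv <- extract_image_features(ds[[i]]$image, cfg)$features
    if (is.null(colnames(feats))) colnames(feats) <- names(fv)
    feats[i, ] <- fv
  }
  is_train <- unlist(lapply(split(seq_len(n), factor(labels, unique(labels))),
                            function(ix) ix[seq_len(n_train)]))
  train_idx <- sort(unname(is_train))
  test_idx <- setdiff(seq_len(n), train_idx)
  sig <- if (is.na(cfg$sigma)) NULL else cfg$sigma
  model <- svm_train(feats[train_idx, ], labels[train_idx], C = cfg$C, sigma = sig)
  tab <- svm_evaluate(model, feats[test_idx, ], labels[test_idx])
  svm1 <- suppressWarnings(
    svm_train(feats[train_idx, 1:10], labels[train_idx], C = cfg$C, sigma = sig))
  svm2 <- suppressWarnings(
    svm_train(feats[train_idx, 11, drop = FALSE], labels[train_idx],
              C = cfg$C, sigma = sig))
  ov1 <- attr(svm_evaluate(svm1, feats[test_idx, 1:10], labels[test_idx]), "overall_pct")
  ov2 <- attr(svm_evaluate(svm2, feats[test_idx, 11, drop = FALSE], labels[test_idx]),
              "overall_pct")
  list(table = tab,
       overall_pct = attr(tab, "overall_pct"),
       svm1_overall_pct = ov1,
       svm2_overall_pct = ov2,
       model = model, features = feats, labels = labels,
       split = ifelse(seq_len(n) %in% train_idx, "train", "test"))
}
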