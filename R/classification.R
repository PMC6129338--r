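#' RBF-kernel SVM classification of skin-disease feature vectors
#'
#' The classifier consumes an 11-dimensional feature vector per image:
#' the (min, max) over the ten vertical regions of each of the five GLCM
#' statistics (the texture part, mirroring the minimum/maximum layout of
#' clinical texture tables) plus the lesion area fraction (the colour
#' part). One-vs-one soft-margin SVMs with a radial basis function kernel
#' `k(u, v) = exp(-||u - v||^2 / (2 sigma^2))` and penalty `C = 50` are
#' trained by an SMO-style dual solver; prediction takes the sign of
#' `sum_j a_j y_j k(x, x_j) + b` per class pair and a majority vote.
#'
#' @name classification
NULL

#' Radial basis function kernel
#'
#' @param u,v numeric vectors of equal length.
#' @param sigma kernel width, > 0.
#' @return `exp(-||u - v||^2 / (2 sigma^2))`.
#' @export
rbf_kernel <- function(u, v, sigma) {
  if (length(u) != length(v)) stop("`u` and `v` must have equal length")
  if (!is.numeric(sigma) || sigma <= 0) stop("invalid `sigma`: must be > 0")
  exp(-sum((u - v)^2) / (2 * sigma^2))
}

# full RBF Gram matrix between rows of A and rows of B
rbf_gram <- function(A, B, sigma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

# SMO-style solver for the binary soft-margin dual. Deterministic: second
# index chosen by maximal |E_i - E_j|. Maintains sum(alpha * y) = 0 exactly.
smo_binary <- function(K, y, C, tol = 1e-3, max_sweeps = 10000L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  f <- function() as.numeric(K %*% (alpha * y)) + b
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    changed <- 0L
    E <- f() - y
    for (i in seq_len(n)) {
      Ei <- sum(K[i, ] * alpha * y) + b - y[i]
      if (!((y[i] * Ei < -tol && alpha[i] < C) || (y[i] * Ei > tol && alpha[i] > 0)))
        next
      E <- as.numeric(K %*% (alpha * y)) + b - y
      j <- which.max(abs(E - E[i]) + ifelse(seq_len(n) == i, -Inf, 0))
      Ej <- E[j]
      ai_old <- alpha[i]; aj_old <- alpha[j]
      if (y[i] != y[j]) {
        L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
      } else {
        L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
      }
      if (H - L < 1e-12) next
      eta <- 2 * K[i, j] - K[i, i] - K[j, j]
      if (eta >= 0) next
      aj <- aj_old - y[j] * (Ei - Ej) / eta
      aj <- min(max(aj, L), H)
      if (abs(aj - aj_old) < 1e-7) next
      ai <- ai_old + y[i] * y[j] * (aj_old - aj)
      b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] - y[j] * (aj - aj_old) * K[i, j]
      b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] - y[j] * (aj - aj_old) * K[j, j]
      alpha[i] <- ai; alpha[j] <- aj
      b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
      changed <- changed + 1L
    }
    if (changed == 0L || sweeps >= max_sweeps) break
  }
  list(alpha = alpha, b = b, sweeps = sweeps)
}

#' Train the one-vs-one RBF-kernel SVM classifier
#'
#' Features are rescaled to \[0, 1\] per dimension from the training data
#' (dimensions with zero spread are dropped with a warning); one binary
#' soft-margin SVM is trained per class pair.
#'
#' @param X numeric matrix, one feature vector per row (e.g. from
#'   [build_feature_vector()]).
#' @param labels factor or character vector of class labels, one per row;
#'   at least 2 classes with >= 2 samples each.
#' @param C soft-margin penalty bounding the dual multipliers
#'   (default 50, the value at which recognition is best).
#' @param sigma RBF width; `NULL` (default) selects the median heuristic,
#'   the median pairwise distance between scaled training points.
#' @param tol SMO KKT tolerance.
#' @return an object of class `svm_model`: scaler, kept dimensions,
#'   `sigma`, `C`, class levels and one sub-model per class pair
#'   (support vectors, multipliers `a_j`, labels `y_j`, bias).
#' @export
svm_train <- function(X, labels, C = 50, sigma = NULL, tol = 1e-3) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) < 2L) stop("single-class data: need >= 2 classes")
  if (any(table(labels) < 2L)) stop("need >= 2 samples per class")
  if (!is.numeric(C) || C <= 0) stop("invalid `C`: must be > 0")
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  keep <- which(hi - lo > 1e-12)
  if (length(keep) < ncol(X))
    warning(sprintf("dropping %d zero-spread feature dimension(s)", ncol(X) - length(keep)))
  if (!length(keep)) stop("no informative feature dimensions")
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, lo[keep]), 2, hi[keep] - lo[keep], "/")
  if (is.null(sigma)) {
    d <- stats::dist(Xs)
    sigma <- stats::median(d[d > 0])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  sub <- lapply(pairs, function(pr) {
    sel <- labels %in% pr
    Xp <- Xs[sel, , drop = FALSE]
    y <- ifelse(labels[sel] == pr[1], 1, -1)
    K <- rbf_gram(Xp, Xp, sigma)
    fit <- smo_binary(K, y, C, tol = tol)
    sv <- fit$alpha > 1e-8
    list(classes = pr, X = Xp[sv, , drop = FALSE],
         alpha = fit$alpha[sv], y = y[sv], b = fit$b,
         alpha_all = fit$alpha, y_all = y)
  })
  structure(list(scaler = list(lo = lo, hi = hi, keep = keep),
                 sigma = sigma, C = C, levels = lev, sub_models = sub),
            class = "svm_model")
}

scale_features <- function(model, X) {
  s <- model$scaler
  X <- as.matrix(X)
  if (ncol(X) != length(s$lo)) stop("feature dimension mismatch")
  sweep(sweep(X[, s$keep, drop = FALSE], 2, s$lo[s$keep]), 2,
        (s$hi - s$lo)[s$keep], "/")
}

#' Predict classes with a trained one-vs-one SVM
#'
#' Evaluates the decision function `sgn(sum_j a_j y_j k(x, x_j) + b)` for
#' every class pair and takes the majority vote; ties go to the class
#' listed first in the model's level order.
#'
#' @param model an `svm_model` from [svm_train()].
#' @param X feature matrix (rows = samples) on the original scale.
#' @return list with `class` (character vector) and `votes` (matrix of
#'   per-class vote counts).
#' @export
svm_predict <- function(model, X) {
  stopifnot(inherits(model, "svm_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Xs <- scale_features(model, X)
  votes <- matrix(0L, nrow(Xs), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (sm in model$sub_models) {
    K <- rbf_gram(Xs, sm$X, model$sigma)
    dec <- as.numeric(K %*% (sm$alpha * sm$y)) + sm$b
    winner <- ifelse(dec >= 0, sm$classes[1], sm$classes[2])
    for (cl in model$levels) votes[, cl] <- votes[, cl] + (winner == cl)
  }
  cls <- model$levels[apply(votes, 1, which.max)]  # first max -> lowest index
  list(class = cls, votes = votes)
}

#' Assemble the 11-dimensional classifier feature vector
#'
#' Texture part: per-statistic minimum and maximum over the ten vertical
#' regions (10 values); colour part: the lesion area fraction (1 value).
#'
#' @param tex 10 x 5 matrix from [features_for_segments()].
#' @param area a `lesion_segmentation` from [segment_lesion()], or a bare
#'   area fraction in \[0, 1\].
#' @return named numeric vector of length 11.
#' @export
build_feature_vector <- function(tex, area) {
  tex <- as.matrix(tex)
  if (nrow(tex) != 10L || ncol(tex) != 5L)
    stop("`tex` must be a 10 x 5 segment-by-statistic matrix")
  af <- if (inherits(area, "lesion_segmentation")) area$area_fraction else area
  if (!is.numeric(af) || af < 0 || af > 1) stop("invalid area fraction")
  mins <- apply(tex, 2, min); maxs <- apply(tex, 2, max)
  out <- c(rbind(mins, maxs))
  names(out) <- as.vector(rbind(paste0(colnames(tex), "_min"),
                                paste0(colnames(tex), "_max")))
  c(out, area_fraction = af)
}

#' Per-class recognition rates of a trained classifier
#'
#' @param model an `svm_model`.
#' @param X labelled test feature matrix.
#' @param labels true class per row.
#' @return data frame with one row per class: `class`, `n_test`,
#'   `n_recognized`, `rate_pct`, plus an `overall_pct` attribute.
#' @export
svm_evaluate <- function(model, X, labels) {
  labels <- as.character(labels)
  if (!length(labels)) stop("empty test set")
  pred <- svm_predict(model, X)$class
  lev <- unique(c(model$levels, labels))
  lev <- lev[lev %in% labels]
  rows <- lapply(lev, function(cl) {
    sel <- labels == cl
    data.frame(class = cl, n_test = sum(sel),
               n_recognized = sum(pred[sel] == cl),
               rate_pct = 100 * sum(pred[sel] == cl) / sum(sel))
  })
  out <- do.call(rbind, rows)
  attr(out, "overall_pct") <- 100 * mean(pred == labels)
  out
}

#' Serialize a trained SVM model to a JSON archive
#'
#' The archive is a versioned single-file JSON document holding the
#' scaler, kernel width, penalty and per-pair support vectors,
#' multipliers and biases; [load_model()] restores it.
#'
#' @param model an `svm_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  doc <- list(format = "dermatex-svm", version = 1L,
              scaler = list(lo = model$scaler$lo, hi = model$scaler$hi,
                            keep = model$scaler$keep),
              sigma = model$sigma, C = model$C, levels = model$levels,
              sub_models = lapply(model$sub_models, function(sm)
                list(classes = sm$classes,
                     n_sv = nrow(sm$X), n_dim = ncol(sm$X),
                     X = as.numeric(sm$X), alpha = sm$alpha,
                     y = sm$y, b = sm$b)))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a serialized SVM model
#'
#' @param path file written by [save_model()].
#' @return an `svm_model`.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "dermatex-svm"))
    stop("not a dermatex SVM model file: ", path)
  num <- function(x) as.numeric(unlist(x))
  sub <- lapply(doc$sub_models, function(sm)
    list(classes = as.character(unlist(sm$classes)),
         X = matrix(num(sm$X), nrow = sm$n_sv, ncol = sm$n_dim),
         alpha = num(sm$alpha), y = num(sm$y), b = num(sm$b)))
  structure(list(scaler = list(lo = num(doc$scaler$lo),
                               hi = num(doc$scaler$hi),
                               keep = as.integer(unlist(doc$scaler$keep))),
                 sigma = num(doc$sigma), C = num(doc$C),
                 levels = as.character(unlist(doc$levels)),
                 sub_models = sub),
            class = "svm_model")
}
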