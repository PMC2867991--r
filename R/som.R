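asFeatureMatrix <- function(features) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  storage.mode(features) <- "double"
  features
}

somGridCoords <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

normalizeFeatures <- function(som, X) {
  X <- asFeatureMatrix(X)
  if (ncol(X) != ncol(som@weights))
    stop(sprintf("feature dimension %d does not match the grid's %d",
                 ncol(X), ncol(som@weights)))
  if (any(!is.finite(X)))
    stop("features contain non-finite values")
  sweep(sweep(X, 2L, som@center, "-"), 2L, som@scale, "/")
}

#' Train a two-dimensional self-organizing map
#'
#' Classical Kohonen training: node weights are initialised from seeded
#' uniform samples within per-dimension data ranges; for each sample the
#' best-matching unit (BMU) is the node with the smallest Euclidean
#' distance (ties to the smallest row-major index), and all nodes are pulled
#' toward the sample with a Gaussian neighbourhood factor on the grid
#' coordinates. The learning rate decays exponentially from 0.5 to 0.01 and
#' the neighbourhood radius from `max(rows, cols)/2` to 0.5 over the
#' epochs; the sample order is reshuffled each epoch by the seeded RNG, so
#' training is fully deterministic given (data, seed, hyperparameters).
#'
#' Features are z-scored per dimension with training-set statistics before
#' training (otherwise Euclidean distances are dominated by the
#' largest-scale feature); the constants are stored in the grid and reused
#' at prediction time. Set `scale = FALSE` for raw distances.
#'
#' @param features numeric matrix or data frame, one row per training
#'   vector.
#' @param rows,cols grid shape (default 8 x 6).
#' @param epochs training epochs (default 500).
#' @param seed integer RNG seed.
#' @param scale z-score features before training?
#' @return A [SOMGrid-class].
#' @examples
#' X <- matrix(rnorm(300), ncol = 3)
#' som <- trainSOM(X, rows = 4, cols = 4, epochs = 50, seed = 1)
#' @export
trainSOM <- function(features, rows = 8L, cols = 6L, epochs = 500L,
                     seed = 1L, scale = TRUE) {
  X <- asFeatureMatrix(features)
  n <- nrow(X); d <- ncol(X)
  if (n == 0L) stop("empty training set")
  if (any(!is.finite(X))) stop("features contain non-finite values")
  rows <- as.integer(rows); cols <- as.integer(cols)
  epochs <- as.integer(epochs)
  nNodes <- rows * cols
  if (n < nNodes)
    warning(sprintf("only %d training vectors for %d nodes", n, nNodes))
  center <- if (scale) colMeans(X) else rep(0, d)
  scl <- if (scale) apply(X, 2L, sd) else rep(1, d)
  scl[!is.finite(scl) | scl == 0] <- 1
  X <- sweep(sweep(X, 2L, center, "-"), 2L, scl, "/")
  grid <- somGridCoords(rows, cols)
  lr0 <- 0.5; lr1 <- 0.01
  r0 <- max(rows, cols) / 2; r1 <- 0.5
  frac <- if (epochs > 1L) (seq_len(epochs) - 1) / (epochs - 1) else 0
  lrs <- lr0 * (lr1 / lr0)^frac
  rads <- r0 * (r1 / r0)^frac
  W <- withSeed(seed, {
    lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
    W <- matrix(runif(nNodes * d), nNodes, d)
    W <- sweep(sweep(W, 2L, hi - lo, "*"), 2L, lo, "+")
    for (e in seq_len(epochs)) {
      lr <- lrs[e]; sig2 <- 2 * rads[e]^2
      ord <- sample.int(n)
      for (idx in ord) {
        x <- X[idx, ]
        diffs <- sweep(W, 2L, x, "-")
        bmu <- which.min(rowSums(diffs^2))
        g2 <- (grid[, 1L] - grid[bmu, 1L])^2 + (grid[, 2L] - grid[bmu, 2L])^2
        h <- lr * exp(-g2 / sig2)
        W <- W - h * diffs
      }
    }
    W
  })
  new("SOMGrid", rows = rows, cols = cols, weights = W,
      nodeLabels = character(), center = center, scale = scl,
      featureNames = if (is.null(colnames(features))) character()
                     else colnames(features),
      trainingLog = list(epochs = epochs, lr_final = lrs[epochs],
                         radius_final = rads[epochs]),
      seed = as.integer(seed))
}

#' Best-matching unit indices
#'
#' Row-major node index of the BMU of each feature vector (after applying
#' the grid's stored normalisation); ties go to the smallest index.
#'
#' @param som a [SOMGrid-class].
#' @param features matrix/data frame of feature vectors (or a single
#'   vector).
#' @return Integer vector of node indices.
#' @export
somBMU <- function(som, features) {
  X <- normalizeFeatures(som, features)
  W <- som@weights
  apply(X, 1L, function(x) which.min(rowSums(sweep(W, 2L, x, "-")^2)))
}

#' Label SOM nodes by majority vote
#'
#' Each node takes the majority class of the training vectors mapped to it
#' (ties resolved toward the class most frequent overall); nodes hit by no
#' training vector inherit the label of the nearest labelled node in grid
#' coordinates (ties to the smallest row-major index).
#'
#' @param som a trained [SOMGrid-class].
#' @param features labelled training features.
#' @param labels character vector of class labels, one per row.
#' @return The grid with `nodeLabels` filled in.
#' @export
labelNodes <- function(som, features, labels) {
  stopifnot(is(som, "SOMGrid"))
  labels <- as.character(labels)
  X <- asFeatureMatrix(features)
  if (length(labels) != nrow(X))
    stop("need one label per training vector")
  if (anyNA(labels)) stop("training labels contain NA")
  bmu <- somBMU(som, X)
  nNodes <- nrow(som@weights)
  globalFreq <- table(labels)
  nodeLab <- rep(NA_character_, nNodes)
  for (k in unique(bmu)) {
    tab <- table(labels[bmu == k])
    topCount <- max(tab)
    cand <- names(tab)[tab == topCount]
    if (length(cand) > 1L)
      cand <- cand[order(-as.numeric(globalFreq[cand]), cand)][1L]
    nodeLab[k] <- cand
  }
  if (anyNA(nodeLab)) {
    grid <- somGridCoords(som@rows, som@cols)
    labelled <- which(!is.na(nodeLab))
    for (k in which(is.na(nodeLab))) {
      d2 <- (grid[labelled, 1L] - grid[k, 1L])^2 +
            (grid[labelled, 2L] - grid[k, 2L])^2
      nodeLab[k] <- nodeLab[labelled[order(d2, labelled)[1L]]]
    }
  }
  som@nodeLabels <- nodeLab
  validObject(som)
  som
}

#' Predict classes with a labelled SOM
#'
#' Returns the label of the best-matching unit of each feature vector.
#'
#' @param object a labelled [SOMGrid-class].
#' @param newdata feature matrix/data frame, or a single feature vector.
#' @param ... ignored.
#' @return Character vector of predicted classes.
#' @aliases predict,SOMGrid-method
#' @export
setMethod("predict", "SOMGrid", function(object, newdata, ...) {
  if (!length(object@nodeLabels))
    stop("grid is unlabelled; run labelNodes() first")
  object@nodeLabels[somBMU(object, newdata)]
})

#' Per-class and overall correct resolution
#'
#' Evaluates a labelled grid on a test set: per-class accuracy (correct /
#' class size), overall accuracy, and the confusion matrix (rows = true
#' classes, columns = predicted).
#'
#' @param som a labelled [SOMGrid-class].
#' @param features test features.
#' @param labels true class labels.
#' @return List of class `"ResolutionReport"`: `per_class`, `overall`,
#'   `confusion`, `n`.
#' @export
resolutionReport <- function(som, features, labels) {
  labels <- as.character(labels)
  X <- asFeatureMatrix(features)
  if (nrow(X) == 0L) stop("empty test set")
  if (length(labels) != nrow(X)) stop("need one label per test vector")
  pred <- predict(som, X)
  classes <- sort(unique(labels))
  confusion <- table(factor(labels, levels = classes),
                     factor(pred, levels = sort(unique(c(classes, pred)))))
  perClass <- vapply(classes, function(cl)
    mean(pred[labels == cl] == cl), numeric(1))
  structure(list(per_class = perClass, overall = mean(pred == labels),
                 confusion = confusion, n = length(labels)),
            class = "ResolutionReport")
}

#' @export
print.ResolutionReport <- function(x, ...) {
  cat(sprintf("Resolution on %d test vectors: overall %.3f\n", x$n,
              x$overall))
  for (cl in names(x$per_class))
    cat(sprintf("  %-8s %.3f\n", cl, x$per_class[cl]))
  invisible(x)
}

#' Save / load a SOM as a flat JSON artifact
#'
#' Persists grid shape, row-major weights, node labels, normalisation
#' constants and training log as plain JSON.
#'
#' @param som a [SOMGrid-class].
#' @param path file path.
#' @return `saveSOM` returns the path invisibly; `loadSOM` a `SOMGrid`.
#' @export
saveSOM <- function(som, path) {
  stopifnot(is(som, "SOMGrid"))
  obj <- list(rows = som@rows, cols = som@cols,
              weights = as.numeric(t(som@weights)),
              d = ncol(som@weights),
              node_labels = som@nodeLabels, center = som@center,
              scale = som@scale, feature_names = som@featureNames,
              training_log = som@trainingLog, seed = som@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveSOM
#' @export
loadSOM <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SOMGrid", rows = as.integer(obj$rows), cols = as.integer(obj$cols),
      weights = matrix(obj$weights, ncol = obj$d, byrow = TRUE),
      nodeLabels = as.character(obj$node_labels %||% character()),
      center = as.numeric(obj$center), scale = as.numeric(obj$scale),
      featureNames = as.character(obj$feature_names %||% character()),
      trainingLog = as.list(obj$training_log), seed = as.integer(obj$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
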