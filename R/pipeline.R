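featureNames <- c("alpha", "beta", "ctm", "s", "apen", "d2", "lambda1")

#' Extract the nonlinear/spectral feature vector of a recording
#'
#' Ranks the leads by EOG contamination, keeps the 3 least-contaminated EEG
#' leads, and averages per-lead features over them: alpha and beta band
#' energies from the AIC-order Burg PSD, CTM and the surrogate determinism
#' ratio S, approximate entropy (`cfg$apen_m`, `cfg$apen_r_factor * SD`),
#' the correlation dimension D2 (single-lead delay embedding, averaged over
#' the leads where a scaling region is found), and the largest Lyapunov
#' exponent from the spliced leads. Individual feature failures (no scaling
#' region, no stable divergence window) are recorded as `NA` with a flag,
#' not fatal errors. If no EOG lead is present, all leads are used with a
#' warning.
#'
#' @param rec a [Recording-class].
#' @param cfg an [analysisConfig()]; its seed drives the surrogate
#'   ensembles, so identical recordings give identical features.
#' @return Named numeric vector `alpha, beta, ctm, s, apen, d2, lambda1`
#'   with a character attribute `"flags"`.
#' @export
extractFeatures <- function(rec, cfg = analysisConfig()) {
  stopifnot(is(rec, "Recording"))
  validateConfig(cfg)
  flags <- character()
  leads <- if ("EOG" %in% leadLabels(rec)) {
    rankLeadsByEOG(rec)
  } else {
    warning("no EOG lead; using all leads without contamination ranking")
    flags <- c(flags, "no_eog")
    leadLabels(rec)
  }
  top <- head(leads, 3L)
  fs <- samplingRate(rec)
  alphaBand <- cfg$bands$alpha
  betaBand <- cfg$bands$beta
  alpha <- beta <- ctmv <- sv <- ap <- numeric(length(top))
  d2v <- rep(NA_real_, length(top))
  seeds <- deriveSeeds(cfg$seed, length(top))
  for (i in seq_along(top)) {
    x <- getLead(rec, top[i])
    spec <- arSpectrum(x, fs = fs, pMax = cfg$ar_order_max)
    alpha[i] <- bandEnergy(spec, alphaBand[1], alphaBand[2])
    beta[i] <- bandEnergy(spec, betaBand[1], betaBand[2])
    cfgLead <- cfg
    cfgLead$seed <- seeds[i]
    det <- determinismRatio(x, cfgLead)
    ctmv[i] <- det$ctm_data
    sv[i] <- det$S
    ap[i] <- apenScaled(x, cfg$apen_m, cfg$apen_r_factor)
    d2v[i] <- tryCatch(correlationDimension(x, cfg)$D2,
                       noScalingRegionError = function(e) NA_real_)
  }
  if (all(is.na(d2v))) flags <- c(flags, "d2_no_scaling_region")
  lambda1 <- tryCatch(
    as.numeric(lyapunovFromRecording(rec, cfg, leads = top)),
    noFitWindowError = function(e) {
      NA_real_
    })
  if (is.na(lambda1)) flags <- c(flags, "lambda1_no_fit_window")
  out <- c(alpha = mean(alpha), beta = mean(beta), ctm = mean(ctmv),
           s = mean(sv), apen = mean(ap),
           d2 = if (all(is.na(d2v))) NA_real_ else mean(d2v, na.rm = TRUE),
           lambda1 = lambda1)
  attr(out, "flags") <- flags
  out
}

#' Build a feature table for a labelled dataset
#'
#' Applies [extractFeatures()] to every recording of a dataset.
#'
#' @param dataset a `"LabeledDataset"` (from [syntheticDataset()]), or a
#'   plain list of [Recording-class] objects.
#' @param cfg an [analysisConfig()].
#' @param labels class labels (taken from the dataset if present).
#' @param ids recording identifiers; default `rec_1 .. rec_n`.
#' @return Data frame of class `"FeatureTable"` with columns `id, label,
#'   alpha, beta, ctm, s, apen, d2, lambda1, flags`.
#' @export
featureTable <- function(dataset, cfg = analysisConfig(), labels = NULL,
                         ids = NULL) {
  recs <- if (inherits(dataset, "LabeledDataset")) dataset$recordings
          else dataset
  if (is.null(labels) && inherits(dataset, "LabeledDataset"))
    labels <- dataset$labels
  n <- length(recs)
  if (is.null(labels)) labels <- rep(NA_character_, n)
  if (is.null(ids)) ids <- sprintf("rec_%d", seq_len(n))
  if (anyDuplicated(ids)) stop("recording ids must be unique")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fv <- extractFeatures(recs[[i]], cfg)
    rows[[i]] <- data.frame(id = ids[i], label = labels[i],
                            as.list(fv),
                            flags = paste(attr(fv, "flags"),
                                          collapse = ";"),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("FeatureTable", "data.frame")
  out
}

#' Read / write a feature table as TSV
#'
#' Fixed column layout: `id, label, alpha, beta, ctm, s, apen, d2, lambda1,
#' flags`.
#'
#' @param x a `"FeatureTable"`.
#' @param path file path.
#' @return `writeFeatureTable` returns the path invisibly;
#'   `readFeatureTable` a `"FeatureTable"`.
#' @export
writeFeatureTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(id = "character",
                                          label = "character",
                                          flags = "character"))
  need <- c("id", "label", featureNames, "flags")
  if (!all(need %in% names(out)))
    stop("feature table is missing required columns")
  class(out) <- c("FeatureTable", "data.frame")
  out
}

stratifiedSplit <- function(labels, trainFrac, seed) {
  classes <- unique(labels)
  train <- logical(length(labels))
  withSeed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      if (length(idx) < 2L)
        stop(sprintf("class '%s' has fewer than 2 recordings", cl))
      nTr <- max(1L, min(length(idx) - 1L,
                         as.integer(round(trainFrac * length(idx)))))
      train[sample(idx, nTr)] <- TRUE
    }
  })
  train
}

imputeWithMeans <- function(X, means) {
  for (j in seq_len(ncol(X))) {
    bad <- is.na(X[, j])
    if (any(bad)) X[bad, j] <- means[j]
  }
  X
}

#' Run the end-to-end classification experiment
#'
#' Extracts features (unless a precomputed [featureTable()] is supplied),
#' makes a seeded stratified 70/30 train/test split, imputes missing
#' features with training-split means, trains and labels the SOM on the
#' training split (features z-scored with training statistics inside
#' [trainSOM()]), and evaluates on the test split. Also computes the
#' mixed-task curve: overall accuracy when only the first `k` classes (in
#' canonical class order) are pooled, `k = 1..K`, re-splitting and
#' re-training for each subset.
#'
#' @param dataset a `"LabeledDataset"`, or a precomputed `"FeatureTable"`
#'   with labels.
#' @param cfg an [analysisConfig()].
#' @param trainFrac training fraction (default 0.7).
#' @param scaleFeatures z-score features before SOM training? (Exposed so
#'   the necessity of scaling can be demonstrated; keep `TRUE`.)
#' @return List of class `"ExperimentResult"`: `report` (a
#'   `"ResolutionReport"`), `mixed_curve` (accuracy for class subsets
#'   `1..K`), `som`, `features` (the full `"FeatureTable"`), `split_seed`,
#'   `train_index`.
#' @export
runExperiment <- function(dataset, cfg = analysisConfig(), trainFrac = 0.7,
                          scaleFeatures = TRUE) {
  ft <- if (inherits(dataset, "FeatureTable")) dataset
        else featureTable(dataset, cfg)
  if (anyNA(ft$label)) stop("dataset labels are required")
  classOrder <- if (inherits(dataset, "LabeledDataset"))
    dataset$classOrder else unique(ft$label)
  if (length(unique(ft$label)) < 2L)
    stop("need at least 2 classes to run the experiment")
  evalSubset <- function(tab) {
    X <- as.matrix(tab[, featureNames])
    train <- stratifiedSplit(tab$label, trainFrac, cfg$seed)
    Xtr <- X[train, , drop = FALSE]
    means <- colMeans(Xtr, na.rm = TRUE)
    means[is.nan(means)] <- 0
    Xtr <- imputeWithMeans(Xtr, means)
    Xte <- imputeWithMeans(X[!train, , drop = FALSE], means)
    som <- trainSOM(Xtr, rows = cfg$som_rows, cols = cfg$som_cols,
                    epochs = cfg$som_epochs, seed = cfg$seed,
                    scale = scaleFeatures)
    som <- labelNodes(som, Xtr, tab$label[train])
    list(som = som, train = train,
         report = resolutionReport(som, Xte, tab$label[!train]))
  }
  full <- evalSubset(ft)
  mixed <- numeric(length(classOrder))
  names(mixed) <- as.character(seq_along(classOrder))
  for (k in seq_along(classOrder)) {
    sub <- ft[ft$label %in% classOrder[seq_len(k)], , drop = FALSE]
    mixed[k] <- if (k == 1L) 1.0 else evalSubset(sub)$report$overall
  }
  structure(list(report = full$report, mixed_curve = mixed,
                 som = full$som, features = ft, split_seed = cfg$seed,
                 train_index = which(full$train)),
            class = "ExperimentResult")
}

#' @export
print.ExperimentResult <- function(x, ...) {
  cat("End-to-end classification experiment\n")
  print(x$report)
  cat("  mixed-task curve (accuracy vs pooled classes):\n   ",
      paste(sprintf("%s:%.2f", names(x$mixed_curve), x$mixed_curve),
            collapse = "  "), "\n")
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' Persists per-class resolution, overall accuracy, the confusion matrix,
#' the mixed-task curve and the split seed.
#'
#' @param result an `"ExperimentResult"`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
writeReportJSON <- function(result, path) {
  stopifnot(inherits(result, "ExperimentResult"))
  conf <- as.data.frame.matrix(result$report$confusion)
  obj <- list(per_class_resolution = as.list(result$report$per_class),
              overall_accuracy = result$report$overall,
              confusion = conf,
              mixed_task_curve = as.list(result$mixed_curve),
              split_seed = result$split_seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
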