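#' 3-D CNN configuration
#'
#' The regressor is a compact 3-D convolutional network: a stride-`stemPool`
#' average-pooling stem, then one block per entry of `channels`
#' (3x3x3 convolution with same padding, ReLU, 2x max pooling), global
#' average pooling and a single linear output.  Loss is mean squared error,
#' optimized with Adam.  The cube side divided by `stemPool` must be
#' divisible by `2^length(channels)`.
#'
#' @param channels integer vector of feature channels per conv block.
#' @param stemPool input average-pooling factor (1 = none).
#' @param epochs training epochs per fold.
#' @param batchSize minibatch size.
#' @param learningRate Adam step size.
#' @param nAug rotated copies of each training sample per epoch (0
#'   disables augmentation); angles are redrawn at every appearance.
#' @param angleRange rotation range in degrees.
#' @param seed integer seed controlling weight init, shuffling and
#'   augmentation.
#' @return list of class `CNNConfig`.
#' @export
cnnConfig <- function(channels = c(4L, 8L, 16L), stemPool = 2L, epochs = 3L,
                      batchSize = 16L, learningRate = 1e-3, nAug = 15L,
                      angleRange = c(0, 90), seed = 1L) {
  cfg <- list(channels = as.integer(channels), stemPool = as.integer(stemPool),
              epochs = as.integer(epochs), batchSize = as.integer(batchSize),
              learningRate = learningRate, nAug = as.integer(nAug),
              angleRange = as.numeric(angleRange), seed = as.integer(seed))
  stopifnot(length(cfg$channels) >= 1L, all(cfg$channels >= 1L),
            cfg$stemPool >= 1L, cfg$epochs >= 1L, cfg$batchSize >= 1L,
            cfg$learningRate > 0, cfg$nAug >= 0L)
  class(cfg) <- "CNNConfig"
  cfg
}

cubes_to_array <- function(cubes) {
  if (is.array(cubes) && length(dim(cubes)) == 4L) return(cubes)
  if (is(cubes, "TumorCube")) cubes <- list(cubes)
  stopifnot(is.list(cubes), length(cubes) >= 1L)
  S <- dim(petData(cubes[[1]]))[1]
  arr <- array(0, dim = c(S, S, S, length(cubes)))
  for (i in seq_along(cubes)) {
    d <- petData(cubes[[i]])
    if (!identical(dim(d), c(S, S, S)))
      stop("cube shape mismatch at position ", i)
    arr[, , , i] <- d
  }
  arr
}

# near-equal fold split by seeded shuffle (sizes differ by at most 1)
assign_folds <- function(n, folds, seed) {
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(folds), length.out = n)
  fold
}

#' Train the CytAct regressor with k-fold cross-validation
#'
#' Samples are partitioned into `folds` near-equal folds by a seeded
#' shuffle.  For every fold a fresh network is trained on the remaining
#' samples only -- augmentation copies are generated from training samples
#' exclusively, so no augmented view of a validation sample ever enters
#' training -- and predicts its held-out fold.  Pooling those out-of-fold
#' predictions gives one prediction per sample and the pooled Spearman
#' correlation with the targets.
#'
#' @param cubes list of [TumorCube-class] (or a 4-D array, last axis =
#'   samples).
#' @param targets numeric CytAct target per cube.
#' @param config a [cnnConfig()].
#' @param folds number of CV folds (default 10).
#' @return A [CytActCVResult-class].
#' @export
trainCytActCNN <- function(cubes, targets, config = cnnConfig(), folds = 10L) {
  stopifnot(inherits(config, "CNNConfig"))
  arr <- cubes_to_array(cubes)
  n <- dim(arr)[4]
  folds <- as.integer(folds)
  if (length(targets) != n) stop("one target per cube required")
  if (!all(is.finite(targets))) stop("targets must be finite")
  if (folds < 2L) stop("folds must be >= 2")
  if (n < folds) stop("need at least as many samples as folds")
  fold <- assign_folds(n, folds, config$seed)
  pred <- numeric(n)
  models <- vector("list", folds)
  eloss <- matrix(NA_real_, nrow = config$epochs, ncol = folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f) - 1L
    va <- which(fold == f) - 1L
    fit <- .cpp_cnn_train(arr, as.numeric(targets), tr, va,
                          config$channels, config$stemPool, config$epochs,
                          config$batchSize, config$learningRate, config$nAug,
                          config$angleRange[1], config$angleRange[2],
                          derive_seed(config$seed, f))
    pred[va + 1L] <- fit$val_pred
    eloss[, f] <- fit$epoch_loss
    models[[f]] <- new("CytActCNN", weights = fit$weights,
                       config = unclass(config))
  }
  rho <- if (sd(targets) == 0 || sd(pred) == 0) NA_real_
         else cor(pred, targets, method = "spearman")
  new("CytActCVResult",
      predictions = data.frame(sample = seq_len(n), fold = fold,
                               observed = as.numeric(targets),
                               predicted = pred),
      models = models, rho = rho, epochLoss = eloss, folds = fold)
}

#' Predict CytAct for new cubes
#'
#' Inference is deterministic given fixed weights.  When given a
#' [CytActCVResult-class] (or a list of models) the ensemble mean of the
#' fold models is returned.
#'
#' @param model a [CytActCNN-class], list of them, or a
#'   [CytActCVResult-class].
#' @param cubes list of [TumorCube-class] or 4-D array.
#' @return numeric vector of predicted CytAct.
#' @export
predictCytAct <- function(model, cubes) {
  arr <- cubes_to_array(cubes)
  if (is(model, "CytActCVResult")) model <- model@models
  if (is(model, "CytActCNN")) model <- list(model)
  stopifnot(length(model) >= 1L)
  preds <- vapply(model, function(m) {
    stopifnot(is(m, "CytActCNN"))
    cfg <- m@config
    side <- dim(arr)[1] / cfg$stemPool
    if (side %% 2^length(cfg$channels) != 0 || side != round(side))
      stop("cube shape does not match model configuration")
    .cpp_cnn_predict(m@weights, arr, cfg$channels, cfg$stemPool)
  }, numeric(dim(arr)[4]))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' Save / load a trained model directory
#'
#' The directory holds `config.json` plus one `fold_<k>.rds` weight
#' checkpoint per model.
#'
#' @param result a [CytActCVResult-class].
#' @param dir checkpoint directory (created if needed).
#' @return `dir` (save) or a list of [CytActCNN-class] (load).
#' @export
saveCNNModels <- function(result, dir) {
  stopifnot(is(result, "CytActCVResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result@models[[1]]@config
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  for (k in seq_along(result@models))
    saveRDS(result@models[[k]]@weights,
            file.path(dir, sprintf("fold_%02d.rds", k)))
  write.csv(result@predictions, file.path(dir, "oof_predictions.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname saveCNNModels
#' @export
loadCNNModels <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^fold_\\d+\\.rds$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no checkpoints found in ", dir)
  lapply(files, function(f) new("CytActCNN", weights = readRDS(f),
                                config = as.list(cfg)))
}
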