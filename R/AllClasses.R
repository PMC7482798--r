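#' PETVolume: a 3-D PET uptake volume
#'
#' Holds a 3-D array of non-negative uptake values together with its voxel
#' spacing in mm and optional acquisition metadata.  Array axes follow the
#' fixed (z, y, x) convention; masks and volumes derived from one another
#' are always co-registered by construction.
#'
#' @slot data 3-D numeric array of uptake values (SUV, Bq/mL, or arbitrary).
#' @slot spacing numeric(3), voxel spacing in mm along (z, y, x); all > 0.
#' @slot units one of `"SUV"`, `"Bq/mL"`, `"arbitrary"`.
#' @slot meta named list; recognised entries are `injected_dose_Bq`,
#'   `body_weight_g` and `decay_corrected`.
#' @exportClass PETVolume
setClass("PETVolume",
  representation(data = "array", spacing = "numeric", units = "character",
                 meta = "list"),
  prototype(units = "arbitrary", meta = list()))

setValidity("PETVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3-D array")
  if (!all(is.finite(d))) return("voxel values must be finite")
  if (any(d < 0)) return("voxel values must be non-negative")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive values (mm)")
  if (!object@units %in% c("SUV", "Bq/mL", "arbitrary"))
    return("units must be one of 'SUV', 'Bq/mL', 'arbitrary'")
  TRUE
})

#' SegmentationMask: a boolean lesion mask aligned to a PETVolume
#'
#' @slot data 3-D logical array, same shape as the parent volume.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @exportClass SegmentationMask
setClass("SegmentationMask",
  representation(data = "array", spacing = "numeric"))

setValidity("SegmentationMask", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (!is.logical(object@data)) return("mask data must be logical")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 strictly positive values (mm)")
  TRUE
})

#' TumorCube: fixed-shape normalized network input patch
#'
#' @slot data cubic 3-D numeric array.
#' @slot normMode `"max"` (divided by cube maximum) or `"none"`.
#' @slot spacing voxel spacing in mm (isotropic).
#' @slot patientId,lesionId source identifiers.
#' @exportClass TumorCube
setClass("TumorCube",
  representation(data = "array", normMode = "character", spacing = "numeric",
                 patientId = "character", lesionId = "character"),
  prototype(normMode = "max", spacing = 2, patientId = NA_character_,
            lesionId = NA_character_))

setValidity("TumorCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || length(unique(d)) != 1L)
    return("cube data must be a cubic 3-D array")
  if (!all(is.finite(object@data))) return("cube values must be finite")
  if (!object@normMode %in% c("max", "none"))
    return("normMode must be 'max' or 'none'")
  if (object@normMode == "max" && max(object@data) > 0 &&
      abs(max(object@data) - 1) > 1e-9)
    return("max-normalized cube must have maximum 1")
  TRUE
})

#' ExpressionMatrix: genes x samples expression table
#'
#' @slot values numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = unique sample ids).
#' @slot logScale TRUE if values are log2-scale; raw values must be >= 0
#'   and are transformed log2(x + 1) before scoring.
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  representation(values = "matrix", logScale = "logical"),
  prototype(logScale = FALSE))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have gene rownames and sample colnames")
  if (anyDuplicated(toupper(rownames(v))))
    return("duplicate gene symbols after canonicalization")
  if (anyDuplicated(colnames(v))) return("duplicate sample ids")
  if (!all(is.finite(v))) return("expression values must be finite")
  if (!isTRUE(object@logScale) && any(v < 0))
    return("raw-scale expression values must be non-negative")
  TRUE
})

#' CytActCNN: a trained 3-D convolutional CytAct regressor
#'
#' @slot weights list of per-layer weight matrices as returned by the
#'   C++ trainer.
#' @slot config the `cnnConfig()` the model was trained with.
#' @exportClass CytActCNN
setClass("CytActCNN",
  representation(weights = "list", config = "list"))

#' CytActCVResult: pooled out-of-fold cross-validation result
#'
#' @slot predictions data.frame with one row per training sample: `sample`,
#'   `fold`, `observed`, `predicted` (each sample predicted exactly once,
#'   by the model whose validation fold it belonged to).
#' @slot models list of [CytActCNN-class] fold models.
#' @slot rho pooled Spearman correlation of predicted vs observed CytAct.
#' @slot epochLoss matrix (epochs x folds) of mean training MSE.
#' @slot folds fold assignment integer vector.
#' @exportClass CytActCVResult
setClass("CytActCVResult",
  representation(predictions = "data.frame", models = "list", rho = "numeric",
                 epochLoss = "matrix", folds = "integer"))

setValidity("CytActCVResult", function(object) {
  p <- object@predictions
  need <- c("sample", "fold", "observed", "predicted")
  if (!all(need %in% names(p))) return("predictions lacks required columns")
  if (anyDuplicated(p$sample))
    return("each sample must have exactly one out-of-fold prediction")
  TRUE
})

setMethod("show", "PETVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("PETVolume %dx%dx%d voxels, spacing (%g, %g, %g) mm, units %s\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], object@units))
  cat(sprintf("  uptake range [%.4g, %.4g]\n", min(object@data),
              max(object@data)))
})

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("SegmentationMask %dx%dx%d voxels, %d foreground (%.3g mL)\n",
              d[1], d[2], d[3], sum(object@data),
              sum(object@data) * prod(object@spacing) / 1000))
})

setMethod("show", "TumorCube", function(object) {
  cat(sprintf("TumorCube %d^3 voxels at %g mm, norm '%s' (patient %s, lesion %s)\n",
              dim(object@data)[1], object@spacing[1], object@normMode,
              object@patientId, object@lesionId))
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
              nrow(object@values), ncol(object@values),
              if (object@logScale) "log2" else "raw"))
})

setMethod("show", "CytActCVResult", function(object) {
  cat(sprintf("CytActCVResult: %d samples, %d folds, pooled Spearman rho %.3f\n",
              nrow(object@predictions), length(object@models), object@rho))
})

#' Construct a PETVolume
#'
#' @param data 3-D numeric array (axes z, y, x).
#' @param spacing voxel spacing in mm; scalar spacing is recycled.
#' @param units intensity units.
#' @param meta named list of acquisition metadata.
#' @return A [PETVolume-class] object.
#' @export
PETVolume <- function(data, spacing = c(1, 1, 1), units = "arbitrary",
                      meta = list()) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("PETVolume", data = data, spacing = as.numeric(spacing),
      units = units, meta = meta)
}

#' Construct an ExpressionMatrix
#'
#' @param values genes x samples numeric matrix with dimnames.
#' @param logScale whether values are already log2-scale.
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values, logScale = FALSE) {
  new("ExpressionMatrix", values = as.matrix(values),
      logScale = isTRUE(logScale))
}

#' @name accessors
#' @title Accessors for imaging and expression containers
#' @param x an immunoPET object.
#' @return `petData` the voxel array; `voxelSpacing` the mm spacing triple;
#'   `exprValues` the expression matrix; `oofPredictions` the pooled
#'   out-of-fold prediction table; `cvRho` the pooled Spearman rho.
NULL

#' @rdname accessors
#' @export
setGeneric("petData", function(x) standardGeneric("petData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("oofPredictions", function(x) standardGeneric("oofPredictions"))
#' @rdname accessors
#' @export
setGeneric("cvRho", function(x) standardGeneric("cvRho"))

#' @rdname accessors
setMethod("petData", "PETVolume", function(x) x@data)
#' @rdname accessors
setMethod("petData", "SegmentationMask", function(x) x@data)
#' @rdname accessors
setMethod("petData", "TumorCube", function(x) x@data)
#' @rdname accessors
setMethod("voxelSpacing", "PETVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "SegmentationMask", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "TumorCube", function(x) x@spacing)
#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)
#' @rdname accessors
setMethod("oofPredictions", "CytActCVResult", function(x) x@predictions)
#' @rdname accessors
setMethod("cvRho", "CytActCVResult", function(x) x@rho)
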