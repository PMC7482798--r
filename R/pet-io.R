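#' Read a PET volume from NIfTI
#'
#' Reads a 3-D NIfTI image into a [PETVolume-class], preserving voxel values
#' and spacing.  If a JSON sidecar with the same stem exists (e.g.
#' `vol.json` next to `vol.nii.gz`) it is read into `meta`; a sidecar entry
#' `units` overrides the default `"arbitrary"`.
#'
#' @param path path to a `.nii` / `.nii.gz` file with 3 spatial dimensions.
#' @return A [PETVolume-class].
#' @export
readPETVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3-D volume, got ", length(d), " dimensions")
  sp <- RNifti::pixdim(img)[seq_len(3L)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in NIfTI header")
  meta <- list()
  units <- "arbitrary"
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$units)) {
      units <- meta$units
      meta$units <- NULL
    }
  }
  PETVolume(array(as.numeric(img), dim = d), spacing = sp, units = units,
            meta = as.list(meta))
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a PET volume to NIfTI
#'
#' Writes voxel values and spacing; metadata (including the units tag) goes
#' to a JSON sidecar so that `readPETVolume(writePETVolume(v))` is
#' value-identical.
#'
#' @param vol a [PETVolume-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writePETVolume <- function(vol, path) {
  stopifnot(is(vol, "PETVolume"))
  a <- vol@data
  attr(a, "pixdim") <- vol@spacing
  img <- RNifti::asNifti(a, datatype = "double")
  RNifti::writeNifti(img, path)
  meta <- vol@meta
  meta$units <- vol@units
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write a segmentation mask (NIfTI, 0/1 voxels)
#'
#' @param path NIfTI path.
#' @return [SegmentationMask-class].
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3-D volume, got ", length(d), " dimensions")
  sp <- RNifti::pixdim(img)[seq_len(3L)]
  new("SegmentationMask", data = array(as.numeric(img) > 0.5, dim = d),
      spacing = sp)
}

#' @rdname readMask
#' @param mask a [SegmentationMask-class].
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "SegmentationMask"))
  a <- array(as.integer(mask@data), dim = dim(mask@data))
  attr(a, "pixdim") <- mask@spacing
  img <- RNifti::asNifti(a, datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert raw activity concentration to SUV
#'
#' Standardized uptake value: voxel activity (Bq/mL) divided by injected
#' dose per body weight, `SUV = v * body_weight_g / injected_dose_Bq`
#' (1 g of tissue taken as 1 mL).  The conversion is linear in the voxel
#' values.
#'
#' @param vol a [PETVolume-class] in Bq/mL whose `meta` carries
#'   `injected_dose_Bq` and `body_weight_g` (both > 0).
#' @return A [PETVolume-class] flagged as SUV.
#' @export
suvNormalize <- function(vol) {
  stopifnot(is(vol, "PETVolume"))
  dose <- vol@meta$injected_dose_Bq
  wt <- vol@meta$body_weight_g
  if (is.null(dose) || !is.finite(dose) || dose <= 0)
    stop("meta$injected_dose_Bq must be a positive number")
  if (is.null(wt) || !is.finite(wt) || wt <= 0)
    stop("meta$body_weight_g must be a positive number")
  if (identical(vol@units, "SUV"))
    warning("volume already flagged as SUV; converting anyway")
  PETVolume(vol@data * wt / dose, spacing = vol@spacing, units = "SUV",
            meta = vol@meta)
}

#' Resample a volume to isotropic voxels
#'
#' Trilinear interpolation onto an isotropic grid of `target_mm` spacing
#' with pixel-center alignment and edge clamping; a constant field is
#' preserved exactly and resampling an already-isotropic volume to its own
#' spacing is the identity.  Masks are resampled nearest-neighbour.
#'
#' @param vol a [PETVolume-class] or [SegmentationMask-class], at least 2
#'   voxels along every axis.
#' @param target_mm target isotropic spacing (> 0) in mm.
#' @return Resampled object of the same class.
#' @export
resampleIsotropic <- function(vol, target_mm) {
  stopifnot(target_mm > 0)
  if (is(vol, "SegmentationMask")) {
    d <- dim(vol@data)
    if (any(d < 2L)) stop("degenerate input shape: need >= 2 voxels per axis")
    # nearest-neighbour index mapping per axis (monotone, label-preserving)
    src <- lapply(seq_len(3L), function(k) {
      n_out <- max(1L, round(d[k] * vol@spacing[k] / target_mm))
      i <- round((seq_len(n_out) - 0.5) * target_mm / vol@spacing[k] + 0.5)
      pmin(pmax(i, 1L), d[k])
    })
    return(new("SegmentationMask",
               data = vol@data[src[[1]], src[[2]], src[[3]], drop = FALSE],
               spacing = rep(target_mm, 3)))
  }
  stopifnot(is(vol, "PETVolume"))
  if (any(dim(vol@data) < 2L))
    stop("degenerate input shape: need >= 2 voxels per axis")
  out <- .cpp_resample_trilinear(vol@data, vol@spacing, target_mm)
  PETVolume(pmax(out, 0), spacing = rep(target_mm, 3), units = vol@units,
            meta = vol@meta)
}
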