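#' Read a diffusion-weighted dataset (NIfTI + FSL gradient tables)
#'
#' Loads a 4D NIfTI volume together with FSL-dialect `bval`/`bvec` tables and
#' returns a `dwi_dataset`. Measurements with b below 50 s/mm^2 are flagged as
#' b0 (unweighted) images; the threshold absorbs header rounding.
#'
#' @param nifti_path Path to the 4D volume (x, y, z, measurement).
#' @param bval_path Whitespace-separated b-values, one row.
#' @param bvec_path 3 x N whitespace-separated unit direction table.
#' @return A `dwi_dataset`: `volume` (4D array), `bvals` (s/mm^2), `bvecs`
#'   (N x 3), `voxel_size` (mm), `is_b0` (logical per measurement).
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(nifti_path)
  vol <- as.array(img)
  vol <- array(as.numeric(vol), dim(vol)) # plain array, no NIfTI attributes
  if (length(dim(vol)) == 3) dim(vol) <- c(dim(vol), 1L)
  if (length(dim(vol)) != 4) stop("format error: expected a 4D volume")
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_raw <- as.matrix(read.table(bvec_path))
  if (nrow(bvec_raw) != 3)
    stop("format error: bvec table must have exactly 3 rows")
  bvecs <- t(unname(bvec_raw))
  vs <- RNifti::pixdim(img)[seq_len(3)]
  dwi_dataset(vol, bvals, bvecs, voxel_size = vs)
}

#' Construct a diffusion-weighted dataset
#'
#' @param volume 4D array (x, y, z, measurement).
#' @param bvals b-value per measurement, s/mm^2.
#' @param bvecs N x 3 direction matrix; non-b0 rows must have unit norm
#'   within 1e-3.
#' @param voxel_size Voxel edge lengths, mm.
#' @param b0_threshold b-values below this count as unweighted.
#' @return A `dwi_dataset`.
#' @export
dwi_dataset <- function(volume, bvals, bvecs, voxel_size = c(0.125, 0.125, 0.125),
                        b0_threshold = B0_THRESHOLD) {
  if (length(dim(volume)) != 4) stop("format error: volume must be 4D")
  n <- dim(volume)[4]
  if (length(bvals) != n || nrow(bvecs) != n)
    stop("format error: measurement axis length must match bvals and bvecs")
  is_b0 <- bvals < b0_threshold
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- !is_b0 & abs(nrm - 1) > 1e-3
  if (any(bad))
    stop(sprintf("format error: %d non-b0 bvec(s) not unit norm", sum(bad)))
  structure(list(volume = volume, bvals = as.numeric(bvals),
                 bvecs = unname(bvecs), voxel_size = voxel_size,
                 is_b0 = is_b0),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("dwi_dataset: %dx%dx%d voxels, %d measurements (%d b0), shells: %s\n",
              d[1], d[2], d[3], d[4], sum(x$is_b0),
              paste(sort(unique(round(x$bvals[!x$is_b0]))), collapse = ", ")))
  invisible(x)
}

#' Write a diffusion-weighted dataset to NIfTI + bval/bvec
#'
#' @param dataset A `dwi_dataset`.
#' @param nifti_path,bval_path,bvec_path Output paths.
#' @export
write_dwi <- function(dataset, nifti_path, bval_path, bvec_path) {
  img <- RNifti::asNifti(dataset$volume)
  RNifti::pixdim(img) <- c(dataset$voxel_size, 1)
  RNifti::writeNifti(img, nifti_path)
  writeLines(paste(sprintf("%.10g", dataset$bvals), collapse = " "),
             bval_path)
  write.table(t(dataset$bvecs), bvec_path, row.names = FALSE,
              col.names = FALSE)
  invisible(c(nifti_path, bval_path, bvec_path))
}

#' Read an axon/myelin label mask
#'
#' Reads an integer-valued PNG or TIFF class image and maps its values onto
#' the three semantic classes background / axon / myelin.
#'
#' @param image_path PNG or TIFF path (8- or 16-bit integer classes).
#' @param class_map Named integer vector with entries `background`, `axon`,
#'   `myelin` giving the stored label codes.
#' @param pixel_size_um Pixel edge length, micrometres.
#' @param preparation `"epon"` or `"cryo"` (selects downstream filter rules).
#' @param strict If `TRUE` (default) unknown label values are a format error;
#'   otherwise they are mapped to background with a warning.
#' @return A `label_mask`.
#' @export
read_label_mask <- function(image_path,
                            class_map = c(background = 0L, axon = 1L, myelin = 2L),
                            pixel_size_um, preparation = "epon",
                            strict = TRUE) {
  ext <- tolower(tools::file_ext(image_path))
  raw <- switch(ext,
    png = png::readPNG(image_path),
    tif = ,
    tiff = tiff::readTIFF(image_path),
    stop("format error: unsupported mask format ", ext))
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  ## readPNG/readTIFF scale integer samples to [0,1]; recover the stored
  ## codes at whichever depth the file used (float TIFFs are rejected)
  v8 <- raw * 255
  v16 <- raw * 65535
  ints <- if (max(abs(v8 - round(v8))) < 1e-6) round(v8)
    else if (max(abs(v16 - round(v16))) < 1e-6) round(v16)
    else stop("format error: mask image is not integer-valued")
  label_mask(matrix(as.integer(ints), nrow(raw), ncol(raw)),
             pixel_size = pixel_size_um, preparation = preparation,
             class_map = class_map, strict = strict)
}

#' Construct an axon/myelin label mask
#'
#' @param classes Integer matrix of raw label codes.
#' @param pixel_size Pixel edge length, micrometres.
#' @param preparation `"epon"` or `"cryo"`.
#' @param class_map Named codes for `background`, `axon`, `myelin`.
#' @param strict Unknown codes are an error (`TRUE`) or logged and mapped to
#'   background (`FALSE`).
#' @return A `label_mask` whose `classes` matrix is recoded to 0 = background,
#'   1 = axon, 2 = myelin.
#' @export
label_mask <- function(classes, pixel_size, preparation = "epon",
                       class_map = c(background = 0L, axon = 1L, myelin = 2L),
                       strict = TRUE) {
  stopifnot(is.matrix(classes))
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive")
  preparation <- match.arg(preparation, c("epon", "cryo"))
  needed <- c("background", "axon", "myelin")
  if (!all(needed %in% names(class_map)))
    stop("class_map must name background, axon and myelin codes")
  known <- classes %in% class_map
  if (!all(known)) {
    if (strict)
      stop(sprintf("format error: %d pixel(s) with unknown label value(s) %s",
                   sum(!known),
                   paste(unique(classes[!known]), collapse = ", ")))
    warning(sprintf("mapping %d unknown-label pixel(s) to background",
                    sum(!known)))
  }
  out <- matrix(0L, nrow(classes), ncol(classes))
  out[classes == class_map[["axon"]]] <- 1L
  out[classes == class_map[["myelin"]]] <- 2L
  structure(list(classes = out, pixel_size = pixel_size,
                 preparation = preparation),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask: %dx%d px at %g um/px (%s), %.1f%% axon, %.1f%% myelin\n",
              nrow(x$classes), ncol(x$classes), x$pixel_size, x$preparation,
              100 * mean(x$classes == 1L), 100 * mean(x$classes == 2L)))
  invisible(x)
}

#' Write a label mask as an 8-bit PNG or TIFF
#'
#' Codes are written as 0 (background), 1 (axon), 2 (myelin); the round trip
#' through [read_label_mask()] is bit-exact.
#'
#' @param mask A `label_mask`.
#' @param image_path Output path (`.png`, `.tif`/`.tiff`).
#' @export
write_label_mask <- function(mask, image_path) {
  img <- mask$classes / 255
  ext <- tolower(tools::file_ext(image_path))
  switch(ext,
    png = png::writePNG(img, image_path),
    tif = ,
    tiff = tiff::writeTIFF(img, image_path, bits.per.sample = 8),
    stop("format error: unsupported mask format ", ext))
  invisible(image_path)
}
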