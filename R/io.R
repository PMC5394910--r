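# Grayscale image readers/writers. Supported formats: PNG and TIFF (8/16
# bit, via the png and tiff packages) and NIfTI-1 (via RNifti). Inputs are
# normalized to [0,1] on load; the original intensity range is recorded so
# results can be written back at source scale.

.LUMA <- c(0.299, 0.587, 0.114)  # Rec. 601 luminance weights

.detectFormat <- function(path) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  switch(ext,
         png = "PNG",
         tif = , tiff = "TIFF",
         nii = "NIfTI",
         stop(sprintf("unsupported image format '%s' (supported: png, tif/tiff, nii[.gz])",
                      ext), call. = FALSE))
}

# collapse a H x W x C array to a single-channel luminance matrix
.toGray <- function(a) {
  d <- dim(a)
  if (length(d) == 2L) return(matrix(as.vector(a), d[1], d[2]))
  g <- if (d[3] >= 3L)                                 # RGB(A)
    .LUMA[1] * a[, , 1L] + .LUMA[2] * a[, , 2L] + .LUMA[3] * a[, , 3L]
  else a[, , 1L]                                       # gray (+ alpha)
  matrix(as.vector(g), d[1], d[2])
}

#' Read a grayscale image from PNG, TIFF or NIfTI
#'
#' Returns a single-channel image in `[0,1]`. Multi-channel PNG/TIFF inputs
#' are collapsed by Rec. 601 luminance (0.299 R + 0.587 G + 0.114 B, alpha
#' ignored). 3-D NIfTI volumes require an explicit `slice` index; NIfTI
#' intensities are min-max rescaled and the original range recorded in the
#' result so [writeGrayImage()] can invert the rescaling.
#'
#' @param path Path to the image file.
#' @param slice Slice index for 3-D volumes (third dimension).
#' @return A [LoadedImage-class]; the matrix is available via [pixels()].
#' @export
readGrayImage <- function(path, slice = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  fmt <- .detectFormat(path)
  if (fmt == "PNG" || fmt == "TIFF") {
    a <- if (fmt == "PNG") png::readPNG(path) else tiff::readTIFF(path)
    px <- .toGray(a)
    res <- new("LoadedImage", pixels = px, sourceDtype = "unorm",
               sourcePath = path, format = fmt, sourceRange = c(0, 1))
  } else {
    v <- RNifti::readNifti(path)
    a <- as.array(v)
    a <- array(as.vector(a), dim(a))  # strip the niftiImage class
    if (length(dim(a)) == 3L) {
      if (is.null(slice))
        stop("3-D NIfTI volume: pass an explicit 'slice' index", call. = FALSE)
      if (slice < 1L || slice > dim(a)[3])
        stop(sprintf("slice %d out of range 1..%d", slice, dim(a)[3]),
             call. = FALSE)
      a <- a[, , slice]
    } else if (length(dim(a)) != 2L) {
      stop("only 2-D images or 3-D volumes are supported", call. = FALSE)
    }
    rng <- range(a)
    px <- if (rng[2] > rng[1]) (a - rng[1]) / (rng[2] - rng[1])
          else matrix(0, nrow(a), ncol(a))
    res <- new("LoadedImage", pixels = px, sourceDtype = "float",
               sourcePath = path, format = fmt, sourceRange = rng)
  }
  if (!all(is.finite(res@pixels)))
    stop(sprintf("image '%s' contains non-finite values", path), call. = FALSE)
  res
}

#' Write a grayscale image to PNG, TIFF or NIfTI
#'
#' The format is chosen by extension. Values outside `[0,1]` are clipped
#' with a warning. PNG writes 8-bit; TIFF writes at the requested bit
#' depth; NIfTI writes 32-bit float, optionally mapped back to a source
#' intensity range.
#'
#' @param image Matrix in `[0,1]`, or a [LoadedImage-class].
#' @param path Output path (`.png`, `.tif`/`.tiff`, `.nii`).
#' @param dtype `"uint8"`, `"uint16"` (TIFF only) or `"float32"` (TIFF and
#'   NIfTI).
#' @param sourceRange Optional `(min, max)`; NIfTI output is mapped back to
#'   this range (defaults to the range recorded in a `LoadedImage`).
#' @return Invisibly, `path`.
#' @export
writeGrayImage <- function(image, path, dtype = c("uint8", "uint16", "float32"),
                           sourceRange = NULL) {
  if (is(image, "LoadedImage")) {
    if (is.null(sourceRange)) sourceRange <- image@sourceRange
    image <- image@pixels
  }
  .assertImage(image)
  dtype <- match.arg(dtype)
  fmt <- .detectFormat(path)
  if (min(image) < 0 || max(image) > 1) {
    warning("intensities outside [0,1] clipped on write")
    image <- .clamp01(image)
  }
  if (fmt == "PNG") {
    png::writePNG(image, path)
  } else if (fmt == "TIFF") {
    bits <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
    tiff::writeTIFF(image, path, bits.per.sample = bits)
  } else {
    out <- image
    if (!is.null(sourceRange) && sourceRange[2] > sourceRange[1])
      out <- image * (sourceRange[2] - sourceRange[1]) + sourceRange[1]
    RNifti::writeNifti(RNifti::asNifti(out), path, datatype = "float")
  }
  invisible(path)
}
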