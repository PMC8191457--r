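#' In-memory 3D image volume
#'
#' Container for a 3D scalar grid (typically CT attenuation in Hounsfield
#' units) together with its voxel spacing and physical origin. All analysis
#' in this package operates on voxel index space of a shared grid; spacing
#' and origin are carried so that volumes and masks can be checked for grid
#' compatibility and written back to NIfTI.
#'
#' @param data numeric 3D array. `NA` marks missing voxels (outside the
#'   analysis window or excluded tissue).
#' @param spacing numeric length-3, voxel size in mm along (x, y, z); all
#'   entries must be finite and positive.
#' @param origin numeric length-3, physical position (mm) of the center of
#'   voxel (1, 1, 1).
#' @return An object of class `image_volume` with elements `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- image_volume(array(0, c(10, 10, 10)), spacing = c(1, 1, 3))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array (non-3D array)")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 finite positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Binary region-of-interest mask on an image grid
#'
#' A mask shares the grid (shape, spacing, origin) of its companion image.
#' Any nonzero/`TRUE` voxel is foreground. An empty mask is valid at the I/O
#' level; downstream operations validate minimum sizes.
#'
#' @param data logical or numeric 3D array; nonzero means foreground.
#' @param spacing,origin grid geometry, as in [image_volume()].
#' @param reference optional `image_volume`; when given, grid equality with
#'   the reference is enforced (tolerance 1e-3 mm).
#' @return An object of class `roi_mask` with a logical `data` array.
#' @export
roi_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     reference = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array (non-3D array)")
  storage <- array(as.logical(data != 0 & !is.na(data)), dim(data))
  m <- structure(list(data = storage, spacing = as.numeric(spacing),
                      origin = as.numeric(origin)),
                 class = "roi_mask")
  if (!is.null(reference)) check_same_grid(m, reference)
  m
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume: %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  v <- x$data[!is.na(x$data)]
  if (length(v))
    cat(sprintf("  values: [%.2f, %.2f], %d missing\n", min(v), max(v),
                sum(is.na(x$data))))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %s voxels, %d foreground\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Check that two volumes/masks share a grid
#'
#' @param a,b `image_volume` or `roi_mask` objects.
#' @param tol tolerance in mm for spacing/origin agreement.
#' @return `TRUE` invisibly; signals an error on mismatch.
#' @export
check_same_grid <- function(a, b, tol = 1e-3) {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("grid mismatch: shapes %s vs %s",
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")))
  if (max(abs(a$spacing - b$spacing)) > tol)
    stop("grid mismatch: spacing differs beyond tolerance")
  if (max(abs(a$origin - b$origin)) > tol)
    stop("grid mismatch: origin differs beyond tolerance")
  invisible(TRUE)
}

# Sentinel used on disk for NA voxels; recorded in a sidecar so that reads
# can restore missingness without guessing.
.na_sentinel <- -999999

sidecar_path <- function(path) paste0(path, ".meta.txt")

#' Read a 3D volume from a NIfTI file
#'
#' Axis order is fixed as (x, y, z); spacing is taken from the header and the
#' origin from the qform/sform translation. If a sidecar metadata file
#' (written by [write_volume()]) records a missing-value sentinel, voxels
#' equal to the sentinel are restored to `NA`.
#'
#' @param path path to a readable NIfTI-1 file containing a 3D array.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop(sprintf("non-3D array in %s (%d dims)",
                                    path, length(d)))
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-finite or non-positive spacing in header")
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  data <- array(as.numeric(img), d)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- readLines(sc, warn = FALSE)
    sent <- sub("^sentinel=", "", grep("^sentinel=", meta, value = TRUE))
    if (length(sent) == 1L) data[data == as.numeric(sent)] <- NA_real_
  }
  image_volume(data, spacing = spacing, origin = origin)
}

#' Write a volume (or parametric map) to a NIfTI file
#'
#' Missing voxels (`NA`) are stored as a sentinel value recorded in a plain
#' text sidecar file `<path>.meta.txt`, so a round trip through
#' [read_volume()] restores them.
#'
#' @param vol an [image_volume()] or [roi_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "roi_mask"))
    vol <- image_volume(array(as.numeric(vol$data), dim(vol$data)),
                        vol$spacing, vol$origin)
  if (!inherits(vol, "image_volume")) stop("'vol' must be an image_volume")
  data <- vol$data
  has_na <- anyNA(data)
  if (has_na) data[is.na(data)] <- .na_sentinel
  if (any(!is.finite(data))) stop("non-finite values cannot be written")
  img <- RNifti::asNifti(data)
  m <- diag(4)
  diag(m)[1:3] <- vol$spacing
  m[1:3, 4] <- vol$origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  RNifti::writeNifti(img, path)
  sc <- sidecar_path(path)
  if (has_na) {
    writeLines(c(sprintf("sentinel=%s", format(.na_sentinel, scientific = FALSE)),
                 "meaning=missing (out-of-ROI or out-of-window) voxel"), sc)
  } else if (file.exists(sc)) {
    unlink(sc)
  }
  invisible(path)
}

#' Read a binary mask and verify it against a reference grid
#'
#' @param path NIfTI file with values in `{0, nonzero}`.
#' @param reference an [image_volume()] defining the expected grid; a grid
#'   mismatch signals mis-registered inputs and is an error.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path, reference = NULL) {
  vol <- read_volume(path)
  m <- roi_mask(vol$data, vol$spacing, vol$origin)
  if (!is.null(reference)) check_same_grid(m, reference)
  m
}
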