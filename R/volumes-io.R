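#' @useDynLib mmdnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor setNames aggregate
#' @importFrom utils read.delim write.table
NULL

#' Volumetric containers
#'
#' Three light S3 containers hold everything the pipeline reads from disk:
#' `intensity_volume` (real-valued 3D grid, e.g. a brainstem-normalized
#' FDG-PET image), `label_volume` (non-negative integer 3D grid of ROI or
#' patch labels, 0 = background) and `displacement_field` (one 3-vector of
#' millimetre displacements per voxel, stored as a 4D array whose fourth
#' axis has length 3). Displacement fields use the pull-back convention:
#' subject voxel centre + vector = template coordinate.
#'
#' Physical coordinates are `(index - 1) * spacing` (0-based voxel
#' indexing); the optional `header` is an opaque token carried through I/O
#' untouched.
#'
#' @param data numeric array; 3D for volumes, 4D (x, y, z, component) with
#'   three components for fields.
#' @param spacing numeric length-3 vector of positive voxel edge lengths
#'   in millimetres.
#' @param header opaque header token (e.g. a NIfTI header) passed through
#'   on save; may be `NULL`.
#' @return An object of the corresponding class with elements `data`,
#'   `spacing` and `header`.
#' @examples
#' v <- intensity_volume(array(rnorm(8), c(2, 2, 2)))
#' lab <- label_volume(array(0:7, c(2, 2, 2)))
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1), header = NULL) {
  check_grid(data, spacing, n_dim = 3)
  if (!all(is.finite(data))) stop("intensity volume contains non-finite values")
  structure(list(data = data, spacing = as.numeric(spacing), header = header),
            class = c("intensity_volume", "brain_volume"))
}

#' @rdname intensity_volume
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), header = NULL) {
  check_grid(data, spacing, n_dim = 3)
  if (!all(is.finite(data))) stop("label volume contains non-finite values")
  if (any(data < 0) || max(abs(data - round(data))) > 0)
    stop("label volume must hold non-negative integers (0 = background)")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = as.numeric(spacing), header = header),
            class = c("label_volume", "brain_volume"))
}

#' @rdname intensity_volume
#' @export
displacement_field <- function(data, spacing = c(1, 1, 1), header = NULL) {
  check_grid(data, spacing, n_dim = 4)
  if (dim(data)[4] != 3L)
    stop("displacement field must have 3 components on the 4th axis, got ",
         dim(data)[4])
  if (!all(is.finite(data))) stop("displacement field contains non-finite values")
  structure(list(data = data, spacing = as.numeric(spacing), header = header),
            class = c("displacement_field", "brain_volume"))
}

check_grid <- function(data, spacing, n_dim) {
  if (!is.array(data) || length(dim(data)) != n_dim)
    stop("expected a ", n_dim, "D array, got dimensions (",
         paste(dim(data), collapse = ", "), ")")
  if (any(dim(data)[1:3] < 1)) stop("all grid dimensions must be positive")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm per voxel)")
  invisible(TRUE)
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", class(x)[1],
              paste(dim(x$data)[1:3], collapse = "x"),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

grid_shape <- function(vol) dim(vol$data)[1:3]

#' Load a volume from a NIfTI-1 file
#'
#' Reads `.nii`/`.nii.gz` through RNifti and wraps the result in the
#' container matching `kind`. Voxel spacing is taken from the header
#' `pixdim`; the full NIfTI header is retained as the opaque `header`
#' token so geometry metadata survives a save/load round trip.
#'
#' @param path path to an existing NIfTI-1 file.
#' @param kind one of `"intensity"`, `"label"` or `"field"`. Labels must
#'   be integer-valued and non-negative; fields must be 4D with three
#'   components.
#' @return An [intensity_volume()], [label_volume()] or
#'   [displacement_field()].
#' @seealso [save_volume()]
#' @export
load_volume <- function(path, kind = c("intensity", "label", "field")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  hdr <- RNifti::niftiHeader(img)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (kind == "field") {
    if (length(dim(arr)) != 4)
      stop("kind = 'field' expects a 4D NIfTI, got ", length(dim(arr)), "D")
    return(displacement_field(arr, spacing, header = hdr))
  }
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1L) arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3)
    stop("kind = '", kind, "' expects a 3D NIfTI, got ", length(dim(arr)), "D")
  if (kind == "label") {
    if (any(arr < 0) || max(abs(arr - round(arr))) > 1e-8)
      stop("kind = 'label' but file holds non-integer or negative values")
    return(label_volume(round(arr), spacing, header = hdr))
  }
  intensity_volume(arr, spacing, header = hdr)
}

#' Save a volume to a NIfTI-1 file
#'
#' Labels are written as 32-bit integers, intensities and displacement
#' fields as 64-bit floats, so [load_volume()] round-trips the data
#' bit-for-bit and preserves the exact label set. Gzip compression follows
#' the file extension.
#'
#' @param vol an [intensity_volume()], [label_volume()] or
#'   [displacement_field()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  if (!inherits(vol, "brain_volume"))
    stop("vol must be an intensity_volume, label_volume or displacement_field")
  arr <- vol$data
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr, reference = vol$header)
  RNifti::pixdim(img) <- vol$spacing
  datatype <- if (inherits(vol, "label_volume")) "int32" else "double"
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Assert two volumes live on the same grid
#'
#' Passes silently iff the 3D shapes are equal and spacings agree within
#' 1e-6 mm; otherwise raises an error naming the differing attribute.
#' Accepts any pair of volumetric containers (a field is compared on its
#' first three axes).
#'
#' @param a,b volumetric containers.
#' @return `TRUE` invisibly on success.
#' @export
assert_same_grid <- function(a, b) {
  sa <- grid_shape(a); sb <- grid_shape(b)
  if (!identical(as.integer(sa), as.integer(sb)))
    stop(sprintf("grid mismatch: shape (%s) vs (%s)",
                 paste(sa, collapse = ","), paste(sb, collapse = ",")))
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop(sprintf("grid mismatch: spacing (%s) vs (%s) mm",
                 paste(format(a$spacing), collapse = ","),
                 paste(format(b$spacing), collapse = ",")))
  invisible(TRUE)
}
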