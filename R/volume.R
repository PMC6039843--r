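#' Construct a template-space volume
#'
#' A `svd_volume` is a 3-D scalar lattice on the shared analysis grid: an
#' ordinary numeric array carrying the isotropic voxel size (mm) and a space
#' tag identifying the template space. Every voxel-wise quantity in the
#' pipeline -- tissue probability maps, Jacobian determinants, divergence
#' maps, rate maps, t-maps -- is carried by this one class. All volumes
#' entering a single analysis must share shape, voxel size and space tag.
#'
#' @param data numeric 3-D array; all values must be finite (rate/p maps may
#'   opt into `NA` for out-of-mask voxels via `allow_na`).
#' @param voxel_size_mm positive scalar, isotropic voxel edge length in mm.
#' @param space_tag identifier of the shared template space.
#' @param allow_na logical; permit `NA` voxels (used for masked-out outputs).
#' @return object of class `svd_volume`.
#' @export
volume <- function(data, voxel_size_mm = 2, space_tag = "template",
                   allow_na = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3-D volume, got ", length(dim(data)), " dimension(s)")
  storage.mode(data) <- "double"
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L) {
    if (!allow_na || any(is.nan(data) | is.infinite(data)))
      stop("volume contains ", n_bad, " non-finite voxel(s)")
  }
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("voxel_size_mm must be a positive scalar")
  structure(data,
            voxel_size_mm = as.numeric(voxel_size_mm),
            space_tag = as.character(space_tag),
            class = "svd_volume")
}

#' @export
print.svd_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<svd_volume> %d x %d x %d @ %g mm [%s]\n",
              d[1], d[2], d[3], attr(x, "voxel_size_mm"), attr(x, "space_tag")))
  cat(sprintf("  range [%g, %g], %d NA\n",
              suppressWarnings(min(x, na.rm = TRUE)),
              suppressWarnings(max(x, na.rm = TRUE)), sum(is.na(x))))
  invisible(x)
}

#' @rdname volume
#' @param x object to test or coerce.
#' @export
is_volume <- function(x) inherits(x, "svd_volume")

# strip class/attributes, returning the bare array
vol_data <- function(x) {
  a <- unclass(x)
  attr(a, "voxel_size_mm") <- NULL
  attr(a, "space_tag") <- NULL
  a
}

#' @rdname volume
#' @export
voxel_size <- function(x) attr(x, "voxel_size_mm")

# volume of one voxel in mm^3
voxel_volume_mm3 <- function(x) attr(x, "voxel_size_mm")^3

# build a new volume on the same grid as `like`
volume_like <- function(data, like, allow_na = FALSE) {
  volume(data, voxel_size_mm = attr(like, "voxel_size_mm"),
         space_tag = attr(like, "space_tag"), allow_na = allow_na)
}

#' Check that volumes share the analysis grid
#'
#' All modules reject mixed-grid inputs (shape, voxel size or space mismatch)
#' with this single uniform error.
#'
#' @param ... `svd_volume` objects (or lists of them).
#' @return invisibly `TRUE`; stops otherwise.
#' @export
check_same_grid <- function(...) {
  vols <- list(...)
  # flatten one level so lists of volumes can be passed directly
  vols <- unlist(lapply(vols, function(v) if (is_volume(v)) list(v) else v),
                 recursive = FALSE)
  vols <- Filter(Negate(is.null), vols)
  if (length(vols) < 2L) return(invisible(TRUE))
  ref <- vols[[1L]]
  for (v in vols[-1L]) {
    if (!identical(dim(v), dim(ref)) ||
        !isTRUE(all.equal(voxel_size(v), voxel_size(ref))) ||
        !identical(attr(v, "space_tag"), attr(ref, "space_tag")))
      stop("mixed-grid input: volumes differ in shape, voxel size or space tag")
  }
  invisible(TRUE)
}

#' Read a volume from a NIfTI-1 file
#'
#' Reads a single-precision NIfTI-1 image into a [volume()]. Anisotropic
#' voxels and non-3-D images are rejected; any non-finite voxel aborts with
#' a count of offending voxels.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param space_tag template-space tag to attach.
#' @return a `svd_volume`.
#' @export
read_volume <- function(path, space_tag = "template") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3-D volume, got ", length(d), "-D image: ", path)
  pd <- RNifti::pixdim(img)[seq_len(3L)]
  if (diff(range(pd)) > 1e-6 * mean(pd))
    stop("anisotropic voxels (", paste(signif(pd, 6), collapse = " x "),
         " mm) are not supported: ", path)
  a <- array(as.numeric(img), dim = d)
  n_bad <- sum(!is.finite(a))
  if (n_bad > 0L) stop("volume contains ", n_bad, " non-finite voxel(s): ", path)
  volume(a, voxel_size_mm = pd[1L], space_tag = space_tag)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param v a `svd_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; `"float"` (single precision, the
#'   standard interchange format) or `"double"` for bit-exact round-trips.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "float") {
  stopifnot(is_volume(v))
  vs <- voxel_size(v)
  a <- vol_data(v)
  attr(a, "pixdim") <- c(vs, vs, vs)
  RNifti::writeNifti(RNifti::asNifti(a, datatype = datatype), path)
  invisible(path)
}
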