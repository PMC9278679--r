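#' 3D image volumes
#'
#' A `volume3d` is a regular 3D scalar grid: a numeric array plus voxel
#' spacing (mm) and the physical position of the first voxel center (origin,
#' mm). The axis convention is x = left-right, y = anterior-posterior,
#' z = superior-inferior; voxel `(i, j, k)` (1-based) sits at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data numeric 3D array, finite everywhere.
#' @param spacing numeric length-3, mm per voxel, all > 0.
#' @param origin numeric length-3, mm.
#' @return object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array", call. = FALSE)
  if (any(!is.finite(data)))
    stop("data must be finite everywhere", call. = FALSE)
  spacing <- .check_vec3(spacing, "spacing")
  if (any(spacing <= 0)) stop("spacing components must be > 0", call. = FALSE)
  origin <- .check_vec3(origin, "origin")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (mm): %.2f %.2f %.2f; intensity range [%.3g, %.3g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Geometric center of a volume (mm)
#'
#' @param vol `volume3d`.
#' @return numeric length-3: the physical midpoint of the voxel-center grid,
#'   the default rotation center for registration.
#' @export
volume_center <- function(vol) {
  stopifnot(inherits(vol, "volume3d"))
  vol$origin + (dim(vol$data) - 1) / 2 * vol$spacing
}

.same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Read / write a volume as NIfTI-1
#'
#' Spacing and origin are carried in the NIfTI header (pixdim and the sform
#' offset). Only axis-aligned volumes are produced; obliquely oriented input
#' headers are rejected.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_nifti_volume`: a `volume3d`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  x <- RNifti::xform(img)
  rot <- x[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4 * max(abs(diag(rot))))
    stop("obliquely oriented NIfTI volumes are not supported", call. = FALSE)
  volume3d(array(as.numeric(img), dim = dim(img)),
           spacing = abs(diag(rot)), origin = x[1:3, 4])
}

#' @rdname read_nifti_volume
#' @param vol `volume3d` to write.
#' @export
write_nifti_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Downsample a volume by integer block averaging
#'
#' Each output voxel is the mean of a `factor^3` block; trailing voxels that
#' do not fill a block are dropped. Spacing is multiplied by `factor` and the
#' origin moves to the center of the first block, so physical geometry is
#' preserved. Used to build the coarse levels of the registration pyramid.
#'
#' @param vol `volume3d`.
#' @param factor positive integer.
#' @return `volume3d`.
#' @export
downsample_volume <- function(vol, factor) {
  stopifnot(inherits(vol, "volume3d"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  if (factor == 1L) return(vol)
  d <- dim(vol$data)
  nd <- d %/% factor
  if (any(nd < 1L)) stop("volume too small for this downsampling factor",
                         call. = FALSE)
  a <- vol$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  a <- aperm(a, c(1L, 3L, 5L, 2L, 4L, 6L))
  dim(a) <- c(factor^3, prod(nd))
  m <- array(colMeans(a), dim = nd)
  volume3d(m, spacing = vol$spacing * factor,
           origin = vol$origin + (factor - 1) / 2 * vol$spacing)
}
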