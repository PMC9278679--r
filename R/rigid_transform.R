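#' Rigid-body transforms and Euler-angle algebra
#'
#' Rotations follow the extrinsic x-then-y-then-z convention
#' `R = Rx(pitch) %*% Ry(roll) %*% Rz(yaw)` with right-handed single-axis
#' matrices, the convention used when setup rotations are read off a
#' registration matrix in head-and-neck positioning QA: pitch is the rotation
#' about the left-right axis (x), roll about the anterior-posterior axis (y)
#' and yaw about the superior-inferior axis (z). Angles are degrees at every
#' interface and radians only internally.
#'
#' @name rigid-transforms
NULL

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.check_angles <- function(angles) {
  if (!is.numeric(angles) || length(angles) != 3L || any(!is.finite(angles)))
    stop("angles must be 3 finite numbers (pitch, roll, yaw in degrees)",
         call. = FALSE)
  as.numeric(angles)
}

.check_vec3 <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    stop(what, " must be 3 finite numbers", call. = FALSE)
  as.numeric(x)
}

#' Compose a rotation matrix from pitch, roll and yaw
#'
#' Builds the 3x3 rotation matrix `Rx(pitch) %*% Ry(roll) %*% Rz(yaw)` from
#' its closed-form entries. The first row is
#' `(cos(roll)cos(yaw), -cos(roll)sin(yaw), sin(roll))`.
#'
#' @param angles numeric length-3, `c(pitch, roll, yaw)` in degrees.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @examples
#' compose_rotation_matrix(c(0, 0, 0))      # identity
#' compose_rotation_matrix(c(0, 90, 0))[1, 3]  # sin(roll) = 1
#' @export
compose_rotation_matrix <- function(angles) {
  a <- .deg2rad(.check_angles(angles))
  cp <- cos(a[1]); sp <- sin(a[1])  # pitch (phi, about x)
  cr <- cos(a[2]); sr <- sin(a[2])  # roll (theta, about y)
  cy <- cos(a[3]); sy <- sin(a[3])  # yaw (alpha, about z)
  matrix(c(
    cr * cy,                 -cr * sy,                  sr,
    cp * sy + sp * sr * cy,   cp * cy - sp * sr * sy,  -sp * cr,
    sp * sy - cp * sr * cy,   sp * cy + cp * sr * sy,   cp * cr
  ), nrow = 3L, byrow = TRUE)
}

.check_rotation_matrix <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || !identical(dim(R), c(3L, 3L)) || any(!is.finite(R)))
    stop("R must be a finite 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("R is not orthonormal (R'R != I within ", tol, ")", call. = FALSE)
  if (abs(det(R) - 1) > tol)
    stop("R is not a proper rotation (det != +1)", call. = FALSE)
  R
}

#' Recover pitch, roll and yaw from a rotation matrix
#'
#' Solves `R = Rx(pitch) %*% Ry(roll) %*% Rz(yaw)` for the three Euler
#' angles: `roll = asin(R[1,3])`, `yaw = atan2(-R[1,2], R[1,1])`,
#' `pitch = atan2(-R[2,3], R[3,3])`. At gimbal lock (`|roll| = 90` degrees)
#' yaw and pitch are degenerate; yaw is conventionally set to 0, pitch
#' absorbs the remaining rotation, and the result carries attribute
#' `gimbal_lock = TRUE`.
#'
#' @param R 3x3 proper orthonormal matrix.
#' @param tol orthonormality tolerance for input validation.
#' @return named numeric `c(pitch_deg, roll_deg, yaw_deg)`; pitch and yaw in
#'   (-180, 180], roll in \[-90, 90\].
#' @export
decompose_rotation_matrix <- function(R, tol = 1e-8) {
  .check_rotation_matrix(R, tol)
  s <- min(1, max(-1, R[1, 3]))
  if (abs(s) >= 1 - 1e-12) {
    # gimbal lock: only pitch +/- yaw is determined; put it all in pitch
    roll <- if (s > 0) 90 else -90
    pitch <- .rad2deg(atan2(R[2, 1], R[2, 2])) * sign(s)
    out <- c(pitch_deg = pitch, roll_deg = roll, yaw_deg = 0)
    attr(out, "gimbal_lock") <- TRUE
    return(out)
  }
  out <- c(pitch_deg = .rad2deg(atan2(-R[2, 3], R[3, 3])),
           roll_deg  = .rad2deg(asin(s)),
           yaw_deg   = .rad2deg(atan2(-R[1, 2], R[1, 1])))
  attr(out, "gimbal_lock") <- FALSE
  out
}

#' Construct a rigid transform
#'
#' A rigid transform maps a physical point `p` (mm) to
#' `R %*% (p - center) + center + translation`, where `R` is the rotation
#' matrix of [compose_rotation_matrix()]. Axes are x = left-right,
#' y = anterior-posterior, z = superior-inferior.
#'
#' @param translation numeric length-3, `c(tx, ty, tz)` in mm.
#' @param angles numeric length-3, `c(pitch, roll, yaw)` in degrees.
#' @param center numeric length-3 rotation center in mm (defaults to the
#'   origin; registration routines use the fixed-volume geometric center).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), angles = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  t <- structure(list(translation = .check_vec3(translation, "translation"),
                      angles = .check_angles(angles),
                      center = .check_vec3(center, "center")),
                 class = "rigid_transform")
  t
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  cat(sprintf("  translation (mm): %8.4f %8.4f %8.4f\n",
              x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  pitch/roll/yaw (deg): %8.4f %8.4f %8.4f\n",
              x$angles[1], x$angles[2], x$angles[3]))
  cat(sprintf("  center (mm): %.2f %.2f %.2f\n",
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param t `rigid_transform`.
#' @param points numeric matrix with 3 columns (one point per row, mm) or a
#'   single length-3 vector.
#' @return matrix of transformed points (same shape as input).
#' @export
apply_transform <- function(t, points) {
  stopifnot(inherits(t, "rigid_transform"))
  p <- if (is.null(dim(points))) matrix(points, ncol = 3L) else points
  R <- compose_rotation_matrix(t$angles)
  out <- sweep(p, 2L, t$center) %*% t(R)
  out <- sweep(out, 2L, t$center + t$translation, FUN = "+")
  if (is.null(dim(points))) drop(out) else out
}

#' Invert a rigid transform
#'
#' Returns the transform that exactly undoes `t` (same rotation center).
#'
#' @param t `rigid_transform`.
#' @return `rigid_transform` such that applying `t` then the result is the
#'   identity map.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  R <- compose_rotation_matrix(t$angles)
  ang <- decompose_rotation_matrix(t(R))
  rigid_transform(translation = as.numeric(-crossprod(R, t$translation)),
                  angles = as.numeric(ang), center = t$center)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(t2, t1)` is the transform equivalent to applying `t1`
#' first, then `t2`. Both must share the same rotation center.
#'
#' @param t2,t1 `rigid_transform` objects with identical centers.
#' @return `rigid_transform`.
#' @export
compose_transforms <- function(t2, t1) {
  stopifnot(inherits(t1, "rigid_transform"), inherits(t2, "rigid_transform"))
  if (max(abs(t1$center - t2$center)) > 1e-9)
    stop("transforms must share the same rotation center", call. = FALSE)
  R1 <- compose_rotation_matrix(t1$angles)
  R2 <- compose_rotation_matrix(t2$angles)
  ang <- decompose_rotation_matrix(R2 %*% R1)
  rigid_transform(translation = as.numeric(R2 %*% t1$translation + t2$translation),
                  angles = as.numeric(ang), center = t1$center)
}

#' Six-component view of a rigid transform
#'
#' @param t `rigid_transform`.
#' @return named numeric `c(tx_mm, ty_mm, tz_mm, pitch_deg, roll_deg, yaw_deg)`.
#' @export
transform_components <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  c(tx_mm = t$translation[1], ty_mm = t$translation[2], tz_mm = t$translation[3],
    pitch_deg = t$angles[1], roll_deg = t$angles[2], yaw_deg = t$angles[3])
}

#' Componentwise difference between an induced and a recovered transform
#'
#' `recovered` is the *estimate* of the induced transform (for a registration
#' run this is the inverse of the raw registration output, since registering
#' a displaced volume recovers the displacement's inverse). The difference is
#' computed by matrix composition, as the six components of
#' `recovered` composed with the inverse of `induced`; it is the zero vector
#' exactly when the estimate equals the induced transform, and for the small
#' rotations of positioning QA it reduces to componentwise
#' recovered - expected (e.g. induced tx = 10 mm, recovered tx = 9.5 mm gives
#' dtx = -0.5 mm).
#'
#' @param induced `rigid_transform` actually applied to the volume.
#' @param recovered `rigid_transform` estimated by registration (after
#'   inversion); must share `induced`'s rotation center.
#' @return named numeric
#'   `c(dtx_mm, dty_mm, dtz_mm, dpitch_deg, droll_deg, dyaw_deg)`.
#' @export
transform_difference <- function(induced, recovered) {
  stopifnot(inherits(induced, "rigid_transform"),
            inherits(recovered, "rigid_transform"))
  if (max(abs(induced$center - recovered$center)) > 1e-9)
    stop("induced and recovered transforms must share the same rotation center",
         call. = FALSE)
  d <- transform_components(compose_transforms(recovered, invert_transform(induced)))
  names(d) <- c("dtx_mm", "dty_mm", "dtz_mm",
                "dpitch_deg", "droll_deg", "dyaw_deg")
  d
}

#' Export a rigid transform as a 4x4 homogeneous matrix
#'
#' The matrix acts on physical column points in mm:
#' `H %*% c(p, 1) = R (p - center) + center + translation`.
#'
#' @param t `rigid_transform`.
#' @return 4x4 numeric matrix (row-major semantics are the usual R matrix).
#' @export
transform_to_matrix <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  R <- compose_rotation_matrix(t$angles)
  H <- diag(4)
  H[1:3, 1:3] <- R
  H[1:3, 4] <- t$translation + t$center - R %*% t$center
  H
}

#' Serialize / deserialize a rigid transform as flat JSON
#'
#' Keys: `tx_mm, ty_mm, tz_mm, pitch_deg, roll_deg, yaw_deg, center_mm`.
#'
#' @param t `rigid_transform`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `transform_to_json`: JSON string (invisibly, when writing to file);
#'   `transform_from_json`: `rigid_transform`.
#' @export
transform_to_json <- function(t, path = NULL) {
  stopifnot(inherits(t, "rigid_transform"))
  obj <- list(tx_mm = t$translation[1], ty_mm = t$translation[2],
              tz_mm = t$translation[3], pitch_deg = t$angles[1],
              roll_deg = t$angles[2], yaw_deg = t$angles[3],
              center_mm = t$center)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname transform_to_json
#' @param json JSON string or path to a JSON file.
#' @export
transform_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  rigid_transform(translation = c(obj$tx_mm, obj$ty_mm, obj$tz_mm),
                  angles = c(obj$pitch_deg, obj$roll_deg, obj$yaw_deg),
                  center = as.numeric(obj$center_mm))
}
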