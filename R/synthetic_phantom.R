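#' Digital skull-phantom configuration
#'
#' Describes a desk-scale digital analogue of a gelatin-filled skull phantom:
#' an ellipsoidal bony shell ("skull") enclosing a homogeneous interior
#' ("gelatin") in an empty background, imaged by two modalities with
#' deliberately different intensity mappings so that registering them is a
#' genuinely multimodal problem. Default geometry: a 64^3 grid at 2.5 mm
#' isotropic spacing (the slice thickness typical of radiotherapy head
#' protocols), semi-axes 50 x 65 x 55 mm, 6 mm shell. Default intensities are
#' HU-like for CT (air -1000, gelatin 40, bone 700) and T1-like for MRI
#' (background 5, gelatin 900, bone 150): bone is bright on CT and dark on
#' MRI, gelatin the reverse. MRI additionally gets a smooth multiplicative
#' bias field, CT does not.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing_mm numeric length-3 voxel spacing in mm.
#' @param semi_axes_mm ellipsoid outer semi-axes (x, y, z) in mm.
#' @param shell_thickness_mm nominal skull shell thickness in mm; must be
#'   positive and smaller than the smallest semi-axis.
#' @param inner_offset_mm displacement (mm) of the inner ellipsoid relative
#'   to the outer one. A nonzero offset makes the shell thickness vary
#'   across the surface, the way a real skull is thicker at the base than at
#'   the vault; this breaks the rotational near-symmetry of a concentric
#'   shell, without which small rotations would be nearly unidentifiable by
#'   any intensity-based registration. Each component must be smaller in
#'   magnitude than the shell thickness so the shell never vanishes.
#' @param ct_intensities named or positional length-3 vector
#'   (background, gelatin, skull) for the CT-like volume.
#' @param mri_intensities same for the MRI-like volume.
#' @param noise_sd length-2 vector `c(ct, mri)` of additive Gaussian noise
#'   standard deviations (intensity units; >= 0).
#' @param bias_field_amplitude fractional amplitude of the low-frequency
#'   multiplicative bias field applied to the MRI volume (0 disables).
#' @param seed integer RNG seed; the generated pair is a pure function of
#'   this configuration.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64L, 64L, 64L),
                           spacing_mm = c(2.5, 2.5, 2.5),
                           semi_axes_mm = c(50, 65, 55),
                           shell_thickness_mm = 6,
                           inner_offset_mm = c(3, -4, 2),
                           ct_intensities = c(background = -1000,
                                              gelatin = 40, skull = 700),
                           mri_intensities = c(background = 5,
                                               gelatin = 900, skull = 150),
                           noise_sd = c(ct = 15, mri = 25),
                           bias_field_amplitude = 0.1,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("shape must be 3 integers >= 8", call. = FALSE)
  spacing_mm <- .check_vec3(spacing_mm, "spacing_mm")
  semi_axes_mm <- .check_vec3(semi_axes_mm, "semi_axes_mm")
  if (shell_thickness_mm <= 0 || shell_thickness_mm >= min(semi_axes_mm))
    stop("shell_thickness_mm must be > 0 and < the smallest semi-axis",
         call. = FALSE)
  inner_offset_mm <- .check_vec3(inner_offset_mm, "inner_offset_mm")
  if (any(abs(inner_offset_mm) >= shell_thickness_mm))
    stop("each inner_offset_mm component must be smaller in magnitude than ",
         "the shell thickness", call. = FALSE)
  if (length(noise_sd) != 2L || any(noise_sd < 0))
    stop("noise_sd must be 2 non-negative values c(ct, mri)", call. = FALSE)
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 semi_axes_mm = semi_axes_mm,
                 shell_thickness_mm = shell_thickness_mm,
                 inner_offset_mm = inner_offset_mm,
                 ct_intensities = as.numeric(ct_intensities),
                 mri_intensities = as.numeric(mri_intensities),
                 noise_sd = as.numeric(noise_sd),
                 bias_field_amplitude = bias_field_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# run code under a local RNG state without disturbing the caller's stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a paired CT-like / MRI-like digital skull phantom
#'
#' Both volumes share one grid and one geometry, so the ground-truth
#' transform between them is exactly the identity; any transform later
#' injected into one of them is therefore known exactly.
#'
#' @param cfg `phantom_config`.
#' @return list with elements `ct` and `mri`, both `volume3d`.
#' @export
generate_skull_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  d <- cfg$shape
  # physical coordinates with the grid centered on the origin
  origin <- -(d - 1) / 2 * cfg$spacing_mm
  cx <- origin[1] + (seq_len(d[1]) - 1) * cfg$spacing_mm[1]
  cy <- origin[2] + (seq_len(d[2]) - 1) * cfg$spacing_mm[2]
  cz <- origin[3] + (seq_len(d[3]) - 1) * cfg$spacing_mm[3]
  a <- cfg$semi_axes_mm
  ain <- a - cfg$shell_thickness_mm
  off <- cfg$inner_offset_mm
  ex <- (cx / a[1])^2; ey <- (cy / a[2])^2; ez <- (cz / a[3])^2
  exi <- ((cx - off[1]) / ain[1])^2
  eyi <- ((cy - off[2]) / ain[2])^2
  ezi <- ((cz - off[3]) / ain[3])^2
  eout <- outer(outer(ex, ey, "+"), ez, "+")
  ein <- outer(outer(exi, eyi, "+"), ezi, "+")
  lab <- array(1L, dim = d)              # 1 background
  lab[eout <= 1] <- 3L                   # 3 skull shell
  lab[ein <= 1] <- 2L                    # 2 gelatin interior
  ct <- array(cfg$ct_intensities[lab], dim = d)
  mri <- array(cfg$mri_intensities[lab], dim = d)
  if (cfg$bias_field_amplitude != 0) {
    ux <- cx / max(abs(cx)); uy <- cy / max(abs(cy)); uz <- cz / max(abs(cz))
    bias <- 1 + cfg$bias_field_amplitude *
      outer(outer(cos(pi * ux / 2), cos(pi * uy / 2)), cos(pi * uz / 2))
    mri <- mri * bias
  }
  if (any(cfg$noise_sd > 0)) {
    .with_seed(cfg$seed, {
      if (cfg$noise_sd[1] > 0)
        ct <- ct + array(rnorm(prod(d), sd = cfg$noise_sd[1]), dim = d)
      if (cfg$noise_sd[2] > 0)
        mri <- mri + array(rnorm(prod(d), sd = cfg$noise_sd[2]), dim = d)
    })
  }
  list(ct = volume3d(ct, spacing = cfg$spacing_mm, origin = origin),
       mri = volume3d(mri, spacing = cfg$spacing_mm, origin = origin))
}

#' Analytic shell volume of the phantom skull (mm^3)
#'
#' Volume of the ellipsoidal shell between the outer semi-axes and the inner
#' ones (outer minus shell thickness): `4/3 pi (prod(a) - prod(a - th))`.
#' Used to validate the voxelized geometry.
#'
#' @param cfg `phantom_config`.
#' @return scalar, mm^3.
#' @export
phantom_shell_volume <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  a <- cfg$semi_axes_mm
  4 / 3 * pi * (prod(a) - prod(a - cfg$shell_thickness_mm))
}

#' Apply a known transform to a volume
#'
#' Resamples `vol` under `t` on its own grid (see [resample_volume()]) and
#' records the induced transform as an attribute, so downstream accuracy
#' protocols can compare what was injected with what registration recovers.
#'
#' @param vol `volume3d`.
#' @param t `rigid_transform` to induce.
#' @param background out-of-field fill value.
#' @return `volume3d` with attribute `induced_transform`.
#' @export
inject_transform <- function(vol, t, background = min(vol$data)) {
  out <- resample_volume(vol, t, vol, background = background)
  attr(out, "induced_transform") <- t
  out
}
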