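#' Resample a volume onto a reference grid under a rigid transform
#'
#' Pull-back resampling with trilinear interpolation: the output value at a
#' reference grid point `x` is the moving volume sampled at `t(x)`. Voxels
#' that map outside the moving field of view receive `background`, which
#' defaults to the moving volume's minimum so that signed (CT-like)
#' intensities do not acquire spurious histogram mass at zero.
#'
#' @param moving `volume3d` to be resampled.
#' @param t `rigid_transform` mapping reference physical space into moving
#'   physical space.
#' @param reference `volume3d` defining the output grid.
#' @param background value for out-of-field voxels.
#' @return `volume3d` on the reference grid.
#' @export
resample_volume <- function(moving, t, reference,
                            background = min(moving$data)) {
  stopifnot(inherits(moving, "volume3d"), inherits(reference, "volume3d"),
            inherits(t, "rigid_transform"))
  R <- compose_rotation_matrix(t$angles)
  b <- t$translation + t$center - as.numeric(R %*% t$center)
  out <- resample_affine_cpp(as.numeric(moving$data), dim(moving$data),
                             moving$spacing, moving$origin,
                             dim(reference$data), reference$spacing,
                             reference$origin, R, b, background)
  volume3d(array(out, dim = dim(reference$data)),
           spacing = reference$spacing, origin = reference$origin)
}

.intensity_range <- function(x, clamp = c(0.01, 0.99)) {
  r <- as.numeric(quantile(x, probs = clamp, names = FALSE, type = 7))
  if (r[2] <= r[1]) r <- range(x)
  r
}

.mi_from_counts <- function(h) {
  n <- sum(h)
  if (n == 0) return(0)
  p <- h / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  sum(p[nz] * log2(p[nz] / (px[nz[, 1]] * py[nz[, 2]])))
}

#' Mutual information between two volumes on a shared grid
#'
#' Shannon mutual information, in bits, of the joint intensity histogram
#' `MI = sum p(i,j) log2( p(i,j) / (p(i) p(j)) )`. Intensities are binned
#' linearly between each volume's 1st and 99th percentiles (robust to CT
#' tails); out-of-range values are clamped into the edge bins.
#'
#' @param a,b `volume3d` objects on the same grid.
#' @param bins number of histogram bins per volume (>= 8).
#' @return mutual information in bits (non-negative, symmetric in `a`, `b`).
#' @export
mutual_information <- function(a, b, bins = 64L) {
  stopifnot(inherits(a, "volume3d"), inherits(b, "volume3d"))
  if (!.same_grid(a, b))
    stop("volumes must share the same grid", call. = FALSE)
  bins <- as.integer(bins)
  if (bins < 8L) stop("bins must be >= 8", call. = FALSE)
  ra <- .intensity_range(a$data)
  rb <- .intensity_range(b$data)
  ab <- bin_intensities_cpp(as.numeric(a$data), bins, ra[1], ra[2])
  bb <- bin_intensities_cpp(as.numeric(b$data), bins, rb[1], rb[2])
  .mi_from_counts(joint_hist_cpp(ab, bb, bins))
}

#' Registration configuration
#'
#' Settings for [register_rigid()]. The defaults implement a standard
#' mutual-information rigid registration: 64 histogram bins, a 3-level
#' multi-resolution pyramid (block-mean downsampling by 4, 2, 1) and
#' derivative-free Nelder-Mead optimization of the 6 rigid parameters with
#' 1 mm and 1 degree treated as commensurate unit steps. A deterministic
#' coarse grid search over translations seeds the coarsest level so that
#' offsets up to `init_range_mm` are inside the capture range.
#'
#' @param histogram_bins bins per intensity axis at the finest level (>= 8);
#'   coarser levels use proportionally fewer bins (never below 16) because
#'   they hold fewer voxels.
#' @param pyramid_levels number of resolution levels (>= 1); level `l` uses
#'   downsampling factor `2^(pyramid_levels - l)`.
#' @param optimizer_max_iter Nelder-Mead iteration cap per level.
#' @param value_tolerance relative convergence tolerance on the metric.
#' @param initial_transform optional `rigid_transform` starting point; its
#'   center is overridden by the fixed-volume center.
#' @param init_grid logical: run the coarse translation grid search.
#' @param init_range_mm half-width (mm) of the coarse translation search.
#' @param init_step_mm step (mm) of the coarse translation search.
#' @param smoothing_sigma_voxels light Gaussian pre-smoothing, in voxels,
#'   applied to both volumes at every pyramid level (default 0.3). Damps
#'   voxel-noise histogram artifacts; sigmas approaching a voxel blur the
#'   few-voxel-thick skull shell that localizes rotations and degrade
#'   accuracy, so the default is deliberately small.
#' @param mask_threshold_frac body-contour masking: metric sample points are
#'   kept only where the fixed image exceeds its 1st percentile plus this
#'   fraction of its robust intensity range. Air fills most of a head field
#'   of view, and its noise otherwise dominates the joint histogram; 0
#'   disables masking (the mask is also ignored if it would leave fewer
#'   than 1000 sample points).
#' @return object of class `registration_config`.
#' @export
registration_config <- function(histogram_bins = 64L, pyramid_levels = 3L,
                                optimizer_max_iter = 500L,
                                value_tolerance = 1e-7,
                                initial_transform = NULL,
                                init_grid = TRUE, init_range_mm = 12,
                                init_step_mm = 4,
                                smoothing_sigma_voxels = 0.3,
                                mask_threshold_frac = 0.1) {
  histogram_bins <- as.integer(histogram_bins)
  pyramid_levels <- as.integer(pyramid_levels)
  if (histogram_bins < 8L) stop("histogram_bins must be >= 8", call. = FALSE)
  if (pyramid_levels < 1L) stop("pyramid_levels must be >= 1", call. = FALSE)
  structure(list(histogram_bins = histogram_bins,
                 pyramid_levels = pyramid_levels,
                 optimizer_max_iter = as.integer(optimizer_max_iter),
                 value_tolerance = value_tolerance,
                 initial_transform = initial_transform,
                 init_grid = isTRUE(init_grid),
                 init_range_mm = init_range_mm,
                 init_step_mm = init_step_mm,
                 smoothing_sigma_voxels = smoothing_sigma_voxels,
                 mask_threshold_frac = mask_threshold_frac),
            class = "registration_config")
}

# Negative MI of (fixed, moving sampled under params) at one pyramid level.
# Two standard metric refinements over a naive joint histogram:
#  - Parzen-windowed (linear) binning, so the metric is smooth in the
#    transform parameters (hard binning is piecewise constant at fine scales
#    and stalls a derivative-free optimizer);
#  - a fixed, deterministically jittered sample-point set (voxel centers
#    plus a frozen sub-voxel offset per point), so the fixed and moving
#    images are both interpolated at every candidate transform. Sampling the
#    fixed image exactly on its own grid leaves its noise unsmoothed while
#    any off-grid transform smooths the moving image's, which biases the MI
#    optimum away from grid-aligned truth.
.make_objective <- function(fixed, moving, center, bins, mask_frac = 0.1) {
  rf <- .intensity_range(fixed$data)
  rmov <- .intensity_range(moving$data)
  d <- dim(fixed$data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3]))) - 1
  jit <- .with_seed(760817L,
                    matrix(runif(length(idx)) - 0.5, ncol = 3L))
  pts <- sweep((idx + jit) %*% diag(fixed$spacing), 2L, fixed$origin, "+")
  fbg <- min(fixed$data)
  fvals <- sample_points_cpp(as.numeric(fixed$data), d, fixed$spacing,
                             fixed$origin, pts, diag(3), c(0, 0, 0), fbg)
  if (mask_frac > 0) {
    # body-contour mask on the fixed image: keep sample points whose fixed
    # intensity clears the background band, so the metric is driven by
    # tissue, not by the air noise that fills most of the field of view
    keep <- fvals > rf[1] + mask_frac * (rf[2] - rf[1])
    if (sum(keep) >= 1000) {
      pts <- pts[keep, , drop = FALSE]
      fvals <- fvals[keep]
    }
  }
  background <- min(moving$data)
  force(center)
  function(par) {
    t <- rigid_transform(translation = par[1:3], angles = par[4:6],
                         center = center)
    R <- compose_rotation_matrix(t$angles)
    b <- t$translation + t$center - as.numeric(R %*% t$center)
    mvals <- sample_points_cpp(as.numeric(moving$data), dim(moving$data),
                               moving$spacing, moving$origin, pts, R, b,
                               background)
    -.mi_from_counts(joint_hist_soft_cpp(fvals, mvals, bins,
                                         rf[1], rf[2], rmov[1], rmov[2]))
  }
}

#' Rigid registration by mutual-information maximization
#'
#' Registers `moving` onto `fixed` (for CT-MRI positioning QA: fixed = CT,
#' moving = MRI) by maximizing the mutual information of their joint
#' intensity histogram over the 6 rigid parameters, using a coarse-to-fine
#' pyramid and Nelder-Mead optimization. The rotation center is the fixed
#' volume's geometric center. The procedure is fully deterministic: identical
#' inputs and configuration reproduce the result exactly.
#'
#' The returned transform `T` maximizes `MI(fixed, moving o T)`; when
#' `moving` was produced by displacing `fixed` with a transform `t`,
#' `T` estimates `t^{-1}`, so the estimate of the displacement itself is
#' `invert_transform(T)`.
#'
#' @param fixed,moving `volume3d` objects with overlapping fields of view.
#' @param cfg `registration_config`.
#' @return list of class `registration_result`: `transform`
#'   (`rigid_transform`), `final_metric` and `initial_metric`
#'   (Parzen-windowed MI in bits at the finest level, for the returned and
#'   the starting transform; the former never falls below the latter),
#'   `iterations` (total objective evaluations), `converged` (logical).
#' @export
register_rigid <- function(fixed, moving, cfg = registration_config()) {
  stopifnot(inherits(fixed, "volume3d"), inherits(moving, "volume3d"),
            inherits(cfg, "registration_config"))
  center <- volume_center(fixed)
  par <- c(0, 0, 0, 0, 0, 0)
  if (!is.null(cfg$initial_transform)) {
    it <- cfg$initial_transform
    par <- c(it$translation, it$angles)
  }
  par0 <- par
  factors <- 2^((cfg$pyramid_levels - 1):0)
  evals <- 0L
  conv_ok <- TRUE
  obj <- NULL
  initial_metric <- NA_real_
  for (li in seq_along(factors)) {
    f <- factors[li]
    flev <- downsample_volume(fixed, f)
    mlev <- downsample_volume(moving, f)
    if (cfg$smoothing_sigma_voxels > 0) {
      flev$data <- array(smooth_gaussian_cpp(as.numeric(flev$data),
                                             dim(flev$data),
                                             cfg$smoothing_sigma_voxels),
                         dim = dim(flev$data))
      mlev$data <- array(smooth_gaussian_cpp(as.numeric(mlev$data),
                                             dim(mlev$data),
                                             cfg$smoothing_sigma_voxels),
                         dim = dim(mlev$data))
    }
    bins <- max(16L, as.integer(round(cfg$histogram_bins / f)))
    obj <- .make_objective(flev, mlev, center, bins,
                           mask_frac = cfg$mask_threshold_frac)
    if (li == 1L && cfg$init_grid && cfg$init_range_mm > 0) {
      g <- seq(-cfg$init_range_mm, cfg$init_range_mm, by = cfg$init_step_mm)
      grid <- as.matrix(expand.grid(tx = g + par[1], ty = g + par[2],
                                    tz = g + par[3]))
      vals <- apply(grid, 1L, function(tr) obj(c(tr, par[4:6])))
      evals <- evals + nrow(grid)
      par[1:3] <- grid[which.min(vals), ]
    }
    best_val <- obj(par)
    evals <- evals + 1L
    # Nelder-Mead with simplex restarts at shrinking scales: a fresh simplex
    # around the incumbent escapes collapsed configurations, the usual
    # failure mode of a single NM run in 6 dimensions
    for (scale in c(1, 0.25, 0.0625)) {
      ps <- scale * c(rep(2.5 * f, 3), rep(2.5, 3))  # mm and degree steps
      opt <- optim(par, obj, method = "Nelder-Mead",
                   control = list(maxit = cfg$optimizer_max_iter,
                                  reltol = cfg$value_tolerance,
                                  parscale = ps))
      evals <- evals + opt$counts[["function"]]
      # keep the incumbent unless the restart improved on it
      if (opt$value < best_val) {
        par <- opt$par
        best_val <- opt$value
      }
      if (li == length(factors)) conv_ok <- opt$convergence == 0L
    }
  }
  # metric monotonicity at full resolution: never return a transform worse
  # than the starting one
  init_val <- obj(par0)
  evals <- evals + 1L
  initial_metric <- -init_val
  if (best_val > init_val) {
    # the starting point was already (at least locally) optimal; returning
    # it is a valid converged outcome, e.g. self-registration at identity
    par <- par0
    best_val <- init_val
  }
  final_mi <- -best_val
  # overlap sanity: a degenerate solution with (near-)constant overlap has
  # essentially zero mutual information
  if (final_mi < 1e-6) conv_ok <- FALSE
  structure(list(transform = rigid_transform(translation = par[1:3],
                                             angles = par[4:6],
                                             center = center),
                 final_metric = final_mi, initial_metric = initial_metric,
                 iterations = evals, converged = conv_ok),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result (MI = %.4f bits, %d evaluations, %s)\n",
              x$final_metric, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(x$transform)
  invisible(x)
}

#' Write a registration result as JSON
#'
#' The transform JSON of [transform_to_json()] plus `final_metric_bits`,
#' `iterations` and `converged` fields.
#'
#' @param res `registration_result`.
#' @param path output file path.
#' @export
write_registration_result <- function(res, path) {
  stopifnot(inherits(res, "registration_result"))
  t <- res$transform
  obj <- list(tx_mm = t$translation[1], ty_mm = t$translation[2],
              tz_mm = t$translation[3], pitch_deg = t$angles[1],
              roll_deg = t$angles[2], yaw_deg = t$angles[3],
              center_mm = t$center, final_metric_bits = res$final_metric,
              iterations = res$iterations, converged = res$converged)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
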