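#' Known-transform grids for registration accuracy validation
#'
#' The validation protocol injects one nonzero transform component at a time
#' into the moving volume, re-registers, and records expected-vs-recovered
#' differences. The default grid covers translations from 0.5 to 20 mm in
#' 1 mm increments (20 values per axis: 0.5, 1.5, ..., 19.5) and rotations
#' from 0.2 to 5 degrees in 0.2-degree increments (25 values per axis), each
#' repeated 10 times. `figure_n = TRUE` switches to the sparser 10-values-per
#' -axis translation preset (0.5, 2.5, ..., 18.5) matching published
#' per-figure sample counts of n = 10 per translation axis.
#'
#' @param translation_values_mm strictly positive increasing values (mm).
#' @param rotation_values_deg strictly positive increasing values (degrees).
#' @param repeats repetitions per grid point (>= 1).
#' @return object of class `induced_grid`.
#' @export
induced_grid <- function(translation_values_mm = seq(0.5, 19.5, by = 1),
                         rotation_values_deg = seq(0.2, 5, by = 0.2),
                         repeats = 10L) {
  chk <- function(x, what) {
    if (length(x) < 1L || any(x <= 0) || is.unsorted(x, strictly = TRUE))
      stop(what, " must be strictly positive and increasing", call. = FALSE)
    as.numeric(x)
  }
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  structure(list(translation_values_mm = chk(translation_values_mm,
                                             "translation_values_mm"),
                 rotation_values_deg = chk(rotation_values_deg,
                                           "rotation_values_deg"),
                 repeats = repeats),
            class = "induced_grid")
}

#' @rdname induced_grid
#' @param figure_n logical; use the 10-per-axis translation preset.
#' @export
build_default_grid <- function(figure_n = FALSE) {
  if (figure_n)
    induced_grid(translation_values_mm = seq(0.5, 18.5, by = 2))
  else
    induced_grid()
}

#' Run the known-transform accuracy protocol
#'
#' For every axis, grid value and repeat, injects a single-component rigid
#' transform into `moving` (translations and rotations studied
#' independently), registers the modified volume back onto `fixed`, inverts
#' the registration output to obtain the estimate of the induced transform,
#' and records the componentwise difference. Registration failures are
#' flagged in the `converged` column, never dropped.
#'
#' @param fixed,moving `volume3d` volumes (e.g. the CT and MRI of a
#'   generated phantom pair).
#' @param grid `induced_grid`.
#' @param cfg `registration_config` passed to the registrar.
#' @param registrar function `(fixed, moving, cfg)` returning a
#'   `registration_result`; defaults to [register_rigid()]. An oracle
#'   registrar (e.g. one returning the exact inverse of the induced
#'   transform) can be substituted for protocol verification.
#' @return `data.frame` with columns `axis` (x/y/z), `component_kind`
#'   (translation/rotation), `induced_value`, `repeat`,
#'   `dtx_mm, dty_mm, dtz_mm, dpitch_deg, droll_deg, dyaw_deg`, `converged`.
#' @export
run_accuracy_protocol <- function(fixed, moving, grid = build_default_grid(),
                                  cfg = registration_config(),
                                  registrar = register_rigid) {
  stopifnot(inherits(grid, "induced_grid"))
  center <- volume_center(fixed)
  cases <- rbind(
    expand.grid(axis = c("x", "y", "z"),
                component_kind = "translation",
                induced_value = grid$translation_values_mm,
                stringsAsFactors = FALSE),
    expand.grid(axis = c("x", "y", "z"),
                component_kind = "rotation",
                induced_value = grid$rotation_values_deg,
                stringsAsFactors = FALSE))
  out <- vector("list", nrow(cases) * grid$repeats)
  n <- 0L
  for (ci in seq_len(nrow(cases))) {
    ax <- match(cases$axis[ci], c("x", "y", "z"))
    kind <- cases$component_kind[ci]
    v6 <- numeric(6)
    v6[if (kind == "translation") ax else 3L + ax] <- cases$induced_value[ci]
    induced <- rigid_transform(translation = v6[1:3], angles = v6[4:6],
                               center = center)
    displaced <- inject_transform(moving, induced)
    for (r in seq_len(grid$repeats)) {
      res <- registrar(fixed, displaced, cfg)
      estimate <- invert_transform(res$transform)
      d <- transform_difference(induced, estimate)
      n <- n + 1L
      out[[n]] <- data.frame(axis = cases$axis[ci], component_kind = kind,
                             induced_value = cases$induced_value[ci],
                             `repeat` = r, as.list(d),
                             converged = isTRUE(res$converged),
                             check.names = FALSE)
    }
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  rec
}

#' Oracle registrar recovering each induced transform exactly
#'
#' Returns the exact inverse of the transform recorded by
#' [inject_transform()] on the moving volume; use with
#' [run_accuracy_protocol()] to verify protocol bookkeeping independently of
#' any real registration engine.
#'
#' @param fixed,moving `volume3d`; `moving` must carry an
#'   `induced_transform` attribute.
#' @param cfg ignored.
#' @return `registration_result` whose transform exactly undoes the induced
#'   one.
#' @export
oracle_registrar <- function(fixed, moving, cfg = NULL) {
  t <- attr(moving, "induced_transform")
  if (is.null(t)) stop("moving volume carries no induced_transform attribute",
                       call. = FALSE)
  structure(list(transform = invert_transform(t), final_metric = Inf,
                 iterations = 0L, converged = TRUE),
            class = "registration_result")
}

#' Summarize accuracy records with Bland-Altman statistics per group
#'
#' Pools the differences the way the validation analysis groups them: the
#' in-plane translations x and y together (the difference along the induced
#' axis), the z translations separately, and all rotation axes together.
#'
#' @param records output of [run_accuracy_protocol()].
#' @param k Bland-Altman coverage factor (see [bland_altman()]).
#' @return `data.frame` with one row per group (`xy`, `z`, `rotations`):
#'   `n`, `mean`, `sd`, `limit_upper`, `limit_lower`.
#' @export
summarize_accuracy <- function(records, k = 1.96) {
  along_axis <- function(rec) {
    cols <- ifelse(rec$component_kind == "translation",
                   c(x = "dtx_mm", y = "dty_mm", z = "dtz_mm")[rec$axis],
                   c(x = "dpitch_deg", y = "droll_deg",
                     z = "dyaw_deg")[rec$axis])
    vapply(seq_len(nrow(rec)), function(i) rec[[cols[i]]][i], numeric(1))
  }
  tr <- records[records$component_kind == "translation", ]
  rot <- records[records$component_kind == "rotation", ]
  groups <- list(xy = along_axis(tr[tr$axis %in% c("x", "y"), ]),
                 z = along_axis(tr[tr$axis == "z", ]),
                 rotations = along_axis(rot))
  do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    ba <- bland_altman(v, k = k)
    data.frame(group = g, n = length(v), mean = ba$mean_of_deviations,
               sd = ba$standard_deviation, limit_upper = ba$limit_upper,
               limit_lower = ba$limit_lower)
  }))
}

#' Write accuracy records as CSV
#'
#' Schema:
#' `axis,component_kind,induced_value,repeat,dtx_mm,dty_mm,dtz_mm,dpitch_deg,droll_deg,dyaw_deg,converged`.
#'
#' @param records output of [run_accuracy_protocol()].
#' @param path CSV path.
#' @export
write_accuracy_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
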