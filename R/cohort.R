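#' Cohort shift-simulation configuration
#'
#' Simulates per-subject setup shifts (3 translations in mm, 3 rotations in
#' degrees) for the two positioning workflows compared in trimodality QA:
#' C1 (patient transported between scanners on an air-cushion transfer table,
#' never repositioned) and C2 (patient repositioned on each scanner from mask
#' markings and lasers). Each component is drawn independently as
#' `Normal(offset, spread)`; components are assumed uncorrelated, a modeling
#' choice (correlations between, say, pitch and anterior-posterior shift are
#' plausible but are not modeled).
#'
#' Defaults reproduce the head-and-neck patient-study conditions: 15 subjects
#' per setup, per-setup systematic offsets equal to the reference mean shifts
#' bundled with the package, and spreads derived from the reference
#' interquartile ranges via `IQR / 1.349` (the normal-distribution
#' conversion).
#'
#' @param n_per_setup subjects per setup label (>= 2).
#' @param offsets systematic per-component offsets: either a single numeric
#'   length-6 vector `c(tx, ty, tz, pitch, roll, yaw)` shared by both setups,
#'   or a named list with one such vector per setup. `NULL` uses the bundled
#'   patient-study means.
#' @param spreads per-component standard deviations, same shapes as
#'   `offsets`; all >= 0. `NULL` uses the bundled patient-study IQRs / 1.349.
#' @param setups character vector of setup labels.
#' @param seed integer RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_setup = 15L, offsets = NULL, spreads = NULL,
                          setups = c("C1", "C2"), seed = 1L) {
  n_per_setup <- as.integer(n_per_setup)
  if (n_per_setup < 2L) stop("n_per_setup must be >= 2", call. = FALSE)
  if (is.null(offsets) || is.null(spreads)) {
    ref <- reference_shift_summary("patient")
    ref <- ref[order(match(ref$component, .component_names())), ]
    def_off <- lapply(split(ref, ref$setup), function(d)
      d$mean[match(.component_names(), d$component)])
    def_spr <- lapply(split(ref, ref$setup), function(d)
      d$iqr[match(.component_names(), d$component)] / 1.349)
    if (is.null(offsets)) offsets <- def_off
    if (is.null(spreads)) spreads <- def_spr
  }
  norm6 <- function(x, what, setups) {
    if (is.numeric(x)) {
      if (length(x) != 6L) stop(what, " must have 6 components", call. = FALSE)
      x <- stats::setNames(rep(list(as.numeric(x)), length(setups)), setups)
    }
    if (!all(setups %in% names(x)))
      stop(what, " must cover every setup label", call. = FALSE)
    lapply(x[setups], function(v) {
      if (length(v) != 6L || any(!is.finite(v)))
        stop(what, " entries must be finite length-6 vectors", call. = FALSE)
      as.numeric(v)
    })
  }
  offsets <- norm6(offsets, "offsets", setups)
  spreads <- norm6(spreads, "spreads", setups)
  if (any(unlist(spreads) < 0)) stop("spreads must be >= 0", call. = FALSE)
  structure(list(n_per_setup = n_per_setup, offsets = offsets,
                 spreads = spreads, setups = setups, seed = as.integer(seed)),
            class = "cohort_config")
}

.component_names <- function() {
  c("tx_mm", "ty_mm", "tz_mm", "pitch_deg", "roll_deg", "yaw_deg")
}

#' Simulate a cohort shift table
#'
#' Draws `n_per_setup` subjects per setup label with each of the six shift
#' components independently `Normal(offset_k, spread_k)`. Reproducible: the
#' table is a pure function of the configuration (seed included).
#'
#' @param cfg `cohort_config`.
#' @return `data.frame` (a shift table) with columns
#'   `trial_id, setup, tx_mm, ty_mm, tz_mm, pitch_deg, roll_deg, yaw_deg`.
#' @export
simulate_cohort_shifts <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  comp <- .component_names()
  .with_seed(cfg$seed, {
    rows <- lapply(cfg$setups, function(s) {
      m <- vapply(seq_along(comp), function(k)
        rnorm(cfg$n_per_setup, mean = cfg$offsets[[s]][k],
              sd = cfg$spreads[[s]][k]),
        numeric(cfg$n_per_setup))
      colnames(m) <- comp
      data.frame(setup = s, m, check.names = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- cbind(trial_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}

#' Read / write a shift table as CSV
#'
#' The on-disk schema is exactly
#' `trial_id,setup,tx_mm,ty_mm,tz_mm,pitch_deg,roll_deg,yaw_deg`.
#'
#' @param path CSV file path.
#' @return `read_shift_table`: validated `data.frame`.
#' @export
read_shift_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  .check_shift_table(tab)
}

#' @rdname read_shift_table
#' @param shifts shift table `data.frame`.
#' @export
write_shift_table <- function(shifts, path) {
  shifts <- .check_shift_table(shifts)
  write.csv(shifts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.check_shift_table <- function(tab) {
  need <- c("trial_id", "setup", .component_names())
  if (!all(need %in% names(tab)))
    stop("shift table must have columns: ", paste(need, collapse = ","),
         call. = FALSE)
  tab <- tab[, need]
  if (any(!is.finite(as.matrix(tab[, .component_names()]))))
    stop("shift components must all be finite", call. = FALSE)
  tab
}
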