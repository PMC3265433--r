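# run code with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Cohort simulation configuration
#'
#' Describes a simulated study: `n_subjects` subjects drawn from the four
#' anthropometric presets with proportions `preset_mix`, each lying on
#' every configured surface. Uniform surfaces are given as per-block
#' stiffness in N/mm (defaults: soft 2, firm 100); the entry `"optimized"`
#' requests a per-subject customized arrangement from [optimize_zones()].
#' Subject-to-subject variability is multiplicative log-normal jitter
#' (standard deviation `jitter_sd` on the log scale) applied independently
#' to every segment mass and contour half-width; marker measurement noise
#' is additive Gaussian with `marker_noise_sd` mm on both coordinates.
#' Uniform surfaces are measured `n_repeats` times per subject (two trials
#' per surface in the emulated protocol); the customized arrangement, being
#' the end point of the per-subject tuning, once.
#'
#' @param n_subjects Subjects per surface (>= 1).
#' @param preset_mix Named proportions over HTM/HSM/LTM/LSM, summing to 1.
#' @param surfaces Named list: per-block stiffness (N/mm) or `"optimized"`.
#' @param jitter_sd Log-scale sd of subject jitter (>= 0).
#' @param marker_noise_sd Marker noise sd in mm (>= 0).
#' @param n_repeats Trials per subject on each uniform surface.
#' @param coupling Trunk-bending weight for the equilibrium model.
#' @param bounds Stiffness bounds for the customized arrangement.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 25,
                          preset_mix = c(HTM = 0.25, HSM = 0.25,
                                         LTM = 0.25, LSM = 0.25),
                          surfaces = list(soft = 2, firm = 100,
                                          custom = "optimized"),
                          jitter_sd = 0.05,
                          marker_noise_sd = 2,
                          n_repeats = 2,
                          coupling = 0.1,
                          bounds = c(0.5, 20),
                          seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (abs(sum(preset_mix) - 1) > 1e-9 || any(preset_mix < 0)) {
    stop("preset_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!all(names(preset_mix) %in% anthropometric_presets()$name)) {
    stop("preset_mix must be named by HTM/HSM/LTM/LSM", call. = FALSE)
  }
  if (jitter_sd < 0 || marker_noise_sd < 0) {
    stop("jitter and noise standard deviations must be >= 0", call. = FALSE)
  }
  if (length(surfaces) < 1L || is.null(names(surfaces))) {
    stop("surfaces must be a named list", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 preset_mix = preset_mix, surfaces = surfaces,
                 jitter_sd = jitter_sd, marker_noise_sd = marker_noise_sd,
                 n_repeats = as.integer(n_repeats), coupling = coupling,
                 bounds = bounds, seed = as.integer(seed)),
            class = "cohort_config")
}

# multiplicative log-normal jitter of segment masses and half-widths
jitter_body <- function(body, sd) {
  if (sd == 0) return(body)
  seg <- body$segments
  n <- nrow(seg)
  seg$mass_kg <- seg$mass_kg * exp(stats::rnorm(n, 0, sd))
  seg$half_width_mm <- seg$half_width_mm * exp(stats::rnorm(n, 0, sd))
  body_profile(seg[, c("name", "mass_kg", "extent_mm", "half_width_mm")],
               vertebra_map = body$vertebra_map, name = body$name)
}

add_marker_noise <- function(curve, sd) {
  if (sd == 0) return(curve)
  spinal_curve(curve$vertebra,
               curve$x + stats::rnorm(12, 0, sd),
               curve$y + stats::rnorm(12, 0, sd),
               frame = "raw")
}

#' Generate a synthetic cohort of spinal curves with known ground truth
#'
#' For each subject: draws a preset by the configured mix, jitters the
#' segment masses and half-widths, solves the lying equilibrium on every
#' configured surface (building the customized arrangement per subject
#' where requested), records the noiseless deviation angle as ground truth,
#' and emits marker curves with additive Gaussian noise, one per repeat.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"cohort"`: `index` (data frame: `curve_id`,
#'   `subject`, `surface`, `trial`, `preset`), `curves` (named list of raw
#'   [spinal_curve()]s), `ground_truth` (data frame: `subject`, `surface`,
#'   `preset`, `true_dev_deg`), `arrangements` (per-subject customized
#'   [mattress_arrangement()]s, when a `"custom"` surface is configured),
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    presets <- sample(names(config$preset_mix), n, replace = TRUE,
                      prob = config$preset_mix)
    index <- list(); curves <- list(); truth <- list()
    arrangements <- list()
    for (s in seq_len(n)) {
      sid <- sprintf("S%02d", s)
      body <- jitter_body(build_body(presets[s]), config$jitter_sd)
      for (surf in names(config$surfaces)) {
        spec <- config$surfaces[[surf]]
        if (identical(spec, "optimized")) {
          opt <- optimize_zones(body, bounds = config$bounds,
                                coupling = config$coupling)
          bed <- opt$arrangement
          arrangements[[sid]] <- bed
          reps <- 1L
        } else {
          bed <- uniform_bed(as.numeric(spec), body)
          reps <- config$n_repeats
        }
        eq <- solve_equilibrium(body, bed, coupling = config$coupling)
        truth[[length(truth) + 1L]] <- data.frame(
          subject = sid, surface = surf, preset = presets[s],
          true_dev_deg = compute_p8(eq$curve)$dev_deg,
          stringsAsFactors = FALSE)
        for (r in seq_len(reps)) {
          cid <- sprintf("%s_%s_t%d", sid, surf, r)
          curves[[cid]] <- add_marker_noise(eq$curve,
                                            config$marker_noise_sd)
          index[[length(index) + 1L]] <- data.frame(
            curve_id = cid, subject = sid, surface = surf, trial = r,
            preset = presets[s], stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(index = do.call(rbind, index),
                   curves = curves,
                   ground_truth = do.call(rbind, truth),
                   arrangements = arrangements,
                   config = config),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d surface(s), %d curves (seed %d)\n",
              x$config$n_subjects, length(x$config$surfaces),
              nrow(x$index), x$config$seed))
  invisible(x)
}

#' Write and read a cohort as marker CSV files
#'
#' Writes one marker CSV per curve plus `index.csv` and
#' `ground_truth.csv`; `read_cohort_dir` restores the curves and index
#' (ground truth is reloaded when present).
#'
#' @param cohort A `"cohort"`.
#' @param dir Directory (created if needed).
#' @return The directory (writer, invisibly) or a list with `index`,
#'   `curves` and optionally `ground_truth` (reader).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cid in names(cohort$curves)) {
    write_marker_csv(cohort$curves[[cid]],
                     file.path(dir, paste0(cid, ".csv")))
  }
  utils::write.csv(cohort$index, file.path(dir, "index.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort_dir <- function(dir) {
  index <- utils::read.csv(file.path(dir, "index.csv"),
                           stringsAsFactors = FALSE)
  curves <- lapply(index$curve_id, function(cid) {
    read_marker_csv(file.path(dir, paste0(cid, ".csv")))
  })
  names(curves) <- index$curve_id
  out <- list(index = index, curves = curves)
  gt <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt)) {
    out$ground_truth <- utils::read.csv(gt, stringsAsFactors = FALSE)
  }
  out
}

#' Render a spinal curve as a synthetic marker image
#'
#' Draws a Gaussian-profile bright spot (peak intensity 1, sd =
#' `marker_radius_px / 2`) at every marker position on a dark background,
#' optionally adds the four reference markers of the capture protocol (two
#' 50 mm caudal of L5 at lateral offsets of +/- 30 mm, two 100 mm cephalad
#' of C7, likewise offset), and adds clamped Gaussian pixel noise. The
#' canvas is auto-sized to the markers plus `pad_mm` unless explicit
#' dimensions are given, in which case out-of-canvas markers are an error.
#'
#' @param curve A [spinal_curve()].
#' @param marker_radius_px Marker radius in pixels (>= 2).
#' @param scale mm per pixel.
#' @param noise_sd Additive pixel noise sd (intensity units).
#' @param seed Optional seed for the noise.
#' @param pad_mm Canvas padding around the markers.
#' @param include_reference Add the four reference markers.
#' @param width_px,height_px Optional fixed canvas size.
#' @return A [marker_image()] with attributes `truth` (data frame of spot
#'   centres: `x_px`, `y_px`, `x_mm`, `y_mm`, `is_reference`) and
#'   `origin_mm` (the mm coordinates of pixel (0, 0)).
#' @export
render_marker_image <- function(curve, marker_radius_px = 4, scale = 1,
                                noise_sd = 0, seed = NULL, pad_mm = 30,
                                include_reference = FALSE,
                                width_px = NULL, height_px = NULL) {
  stopifnot(inherits(curve, "spinal_curve"))
  if (marker_radius_px < 2) {
    stop("marker_radius_px must be >= 2", call. = FALSE)
  }
  xs <- curve$x; ys <- curve$y
  is_ref <- rep(FALSE, 12)
  if (include_reference) {
    p_l5 <- as.numeric(curve[curve$vertebra == "L5", c("x", "y")])
    p_c7 <- as.numeric(curve[curve$vertebra == "C7", c("x", "y")])
    u <- (p_c7 - p_l5) / sqrt(sum((p_c7 - p_l5)^2))
    v <- c(-u[2], u[1])
    refs <- rbind(p_l5 - 50 * u + 30 * v, p_l5 - 50 * u - 30 * v,
                  p_c7 + 100 * u + 30 * v, p_c7 + 100 * u - 30 * v)
    xs <- c(xs, refs[, 1]); ys <- c(ys, refs[, 2])
    is_ref <- c(is_ref, rep(TRUE, 4))
  }
  ox <- min(xs) - pad_mm; oy <- min(ys) - pad_mm
  cx <- (xs - ox) / scale; cy <- (ys - oy) / scale
  nc <- if (is.null(width_px)) ceiling(max(cx) + pad_mm / scale) else width_px
  nr <- if (is.null(height_px)) ceiling(max(cy) + pad_mm / scale) else height_px
  if (any(cx < 1 | cx > nc | cy < 1 | cy > nr)) {
    stop("markers fall outside the image canvas", call. = FALSE)
  }
  px <- matrix(0, nr, nc)
  sigma <- marker_radius_px / 2
  col_idx <- seq_len(nc); row_idx <- seq_len(nr)
  for (i in seq_along(cx)) {
    gx <- exp(-(col_idx - cx[i])^2 / (2 * sigma^2))
    gy <- exp(-(row_idx - cy[i])^2 / (2 * sigma^2))
    px <- px + outer(gy, gx)
  }
  px <- pmin(px, 1)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) {
      stats::rnorm(length(px), 0, noise_sd)
    } else {
      with_seed(seed, stats::rnorm(length(px), 0, noise_sd))
    }
    px <- pmin(pmax(px + noise, 0), 1)
  }
  img <- marker_image(px, scale = scale)
  attr(img, "truth") <- data.frame(
    x_px = cx, y_px = cy,
    x_mm = cx * scale, y_mm = cy * scale,
    is_reference = is_ref)
  attr(img, "origin_mm") <- c(x = ox, y = oy)
  img
}

#' Generate a synthetic load-deflection curve
#'
#' Three element families: `linear` (coil spring, F = k d), `cubic`
#' (densifying elastomer, F = a d^3) and `foam` (initial stiffness that
#' relaxes into a plateau, plus cubic densification:
#' F = k0 d exp(-d / d_plateau) + k_dens d^3). Samples are validated
#' against the loading-curve invariants, so a parameter set whose force is
#' not monotone is rejected.
#'
#' @param model `"linear"`, `"cubic"` or `"foam"`.
#' @param k Linear stiffness (N/mm).
#' @param a Cubic coefficient (N/mm^3).
#' @param k0,d_plateau,k_dens Foam parameters (N/mm, mm, N/mm^3).
#' @param f_max Peak force to sample up to (N, > 450).
#' @param step_mm Deflection sampling step.
#' @return A [load_deflection_curve()].
#' @export
#' @examples
#' compute_E(generate_load_curve("linear", k = 1))  # 101250
generate_load_curve <- function(model = c("linear", "cubic", "foam"),
                                k = 1, a = 1e-5, k0 = 3, d_plateau = 40,
                                k_dens = 1.5e-4, f_max = 500,
                                step_mm = 0.5) {
  model <- match.arg(model)
  if (f_max <= 450) stop("f_max must exceed 450 N", call. = FALSE)
  f <- switch(model,
    linear = function(d) k * d,
    cubic = function(d) a * d^3,
    foam = function(d) k0 * d * exp(-d / d_plateau) + k_dens * d^3
  )
  d_hi <- 10
  while (f(d_hi) < f_max) d_hi <- d_hi * 2
  d_max <- stats::uniroot(function(d) f(d) - f_max, c(0, d_hi),
                          tol = 1e-10)$root
  d <- seq(0, d_max, by = step_mm)
  if (d[length(d)] < d_max) d <- c(d, d_max)
  load_deflection_curve(d, f(d))
}
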