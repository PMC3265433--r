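#' Load-deflection curve of a mattress element
#'
#' The loading branch of a compression test: deflection (mm, strictly
#' increasing, starting at 0) against force (N, non-decreasing, starting at
#' 0). The LGA summary requires the curve to reach at least 450 N.
#'
#' @param deflection_mm,force_N Numeric sample vectors of equal length.
#' @return A data frame of class `"load_deflection_curve"` with columns
#'   `deflection_mm`, `force_N`.
#' @seealso [compute_E()], [compute_C()], [lga_metrics()]
#' @export
load_deflection_curve <- function(deflection_mm, force_N) {
  d <- as.numeric(deflection_mm); f <- as.numeric(force_N)
  if (length(d) != length(f) || length(d) < 2L) {
    stop("need matching deflection and force vectors (>= 2 samples)",
         call. = FALSE)
  }
  if (!all(is.finite(d)) || !all(is.finite(f))) {
    stop("samples must be finite", call. = FALSE)
  }
  if (abs(d[1]) > 1e-9 || abs(f[1]) > 1e-9) {
    stop("loading curve must start at (0, 0)", call. = FALSE)
  }
  if (any(diff(d) <= 0)) {
    stop("deflection must be strictly increasing", call. = FALSE)
  }
  if (any(diff(f) < 0)) {
    stop("force must be non-decreasing along the loading branch",
         call. = FALSE)
  }
  out <- data.frame(deflection_mm = d, force_N = f)
  class(out) <- c("load_deflection_curve", "data.frame")
  out
}

# deflection at which the loading curve first reaches force level (N),
# linearly interpolated between the bracketing samples
deflection_at_force <- function(curve, level) {
  d <- curve$deflection_mm; f <- curve$force_N
  if (max(f) < level) {
    stop(sprintf(
      "loading curve peaks at %.4g N, %.4g N short of the required %g N",
      max(f), level - max(f), level), call. = FALSE)
  }
  i <- which(f >= level)[1]
  if (i == 1L) return(d[1])
  if (f[i] == f[i - 1L]) return(d[i])  # flat step ending at the level
  d[i - 1L] + (level - f[i - 1L]) / (f[i] - f[i - 1L]) * (d[i] - d[i - 1L])
}

#' LGA compression work E
#'
#' The work (N mm) needed to compress the element up to a force of 450 N:
#' the trapezoidal integral of force over deflection from 0 to the
#' deflection at which the force first reaches 450 N (that endpoint is hit
#' exactly by linear interpolation of the bracketing samples).
#'
#' @param curve A [load_deflection_curve()] reaching at least 450 N.
#' @return E in N mm.
#' @export
#' @examples
#' lin <- load_deflection_curve(0:500, 0:500)  # 1 N/mm spring
#' compute_E(lin)  # 101250 = 450^2 / 2
compute_E <- function(curve) {
  stopifnot(inherits(curve, "load_deflection_curve"))
  d450 <- deflection_at_force(curve, 450)
  d <- curve$deflection_mm; f <- curve$force_N
  keep <- d < d450
  dd <- c(d[keep], d450)
  ff <- c(f[keep], 450)
  sum(diff(dd) * (utils::head(ff, -1) + utils::tail(ff, -1)) / 2)
}

#' LGA average differential stiffness C
#'
#' The mean of the local slope dF/dd of the loading curve at the three
#' deflections where the force equals 210, 275 and 340 N. The slope at each
#' level is a central finite difference on the sampled curve: the secant
#' across the two samples bracketing the level (across the two neighbours
#' when the level falls exactly on a sample).
#'
#' @param curve A [load_deflection_curve()] spanning at least 340 N.
#' @return C in N/mm.
#' @export
compute_C <- function(curve) {
  stopifnot(inherits(curve, "load_deflection_curve"))
  d <- curve$deflection_mm; f <- curve$force_N
  slope_at <- function(level) {
    dL <- deflection_at_force(curve, level)
    j <- which(abs(d - dL) < 1e-9)
    if (length(j) == 1L && j > 1L && j < length(d)) {
      i0 <- j - 1L; i1 <- j + 1L        # level on a sample: centred difference
    } else {
      i0 <- min(max(findInterval(dL, d), 1L), length(d) - 1L)
      i1 <- i0 + 1L                     # secant across the bracketing samples
    }
    if (f[i1] == f[i0]) {
      stop(sprintf(
        "force is locally flat at the %g N level; slope undefined", level),
        call. = FALSE)
    }
    (f[i1] - f[i0]) / (d[i1] - d[i0])
  }
  mean(vapply(c(210, 275, 340), slope_at, 0))
}

#' Softness class bands on the E/C ratio
#'
#' The LGA E/C ratio (mm^2) increases with softness. Class boundaries are
#' configurable because the standard's official limits are not published
#' here; the defaults anchor the soft class at >= 2000 mm^2 (so the
#' polyurethane/memory-foam example set with E/C = 2476 mm^2 classifies as
#' soft) and the firm class below 1000 mm^2. Bands are closed on their
#' lower edge, so a ratio exactly on a boundary falls in the softer class.
#'
#' @param soft_min Lower edge of the soft band (mm^2).
#' @param firm_max Upper edge (exclusive) of the firm band (mm^2).
#' @return A list of class `"lga_bands"`.
#' @export
lga_bands <- function(soft_min = 2000, firm_max = 1000) {
  if (!is.numeric(soft_min) || !is.numeric(firm_max) ||
      firm_max <= 0 || soft_min <= firm_max) {
    stop("bands must satisfy 0 < firm_max < soft_min", call. = FALSE)
  }
  structure(list(soft_min = soft_min, firm_max = firm_max),
            class = "lga_bands")
}

#' Classify a surface by its E/C ratio
#'
#' @param ratio E/C in mm^2, or an [lga_metrics()] object.
#' @param bands An [lga_bands()] configuration.
#' @return `"soft"`, `"medium"` or `"firm"`.
#' @export
#' @examples
#' classify_surface(2476)  # "soft"
classify_surface <- function(ratio, bands = lga_bands()) {
  stopifnot(inherits(bands, "lga_bands"))
  if (inherits(ratio, "lga_metrics")) ratio <- ratio$ratio
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0) {
    stop("ratio must be a single positive number (mm^2)", call. = FALSE)
  }
  if (ratio >= bands$soft_min) "soft"
  else if (ratio >= bands$firm_max) "medium"
  else "firm"
}

#' LGA stiffness summary of a loading curve
#'
#' Computes E (compression work to 450 N), C (average differential
#' stiffness at 210/275/340 N) and their ratio E/C (mm^2), and classifies
#' the surface under the given bands.
#'
#' @inheritParams compute_E
#' @inheritParams classify_surface
#' @return A list of class `"lga_metrics"` with `E`, `C`, `ratio`,
#'   `surface_class`.
#' @export
lga_metrics <- function(curve, bands = lga_bands()) {
  E <- compute_E(curve)
  C <- compute_C(curve)
  structure(list(E = E, C = C, ratio = E / C,
                 surface_class = classify_surface(E / C, bands)),
            class = "lga_metrics")
}

#' @export
print.lga_metrics <- function(x, ...) {
  cat(sprintf("LGA metrics: E = %.1f N mm, C = %.4g N/mm, E/C = %.1f mm^2 (%s)\n",
              x$E, x$C, x$ratio, x$surface_class))
  invisible(x)
}

#' Zonal stiffness table
#'
#' Ordered zone stiffnesses of a zoned mattress, with values normalized to
#' percent of the stiffest zone for reporting (`normalized_pct`, rounded to
#' one decimal; the raw values are retained).
#'
#' @param zone Zone identifiers (1-6 by convention).
#' @param stiffness_N_per_mm Positive per-block stiffness of each zone.
#' @return A data frame of class `"stiffness_table"`.
#' @export
stiffness_table <- function(zone, stiffness_N_per_mm) {
  k <- as.numeric(stiffness_N_per_mm)
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("all zone stiffnesses must be positive and finite", call. = FALSE)
  }
  out <- data.frame(zone = zone, stiffness_N_per_mm = k,
                    normalized_pct = round(100 * k / max(k), 1))
  class(out) <- c("stiffness_table", "data.frame")
  out
}

#' Normalize a zonal stiffness table to its maximum
#'
#' Each zone's stiffness is expressed as 100 k / max(k) percent (rounded to
#' one decimal for reporting; raw stiffnesses are kept alongside). The
#' stiffest zone is exactly 100 and the result is invariant to rescaling
#' all raw values by a common factor.
#'
#' @param table A [stiffness_table()] or data frame with columns `zone` and
#'   `stiffness_N_per_mm`.
#' @return A [stiffness_table()] with refreshed `normalized_pct`.
#' @export
#' @examples
#' normalize_stiffness(stiffness_table(1:6, c(10, 10, 13, 13, 17, 17)))
normalize_stiffness <- function(table) {
  if (!all(c("zone", "stiffness_N_per_mm") %in% names(table))) {
    stop("table must have columns zone and stiffness_N_per_mm",
         call. = FALSE)
  }
  stiffness_table(table$zone, table$stiffness_N_per_mm)
}

#' Read and write load-deflection and stiffness-table CSV files
#'
#' @param path File path.
#' @param curve A [load_deflection_curve()].
#' @param table A [stiffness_table()].
#' @return The read object, or (invisibly) the path for writers.
#' @export
read_load_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  load_deflection_curve(df$deflection_mm, df$force_N)
}

#' @rdname read_load_csv
#' @export
write_load_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_load_csv
#' @export
read_stiffness_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  stiffness_table(df$zone, df$stiffness_N_per_mm)
}

#' @rdname read_load_csv
#' @export
write_stiffness_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
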