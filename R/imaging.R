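#' Grayscale marker image
#'
#' A frontal-plane camera frame holding bright circular markers on a dark
#' background. Pixels are intensities in \[0, 1\]; `scale` converts pixel
#' units to mm. Pixel centres sit at integer coordinates, x along columns
#' and y along rows, both starting at 1.
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\] (rows = y,
#'   columns = x).
#' @param scale mm per pixel, > 0.
#' @return An object of class `"marker_image"`.
#' @export
marker_image <- function(pixels, scale = 1) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels))) {
    stop("pixels must be a finite numeric matrix", call. = FALSE)
  }
  if (any(pixels < 0 | pixels > 1)) {
    stop("pixel intensities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("scale must be a single positive number (mm per pixel)",
         call. = FALSE)
  }
  structure(list(pixels = pixels, scale = scale), class = "marker_image")
}

#' @export
print.marker_image <- function(x, ...) {
  cat(sprintf("Marker image: %d x %d px, %.4g mm/px\n",
              nrow(x$pixels), ncol(x$pixels), x$scale))
  invisible(x)
}

# 8-connected component labelling of a logical mask by breadth-first search.
# Small images and sparse foregrounds only; returns an integer label matrix.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  cur <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    queue <- seed
    lab[seed] <- cur
    while (length(queue) > 0L) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Detect marker centroids in an image
#'
#' Binarizes the image at `intensity_threshold`, labels 8-connected
#' components, discards components smaller than `min_area` pixels, and
#' returns the intensity-weighted centroid of each remaining component
#' (weights are the original intensities, honouring the sub-pixel locus of
#' the marker centre), converted to mm through the image scale.
#'
#' @param image A [marker_image()].
#' @param intensity_threshold Binarization threshold, strictly in (0, 1).
#' @param min_area Minimum component area in pixels (>= 1).
#' @return A data frame of class `"marker_detection"` with columns `x_mm`,
#'   `y_mm`, `area` (one row per component; zero rows when nothing is
#'   detected, which is not an error).
#' @export
detect_marker_centroids <- function(image, intensity_threshold = 0.5,
                                    min_area = 4) {
  stopifnot(inherits(image, "marker_image"))
  if (intensity_threshold <= 0 || intensity_threshold >= 1) {
    stop("intensity_threshold must lie strictly in (0, 1)", call. = FALSE)
  }
  if (min_area < 1) stop("min_area must be >= 1", call. = FALSE)
  px <- image$pixels
  lab <- label_components(px > intensity_threshold)
  out <- data.frame(x_mm = numeric(0), y_mm = numeric(0), area = integer(0))
  if (any(lab > 0L)) {
    idx <- which(lab > 0L)
    comp <- lab[idx]
    rows <- ((idx - 1L) %% nrow(px)) + 1L
    cols <- ((idx - 1L) %/% nrow(px)) + 1L
    w <- px[idx]
    area <- tabulate(comp)
    sw <- vapply(split(w, comp), sum, 0)
    cx <- vapply(split(w * cols, comp), sum, 0) / sw
    cy <- vapply(split(w * rows, comp), sum, 0) / sw
    keep <- area >= min_area
    out <- data.frame(x_mm = cx[keep] * image$scale,
                      y_mm = cy[keep] * image$scale,
                      area = area[keep])
    rownames(out) <- NULL
  }
  class(out) <- c("marker_detection", "data.frame")
  out
}

#' Order detected centroids into a spinal curve
#'
#' Projects centroids onto the caudal-to-cephalad axis hint, excludes
#' reference markers, and assigns the remaining 12 centroids the labels L5
#' (most caudal) through C7 (most cephalad) in order of projection.
#'
#' Reference markers are placed outside the vertebral chain (two beyond L5,
#' two beyond C7). The chain is identified as a run of 12 centroids,
#' consecutive in longitudinal projection, such that every other centroid
#' lies beyond the run's longitudinal extremes by more than
#' `ref_margin_mm`; those outliers are flagged as reference markers and
#' dropped. When more than one run qualifies, the run with the smoothest
#' lateral profile wins (reference markers sit well off the spinal line).
#' Anything else (fewer than 12 candidates, no admissible run) is an error
#' reporting the count.
#'
#' @param detection A `"marker_detection"` data frame (or any data frame
#'   with `x_mm`, `y_mm`).
#' @param axis_hint Unit-normalizable vector giving the caudal-to-cephalad
#'   direction in the image frame (default: +x).
#' @param ref_margin_mm Exclusion margin in mm (default 30).
#' @return A raw-frame [spinal_curve()]; `x` is the longitudinal projection
#'   and `y` the lateral offset, both in mm.
#' @export
centroids_to_curve <- function(detection, axis_hint = c(1, 0),
                               ref_margin_mm = 30) {
  if (!all(c("x_mm", "y_mm") %in% names(detection))) {
    stop("detection must have columns x_mm and y_mm", call. = FALSE)
  }
  a <- axis_hint / sqrt(sum(axis_hint^2))
  nv <- c(-a[2], a[1])
  t <- detection$x_mm * a[1] + detection$y_mm * a[2]
  s <- detection$x_mm * nv[1] + detection$y_mm * nv[2]
  n <- length(t)
  if (n < 12L) {
    stop(sprintf("expected 12 vertebral centroids, got %d", n),
         call. = FALSE)
  }
  o <- order(t)
  # candidate chains: runs of 12 consecutive projections whose excluded
  # centroids all lie > margin beyond the run's extremes. When several
  # runs qualify, the vertebral chain is the one with the smoothest
  # lateral profile: reference markers sit well off the spinal line, so a
  # run that includes them shows large second differences in the lateral
  # offset, while the true chain is a smooth curve.
  valid <- list(); rough <- numeric(0)
  for (start in seq_len(n - 12L + 1L)) {
    win <- o[start:(start + 11L)]
    rest <- o[-(start:(start + 11L))]
    lo <- t[win[1L]]; hi <- t[win[12L]]
    if (length(rest) == 0L ||
        all(t[rest] < lo - ref_margin_mm | t[rest] > hi + ref_margin_mm)) {
      valid[[length(valid) + 1L]] <- win
      rough[length(rough) + 1L] <- sum(diff(diff(s[win]))^2)
    }
  }
  pick <- NULL
  if (length(valid) == 1L) {
    pick <- valid[[1L]]
  } else if (length(valid) > 1L) {
    best <- which(rough <= min(rough) * (1 + 1e-9))
    if (length(best) == 1L) {
      pick <- valid[[best]]
    } else {
      stop(sprintf("ambiguous vertebral chain among %d centroids", n),
           call. = FALSE)
    }
  }
  if (is.null(pick)) {
    stop(sprintf(
      "expected 12 vertebral centroids after excluding reference markers, got %d",
      n), call. = FALSE)
  }
  spinal_curve(rev(vertebra_labels()), x = t[pick], y = s[pick],
               frame = "raw")
}

#' Read and write plain PGM (P2) grayscale images
#'
#' Text-format portable graymap, the simplest interchange format for
#' grayscale frames; intensities are scaled to \[0, 1\] on read.
#'
#' @param path File path.
#' @param image A [marker_image()].
#' @param maxval Maximum gray value used on write (default 255).
#' @param scale mm per pixel to attach on read (default 1).
#' @return `read_pgm` returns a [marker_image()].
#' @export
read_pgm <- function(path, scale = 1) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tok[1] != "P2") stop("only plain (P2) PGM is supported", call. = FALSE)
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
  maxval <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != nr * nc) stop("corrupt PGM payload", call. = FALSE)
  px <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE) / maxval
  marker_image(px, scale = scale)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(image, path, maxval = 255) {
  stopifnot(inherits(image, "marker_image"))
  px <- round(image$pixels * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), as.character(maxval)), con)
  apply(px, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
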