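#' Fit a line to marker points by orthogonal (total least squares) regression
#'
#' The fitted line minimizes the sum of squared orthogonal distances of the
#' points to the line. Orthogonal regression is used rather than ordinary
#' regression of y on x because marker deviations are perpendicular to the
#' spine axis and the axis orientation in the image is arbitrary; the fit is
#' therefore invariant under rotation of the coordinate frame. The direction
#' is the leading eigenvector of the point covariance, with its sign chosen
#' caudal-to-cephalad, i.e. pointing from the last supplied point towards
#' the first (points are supplied cephalad first, as in a spinal curve).
#'
#' @param points A two-column matrix or data frame of (x, y) coordinates in
#'   mm, ordered cephalad to caudal; at least two distinct points.
#' @return A list with `direction` (unit vector, caudal to cephalad) and
#'   `centroid`.
#' @export
fit_segment_line <- function(points) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2L) {
    stop("points must be a two-column numeric matrix", call. = FALSE)
  }
  if (nrow(pts) < 2L || nrow(unique(pts)) < 2L) {
    stop("need at least 2 distinct points to fit a line", call. = FALSE)
  }
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  dir <- ev$vectors[, 1]
  # orient caudal -> cephalad: first row is the cephalad end
  axis <- pts[1, ] - pts[nrow(pts), ]
  s <- sum(dir * axis)
  if (s < 0 || (s == 0 && (dir[1] < 0 || (dir[1] == 0 && dir[2] < 0)))) {
    dir <- -dir
  }
  list(direction = as.numeric(dir), centroid = as.numeric(ctr))
}

#' Frontal kink angle P8 and its deviation statistic
#'
#' Splits the 12 markers at the thoracolumbar transition (which lies near
#' the unmarked T11, i.e. strictly between the T10 and T12 markers), fits an
#' orthogonal-regression line to the thoracic set (C7, T1, T2, T3, T4, T6,
#' T8, T10) and to the lumbar set (T12, L1, L2, L5), and reports:
#'
#' * `p8_deg`: 180 minus the angle between the two caudal-to-cephalad line
#'   directions, so a perfectly straight spine gives P8 = 180 degrees;
#' * `dev_deg`: the deviation from straightness, 180 - P8 (the "pi - P8"
#'   statistic used as the customization criterion and the dependent
#'   variable of the group comparison);
#' * `chord_dev_mm`: signed orthogonal deviation of every marker from the
#'   L5-C7 chord, a per-vertebra descriptive supplement.
#'
#' All three are invariant under translation, rotation, reflection and
#' uniform scaling of the input, so raw and normalized curves give the same
#' angles.
#'
#' @param curve A [spinal_curve()] (raw or normalized frame).
#' @return A list of class `"frontal_parameters"` with elements `p8_deg`,
#'   `dev_deg` and `chord_dev_mm` (named numeric vector, mm of the input
#'   frame).
#' @export
#' @examples
#' straight <- spinal_curve(vertebra_labels(), seq(0, 660, 60), rep(0, 12))
#' compute_p8(straight)$p8_deg   # 180
compute_p8 <- function(curve) {
  stopifnot(inherits(curve, "spinal_curve"))
  missing <- setdiff(vertebra_labels(), curve$vertebra)
  if (length(missing) > 0L) {
    stop("missing vertebra marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tho <- curve[match(thoracic_labels(), curve$vertebra), c("x", "y")]
  lum <- curve[match(lumbar_labels(), curve$vertebra), c("x", "y")]
  d_t <- fit_segment_line(tho)$direction
  d_l <- fit_segment_line(lum)$direction
  # atan2(|cross|, dot) resolves near-zero angles to machine precision,
  # where acos(dot) bottoms out around 1e-6 degrees
  cross <- d_t[1] * d_l[2] - d_t[2] * d_l[1]
  dev_deg <- atan2(abs(cross), sum(d_t * d_l)) * 180 / pi
  # signed orthogonal distance from the L5-C7 chord
  p_l5 <- as.numeric(curve[curve$vertebra == "L5", c("x", "y")])
  p_c7 <- as.numeric(curve[curve$vertebra == "C7", c("x", "y")])
  chord <- p_c7 - p_l5
  len <- sqrt(sum(chord^2))
  if (len < sqrt(.Machine$double.eps)) {
    stop("zero-length spine: L5 and C7 markers coincide", call. = FALSE)
  }
  nrm <- c(-chord[2], chord[1]) / len
  chord_dev <- (curve$x - p_l5[1]) * nrm[1] + (curve$y - p_l5[2]) * nrm[2]
  names(chord_dev) <- curve$vertebra
  structure(list(p8_deg = 180 - dev_deg,
                 dev_deg = dev_deg,
                 chord_dev_mm = chord_dev),
            class = "frontal_parameters")
}

#' @export
print.frontal_parameters <- function(x, ...) {
  cat(sprintf("P8 = %.3f deg   deviation from straight (180 - P8) = %.3f deg\n",
              x$p8_deg, x$dev_deg))
  cat("chord deviations (mm):\n")
  print(round(x$chord_dev_mm, 2))
  invisible(x)
}
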