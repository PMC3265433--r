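#' Construct a frontal-plane spinal curve
#'
#' A spinal curve holds one frontal-plane coordinate pair per marked
#' vertebra: `x` is the longitudinal position along the body axis (mm,
#' strictly monotone along the chain) and `y` the lateral deviation in the
#' frontal plane (mm). Rows are stored in the canonical cephalad-to-caudal
#' order C7 ... L5 regardless of input order.
#'
#' @param vertebra Character vector of vertebra labels; must contain each of
#'   [vertebra_labels()] exactly once.
#' @param x,y Numeric coordinates in mm (finite).
#' @param frame Coordinate frame tag, `"raw"` or `"normalized"`.
#'
#' @return A data frame of class `"spinal_curve"` with columns `vertebra`,
#'   `x`, `y` and attribute `frame`.
#' @seealso [normalize_curve()], [compute_p8()], [read_marker_csv()]
#' @export
#' @examples
#' cv <- spinal_curve(vertebra_labels(), x = seq(0, 660, by = 60),
#'                    y = rep(0, 12))
#' compute_p8(cv)$dev_deg
spinal_curve <- function(vertebra, x, y, frame = c("raw", "normalized")) {
  frame <- match.arg(frame)
  vertebra <- as.character(vertebra)
  labels <- vertebra_labels()
  missing <- setdiff(labels, vertebra)
  if (length(missing) > 0L) {
    stop("missing vertebra marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(vertebra, labels)
  if (length(extra) > 0L || length(vertebra) != 12L) {
    stop("expected exactly the 12 labels ", paste(labels, collapse = ", "),
         call. = FALSE)
  }
  if (length(x) != 12L || length(y) != 12L) {
    stop("x and y must each have 12 values", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  ord <- match(labels, vertebra)
  x <- as.numeric(x)[ord]
  y <- as.numeric(y)[ord]
  dx <- diff(x)
  if (!(all(dx > 0) || all(dx < 0))) {
    stop("x must be strictly monotone along the vertebral chain",
         call. = FALSE)
  }
  out <- data.frame(vertebra = labels, x = x, y = y,
                    stringsAsFactors = FALSE)
  class(out) <- c("spinal_curve", "data.frame")
  attr(out, "frame") <- frame
  out
}

#' @export
print.spinal_curve <- function(x, ...) {
  cat(sprintf("Spinal curve (%s frame), 12 markers C7-L5\n",
              attr(x, "frame")))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

curve_frame <- function(curve) attr(curve, "frame")

#' Normalize a spinal curve to a common chord
#'
#' Applies the similarity transform (translation, rotation, uniform scale)
#' that maps L5 to (0, 0) and C7 to (1000, 0). Relative geometry, and hence
#' the P8 angle, is preserved exactly; the unit of the normalized frame is
#' "normalized mm" on a fixed 1000 mm L5-C7 chord, so curves from subjects
#' of different size can be overlaid.
#'
#' @param curve A raw-frame [spinal_curve()].
#' @return A `spinal_curve` in the `"normalized"` frame.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "spinal_curve"))
  if (!identical(curve_frame(curve), "raw")) {
    stop("curve is already normalized", call. = FALSE)
  }
  p_l5 <- as.numeric(curve[curve$vertebra == "L5", c("x", "y")])
  p_c7 <- as.numeric(curve[curve$vertebra == "C7", c("x", "y")])
  chord <- p_c7 - p_l5
  len <- sqrt(sum(chord^2))
  if (len < sqrt(.Machine$double.eps)) {
    stop("zero-length spine: L5 and C7 markers coincide", call. = FALSE)
  }
  u <- chord / len          # unit chord direction
  v <- c(-u[2], u[1])       # left-hand normal
  scale <- 1000 / len
  dx <- curve$x - p_l5[1]
  dy <- curve$y - p_l5[2]
  spinal_curve(curve$vertebra,
               x = scale * (dx * u[1] + dy * u[2]),
               y = scale * (dx * v[1] + dy * v[2]),
               frame = "normalized")
}

#' Read and write marker coordinate files
#'
#' Marker CSV files have a header `vertebra,x_mm,y_mm`, one row per marked
#' vertebra, and may contain `#` comment lines. The writer prepends a
#' `# frame: <frame>` comment recording the coordinate frame.
#'
#' @param path File path.
#' @param curve A [spinal_curve()].
#' @return `read_marker_csv` returns a `spinal_curve`; the frame is taken
#'   from a `# frame:` comment when present (default `"raw"`).
#' @export
read_marker_csv <- function(path) {
  lines <- readLines(path)
  frame <- "raw"
  m <- grep("^#\\s*frame:", lines, value = TRUE)
  if (length(m) > 0 && grepl("normalized", m[1])) frame <- "normalized"
  df <- utils::read.csv(text = lines, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("vertebra", "x_mm", "y_mm")
  if (!all(need %in% names(df))) {
    stop("marker CSV must have columns vertebra,x_mm,y_mm", call. = FALSE)
  }
  spinal_curve(df$vertebra, df$x_mm, df$y_mm, frame = frame)
}

#' @rdname read_marker_csv
#' @export
write_marker_csv <- function(curve, path) {
  stopifnot(inherits(curve, "spinal_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame: %s", curve_frame(curve)), con)
  writeLines("vertebra,x_mm,y_mm", con)
  writeLines(sprintf("%s,%.17g,%.17g", curve$vertebra, curve$x, curve$y),
             con)
  invisible(path)
}
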