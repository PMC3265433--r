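#' Anthropometric presets
#'
#' Four reference male body types spanning weight and shoulder-to-pelvis
#' width proportion: Heavy/Light x Triangular/Square. A proportion above
#' 1.45 is termed triangular, otherwise square.
#'
#' @return A data frame with columns `name`, `height_cm`, `weight_kg`,
#'   `shoulder_pelvis_ratio`, `shape`.
#' @export
anthropometric_presets <- function() {
  df <- data.frame(
    name = c("HTM", "HSM", "LTM", "LSM"),
    height_cm = c(181, 183, 182, 184),
    weight_kg = c(103, 93, 74, 76),
    shoulder_pelvis_ratio = c(1.59, 1.33, 1.52, 1.28),
    stringsAsFactors = FALSE
  )
  df$shape <- vapply(df$shoulder_pelvis_ratio, classify_body_shape, "")
  df
}

#' Classify body shape from the shoulder-to-pelvis width ratio
#'
#' @param shoulder_pelvis_ratio Positive ratio of shoulder width (deltoid
#'   distance) to pelvis width.
#' @return `"triangular"` when the ratio is above 1.45, else `"square"`.
#' @export
#' @examples
#' classify_body_shape(1.59)  # triangular
#' classify_body_shape(1.45)  # square (strictly above 1.45 is triangular)
classify_body_shape <- function(shoulder_pelvis_ratio) {
  if (!is.numeric(shoulder_pelvis_ratio) ||
      length(shoulder_pelvis_ratio) != 1L ||
      !is.finite(shoulder_pelvis_ratio) || shoulder_pelvis_ratio <= 0) {
    stop("shoulder_pelvis_ratio must be a single positive number",
         call. = FALSE)
  }
  if (shoulder_pelvis_ratio > 1.45) "triangular" else "square"
}

#' Default segment contour configuration
#'
#' Per-segment mass fractions, longitudinal extent fractions and lateral
#' contour half-widths used by [build_body()]. The six segments (head,
#' shoulder/thorax, waist, pelvis, thigh, leg) approximate a body lying on
#' its side: the pelvis region is both wide and heavy, the thorax is wide
#' (rib cage) but relatively light for its width, and the waist is the
#' narrowest part of the trunk. The shoulder half-width is derived from the
#' pelvis half-width and the preset's shoulder-to-pelvis ratio, so it is
#' `NA` here.
#'
#' `pelvis_spine_fraction` is the cranial fraction of the pelvis extent
#' spanned by the vertebral chain (L5 sits at the sacral end of the spine,
#' within the cranial part of the pelvis segment).
#'
#' @return A list with `mass_fractions`, `extent_fractions`,
#'   `half_widths_mm` (named by segment) and `pelvis_spine_fraction`.
#' @export
body_contour_defaults <- function() {
  segs <- c("head", "shoulder", "waist", "pelvis", "thigh", "leg")
  list(
    mass_fractions = stats::setNames(
      c(0.08, 0.32, 0.12, 0.26, 0.14, 0.08), segs),
    extent_fractions = stats::setNames(
      c(0.13, 0.30, 0.11, 0.10, 0.20, 0.16), segs),
    half_widths_mm = stats::setNames(
      c(90, NA, 140, 150, 120, 70), segs),
    pelvis_spine_fraction = 0.3
  )
}

#' Construct a segmented body profile
#'
#' Splits a body of the given preset into six longitudinal segments with
#' masses `mass_fractions * weight`, extents `extent_fractions * height`
#' and lateral contour half-widths from the contour configuration; the
#' shoulder half-width is `shoulder_pelvis_ratio * pelvis half-width`, so
#' the preset's width proportion is realized exactly. The twelve vertebra
#' markers are distributed linearly from the cranial end of the shoulder
#' segment (C7) across the waist into the cranial part of the pelvis
#' segment (L5).
#'
#' The lateral-lying posture the model assumes (trunk angle 135 degrees,
#' knee flexion 90 degrees, the neutral limb angles) is recorded as
#' metadata; segments are stacked along a straight longitudinal axis.
#'
#' @param preset A preset name (`"HTM"`, `"HSM"`, `"LTM"`, `"LSM"`), a row
#'   of [anthropometric_presets()], or a list with `height_cm`, `weight_kg`,
#'   `shoulder_pelvis_ratio`.
#' @param contour Contour configuration, see [body_contour_defaults()].
#' @return An object of class `"body_profile"`: list with `segments` (data
#'   frame: `name`, `mass_kg`, `extent_mm`, `half_width_mm`),
#'   `vertebra_map` (named numeric, mm from the cranial end), `height_mm`,
#'   `weight_kg`, `shoulder_pelvis_ratio`, `shape`, `posture`.
#' @export
#' @examples
#' b <- build_body("HTM")
#' sum(b$segments$mass_kg)  # 103
build_body <- function(preset, contour = body_contour_defaults()) {
  if (is.character(preset) && length(preset) == 1L) {
    tab <- anthropometric_presets()
    if (!preset %in% tab$name) {
      stop("unknown preset: ", preset, call. = FALSE)
    }
    preset <- as.list(tab[tab$name == preset, ])
  }
  height_mm <- preset$height_cm * 10
  weight_kg <- preset$weight_kg
  ratio <- preset$shoulder_pelvis_ratio
  name <- if (!is.null(preset$name)) preset$name else "custom"
  mf <- contour$mass_fractions
  ef <- contour$extent_fractions
  hw <- contour$half_widths_mm
  segs <- names(mf)
  if (abs(sum(mf) - 1) > 1e-9) {
    stop("mass fractions must sum to 1", call. = FALSE)
  }
  if (abs(sum(ef) - 1) > 1e-9) {
    stop("extent fractions must sum to 1", call. = FALSE)
  }
  hw["shoulder"] <- ratio * hw["pelvis"]
  if (any(!is.finite(hw)) || any(hw <= 0)) {
    stop("contour half-widths must be positive", call. = FALSE)
  }
  segments <- data.frame(
    name = segs,
    mass_kg = as.numeric(mf * weight_kg),
    extent_mm = as.numeric(ef * height_mm),
    half_width_mm = as.numeric(hw[segs]),
    stringsAsFactors = FALSE
  )
  ends <- cumsum(segments$extent_mm)
  starts <- c(0, ends[-length(ends)])
  segments$start_mm <- starts
  segments$end_mm <- ends
  spine_start <- starts[segs == "shoulder"]
  spine_end <- ends[segs == "pelvis"] -
    (1 - contour$pelvis_spine_fraction) * segments$extent_mm[segs == "pelvis"]
  vmap <- stats::setNames(
    spine_start + (seq_len(12) - 1) / 11 * (spine_end - spine_start),
    vertebra_labels())
  structure(list(
    name = name,
    segments = segments,
    vertebra_map = vmap,
    height_mm = height_mm,
    weight_kg = weight_kg,
    shoulder_pelvis_ratio = ratio,
    shape = classify_body_shape(ratio),
    posture = c(trunk_angle_deg = 135, knee_flexion_deg = 90)
  ), class = "body_profile")
}

#' @export
print.body_profile <- function(x, ...) {
  cat(sprintf("Body profile '%s': %.0f cm, %.0f kg, shoulder/pelvis %.2f (%s)\n",
              x$name, x$height_mm / 10, x$weight_kg,
              x$shoulder_pelvis_ratio, x$shape))
  print(x$segments[, c("name", "mass_kg", "extent_mm", "half_width_mm")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Assemble a body profile from explicit segments
#'
#' Lower-level constructor for bespoke bodies (toy models, jittered cohort
#' subjects). No fraction bookkeeping is applied; the caller supplies the
#' segment table directly.
#'
#' @param segments Data frame with columns `name`, `mass_kg`, `extent_mm`,
#'   `half_width_mm`.
#' @param vertebra_map Optional named numeric vector of the 12 vertebra
#'   positions (mm from the cranial end); `NULL` for bodies without a
#'   marked spine.
#' @param name Label for printing.
#' @return A `"body_profile"` object.
#' @export
body_profile <- function(segments, vertebra_map = NULL, name = "custom") {
  need <- c("name", "mass_kg", "extent_mm", "half_width_mm")
  if (!all(need %in% names(segments))) {
    stop("segments must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(segments$mass_kg < 0) || any(segments$extent_mm <= 0) ||
      any(segments$half_width_mm <= 0)) {
    stop("segment masses must be >= 0, extents and half-widths > 0",
         call. = FALSE)
  }
  ends <- cumsum(segments$extent_mm)
  segments$end_mm <- ends
  # starts must be bitwise-identical to the neighbouring ends so that a
  # vertebra sitting exactly on a boundary maps to the caudal segment
  segments$start_mm <- c(0, ends[-length(ends)])
  if (!is.null(vertebra_map)) {
    if (!setequal(names(vertebra_map), vertebra_labels())) {
      stop("vertebra_map must name all 12 vertebrae", call. = FALSE)
    }
    vertebra_map <- vertebra_map[vertebra_labels()]
  }
  structure(list(
    name = name,
    segments = segments,
    vertebra_map = vertebra_map,
    height_mm = sum(segments$extent_mm),
    weight_kg = sum(segments$mass_kg),
    shoulder_pelvis_ratio = NA_real_,
    shape = NA_character_,
    posture = c(trunk_angle_deg = 135, knee_flexion_deg = 90)
  ), class = "body_profile")
}
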