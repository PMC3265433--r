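#' Zoned mattress arrangement
#'
#' A mattress built from free-standing elastic blocks on a rigid base,
#' grouped into longitudinal zones of equal per-block stiffness. Blocks are
#' `block_length_mm` long along the body axis and `block_height_mm` tall
#' (defaults 100 mm and 200 mm, i.e. 20 x 100 x 10 cm blocks spanning the
#' full mattress width); compression saturates at 80 % of the block height.
#' Zones must tile the supported body length.
#'
#' @param stiffness Numeric vector of per-block stiffness (N/mm), one per
#'   zone.
#' @param extent_mm Numeric vector of zone extents along the body axis
#'   (mm), same length as `stiffness`.
#' @param block_length_mm,block_height_mm Block geometry (mm).
#' @return An object of class `"mattress_arrangement"`.
#' @seealso [uniform_bed()], [default_zone_extents()], [solve_equilibrium()]
#' @export
mattress_arrangement <- function(stiffness, extent_mm,
                                 block_length_mm = 100,
                                 block_height_mm = 200) {
  k <- as.numeric(stiffness); ext <- as.numeric(extent_mm)
  if (length(k) != length(ext) || length(k) < 1L) {
    stop("stiffness and extent_mm must have equal positive length",
         call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("zone stiffnesses must be positive", call. = FALSE)
  }
  if (any(!is.finite(ext)) || any(ext <= 0)) {
    stop("zone extents must be positive", call. = FALSE)
  }
  zones <- data.frame(zone = seq_along(k), extent_mm = ext,
                      stiffness_N_per_mm = k)
  zones$end_mm <- cumsum(ext)
  zones$start_mm <- zones$end_mm - ext
  structure(list(zones = zones,
                 block_length_mm = block_length_mm,
                 block_height_mm = block_height_mm),
            class = "mattress_arrangement")
}

#' @export
print.mattress_arrangement <- function(x, ...) {
  cat(sprintf("Zoned mattress: %d zones, blocks %g mm long x %g mm high\n",
              nrow(x$zones), x$block_length_mm, x$block_height_mm))
  print(x$zones[, c("zone", "extent_mm", "stiffness_N_per_mm")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Default six-zone layout for a body
#'
#' Zones 1-2 split the head-plus-shoulder region, zones 3-4 split the
#' waist, zone 5 covers the pelvis and zone 6 the thigh and leg, tiling the
#' full body length. This mirrors the customization layout in which the
#' shoulder area (zones 1-2) and the waist (zones 3-4, against the pelvic
#' zones 5-6 region) are tuned separately.
#'
#' @param body A `"body_profile"`.
#' @return Named numeric vector of six zone extents (mm).
#' @export
default_zone_extents <- function(body) {
  seg <- body$segments
  ext <- function(nm) seg$extent_mm[seg$name == nm]
  shoulder_half <- (ext("head") + ext("shoulder")) / 2
  c(zone1 = shoulder_half, zone2 = shoulder_half,
    zone3 = ext("waist") / 2, zone4 = ext("waist") / 2,
    zone5 = ext("pelvis"), zone6 = ext("thigh") + ext("leg"))
}

#' Uniform bed of a given per-block stiffness
#'
#' @param stiffness Per-block stiffness (N/mm) applied to all six zones.
#' @param body The `"body_profile"` whose length the zones tile.
#' @inheritParams mattress_arrangement
#' @return A [mattress_arrangement()].
#' @export
uniform_bed <- function(stiffness, body, block_length_mm = 100,
                        block_height_mm = 200) {
  mattress_arrangement(rep(stiffness, 6), default_zone_extents(body),
                       block_length_mm = block_length_mm,
                       block_height_mm = block_height_mm)
}

# Summed block stiffness under each body segment: each zone contributes
# stiffness * (overlap length / block length), i.e. blocks are prorated
# continuously over the zone. Errors if any segment is not fully covered.
segment_support <- function(body, bed) {
  seg <- body$segments
  zn <- bed$zones
  if (max(zn$end_mm) < max(seg$end_mm) - 1e-9) {
    stop(sprintf(
      "mattress zones end at %.0f mm but the body extends to %.0f mm: uncovered segment",
      max(zn$end_mm), max(seg$end_mm)), call. = FALSE)
  }
  K <- vapply(seq_len(nrow(seg)), function(i) {
    ov <- pmax(0, pmin(seg$end_mm[i], zn$end_mm) -
                  pmax(seg$start_mm[i], zn$start_mm))
    sum(zn$stiffness_N_per_mm * ov) / bed$block_length_mm
  }, 0)
  stats::setNames(K, seg$name)
}
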