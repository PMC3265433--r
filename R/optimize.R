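#' Customize zonal stiffness to straighten the simulated spine
#'
#' Tunes the per-block stiffness of each mattress zone so that the
#' simulated frontal-plane spinal curve of the given body is as straight as
#' possible, i.e. minimizes the deviation statistic 180 - P8 of the
#' equilibrium curve. The search is deterministic cyclic coordinate
#' descent: starting from a uniform bed at the geometric mean of the
#' bounds, zones are visited in fixed order 1..6 and each zone's stiffness
#' is optimized on the bounded interval by golden-section/parabolic search
#' ([stats::optimize()]); a candidate is accepted only when it strictly
#' improves the deviation. Passes repeat until a full pass improves the
#' deviation by less than `tol` degrees.
#'
#' @param body A `"body_profile"` with a vertebra map.
#' @param bounds Length-2 positive vector, min < max, of admissible
#'   per-block stiffness (N/mm).
#' @param coupling Trunk-bending weight passed to [solve_equilibrium()].
#' @param tol Convergence tolerance on the deviation improvement per pass
#'   (degrees).
#' @param bed Optional starting [mattress_arrangement()]; default is the
#'   uniform geometric-mean bed on [default_zone_extents()].
#' @param max_passes Safety cap on coordinate-descent passes.
#' @return A list of class `"zone_optimum"`: `arrangement` (the optimized
#'   [mattress_arrangement()]), `dev_deg` (achieved deviation),
#'   `start_dev_deg`, `table` (normalized [stiffness_table()]), `improved`
#'   (FALSE when no zone move improved on the starting bed), `passes`.
#' @export
optimize_zones <- function(body, bounds = c(0.5, 20), coupling = 0.1,
                           tol = 1e-4, bed = NULL, max_passes = 25) {
  if (length(bounds) != 2L || any(bounds <= 0) || bounds[1] >= bounds[2]) {
    stop("bounds must be positive with min < max", call. = FALSE)
  }
  if (is.null(body$vertebra_map)) {
    stop("body has no vertebra map; nothing to straighten", call. = FALSE)
  }
  if (is.null(bed)) {
    bed <- uniform_bed(sqrt(prod(bounds)), body)
  }
  dev_of <- function(b) {
    compute_p8(solve_equilibrium(body, b, coupling = coupling)$curve)$dev_deg
  }
  k <- bed$zones$stiffness_N_per_mm
  nz <- length(k)
  make_bed <- function(kk) {
    mattress_arrangement(kk, bed$zones$extent_mm,
                         block_length_mm = bed$block_length_mm,
                         block_height_mm = bed$block_height_mm)
  }
  start_dev <- dev_of(make_bed(k))
  cur_dev <- start_dev
  passes <- 0L
  while (cur_dev > tol) {  # an already-straight start is a fixed point
    passes <- passes + 1L
    pass_start <- cur_dev
    for (z in seq_len(nz)) {
      f <- function(kz) {
        kk <- k; kk[z] <- kz
        dev_of(make_bed(kk))
      }
      cand <- stats::optimize(f, interval = bounds, tol = 1e-4)
      if (cand$objective < cur_dev - 1e-12) {
        k[z] <- cand$minimum
        cur_dev <- cand$objective
      }
    }
    if (pass_start - cur_dev < tol || passes >= max_passes) break
  }
  improved <- cur_dev < start_dev - 1e-12
  if (!improved && start_dev > tol) {
    warning("no zone adjustment improved on the starting arrangement",
            call. = FALSE)
  }
  arrangement <- make_bed(k)
  structure(list(arrangement = arrangement,
                 dev_deg = cur_dev,
                 start_dev_deg = start_dev,
                 table = stiffness_table(seq_len(nz), k),
                 improved = improved,
                 passes = passes),
            class = "zone_optimum")
}

#' @export
print.zone_optimum <- function(x, ...) {
  cat(sprintf(
    "Zone optimization: deviation %.4f deg -> %.4f deg in %d pass(es)\n",
    x$start_dev_deg, x$dev_deg, x$passes))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}
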