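#' Quasi-static equilibrium of a body on a zoned mattress
#'
#' Computes the lying posture of a segmented body on a zoned elastic
#' mattress as the minimum of a quasi-static potential. Each segment `i`
#' rests on the blocks beneath it (summed stiffness `K_i`, see the zone
#' proration in [mattress_arrangement()]); `h_i` is the height of the spine
#' (the body midline) above the rigid base, and the mattress under segment
#' `i` is compressed by `max(w_i - h_i, 0)` where `w_i` is the contour
#' half-width (a segment can bridge clear of the mattress when its
#' neighbours hold it up). The potential is
#'
#'   sum_i 1/2 K_i max(w_i - h_i, 0)^2 + sum_i m_i g h_i
#'     + coupling * sum_j (h_(j-1) - 2 h_j + h_(j+1))^2
#'
#' the elastic energy of the compressed blocks, the gravitational
#' potential, and a trunk-bending penalty on the second differences of the
#' segment heights whose weight `coupling` (N/mm) plays the role of a
#' bending stiffness. With `coupling = 0` the segments decouple and each
#' sinks independently by `m_i g / K_i` (capped at 80 % of the block
#' height, the densification limit). Compression is likewise capped at 80 %
#' of the block height; the minimization is a smooth convex box-constrained
#' problem solved by L-BFGS-B with an analytic gradient.
#'
#' Vertebra markers take the height of the segment beneath them, yielding
#' the frontal-plane spinal curve passed to [compute_p8()].
#'
#' @param body A `"body_profile"`.
#' @param bed A [mattress_arrangement()] covering the body.
#' @param coupling Trunk-bending weight (N/mm), >= 0. Default 0.1, the
#'   package-wide calibration (see the methods vignette).
#' @param g Gravitational acceleration (m/s^2).
#' @return An object of class `"equilibrium_result"`: list with `segments`
#'   (data frame: `name`, `K_N_per_mm`, `sag_mm`, `height_mm`, `contact`),
#'   `spine_heights_mm` (named by vertebra, `NULL` if the body has no
#'   vertebra map), `curve` (a raw [spinal_curve()], ditto), `coupling`,
#'   `converged`.
#' @export
solve_equilibrium <- function(body, bed, coupling = 0.1, g = 9.81) {
  stopifnot(inherits(body, "body_profile"),
            inherits(bed, "mattress_arrangement"))
  if (!is.numeric(coupling) || length(coupling) != 1L || coupling < 0) {
    stop("coupling must be a single non-negative number", call. = FALSE)
  }
  seg <- body$segments
  K <- segment_support(body, bed)
  if (any(K <= 0)) stop("uncovered segment: zero support stiffness",
                        call. = FALSE)
  w <- seg$half_width_mm
  m <- seg$mass_kg
  max_sag <- 0.8 * bed$block_height_mm
  n <- length(w)
  free_sag <- pmin(m * g / K, max_sag)
  if (coupling == 0) {
    h <- w - free_sag
    converged <- TRUE
  } else {
    # second-difference operator over the segment chain
    D2 <- matrix(0, nrow = max(n - 2L, 0L), ncol = n)
    for (j in seq_len(max(n - 2L, 0L))) D2[j, j:(j + 2L)] <- c(1, -2, 1)
    fn <- function(h) {
      comp <- pmax(w - h, 0)
      sum(0.5 * K * comp^2) + sum(m * g * h) +
        coupling * sum((D2 %*% h)^2)
    }
    gr <- function(h) {
      comp <- pmax(w - h, 0)
      -K * comp + m * g + 2 * coupling * as.numeric(crossprod(D2, D2 %*% h))
    }
    opt <- stats::optim(w - free_sag, fn, gr, method = "L-BFGS-B",
                        lower = w - max_sag, upper = rep(Inf, n),
                        control = list(maxit = 500, factr = 1e4))
    if (opt$convergence != 0) {
      stop(sprintf(
        "equilibrium minimization did not converge (code %d, residual %.3g): %s",
        opt$convergence, max(abs(gr(opt$par))), opt$message), call. = FALSE)
    }
    h <- opt$par
    converged <- TRUE
  }
  sag <- pmax(w - h, 0)
  segments <- data.frame(name = seg$name, K_N_per_mm = as.numeric(K),
                         sag_mm = sag, height_mm = h,
                         contact = h <= w + 1e-9,
                         stringsAsFactors = FALSE)
  spine_heights <- NULL
  curve <- NULL
  if (!is.null(body$vertebra_map)) {
    vx <- body$vertebra_map
    idx <- findInterval(vx, seg$start_mm, rightmost.closed = FALSE)
    idx <- pmin(pmax(idx, 1L), n)
    spine_heights <- stats::setNames(h[idx], names(vx))
    curve <- spinal_curve(names(vx), x = as.numeric(vx),
                          y = as.numeric(spine_heights), frame = "raw")
  }
  structure(list(segments = segments,
                 spine_heights_mm = spine_heights,
                 curve = curve,
                 coupling = coupling,
                 converged = converged),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Equilibrium (coupling = %g N/mm):\n", x$coupling))
  print(x$segments, row.names = FALSE, digits = 4)
  if (!is.null(x$curve)) {
    fp <- compute_p8(x$curve)
    cat(sprintf("spinal deviation from straight: %.3f deg\n", fp$dev_deg))
  }
  invisible(x)
}
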