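# Independent oracles and fixture builders for the test suite. These
# deliberately avoid the package's own code paths: the line fit is a
# brute-force angle scan, the ANOVA statistics are spelled out formula by
# formula.

# total-least-squares direction by coarse-to-fine scan of the orthogonal
# residual sum over the line angle (final grid 1e-4 degrees)
oracle_tls_direction <- function(points) {
  pts <- as.matrix(points)
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  resid_sum <- function(theta_deg) {
    th <- theta_deg * pi / 180
    sum((-sin(th) * cc[, 1] + cos(th) * cc[, 2])^2)
  }
  grid <- seq(0, 180, by = 0.1)
  best <- grid[which.min(vapply(grid, resid_sum, 0))]
  for (step in c(0.01, 1e-3, 1e-4)) {
    grid <- seq(best - 10 * step, best + 10 * step, by = step)
    best <- grid[which.min(vapply(grid, resid_sum, 0))]
  }
  th <- best * pi / 180
  d <- c(cos(th), sin(th))
  axis <- pts[1, ] - pts[nrow(pts), ]   # caudal -> cephalad
  if (sum(d * axis) < 0) d <- -d
  d
}

# deviation angle via the scan oracle and an explicit arccos
oracle_dev_deg <- function(curve) {
  tho <- curve[match(thoracic_labels(), curve$vertebra), c("x", "y")]
  lum <- curve[match(lumbar_labels(), curve$vertebra), c("x", "y")]
  d_t <- oracle_tls_direction(tho)
  d_l <- oracle_tls_direction(lum)
  acos(max(-1, min(1, sum(d_t * d_l)))) * 180 / pi
}

# random marker curve: monotone longitudinal spacing, smooth random lateral
# drift (uses the session RNG; seed at the call site)
random_curve <- function(y_scale = 5) {
  x <- cumsum(runif(12, 40, 80))
  y <- cumsum(rnorm(12, 0, y_scale))
  spinal_curve(rev(vertebra_labels()), x, y)
}

# curve with an exact kink of theta degrees between straight lumbar and
# straight thoracic runs, meeting between the T10 and T12 markers
kinked_curve <- function(theta_deg) {
  th <- theta_deg * pi / 180
  lum_x <- c(180, 130, 80, 0)              # T12, L1, L2, L5
  junction <- c(205, 0)
  t_tho <- c(375, 325, 275, 225, 175, 125, 75, 25)  # C7 ... T10
  tho <- cbind(junction[1] + t_tho * cos(th), junction[2] + t_tho * sin(th))
  spinal_curve(
    c(thoracic_labels(), lumbar_labels()),
    x = c(tho[, 1], lum_x),
    y = c(tho[, 2], rep(0, 4))
  )
}

# Welch's heteroscedastic F, step by step
oracle_welch <- function(groups) {
  n <- vapply(groups, length, 0L)
  m <- vapply(groups, mean, 0)
  v <- vapply(groups, stats::var, 0)
  k <- length(groups)
  w <- n / v
  W <- sum(w)
  xw <- sum(w * m) / W
  A <- sum(w * (m - xw)^2) / (k - 1)
  t2 <- sum((1 - w / W)^2 / (n - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * t2
  Fw <- A / B
  df2 <- (k^2 - 1) / (3 * t2)
  list(statistic = Fw, df1 = k - 1, df2 = df2,
       p.value = stats::pf(Fw, k - 1, df2, lower.tail = FALSE))
}

# classical one-way F from explicit sums of squares
oracle_classic <- function(groups) {
  all <- unlist(groups)
  n <- vapply(groups, length, 0L)
  k <- length(groups)
  ssb <- sum(n * (vapply(groups, mean, 0) - mean(all))^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1
  df2 <- length(all) - k
  F <- (ssb / df1) / (ssw / df2)
  list(statistic = F, df1 = df1, df2 = df2,
       p.value = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# pairwise Welch t with Welch-Satterthwaite df, explicit
oracle_welch_t <- function(x, y) {
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

# fixed three-group fixture used across the statistics tests
stats_fixture <- function() {
  list(a = c(10, 12, 14, 16), b = c(11, 13, 15), c = c(20, 22, 24, 26, 28))
}

# apply a similarity transform (rotation deg, scale, translation) to a curve
transform_curve <- function(curve, rot_deg = 0, scale = 1, dx = 0, dy = 0,
                            reflect = FALSE) {
  th <- rot_deg * pi / 180
  x <- curve$x; y <- if (reflect) -curve$y else curve$y
  spinal_curve(curve$vertebra,
               scale * (cos(th) * x - sin(th) * y) + dx,
               scale * (sin(th) * x + cos(th) * y) + dy)
}
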