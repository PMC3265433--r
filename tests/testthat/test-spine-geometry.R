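test_that("spinal_curve validates its marker set and geometry", {
  x <- seq(0, 660, by = 60)
  expect_s3_class(spinal_curve(vertebra_labels(), x, rep(0, 12)),
                  "spinal_curve")
  # rows come back in canonical order whatever the input order
  shuffled <- sample(12)
  cv <- spinal_curve(vertebra_labels()[shuffled], x[shuffled],
                     (x * 0.1)[shuffled])
  expect_identical(cv$vertebra, vertebra_labels())
  expect_equal(cv$y, x * 0.1)
  # a missing marker is an error naming it
  expect_error(spinal_curve(vertebra_labels()[-12], x[-12], rep(0, 11)),
               "L5")
  expect_error(spinal_curve(replace(vertebra_labels(), 5, "T6"), x,
                            rep(0, 12)), "T4")
  expect_error(spinal_curve(vertebra_labels(), rep(1, 12), rep(0, 12)),
               "monotone")
  expect_error(spinal_curve(vertebra_labels(), x, c(NA, rep(0, 11))),
               "finite")
})

test_that("normalize_curve maps the chord to (0,0)-(1000,0) and preserves shape", {
  set.seed(11)
  cv <- random_curve()
  nc <- normalize_curve(cv)
  expect_identical(attr(nc, "frame"), "normalized")
  expect_equal(as.numeric(nc[nc$vertebra == "L5", c("x", "y")]), c(0, 0),
               tolerance = 1e-12)
  expect_equal(as.numeric(nc[nc$vertebra == "C7", c("x", "y")]),
               c(1000, 0), tolerance = 1e-9)
  # collinear input stays collinear: all y exactly 0
  straight <- spinal_curve(vertebra_labels(), seq(0, 660, 60),
                           2 + 0.25 * seq(0, 660, 60))
  expect_equal(normalize_curve(straight)$y, rep(0, 12), tolerance = 1e-9)
  # P8 is unchanged by normalization
  expect_equal(compute_p8(nc)$dev_deg, compute_p8(cv)$dev_deg,
               tolerance = 1e-9)
  # a rotated and scaled copy normalizes to the identical curve
  tc <- transform_curve(cv, rot_deg = 30, scale = 2, dx = 40, dy = -15)
  ntc <- normalize_curve(tc)
  expect_equal(ntc$x, nc$x, tolerance = 1e-9)
  expect_equal(ntc$y, nc$y, tolerance = 1e-9)
  expect_error(normalize_curve(normalize_curve(cv)), "already normalized")
  # degenerate chord: L5 and C7 coincide
  deg_x <- c(0, seq(20, 200, length.out = 10), 0)
  expect_error(spinal_curve(vertebra_labels(), deg_x, rep(0, 12)),
               "monotone")  # cannot even build such a curve monotonically
})

test_that("fit_segment_line is the orthogonal-regression line", {
  flat <- cbind(seq(5, 0, length.out = 6), rep(0, 6))
  expect_equal(fit_segment_line(flat)$direction, c(1, 0), tolerance = 1e-12)
  diag45 <- cbind(5:1, 5:1)
  expect_equal(fit_segment_line(diag45)$direction,
               c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-9)
  expect_error(fit_segment_line(rbind(c(1, 1), c(1, 1))), "distinct")
  # jittered points against the brute-force angle-scan oracle
  set.seed(21)
  for (i in 1:20) {
    pts <- cbind(sort(runif(6, 0, 100), decreasing = TRUE),
                 rnorm(6, 0, 8))
    got <- fit_segment_line(pts)$direction
    want <- oracle_tls_direction(pts)
    ang <- acos(max(-1, min(1, sum(got * want)))) * 180 / pi
    expect_lt(ang, 1e-3)
  }
})

test_that("compute_p8 recovers constructed and random kink angles", {
  straight <- spinal_curve(vertebra_labels(), seq(0, 660, 60), rep(0, 12))
  fp <- compute_p8(straight)
  expect_equal(fp$p8_deg, 180)
  expect_equal(fp$dev_deg, 0)
  expect_equal(unname(fp$chord_dev_mm), rep(0, 12))
  # exact constructed kink between T10 and T12
  expect_equal(compute_p8(kinked_curve(10))$dev_deg, 10, tolerance = 1e-6)
  for (theta in c(1, 5, 17.3, 30)) {
    expect_equal(compute_p8(kinked_curve(theta))$dev_deg, theta,
                 tolerance = 1e-6)
  }
  # random curves against the independent brute-force implementation
  set.seed(31)
  for (i in 1:10) {
    cv <- random_curve()
    expect_equal(compute_p8(cv)$dev_deg, oracle_dev_deg(cv),
                 tolerance = 1e-3)
  }
})

test_that("dev_deg is invariant under similarity transforms", {
  set.seed(41)
  for (i in 1:10) {
    cv <- random_curve(y_scale = 3)
    ref <- compute_p8(cv)$dev_deg
    tc <- transform_curve(cv, rot_deg = runif(1, -25, 25),
                          scale = runif(1, 0.3, 3),
                          dx = runif(1, -500, 500), dy = runif(1, -500, 500),
                          reflect = i %% 2 == 0)
    expect_equal(compute_p8(tc)$dev_deg, ref, tolerance = 1e-9)
  }
})

test_that("dev_deg is zero iff the segment lines are parallel", {
  # two separately-collinear, mutually parallel segments, laterally offset
  th <- 12 * pi / 180
  tho_t <- c(375, 325, 275, 225, 175, 125, 75, 25)   # C7 ... T10
  lum_x <- c(180, 130, 80, 0)                        # T12 ... L5
  cv <- spinal_curve(
    c(thoracic_labels(), lumbar_labels()),
    x = c(205 + tho_t * cos(th), lum_x),
    y = c(30 + tho_t * sin(th), lum_x * tan(th))
  )
  expect_equal(compute_p8(cv)$dev_deg, 0, tolerance = 1e-9)
})

test_that("marker CSV files round-trip with their frame tag", {
  set.seed(51)
  cv <- normalize_curve(random_curve())
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_csv(cv, path)
  back <- read_marker_csv(path)
  expect_identical(attr(back, "frame"), "normalized")
  expect_equal(back$x, cv$x, tolerance = 1e-9)
  expect_equal(back$y, cv$y, tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("x,y\n1,2", bad)
  expect_error(read_marker_csv(bad), "vertebra")
})
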