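#' Compare spinal alignment across surfaces
#'
#' End-to-end replication of the comparison analysis: every input marker
#' curve is normalized, its deviation angle (180 - P8) computed, repeats
#' are averaged per subject and surface, and the surface groups are
#' compared by classical and Welch ANOVA, Levene's test and Tamhane T2
#' post hoc pairs.
#'
#' Curves that fail to parse or validate are skipped with a warning and
#' listed in the report; the run only errors when fewer than two usable
#' groups (or fewer than two subjects in a group) remain. When a group is
#' degenerate (zero variance, e.g. all curves exactly straight), the
#' statistical tests are not applicable and the report records the
#' degeneracy instead.
#'
#' @param inputs A `"cohort"` from [generate_cohort()], a directory written
#'   by [write_cohort()], or a list with `curves` (named list of
#'   [spinal_curve()]) and `index` (data frame: `curve_id`, `subject`,
#'   `surface`).
#' @param alpha Familywise level for the post hoc test.
#' @return A list of class `"run_report"`: `per_subject` (subject, surface,
#'   dev_deg averaged over trials), `group_summary`, `comparison` (a
#'   [group_comparison()] or `NULL`), `degenerate`, `skipped`, `provenance`.
#' @export
run_comparison <- function(inputs, alpha = 0.05) {
  if (is.character(inputs) && length(inputs) == 1L) {
    inputs <- read_cohort_dir(inputs)
  }
  if (is.null(inputs$curves) || is.null(inputs$index)) {
    stop("inputs must provide curves and an index", call. = FALSE)
  }
  index <- inputs$index
  seed <- if (!is.null(inputs$config$seed)) inputs$config$seed else NA_integer_
  devs <- rep(NA_real_, nrow(index))
  skipped <- character(0)
  for (i in seq_len(nrow(index))) {
    cid <- index$curve_id[i]
    devs[i] <- tryCatch({
      cv <- inputs$curves[[cid]]
      if (identical(attr(cv, "frame"), "raw")) cv <- normalize_curve(cv)
      compute_p8(cv)$dev_deg
    }, error = function(e) {
      warning(sprintf("skipping curve %s: %s", cid, conditionMessage(e)),
              call. = FALSE)
      NA_real_
    })
    if (is.na(devs[i])) skipped <- c(skipped, cid)
  }
  ok <- !is.na(devs)
  per_trial <- data.frame(index[ok, c("subject", "surface")],
                          dev_deg = devs[ok])
  agg <- stats::aggregate(dev_deg ~ subject + surface, data = per_trial,
                          FUN = mean)
  agg <- agg[order(agg$surface, agg$subject), ]
  rownames(agg) <- NULL
  counts <- table(agg$surface)
  usable <- names(counts)[counts >= 2L]
  if (length(usable) < 2L) {
    stop("fewer than 2 surfaces with at least 2 subjects each",
         call. = FALSE)
  }
  agg <- agg[agg$surface %in% usable, ]
  groups <- split(agg$dev_deg, agg$surface)
  comparison <- NULL
  degenerate <- NULL
  comparison <- tryCatch(group_comparison(groups, alpha = alpha),
                         error = function(e) {
                           degenerate <<- conditionMessage(e)
                           NULL
                         })
  group_summary <- data.frame(
    surface = names(groups),
    n = vapply(groups, length, 0L),
    mean_dev_deg = vapply(groups, mean, 0),
    sd_dev_deg = vapply(groups, stats::sd, 0),
    stringsAsFactors = FALSE
  )
  rownames(group_summary) <- NULL
  structure(list(
    per_subject = agg,
    group_summary = group_summary,
    comparison = comparison,
    degenerate = degenerate,
    skipped = skipped,
    provenance = list(
      seed = seed,
      n_curves_in = nrow(index),
      n_curves_used = sum(ok),
      alpha = alpha,
      package_version = as.character(utils::packageVersion("spinealign"))
    )
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Alignment comparison report\n")
  print(x$group_summary, row.names = FALSE, digits = 4)
  if (!is.null(x$degenerate)) {
    cat("statistical tests not applicable (degenerate):", x$degenerate, "\n")
  } else if (!is.null(x$comparison)) {
    print(x$comparison)
  }
  if (length(x$skipped) > 0) {
    cat("skipped curves:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize and restore a run report
#'
#' JSON round trip at full double precision; `read_run_report` restores the
#' report structure (data frames and statistics) losslessly.
#'
#' @param report A `"run_report"`.
#' @param path File path (`.json`).
#' @return The path (writer, invisibly) or the restored `"run_report"`.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  payload <- list(
    schema = "spinealign/run_report/1",
    per_subject = report$per_subject,
    group_summary = report$group_summary,
    comparison = if (is.null(report$comparison)) NULL else list(
      summary = report$comparison$summary,
      classic = report$comparison$classic,
      welch = report$comparison$welch,
      levene = report$comparison$levene,
      pairwise = as.data.frame(report$comparison$pairwise),
      alpha = attr(report$comparison$pairwise, "alpha")
    ),
    degenerate = report$degenerate,
    skipped = report$skipped,
    provenance = report$provenance
  )
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_run_report
#' @export
read_run_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  comparison <- NULL
  if (!is.null(p$comparison)) {
    pw <- as.data.frame(p$comparison$pairwise)
    attr(pw, "alpha") <- p$comparison$alpha
    class(pw) <- c("tamhane_t2", "data.frame")
    comparison <- structure(list(
      summary = as.data.frame(p$comparison$summary),
      classic = as.list(p$comparison$classic),
      welch = as.list(p$comparison$welch),
      levene = as.list(p$comparison$levene),
      pairwise = pw
    ), class = "group_comparison")
  }
  structure(list(
    per_subject = as.data.frame(p$per_subject),
    group_summary = as.data.frame(p$group_summary),
    comparison = comparison,
    degenerate = p$degenerate,
    skipped = as.character(p$skipped %||% character(0)),
    provenance = as.list(p$provenance)
  ), class = "run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Customize a mattress for an anthropometric preset
#'
#' Builds the preset body, optimizes the six zone stiffnesses to straighten
#' its simulated spine, and reports the achieved deviation angle against
#' uniform soft and firm baselines together with the normalized zonal
#' stiffness table.
#'
#' @param preset Preset name or object accepted by [build_body()].
#' @param bounds,coupling,tol Passed to [optimize_zones()].
#' @param soft_stiffness,firm_stiffness Per-block stiffness of the baseline
#'   uniform beds (N/mm).
#' @return A list of class `"customization"`: `preset`, `table` (normalized
#'   [stiffness_table()]), `dev_custom_deg`, `dev_soft_deg`,
#'   `dev_firm_deg`, `arrangement`, `optimum` (the full [optimize_zones()]
#'   result).
#' @export
run_customization <- function(preset, bounds = c(0.5, 20), coupling = 0.1,
                              tol = 1e-4, soft_stiffness = 2,
                              firm_stiffness = 100) {
  body <- if (inherits(preset, "body_profile")) preset else build_body(preset)
  dev_on <- function(bed) {
    compute_p8(solve_equilibrium(body, bed, coupling = coupling)$curve)$dev_deg
  }
  dev_soft <- dev_on(uniform_bed(soft_stiffness, body))
  dev_firm <- dev_on(uniform_bed(firm_stiffness, body))
  opt <- optimize_zones(body, bounds = bounds, coupling = coupling,
                        tol = tol)
  structure(list(preset = body$name,
                 table = opt$table,
                 dev_custom_deg = opt$dev_deg,
                 dev_soft_deg = dev_soft,
                 dev_firm_deg = dev_firm,
                 arrangement = opt$arrangement,
                 optimum = opt),
            class = "customization")
}

#' @export
print.customization <- function(x, ...) {
  cat(sprintf("Customization for %s\n", x$preset))
  cat(sprintf(
    "deviation: soft %.2f deg, firm %.2f deg, customized %.3f deg\n",
    x$dev_soft_deg, x$dev_firm_deg, x$dev_custom_deg))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}
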