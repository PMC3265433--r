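# group handling ------------------------------------------------------------

as_group_list <- function(groups, min_n = 2L, check_var = TRUE) {
  if (is.data.frame(groups)) {
    if (!all(c("surface", "dev_deg") %in% names(groups))) {
      stop("data frame input needs columns surface and dev_deg",
           call. = FALSE)
    }
    groups <- split(groups$dev_deg, groups$surface)
  }
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  groups <- lapply(groups, as.numeric)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  ns <- vapply(groups, length, 0L)
  if (any(ns < min_n)) {
    stop(sprintf("every group needs n >= %d", min_n), call. = FALSE)
  }
  if (check_var) {
    vs <- vapply(groups, stats::var, 0)
    if (any(vs <= 0)) {
      stop("zero within-group variance in group(s): ",
           paste(names(groups)[vs <= 0], collapse = ", "), call. = FALSE)
    }
  }
  groups
}

stack_groups <- function(groups) {
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 0L)),
                   levels = names(groups))
  )
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Compares group means without assuming equal variances, using Welch's
#' weighted-means F statistic with its adjusted denominator degrees of
#' freedom. This is the primary omnibus test for the deviation angle across
#' surfaces, whose variances differ strongly between surface types.
#'
#' @param groups A named list of numeric vectors (n >= 2 and positive
#'   variance each), or a long data frame with columns `surface`,
#'   `dev_deg`.
#' @return A list with `statistic` (F_w), `df1`, `df2`, `p.value`,
#'   `method`.
#' @seealso [classic_anova()], [levene_test()], [tamhane_t2()]
#' @export
welch_anova <- function(groups) {
  groups <- as_group_list(groups)
  df <- stack_groups(groups)
  ht <- stats::oneway.test(value ~ group, data = df, var.equal = FALSE)
  list(statistic = unname(ht$statistic),
       df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]),
       p.value = unname(ht$p.value),
       method = "Welch one-way ANOVA")
}

#' Classical one-way ANOVA
#'
#' Standard between/within mean-square F test assuming equal group
#' variances; reported alongside the Welch statistic.
#'
#' @inheritParams welch_anova
#' @return A list with `statistic` (F), `df1`, `df2`, `p.value`, `method`.
#' @export
classic_anova <- function(groups) {
  groups <- as_group_list(groups)
  df <- stack_groups(groups)
  ht <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
  list(statistic = unname(ht$statistic),
       df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]),
       p.value = unname(ht$p.value),
       method = "one-way ANOVA")
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on the absolute deviations of each observation from its
#' group centre. The centre defaults to the group mean (the convention of
#' classical statistical packages); the more robust median centring
#' (Brown-Forsythe) is available by flag.
#'
#' @inheritParams welch_anova
#' @param center `"mean"` (default) or `"median"`.
#' @return A list with `statistic` (W), `df1`, `df2`, `p.value`, `method`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- as_group_list(groups, check_var = FALSE)
  cfun <- if (center == "mean") mean else stats::median
  absdev <- lapply(groups, function(v) abs(v - cfun(v)))
  if (all(unlist(absdev) == 0)) {
    stop("degenerate input: all deviations from the group centre are zero",
         call. = FALSE)
  }
  k <- length(groups)
  n_tot <- length(unlist(groups))
  # equal mean spread in every group: W is exactly 0 (the 0/0 form when the
  # within-group spread of the deviations also vanishes)
  if (stats::var(vapply(absdev, mean, 0)) < .Machine$double.eps) {
    return(list(statistic = 0, df1 = k - 1, df2 = n_tot - k, p.value = 1,
                method = sprintf("Levene test (center = %s)", center)))
  }
  df <- stack_groups(groups)
  ht <- car::leveneTest(df$value, df$group, center = cfun)
  list(statistic = ht[1, "F value"],
       df1 = ht[1, "Df"],
       df2 = ht[2, "Df"],
       p.value = ht[1, "Pr(>F)"],
       method = sprintf("Levene test (center = %s)", center))
}

#' Tamhane's T2 post hoc pairwise comparisons
#'
#' Pairwise comparisons appropriate under heterogeneous variances: each
#' pair is compared by Welch's t statistic with Welch-Satterthwaite
#' degrees of freedom, and the familywise error is controlled by the Sidak
#' inequality over the m = k(k-1)/2 pairs: a pair is significant when its
#' raw p-value falls below 1 - (1 - alpha)^(1/m), and the adjusted p-value
#' reported is min(1, 1 - (1 - p)^m).
#'
#' @inheritParams welch_anova
#' @param alpha Familywise significance level.
#' @return A data frame of class `"tamhane_t2"` with one row per pair:
#'   `group1`, `group2`, `t`, `df`, `p_raw`, `p_adj`, `significant`.
#' @export
tamhane_t2 <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  nm <- names(groups)
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  alpha_pair <- 1 - (1 - alpha)^(1 / m)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    x <- groups[[i1]]; y <- groups[[i2]]
    v1 <- stats::var(x) / length(x)
    v2 <- stats::var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 /
      (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    data.frame(group1 = nm[i1], group2 = nm[i2], t = t, df = df,
               p_raw = p,
               p_adj = min(1, 1 - (1 - p)^m),
               significant = p < alpha_pair,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("tamhane_t2", "data.frame")
  out
}

#' Full group comparison of deviation angles across surfaces
#'
#' Runs the classical and Welch one-way ANOVA, Levene's variance test and
#' Tamhane T2 post hoc comparisons on per-subject deviation angles grouped
#' by surface.
#'
#' @inheritParams welch_anova
#' @param alpha Familywise level for the post hoc test.
#' @return A list of class `"group_comparison"` with elements `summary`
#'   (per-group n, mean, sd), `classic`, `welch`, `levene`, `pairwise`.
#' @export
group_comparison <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  summary <- data.frame(
    surface = names(groups),
    n = vapply(groups, length, 0L),
    mean_dev_deg = vapply(groups, mean, 0),
    sd_dev_deg = vapply(groups, stats::sd, 0),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  structure(list(summary = summary,
                 classic = classic_anova(groups),
                 welch = welch_anova(groups),
                 levene = levene_test(groups),
                 pairwise = tamhane_t2(groups, alpha = alpha)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison of deviation angles (180 - P8, degrees)\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("classic ANOVA: F = %.4g (df %g, %.4g), p = %.3g\n",
              x$classic$statistic, x$classic$df1, x$classic$df2,
              x$classic$p.value))
  cat(sprintf("Welch ANOVA:   F_w = %.4g (df %g, %.4g), p = %.3g\n",
              x$welch$statistic, x$welch$df1, x$welch$df2,
              x$welch$p.value))
  cat(sprintf("Levene:        W = %.4g, p = %.3g\n",
              x$levene$statistic, x$levene$p.value))
  cat("Tamhane T2 pairwise:\n")
  print(as.data.frame(x$pairwise), row.names = FALSE, digits = 4)
  invisible(x)
}
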