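#' One-way fixed-effects analysis of variance
#'
#' Classic omnibus F test for equality of k group means:
#' F = MS_between / MS_within on (k - 1, N - k) degrees of freedom,
#' delegated to [stats::oneway.test()] with `var.equal = TRUE`.
#'
#' @param groups Named list of numeric vectors, one per group; at least two
#'   groups with at least two observations each.
#' @return A `test_result` list: `statistic`, `p_value`, `df` (length 2),
#'   `method`.
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
one_way_anova <- function(groups) {
  check_groups(groups, min_groups = 2L)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(values) == 0) {
    stop("one_way_anova: all observations identical; ",
         "F statistic undefined", call. = FALSE)
  }
  ft <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  test_result(unname(ft$statistic), unname(ft$p.value),
              unname(c(ft$parameter[1], ft$parameter[2])),
              "one-way ANOVA (fixed effects)")
}

#' Levene's test for equality of group variances
#'
#' Homogeneity-of-variance check run before the planned contrasts: a
#' one-way ANOVA on the absolute deviations of each observation from its
#' group centre (mean by default; median gives the Brown-Forsythe
#' variant).
#'
#' @param groups Named list of numeric vectors.
#' @param center `"mean"` or `"median"`.
#' @return A `test_result`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  check_groups(groups, min_groups = 2L)
  cfun <- if (center == "mean") mean else stats::median
  deviations <- lapply(groups, function(g) abs(g - cfun(g)))
  res <- one_way_anova(deviations)
  res$method <- paste0("Levene's test (center = ", center, ")")
  res
}

#' Planned two-group contrast
#'
#' Pre-specified two-sample t contrast between two groups, with pooled
#' variance when the homogeneity assumption holds and the Welch
#' approximation otherwise (the usual consequence of a significant
#' Levene's test). Two-sided p-value.
#'
#' @param g1,g2 Numeric vectors, each with at least two observations.
#' @param variance_mode `"pooled"` or `"welch"`.
#' @return A `test_result`; the statistic is signed as mean(g1) - mean(g2).
#' @export
planned_contrast <- function(g1, g2, variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  check_groups(list(g1, g2), min_groups = 2L)
  if (stats::var(g1) == 0 && stats::var(g2) == 0) {
    if (mean(g1) == mean(g2)) {
      stop("planned_contrast: zero variance in both groups with equal ",
           "means; statistic undefined", call. = FALSE)
    }
  }
  tt <- stats::t.test(g1, g2, var.equal = (variance_mode == "pooled"))
  test_result(unname(tt$statistic), unname(tt$p.value),
              unname(tt$parameter),
              paste0("planned contrast (", variance_mode, " t)"))
}

#' Gate planned contrasts on the omnibus test
#'
#' The planned pairwise contrasts are computed only for metrics whose
#' omnibus ANOVA is significant: strictly below `alpha`.
#'
#' @param omnibus A `test_result` from [one_way_anova()].
#' @param alpha Significance level.
#' @return `TRUE` iff the omnibus p-value is strictly below `alpha`.
#' @export
gate_contrasts <- function(omnibus, alpha = 0.05) {
  stopifnot(is.list(omnibus), is.numeric(omnibus$p_value),
            alpha > 0, alpha < 1)
  omnibus$p_value < alpha
}

#' Pearson correlation with t-based test
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A `test_result` with the correlation coefficient in `statistic`
#'   and the t-test degrees of freedom in `df`; `estimate` carries r as
#'   well.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 3L) {
    stop("pearson_correlation: need equal lengths >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("pearson_correlation: zero variance input; r undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  res <- test_result(unname(ct$estimate), unname(ct$p.value),
                     unname(ct$parameter), "Pearson correlation")
  res$t_statistic <- unname(ct$statistic)
  res
}

#' Advisory normality check
#'
#' One-sample Kolmogorov-Smirnov test of each group against a normal
#' distribution with the group's own mean and SD. Advisory only: no
#' downstream branch depends on it.
#'
#' @param groups Named list of numeric vectors.
#' @return Data frame with group, statistic and p-value.
#' @export
normality_check <- function(groups) {
  check_groups(groups, min_groups = 1L)
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    kt <- suppressWarnings(
      stats::ks.test(g, "pnorm", mean = mean(g), sd = stats::sd(g)))
    data.frame(group = nm, statistic = unname(kt$statistic),
               p_value = unname(kt$p.value))
  })
  do.call(rbind, rows)
}

#' Three-group comparison for one metric
#'
#' Runs the study's statistical design for a single metric: descriptive
#' per-group summaries, omnibus one-way ANOVA, Levene's test, and - only
#' when the omnibus test is significant at `alpha` - the three planned
#' pairwise contrasts, pooled when Levene's p >= 0.05 and Welch otherwise.
#'
#' @param groups Named list of numeric vectors (one per group, typically
#'   `MS_ON`, `MS_noON`, `healthy`).
#' @param alpha Significance level for the omnibus gate.
#' @return List with `summary` (data frame of n/mean/sd per group),
#'   `anova`, `levene`, `contrasts` (data frame, or `NULL` when gated
#'   out) and `gated` (logical).
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  check_groups(groups, min_groups = 2L)
  summary_df <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    row.names = NULL
  )
  omnibus <- one_way_anova(groups)
  lev <- levene_test(groups)
  contrasts <- NULL
  gated <- gate_contrasts(omnibus, alpha)
  if (gated) {
    mode <- if (lev$p_value >= 0.05) "pooled" else "welch"
    pairs <- utils::combn(names(groups), 2L)
    contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      ct <- planned_contrast(groups[[a]], groups[[b]], mode)
      data.frame(group1 = a, group2 = b, statistic = ct$statistic,
                 df = ct$df, p_value = ct$p_value, mode = mode)
    }))
  }
  list(summary = summary_df, anova = omnibus, levene = lev,
       contrasts = contrasts, gated = gated)
}

# internal: test-result container shared by all statistics
test_result <- function(statistic, p_value, df, method) {
  structure(list(statistic = statistic, p_value = p_value, df = df,
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4f, df %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(x$df, 4), collapse = "/"),
              x$p_value))
  invisible(x)
}

# internal: validate a list-of-groups argument
check_groups <- function(groups, min_groups) {
  if (!is.list(groups) || length(groups) < min_groups) {
    stop("need at least ", min_groups, " group(s)", call. = FALSE)
  }
  ok <- vapply(groups, function(g) is.numeric(g) && length(g) >= 2L,
               logical(1))
  if (!all(ok)) {
    stop("each group needs at least two numeric observations",
         call. = FALSE)
  }
  invisible(TRUE)
}
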