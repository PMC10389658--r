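# Replication statistics: linear associations, chi-squared presence/absence
# tests, ordinal group summaries, two-group mean comparisons and the Pearson
# correlogram.  All operations use pairwise-complete deletion of missing
# values and report the n actually analysed.

#' Ordinary linear association between two variables
#'
#' Least-squares fit of `y` on `x` with `r2` equal to the squared Pearson
#' correlation and a two-sided t-test on the slope.  Pairs with a missing
#' value are dropped (count in `n_dropped`).  A constant `y` returns slope 0
#' and r2 0 by convention with `p = NA`; a constant `x` is rejected.
#'
#' @param x,y paired numeric vectors.
#' @return object of class `linear_fit`: `n`, `slope`, `intercept`, `r2`,
#'   `p`, `n_dropped`.
#' @export
linear_assoc <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("x has zero variance", call. = FALSE)
  if (stats::var(y) == 0) {
    fit <- list(n = n, slope = 0, intercept = mean(y), r2 = 0, p = NA_real_,
                n_dropped = n_dropped)
    return(structure(fit, class = "linear_fit"))
  }
  m <- stats::lm(y ~ x)
  sm <- summary(m)
  structure(
    list(n = n,
         slope = unname(stats::coef(m)[2]),
         intercept = unname(stats::coef(m)[1]),
         r2 = unname(stats::cor(x, y)^2),
         p = unname(sm$coefficients[2, 4]),
         n_dropped = n_dropped),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit: n = %d, slope = %.6g, intercept = %.6g, R2 = %.4f, p = %.4g\n",
              x$n, x$slope, x$intercept, x$r2, x$p))
  invisible(x)
}

#' Dichotomize a continuous variable
#'
#' `rule = "median"` splits at the sample median with exact-median ties
#' assigned to the lower group; `rule = "threshold"` splits at `threshold`.
#' `TRUE` marks values above the split.
#'
#' @param values numeric vector (`NA` passes through).
#' @param rule `"median"` or `"threshold"`.
#' @param threshold split point when `rule = "threshold"`.
#' @return logical vector.
#' @export
dichotomize <- function(values, rule = c("median", "threshold"), threshold = NULL) {
  rule <- match.arg(rule)
  if (rule == "median") {
    v <- values[!is.na(values)]
    if (length(unique(v)) < 2) stop("all values equal: median split undefined",
                                    call. = FALSE)
    values > stats::median(v)
  } else {
    if (is.null(threshold)) stop("threshold required", call. = FALSE)
    values > threshold
  }
}

#' Chi-squared test of a presence/absence trait against a dichotomized
#' environment
#'
#' Pearson chi-squared on the 2x2 table of trait presence against the
#' environmental split, without continuity correction by default.  Expected
#' cell counts below 5 set a `low_expected` flag.  Pairs with a missing
#' value are dropped.
#'
#' @param trait logical vector (trait present).
#' @param env_high logical vector (environment above split).
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return object of class `contingency_result`: `table`, `chi2`, `p`,
#'   `expected_minimum`, `low_expected`, `correction_applied`, `n`.
#' @export
chi_square_presence <- function(trait, env_high, correct = FALSE) {
  stopifnot(length(trait) == length(env_high))
  keep <- !is.na(trait) & !is.na(env_high)
  trait <- trait[keep]; env_high <- env_high[keep]
  tab <- table(factor(trait, levels = c(FALSE, TRUE)),
               factor(env_high, levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a zero marginal row/column makes the test undefined", call. = FALSE)
  }
  # chisq.test's own small-sample warning is redundant with the
  # expected_minimum / low_expected fields reported below
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(
    list(table = tab,
         chi2 = unname(ct$statistic),
         p = unname(ct$p.value),
         expected_minimum = min(ct$expected),
         low_expected = min(ct$expected) < 5,
         correction_applied = correct,
         n = sum(tab)),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("chi-squared: X2 = %.4f, p = %.4g, n = %d%s\n", x$chi2, x$p, x$n,
              if (x$low_expected) " [expected cell count < 5]" else ""))
  invisible(x)
}

# boxplot-style summary shared by group_summary and summarize_by_class:
# type-7 quartiles and Tukey whiskers at 1.5 IQR (whisker = most extreme
# observation inside the fence)
boxplot_stats <- function(x, quantile_type = 7) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = quantile_type, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = if (length(inside)) min(inside) else NA_real_,
       whisker_hi = if (length(inside)) max(inside) else NA_real_,
       outliers = sort(x[x < lo_fence | x > hi_fence]))
}

#' Boxplot statistics of a variable by ordinal level
#'
#' One row per occupied level (0-3, e.g. tone-system complexity) with n,
#' median, quartiles, Tukey whisker bounds and the outlying observations.
#'
#' @param values numeric vector.
#' @param level integer ordinal vector in 0-3, paired with `values`.
#' @param quantile_type quartile algorithm.
#' @return tibble with one row per occupied level; `outliers` is a list
#'   column.
#' @export
group_summary <- function(values, level, quantile_type = 7) {
  stopifnot(length(values) == length(level))
  if (any(!is.na(level) & !level %in% 0:3)) {
    stop("levels must be in 0-3", call. = FALSE)
  }
  keep <- !is.na(values) & !is.na(level)
  values <- values[keep]; level <- level[keep]
  rows <- lapply(sort(unique(level)), function(lv) {
    s <- boxplot_stats(values[level == lv], quantile_type = quantile_type)
    tibble::tibble(level = lv, n = s$n, median = s$median, q1 = s$q1,
                   q3 = s$q3, whisker_lo = s$whisker_lo,
                   whisker_hi = s$whisker_hi, outliers = list(s$outliers))
  })
  do.call(rbind, rows)
}

#' Two-group mean comparison
#'
#' Group means with a p-value from Welch's unequal-variance t-test.  If both
#' groups are constant the p-value degenerates: 1 when the means agree, 0
#' otherwise.  Groups of size < 2 yield means with `p = NA`.
#'
#' @param values numeric vector.
#' @param flag logical vector defining the two groups.
#' @return list: `mean_true`, `mean_false`, `n_true`, `n_false`, `p`.
#' @export
two_group_means <- function(values, flag) {
  stopifnot(length(values) == length(flag))
  keep <- !is.na(values) & !is.na(flag)
  values <- values[keep]; flag <- flag[keep]
  a <- values[flag]; b <- values[!flag]
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  out <- list(mean_true = mean(a), mean_false = mean(b),
              n_true = length(a), n_false = length(b), p = NA_real_)
  if (length(a) < 2 || length(b) < 2) return(out)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    out$p <- if (mean(a) == mean(b)) 1 else 0
    return(out)
  }
  out$p <- stats::t.test(a, b, var.equal = FALSE)$p.value
  out
}

#' Pairwise Pearson correlation matrix
#'
#' Symmetric matrix of Pearson correlation coefficients over
#' pairwise-complete observations, unit diagonal.  Variables with zero
#' variance are dropped (with a warning) rather than emitted as NA rows.
#'
#' @param table data frame of observations.
#' @param variables character vector of (numeric) column names; default all
#'   numeric columns.
#' @return correlation matrix.
#' @export
correlogram <- function(table, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  stopifnot(length(variables) >= 2, all(variables %in% names(table)))
  m <- as.matrix(table[variables])
  v <- apply(m, 2, function(col) stats::var(col, na.rm = TRUE))
  degenerate <- !is.finite(v) | v == 0
  if (any(degenerate)) {
    warning("dropping zero-variance variables: ",
            paste(variables[degenerate], collapse = ", "), call. = FALSE)
    m <- m[, !degenerate, drop = FALSE]
  }
  if (ncol(m) < 2) stop("fewer than 2 usable variables", call. = FALSE)
  r <- stats::cor(m, use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}

#' Plot a correlogram
#'
#' Dot-style display of a correlation matrix: dot area scales with the
#' magnitude of the coefficient, hue encodes its sign.
#'
#' @param r correlation matrix from [correlogram()].
#' @return a ggplot object.
#' @export
plot_correlogram <- function(r) {
  df <- expand.grid(var_x = colnames(r), var_y = rownames(r),
                    stringsAsFactors = FALSE)
  df$r <- as.vector(t(r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var_x, y = .data$var_y,
                                   size = abs(.data$r), colour = .data$r)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient2(low = "firebrick", mid = "white",
                                    high = "steelblue", limits = c(-1, 1)) +
    ggplot2::scale_size_area(max_size = 8, limits = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, colour = "r", size = "|r|")
}
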