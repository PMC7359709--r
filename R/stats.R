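#' Linear fit constrained through the origin
#'
#' Validation fit for measured-vs-reference quantities that must agree
#' identically (e.g. image-measured length against caliper length): a
#' least-squares line with the intercept constrained to (0,0). The slope is
#' Sxy / Sxx. Because the centered coefficient of determination is undefined
#' in intent for forced-origin fits (it can be negative), the uncentered
#' R^2 = 1 - SSres / Syy is reported, with significance from the F statistic
#' on (1, n-1) degrees of freedom.
#'
#' @param x reference values (e.g. caliper-measured lengths).
#' @param y measured values.
#' @return object of class `fit_result`: `slope`, `r_squared`, `f_statistic`,
#'   `p_value`, `n`, `df`.
#' @examples
#' fit_through_origin(1:10, 1:10) # slope 1, R^2 1
#' @export
fit_through_origin <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least two points", call. = FALSE)
  sxx <- sum(x^2)
  if (sxx == 0) stop("all x are zero: slope undefined", call. = FALSE)
  slope <- sum(x * y) / sxx
  ss_res <- sum((y - slope * x)^2)
  ss_tot <- sum(y^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  f <- if (r2 >= 1) Inf else r2 / (1 - r2) * (n - 1)
  p <- stats::pf(f, 1, n - 1, lower.tail = FALSE)
  structure(list(slope = slope, r_squared = r2, f_statistic = f, p_value = p,
                 n = n, df = c(1L, n - 1L)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> slope = %.6g, R^2 = %.4g, F(%d, %d) = %.4g, p = %.3g, n = %d\n",
              x$slope, x$r_squared, x$df[1], x$df[2], x$f_statistic, x$p_value, x$n))
  invisible(x)
}

#' F statistic implied by R-squared in single-predictor regression
#'
#' The regression-ANOVA identity F = R^2 (n - 2) / (1 - R^2) for an ordinary
#' least-squares fit with intercept and one predictor; used as an internal
#' consistency check between reported R^2 and F values.
#'
#' @param r_squared coefficient of determination in `[0, 1]`.
#' @param n number of observations (>= 3).
#' @return the F statistic on (1, n - 2) degrees of freedom.
#' @export
f_from_r_squared <- function(r_squared, n) {
  if (r_squared < 0 || r_squared > 1) stop("R^2 must lie in [0, 1]", call. = FALSE)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (r_squared >= 1) return(Inf)
  r_squared * (n - 2) / (1 - r_squared)
}

#' Read a platelet/fibrin accumulation table
#'
#' Expects columns `sample_id`, `material_group` (PVA, ePTFE or
#' collagen_ePTFE), `platelets_per_mm` (billions per mm graft length),
#' `fibrin` (endpoint units) and `average_luminal_area` (mm^2).
#'
#' @param path CSV path.
#' @return data frame of accumulation records.
#' @export
read_accumulation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "material_group", "platelets_per_mm", "fibrin",
              "average_luminal_area")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("accumulation table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  num <- c("platelets_per_mm", "fibrin", "average_luminal_area")
  if (any(vapply(df[num], function(v) any(v < 0, na.rm = TRUE), TRUE))) {
    stop("accumulation measurements must be non-negative", call. = FALSE)
  }
  df
}

#' Regress luminal area on an accumulation endpoint within one material group
#'
#' Ordinary least squares (with intercept) of average luminal cross-sectional
#' area on the platelet or fibrin endpoint for the records of one material
#' type, with the regression-ANOVA F test of the correlation. More deposition
#' should narrow the lumen, so the expected slope sign is negative.
#'
#' @param records accumulation records (see [read_accumulation_csv()]) for a
#'   single group.
#' @param predictor `"platelets"` (column `platelets_per_mm`) or `"fibrin"`.
#' @return a `fit_result` (slope, uncentered-convention fields as for
#'   regression with intercept: R^2, F on (1, n-2), p, n).
#' @export
correlate_group <- function(records, predictor = c("platelets", "fibrin")) {
  predictor <- match.arg(predictor)
  col <- if (predictor == "platelets") "platelets_per_mm" else "fibrin"
  x <- records[[col]]
  y <- records[["average_luminal_area"]]
  if (is.null(x) || is.null(y)) stop("records lack required columns", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 records per group", call. = FALSE)
  if (stats::var(x) == 0) stop("predictor has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("response has zero variance", call. = FALSE)
  r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  f <- f_from_r_squared(r2, n)
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  structure(list(slope = unname(stats::coef(fit)[2]), r_squared = r2,
                 f_statistic = f, p_value = p, n = n, df = c(1L, n - 2L)),
            class = "fit_result")
}

#' Significance of a correlation at level alpha
#'
#' Strict inequality: `p == alpha` is not significant.
#'
#' @param fit a `fit_result`.
#' @param alpha significance level (default 0.05).
#' @return logical.
#' @export
significance_flag <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "fit_result"))
  fit$p_value < alpha
}

#' Per-group, per-predictor correlation table
#'
#' Runs [correlate_group()] for every material group and both endpoints and
#' returns the tidy results table (group, predictor, n, slope, R^2, F, p,
#' significant at `alpha`).
#'
#' @param records accumulation records for the whole study.
#' @param alpha significance level for the flag column.
#' @return data frame, one row per group x predictor.
#' @export
correlation_table <- function(records, alpha = 0.05) {
  groups <- unique(records$material_group)
  rows <- list()
  for (g in groups) {
    sub <- records[records$material_group == g, , drop = FALSE]
    for (pr in c("platelets", "fibrin")) {
      fit <- correlate_group(sub, pr)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, predictor = pr, n = fit$n, slope = fit$slope,
        r_squared = fit$r_squared, f_statistic = fit$f_statistic,
        p_value = fit$p_value, significant = significance_flag(fit, alpha))
    }
  }
  do.call(rbind, rows)
}
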