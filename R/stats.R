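#' Theil-Sen robust trend with Mann-Kendall significance
#'
#' The slope is the median of the slopes of all lines through pairs of
#' points; the intercept is `median(y) - slope * median(t)`. Significance
#' is assessed with the Mann-Kendall test (Kendall rank correlation of y
#' against time). The interannual variability (IAV) is the sample SD of
#' the residuals about the fitted line.
#'
#' @param t time axis (distinct values, n >= 3).
#' @param y series values.
#' @return object of class `trend_result`: list with `slope`,
#'   `intercept`, `iav`, `n`, `p_value`.
#' @export
#' @examples
#' theil_sen(0:2, c(0, 1, 4))$slope  # 2 (median of 1, 3, 2)
theil_sen <- function(t, y) {
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  n <- length(t)
  if (n < 3) stop("insufficient data: need at least 3 points")
  if (anyDuplicated(t)) stop("time values must be distinct")
  dt <- outer(t, t, "-")
  dy <- outer(y, y, "-")
  slope <- stats::median(dy[lower.tri(dy)] / dt[lower.tri(dt)])
  intercept <- stats::median(y) - slope * stats::median(t)
  resid <- y - (intercept + slope * t)
  p <- suppressWarnings(
    stats::cor.test(t, y, method = "kendall", exact = FALSE)$p.value)
  structure(list(slope = slope, intercept = intercept,
                 iav = stats::sd(resid), n = n, p_value = p),
            class = "trend_result")
}

#' Interannual variability about a Theil-Sen trend
#'
#' Sample SD (n-1 denominator) of the residuals about the robust trend
#' line. Invariant to adding a constant to the series; zero for an exact
#' line.
#'
#' @param t time axis.
#' @param y series values.
#' @param trend optional precomputed [theil_sen()] result for the same
#'   series.
#' @return IAV in the units of `y`.
#' @export
iav <- function(t, y, trend = NULL) {
  if (is.null(trend)) trend <- theil_sen(t, y)
  stats::sd(y - (trend$intercept + trend$slope * t))
}

#' Taylor-diagram agreement statistics
#'
#' Pearson correlation, normalized SD (`SD(pred)/SD(obs)`) and centered
#' RMSE between an observed and a predicted series. The three satisfy the
#' law-of-cosines identity
#' `cRMSE^2 = SD_p^2 + SD_o^2 - 2 SD_p SD_o r`.
#'
#' @param obs,pred equal-length series (n >= 3).
#' @return list with `r`, `sd_obs`, `sd_pred`, `norm_sd`, `crmse` (in the
#'   units of the series) and `bias` (mean pred - mean obs).
#' @export
taylor_stats <- function(obs, pred) {
  keep <- is.finite(obs) & is.finite(pred)
  obs <- obs[keep]; pred <- pred[keep]
  if (length(obs) < 3) stop("need at least 3 paired values")
  sd_o <- stats::sd(obs); sd_p <- stats::sd(pred)
  if (sd_o == 0 || sd_p == 0) stop("undefined statistic: zero variance")
  r <- stats::cor(obs, pred)
  crmse <- sqrt(mean(((pred - mean(pred)) - (obs - mean(obs)))^2) *
                  length(obs) / (length(obs) - 1))
  list(r = r, sd_obs = sd_o, sd_pred = sd_p, norm_sd = sd_p / sd_o,
       crmse = crmse, bias = mean(pred) - mean(obs))
}

#' Climate-binned mean scores
#'
#' Bins points along one or more climate axes (half-open intervals
#' `[lo, hi)`) and reports the arithmetic mean of the value within each
#' cell; cells with `count <= min_count` are masked (mean set to NA but
#' the count retained). Default axis widths follow the convention of 5
#' degC in air temperature, 0.4 kPa in vapor pressure deficit and 0.1 in
#' soil water availability.
#'
#' @param values score values per point (e.g. trend or correlation at a
#'   grid point).
#' @param climate data.frame of climate coordinates per point.
#' @param axes named list of bin-edge vectors, one per column of
#'   `climate`.
#' @param min_count mask threshold: cells need strictly more than
#'   `min_count` points (default 20).
#' @return object of class `score_grid`: data.frame with per-axis
#'   `<axis>_lo`/`<axis>_hi` columns, `mean` and `count`, one row per
#'   non-empty cell.
#' @export
binned_score <- function(values, climate, axes, min_count = 20) {
  stopifnot(is.data.frame(climate), nrow(climate) == length(values),
            all(names(axes) %in% names(climate)))
  if (length(values) == 0) {
    out <- data.frame()
    class(out) <- c("score_grid", "data.frame")
    return(out)
  }
  idx <- lapply(names(axes), function(ax) {
    cut(climate[[ax]], breaks = axes[[ax]], right = FALSE,
        include.lowest = FALSE, labels = FALSE)
  })
  names(idx) <- names(axes)
  inrange <- Reduce(`&`, lapply(idx, function(i) !is.na(i)))
  cellkey <- do.call(paste, c(idx, sep = "|"))[inrange]
  vals <- values[inrange]
  cells <- split(seq_along(vals), cellkey)
  rows <- lapply(names(cells), function(k) {
    ii <- cells[[k]]
    bins <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    row <- list()
    for (j in seq_along(axes)) {
      ax <- names(axes)[j]
      row[[paste0(ax, "_lo")]] <- axes[[ax]][bins[j]]
      row[[paste0(ax, "_hi")]] <- axes[[ax]][bins[j] + 1]
    }
    row$mean <- if (length(ii) > min_count) mean(vals[ii]) else NA_real_
    row$count <- length(ii)
    as.data.frame(row)
  })
  out <- do.call(rbind, rows)
  out <- out[do.call(order, out[seq_len(2 * length(axes))]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("score_grid", "data.frame")
  out
}

#' Standardized multiple regression with variance partitioning
#'
#' Ordinary least squares of a standardized response on standardized
#' drivers, with each driver's share of explained variance computed by
#' averaging its sequential R-squared increments over all orderings of
#' the drivers (relative-importance decomposition); the shares sum to
#' R-squared (reported as percentages of total variance). A conditioning
#' warning is attached when the driver correlation matrix is nearly
#' singular.
#'
#' @param y response.
#' @param drivers data.frame of driver columns (e.g. CO2, air
#'   temperature, vapor pressure deficit).
#' @return object of class `regression_summary`: list with `coefficients`
#'   (standardized), `variance_pct` (per-driver percent of variance),
#'   `r_squared`, `n`, and `conditioning_warning` (logical).
#' @export
variance_partition <- function(y, drivers) {
  stopifnot(is.data.frame(drivers), nrow(drivers) == length(y))
  p <- ncol(drivers)
  n <- length(y)
  if (n <= p + 1) stop("need more observations than drivers plus one")
  z <- function(v) (v - mean(v)) / stats::sd(v)
  ys <- z(y)
  X <- as.data.frame(lapply(drivers, z))
  dat <- cbind(ys = ys, X)
  r2 <- function(vars) {
    if (length(vars) == 0) return(0)
    fml <- stats::reformulate(vars, response = "ys")
    # suppress the "essentially perfect fit" note for noise-free inputs
    suppressWarnings(summary(stats::lm(fml, data = dat))$r.squared)
  }
  vars <- names(X)
  orderings <- perms(vars)
  incr <- matrix(0, nrow = length(orderings), ncol = p,
                 dimnames = list(NULL, vars))
  for (i in seq_along(orderings)) {
    ord <- orderings[[i]]
    prev <- 0
    for (j in seq_along(ord)) {
      cur <- r2(ord[seq_len(j)])
      incr[i, ord[j]] <- cur - prev
      prev <- cur
    }
  }
  shares <- colMeans(incr)
  fit <- stats::lm(stats::reformulate(vars, response = "ys"), data = dat)
  kappa_x <- kappa(stats::cor(X), exact = TRUE)
  structure(list(coefficients = stats::coef(fit)[vars],
                 variance_pct = shares * 100,
                 r_squared = suppressWarnings(summary(fit)$r.squared), n = n,
                 conditioning_warning = kappa_x > 1e6),
            class = "regression_summary")
}

# all permutations of a character vector (small p only)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(perms(v[-i]), function(rest) c(v[i], rest)))
  out
}
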