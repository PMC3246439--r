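#' Tang/tip measurement from an oriented outline
#'
#' Splits each tool outline into tang (hafted stem, at smaller x) and tip
#' (the active part) at the shoulder: the boundary is detected as the
#' largest positive jump of the smoothed width profile w(x) — the step up
#' from the narrow stem, above the tang notches, to the blade — searched
#' within the left 60 % of the length. Tool length is the x-extent;
#' `tang_length = boundary_x - min(x)` and `tip_length` is the remainder.
#' An explicit per-specimen boundary hint bypasses detection entirely. A
#' monotone width profile with no detectable shoulder (e.g. a plain
#' ellipse) and no hint is an error naming the specimen.
#'
#' @param outlines An outline tibble, oriented tang-left.
#' @param hints Optional boundary x-positions: a numeric vector named by
#'   specimen, or a data frame with `specimen_id` and `boundary_x`.
#' @param min_jump Minimum width step, as a fraction of the maximum width,
#'   for a shoulder to count as detected.
#' @return A tibble with columns `specimen_id`, `length`, `tang_length`,
#'   `tip_length`, `boundary_x`.
#' @export
measure_tang_tip <- function(outlines, hints = NULL, min_jump = 0.15) {
  outlines <- as_outlines(outlines)
  if (is.data.frame(hints)) {
    hints <- stats::setNames(hints$boundary_x, hints$specimen_id)
  }
  dplyr::bind_rows(purrr::imap(outline_split(outlines), function(xy, id) {
    xr <- range(xy[, 1])
    len <- diff(xr)
    bx <- if (!is.null(hints) && id %in% names(hints)) {
      hints[[id]]
    } else {
      detect_shoulder(xy, min_jump = min_jump, id = id)
    }
    tibble::tibble(
      specimen_id = id,
      length = len,
      tang_length = bx - xr[1],
      tip_length = len - (bx - xr[1]),
      boundary_x = bx
    )
  }))
}

# Width of the polygon along vertical lines at the given x positions.
width_profile <- function(xy, grid) {
  n <- nrow(xy)
  x1 <- xy[, 1]; y1 <- xy[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  vapply(grid, function(g) {
    hit <- (x1 - g) * (x2 - g) < 0
    if (!any(hit)) {
      return(0)
    }
    t <- (g - x1[hit]) / (x2[hit] - x1[hit])
    yc <- y1[hit] + t * (y2[hit] - y1[hit])
    max(yc) - min(yc)
  }, double(1))
}

detect_shoulder <- function(xy, min_jump, id, n_grid = 200) {
  xr <- range(xy[, 1])
  len <- diff(xr)
  grid <- seq(xr[1] + 0.03 * len, xr[2] - 0.03 * len, length.out = n_grid)
  w <- width_profile(xy, grid)
  w <- stats::filter(w, rep(1 / 5, 5), sides = 2)
  w[is.na(w)] <- 0
  k <- 3L
  idx <- (k + 1):(n_grid - k)
  jump <- as.numeric(w[idx + k] - w[idx - k])
  centers <- grid[idx]
  inside <- centers >= xr[1] + 0.05 * len & centers <= xr[1] + 0.6 * len
  jump[!inside] <- -Inf
  best <- which.max(jump)
  if (jump[best] < min_jump * max(as.numeric(w))) {
    rlang::abort(paste0(
      "no tang/tip shoulder detected for specimen '", id,
      "'; supply a boundary hint"
    ), class = "tangmorph_detection_error")
  }
  centers[best]
}

#' Welch two-sample comparison
#'
#' Unequal-variance two-sample t statistic with Welch–Satterthwaite degrees
#' of freedom and a two-sided p value. The groups are taken from a
#' two-level grouping column; the statistic's sign follows
#' `mean(group1) - mean(group2)` with groups in sorted level order.
#'
#' @param data A data frame.
#' @param value Unquoted column of values.
#' @param by Unquoted two-level grouping column.
#' @return A one-row tibble: `group1`, `group2`, `n1`, `n2`, `mean1`,
#'   `mean2`, `t`, `df`, `p`.
#' @export
welch_test <- function(data, value, by) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(by), data)
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  levels <- sort(unique(g))
  if (length(levels) != 2) {
    rlang::abort("the grouping column must have exactly two levels",
      class = "tangmorph_parameter_error")
  }
  x <- v[g == levels[1]]
  y <- v[g == levels[2]]
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("each group needs at least 2 observations",
      class = "tangmorph_parameter_error")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    rlang::abort("both groups have zero variance",
      class = "tangmorph_parameter_error")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    group1 = as.character(levels[1]),
    group2 = as.character(levels[2]),
    n1 = length(x),
    n2 = length(y),
    mean1 = mean(x),
    mean2 = mean(y),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value
  )
}

#' Regress a shape score on size measurements
#'
#' Ordinary least squares with an intercept, reporting signed slopes, the
#' adjusted R-squared and the overall F-test p value — the form in which
#' size-dependence of shape components (elongation, relative tang length)
#' is assessed against length and tip length. A near-singular design
#' (condition number above 1e10) is flagged with a warning in the result.
#'
#' @param data A data frame holding the response and predictors.
#' @param response Name of the response column (a PC score).
#' @param predictors Character vector of predictor column names.
#' @return A list of class `size_regression` with `coefficients` (tibble of
#'   `term`, `estimate`, `std_error`, `p_value`), `adjusted_r2`,
#'   `overall_p`, `n`, `response`, and `collinear`.
#' @export
regress_pc_on_size <- function(data, response,
                               predictors = c("length", "tip_length")) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  if (nrow(data) <= length(predictors) + 1) {
    rlang::abort("too few observations for the number of predictors",
      class = "tangmorph_parameter_error")
  }
  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = data)
  collinear <- kappa(stats::model.matrix(fit), exact = TRUE) > 1e10
  if (collinear) {
    rlang::warn("predictors are nearly collinear; slopes are unstable")
  }
  sm <- summary(fit)
  cf <- stats::coef(sm)
  fstat <- sm$fstatistic
  structure(
    list(
      coefficients = tibble::tibble(
        term = rownames(cf),
        estimate = unname(cf[, 1]),
        std_error = unname(cf[, 2]),
        p_value = unname(cf[, 4])
      ),
      adjusted_r2 = sm$adj.r.squared,
      overall_p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
        lower.tail = FALSE)),
      n = nrow(stats::model.frame(fit)),
      response = response,
      collinear = collinear
    ),
    class = "size_regression"
  )
}

#' @export
print.size_regression <- function(x, ...) {
  cat("Regression of", x$response, "on",
    paste(setdiff(x$coefficients$term, "(Intercept)"), collapse = " + "),
    sprintf("(n = %d)\n", x$n))
  cat(sprintf("adjusted R^2 = %.3f, overall p = %.3g\n",
    x$adjusted_r2, x$overall_p))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.size_regression <- function(x, ...) x$coefficients

#' @export
glance.size_regression <- function(x, ...) {
  tibble::tibble(
    adjusted_r2 = x$adjusted_r2,
    overall_p = x$overall_p,
    n = x$n,
    collinear = x$collinear
  )
}

#' Major-axis (model II) regression with a bootstrap isometry test
#'
#' The major-axis slope is the slope of the first principal axis of the
#' bivariate covariance of (x, y) — the appropriate line when both
#' variables carry error, as log tip length and log tang length both do.
#' On log-log scales a slope of 1 is isometry; the slope's confidence
#' interval is a seeded percentile bootstrap over specimens, and isometry
#' is rejected when 1 falls outside it.
#'
#' @param data A data frame.
#' @param x,y Unquoted columns (already logged by the caller for
#'   allometry; the slope is invariant to the logarithm base).
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed for the bootstrap (the caller's RNG state is
#'   left untouched).
#' @param level Confidence level of the percentile interval.
#' @return A one-row tibble: `slope`, `intercept`, `ci_low`, `ci_high`,
#'   `isometry_rejected`, `n`, `n_boot`, `level`.
#' @export
major_axis <- function(data, x, y, n_boot = 1000, seed = NULL, level = 0.95) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 10) {
    rlang::abort("major-axis regression needs at least 10 observations",
      class = "tangmorph_parameter_error")
  }
  if (stats::var(xv) == 0) {
    rlang::abort("zero variance in x", class = "tangmorph_parameter_error")
  }
  b <- ma_slope(xv, yv)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::var(xv[idx]) == 0) {
        return(NA_real_)
      }
      ma_slope(xv[idx], yv[idx])
    }, double(1))
  })
  ci <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
    na.rm = TRUE, names = FALSE)
  tibble::tibble(
    slope = b,
    intercept = mean(yv) - b * mean(xv),
    ci_low = ci[1],
    ci_high = ci[2],
    isometry_rejected = !(ci[1] <= 1 && 1 <= ci[2]),
    n = n,
    n_boot = n_boot,
    level = level
  )
}

# First-principal-axis slope of the 2x2 covariance; sign follows the
# covariance.
ma_slope <- function(x, y) {
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0) {
    if (syy > sxx) {
      rlang::abort("major axis is vertical; slope undefined",
        class = "tangmorph_parameter_error")
    }
    return(0)
  }
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

#' Score spread by length class
#'
#' Summarizes a shape score within length classes: either quantile bins
#' holding roughly equal numbers of specimens (`equal_n`) or equal-width
#' length segments (`equal_width`). Reports per bin the count, the median
#' and interquartile range of the score, and the fraction of retouched
#' pieces — the descriptive device for reading increasing asymmetry in
#' shorter (more reduced) tools.
#'
#' @param data A data frame.
#' @param value Unquoted score column.
#' @param length Unquoted length column.
#' @param mode `"equal_n"` or `"equal_width"`.
#' @param bins Number of length classes (at least 2; n must be at least
#'   4 bins).
#' @param retouched Optional unquoted logical column of retouch flags.
#' @return A tibble with columns `bin`, `lower`, `upper`, `n`, `median`,
#'   `iqr`, `retouched_fraction`.
#' @export
spread_by_length <- function(data, value, length,
                             mode = c("equal_n", "equal_width"), bins = 4,
                             retouched = NULL) {
  mode <- match.arg(mode)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  len <- rlang::eval_tidy(rlang::enquo(length), data)
  rq <- rlang::enquo(retouched)
  rt <- if (rlang::quo_is_null(rq)) NULL else rlang::eval_tidy(rq, data)
  if (bins < 2) {
    rlang::abort("bins must be at least 2", class = "tangmorph_parameter_error")
  }
  if (base::length(len) < 4 * bins) {
    rlang::abort("need at least 4 observations per bin",
      class = "tangmorph_parameter_error")
  }
  breaks <- if (mode == "equal_n") {
    stats::quantile(len, probs = seq(0, 1, length.out = bins + 1),
      names = FALSE)
  } else {
    seq(min(len), max(len), length.out = bins + 1)
  }
  if (anyDuplicated(breaks)) {
    empty <- which(duplicated(breaks))[1] - 1
    rlang::abort(paste0(
      "length ties leave quantile bin ", empty, " empty; use equal_width"
    ), class = "tangmorph_parameter_error")
  }
  cls <- cut(len, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  dplyr::bind_rows(purrr::map(seq_len(bins), function(b) {
    sel <- cls == b
    tibble::tibble(
      bin = b,
      lower = breaks[b],
      upper = breaks[b + 1],
      n = sum(sel),
      median = stats::median(v[sel]),
      iqr = stats::IQR(v[sel]),
      retouched_fraction = if (is.null(rt)) NA_real_ else mean(rt[sel])
    )
  }))
}

#' Cumulative type-frequency curve
#'
#' The classic cumulative percentage graph over ascending integer type
#' codes. With `reclassify_endscrapers = TRUE`, endscraper-tip codes 30 and
#' 31 are re-classified as transverse scrapers 22 and 23 before
#' accumulation — the comparison that shows how tip orientation inflates
#' the endscraper class.
#'
#' @param data A data frame.
#' @param type Unquoted column of integer type codes.
#' @param reclassify_endscrapers Recode 30 to 22 and 31 to 23 first.
#' @return A tibble with columns `type_code`, `n`, `percent`,
#'   `cumulative_percent`; the final cumulative value is 100.
#' @export
cumulative_type_curve <- function(data, type, reclassify_endscrapers = FALSE) {
  codes <- rlang::eval_tidy(rlang::enquo(type), data)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) {
    rlang::abort("no type codes supplied", class = "tangmorph_parameter_error")
  }
  if (reclassify_endscrapers) {
    codes[codes == 30] <- 22
    codes[codes == 31] <- 23
  }
  tab <- table(codes)
  tibble::tibble(
    type_code = as.integer(names(tab)),
    n = as.integer(tab),
    percent = 100 * as.integer(tab) / length(codes),
    cumulative_percent = cumsum(100 * as.integer(tab) / length(codes))
  )
}
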