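#' Map ensemble scores to quantitative enzyme activity
#'
#' Relates the ensemble functionality score to measured in-vitro activity
#' (percent of wild-type intrinsic clearance) by binning variants into
#' equal-width score bins over \code{[0, 1]} and regressing the bin-mean
#' activity on the bin midpoints by ordinary least squares.  Binning before
#' regressing smooths the heavy variant-to-variant assay noise so the fit
#' captures the score-activity trend.
#'
#' @param scores Numeric ensemble scores in \code{[0, 1]}.
#' @param activities Numeric measured activities (percent of wild type),
#'   aligned with \code{scores}; pairs with \code{NA} in either are dropped.
#' @param n_bins Number of equal-width bins (default 7).
#' @return An object of class \code{"activity_map"}: list with \code{bins}
#'   (data frame of \code{midpoint}, \code{mean_activity}, \code{n}),
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{p_value}
#'   (two-sided, on the slope), \code{n_bins}, \code{max_activity}.
#' @seealso [predict_activity()]
#' @export
fit_activity_map <- function(scores, activities, n_bins = 7) {
  stopifnot(length(scores) == length(activities), n_bins >= 3)
  ok <- !is.na(scores) & !is.na(activities)
  scores <- scores[ok]; activities <- activities[ok]
  if (length(scores) < 3L) {
    stop("need at least 3 variants with both score and activity",
         call. = FALSE)
  }
  stopifnot(all(scores >= 0 & scores <= 1))
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(scores, edges, rightmost.closed = TRUE), n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  occupied <- sort(unique(bin))
  if (length(occupied) < 3L) {
    stop("fewer than 3 non-empty score bins; cannot fit the activity map",
         call. = FALSE)
  }
  bins <- data.frame(
    midpoint = mids[occupied],
    mean_activity = vapply(occupied, function(b) mean(activities[bin == b]), 0),
    n = vapply(occupied, function(b) sum(bin == b), 0L))
  if (stats::var(bins$mean_activity) < .Machine$double.eps) {
    slope <- 0; intercept <- bins$mean_activity[1]
    r2 <- 0; p <- 1
  } else {
    fit <- stats::lm(mean_activity ~ midpoint, data = bins)
    sm <- suppressWarnings(summary(fit))  # exact fits trip a precision warning
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- sm$r.squared
    p <- sm$coefficients[2, 4]
  }
  structure(list(bins = bins, slope = slope, intercept = intercept,
                 r_squared = r2, p_value = p, n_bins = n_bins,
                 max_activity = max(activities)),
            class = "activity_map")
}

#' Predict enzyme activity from an ensemble score
#'
#' Linear prediction from a fitted [fit_activity_map()], clamped to
#' \code{[0, max observed activity]} so extrapolation never produces
#' negative or implausibly high activities.
#'
#' @param score Numeric ensemble scores in \code{[0, 1]}.
#' @param map A fitted \code{activity_map}.
#' @return Predicted activity in percent of wild type.
#' @export
predict_activity <- function(score, map) {
  stopifnot(inherits(map, "activity_map"),
            all(is.na(score) | (score >= 0 & score <= 1)))
  pred <- map$intercept + map$slope * score
  pmin(pmax(pred, 0), map$max_activity)
}

#' @export
predict.activity_map <- function(object, score, ...) {
  predict_activity(score, object)
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf(
    "<activity_map> %d of %d bins occupied; activity = %.1f + %.1f * score (R^2 = %.3f, p = %.3g)\n",
    nrow(x$bins), x$n_bins, x$intercept, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' @export
plot.activity_map <- function(x, ...) {
  graphics::plot(x$bins$midpoint, x$bins$mean_activity,
                 xlab = "ensemble score (bin midpoint)",
                 ylab = "mean activity (% wild type)",
                 xlim = c(0, 1), pch = 19, ...)
  graphics::abline(x$intercept, x$slope, col = "red")
  invisible(x)
}
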