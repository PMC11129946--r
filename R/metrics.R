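#' Dichotomize predictor scores into deleterious/neutral calls
#'
#' Applies an algorithm's decision rule to a numeric score vector, honoring
#' the rule's direction and operator strictness; missing scores propagate as
#' \code{NA} calls.
#'
#' @param scores Numeric vector, \code{NA} for missing.
#' @param spec An [algorithm_spec()].
#' @return Character vector in \code{{"deleterious", "neutral", NA}}.
#' @examples
#' binarize(c(0.05, 0.051, NA), registry_spec("SIFT"))
#' binarize(c(15, 15.1), registry_spec("CADD"))   # 15 itself is neutral
#' @export
binarize <- function(scores, spec) {
  stopifnot(inherits(spec, "algorithm_spec"))
  del <- if (spec$direction == "deleterious_if_high") {
    if (spec$strict) scores > spec$threshold else scores >= spec$threshold
  } else {
    if (spec$strict) scores < spec$threshold else scores <= spec$threshold
  }
  ifelse(del, "deleterious", "neutral")
}

#' Tally calls against labels
#'
#' Counts true/false positives and negatives, treating the deleterious label
#' as the positive class.  Missing calls are counted separately and never
#' enter the four cells.
#'
#' @param calls Character vector in \code{{"deleterious","neutral", NA}}.
#' @param labels Character vector (or \code{labeled_variants}, whose
#'   \code{label} column is used) aligned with \code{calls}.
#' @return An object of class \code{"confusion_counts"}: a list with
#'   \code{TP}, \code{TN}, \code{FP}, \code{FN}, \code{n_missing},
#'   \code{n_total}.
#' @export
confusion_counts <- function(calls, labels) {
  if (inherits(labels, "labeled_variants")) labels <- labels$label
  stopifnot(length(calls) == length(labels), !anyNA(labels))
  ok <- !is.na(calls)
  pos <- labels == "deleterious"
  cd <- calls == "deleterious"
  structure(list(
    TP = sum(ok & pos & cd), TN = sum(ok & !pos & !cd),
    FP = sum(ok & !pos & cd), FN = sum(ok & pos & !cd),
    n_missing = sum(!ok), n_total = length(calls)),
    class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (missing %d of %d)\n",
              x$TP, x$TN, x$FP, x$FN, x$n_missing, x$n_total))
  invisible(x)
}

.ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from confusion counts
#'
#' Computes sensitivity, specificity, accuracy, predictive values, error
#' rates and Youden's J (informedness, \code{SEN + SPE - 1}).  A ratio whose
#' denominator is zero is undefined and returned as \code{NA} rather than
#' coerced to zero; \code{NA} serializes to \code{null} in JSON reports.
#' Metrics are computed over the scored variants only; missingness is
#' reported alongside as a count and a fraction of the full set.
#'
#' @param counts A [confusion_counts()] object.
#' @param auc Optional AUC to carry in the report (computed from scores, not
#'   from counts; see [auc()]).
#' @return An object of class \code{"metric_report"}: a list with
#'   \code{SEN}, \code{SPE}, \code{ACC}, \code{PPV}, \code{NPV}, \code{FPR},
#'   \code{FNR}, \code{J}, \code{AUC}, \code{missing_count},
#'   \code{missing_pct}.
#' @examples
#' # sensitivity 0.91, specificity 0.93 imply J = 0.84 and FPR = 0.07
#' m <- compute_metrics(confusion_counts(
#'   rep(c("deleterious", "neutral"), c(100, 100)),
#'   rep(c("deleterious", "neutral", "deleterious", "neutral"),
#'       c(91, 9, 7, 93))))
#' round(c(m$J, m$FPR), 2)
#' @export
compute_metrics <- function(counts, auc = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  c_ <- counts
  sen <- .ratio(c_$TP, c_$TP + c_$FN)
  spe <- .ratio(c_$TN, c_$TN + c_$FP)
  structure(list(
    SEN = sen, SPE = spe,
    ACC = .ratio(c_$TP + c_$TN, c_$TP + c_$TN + c_$FP + c_$FN),
    PPV = .ratio(c_$TP, c_$TP + c_$FP),
    NPV = .ratio(c_$TN, c_$TN + c_$FN),
    FPR = if (is.na(spe)) NA_real_ else 1 - spe,
    FNR = if (is.na(sen)) NA_real_ else 1 - sen,
    J = sen + spe - 1,
    AUC = auc,
    missing_count = c_$n_missing,
    missing_pct = .ratio(c_$n_missing, c_$n_total)),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 2, ...) {
  v <- unlist(x[c("SEN", "SPE", "ACC", "PPV", "NPV", "FPR", "FNR", "J", "AUC")])
  cat("<metric_report>\n")
  print(round(v, digits))
  cat(sprintf("missing: %d (%s%%)\n", x$missing_count,
              formatC(100 * x$missing_pct, format = "fg", digits = 2)))
  invisible(x)
}

#' ROC curve of a predictor against binary labels
#'
#' Sweeps the decision threshold over the observed scores, oriented by the
#' predictor's deleteriousness direction so that an informative predictor's
#' curve lies above the diagonal.  Missing scores are excluded; tied scores
#' collapse to a single operating point.
#'
#' @param scores Numeric vector, \code{NA} for missing.
#' @param labels Character vector or \code{labeled_variants} aligned with
#'   \code{scores}; needs both classes among the scored variants.
#' @param direction \code{"deleterious_if_high"} (default) or
#'   \code{"deleterious_if_low"}.
#' @return An object of class \code{"roc_curve"}: a data frame with columns
#'   \code{threshold} (on the original score scale; \code{-Inf}/\code{Inf}
#'   bound the sweep), \code{FPR}, \code{SEN}, starting at (0, 0) and ending
#'   at (1, 1) with non-decreasing FPR.
#' @export
roc_points <- function(scores, labels,
                       direction = c("deleterious_if_high",
                                     "deleterious_if_low")) {
  direction <- match.arg(direction)
  if (inherits(labels, "labeled_variants")) labels <- labels$label
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == "deleterious"
  P <- sum(pos); N <- sum(!pos)
  if (P == 0L || N == 0L) {
    stop("ROC needs both classes among non-missing scores", call. = FALSE)
  }
  d <- if (direction == "deleterious_if_high") scores else -scores
  ord <- order(d, decreasing = TRUE)
  d <- d[ord]; pos <- pos[ord]
  last <- !duplicated(d, fromLast = TRUE)       # end of each tie block
  tp <- cumsum(pos)[last]
  fp <- cumsum(!pos)[last]
  thr <- d[last]
  if (direction == "deleterious_if_low") thr <- -thr
  out <- data.frame(threshold = c(if (direction == "deleterious_if_high")
    Inf else -Inf, thr),
    FPR = c(0, fp / N), SEN = c(0, tp / P))
  structure(out, direction = direction, n_pos = P, n_neg = N,
            class = c("roc_curve", "data.frame"))
}

#' Area under a ROC curve
#'
#' Trapezoidal area under the curve from [roc_points()].  With tie blocks
#' collapsed to single points this equals the Mann-Whitney concordance
#' probability with tied pairs counted one half.
#'
#' @param curve A \code{roc_curve}.
#' @return AUC in \code{[0, 1]}.
#' @examples
#' curve <- roc_points(c(0.9, 0.3, 0.5, 0.1),
#'                     c("deleterious", "deleterious", "neutral", "neutral"))
#' auc(curve)  # 3 of 4 concordant pairs
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  x <- curve$FPR; y <- curve$SEN
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# AUC straight from scores; NA when only one class is scored.
.auc_scores <- function(scores, labels, direction = "deleterious_if_high") {
  ok <- !is.na(scores)
  l <- labels[ok]
  if (length(unique(l)) < 2L) return(NA_real_)
  auc(roc_points(scores, labels, direction))
}

#' Benchmark predictors on a labeled variant set
#'
#' Applies each predictor's decision rule to the score table, tallies calls
#' against the labels, and reports the full metric panel per predictor.
#' Metrics are computed on each predictor's non-missing variants;
#' missingness is reported as a count and percent of the full set.
#'
#' @param table A [score_table()].
#' @param labels A [labeled_variants()] set covering the table's variants.
#' @param specs An \code{algorithm_registry} (default [builtin_registry()])
#'   or a list of [algorithm_spec()]s.  Only predictors present among the
#'   table's columns are benchmarked.
#' @return A data frame of class \code{"apf2_benchmark"}, one row per
#'   predictor with columns \code{algorithm}, \code{SEN} \ldots \code{AUC},
#'   \code{missing_n}, \code{missing_pct}, sorted by decreasing AUC.
#' @export
benchmark <- function(table, labels, specs = builtin_registry()) {
  stopifnot(inherits(table, "score_table"))
  lab <- .align_labels(table, labels)$label
  if (inherits(specs, "data.frame")) {
    specs <- lapply(seq_len(nrow(specs)), function(i)
      algorithm_spec(specs$name[i], specs$direction[i], specs$threshold[i],
                     specs$strict[i]))
  }
  names(specs) <- vapply(specs, `[[`, "", "name")
  use <- intersect(algorithms(table), names(specs))
  if (!length(use)) stop("no table column matches a registered algorithm",
                         call. = FALSE)
  rows <- lapply(use, function(a) {
    sp <- specs[[a]]
    s <- table[[a]]
    m <- compute_metrics(confusion_counts(binarize(s, sp), lab),
                         auc = .auc_scores(s, lab, sp$direction))
    data.frame(algorithm = a, SEN = m$SEN, SPE = m$SPE, ACC = m$ACC,
               PPV = m$PPV, NPV = m$NPV, FPR = m$FPR, FNR = m$FNR,
               J = m$J, AUC = m$AUC, missing_n = m$missing_count,
               missing_pct = m$missing_pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$AUC, out$algorithm), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("apf2_benchmark", "data.frame"))
}

#' @export
print.apf2_benchmark <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- c("SEN", "SPE", "ACC", "PPV", "NPV", "FPR", "FNR", "J", "AUC")
  y[num] <- lapply(y[num], round, digits)
  y$missing <- sprintf("%d (%.0f%%)", y$missing_n, 100 * y$missing_pct)
  print(y[, c("algorithm", num, "missing")], row.names = FALSE)
  invisible(x)
}
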