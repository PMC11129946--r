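# Reproducible randomness without clobbering the caller's RNG stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Candidate cutoffs for threshold search
#'
#' Midpoints between consecutive distinct sorted scores, extended by one
#' candidate below the minimum and one above the maximum (offset by half the
#' adjacent gap, or 0.5 when all scores coincide).  Searching midpoints
#' rather than observed values means strict and non-strict comparison
#' operators yield identical partitions at every candidate.
#'
#' @param scores Numeric vector; \code{NA} ignored.
#' @return Sorted numeric vector of n+1 candidates for n distinct scores.
#' @examples
#' candidate_thresholds(c(1, 2, 3))  # 0.5 1.5 2.5 3.5
#' @export
candidate_thresholds <- function(scores) {
  s <- sort(unique(scores[!is.na(scores)]))
  n <- length(s)
  if (n == 0L) stop("no non-missing scores", call. = FALSE)
  if (n == 1L) return(c(s - 0.5, s + 0.5))
  mid <- (s[-1] + s[-n]) / 2
  c(s[1] - (s[2] - s[1]) / 2, mid, s[n] + (s[n] - s[n - 1]) / 2)
}

# J and SPE at every candidate cutoff, vectorized over the sorted scores.
# Returns a list of vectors aligned with candidate_thresholds(scores).
.j_scan <- function(scores, labels, direction) {
  ok <- !is.na(scores)
  s <- scores[ok]; pos <- labels[ok] == "deleterious"
  P <- sum(pos); N <- sum(!pos)
  if (P == 0L || N == 0L) {
    stop("threshold optimization needs both classes among non-missing scores",
         call. = FALSE)
  }
  ord <- order(s)
  s <- s[ord]; pos <- pos[ord]
  block_end <- which(!duplicated(s, fromLast = TRUE))
  # n_below[i]: scores <= candidate i; cd[i]: deleterious-labeled among them
  n_below <- c(0L, block_end)
  cd <- c(0L, cumsum(pos)[block_end])
  if (direction == "deleterious_if_low") {
    tp <- cd; fp <- n_below - cd
  } else {
    tp <- P - cd; fp <- (length(s) - n_below) - (P - cd)
  }
  sen <- tp / P
  spe <- (N - fp) / N
  list(candidates = candidate_thresholds(s), J = sen + spe - 1,
       SEN = sen, SPE = spe, n_pos = P, n_neg = N)
}

#' Re-parametrize a predictor's threshold by maximizing Youden's J
#'
#' Scans every candidate cutoff (see [candidate_thresholds()]) and returns
#' the one maximizing informedness J = sensitivity + specificity - 1 on the
#' given labeled scores, keeping the predictor's deleteriousness direction
#' fixed.  Ties on J are broken in favor of higher specificity, then the
#' smallest candidate, so the result is deterministic.  Missing scores are
#' excluded.
#'
#' @param scores Numeric vector, \code{NA} for missing.
#' @param labels Character vector or \code{labeled_variants} aligned with
#'   \code{scores}; both classes must be present among non-missing scores.
#' @param spec The predictor's conventional [algorithm_spec()]; supplies the
#'   direction, strictness and the baseline threshold that
#'   \code{J_conventional} is evaluated at.
#' @return An object of class \code{"threshold_fit"}: list with
#'   \code{algorithm}, \code{direction}, \code{strict},
#'   \code{optimized_threshold}, \code{J_optimized}, \code{J_conventional},
#'   \code{delta_J}, \code{n_used}.
#' @export
optimize_threshold <- function(scores, labels, spec) {
  stopifnot(inherits(spec, "algorithm_spec"))
  if (inherits(labels, "labeled_variants")) labels <- labels$label
  stopifnot(length(scores) == length(labels))
  scan <- .j_scan(scores, labels, spec$direction)
  best_j <- max(scan$J)
  cand_i <- which(scan$J >= best_j - 1e-12)
  cand_i <- cand_i[order(-scan$SPE[cand_i], scan$candidates[cand_i])][1]
  ok <- !is.na(scores)
  j_conv <- {
    cc <- confusion_counts(binarize(scores[ok], spec), labels[ok])
    m <- compute_metrics(cc)
    m$J
  }
  fit <- spec
  fit$threshold <- scan$candidates[cand_i]
  structure(list(
    algorithm = spec$name, direction = spec$direction, strict = spec$strict,
    optimized_threshold = scan$candidates[cand_i],
    J_optimized = scan$J[cand_i],
    SEN = scan$SEN[cand_i], SPE = scan$SPE[cand_i],
    J_conventional = j_conv,
    delta_J = scan$J[cand_i] - j_conv,
    conventional_threshold = spec$threshold,
    n_used = sum(ok)),
    class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf(
    "<threshold_fit> %s (%s): threshold %g -> %g, J %.3f -> %.3f (dJ %.3f)\n",
    x$algorithm, x$direction, x$conventional_threshold,
    x$optimized_threshold, x$J_conventional, x$J_optimized, x$delta_J))
  invisible(x)
}

# An algorithm_spec carrying a fitted threshold (strictness immaterial at
# midpoint candidates, inherited for form).
.spec_from_fit <- function(fit) {
  algorithm_spec(fit$algorithm, fit$direction, fit$optimized_threshold,
                 fit$strict)
}

#' Reproducible k-fold partition, optionally label-stratified
#'
#' Assigns n items to k folds whose sizes differ by at most one.  With
#' \code{labels}, the assignment is stratified: items are dealt to folds
#' class by class in one continuous cycle, so each class is also spread
#' across folds as evenly as possible.
#'
#' @param n Number of items.
#' @param k Number of folds, \code{2 <= k <= n} (k = n gives leave-one-out).
#' @param seed Integer seed; same seed, same assignment.
#' @param labels Optional vector of class labels of length n for
#'   stratification.
#' @return Integer vector of length n with fold ids in \code{1..k}.
#' @examples
#' table(kfold_partition(530, 5, seed = 1))  # five folds of 106
#' @export
kfold_partition <- function(n, k, seed = 1, labels = NULL) {
  stopifnot(n >= k, k >= 1)
  .with_seed(seed, {
    ord <- if (is.null(labels)) {
      sample.int(n)
    } else {
      stopifnot(length(labels) == n)
      idx <- sample.int(n)                  # shuffle, then group by class
      idx[order(as.integer(factor(labels[idx])))]
    }
    fold <- integer(n)
    fold[ord] <- rep_len(seq_len(k), n)
    fold
  })
}

#' Cross-validated threshold re-parametrization
#'
#' Runs [optimize_threshold()] under k-fold cross-validation: in each fold
#' the threshold is fitted on the k-1 training partitions and the gain in
#' informedness over the conventional threshold (delta J) is evaluated on
#' both the training portion and the held-out validation fold.  The
#' reported final fit is re-estimated on the full set; the cross-validation
#' exists to report honest train/validation delta-J distributions and the
#' mean validation-fold J used for ensemble weighting.
#'
#' @param scores,labels,spec As in [optimize_threshold()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold partition (default 1).
#' @return An object of class \code{"cv_threshold"}: list with
#'   \code{algorithm}, \code{k}, \code{seed}, \code{folds} (data frame with
#'   per-fold \code{threshold}, \code{train_delta_J}, \code{val_delta_J},
#'   \code{val_J}), \code{mean_val_J}, \code{final_fit}.
#' @export
crossvalidate_threshold <- function(scores, labels, spec, k = 5, seed = 1) {
  if (inherits(labels, "labeled_variants")) labels <- labels$label
  stopifnot(length(scores) == length(labels))
  n <- length(scores)
  fold <- kfold_partition(n, k, seed = seed, labels = labels)
  eval_j <- function(idx, sp) {
    ok <- idx & !is.na(scores)
    compute_metrics(confusion_counts(binarize(scores[ok], sp),
                                     labels[ok]))$J
  }
  rows <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- optimize_threshold(scores[tr], labels[tr], spec)
    fsp <- .spec_from_fit(fit)
    val_j_opt <- eval_j(fold == f, fsp)
    val_j_conv <- eval_j(fold == f, spec)
    data.frame(fold = f, threshold = fit$optimized_threshold,
               train_delta_J = fit$delta_J,
               val_delta_J = val_j_opt - val_j_conv,
               val_J = val_j_opt)
  })
  folds <- do.call(rbind, rows)
  structure(list(algorithm = spec$name, k = k, seed = seed, folds = folds,
                 mean_val_J = mean(folds$val_J),
                 final_fit = optimize_threshold(scores, labels, spec)),
            class = "cv_threshold")
}

#' @export
print.cv_threshold <- function(x, digits = 3, ...) {
  cat(sprintf("<cv_threshold> %s, %d folds (seed %d)\n", x$algorithm, x$k,
              x$seed))
  print(cbind(x$folds[1], round(x$folds[-1], digits)), row.names = FALSE)
  cat(sprintf("mean validation J: %.3f\n", x$mean_val_J))
  print(x$final_fit)
  invisible(x)
}
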