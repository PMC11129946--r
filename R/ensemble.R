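#' Components of the shipped reference ensemble
#'
#' The five re-parametrized component predictors of the reference ensemble
#' with their optimized thresholds and published combined-set informedness,
#' from which the shipped model's J-proportional weights are derived.
#' @return Data frame with columns \code{algorithm}, \code{direction},
#'   \code{strict}, \code{threshold}, \code{J}.
#' @keywords internal
.default_components <- function() {
  data.frame(
    algorithm = c("AlphaMissense", "PROVEAN", "MutationAssessor",
                  "PolyPhen-2", "VEST4"),
    direction = c("deleterious_if_high", "deleterious_if_low",
                  "deleterious_if_high", "deleterious_if_high",
                  "deleterious_if_high"),
    strict    = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    threshold = c(0.152, -3.2925, 2.08, 0.42, 0.2905),
    J         = c(0.46, 0.44, 0.38, 0.42, 0.37),
    stringsAsFactors = FALSE)
}

.new_apf2_model <- function(components, cutoff, min_components, weighting) {
  stopifnot(is.data.frame(components),
            all(c("algorithm", "direction", "strict", "threshold",
                  "weight") %in% names(components)),
            all(components$weight > 0),
            abs(sum(components$weight) - 1) < 1e-9,
            cutoff > 0, cutoff < 1,
            min_components >= 1, min_components <= nrow(components))
  rownames(components) <- NULL
  structure(list(components = components, cutoff = cutoff,
                 min_components = as.integer(min_components),
                 weighting = weighting),
            class = "apf2_model")
}

#' The shipped reference ensemble model
#'
#' The published parametrization of the five-component ensemble:
#' AlphaMissense (deleterious at scores \eqn{\ge} 0.152), PROVEAN
#' (< -3.2925), MutationAssessor (> 2.08), PolyPhen-2 (> 0.42) and VEST4
#' (> 0.2905), weighted proportionally to each component's combined-set
#' informedness at its optimized threshold, with the fixed deleterious
#' cutoff 0.367 on the ensemble score.  Use [apf2()] to refit thresholds
#' and weights on your own labeled data instead.
#'
#' @param cutoff Deleterious cutoff on the ensemble score (default 0.367;
#'   scores at or below it are called deleterious).
#' @param min_components Minimum number of scored components for a call
#'   (default 3 of 5; fewer yields \code{NO_CALL}).
#' @return An object of class \code{"apf2_model"}.
#' @examples
#' m <- apf2_default_model()
#' coef(m)
#' @export
apf2_default_model <- function(cutoff = 0.367, min_components = 3) {
  comp <- .default_components()
  comp$weight <- comp$J / sum(comp$J)
  .new_apf2_model(comp[, c("algorithm", "direction", "strict", "threshold",
                           "J", "weight")],
                  cutoff, min_components, weighting = "published_J")
}

#' Combine re-parametrized predictors into a weighted ensemble model
#'
#' Builds the ensemble model from per-component threshold fits.  By default
#' each component's weight is proportional to its cross-validated mean
#' validation-fold informedness J (its fitting-data J when plain
#' [optimize_threshold()] fits are supplied), normalized to sum to one;
#' informedness is the objective the thresholds themselves maximize, and
#' validation-fold J guards against rewarding overfit components.
#' Components with non-positive J are dropped with a warning; at least two
#' must remain.
#'
#' @param fits List of [crossvalidate_threshold()] or [optimize_threshold()]
#'   results, one per component.
#' @param cutoff Deleterious cutoff on the ensemble score (default 0.367).
#' @param min_components Minimum scored components for a call (default
#'   \code{min(3, number of components)}).
#' @param weighting \code{"cv_J"} (default), \code{"uniform"}, or a numeric
#'   vector of positive weights aligned with \code{fits}.
#' @return An object of class \code{"apf2_model"}.
#' @export
fit_ensemble <- function(fits, cutoff = 0.367, min_components = NULL,
                         weighting = "cv_J") {
  stopifnot(is.list(fits), length(fits) >= 1)
  comp_j <- vapply(fits, function(f) {
    if (inherits(f, "cv_threshold")) f$mean_val_J
    else if (inherits(f, "threshold_fit")) f$J_optimized
    else stop("fits must be cv_threshold or threshold_fit objects",
              call. = FALSE)
  }, 0)
  final <- lapply(fits, function(f) {
    if (inherits(f, "cv_threshold")) f$final_fit else f
  })
  comp <- data.frame(
    algorithm = vapply(final, `[[`, "", "algorithm"),
    direction = vapply(final, `[[`, "", "direction"),
    strict = vapply(final, `[[`, TRUE, "strict"),
    threshold = vapply(final, `[[`, 0, "optimized_threshold"),
    J = comp_j, stringsAsFactors = FALSE)
  if (is.numeric(weighting)) {
    stopifnot(length(weighting) == nrow(comp), all(weighting > 0))
    comp$weight <- weighting / sum(weighting)
    scheme <- "user"
  } else {
    scheme <- match.arg(weighting, c("cv_J", "uniform"))
    drop <- comp$J <= 0
    if (any(drop)) {
      warning("dropping component(s) with non-positive informedness: ",
              paste(comp$algorithm[drop], collapse = ", "), call. = FALSE)
      comp <- comp[!drop, , drop = FALSE]
    }
    if (nrow(comp) == 0L) {
      stop("no informative components remain", call. = FALSE)
    }
    if (nrow(comp) < 2L && length(fits) >= 2L) {
      stop("fewer than 2 informative components remain", call. = FALSE)
    }
    comp$weight <- if (scheme == "uniform") {
      rep(1 / nrow(comp), nrow(comp))
    } else {
      comp$J / sum(comp$J)
    }
  }
  if (is.null(min_components)) min_components <- min(3L, nrow(comp))
  .new_apf2_model(comp, cutoff, min_components, scheme)
}

#' Classify ensemble scores at the deleterious cutoff
#'
#' Low ensemble scores indicate loss of function: a variant is called
#' deleterious when its score is at or below the cutoff, functionally
#' neutral strictly above it.
#'
#' @param score Numeric ensemble scores in \code{[0, 1]} (\code{NA} gives
#'   \code{NA}).
#' @param cutoff Cutoff (default 0.367).
#' @return Character vector in \code{{"deleterious", "neutral", NA}}.
#' @examples
#' classify(c(0.367, 0.368))
#' @export
classify <- function(score, cutoff = 0.367) {
  stopifnot(all(is.na(score) | (score >= 0 & score <= 1)))
  ifelse(score <= cutoff, "deleterious", "neutral")
}

#' Ensemble functionality score for one variant
#'
#' Each scored component casts a binary functionality vote: 1 when its
#' re-parametrized call is neutral/functional, 0 when deleterious.  The
#' ensemble score is the weighted mean of the available votes, with weights
#' renormalized over the scored components, so it lies in \code{[0, 1]} with
#' 0 meaning unanimously deleterious and 1 unanimously functional.  When
#' fewer than \code{min_components} components are scored the variant gets
#' \code{NO_CALL}.
#'
#' @param variant_scores Named numeric vector of raw component scores
#'   (names matching the model's algorithms; \code{NA} = missing).
#' @param model An \code{apf2_model}.
#' @return A list with \code{score} (\code{NA} when \code{NO_CALL}),
#'   \code{call} (\code{"deleterious"}, \code{"neutral"} or
#'   \code{"no_call"}), \code{n_components_used}, and the per-component
#'   \code{votes} (named, \code{NA} where unscored).
#' @examples
#' m <- apf2_default_model()
#' s <- c(AlphaMissense = 0.9, PROVEAN = -6, MutationAssessor = 3.1,
#'        "PolyPhen-2" = 0.99, VEST4 = 0.8)
#' apf2_score(s, m)$call  # all five vote deleterious -> score 0
#' @export
apf2_score <- function(variant_scores, model) {
  stopifnot(inherits(model, "apf2_model"))
  comp <- model$components
  s <- variant_scores[comp$algorithm]
  votes <- vapply(seq_len(nrow(comp)), function(i) {
    if (is.na(s[i])) return(NA_real_)
    sp <- algorithm_spec(comp$algorithm[i], comp$direction[i],
                         comp$threshold[i], comp$strict[i])
    if (binarize(s[[i]], sp) == "deleterious") 0 else 1
  }, 0)
  names(votes) <- comp$algorithm
  avail <- !is.na(votes)
  n_used <- sum(avail)
  if (n_used < model$min_components) {
    return(list(score = NA_real_, call = "no_call",
                n_components_used = n_used, votes = votes))
  }
  w <- comp$weight[avail] / sum(comp$weight[avail])
  score <- sum(w * votes[avail])
  list(score = score, call = classify(score, model$cutoff),
       n_components_used = n_used, votes = votes)
}

#' Fit the ensemble variant effect model
#'
#' The main model-fitting interface: re-parametrizes each component
#' predictor's threshold by cross-validated maximization of Youden's J on
#' the labeled variants, then aggregates the components into a weighted
#' ensemble (see [crossvalidate_threshold()] and [fit_ensemble()]).
#'
#' @param table A [score_table()] whose columns include the component
#'   predictors.
#' @param labels A [labeled_variants()] set covering the table's variants.
#' @param components Predictor names to include (default: the five
#'   reference components).  Must be columns of \code{table} and resolvable
#'   in \code{registry}.
#' @param k Cross-validation folds (default 5).
#' @param seed Integer seed for fold assignment (default 1).
#' @param cutoff Deleterious cutoff on the ensemble score: a number, or
#'   \code{"refit"} to re-derive it as the J-optimal cutoff on the fitted
#'   ensemble scores of the training variants (default 0.367).
#' @param min_components,weighting Passed to [fit_ensemble()].
#' @param registry Registry supplying each component's conventional rule.
#' @return An object of class \code{"apf2"}: the fitted
#'   \code{model} (\code{apf2_model}) plus per-component \code{cv} results
#'   and the training call.  Methods: \code{print}, \code{summary},
#'   \code{coef} (component weights), \code{predict} (score new variants),
#'   \code{plot} (cross-validated delta-J distributions).
#' @examples
#' sim <- simulate_labeled_scores(sim_config(n_deleterious = 150,
#'                                           n_neutral = 150, seed = 7))
#' fit <- apf2(sim$scores, sim$labels, seed = 7)
#' coef(fit)
#' head(predict(fit, sim$scores))
#' @export
apf2 <- function(table, labels,
                 components = c("AlphaMissense", "PROVEAN",
                                "MutationAssessor", "PolyPhen-2", "VEST4"),
                 k = 5, seed = 1, cutoff = 0.367, min_components = NULL,
                 weighting = "cv_J", registry = builtin_registry()) {
  stopifnot(inherits(table, "score_table"))
  lab <- .align_labels(table, labels)$label
  missing_cols <- setdiff(components, algorithms(table))
  if (length(missing_cols)) {
    stop("score table lacks component column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cv <- lapply(components, function(a)
    crossvalidate_threshold(table[[a]], lab, registry_spec(a, registry),
                            k = k, seed = seed))
  names(cv) <- components
  refit_cutoff <- identical(cutoff, "refit")
  model <- fit_ensemble(cv, cutoff = if (refit_cutoff) 0.367 else cutoff,
                        min_components = min_components,
                        weighting = weighting)
  obj <- structure(list(model = model, cv = cv, k = k, seed = seed,
                        n_variants = nrow(table),
                        call = match.call()),
                   class = "apf2")
  if (refit_cutoff) {
    sc <- predict(obj, table)$apf2_score
    ok <- !is.na(sc)
    # low score = deleterious, and calls use "<= cutoff": candidates are
    # midpoints so the boundary convention cannot flip the optimum
    fit <- optimize_threshold(sc[ok], lab[ok],
                              algorithm_spec("apf2", "deleterious_if_low",
                                             0.367, strict = FALSE))
    cut <- min(max(fit$optimized_threshold, 1e-6), 1 - 1e-6)
    obj$model$cutoff <- cut
  }
  obj
}

#' Score variants with a fitted ensemble model
#'
#' @param object An \code{apf2} fit (or use [apf2_score()] directly with an
#'   \code{apf2_model}).
#' @param newdata A [score_table()] containing the component columns.
#' @param ... Unused.
#' @return A data frame with one row per variant: \code{variant} (key),
#'   \code{apf2_score}, \code{call}, \code{n_components_used}, and one
#'   \code{vote_*} column per component (1 functional, 0 deleterious,
#'   \code{NA} unscored).
#' @export
predict.apf2 <- function(object, newdata, ...) {
  model <- if (inherits(object, "apf2_model")) object else object$model
  stopifnot(inherits(newdata, "score_table"))
  comp <- model$components$algorithm
  have <- intersect(comp, algorithms(newdata))
  res <- lapply(seq_len(nrow(newdata)), function(i) {
    s <- vapply(comp, function(a)
      if (a %in% have) newdata[[a]][i] else NA_real_, 0)
    apf2_score(s, model)
  })
  votes <- do.call(rbind, lapply(res, `[[`, "votes"))
  colnames(votes) <- paste0("vote_", comp)
  out <- data.frame(
    variant = variant_keys(newdata),
    apf2_score = vapply(res, `[[`, 0, "score"),
    call = vapply(res, `[[`, "", "call"),
    n_components_used = vapply(res, `[[`, 0L, "n_components_used"),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(votes))
}

#' @rdname predict.apf2
#' @export
predict.apf2_model <- predict.apf2

#' @export
coef.apf2 <- function(object, ...) {
  stats::setNames(object$model$components$weight,
                  object$model$components$algorithm)
}

#' @export
coef.apf2_model <- function(object, ...) {
  stats::setNames(object$components$weight, object$components$algorithm)
}

#' @export
print.apf2_model <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<apf2_model> %d components, cutoff %.3f (<= deleterious), min %d scored; %s weights\n",
    nrow(x$components), x$cutoff, x$min_components, x$weighting))
  comp <- x$components
  num <- vapply(comp, is.numeric, TRUE)
  comp[num] <- lapply(comp[num], round, digits)
  print(comp, row.names = FALSE)
  invisible(x)
}

#' @export
print.apf2 <- function(x, ...) {
  cat("Ensemble variant effect model (", x$k, "-fold CV, seed ", x$seed,
      ", n = ", x$n_variants, " variants)\n\n", sep = "")
  print(x$model)
  invisible(x)
}

#' @export
summary.apf2 <- function(object, ...) {
  per <- do.call(rbind, lapply(object$cv, function(cv) {
    ff <- cv$final_fit
    data.frame(algorithm = cv$algorithm,
               conventional_threshold = ff$conventional_threshold,
               optimized_threshold = ff$optimized_threshold,
               J_conventional = ff$J_conventional,
               J_optimized = ff$J_optimized, delta_J = ff$delta_J,
               mean_val_J = cv$mean_val_J,
               mean_val_delta_J = mean(cv$folds$val_delta_J),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  per$weight <- coef(object)[per$algorithm]
  structure(list(components = per, cutoff = object$model$cutoff,
                 k = object$k, seed = object$seed,
                 n_variants = object$n_variants),
            class = "summary.apf2")
}

#' @export
print.summary.apf2 <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Ensemble model summary (n = %d variants, %d-fold CV, seed %d)\n",
    x$n_variants, x$k, x$seed))
  comp <- x$components
  num <- vapply(comp, is.numeric, TRUE)
  comp[num] <- lapply(comp[num], round, digits)
  print(comp, row.names = FALSE)
  cat(sprintf("deleterious cutoff on ensemble score: <= %.3f\n", x$cutoff))
  invisible(x)
}

#' @export
plot.apf2 <- function(x, ...) {
  vals <- lapply(x$cv, function(cv) cv$folds$val_delta_J)
  graphics::boxplot(vals, ylab = "validation-fold delta J",
                    main = "Cross-validated informedness gain", las = 2, ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
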