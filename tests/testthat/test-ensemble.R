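test_that("ensemble weights are informedness-proportional and normalized", {
  mk_fit <- function(name, j) {
    structure(list(algorithm = name, direction = "deleterious_if_high",
                   strict = FALSE, optimized_threshold = 0.5,
                   J_optimized = j, J_conventional = j, delta_J = 0,
                   conventional_threshold = 0.5, n_used = 100L),
              class = "threshold_fit")
  }
  m <- fit_ensemble(list(mk_fit("A", 0.4), mk_fit("B", 0.4),
                         mk_fit("C", 0.2)))
  expect_equal(unname(coef(m)), c(0.4, 0.4, 0.2))
  m2 <- fit_ensemble(list(mk_fit("A", 0.3), mk_fit("B", 0.3)))
  expect_equal(unname(coef(m2)), c(0.5, 0.5))
  # single informative component carries all the weight
  m1 <- fit_ensemble(list(mk_fit("A", 0.5)))
  expect_equal(unname(coef(m1)), 1)
  # non-positive informedness is dropped; too few remaining is an error
  expect_warning(
    expect_error(fit_ensemble(list(mk_fit("A", 0.5), mk_fit("B", -0.1))),
                 "fewer than 2"),
    "non-positive")
  expect_equal(unname(coef(fit_ensemble(list(mk_fit("A", 0.5),
                                             mk_fit("B", 0.5)),
                                        weighting = "uniform"))),
               c(0.5, 0.5))
})

test_that("ensemble score hits its bounds at unanimous votes", {
  m <- apf2_default_model()
  all_del <- apf2_score(vote_scores(rep(0, 5), m), m)
  expect_equal(all_del$score, 0)
  expect_equal(all_del$call, "deleterious")
  all_fun <- apf2_score(vote_scores(rep(1, 5), m), m)
  expect_equal(all_fun$score, 1)
  expect_equal(all_fun$call, "neutral")
  expect_equal(all_fun$n_components_used, 5L)
})

test_that("score is monotone under single-vote flips over all patterns", {
  m <- apf2_default_model()
  patterns <- expand.grid(rep(list(0:1), 5))
  score_of <- function(v) apf2_score(vote_scores(as.numeric(v), m), m)$score
  for (r in seq_len(nrow(patterns))) {
    v <- as.numeric(patterns[r, ])
    s0 <- score_of(v)
    expect_equal(s0, sum(coef(m) * v))  # weighted functional fraction
    for (i in which(v == 0)) {
      v2 <- v; v2[i] <- 1
      expect_gt(score_of(v2), s0)       # flipping to functional raises it
    }
  }
})

test_that("weights renormalize over every scorable missingness pattern", {
  m <- apf2_default_model()   # min_components = 3
  w <- coef(m)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), 5))
  for (r in seq_len(nrow(patterns))) {
    avail <- unlist(patterns[r, ])
    votes <- ifelse(avail, 1, NA)       # all available vote functional
    res <- apf2_score(vote_scores(votes, m), m)
    if (sum(avail) >= 3) {
      expect_equal(res$score, 1)        # renormalized weights sum to 1
      expect_equal(res$n_components_used, sum(avail))
      # a mixed pattern: first available votes deleterious
      votes2 <- votes; votes2[which(avail)[1]] <- 0
      res2 <- apf2_score(vote_scores(votes2, m), m)
      expect_equal(res2$score,
                   sum(w[avail][-1]) / sum(w[avail]), tolerance = 1e-12)
    } else {
      expect_equal(res$call, "no_call")
      expect_true(is.na(res$score))
    }
  }
})

test_that("uniform weights reduce the score to the functional fraction", {
  mk_fit <- function(name) {
    structure(list(algorithm = name, direction = "deleterious_if_high",
                   strict = FALSE, optimized_threshold = 0.5,
                   J_optimized = 0.5, J_conventional = 0.5, delta_J = 0,
                   conventional_threshold = 0.5, n_used = 10L),
              class = "threshold_fit")
  }
  m <- fit_ensemble(lapply(c("A", "B", "C", "D"), mk_fit),
                    weighting = "uniform", min_components = 2)
  set.seed(2)
  for (i in 1:20) {
    votes <- sample(0:1, 4, replace = TRUE)
    res <- apf2_score(vote_scores(votes, m), m)
    expect_equal(res$score, mean(votes))   # brute-force majority fraction
  }
})

test_that("classification at the cutoff is deleterious-inclusive", {
  expect_equal(classify(0.367), "deleterious")
  expect_equal(classify(0.368), "neutral")
  expect_equal(classify(0, cutoff = 0), "deleterious")
  expect_equal(classify(c(0.2, 0.9)), c("deleterious", "neutral"))
})

test_that("the fitted model scores new variants through predict", {
  sim <- simulate_labeled_scores(sim_config(n_deleterious = 120,
                                            n_neutral = 120, seed = 31))
  fit <- apf2(sim$scores, sim$labels, seed = 31)
  pred <- predict(fit, sim$scores)
  expect_equal(nrow(pred), 240L)
  expect_true(all(pred$call %in% c("deleterious", "neutral", "no_call")))
  scored <- !is.na(pred$apf2_score)
  expect_true(all(pred$apf2_score[scored] >= 0 &
                  pred$apf2_score[scored] <= 1))
  expect_true(all(pred$n_components_used[!scored] <
                  fit$model$min_components))
  expect_equal(pred$call[scored],
               classify(pred$apf2_score[scored], fit$model$cutoff))
  # weights are positive and normalized
  expect_equal(sum(coef(fit)), 1)
  expect_true(all(coef(fit) > 0))
})

test_that("ensemble does not degrade a dominant component on separable data", {
  alg <- default_sim_algorithms()
  alg$missing_rate[] <- 0
  cfg <- sim_config(n_deleterious = 300, n_neutral = 300,
                    algorithms = alg, seed = 17)
  sim <- simulate_labeled_scores(cfg)
  fit <- apf2(sim$scores, sim$labels, seed = 17)
  pred <- predict(fit, sim$scores)
  lab <- sim$labels$label
  # ensemble score is oriented so low = deleterious
  ens_auc <- auc(roc_points(pred$apf2_score, lab, "deleterious_if_low"))
  single <- vapply(alg$name, function(a)
    auc(roc_points(sim$scores[[a]], lab, alg$direction[match(a, alg$name)])),
    0)
  expect_gte(ens_auc, max(single) - 0.02)
})

test_that("activity map recovers exact linear and degenerate relationships", {
  # variants placed at the bin midpoints, activity exactly linear in score
  mids <- (2 * (1:7) - 1) / 14
  sc <- rep(mids, each = 15)
  map <- fit_activity_map(sc, 10 + 90 * sc)
  expect_equal(map$r_squared, 1, tolerance = 1e-9)
  expect_equal(map$slope, 90, tolerance = 1e-6)
  # prediction at a bin midpoint equals that bin's mean for linear data
  mid <- map$bins$midpoint[3]
  expect_equal(predict_activity(mid, map), map$bins$mean_activity[3],
               tolerance = 1e-6)

  const <- fit_activity_map(sc, rep(42, length(sc)))
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 0)

  expect_error(fit_activity_map(c(0.1, 0.12), c(50, 60)), "at least 3")
  expect_error(fit_activity_map(rep(0.1, 10), runif(10, 0, 100)),
               "non-empty")
})

test_that("activity predictions clamp and stay monotone", {
  set.seed(6)
  sc <- runif(200)
  map <- fit_activity_map(sc, pmax(pmin(5 + 100 * sc + rnorm(200, 0, 5),
                                        120), 0))
  grid <- seq(0, 1, by = 0.05)
  pred <- predict_activity(grid, map)
  expect_true(all(diff(pred) >= 0))              # increasing map
  expect_true(all(pred >= 0 & pred <= map$max_activity))
  # intercept evaluation at score 0 (positive intercept, no clamping)
  mids <- (2 * c(1, 3, 5, 7) - 1) / 14
  map0 <- fit_activity_map(mids, 20 + 50 * mids)
  expect_equal(map0$intercept, 20, tolerance = 1e-6)
  expect_equal(predict_activity(0, map0), map0$intercept, tolerance = 1e-9)
})

test_that("unrelated activities rarely yield a significant slope", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    sc <- runif(500)
    act <- runif(500, 0, 100)        # independent of score
    map <- fit_activity_map(sc, act)
    if (map$p_value <= 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 10L)              # >= 90% of replicates non-significant
})
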