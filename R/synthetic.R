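#' Class-conditional score distributions of the simulated predictors
#'
#' Default generating parameters for five simulated component predictors.
#' Locations and scales are chosen so each simulated tool's theoretical
#' discriminative power (Gaussian two-class AUC
#' \eqn{\Phi(\Delta\mu / (\sigma\sqrt{2}))}) and its missingness rate match
#' the values observed for the corresponding real predictors on the
#' combined pharmacogenomic benchmark (AUCs 0.80, 0.76, 0.75, 0.76, 0.74;
#' missingness 33, 4, 22, 25 and 1 percent), on each tool's own score
#' scale and deleteriousness direction.
#'
#' @return Data frame with columns \code{name}, \code{mu_deleterious},
#'   \code{sd_deleterious}, \code{mu_neutral}, \code{sd_neutral},
#'   \code{missing_rate}, \code{direction}.
#' @export
default_sim_algorithms <- function() {
  data.frame(
    name = c("AlphaMissense", "PROVEAN", "MutationAssessor", "PolyPhen-2",
             "VEST4"),
    mu_deleterious = c(0.5119, -3.4976, 2.3447, 0.6495, 0.6229),
    sd_deleterious = c(0.22, 2.0, 1.2, 0.35, 0.30),
    mu_neutral = c(0.25, -1.5, 1.2, 0.30, 0.35),
    sd_neutral = c(0.22, 2.0, 1.2, 0.35, 0.30),
    missing_rate = c(0.33, 0.04, 0.22, 0.25, 0.01),
    direction = c("deleterious_if_high", "deleterious_if_low",
                  "deleterious_if_high", "deleterious_if_high",
                  "deleterious_if_high"),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the fixture generators: class sizes and
#' per-algorithm class-conditional score distributions with missingness
#' rates for [simulate_labeled_scores()], and the gene/population/allele
#' frequency spectrum parameters for [simulate_frequency_table()].  All
#' generators are pure functions of (config, seed).  The default class
#' sizes (285 deleterious, 245 neutral) reproduce the size and approximate
#' class balance of the 530-variant combined fitting set.
#'
#' @param n_deleterious,n_neutral Number of variants per class.
#' @param algorithms Data frame as returned by [default_sim_algorithms()].
#' @param family Score noise family: \code{"gaussian"} (default, closed-form
#'   oracles) or \code{"t"} (location-scale t, heavy tails, stresses
#'   tie-breaking).
#' @param t_df Degrees of freedom for \code{family = "t"}.
#' @param genes Gene symbols for the frequency fixture.
#' @param n_variants_per_gene Variants simulated per gene and population.
#' @param populations Population labels (default: the eight ethnogeographic
#'   groups of current population-scale sequencing resources).
#' @param prop_rare Proportion of variants drawn from the rare part of the
#'   frequency spectrum (allele frequency below 1 percent).
#' @param seed Mandatory integer seed.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_deleterious = 285, n_neutral = 245,
                       algorithms = default_sim_algorithms(),
                       family = c("gaussian", "t"), t_df = 3,
                       genes = c("CYP2C9", "CYP2D6", "CYP3A5", "SLCO1B1",
                                 "TPMT", "DPYD", "NUDT15", "CYP2C19",
                                 "UGT1A1", "ABCB1"),
                       n_variants_per_gene = 40,
                       populations = c("AFR", "AMR", "ASJ", "EAS", "FIN",
                                       "NFE", "SAS", "MID"),
                       prop_rare = 0.7, seed) {
  family <- match.arg(family)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_deleterious >= 0, n_neutral >= 0,
            is.data.frame(algorithms),
            all(c("name", "mu_deleterious", "sd_deleterious", "mu_neutral",
                  "sd_neutral", "missing_rate", "direction") %in%
                  names(algorithms)),
            all(algorithms$missing_rate >= 0 & algorithms$missing_rate <= 1),
            prop_rare >= 0, prop_rare <= 1,
            n_variants_per_gene >= 1, length(genes) >= 1,
            length(populations) >= 1)
  if (any(algorithms$sd_deleterious <= 0 | algorithms$sd_neutral <= 0)) {
    stop("degenerate scale: class-conditional sd must be > 0", call. = FALSE)
  }
  structure(list(n_deleterious = as.integer(n_deleterious),
                 n_neutral = as.integer(n_neutral),
                 algorithms = algorithms, family = family, t_df = t_df,
                 genes = genes,
                 n_variants_per_gene = as.integer(n_variants_per_gene),
                 populations = populations, prop_rare = prop_rare,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.rclass <- function(n, mu, sd, family, t_df) {
  if (family == "gaussian") stats::rnorm(n, mu, sd)
  else mu + sd * stats::rt(n, df = t_df)
}

#' Simulate a labeled predictor score table
#'
#' Generates a variant set with known binary ground truth: per algorithm,
#' scores are drawn from its class-conditional distribution and missingness
#' is injected completely at random at the configured per-algorithm rate.
#' Simulated in-vitro activities consistent with the labels (deleterious
#' below 50 percent of wild type) are attached so the activity-map fit can
#' be exercised.  Reproducible: same config and seed, same tables.
#'
#' @param cfg A [sim_config()].
#' @return A list with \code{scores} (a [score_table()]) and \code{labels}
#'   (a [labeled_variants()] set).
#' @export
simulate_labeled_scores <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_deleterious + cfg$n_neutral
  alg <- cfg$algorithms
  .with_seed(cfg$seed, {
    variants <- data.frame(
      gene = rep_len(cfg$genes, n),
      protein_change = sprintf("p.V%dA", seq_len(max(n, 1L))[seq_len(n)]),
      stringsAsFactors = FALSE)
    label <- rep(c("deleterious", "neutral"),
                 c(cfg$n_deleterious, cfg$n_neutral))
    scores <- lapply(seq_len(nrow(alg)), function(i) {
      s <- numeric(n)
      del <- label == "deleterious"
      s[del] <- .rclass(sum(del), alg$mu_deleterious[i],
                        alg$sd_deleterious[i], cfg$family, cfg$t_df)
      s[!del] <- .rclass(sum(!del), alg$mu_neutral[i], alg$sd_neutral[i],
                         cfg$family, cfg$t_df)
      s[stats::runif(n) < alg$missing_rate[i]] <- NA_real_
      s
    })
    names(scores) <- alg$name
    activity <- numeric(n)
    del <- label == "deleterious"
    activity[del] <- pmin(pmax(stats::rnorm(sum(del), 20, 15), 0), 49.9)
    activity[!del] <- pmin(pmax(stats::rnorm(sum(!del), 85, 15), 50), 130)
    if (n == 0L) activity <- numeric(0)
    list(scores = score_table(variants,
                              as.data.frame(scores, optional = TRUE)),
         labels = labeled_variants(variants, label,
                                   evidence = rep("in_vitro", n),
                                   activity = activity))
  })
}

#' Large-sample optimal threshold of a simulated predictor
#'
#' Closed-form oracle for threshold-recovery tests: with equal class sizes,
#' the threshold maximizing Youden's J converges to the point where the two
#' class-conditional densities intersect.  For equal scales this is the
#' midpoint of the class means; for unequal scales it is the root of the
#' log-density quadratic lying between the means.
#'
#' @param cfg A [sim_config()] with \code{family = "gaussian"}.
#' @param algorithm Algorithm name in \code{cfg$algorithms}.
#' @return The analytic optimal threshold (numeric scalar).
#' @export
analytic_optimal_threshold <- function(cfg, algorithm) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$family != "gaussian") {
    stop("closed-form threshold available for the gaussian family only",
         call. = FALSE)
  }
  i <- match(algorithm, cfg$algorithms$name)
  if (is.na(i)) stop("unknown algorithm: ", algorithm, call. = FALSE)
  m1 <- cfg$algorithms$mu_deleterious[i]
  s1 <- cfg$algorithms$sd_deleterious[i]
  m2 <- cfg$algorithms$mu_neutral[i]
  s2 <- cfg$algorithms$sd_neutral[i]
  if (isTRUE(all.equal(m1, m2))) {
    stop(sprintf("'%s' has identical class means: no informative threshold",
                 algorithm), call. = FALSE)
  }
  if (isTRUE(all.equal(s1, s2))) return((m1 + m2) / 2)
  # equal-density condition: quadratic in x
  a <- 1 / s1^2 - 1 / s2^2
  b <- -2 * (m1 / s1^2 - m2 / s2^2)
  cc <- m1^2 / s1^2 - m2^2 / s2^2 + 2 * log(s1 / s2)
  disc <- b^2 - 4 * a * cc
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  lo <- min(m1, m2); hi <- max(m1, m2)
  inside <- roots[roots >= lo & roots <= hi]
  if (length(inside)) inside[1] else roots[which.min(abs(roots - (lo + hi) / 2))]
}

#' Simulate a population allele-frequency table
#'
#' Generates a long-format frequency table per gene and population with a
#' configured mixture of common variants (allele frequency uniform on
#' \code{[0.01, 0.5]}) and rare variants (log-uniform on
#' \code{[1e-5, 0.01)}), matching the rare/common dichotomy at the 1
#' percent boundary.  Each variant's rarity class is fixed across
#' populations; its frequency is drawn independently per population.
#' Reproducible: same config and seed, same table.
#'
#' @param cfg A [sim_config()].
#' @return A [frequency_table()].
#' @export
simulate_frequency_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed + 1L, {
    n_var <- length(cfg$genes) * cfg$n_variants_per_gene
    variants <- data.frame(
      gene = rep(cfg$genes, each = cfg$n_variants_per_gene),
      protein_change = sprintf("p.G%dS", seq_len(n_var)),
      stringsAsFactors = FALSE)
    rare <- stats::runif(n_var) < cfg$prop_rare
    rows <- lapply(cfg$populations, function(pop) {
      p <- ifelse(rare,
                  10^stats::runif(n_var, -5, log10(0.01)),
                  stats::runif(n_var, 0.01, 0.5))
      # log-uniform draws can land on the boundary by rounding; keep rare
      # strictly below 1%
      p[rare & p >= 0.01] <- 0.0099
      cbind(variants, population = pop, allele_frequency = p,
            stringsAsFactors = FALSE)
    })
    all_rows <- do.call(rbind, rows)
    frequency_table(all_rows[c("gene", "protein_change")],
                    all_rows$population, all_rows$allele_frequency)
  })
}
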