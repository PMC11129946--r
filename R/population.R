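# Population-scale aggregation assumes Hardy-Weinberg equilibrium and
# independence across variant sites and genes; linkage is ignored.  Only
# allele frequencies are needed, never individual genotypes.

#' Carrier frequency of a variant allele under Hardy-Weinberg equilibrium
#'
#' Probability that a diploid individual carries at least one copy of an
#' allele at frequency p: \code{1 - (1 - p)^2 = 2p - p^2}.
#'
#' @param p Allele frequency in \code{[0, 1]} (vectorized).
#' @return Carrier frequency in \code{[0, 1]}.
#' @examples
#' carrier_frequency(0.1)  # 0.19
#' @export
carrier_frequency <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  1 - (1 - p)^2
}

# Subset a frequency table to (population, optional deleterious keys,
# optional genes), deduplicated by variant key.
.freq_subset <- function(freqs, deleterious = NULL, population, genes = NULL) {
  stopifnot(inherits(freqs, "frequency_table"))
  known <- unique(freqs$population)
  if (!population %in% known) {
    stop(sprintf("unknown population '%s'; known: %s", population,
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  f <- freqs[freqs$population == population, , drop = FALSE]
  if (!is.null(deleterious)) {
    if (inherits(deleterious, "labeled_variants")) {
      deleterious <- variant_keys(
        deleterious[deleterious$label == "deleterious", , drop = FALSE])
    }
    f <- f[variant_keys(f) %in% deleterious, , drop = FALSE]
  }
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, unique(freqs$gene))
    if (length(missing_genes)) {
      stop("unknown gene(s): ", paste(missing_genes, collapse = ", "),
           call. = FALSE)
    }
    f <- f[f$gene %in% genes, , drop = FALSE]
  }
  f[!duplicated(variant_keys(f)), , drop = FALSE]
}

#' Expected deleterious-variant burden per individual
#'
#' Aggregates allele frequencies of a deleterious variant set into the
#' expected number of variant alleles a diploid individual carries,
#' \eqn{\sum_v 2 p_v} under Hardy-Weinberg equilibrium, together with the
#' probability of carrying at least one such allele,
#' \eqn{1 - \prod_v (1 - p_v)^2}, and the fraction of the burden allotted
#' to rare variants (allele frequency below 1 percent).
#'
#' @param freqs A [frequency_table()].
#' @param deleterious Variant keys (character), a \code{labeled_variants}
#'   set (its deleterious variants are used), or \code{NULL} for all
#'   variants in the table.
#' @param population Population label present in \code{freqs}.
#' @param genes Optional gene subset; default genome-wide.
#' @return A list of class \code{"burden_report"} with \code{population},
#'   \code{genes}, \code{n_variants},
#'   \code{expected_variants_per_individual}, \code{carrier_frequency},
#'   \code{rare_fraction}, \code{common_fraction}.
#' @examples
#' ft <- frequency_table(
#'   data.frame(gene = c("CYP2C9", "CYP2C9"),
#'              protein_change = c("p.R144C", "p.I359L")),
#'   population = c("EUR", "EUR"), allele_frequency = c(0.25, 0.25))
#' expected_burden(ft, population = "EUR")$expected_variants_per_individual
#' @export
expected_burden <- function(freqs, deleterious = NULL, population,
                            genes = NULL) {
  f <- .freq_subset(freqs, deleterious, population, genes)
  p <- f$allele_frequency
  burden <- sum(2 * p)
  rare <- if (burden > 0) sum(2 * p[p < 0.01]) / burden else NA_real_
  structure(list(
    population = population,
    genes = if (is.null(genes)) "all" else paste(genes, collapse = ","),
    n_variants = nrow(f),
    expected_variants_per_individual = burden,
    carrier_frequency = 1 - prod((1 - p)^2),
    rare_fraction = rare,
    common_fraction = if (is.na(rare)) NA_real_ else 1 - rare),
    class = "burden_report")
}

#' @export
print.burden_report <- function(x, ...) {
  cat(sprintf(
    "<burden_report> %s / %s: %.3g variants per individual (carrier freq %.3g, rare fraction %s) over %d variants\n",
    x$population, x$genes, x$expected_variants_per_individual,
    x$carrier_frequency,
    if (is.na(x$rare_fraction)) "NA" else sprintf("%.3g", x$rare_fraction),
    x$n_variants))
  invisible(x)
}

#' Split the variant burden into rare and common components
#'
#' Fraction of the expected per-individual burden carried by rare variants:
#' rare means allele frequency strictly below 1 percent, and a frequency of
#' exactly 1 percent counts as common.
#'
#' @inheritParams expected_burden
#' @return Named numeric vector \code{c(rare_fraction, common_fraction)}.
#' @examples
#' ft <- frequency_table(
#'   data.frame(gene = "G", protein_change = c("p.A1B", "p.C2D")),
#'   population = c("EUR", "EUR"), allele_frequency = c(0.005, 0.095))
#' stratify_by_maf(ft, population = "EUR")  # rare fraction 0.05
#' @export
stratify_by_maf <- function(freqs, deleterious = NULL, population,
                            genes = NULL) {
  b <- expected_burden(freqs, deleterious, population, genes)
  c(rare_fraction = b$rare_fraction, common_fraction = b$common_fraction)
}

#' Define a drug-gene actionability rule
#'
#' Describes when an individual's genotype makes them expected to benefit
#' from a dose adjustment or alternative drug: carrying any deleterious
#' variant allele in a rule gene (e.g. dominant-acting transporter
#' variants), or two variant alleles (recessive loss of enzyme function).
#' Multi-gene rules trigger when any member gene triggers.
#'
#' @param drug Drug name.
#' @param genes Character vector of gene symbols (at least one).
#' @param trigger \code{"any_variant_allele"} or \code{"two_variant_alleles"}.
#' @param description Optional free-text note.
#' @return An object of class \code{"risk_rule"}.
#' @export
risk_rule <- function(drug, genes,
                      trigger = c("any_variant_allele",
                                  "two_variant_alleles"),
                      description = "") {
  trigger <- match.arg(trigger)
  stopifnot(is.character(drug), length(drug) == 1L,
            is.character(genes), length(genes) >= 1L)
  structure(list(drug = drug, genes = genes, trigger = trigger,
                 description = description),
            class = "risk_rule")
}

#' Read actionability rules from a JSON file
#'
#' Expects a JSON array of objects with fields \code{drug}, \code{genes},
#' \code{trigger}, optional \code{description}.
#'
#' @param path Path to the JSON file.
#' @return List of [risk_rule()]s.
#' @export
read_risk_rules <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    risk_rule(r$drug, unlist(r$genes), r$trigger,
              if (is.null(r$description)) "" else r$description)
  })
}

#' Fraction of a population at risk under an actionability rule
#'
#' For each rule gene the deleterious allele frequencies are aggregated
#' into the probability \eqn{q = 1 - \prod_v (1 - p_v)} that a random
#' haplotype carries at least one deleterious allele of that gene.  Under
#' Hardy-Weinberg equilibrium the per-gene triggering fraction is
#' \eqn{1 - (1 - q)^2} for an any-allele trigger and \eqn{q^2} for a
#' two-allele trigger; genes combine as \eqn{1 - \prod_g (1 - f_g)}.
#' Reported per 1000 individuals.
#'
#' @param freqs A [frequency_table()].
#' @param deleterious Deleterious variant keys or \code{labeled_variants}
#'   (or \code{NULL} to treat every variant in \code{freqs} as deleterious).
#' @param rule A [risk_rule()].
#' @param population Population label present in \code{freqs}.
#' @return A list of class \code{"risk_report"} with \code{drug},
#'   \code{population}, \code{at_risk_fraction}, \code{at_risk_per_1000}.
#' @examples
#' ft <- frequency_table(
#'   data.frame(gene = "CYP2C19", protein_change = "p.P227P"),
#'   population = "EAS", allele_frequency = 0.2)
#' at_risk_fraction(ft, rule = risk_rule("clopidogrel", "CYP2C19",
#'                  "two_variant_alleles"), population = "EAS")
#' @export
at_risk_fraction <- function(freqs, deleterious = NULL, rule, population) {
  stopifnot(inherits(rule, "risk_rule"))
  per_gene <- vapply(rule$genes, function(g) {
    f <- .freq_subset(freqs, deleterious, population, genes = g)
    q <- 1 - prod(1 - f$allele_frequency)
    switch(rule$trigger,
           any_variant_allele = 1 - (1 - q)^2,
           two_variant_alleles = q^2)
  }, 0)
  frac <- 1 - prod(1 - per_gene)
  structure(list(drug = rule$drug, population = population,
                 at_risk_fraction = frac,
                 at_risk_per_1000 = 1000 * frac),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("<risk_report> %s / %s: %.1f per 1000 individuals\n",
              x$drug, x$population, x$at_risk_per_1000))
  invisible(x)
}

#' Burden and risk tables across populations
#'
#' Convenience wrappers applying [expected_burden()] and
#' [at_risk_fraction()] over every population (and optionally every gene)
#' in a frequency table, producing long-format result tables.
#'
#' @inheritParams expected_burden
#' @param by_gene Also break the burden down per gene (default FALSE).
#' @return A data frame, one row per population (and gene when
#'   \code{by_gene}).
#' @export
burden_table <- function(freqs, deleterious = NULL, by_gene = FALSE) {
  pops <- unique(freqs$population)
  scopes <- if (by_gene) unique(freqs$gene) else list(NULL)
  rows <- list()
  for (pop in pops) {
    for (g in scopes) {
      b <- expected_burden(freqs, deleterious, pop,
                           genes = if (is.null(g)) NULL else g)
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, genes = b$genes, n_variants = b$n_variants,
        expected_variants_per_individual =
          b$expected_variants_per_individual,
        carrier_frequency = b$carrier_frequency,
        rare_fraction = b$rare_fraction, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname burden_table
#' @param rules List of [risk_rule()]s.
#' @export
risk_table <- function(freqs, deleterious = NULL, rules) {
  if (inherits(rules, "risk_rule")) rules <- list(rules)
  pops <- unique(freqs$population)
  rows <- list()
  for (r in rules) {
    for (pop in pops) {
      x <- at_risk_fraction(freqs, deleterious, r, pop)
      rows[[length(rows) + 1L]] <- data.frame(
        drug = x$drug, population = pop,
        at_risk_per_1000 = x$at_risk_per_1000, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
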