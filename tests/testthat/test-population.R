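make_freqs <- function(p, gene = "CYP2C9", population = "EUR") {
  n <- length(p)
  frequency_table(
    data.frame(gene = rep_len(gene, n),
               protein_change = sprintf("p.G%dS", seq_len(n)),
               stringsAsFactors = FALSE),
    rep_len(population, n), p)
}

test_that("carrier frequency follows the Hardy-Weinberg closed form", {
  expect_equal(carrier_frequency(0), 0)
  expect_equal(carrier_frequency(1), 1)
  expect_equal(carrier_frequency(0.1), 0.19)  # 2*0.1*0.9 + 0.1^2
  p <- seq(0, 1, by = 0.05)
  expect_true(all(carrier_frequency(p) <= 2 * p + 1e-12))
  expect_true(all(carrier_frequency(p[p > 0]) < 2 * p[p > 0]))
  expect_error(carrier_frequency(1.1))
})

test_that("expected burden aggregates 2p with closed-form carrier product", {
  b <- expected_burden(make_freqs(0.5), population = "EUR")
  expect_equal(b$expected_variants_per_individual, 1)

  b2 <- expected_burden(make_freqs(c(0.25, 0.25)), population = "EUR")
  expect_equal(b2$expected_variants_per_individual, 1)
  expect_equal(b2$carrier_frequency, 1 - 0.75^4)

  expect_error(expected_burden(make_freqs(0.1), population = "AFR"),
               "unknown population.*EUR")
})

test_that("burden is additive over disjoint variant sets", {
  ft <- make_freqs(c(0.1, 0.2, 0.3, 0.05))
  keys <- variant_keys(ft)
  whole <- expected_burden(ft, population = "EUR")
  part1 <- expected_burden(ft, deleterious = keys[1:2], population = "EUR")
  part2 <- expected_burden(ft, deleterious = keys[3:4], population = "EUR")
  expect_equal(part1$expected_variants_per_individual +
                 part2$expected_variants_per_individual,
               whole$expected_variants_per_individual)
  # empty deleterious subset: zero burden, zero carriers
  none <- expected_burden(ft, deleterious = "GENE0:p.X0Y",
                          population = "EUR")
  expect_equal(none$expected_variants_per_individual, 0)
  expect_equal(none$carrier_frequency, 0)
})

test_that("rare/common stratification splits at the 1% boundary", {
  all_common <- stratify_by_maf(make_freqs(c(0.02, 0.3)), population = "EUR")
  expect_equal(unname(all_common["rare_fraction"]), 0)

  boundary <- stratify_by_maf(make_freqs(c(0.01, 0.005)), population = "EUR")
  # p = 0.01 exactly is common: rare share is 0.005/(0.01+0.005)
  expect_equal(unname(boundary["rare_fraction"]), 0.005 / 0.015)

  mix <- stratify_by_maf(make_freqs(c(0.005, 0.095)), population = "EUR")
  expect_equal(unname(mix["rare_fraction"]), 0.05)
  expect_equal(sum(mix), 1)
})

test_that("burden deduplicates repeated frequency rows by variant key", {
  ft <- make_freqs(c(0.1, 0.2))
  dup <- structure(rbind(as.data.frame(ft), as.data.frame(ft)),
                   class = class(ft))
  expect_equal(expected_burden(dup, population = "EUR")$
                 expected_variants_per_individual,
               expected_burden(ft, population = "EUR")$
                 expected_variants_per_individual)
  expect_equal(unname(stratify_by_maf(dup, population = "EUR")),
               unname(stratify_by_maf(ft, population = "EUR")))
})

test_that("at-risk fractions follow the genotype-trigger closed forms", {
  # aggregate deleterious allele frequency q = 0.2 in one gene
  ft <- make_freqs(0.2)
  any_rule <- risk_rule("drugA", "CYP2C9", "any_variant_allele")
  two_rule <- risk_rule("drugA", "CYP2C9", "two_variant_alleles")
  expect_equal(at_risk_fraction(ft, rule = any_rule,
                                population = "EUR")$at_risk_per_1000, 360)
  expect_equal(at_risk_fraction(ft, rule = two_rule,
                                population = "EUR")$at_risk_per_1000, 40)

  # zero frequency: nobody at risk
  expect_equal(at_risk_fraction(make_freqs(0), rule = any_rule,
                                population = "EUR")$at_risk_per_1000, 0)

  # single variant: any-allele risk equals carrier frequency exactly
  expect_equal(at_risk_fraction(ft, rule = any_rule,
                                population = "EUR")$at_risk_fraction,
               carrier_frequency(0.2))

  expect_error(at_risk_fraction(ft, rule = risk_rule("d", "NOGENE"),
                                population = "EUR"), "unknown gene")
})

test_that("multi-gene rules combine independently and monotonically", {
  vars <- data.frame(gene = c("CYP2C9", "VKORC1"),
                     protein_change = c("p.G1S", "p.G2S"))
  ft <- frequency_table(vars, c("EUR", "EUR"), c(0.2, 0.3))
  rule <- risk_rule("warfarin", c("CYP2C9", "VKORC1"), "any_variant_allele")
  f1 <- 1 - (1 - 0.2)^2
  f2 <- 1 - (1 - 0.3)^2
  expect_equal(at_risk_fraction(ft, rule = rule,
                                population = "EUR")$at_risk_fraction,
               1 - (1 - f1) * (1 - f2))
  # raising any allele frequency never lowers the at-risk fraction
  ft_hi <- frequency_table(vars, c("EUR", "EUR"), c(0.25, 0.3))
  expect_gte(at_risk_fraction(ft_hi, rule = rule,
                              population = "EUR")$at_risk_fraction,
             at_risk_fraction(ft, rule = rule,
                              population = "EUR")$at_risk_fraction)
})

test_that("population-wide tables cover every population and rule", {
  cfg <- sim_config(n_variants_per_gene = 5, seed = 23)
  ft <- simulate_frequency_table(cfg)
  bt <- burden_table(ft)
  expect_equal(sort(bt$population), sort(unique(ft$population)))
  expect_true(all(bt$expected_variants_per_individual >= 0))
  rt <- risk_table(ft, rules = list(
    risk_rule("a", cfg$genes[1], "any_variant_allele"),
    risk_rule("b", cfg$genes[2], "two_variant_alleles")))
  expect_equal(nrow(rt), 2 * length(cfg$populations))
  expect_true(all(rt$at_risk_per_1000 >= 0 & rt$at_risk_per_1000 <= 1000))
})

test_that("risk rules round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0(
    '[{"drug":"clopidogrel","genes":["CYP2C19"],',
    '"trigger":"two_variant_alleles","description":"loss of activation"},',
    '{"drug":"simvastatin","genes":["SLCO1B1"],',
    '"trigger":"any_variant_allele"}]'), path)
  rules <- read_risk_rules(path)
  expect_length(rules, 2L)
  expect_equal(rules[[1]]$trigger, "two_variant_alleles")
  expect_equal(rules[[2]]$genes, "SLCO1B1")
})
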