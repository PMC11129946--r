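# Fixture builders and independent oracles used across the suite.

make_variants <- function(n, gene = "GENE1") {
  data.frame(gene = rep_len(gene, n),
             protein_change = sprintf("p.A%dV", seq_len(n)),
             stringsAsFactors = FALSE)
}

make_score_table <- function(scores_list) {
  n <- length(scores_list[[1]])
  score_table(make_variants(n), as.data.frame(scores_list, optional = TRUE))
}

make_labels <- function(label, gene = "GENE1", activity = NULL) {
  labeled_variants(make_variants(length(label), gene), label,
                   activity = activity)
}

# Independent exhaustive-scan oracle for threshold optimization: classifies
# at every candidate with raw comparisons, no package internals.
brute_optimize <- function(scores, labels, direction) {
  ok <- !is.na(scores)
  s <- scores[ok]; l <- labels[ok]
  pos <- l == "deleterious"
  cands <- candidate_thresholds(s)
  best <- list(J = -Inf, SPE = -Inf, threshold = NA)
  for (t in cands) {
    del <- if (direction == "deleterious_if_high") s > t else s <= t
    sen <- sum(del & pos) / sum(pos)
    spe <- sum(!del & !pos) / sum(!pos)
    j <- sen + spe - 1
    better <- j > best$J + 1e-12 ||
      (abs(j - best$J) <= 1e-12 && spe > best$SPE + 1e-12)
    if (better) best <- list(J = j, SPE = spe, threshold = t)
  }
  best
}

# Independent pairwise-concordance AUC oracle (ties count one half).
concordance_auc <- function(scores, labels, direction = "deleterious_if_high") {
  ok <- !is.na(scores)
  s <- scores[ok]; l <- labels[ok]
  if (direction == "deleterious_if_low") s <- -s
  d <- s[l == "deleterious"]; n <- s[l == "neutral"]
  mean(outer(d, n, ">") + 0.5 * outer(d, n, "=="))
}

# Raw component scores that binarize to the requested votes under `model`
# (vote 1 = functional/neutral, 0 = deleterious, NA = missing).
vote_scores <- function(votes, model) {
  comp <- model$components
  s <- vapply(seq_len(nrow(comp)), function(i) {
    v <- votes[i]
    if (is.na(v)) return(NA_real_)
    off <- if (comp$direction[i] == "deleterious_if_high") 1 else -1
    # push the score clearly to the deleterious (+off) or functional (-off)
    # side of the component threshold
    comp$threshold[i] + if (v == 0) off else -off
  }, 0)
  stats::setNames(s, comp$algorithm)
}
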