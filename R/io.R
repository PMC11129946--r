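# Tables are exchanged as tab-separated text with a header row; "." or an
# empty cell encodes a missing score.  Variant identity is protein-centric:
# matching across tables is on (gene, protein_change) after trimming,
# case-sensitive; rsid/genomic columns are carried through but only used as
# the key when gene/protein_change are absent.

.key_cols <- c("gene", "protein_change", "rsid", "genomic")

#' Variant keys of a table
#'
#' Builds the display/matching key for each row of a variant table:
#' \code{"gene:protein_change"} when both are present, otherwise the rsid,
#' otherwise the genomic coordinate string.
#'
#' @param x A data frame with some of the columns \code{gene},
#'   \code{protein_change}, \code{rsid}, \code{genomic}.
#' @return Character vector of keys, one per row.
#' @export
variant_keys <- function(x) {
  n <- nrow(x)
  get_col <- function(nm) {
    if (nm %in% names(x)) trimws(as.character(x[[nm]])) else rep(NA_character_, n)
  }
  gene <- get_col("gene"); pc <- get_col("protein_change")
  rsid <- get_col("rsid"); genomic <- get_col("genomic")
  key <- ifelse(!is.na(gene) & nzchar(gene) & !is.na(pc) & nzchar(pc),
                paste(gene, pc, sep = ":"),
                ifelse(!is.na(rsid) & nzchar(rsid), rsid, genomic))
  if (anyNA(key) || any(!nzchar(key))) {
    stop("every variant needs gene+protein_change, an rsid, or a genomic key",
         call. = FALSE)
  }
  key
}

.check_unique_keys <- function(keys, what) {
  dup <- keys[duplicated(keys)]
  if (length(dup)) {
    stop(sprintf("duplicate variant key(s) in %s: %s", what,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
}

#' Construct a score table
#'
#' A score table holds one row per variant and one numeric column per
#' predictor; \code{NA} marks a score the predictor could not produce
#' (missingness is first-class and reported, never imputed).
#'
#' @param variants Data frame of variant key columns (\code{gene},
#'   \code{protein_change}, optionally \code{rsid}, \code{genomic}).
#' @param scores Numeric matrix or data frame, rows aligned with
#'   \code{variants}, one column per predictor.
#' @return A data frame of class \code{"score_table"}.
#' @export
score_table <- function(variants, scores) {
  scores <- as.data.frame(scores, optional = TRUE)
  stopifnot(nrow(variants) == nrow(scores))
  bad <- names(scores)[!vapply(scores, is.numeric, TRUE)]
  if (length(bad)) {
    stop("non-numeric score column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  inf <- names(scores)[vapply(scores, function(s) any(is.infinite(s)), TRUE)]
  if (length(inf)) {
    stop("non-finite scores in column(s): ", paste(inf, collapse = ", "),
         call. = FALSE)
  }
  out <- cbind(variants, scores)
  .check_unique_keys(variant_keys(out), "score table")
  rownames(out) <- NULL
  structure(out, algorithms = names(scores),
            class = c("score_table", "data.frame"))
}

#' Predictor columns of a score table
#' @param x A \code{score_table}.
#' @return Character vector of predictor names.
#' @export
algorithms <- function(x) attr(x, "algorithms")

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d variants x %d algorithms, %d missing cells\n",
              nrow(x), length(algorithms(x)),
              sum(is.na(as.matrix(x[, algorithms(x), drop = FALSE])))))
  NextMethod()
}

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, stringsAsFactors = FALSE)
}

.parse_numeric <- function(raw, column, missing_ok = TRUE) {
  raw <- trimws(raw)
  miss <- raw == "." | raw == "" | is.na(raw)
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!miss & is.na(out))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                 raw[bad[1]], column, bad[1]), call. = FALSE)
  }
  if (!missing_ok && any(miss)) {
    stop(sprintf("missing value not allowed in column '%s', row %d",
                 column, which(miss)[1]), call. = FALSE)
  }
  out[miss] <- NA_real_
  out
}

#' Read a predictor score table from TSV
#'
#' Expects a tab-separated file with a header row; columns named
#' \code{gene}, \code{protein_change}, \code{rsid}, \code{genomic} identify
#' the variant, every other column is parsed as one predictor's numeric
#' scores.  \code{"."} or an empty cell is a missing score.
#'
#' @param path Path to the TSV file.
#' @return A [score_table()].
#' @export
read_score_table <- function(path) {
  raw <- .read_tsv(path)
  keyc <- intersect(.key_cols, names(raw))
  algc <- setdiff(names(raw), .key_cols)
  if (!length(keyc)) stop("no variant key columns found", call. = FALSE)
  if (nrow(raw) == 0L) {
    vars <- raw[keyc]
    sc <- as.data.frame(lapply(raw[algc], as.numeric))
    names(sc) <- algc
    return(score_table(vars, sc))
  }
  scores <- lapply(algc, function(cn) .parse_numeric(raw[[cn]], cn))
  names(scores) <- algc
  score_table(raw[keyc], as.data.frame(scores, optional = TRUE))
}

#' Write a score table to TSV
#'
#' Inverse of [read_score_table()]: missing scores are written as
#' \code{"."}, so a read/write round trip is cell-identical.
#'
#' @param x A \code{score_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_score_table <- function(x, path) {
  out <- as.data.frame(x)
  for (a in algorithms(x)) {
    v <- out[[a]]
    out[[a]] <- ifelse(is.na(v), ".", formatC(v, format = "g", digits = 15))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Construct a labeled variant set
#'
#' Binary functional labels with their evidence tier and, when measured, the
#' in-vitro activity as percent of wild type.  When a row has a measured
#' activity but no explicit label, the label is derived from the activity:
#' deleterious below 50 percent of wild-type activity, neutral at or above
#' 50 percent.
#'
#' @param variants Data frame of variant key columns.
#' @param label Character/factor vector in \code{{"deleterious","neutral"}},
#'   or \code{NA} where the label is to be derived from \code{activity}.
#' @param evidence Optional evidence tier per variant (\code{"cpic"},
#'   \code{"in_vitro"}, \code{"pharmgkb_clinvar"}).
#' @param activity Optional numeric, percent of wild-type activity.
#' @return A data frame of class \code{"labeled_variants"}.
#' @export
labeled_variants <- function(variants, label,
                             evidence = NULL, activity = NULL) {
  n <- nrow(variants)
  label <- as.character(label)
  stopifnot(length(label) == n)
  if (is.null(activity)) activity <- rep(NA_real_, n)
  stopifnot(is.numeric(activity), length(activity) == n)
  derived <- is.na(label) & !is.na(activity)
  label[derived] <- ifelse(activity[derived] < 50, "deleterious", "neutral")
  bad <- !is.na(label) & !label %in% c("deleterious", "neutral")
  if (any(bad)) {
    stop("label(s) outside {deleterious, neutral}: ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  }
  if (anyNA(label)) stop("variant(s) with neither label nor activity",
                         call. = FALSE)
  # an in-vitro activity measurement defines the label; a contradicting
  # explicit label means corrupted input
  has_act <- !is.na(activity)
  implied <- ifelse(activity[has_act] < 50, "deleterious", "neutral")
  if (any(label[has_act] != implied)) {
    stop("label contradicts measured activity (deleterious iff < 50% of wild type)",
         call. = FALSE)
  }
  if (is.null(evidence)) evidence <- rep(NA_character_, n)
  out <- cbind(variants,
               data.frame(label = label, evidence = as.character(evidence),
                          activity = activity, stringsAsFactors = FALSE))
  .check_unique_keys(variant_keys(out), "label table")
  rownames(out) <- NULL
  structure(out, class = c("labeled_variants", "data.frame"))
}

#' Read a variant label table from TSV
#'
#' Columns: variant keys, optional \code{label}, optional \code{evidence},
#' optional \code{activity} (percent of wild type).  At least one of
#' \code{label}/\code{activity} must be present per row; labels are derived
#' from activity (deleterious below 50) where absent.
#'
#' @param path Path to the TSV file.
#' @return A [labeled_variants()] set.
#' @export
read_label_table <- function(path) {
  raw <- .read_tsv(path)
  keyc <- intersect(.key_cols, names(raw))
  if (!length(keyc)) stop("no variant key columns found", call. = FALSE)
  n <- nrow(raw)
  lab <- if ("label" %in% names(raw)) {
    v <- trimws(raw$label); v[v == "" | v == "."] <- NA_character_; v
  } else rep(NA_character_, n)
  act <- if ("activity" %in% names(raw)) {
    .parse_numeric(raw$activity, "activity")
  } else NULL
  ev <- if ("evidence" %in% names(raw)) trimws(raw$evidence) else NULL
  labeled_variants(raw[keyc], lab, evidence = ev, activity = act)
}

#' Write a label table to TSV
#' @param x A \code{labeled_variants} set.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_label_table <- function(x, path) {
  out <- as.data.frame(x)
  out$activity <- ifelse(is.na(out$activity), ".",
                         formatC(out$activity, format = "g", digits = 15))
  out$evidence[is.na(out$evidence)] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Construct a population frequency table
#'
#' Long-format allele frequencies: one row per (variant, population) with
#' the variant's gene and its allele frequency in that population.
#'
#' @param variants Data frame of variant key columns including \code{gene}.
#' @param population Character vector of population labels.
#' @param allele_frequency Numeric in \code{[0, 1]}.
#' @return A data frame of class \code{"frequency_table"}.
#' @export
frequency_table <- function(variants, population, allele_frequency) {
  n <- nrow(variants)
  stopifnot(length(population) == n, length(allele_frequency) == n)
  p <- as.numeric(allele_frequency)
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad)) {
    stop(sprintf("allele frequency out of [0, 1] in row %d: %s", bad[1],
                 format(allele_frequency[bad[1]])), call. = FALSE)
  }
  out <- cbind(variants,
               data.frame(population = as.character(population),
                          allele_frequency = p, stringsAsFactors = FALSE))
  key <- paste(variant_keys(out), out$population, sep = "@")
  .check_unique_keys(key, "frequency table (variant, population)")
  rownames(out) <- NULL
  structure(out, class = c("frequency_table", "data.frame"))
}

#' Read a population allele-frequency table from TSV
#'
#' Columns: variant keys (must include \code{gene}), \code{population},
#' \code{allele_frequency}.  Frequencies are validated to \code{[0, 1]};
#' monomorphic rows (frequency 0) are retained.
#'
#' @param path Path to the TSV file.
#' @return A [frequency_table()].
#' @export
read_frequency_table <- function(path) {
  raw <- .read_tsv(path)
  keyc <- intersect(.key_cols, names(raw))
  need <- c("population", "allele_frequency")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  p <- .parse_numeric(raw$allele_frequency, "allele_frequency",
                      missing_ok = FALSE)
  frequency_table(raw[keyc], trimws(raw$population), p)
}

#' Write a frequency table to TSV
#' @param x A \code{frequency_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_frequency_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Align a labeled set to a score table by variant key; errors on variants of
# `x` without a label.
.align_labels <- function(x, labels) {
  i <- match(variant_keys(x), variant_keys(labels))
  if (anyNA(i)) {
    stop(sprintf("%d variant(s) in the score table have no label",
                 sum(is.na(i))), call. = FALSE)
  }
  labels[i, , drop = FALSE]
}
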