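#' Construct an algorithm specification
#'
#' An algorithm specification records how a variant effect predictor's
#' continuous score is dichotomized into deleterious/neutral calls: the
#' direction in which scores indicate deleteriousness, the cutoff value, and
#' whether the cutoff itself counts as deleterious (operator strictness).
#' A predictor published as "score >= t deleterious" is
#' \code{deleterious_if_high}, non-strict; "score < t" is
#' \code{deleterious_if_low}, strict; and so on.
#'
#' @param name Predictor name (e.g. \code{"SIFT"}).
#' @param direction One of \code{"deleterious_if_high"},
#'   \code{"deleterious_if_low"}.
#' @param threshold Finite numeric cutoff.
#' @param strict Logical; \code{TRUE} when the comparison excludes the
#'   threshold value itself (operators \code{>} or \code{<}).
#' @return An object of class \code{"algorithm_spec"}.
#' @examples
#' sift <- algorithm_spec("SIFT", "deleterious_if_low", 0.05, strict = FALSE)
#' binarize(c(0.05, 0.2), sift)
#' @export
algorithm_spec <- function(name, direction, threshold, strict = FALSE) {
  direction <- match.arg(direction,
                         c("deleterious_if_high", "deleterious_if_low"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold), is.logical(strict), length(strict) == 1L)
  structure(list(name = name, direction = direction,
                 threshold = as.numeric(threshold), strict = strict),
            class = "algorithm_spec")
}

#' @export
print.algorithm_spec <- function(x, ...) {
  op <- if (x$direction == "deleterious_if_high") {
    if (x$strict) ">" else ">="
  } else {
    if (x$strict) "<" else "<="
  }
  cat(sprintf("<algorithm_spec> %s: deleterious when score %s %g\n",
              x$name, op, x$threshold))
  invisible(x)
}

# Conventional cutoffs of the benchmarked predictors, operator per predictor
# as published.  VEST appears in two scored versions (VEST3, VEST4); the
# registry carries both rows, so it covers 28 distinct tools in 29 entries.
.registry_table <- function() {
  txt <- c(
    "AlphaMissense   >=  0.564",
    "APF             >   0.5",
    "MutPred         >   0.5",
    "PolyPhen-2      >   0.446",
    "PROVEAN         <   -2.282",
    "MutationAssessor >  1.9",
    "VEST3           >   0.9",
    "ClinPred        >=  0.5",
    "VEST4           >   0.5",
    "SIFT            <=  0.05",
    "MetaRNN         >=  0.5",
    "CADD            >   15",
    "DANN            >   0.96",
    "Eigen           >=  0",
    "REVEL           >   0.5",
    "LRT             <   0.001",
    "LIST-S2         >   0.5",
    "MetaSVM         >=  0",
    "fathmm-MKL      >   0.5",
    "MetaLR          >=  0.5",
    "DEOGEN2         >   0.5",
    "MVP             >   0.75",
    "M-CAP           >=  0.025",
    "PrimateAI       >=  0.803",
    "MPC             >   0.6",
    "fitCons         >   0.7",
    "FATHMM          <=  -1.5",
    "GenoCanyon      >   0.999",
    "MutationTaster  >   0.5")
  parts <- strsplit(trimws(txt), "[[:space:]]+")
  data.frame(
    name      = vapply(parts, `[`, "", 1L),
    operator  = vapply(parts, `[`, "", 2L),
    threshold = as.numeric(vapply(parts, `[`, "", 3L)),
    stringsAsFactors = FALSE)
}

#' Built-in registry of benchmarked predictors
#'
#' Returns the conventional decision rule for every predictor in the
#' benchmark panel: 28 distinct variant effect predictors, with VEST present
#' in both its version-3 and version-4 scorings (29 entries).  Direction and
#' operator strictness follow each tool's published cutoff, e.g. SIFT calls
#' a variant deleterious at scores \code{<= 0.05} while CADD requires a
#' score strictly \code{> 15}.
#'
#' @return A data frame of class \code{"algorithm_registry"} with columns
#'   \code{name}, \code{tool} (version-collapsed tool name),
#'   \code{direction}, \code{strict}, \code{threshold}.
#' @seealso [registry_spec()] to extract one entry as an
#'   [algorithm_spec()].
#' @examples
#' reg <- builtin_registry()
#' nrow(reg)                  # 29 entries
#' length(unique(reg$tool))   # 28 distinct tools
#' @export
builtin_registry <- function() {
  tab <- .registry_table()
  tab$direction <- ifelse(tab$operator %in% c(">", ">="),
                          "deleterious_if_high", "deleterious_if_low")
  tab$strict <- tab$operator %in% c(">", "<")
  tab$tool <- sub("^VEST[34]$", "VEST", tab$name)
  out <- tab[, c("name", "tool", "direction", "strict", "threshold")]
  class(out) <- c("algorithm_registry", "data.frame")
  out
}

#' Look up one predictor's specification
#'
#' @param name Predictor name as listed by [builtin_registry()].  The alias
#'   \code{"VEST"} resolves to VEST4, the version used by the optimized
#'   ensemble.
#' @param registry Registry data frame; defaults to [builtin_registry()].
#' @return An [algorithm_spec()].
#' @examples
#' registry_spec("PROVEAN")
#' @export
registry_spec <- function(name, registry = builtin_registry()) {
  lookup <- if (identical(name, "VEST")) "VEST4" else name
  i <- match(lookup, registry$name)
  if (is.na(i)) {
    stop(sprintf("unknown algorithm '%s'; registry has: %s", name,
                 paste(registry$name, collapse = ", ")), call. = FALSE)
  }
  algorithm_spec(registry$name[i], registry$direction[i],
                 registry$threshold[i], registry$strict[i])
}

#' Sizes of the labeled pharmacogenomic variant sets
#'
#' Summary of the three non-overlapping labeled variant collections the
#' method was developed on: the high-evidence clinical-annotation set, the
#' in-vitro characterized set (these two combined form the fitting set), and
#' the independent test set from curated databases.
#'
#' @return A data frame with columns \code{set}, \code{evidence},
#'   \code{n_variants}, \code{role}.
#' @examples
#' s <- labeled_set_summary()
#' sum(s$n_variants[s$role == "fitting"])  # combined fitting set size
#' @export
labeled_set_summary <- function() {
  data.frame(
    set = c("set1", "set2", "set3"),
    evidence = c("cpic", "in_vitro", "pharmgkb_clinvar"),
    n_variants = c(145L, 385L, 146L),
    role = c("fitting", "fitting", "test"),
    stringsAsFactors = FALSE)
}
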