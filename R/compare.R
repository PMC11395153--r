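# Cross-sample overlap (Venn-style) of protein, peptide, or de novo peptide
# identifier sets.

#' Overlap of two or three identifier sets
#'
#' Computes exact Venn region counts for 2 or 3 labeled sets of identifiers
#' (bare peptide sequences or protein accessions, already deduplicated
#' upstream; duplicates within a set are collapsed here). The headline
#' percentage of common identifiers uses the union as denominator, which is
#' the only denominator comparable between 2-set and 3-set reports;
#' per-set percentages (intersection relative to each set's own size) are
#' reported alongside, since published "percent common" figures are
#' sometimes set-relative.
#'
#' @param sets Named list of 2 or 3 character vectors. Names are the sample
#'   labels and must be unique and non-empty.
#' @return An object of class `overlap_result`: `labels`, `region_counts`
#'   (named integer vector over membership patterns such as `"A"`, `"A&B"`),
#'   `pct_common`, `pct_common_per_set`, `union_size`, `intersection_size`.
#' @examples
#' overlap(list(A = c("x", "y", "z"), B = c("y", "z", "w")))
#' @export
overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3) {
    stop("overlap supports 2 or 3 sets")
  }
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels) > 0) {
    stop("sets must carry unique non-empty labels")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(m) paste(labels[m], collapse = "&"))

  all_patterns <- unlist(lapply(seq_along(labels), function(k) {
    utils::combn(labels, k, paste, collapse = "&")
  }))
  counts <- table(factor(pattern, levels = all_patterns))
  region_counts <- stats::setNames(as.integer(counts), all_patterns)

  inter <- Reduce(intersect, sets)
  pct_common <- if (length(universe) > 0) {
    100 * length(inter) / length(universe)
  } else {
    NA_real_
  }
  per_set <- vapply(sets, function(s) {
    if (length(s) > 0) 100 * length(inter) / length(s) else NA_real_
  }, numeric(1))

  structure(
    list(
      labels = labels,
      region_counts = region_counts,
      pct_common = pct_common,
      pct_common_per_set = per_set,
      union_size = length(universe),
      intersection_size = length(inter)
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Overlap of", length(x$labels), "sets:",
      paste(x$labels, collapse = ", "), "\n")
  cat("union:", x$union_size, " intersection:", x$intersection_size,
      sprintf(" common: %.1f%% of union\n", x$pct_common))
  for (p in names(x$region_counts)) {
    cat(sprintf("  %-12s %d\n", p, x$region_counts[[p]]))
  }
  invisible(x)
}
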