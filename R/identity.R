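# Within-genome homogenization: per-lineage change in mean pairwise identity
# of the concatenated gene regions, and the across-lineage trend test.

#' Per-lineage change in mean pairwise identity
#'
#' Mean pairwise identity (see [mean_pairwise_identity()]) is computed on the
#' concatenated gene-region alignments (e.g. 16S+23S) of the ancestor and of
#' each evolved lineage; the delta is evolved minus ancestral, in percentage
#' points. Spacer regions are excluded.
#'
#' @param ancestor_alns Named list of ancestral [operon_alignment()]s; regions
#'   of type `"gene"` are used.
#' @param evolved List of evolved families, one per lineage: each a named list
#'   of alignments (or a `lineage_state`) sharing the ancestor's shape.
#' @param lineage_ids Labels; defaults to names of `evolved` or an index.
#' @return Data frame with `lineage`, `ancestral_identity`,
#'   `evolved_identity`, `delta` (percentage points).
#' @export
identity_change_per_lineage <- function(ancestor_alns, evolved,
                                        lineage_ids = NULL) {
  if (inherits(ancestor_alns, "operon_alignment")) {
    ancestor_alns <- setNames(list(ancestor_alns), ancestor_alns$region_id)
  }
  gene_ids <- names(ancestor_alns)[vapply(ancestor_alns, function(a)
    a$type == "gene", TRUE)]
  if (!length(gene_ids)) stop("no gene regions to compare", call. = FALSE)
  anc_id <- mean_pairwise_identity(ancestor_alns[gene_ids])$mean
  if (is.null(lineage_ids)) {
    lineage_ids <- names(evolved) %||% as.character(seq_along(evolved))
  }
  deltas <- vapply(seq_along(evolved), function(i) {
    ev <- evolved[[i]]
    if (inherits(ev, "lineage_state")) ev <- ev$alns
    for (rid in gene_ids) {
      if (!identical(dim(ev[[rid]]$mat), dim(ancestor_alns[[rid]]$mat))) {
        stop("alignment-shape error in lineage ", lineage_ids[i],
             ", region ", rid, call. = FALSE)
      }
    }
    mean_pairwise_identity(ev[gene_ids])$mean
  }, 0)
  data.frame(lineage = lineage_ids,
             ancestral_identity = anc_id,
             evolved_identity = deltas,
             delta = deltas - anc_id,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Trend test on identity deltas
#'
#' Two-sided Wilcoxon signed rank test of the per-lineage identity deltas
#' against zero. Zero deltas are dropped (their count is reported); the exact
#' null distribution is used for n <= 25 when the remaining deltas are free of
#' ties, otherwise the normal approximation. An all-zero input returns p = 1
#' with a degenerate flag.
#'
#' @param deltas Numeric vector of identity changes (percentage points), or
#'   the data frame from [identity_change_per_lineage()].
#' @return List with `p_value`, `statistic` (signed rank V), `n_used`,
#'   `n_zero`, `method`, `degenerate`.
#' @export
identity_trend_test <- function(deltas) {
  if (is.data.frame(deltas)) deltas <- deltas$delta
  if (!length(deltas)) stop("empty input", call. = FALSE)
  nz <- deltas[deltas != 0]
  n_zero <- length(deltas) - length(nz)
  if (!length(nz)) {
    return(list(p_value = 1, statistic = NA_real_, n_used = 0L,
                n_zero = n_zero, method = "degenerate (all zero)",
                degenerate = TRUE))
  }
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    wilcox.test(nz, mu = 0, alternative = "two.sided", exact = exact,
                correct = !exact))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_used = length(nz), n_zero = n_zero,
       method = if (exact) "exact signed rank" else "normal approximation",
       degenerate = FALSE)
}
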