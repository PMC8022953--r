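# Conditional resampling null for per-operon and per-site conversion counts,
# quantile envelopes, and Bonferroni-adjusted empirical p-values.

#' Conditional resampling of conversions to a fixed observable count
#'
#' For each replicate, conversions are drawn one at a time (each assigned to a
#' uniformly random lineage) and applied sequentially; after every draw the
#' total observable count over all lineages is recomputed, and drawing stops
#' when it exactly equals `target` — the empirically observed number. Because
#' later draws can hide or revert earlier ones the count is not monotone, so
#' the stop is on equality, with an iteration cap. The observable events of
#' the final sequences (the minimal-event reconstruction, not the raw draws)
#' are tabulated by recipient operon and by changed heterologous column.
#'
#' @param target Observed total to condition on (>= 0).
#' @param cfg An [ma_config()]; `n_replicates` sets the number of resampled
#'   sets.
#' @param fam A [family_state()] (regions in scope, e.g. 16S+23S).
#' @param sampler A [size_sampler()] for `fam`.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param max_draws Per-replicate cap on draws before a non-convergence error.
#' @return Object of class `resample_draws`: list with `operon` (replicates x
#'   copies count matrix), `site` (replicates x heterologous-columns count
#'   matrix, columns named `region:column`), `draws` (draws used per
#'   replicate), `target`.
#' @export
conditional_resample <- function(target, cfg, fam, sampler, seed = NULL,
                                 max_draws = 1e6) {
  stopifnot(inherits(cfg, "ma_config"), inherits(fam, "family_state"),
            inherits(sampler, "size_sampler"), target >= 0)
  run <- function() {
    cpp_conditional_resample(as.integer(target), cfg$n_lineages,
                             cfg$n_replicates, .cpp_regions(fam),
                             .cpp_sampler(sampler), as.integer(max_draws))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  colnames(res$operon) <- fam$operon_ids
  site_names <- unlist(lapply(fam$regions, function(r)
    paste0(r$region_id, ":", r$het)))
  colnames(res$site) <- site_names
  structure(list(operon = res$operon, site = res$site,
                 draws = as.integer(res$draws), target = as.integer(target)),
            class = "resample_draws")
}

#' @export
print.resample_draws <- function(x, ...) {
  cat("resample_draws: ", nrow(x$operon), " replicate(s) conditioned on ",
      x$target, " observable conversion(s); mean draws ",
      round(mean(x$draws), 1), "\n", sep = "")
  invisible(x)
}

#' Null summary of per-category conversion counts
#'
#' Operon categories count observable events by recipient; site categories
#' count, for each ancestral heterologous column, the events whose changed
#' positions include that column. Per-category means and 2.5%/97.5% quantiles
#' (inverse-ECDF quantiles, appropriate for integer counts) are taken over
#' replicates.
#'
#' @param draws A [conditional_resample()] result.
#' @param category_kind `"operon"` or `"site"`.
#' @param observed Optional named or positional vector of observed counts per
#'   category; when supplied, empirical p-values are attached via
#'   [empirical_pvalues()].
#' @return A data frame of class `resampling_summary`: `category`,
#'   `observed` (NA when not supplied), `null_mean`, `q025`, `q975`, and, with
#'   `observed`, `p_raw` and `p_adjusted`.
#' @export
category_null_summary <- function(draws, category_kind = c("operon", "site"),
                                  observed = NULL) {
  category_kind <- match.arg(category_kind)
  stopifnot(inherits(draws, "resample_draws"))
  counts <- draws[[category_kind]]
  if (nrow(counts) < 2L) stop("need >= 2 replicates", call. = FALSE)
  out <- data.frame(
    category = colnames(counts),
    observed = NA_integer_,
    null_mean = colMeans(counts),
    q025 = apply(counts, 2L, quantile, probs = 0.025, type = 1L, names = FALSE),
    q975 = apply(counts, 2L, quantile, probs = 0.975, type = 1L, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(observed)) {
    if (!is.null(names(observed))) {
      obs <- rep(0L, ncol(counts))
      names(obs) <- colnames(counts)
      unknown <- setdiff(names(observed), colnames(counts))
      if (length(unknown)) {
        stop("unknown categor(ies): ", paste(unknown, collapse = ", "),
             call. = FALSE)
      }
      obs[names(observed)] <- observed
    } else {
      stopifnot(length(observed) == ncol(counts))
      obs <- observed
    }
    out$observed <- as.integer(obs)
    pv <- empirical_pvalues(obs, counts)
    out$p_raw <- pv$p_raw
    out$p_adjusted <- pv$p_adjusted
  }
  class(out) <- c("resampling_summary", "data.frame")
  out
}

#' Two-tailed empirical p-values against a resampled null
#'
#' `p_raw` is twice the smaller of the two tail proportions of null replicate
#' counts as or more extreme than the observed count (ties included), capped
#' at 1; `p_adjusted` applies a Bonferroni correction over the categories
#' tested.
#'
#' @param observed_counts Vector of observed counts, one per category.
#' @param null_counts Matrix of null counts, replicates x categories.
#' @param n_categories Bonferroni factor (default: number of categories).
#' @return Data frame with `category`, `p_raw`, `p_adjusted`.
#' @export
empirical_pvalues <- function(observed_counts, null_counts,
                              n_categories = ncol(null_counts)) {
  if (is.null(dim(null_counts))) null_counts <- matrix(null_counts, ncol = 1L)
  if (nrow(null_counts) < 1L) stop("zero replicates", call. = FALSE)
  stopifnot(length(observed_counts) == ncol(null_counts))
  p_raw <- vapply(seq_along(observed_counts), function(i) {
    ge <- mean(null_counts[, i] >= observed_counts[i])
    le <- mean(null_counts[, i] <= observed_counts[i])
    min(1, 2 * min(ge, le))
  }, 0)
  data.frame(
    category = colnames(null_counts) %||% as.character(seq_along(observed_counts)),
    p_raw = p_raw,
    p_adjusted = pmin(1, p_raw * n_categories),
    row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a resampling summary as TSV
#'
#' @param summary A [category_null_summary()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_resampling_tsv <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
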