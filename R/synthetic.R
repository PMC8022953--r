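# Synthetic multicopy families with controlled divergence and simulated MA
# lineages with ground-truth conversion logs, so every pipeline stage is
# testable without external data.

#' Specification of a synthetic operon family
#'
#' Defaults emulate the seven *E. coli* rRNA operons: two gene regions of
#' 1542 and 2904 alignment columns at ~99.6% mean pairwise identity, plus a
#' biallelic 23S-5S spacer with 186-bp and 92-bp variants carried by four and
#' three copies respectively.
#'
#' @param n_copies Number of family copies.
#' @param gene_lengths Named integer vector of gene-region alignment lengths.
#' @param target_identity Target mean pairwise identity over the concatenated
#'   gene regions, in percent.
#' @param tri_allele_prob Probability that a heterologous column carries three
#'   alleles instead of two.
#' @param spacer_lengths Lengths of the long and short spacer alleles.
#' @param n_spacer_long Copies carrying the long spacer allele.
#' @param seed Seed for [generate_operon_family()].
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(n_copies = 7L,
                        gene_lengths = c("16S" = 1542L, "23S" = 2904L),
                        target_identity = 99.6,
                        tri_allele_prob = 0.1,
                        spacer_lengths = c(long = 186L, short = 92L),
                        n_spacer_long = 4L,
                        seed = 1L) {
  stopifnot(n_copies >= 2L, all(gene_lengths >= 1L),
            target_identity > 0, target_identity <= 100,
            tri_allele_prob >= 0, tri_allele_prob <= 1,
            n_spacer_long >= 1L, n_spacer_long < n_copies)
  if (n_copies < 3L) tri_allele_prob <- 0
  structure(list(n_copies = as.integer(n_copies),
                 gene_lengths = gene_lengths,
                 target_identity = target_identity,
                 tri_allele_prob = tri_allele_prob,
                 spacer_lengths = spacer_lengths,
                 n_spacer_long = as.integer(n_spacer_long),
                 seed = as.integer(seed)),
            class = "family_spec")
}

# Expected fraction of unordered copy pairs that differ at one heterologous
# column, under the allele-partition scheme the generator implements: each
# copy is assigned an allele uniformly, conditioned on every allele being
# present. For two alleles the minor-group size k is Binomial(n, 1/2)
# truncated to 1..n-1; three-allele columns are enumerated exactly (n <= 9).
# Solving the target identity for the heterologous-column density uses this
# expectation analytically instead of rejection sampling.
.expected_pair_mismatch <- function(n, tri_prob) {
  pairs <- n * (n - 1) / 2
  k <- 1:(n - 1)
  w <- choose(n, k)
  e_bi <- sum(w * k * (n - k)) / sum(w) / pairs
  if (tri_prob == 0) return(e_bi)
  if (n > 9L) stop("triallelic enumeration supported for n_copies <= 9",
                   call. = FALSE)
  grid <- as.matrix(expand.grid(rep(list(1:3), n)))
  surj <- apply(grid, 1L, function(a) length(unique(a)) == 3L)
  grid <- grid[surj, , drop = FALSE]
  diff_frac <- apply(grid, 1L, function(a) {
    cnt <- tabulate(a, 3L)
    1 - sum(cnt * (cnt - 1) / 2) / pairs
  })
  e_tri <- mean(diff_frac)
  (1 - tri_prob) * e_bi + tri_prob * e_tri
}

#' Generate a synthetic operon family
#'
#' Each gene region gets a random base sequence; heterologous columns are
#' placed uniformly at a density solved analytically so that the realized
#' mean pairwise identity matches the target in expectation, and copies are
#' partitioned among alleles at each such column. The spacer is generated as
#' two divergent length variants that swap as whole units.
#'
#' @param spec A [family_spec()].
#' @return List with `alns` (named list of [operon_alignment()]s: gene regions
#'   plus `"spacer"`), `alleles` (the [spacer_alleles()]), and `spec`.
#' @export
generate_operon_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  n <- spec$n_copies
  ops <- paste0("rrn", LETTERS[c(1:5, 7:8)][seq_len(min(n, 7L))])
  if (n > 7L) ops <- c(ops, paste0("rrn", LETTERS[8L + seq_len(n - 7L)]))
  e_mis <- .expected_pair_mismatch(n, spec$tri_allele_prob)
  q <- (100 - spec$target_identity) / 100
  withr::with_seed(spec$seed, {
    alns <- list()
    for (rid in names(spec$gene_lengths)) {
      L <- spec$gene_lengths[[rid]]
      n_het <- round(q * L / e_mis)
      if (n_het > L) {
        stop("identity target ", spec$target_identity,
             "% needs ", n_het, " heterologous columns in a region of ",
             L, " columns", call. = FALSE)
      }
      base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      mat <- matrix(rep(base, each = n), nrow = n,
                    dimnames = list(ops, NULL))
      if (n_het > 0L) {
        pos <- sort(sample.int(L, n_het))
        for (p in pos) {
          n_alleles <- if (runif(1) < spec$tri_allele_prob) 3L else 2L
          alleles <- c(base[p],
                       sample(setdiff(c("A", "C", "G", "T"), base[p]),
                              n_alleles - 1L))
          repeat {
            assign <- sample.int(n_alleles, n, replace = TRUE)
            if (length(unique(assign)) == n_alleles) break
          }
          mat[, p] <- alleles[assign]
        }
      }
      alns[[rid]] <- operon_alignment(mat, region_id = rid,
                                      operon_ids = ops, type = "gene")
    }
    long_len <- spec$spacer_lengths[["long"]]
    short_len <- spec$spacer_lengths[["short"]]
    long <- paste(sample(c("A", "C", "G", "T"), long_len, replace = TRUE),
                  collapse = "")
    short <- paste(sample(c("A", "C", "G", "T"), short_len, replace = TRUE),
                   collapse = "")
    which_long <- sample.int(n, spec$n_spacer_long)
    rows <- ifelse(seq_len(n) %in% which_long, long,
                   paste0(short, strrep("-", long_len - short_len)))
    names(rows) <- ops
    alns[["spacer"]] <- operon_alignment(rows, region_id = "spacer",
                                         operon_ids = ops, type = "spacer")
  })
  list(alns = alns, alleles = spacer_alleles(alns[["spacer"]]), spec = spec)
}

#' Synthetic conversion size templates
#'
#' Mimics the spread of observed conversion extents: mostly small minimum
#' sizes (single-base changes are common) with wide maximum extents, capped at
#' a contiguous 2137-column span or the region length, whichever is smaller.
#'
#' @param fam A [family_state()].
#' @param n_per_region Named integer vector: number of template events per
#'   gene region (defaults to the observed regional weighting, 7 for the
#'   first gene region and 27 for the second where present).
#' @param seed Seed for the template draw.
#' @param max_cap Upper cap on maximum extents, in columns.
#' @return A [size_sampler()].
#' @export
synthetic_size_sampler <- function(fam, n_per_region = NULL, seed = 1L,
                                   max_cap = 2137L) {
  stopifnot(inherits(fam, "family_state"))
  gene <- which(!vapply(fam$regions, function(r) isTRUE(r$spacer), TRUE))
  if (!length(gene)) stop("no gene regions in family", call. = FALSE)
  if (is.null(n_per_region)) {
    n_per_region <- setNames(rep(10L, length(gene)), fam$region_ids[gene])
    if (length(gene) >= 2L) n_per_region[1:2] <- c(7L, 27L)
  }
  withr::with_seed(seed, {
    rows <- lapply(names(n_per_region), function(rid) {
      i <- match(rid, fam$region_ids)
      k <- n_per_region[[rid]]
      cap <- min(fam$regions[[i]]$ncol, max_cap)
      min_size <- sample(c(1L, 1L, 1L, 2L, 3L, 8L, 25L), k, replace = TRUE)
      max_size <- pmax(min_size,
                       as.integer(round(runif(k, min = 150, max = cap))))
      data.frame(region = rid, min_start = 1L, min_end = min_size,
                 max_start = 1L, max_end = max_size)
    })
  })
  size_sampler(do.call(rbind, rows), fam)
}

#' Simulate mutation accumulation lineages with ground truth
#'
#' Each lineage draws its true number of conversions from
#' Poisson(rate x generations) and applies them sequentially (donors
#' contribute current sequence). The returned log replays exactly.
#'
#' @param family Output of [generate_operon_family()], or a named list of
#'   ancestral [operon_alignment()]s.
#' @param true_rate Per-genome per-generation conversion rate.
#' @param cfg An [ma_config()] (`n_lineages`, `generations`).
#' @param sampler A [size_sampler()]; defaults to [synthetic_size_sampler()]
#'   on the family's gene regions.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return List with `lineages` (per lineage, the evolved named alignment
#'   list), `truth` (data frame log: lineage, order, region, recipient, donor,
#'   start, size), `true_counts` (true events per lineage), and `ancestor`.
#' @export
simulate_ma_lineages <- function(family, true_rate, cfg, sampler = NULL,
                                 seed = NULL) {
  stopifnot(inherits(cfg, "ma_config"), true_rate >= 0)
  alns <- if (!is.null(family$alns)) family$alns else family
  fam <- family_state(alns)
  if (is.null(sampler)) sampler <- synthetic_size_sampler(fam)
  if (is.null(seed)) seed <- cfg$seed
  withr::with_seed(seed, {
    lineages <- vector("list", cfg$n_lineages)
    names(lineages) <- paste0("L", seq_len(cfg$n_lineages))
    logs <- list()
    true_counts <- integer(cfg$n_lineages)
    for (i in seq_len(cfg$n_lineages)) {
      nev <- rpois(1L, true_rate * cfg$generations)
      true_counts[i] <- nev
      st <- lineage_state(alns)
      if (nev > 0L) {
        for (e in seq_len(nev)) {
          cv <- sample_conversion(sampler, fam)
          st <- apply_conversions(st, cv)
          logs[[length(logs) + 1L]] <- data.frame(
            lineage = names(lineages)[i], order = e, region = cv$region_id,
            recipient = cv$recipient, donor = cv$donor,
            start = cv$start, size = cv$size, stringsAsFactors = FALSE)
        }
      }
      lineages[[i]] <- st$alns
    }
  })
  truth <- if (length(logs)) do.call(rbind, logs) else
    data.frame(lineage = character(), order = integer(), region = character(),
               recipient = character(), donor = character(),
               start = integer(), size = integer(), stringsAsFactors = FALSE)
  list(lineages = lineages, truth = truth,
       true_counts = setNames(true_counts, names(lineages)),
       ancestor = alns)
}
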