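# Shared fixture builders. Everything is generated in code; no files.

# thin wrapper for literal toy alignments
toy_aln <- function(rows, region = "16S", ids = NULL, type = "gene") {
  if (is.null(ids)) ids <- LETTERS[seq_along(rows)]
  operon_alignment(rows, region_id = region, operon_ids = ids, type = type)
}

# default synthetic E. coli-like family, built once per test run
ecoli_like_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_operon_family(family_spec(seed = 42L))
    cache
  }
})

ecoli_like_state <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- family_state(ecoli_like_family()$alns[c("16S", "23S")])
    }
    cache
  }
})

# fully observable toy: every column heterologous with copy-unique states is
# impossible with 4 letters and 7 copies, so copies cycle through distinct
# 5-state (incl. gap) patterns guaranteeing every ordered pair differs at
# every column -> every conversion is observable
unique_state_family <- function(n_copies = 5L, n_columns = 40L,
                                region = "16S") {
  states <- c("A", "C", "G", "T", "-")
  stopifnot(n_copies <= length(states))
  mat <- matrix("", n_copies, n_columns)
  for (j in seq_len(n_columns)) {
    mat[, j] <- states[(seq_len(n_copies) + j) %% length(states) + 1L]
  }
  operon_alignment(mat, region_id = region,
                   operon_ids = paste0("op", seq_len(n_copies)))
}

# sampler with a single (lo, hi) template for a one-region family
fixed_size_sampler <- function(fam, min_size, max_size,
                               region = fam$region_ids[1L]) {
  size_sampler(data.frame(region = region, min_start = 1L,
                          min_end = min_size, max_start = 1L,
                          max_end = max_size),
               fam)
}

# random small family plus a random number of applied conversions; returns
# ancestor alignment, final matrix, and the number applied. Used for
# greedy-vs-oracle property tests (copies <= 4 keeps the oracle in bounds).
random_small_instance <- function(n_copies = 3L, n_columns = 30L,
                                  n_het = 6L, max_events = 4L) {
  base <- sample(c("A", "C", "G", "T"), n_columns, replace = TRUE)
  mat <- matrix(rep(base, each = n_copies), nrow = n_copies)
  pos <- sort(sample.int(n_columns, n_het))
  for (p in pos) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), base[p]), 1L)
    k <- sample.int(n_copies - 1L, 1L)
    mat[sample.int(n_copies, k), p] <- alt
  }
  anc <- operon_alignment(mat, region_id = "toy",
                          operon_ids = paste0("op", seq_len(n_copies)))
  fin <- anc$mat
  n_apply <- sample.int(max_events, 1L)
  for (e in seq_len(n_apply)) {
    rec <- sample.int(n_copies, 1L)
    don <- sample(setdiff(seq_len(n_copies), rec), 1L)
    size <- sample.int(n_columns, 1L)
    start <- sample.int(n_columns - size + 1L, 1L)
    cols <- start:(start + size - 1L)
    fin[rec, cols] <- fin[don, cols]
  }
  list(ancestor = anc, final = fin, n_applied = n_apply)
}

# encode a character alignment matrix in the integer state coding of the
# C++ kernel, restricted to the ancestral heterologous columns
encode_at_het <- function(fam_state, region_index, char_mat) {
  r <- fam_state$regions[[region_index]]
  m <- char_mat[, r$het, drop = FALSE]
  matrix(match(m, c("A", "C", "G", "T", "-")), nrow = nrow(char_mat))
}
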