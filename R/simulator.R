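# Forward simulation of gene conversions: size resampling from observed
# events, sequential application, and counting of observable (minimum
# reconstructable) events.

STATE_CODE <- c("A", "C", "G", "T", "-")

#' Compact simulation state of an operon family
#'
#' Conversions copy existing states between copies, so ancestrally
#' monomorphic columns can never change; the simulator therefore tracks state
#' only at heterologous columns. A spacer region is encoded as a single
#' pseudo-column holding allele ids, since its two length variants swap as
#' whole units.
#'
#' @param alns Named list of [operon_alignment()]s (the ancestral family).
#' @return Object of class `family_state` used by the simulation and
#'   resampling functions.
#' @export
family_state <- function(alns) {
  if (inherits(alns, "operon_alignment")) alns <- setNames(list(alns), alns$region_id)
  stopifnot(length(alns) >= 1L, all(vapply(alns, inherits, TRUE, "operon_alignment")))
  ids <- alns[[1L]]$operon_ids
  regions <- lapply(alns, function(aln) {
    if (!identical(aln$operon_ids, ids)) {
      stop("all regions must share the same operon ids in order", call. = FALSE)
    }
    if (aln$type == "spacer") {
      alle <- spacer_alleles(aln)
      anc <- matrix(match(alle$ancestral, c("long", "short")), ncol = 1L)
      list(region_id = aln$region_id, anc = anc, het = 1L,
           ncol = aln$n_columns, spacer = TRUE, alleles = alle)
    } else {
      hs <- heterologous_sites(aln)
      anc <- matrix(match(hs$alleles_at, STATE_CODE),
                    nrow = nrow(aln$mat), ncol = length(hs$positions))
      list(region_id = aln$region_id, anc = anc, het = hs$positions,
           ncol = aln$n_columns, spacer = FALSE)
    }
  })
  structure(list(regions = regions, operon_ids = ids,
                 region_ids = vapply(regions, `[[`, "", "region_id")),
            class = "family_state")
}

#' @export
print.family_state <- function(x, ...) {
  cat("family_state: ", length(x$operon_ids), " copies; regions: ",
      paste(sprintf("%s (%d het col%s)", x$region_ids,
                    vapply(x$regions, function(r) length(r$het), 1L),
                    ifelse(vapply(x$regions, function(r) length(r$het), 1L) == 1L, "", "s")),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# region list in the layout the C++ kernel expects
.cpp_regions <- function(fam) {
  lapply(fam$regions, function(r) {
    list(anc = r$anc, het = as.integer(r$het), ncol = as.integer(r$ncol),
         spacer = isTRUE(r$spacer))
  })
}

#' Build a conversion size sampler from observed events
#'
#' Simulated conversion sizes are drawn by picking an observed event uniformly
#' with replacement and then a uniform integer size between that event's
#' minimum and maximum inferred sizes. A floor (default 50 bp, the size needed
#' for efficient RecA-mediated recombination) is applied to the range; a
#' template whose maximum is below the floor yields the floor size. Spacer
#' templates always produce the whole spacer. The template's region also fixes
#' the simulated event's region, preserving the observed regional weighting of
#' events.
#'
#' @param events An `event_set`, a list of `gene_conversion_event`s, or a data
#'   frame in the [events_to_table()] layout.
#' @param fam A [family_state()] naming the regions events may refer to.
#'   Events in regions absent from `fam` are dropped.
#' @param floor_size Minimum simulated size for gene regions.
#' @return Object of class `size_sampler`.
#' @export
size_sampler <- function(events, fam, floor_size = 50L) {
  stopifnot(inherits(fam, "family_state"))
  if (is.data.frame(events)) {
    df <- events
  } else {
    df <- events_to_table(events)
  }
  df <- df[df$region %in% fam$region_ids, , drop = FALSE]
  if (!nrow(df)) stop("configuration error: no observed events for the regions in scope",
                      call. = FALSE)
  reg_idx <- match(df$region, fam$region_ids)
  min_size <- df$min_end - df$min_start + 1L
  max_size <- df$max_end - df$max_start + 1L
  if (any(min_size > max_size)) {
    stop("configuration error: min_size > max_size in observed events",
         call. = FALSE)
  }
  lo <- pmax(min_size, as.integer(floor_size))
  hi <- pmax(max_size, lo)
  spacer <- vapply(fam$regions[reg_idx], function(r) isTRUE(r$spacer), TRUE)
  structure(list(region = as.integer(reg_idx), lo = as.integer(lo),
                 hi = as.integer(hi), spacer = spacer,
                 region_ids = fam$region_ids, floor_size = as.integer(floor_size)),
            class = "size_sampler")
}

#' @export
print.size_sampler <- function(x, ...) {
  cat("size_sampler: ", length(x$region), " template event(s) over regions ",
      paste(unique(x$region_ids[x$region]), collapse = ", "),
      "; floor ", x$floor_size, "\n", sep = "")
  invisible(x)
}

.cpp_sampler <- function(sampler) {
  list(region = sampler$region, lo = sampler$lo, hi = sampler$hi)
}

#' Draw one simulated conversion
#'
#' Template event uniform with replacement; size uniform on the template's
#' floored range (whole region for the spacer, clamped to the region length);
#' start uniform among placements entirely inside the region; recipient
#' uniform over copies; donor uniform over the remaining copies.
#'
#' @param sampler A [size_sampler()].
#' @param fam The [family_state()] the sampler was built for.
#' @return Object of class `simulated_conversion`: list with `region_id`,
#'   `recipient`, `donor`, `start`, `size`.
#' @export
sample_conversion <- function(sampler, fam) {
  stopifnot(inherits(sampler, "size_sampler"), inherits(fam, "family_state"))
  t <- sample.int(length(sampler$region), 1L)
  reg <- fam$regions[[sampler$region[t]]]
  if (isTRUE(reg$spacer)) {
    size <- reg$ncol
  } else {
    size <- sampler$lo[t] + sample.int(sampler$hi[t] - sampler$lo[t] + 1L, 1L) - 1L
    size <- min(size, reg$ncol)
  }
  start <- sample.int(reg$ncol - size + 1L, 1L)
  n <- length(fam$operon_ids)
  rec <- sample.int(n, 1L)
  don <- sample.int(n - 1L, 1L)
  if (don >= rec) don <- don + 1L
  structure(list(region_id = reg$region_id,
                 recipient = fam$operon_ids[rec],
                 donor = fam$operon_ids[don],
                 start = as.integer(start), size = as.integer(size)),
            class = "simulated_conversion")
}

#' @export
print.simulated_conversion <- function(x, ...) {
  cat(sprintf("simulated_conversion %s: %s <- %s, [%d, %d] (%d columns)\n",
              x$region_id, x$recipient, x$donor, x$start,
              x$start + x$size - 1L, x$size))
  invisible(x)
}

#' Create a mutable lineage state from ancestral alignments
#'
#' @param alns Named list of ancestral [operon_alignment()]s.
#' @return Object of class `lineage_state`: current alignments plus an ordered
#'   log of applied conversions.
#' @export
lineage_state <- function(alns) {
  if (inherits(alns, "operon_alignment")) alns <- setNames(list(alns), alns$region_id)
  structure(list(alns = alns, log = list()), class = "lineage_state")
}

#' Apply simulated conversions sequentially to a lineage
#'
#' Conversions are applied in order; a donor contributes its *current*
#' (possibly previously converted) sequence, so a later event can propagate or
#' revert an earlier one — the physical process the observability correction
#' accounts for.
#'
#' @param state A [lineage_state()].
#' @param convs A `simulated_conversion` or list of them.
#' @return The updated `lineage_state` (log extended).
#' @export
apply_conversions <- function(state, convs) {
  stopifnot(inherits(state, "lineage_state"))
  if (inherits(convs, "simulated_conversion")) convs <- list(convs)
  for (cv in convs) {
    aln <- state$alns[[cv$region_id]]
    if (is.null(aln)) stop("unknown region ", cv$region_id, call. = FALSE)
    end <- cv$start + cv$size - 1L
    if (cv$start < 1L || end > aln$n_columns) {
      stop("conversion window [", cv$start, ",", end,
           "] out of bounds for region ", cv$region_id, call. = FALSE)
    }
    cols <- cv$start:end
    aln$mat[cv$recipient, cols] <- aln$mat[cv$donor, cols]
    state$alns[[cv$region_id]] <- aln
    state$log[[length(state$log) + 1L]] <- cv
  }
  state
}

#' Minimum number of conversion events explaining an evolved family
#'
#' Sums the minimal-event partition size (the algorithm of
#' [infer_events_for_recipient()]) over all recipients of one region. Zero iff
#' the final family equals the ancestor. Because simulated conversions can be
#' silent (between identical stretches), hidden, or reverted, this count is in
#' practice at most — and usually below — the number of truly applied events.
#'
#' @param ancestor Ancestral [operon_alignment()].
#' @param final Evolved family: an `operon_alignment`, a character matrix of
#'   gapped rows (same shape and row order), or a `lineage_state`.
#' @return Integer event count.
#' @export
count_min_events <- function(ancestor, final) {
  stopifnot(inherits(ancestor, "operon_alignment"))
  mat <- .final_mat(ancestor, final)
  if (ancestor$type == "spacer") {
    alle <- spacer_alleles(ancestor)
    evolved <- vapply(ancestor$operon_ids, function(op)
      classify_spacer_allele(paste(mat[op, ], collapse = ""), alle), "")
    return(sum(evolved != alle$ancestral))
  }
  total <- 0L
  for (op in ancestor$operon_ids) {
    total <- total + length(infer_events_for_recipient(ancestor, mat[op, ], op))
  }
  total
}

.final_mat <- function(ancestor, final) {
  if (inherits(final, "lineage_state")) final <- final$alns[[ancestor$region_id]]
  if (inherits(final, "operon_alignment")) final <- final$mat
  if (!is.matrix(final)) final <- do.call(rbind, strsplit(final, "", fixed = TRUE))
  if (is.null(rownames(final))) rownames(final) <- ancestor$operon_ids
  if (!identical(dim(final), dim(ancestor$mat))) {
    stop("alignment-shape error: final family does not match ancestor shape",
         call. = FALSE)
  }
  final[ancestor$operon_ids, , drop = FALSE]
}

#' Exhaustive parsimony oracle for small instances
#'
#' Exact minimum number of conversion events by exhaustive search over all
#' partitions of each recipient's changed positions into contiguous groups,
#' keeping partitions in which every group has at least one donor whose
#' ancestral sequence matches the evolved recipient over the group's whole
#' span. Used to validate the greedy counter; guarded to small instances.
#'
#' @inheritParams count_min_events
#' @param max_copies,max_changed Size guards (instances beyond them error).
#' @return Integer event count.
#' @export
count_min_events_oracle <- function(ancestor, final, max_copies = 4L,
                                    max_changed = 8L) {
  stopifnot(inherits(ancestor, "operon_alignment"))
  if (length(ancestor$operon_ids) > max_copies) {
    stop("size-guard error: more than ", max_copies, " copies", call. = FALSE)
  }
  mat <- .final_mat(ancestor, final)
  anc_mat <- ancestor$mat
  total <- 0L
  for (op in ancestor$operon_ids) {
    ev <- mat[op, ]
    changed <- which(ev != anc_mat[op, ])
    k <- length(changed)
    if (k == 0L) next
    if (k > max_changed) {
      stop("size-guard error: ", k, " changed positions for recipient ", op,
           call. = FALSE)
    }
    others <- setdiff(ancestor$operon_ids, op)
    feasible <- function(i, j) {  # group = changed[i..j]
      length(.compatible_over(anc_mat, ev, others, changed[i], changed[j])) > 0L
    }
    feas <- matrix(FALSE, k, k)
    for (i in seq_len(k)) for (j in i:k) feas[i, j] <- feasible(i, j)
    best <- Inf
    # boundaries between consecutive changed positions: bit b set = cut after b
    for (mask in 0:(2^(k - 1L) - 1L)) {
      cuts <- which(bitwAnd(mask, 2L^(seq_len(k - 1L) - 1L)) > 0L)
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, k)
      if (length(starts) >= best) next
      ok <- all(mapply(function(i, j) feas[i, j], starts, ends))
      if (ok) best <- length(starts)
    }
    if (!is.finite(best)) {
      stop("novel allele error: no feasible partition for recipient ", op,
           call. = FALSE)
    }
    total <- total + best
  }
  total
}

# fast internal counter on a family_state-coded final matrix (used by tests
# to cross-check the R inference path against the C++ kernel)
.count_min_events_cpp <- function(fam, region_index, final_states) {
  r <- fam$regions[[region_index]]
  sum(cpp_count_min_events(r$anc, final_states))
}
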