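# Parsimonious reconstruction of gene conversion events from ancestor/evolved
# sequence pairs: donor candidate sets, minimum and maximum conversion extents.

new_conversion_event <- function(lineage_id, region_id, recipient,
                                 changed_positions, donor_candidates,
                                 min_extent, max_extent) {
  structure(
    list(lineage_id = lineage_id, region_id = region_id, recipient = recipient,
         changed_positions = as.integer(changed_positions),
         donor_candidates = donor_candidates,
         min_extent = as.integer(min_extent),
         max_extent = as.integer(max_extent)),
    class = "gene_conversion_event"
  )
}

#' @export
print.gene_conversion_event <- function(x, ...) {
  cat(sprintf("conversion %s/%s recipient %s: %d changed site(s) at [%s], donors {%s}, min [%d,%d], max [%d,%d]\n",
              x$lineage_id, x$region_id, x$recipient,
              length(x$changed_positions),
              paste(x$changed_positions, collapse = ","),
              paste(x$donor_candidates, collapse = ","),
              x$min_extent[1], x$min_extent[2],
              x$max_extent[1], x$max_extent[2]))
  invisible(x)
}

# Donor d is compatible with a candidate event spanning columns [lo, hi] iff
# the ancestral sequence of d equals the evolved recipient over every column
# of the span (so that copying d over the span reproduces the evolved row and
# nothing else). Compatibility is antitone in the span: growing the span can
# only remove donors, which is what makes the greedy partition minimal.
.compatible_over <- function(anc_mat, ev, donors, lo, hi) {
  cols <- lo:hi
  donors[vapply(donors, function(d) all(anc_mat[d, cols] == ev[cols]), TRUE)]
}

#' Infer the most parsimonious conversion events for one recipient
#'
#' Compares an evolved copy to its ancestral counterpart and partitions the
#' changed columns into the minimum number of gene conversion events, each
#' explainable by copying a single (ancestral) donor over a contiguous span.
#' The partition is built greedily left to right: an event's window is grown
#' rightward while at least one donor remains compatible with every column of
#' the window span, and closed when extension fails. Because compatibility
#' only shrinks as the window grows, the greedy partition attains the minimum
#' (verified against an exhaustive oracle, [count_min_events_oracle()]).
#'
#' @param ancestor An [operon_alignment()] of the ancestral family.
#' @param evolved_row Gapped sequence of the evolved copy (string or character
#'   vector), same width as the ancestor alignment.
#' @param recipient Operon label of the copy being compared.
#' @param lineage_id Label recorded on the returned events.
#' @return List of `gene_conversion_event`s, ordered left to right (empty if
#'   the evolved row equals the ancestral one). Each event carries the maximal
#'   donor candidate set, the minimum extent (first to last changed column),
#'   and the maximum extent (the widest single-donor interval around the event
#'   over which that donor matches the evolved sequence).
#' @export
infer_events_for_recipient <- function(ancestor, evolved_row, recipient,
                                       lineage_id = "lineage") {
  stopifnot(inherits(ancestor, "operon_alignment"))
  ev <- .as_char_vec(evolved_row)
  if (length(ev) != ancestor$n_columns) {
    stop("alignment-shape error: evolved row has ", length(ev),
         " columns, ancestor has ", ancestor$n_columns, call. = FALSE)
  }
  ev <- toupper(ev)
  ev[ev == "U"] <- "T"
  if (!recipient %in% ancestor$operon_ids) {
    stop("identity error: unknown recipient ", recipient, call. = FALSE)
  }
  anc_mat <- ancestor$mat
  changed <- which(ev != anc_mat[recipient, ])
  if (!length(changed)) return(list())
  others <- setdiff(ancestor$operon_ids, recipient)
  for (p in changed) {
    if (!any(anc_mat[others, p] == ev[p])) {
      stop("novel allele error: state ", sQuote(ev[p]), " at column ", p,
           " of ", ancestor$region_id,
           " matches no other ancestral copy", call. = FALSE)
    }
  }
  events <- list()
  first <- changed[1L]
  last <- first
  run <- first
  cand <- .compatible_over(anc_mat, ev, others, first, first)
  for (q in changed[-1L]) {
    surv <- .compatible_over(anc_mat, ev, cand, last + 1L, q)
    if (length(surv)) {
      cand <- surv
      last <- q
      run <- c(run, q)
    } else {
      events[[length(events) + 1L]] <-
        .close_event(ancestor, ev, recipient, lineage_id, run, cand)
      first <- q
      last <- q
      run <- q
      cand <- .compatible_over(anc_mat, ev, others, q, q)
    }
  }
  events[[length(events) + 1L]] <-
    .close_event(ancestor, ev, recipient, lineage_id, run, cand)
  events
}

.close_event <- function(ancestor, ev, recipient, lineage_id, run, cand) {
  ext <- infer_event_extents(ancestor, ev, run, cand)
  new_conversion_event(lineage_id, ancestor$region_id, recipient,
                       run, cand, ext$min_extent, ext$max_extent)
}

.as_char_vec <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "", fixed = TRUE)[[1L]]
  else as.character(x)
}

#' Minimum and maximum extents of a conversion event
#'
#' The minimum extent runs from the first to the last changed column. The
#' maximum extent is the largest region from any single donor that would
#' produce only the observed changes: each donor's interval is grown outward
#' column by column while that donor's ancestral state matches the evolved
#' recipient, stopping at the first mismatch or the region boundary, and the
#' widest donor interval is reported.
#'
#' @param ancestor An [operon_alignment()].
#' @param evolved_row Evolved recipient sequence (string or character vector).
#' @param changed_run Positions (1-based columns) of the event's changes.
#' @param donors Donor candidate labels, compatible over the run's span.
#' @return List with `min_extent` and `max_extent`, each `c(lo, hi)` inclusive.
#' @export
infer_event_extents <- function(ancestor, evolved_row, changed_run, donors) {
  stopifnot(inherits(ancestor, "operon_alignment"))
  if (!length(changed_run)) stop("empty changed run", call. = FALSE)
  if (!length(donors)) stop("empty donor set", call. = FALSE)
  ev <- .as_char_vec(evolved_row)
  anc_mat <- ancestor$mat
  n <- ancestor$n_columns
  lo <- min(changed_run)
  hi <- max(changed_run)
  best <- c(lo, hi)
  for (d in donors) {
    mism <- anc_mat[d, ] != ev
    left <- lo
    if (lo > 1L) {
      blocked <- which(mism[(lo - 1L):1L])  # scanning outward
      left <- if (length(blocked)) lo - blocked[1L] + 1L else 1L
    }
    right <- hi
    if (hi < n) {
      blocked <- which(mism[(hi + 1L):n])
      right <- if (length(blocked)) hi + blocked[1L] - 1L else n
    }
    if ((right - left) > (best[2L] - best[1L]) ||
        ((right - left) == (best[2L] - best[1L]) && left < best[1L])) {
      best <- c(left, right)
    }
  }
  list(min_extent = c(lo, hi), max_extent = best)
}

#' Extract the two spacer alleles from an ancestral spacer alignment
#'
#' The 23S-5S intergenic spacer segregates as two divergent length variants
#' (186 bp and 92 bp in *E. coli*) that swap as whole units.
#'
#' @param aln A spacer [operon_alignment()].
#' @return Object of class `spacer_alleles`: list with `long` and `short`
#'   (ungapped reference sequences) and `ancestral` (named allele id per
#'   operon, `"long"` or `"short"`).
#' @export
spacer_alleles <- function(aln) {
  stopifnot(inherits(aln, "operon_alignment"))
  ungapped <- apply(aln$mat, 1L, function(r) paste(r[r != "-"], collapse = ""))
  uniq <- unique(ungapped)
  if (length(uniq) != 2L) {
    stop("spacer alignment must contain exactly 2 distinct alleles, found ",
         length(uniq), call. = FALSE)
  }
  uniq <- uniq[order(-nchar(uniq))]
  ancestral <- ifelse(ungapped == uniq[1L], "long", "short")
  names(ancestral) <- aln$operon_ids
  structure(list(long = uniq[1L], short = uniq[2L], ancestral = ancestral),
            class = "spacer_alleles")
}

#' Classify a spacer sequence as one of the two alleles
#'
#' @param evolved_spacer Ungapped (or gapped; gaps are stripped) spacer
#'   sequence of one operon copy.
#' @param alleles A [spacer_alleles()] object.
#' @return `"long"` or `"short"`.
#' @export
classify_spacer_allele <- function(evolved_spacer, alleles) {
  stopifnot(inherits(alleles, "spacer_alleles"))
  s <- paste(.as_char_vec(evolved_spacer), collapse = "")
  s <- toupper(gsub("-", "", s, fixed = TRUE))
  if (s == alleles$long) return("long")
  if (s == alleles$short) return("short")
  stop("unclassified spacer sequence: matches neither allele", call. = FALSE)
}

# Spacer conversions are whole-unit allele swaps: one event per operon whose
# evolved allele differs from its ancestral allele, with a single possible
# extent covering the entire spacer.
.infer_spacer_events <- function(ancestor, evolved, lineage_id) {
  alleles <- spacer_alleles(ancestor)
  events <- list()
  for (op in ancestor$operon_ids) {
    ev_allele <- classify_spacer_allele(paste(evolved$mat[op, ], collapse = ""),
                                        alleles)
    if (ev_allele != alleles$ancestral[[op]]) {
      donors <- names(alleles$ancestral)[alleles$ancestral == ev_allele]
      donors <- setdiff(donors, op)
      changed <- which(evolved$mat[op, ] != ancestor$mat[op, ])
      events[[length(events) + 1L]] <- new_conversion_event(
        lineage_id, ancestor$region_id, op, changed, donors,
        c(1L, ancestor$n_columns), c(1L, ancestor$n_columns))
    }
  }
  events
}

#' Infer all conversion events for an evolved clone
#'
#' Runs [infer_events_for_recipient()] over every copy of every gene region
#' and classifies spacer regions by whole-unit allele swaps. Regions are
#' analyzed independently; events never span a region boundary.
#'
#' @param ancestor_alns Named list of ancestral [operon_alignment()]s.
#' @param evolved_alns Named list of evolved alignments (same regions, same
#'   shape, same operon order).
#' @param lineage_id Label recorded on the events.
#' @return An `event_set`: list of `gene_conversion_event`s with a `counts`
#'   attribute (table of events by region).
#' @export
infer_events <- function(ancestor_alns, evolved_alns, lineage_id = "lineage") {
  stopifnot(identical(names(ancestor_alns), names(evolved_alns)))
  events <- list()
  for (rid in names(ancestor_alns)) {
    anc <- ancestor_alns[[rid]]
    evo <- evolved_alns[[rid]]
    if (!identical(dim(anc$mat), dim(evo$mat))) {
      stop("alignment-shape error in region ", rid, call. = FALSE)
    }
    if (anc$type == "spacer") {
      events <- c(events, .infer_spacer_events(anc, evo, lineage_id))
    } else {
      for (op in anc$operon_ids) {
        events <- c(events, infer_events_for_recipient(
          anc, evo$mat[op, ], op, lineage_id))
      }
    }
  }
  event_set(events)
}

#' Bundle conversion events with per-lineage/per-region counts
#'
#' @param events List of `gene_conversion_event`s.
#' @return The list with class `event_set` and a `counts` attribute
#'   (data frame of event counts by lineage and region).
#' @export
event_set <- function(events) {
  if (length(events)) {
    df <- data.frame(
      lineage = vapply(events, `[[`, "", "lineage_id"),
      region = vapply(events, `[[`, "", "region_id"),
      stringsAsFactors = FALSE)
    counts <- as.data.frame(table(lineage = df$lineage, region = df$region),
                            responseName = "n_events")
    counts <- counts[counts$n_events > 0L | TRUE, ]
  } else {
    counts <- data.frame(lineage = character(), region = character(),
                         n_events = integer())
  }
  structure(events, class = "event_set", counts = counts)
}

#' @export
print.event_set <- function(x, ...) {
  cat("event_set with", length(x), "conversion event(s)\n")
  for (e in x) print(e)
  invisible(x)
}

#' Write conversion events as TSV
#'
#' Columns: `lineage`, `region`, `recipient`, `changed_positions` (comma
#' list), `donors` (comma list), `min_start`, `min_end`, `max_start`,
#' `max_end`.
#'
#' @param events An `event_set` or list of `gene_conversion_event`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  df <- events_to_table(events)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @return For `events_to_table`, a data frame in the on-disk column layout.
#' @export
events_to_table <- function(events) {
  data.frame(
    lineage = vapply(events, function(e) as.character(e$lineage_id), ""),
    region = vapply(events, `[[`, "", "region_id"),
    recipient = vapply(events, `[[`, "", "recipient"),
    changed_positions = vapply(events, function(e)
      paste(e$changed_positions, collapse = ","), ""),
    donors = vapply(events, function(e)
      paste(e$donor_candidates, collapse = ","), ""),
    min_start = vapply(events, function(e) e$min_extent[1L], 1L),
    min_end = vapply(events, function(e) e$min_extent[2L], 1L),
    max_start = vapply(events, function(e) e$max_extent[1L], 1L),
    max_end = vapply(events, function(e) e$max_extent[2L], 1L),
    stringsAsFactors = FALSE)
}

#' Read a conversion-events TSV
#'
#' @param path Path to a TSV in the layout written by [write_events_tsv()].
#' @return An `event_set`.
#' @export
read_events_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("lineage", "region", "recipient", "changed_positions", "donors",
            "min_start", "min_end", "max_start", "max_end")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("events table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  events <- lapply(seq_len(nrow(df)), function(i) {
    new_conversion_event(
      df$lineage[i], df$region[i], df$recipient[i],
      as.integer(strsplit(as.character(df$changed_positions[i]), ",")[[1L]]),
      strsplit(as.character(df$donors[i]), ",")[[1L]],
      c(df$min_start[i], df$min_end[i]),
      c(df$max_start[i], df$max_end[i]))
  })
  event_set(events)
}

#' Apply a conversion event to an ancestral alignment
#'
#' Copies one donor candidate's ancestral states over the event's minimum
#' extent. Used to check the round-trip property that inferred events
#' reproduce the evolved sequences.
#'
#' @param aln An [operon_alignment()].
#' @param event A `gene_conversion_event`.
#' @param donor Which donor candidate to realize (default: first).
#' @return The modified alignment.
#' @export
apply_event <- function(aln, event, donor = event$donor_candidates[1L]) {
  stopifnot(inherits(aln, "operon_alignment"), donor %in% event$donor_candidates)
  cols <- event$min_extent[1L]:event$min_extent[2L]
  aln$mat[event$recipient, cols] <- aln$mat[donor, cols]
  aln
}
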