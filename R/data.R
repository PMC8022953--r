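# Packaged example data.

#' Packaged observed-events table (synthetic stand-in)
#'
#' A conversion-events table in the [read_events_tsv()] layout describing 38
#' gene conversions across 15 MA lineages: 7 in the 16S gene, 27 in the 23S
#' gene, and 4 whole-unit swaps of the 23S-5S spacer, with per-operon
#' recipient totals over the gene regions of 4 (rrnA), 9 (rrnB), 11 (rrnC),
#' 4 (rrnD), 3 (rrnE), 0 (rrnG) and 3 (rrnH), including a single-base rrnD
#' 16S conversion at column 210 (donors rrnC/rrnE/rrnG) whose maximum extent
#' spans columns 1-1001, and changing 56 bases in total within the gene
#' regions. The event *tallies* reproduce published counts for the *E. coli*
#' rRNA operon family; the site coordinates, donor assignments and extents
#' are synthetic stand-ins (the original per-event records are not
#' redistributed here), hence the filename. Published summaries also disagree
#' internally on the rrnC total (11 stated once, 10 elsewhere); the table
#' follows the 11-count tally.
#'
#' @return For `observed_events_path`, the path to the packaged TSV; for
#'   `load_observed_events`, the table as an `event_set`.
#' @export
observed_events_path <- function() {
  system.file("extdata", "observed_events_synthetic.tsv", package = "rrnconv",
              mustWork = TRUE)
}

#' @rdname observed_events_path
#' @export
load_observed_events <- function() {
  read_events_tsv(observed_events_path())
}
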