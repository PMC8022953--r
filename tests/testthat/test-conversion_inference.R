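# Ancestor used across several cases: 4 copies, 12 columns.
#   cols:        123456789012
#   A (ref)      ACGTACGTACGT
#   B            ACCTACGTACGT   (differs at 3)
#   C            ACGTACGAACGT   (differs at 8)
#   D            ACCTACGAACGT   (differs at 3 and 8)
inference_toy <- function() {
  toy_aln(c(A = "ACGTACGTACGT",
            B = "ACCTACGTACGT",
            C = "ACGTACGAACGT",
            D = "ACCTACGAACGT"), ids = c("A", "B", "C", "D"))
}

test_that("an unchanged recipient yields no events", {
  anc <- inference_toy()
  expect_length(infer_events_for_recipient(anc, anc$mat["A", ], "A"), 0L)
})

test_that("a single change yields one event with the maximal donor set and extents", {
  anc <- inference_toy()
  # A converted at column 3 (G->C): B and D both carry C there, but D also
  # differs at 8 where A did not change, so only B can span beyond column 7
  ev_row <- anc$mat["A", ]
  ev_row[3L] <- "C"
  events <- infer_events_for_recipient(anc, ev_row, "A", "L1")
  expect_length(events, 1L)
  e <- events[[1L]]
  expect_equal(e$changed_positions, 3L)
  expect_setequal(e$donor_candidates, c("B", "D"))
  expect_equal(e$min_extent, c(3L, 3L))
  # B matches the evolved row everywhere -> max extent is the whole region
  expect_equal(e$max_extent, c(1L, 12L))
})

test_that("a blocking column truncates the maximum extent", {
  anc <- inference_toy()
  # D converted at column 3 back to G: donor must carry G at 3 -> {A, C};
  # D's unchanged difference at column 8 (A vs ancestral G of copy A) blocks
  # copy A there, but C matches through 12; so max extent = [1, 12] via C.
  ev_row <- anc$mat["D", ]
  ev_row[3L] <- "G"
  e <- infer_events_for_recipient(anc, ev_row, "D")[[1L]]
  expect_setequal(e$donor_candidates, c("A", "C"))
  expect_equal(e$max_extent, c(1L, 12L))

  # restrict donors to A only: blocked at column 8 -> right edge 7
  ext <- infer_event_extents(anc, ev_row, 3L, "A")
  expect_equal(ext$min_extent, c(3L, 3L))
  expect_equal(ext$max_extent, c(1L, 7L))
})

test_that("changes compatible only with different donors split into two events", {
  anc <- inference_toy()
  # A takes B's state at 3 and C's state at 8; no single donor matches both
  ev_row <- anc$mat["A", ]
  ev_row[3L] <- "C"   # B or D
  ev_row[8L] <- "A"   # C or D... but D carries C at 3? D has C at 3 and A at 8
  # D matches the evolved row at both changed columns -> 1 event via D
  expect_length(infer_events_for_recipient(anc, ev_row, "A"), 1L)

  # now block D by changing column 8 to a state only C could donate after
  # removing D's compatibility at column 3: convert 3 to ancestral-unique G?
  # Use a different construction: B gets C's state at 8 while keeping its own
  # private C at 3 unchanged is not a change; instead give B the states of A
  # at 3 (G) and C at 8 (A): donors at 3 = {A, C}, at 8 = {C, D}; C spans both
  ev_row <- anc$mat["B", ]
  ev_row[3L] <- "G"
  ev_row[8L] <- "A"
  expect_length(infer_events_for_recipient(anc, ev_row, "B"), 1L)
  expect_setequal(infer_events_for_recipient(anc, ev_row, "B")[[1L]]$donor_candidates,
                  "C")
})

test_that("two-event instances match the exhaustive oracle", {
  # force incompatibility: 3 copies, recipient changes at columns 2 and 8;
  # donor B matches only at 2, donor C only at 8, and B is blocked between
  anc <- toy_aln(c(A = "TAAAAAAAT",
                   B = "TCAAAAAAT",
                   C = "TAAAAAACT"), ids = c("A", "B", "C"))
  ev_row <- strsplit("TCAAAAACT", "")[[1L]]
  events <- infer_events_for_recipient(anc, ev_row, "A")
  expect_length(events, 2L)
  fin <- anc$mat
  fin["A", ] <- ev_row
  expect_equal(count_min_events_oracle(anc, fin), 2L)
  expect_equal(count_min_events(anc, fin), 2L)
})

test_that("a novel allele raises an error", {
  anc <- inference_toy()
  ev_row <- anc$mat["A", ]
  ev_row[5L] <- "T"  # no copy carries T at column 5
  expect_error(infer_events_for_recipient(anc, ev_row, "A"), "novel allele")
})

test_that("inferred events round-trip and donor sets are maximal", {
  withr::with_seed(101, {
    for (i in 1:30) {
      inst <- random_small_instance(n_copies = 4L, n_columns = 40L,
                                    n_het = 8L, max_events = 3L)
      anc <- inst$ancestor
      for (op in anc$operon_ids) {
        events <- infer_events_for_recipient(anc, inst$final[op, ], op)
        # round trip: realize each event over its min extent
        rebuilt <- anc
        for (e in events) rebuilt <- apply_event(rebuilt, e)
        expect_identical(unname(rebuilt$mat[op, ]), unname(inst$final[op, ]))
        # maximality: excluded copies fail somewhere on the event span
        for (e in events) {
          span <- e$min_extent[1L]:e$min_extent[2L]
          excluded <- setdiff(anc$operon_ids, c(op, e$donor_candidates))
          for (d in excluded) {
            expect_false(all(anc$mat[d, span] == inst$final[op, span]))
          }
        }
      }
    }
  })
})

test_that("spacer alleles classify exactly and conversions are whole-unit", {
  fam <- ecoli_like_family()
  alle <- fam$alleles
  expect_equal(nchar(alle$long), 186L)
  expect_equal(nchar(alle$short), 92L)
  expect_equal(sum(alle$ancestral == "long"), 4L)
  expect_identical(classify_spacer_allele(alle$long, alle), "long")
  expect_identical(classify_spacer_allele(tolower(alle$short), alle), "short")
  near <- alle$long
  substr(near, 5L, 5L) <- if (substr(near, 5L, 5L) == "A") "C" else "A"
  expect_error(classify_spacer_allele(near, alle), "unclassified")

  # swapping one operon's spacer registers exactly one whole-unit event
  spacer <- fam$alns$spacer
  swapped <- spacer
  long_op <- names(alle$ancestral)[alle$ancestral == "long"][1L]
  short_op <- names(alle$ancestral)[alle$ancestral == "short"][1L]
  swapped$mat[long_op, ] <- swapped$mat[short_op, ]
  events <- infer_events(list(spacer = spacer), list(spacer = swapped), "L1")
  expect_length(events, 1L)
  e <- events[[1L]]
  expect_identical(e$recipient, long_op)
  expect_equal(e$min_extent, c(1L, spacer$n_columns))
  expect_equal(e$max_extent, c(1L, spacer$n_columns))
  expect_false(long_op %in% e$donor_candidates)
  expect_equal(count_min_events(spacer, swapped), 1L)
})

test_that("events survive a TSV round trip", {
  anc <- inference_toy()
  ev_row <- anc$mat["A", ]
  ev_row[3L] <- "C"
  events <- event_set(infer_events_for_recipient(anc, ev_row, "A", "L7"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(events, path)
  back <- read_events_tsv(path)
  expect_length(back, 1L)
  expect_equal(back[[1L]]$changed_positions, events[[1L]]$changed_positions)
  expect_identical(back[[1L]]$donor_candidates, events[[1L]]$donor_candidates)
  expect_equal(back[[1L]]$max_extent, events[[1L]]$max_extent)
  expect_identical(back[[1L]]$lineage_id, "L7")
})

test_that("the packaged observed-events table parses and is self-consistent", {
  events <- load_observed_events()
  tab <- events_to_table(events)
  expect_true(all(tab$min_start <= tab$min_end))
  expect_true(all(tab$max_start <= tab$min_start & tab$min_end <= tab$max_end))
  expect_true(all(vapply(events, function(e)
    !e$recipient %in% e$donor_candidates, TRUE)))
})
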