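test_that("sampled sizes respect the 50-column floor and the template ranges", {
  fam <- ecoli_like_state()
  smp <- size_sampler(events_to_table(load_observed_events()), fam)
  withr::with_seed(21, {
    draws <- replicate(10000, sample_conversion(smp, fam), simplify = FALSE)
  })
  sizes <- vapply(draws, `[[`, 1L, "size")
  expect_true(all(sizes >= 50L))
  expect_true(all(sizes <= max(smp$hi)))
  starts <- vapply(draws, `[[`, 1L, "start")
  regions <- vapply(draws, `[[`, "", "region_id")
  ncols <- setNames(vapply(fam$regions, `[[`, 1L, "ncol"), fam$region_ids)
  expect_true(all(starts >= 1L & starts + sizes - 1L <= ncols[regions]))
})

test_that("spacer conversions always cover the whole spacer", {
  fam_all <- family_state(ecoli_like_family()$alns)
  smp <- size_sampler(events_to_table(load_observed_events())[35:38, ], fam_all)
  withr::with_seed(8, {
    draws <- replicate(500, sample_conversion(smp, fam_all), simplify = FALSE)
  })
  expect_true(all(vapply(draws, `[[`, "", "region_id") == "spacer"))
  expect_true(all(vapply(draws, `[[`, 1L, "size") == 186L))
  expect_true(all(vapply(draws, `[[`, 1L, "start") == 1L))
})

test_that("recipient-donor pairs are uniform over the 42 ordered pairs", {
  fam <- ecoli_like_state()
  smp <- fixed_size_sampler(fam, 50L, 400L)
  withr::with_seed(33, {
    draws <- replicate(10000, sample_conversion(smp, fam), simplify = FALSE)
  })
  pair <- table(paste(vapply(draws, `[[`, "", "recipient"),
                      vapply(draws, `[[`, "", "donor")))
  expect_length(pair, 42L)
  p <- 1 / 42
  bound <- 4 * sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(pair / 10000 - p) <= bound))
})

test_that("sequential application copies current, not ancestral, sequence", {
  # B <- A over [10, 60], then C <- B over the same window: C must carry A's
  # original states there
  withr::with_seed(2, {
    base <- sample(c("A", "C", "G", "T"), 80, replace = TRUE)
  })
  mat <- rbind(A = base, B = base, C = base)
  mat["B", c(20, 40)] <- "-"   # B's private alleles inside the window
  mat["C", 30] <- if (base[30] == "A") "C" else "A"
  anc <- operon_alignment(mat, region_id = "toy", operon_ids = c("A", "B", "C"))
  st <- lineage_state(anc)
  cv1 <- structure(list(region_id = "toy", recipient = "B", donor = "A",
                        start = 10L, size = 51L), class = "simulated_conversion")
  cv2 <- structure(list(region_id = "toy", recipient = "C", donor = "B",
                        start = 10L, size = 51L), class = "simulated_conversion")
  st <- apply_conversions(st, list(cv1, cv2))
  expect_identical(unname(st$alns$toy$mat["C", 10:60]), unname(base[10:60]))
  expect_identical(unname(st$alns$toy$mat["B", 10:60]), unname(base[10:60]))
  expect_length(st$log, 2L)

  # idempotence: re-applying the same conversion changes nothing
  st2 <- apply_conversions(st, cv2)
  expect_identical(st2$alns$toy$mat, st$alns$toy$mat)

  # a single application leaves recipient equal to donor over the window
  st3 <- apply_conversions(lineage_state(anc), cv1)
  expect_identical(unname(st3$alns$toy$mat["B", 10:60]),
                   unname(st3$alns$toy$mat["A", 10:60]))

  # out-of-bounds window errors
  bad <- structure(list(region_id = "toy", recipient = "B", donor = "A",
                        start = 60L, size = 51L), class = "simulated_conversion")
  expect_error(apply_conversions(st, bad), "out of bounds")
})

test_that("greedy minimum event counts match the exhaustive oracle", {
  withr::with_seed(77, {
    n_exceed <- 0L
    for (i in 1:200) {
      inst <- random_small_instance(n_copies = sample(3:4, 1L),
                                    n_columns = 30L, n_het = 5L,
                                    max_events = 4L)
      greedy <- count_min_events(inst$ancestor, inst$final)
      oracle <- count_min_events_oracle(inst$ancestor, inst$final)
      expect_identical(greedy, oracle)
      if (greedy > inst$n_applied) n_exceed <- n_exceed + 1L
    }
    # observability: the reconstruction almost never needs more events than
    # were applied (donor-mosaic corner cases are possible but rare)
    expect_lte(n_exceed, 2L)
  })
})

test_that("greedy merges separated runs when one donor spans both", {
  # donor B differs from the reference at columns 2 and 8 only; converting
  # both into A leaves a gap of matching columns between the runs, yet a
  # single conversion from B explains everything
  anc <- toy_aln(c(A = "TAAAAAAAT", B = "TCAAAAACT", C = "TAAAAAAAT"),
                 ids = c("A", "B", "C"))
  fin <- anc$mat
  fin["A", c(2L, 8L)] <- c("C", "C")
  expect_equal(count_min_events(anc, fin), 1L)
  expect_equal(count_min_events_oracle(anc, fin), 1L)
})

test_that("the R inference path and the C++ kernel agree on event counts", {
  fam <- ecoli_like_family()
  fs <- ecoli_like_state()
  smp <- synthetic_size_sampler(fs, seed = 5L)
  sim <- simulate_ma_lineages(fam, 5e-4, ma_config(n_lineages = 10L, seed = 3L),
                              smp)
  for (i in seq_along(sim$lineages)) {
    for (ri in seq_along(fs$region_ids)) {
      rid <- fs$region_ids[ri]
      r_count <- count_min_events(fam$alns[[rid]], sim$lineages[[i]][[rid]])
      coded <- encode_at_het(fs, ri, sim$lineages[[i]][[rid]]$mat)
      cpp_count <- sum(rrnconv:::cpp_count_min_events(fs$regions[[ri]]$anc, coded))
      expect_identical(r_count, as.integer(cpp_count))
    }
  }
})

test_that("count_min_events is zero iff nothing changed, and order-invariant", {
  anc <- inference_toy <- toy_aln(c(A = "ACGTACGTACGT", B = "ACCTACGTACGT",
                                    C = "ACGTACGAACGT", D = "ACCTACGAACGT"),
                                  ids = c("A", "B", "C", "D"))
  expect_equal(count_min_events(anc, anc$mat), 0L)
  fin <- anc$mat
  fin["A", 3L] <- "C"
  expect_equal(count_min_events(anc, fin), 1L)
  perm <- c(4L, 2L, 1L, 3L)
  anc_p <- operon_alignment(anc$mat[perm, ], "16S", anc$operon_ids[perm])
  expect_equal(count_min_events(anc_p, fin[perm, ]), 1L)
})

test_that("some conversions are silent on the synthetic family", {
  fam <- ecoli_like_family()
  fs <- ecoli_like_state()
  smp <- fixed_size_sampler(fs, 50L, 400L, region = "16S")
  withr::with_seed(91, {
    counts <- replicate(150, {
      cv <- sample_conversion(smp, fs)
      st <- apply_conversions(lineage_state(fam$alns["16S"]), cv)
      count_min_events(fam$alns[["16S"]], st$alns[["16S"]])
    })
  })
  expect_true(mean(counts) < 1)   # observability loss
  expect_true(any(counts == 1L)) # but not everything is silent
  expect_true(all(counts <= 1L)) # a single conversion is at most one event
})
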