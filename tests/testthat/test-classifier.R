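test_that("classify_nco follows the stated rules on canonical examples", {
  expect_equal(classify_nco("3:5", "single"), "SDSA_canonical")
  expect_equal(classify_nco("3:5_4:4_3:5", "single"), "SDSA_complex")
  expect_equal(classify_nco("3:5_3:5*", "single"), "trans_canonical")
  expect_equal(classify_nco("3:5_4:4_3:5*", "single"), "trans_complex")
  # full conversions only, terminal full conversions, aberrant, opposite
  # directions, multi-chromatid: all route to other
  expect_equal(classify_nco("2:6", "single"), "other")
  expect_equal(classify_nco("3:5_2:6", "single"), "other")
  expect_equal(classify_nco("4:4*_3:5", "two-non-sister"), "other")
  expect_equal(classify_nco("5:3_4:4_3:5", "two-non-sister"), "other")
  expect_equal(classify_nco("3:5", "two-non-sister"), "other")
  expect_equal(classify_nco("3:5_3:5*", "two-sister"), "other")
  # interior full conversion of the matching direction is tolerated
  expect_equal(classify_nco("5:3_6:2_5:3", "single"), "SDSA_complex")
  # mismatched full-conversion direction is not
  expect_equal(classify_nco("5:3_2:6_5:3", "single"), "other")
})

test_that("the NCO inventory partitions into frozen class counts", {
  nco <- pattern_inventory("msh2_nco")
  cls <- classify_nco(nco$pattern, nco$chromatid_assignment)
  counts <- tapply(nco$occurrence, cls, sum)
  expect_equal(counts[["SDSA_canonical"]], 66L)
  expect_equal(counts[["SDSA_complex"]], 11L)
  expect_equal(counts[["trans_canonical"]], 28L)
  expect_equal(counts[["trans_complex"]], 32L)
  expect_equal(counts[["other"]], 32L)
  expect_equal(sum(counts), 169L)
})

test_that("exactly the three documented fixture rows are rule-discordant", {
  nco <- pattern_inventory("msh2_nco")
  cls <- classify_nco(nco$pattern, nco$chromatid_assignment)
  rule_group <- ifelse(cls %in% c("SDSA_canonical", "SDSA_complex"), "sdsa",
                ifelse(cls %in% c("trans_canonical", "trans_complex"),
                       "trans", "other"))
  discordant <- nco$pattern[rule_group != nco$printed_class]
  expect_setequal(discordant, c("3:5_2:6_4:4_3:5", "3:5_4:4_3:5_2:6_3:5",
                                "5:3_4:4_5:3*_6:2_5:3*"))
  expect_equal(sum(nco$occurrence[rule_group != nco$printed_class]), 3L)
})

test_that("classification is stable under canonicalization and row order", {
  nco <- pattern_inventory("msh2_nco")
  cls <- classify_nco(nco$pattern, nco$chromatid_assignment)
  canon <- canonicalize_pattern(nco$pattern)
  expect_equal(classify_nco(canon, nco$chromatid_assignment), cls)
  ord <- rev(seq_len(nrow(nco)))
  expect_equal(classify_nco(nco$pattern[ord], nco$chromatid_assignment[ord]),
               cls[ord])
})

test_that("classify_co distinguishes transfer locations", {
  expect_equal(classify_co("none", "none"), "no_transfer")
  expect_equal(classify_co("2:6", "single"), "single_chromatid")
  expect_equal(classify_co("3:5_4:4*", "two-non-sister"),
               "two_non_sister_other")
  expect_equal(classify_co("3:5_2:6_3:5*", "two-non-sister"),
               "two_non_sister_DSBR_compatible")
  expect_equal(classify_co("2:6_1:7", "two-sister"), "other")
})

test_that("classify_co uses tract geometry for overlap and asymmetry", {
  non_overlap <- tibble::tibble(chromatid = c(1L, 3L),
                                start = c(1000, 2100), end = c(2000, 2600))
  expect_equal(classify_co("3:5_3:5*", "two-non-sister", non_overlap),
               "two_non_sister_DSBR_compatible")
  # length ratio 1000/500 = 2 < 3: compatible; widen to trigger asymmetric
  asym <- tibble::tibble(chromatid = c(1L, 3L),
                         start = c(1000, 5100), end = c(5000, 5600))
  expect_equal(classify_co("3:5_3:5*", "two-non-sister", asym),
               "two_non_sister_DSBR_asymmetric")
  overlap <- tibble::tibble(chromatid = c(1L, 3L),
                            start = c(1000, 1500), end = c(2000, 2600))
  expect_equal(classify_co("4:4*", "two-non-sister", overlap),
               "two_non_sister_other")
})

test_that("the CO inventory reproduces the published complexity counts", {
  co <- pattern_inventory("msh2_co")
  # 112 of the 155 transfer-bearing patterns comprise 2 to 8 tracts
  expect_equal(sum(co$occurrence[co$n_tracts >= 2L]), 112L)
  # 49 comprise more than 3 tracts (the pooled aggregate rows)
  expect_equal(sum(co$occurrence[co$n_tracts >= 4L]), 49L)
  # 36 carry heteroduplex on the two non-sister chromatids, 19 of them
  # DSBR-compatible among the explicit (non-aggregate) rows plus the
  # aggregate contribution is not computable from the pattern alone
  cls <- classify_co(co$pattern, co$chromatid_assignment)
  expect_equal(sum(co$occurrence[cls == "no_transfer"]), 26L)
  expect_equal(sum(co$occurrence[cls == "single_chromatid"]), 119L)
})

test_that("opposite-direction counts match the published CO/NCO contrast", {
  co <- pattern_inventory("msh2_co")
  nco <- pattern_inventory("msh2_nco")
  # explicit (non-aggregate) CO rows contribute 6 of the published 26
  expect_equal(sum(co$occurrence[has_opposite_directions(co$pattern)]), 6L)
  expect_equal(sum(nco$occurrence[has_opposite_directions(nco$pattern)]), 4L)
})

test_that("simulated canonical pathways classify into their own classes", {
  # conditioned on marker-detectable tracts: a pattern can only show the
  # tracts that cover at least one marker
  for (seed in 1:25) {
    s <- simulate_meiosis(small_config(
      seed = seed, pathway_probs = single_pathway("simple_SDSA"),
      complications = FALSE))
    ev <- call_recombination_events(s$marker_map, s$genotypes)
    expect_true(all(ev$kind == "NCO"))
    expect_true(all(ev$class == "SDSA_canonical"))

    s2 <- simulate_meiosis(small_config(
      seed = seed + 1000, pathway_probs = single_pathway("dHJ_dissolution"),
      complications = FALSE))
    ev2 <- call_recombination_events(s2$marker_map, s2$genotypes)
    # events whose two written tracts both span >= 1 marker show the full
    # trans pattern; single-covered events degrade to the SDSA pattern
    vis <- s2$truth$tracts[s2$truth$tracts$state == "hDNA" &
                             s2$truth$tracts$n_markers >= 1L, ]
    both <- tapply(vis$strand, vis$event_id,
                   function(x) length(unique(x)) == 2L)
    full_trans_ids <- as.integer(names(both)[both])
    for (eid in full_trans_ids) {
      te <- s2$truth$events[s2$truth$events$event_id == eid, ]
      tr <- vis[vis$event_id == eid, ]
      hit <- ev2$chrom == te$chrom & ev2$start <= max(tr$end) &
        ev2$end >= min(tr$start)
      if (sum(tr$n_markers) >= 2L) {
        expect_true(any(ev2$class[hit] == "trans_canonical"),
                    info = paste("seed", seed, "event", eid))
      }
    }
  }
})
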