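test_that("marker maps reach the configured density", {
  cfg <- sim_config(chrom_sizes = c(chrA = 1e6), marker_spacing = 194)
  means <- vapply(1:20, function(s) {
    mm <- make_marker_map(cfg, seed = s)
    mean(diff(mm$pos))
  }, numeric(1))
  expect_lt(abs(mean(means) - 194) / 194, 0.1)
  expect_true(all(abs(means - 194) / 194 < 0.15))
})

test_that("degenerate spacing errors; same seed gives identical maps", {
  expect_error(
    make_marker_map(sim_config(chrom_sizes = c(chrA = 1e6),
                               marker_spacing = 2e6)),
    "degenerate"
  )
  cfg <- sim_config(chrom_sizes = c(chrA = 2e5))
  expect_identical(make_marker_map(cfg, seed = 9), make_marker_map(cfg, seed = 9))
})

test_that("simulation is fully determined by (config, seed)", {
  cfg <- small_config(seed = 21, complications = TRUE)
  s1 <- simulate_meiosis(cfg)
  s2 <- simulate_meiosis(cfg)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$truth$events, s2$truth$events)
  expect_identical(s1$truth$tracts, s2$truth$tracts)
  s3 <- simulate_meiosis(small_config(seed = 22, complications = TRUE))
  expect_false(identical(s1$genotypes$calls, s3$genotypes$calls))
})

test_that("strand conservation holds: eight strands per marker, 4:4 without DSBs", {
  s <- simulate_meiosis(small_config(seed = 31))
  counts <- rowSums(s$genotypes$calls == 1L)
  expect_true(all(counts + rowSums(s$genotypes$calls == 0L) == 8L))

  s0 <- simulate_meiosis(sim_config(chrom_sizes = c(chrA = 2e5), dsb_mean = 0,
                                    seed = 1))
  expect_true(all(rowSums(s0$genotypes$calls == 1L) == 4L))
  expect_equal(nrow(s0$truth$events), 0L)
})

test_that("pure simple-SDSA writes one strand of one chromatid per event", {
  for (seed in 1:10) {
    cfg <- small_config(seed = seed, complications = FALSE,
                        pathway_probs = single_pathway("simple_SDSA"))
    s <- simulate_meiosis(cfg)
    vis <- s$truth$tracts[s$truth$tracts$state == "hDNA", ]
    expect_true(all(s$truth$events$outcome %in% c("NCO", "invisible")))
    for (eid in unique(vis$event_id)) {
      tr <- vis[vis$event_id == eid, ]
      expect_equal(length(unique(tr$chromatid)), 1L)
      expect_equal(length(unique(tr$strand)), 1L)
      expect_true(all(tr$strand %in% 1:2))
    }
  }
})

test_that("pure crossover resolution records one reciprocal exchange per event", {
  for (seed in 1:10) {
    cfg <- small_config(seed = seed, complications = FALSE,
                        pathway_probs = single_pathway("dHJ_resolution_CO"))
    s <- simulate_meiosis(cfg)
    ev <- s$truth$events[s$truth$events$outcome == "CO", ]
    expect_true(nrow(ev) > 0)
    # broken and donor are non-sisters (one from each parental pair)
    expect_true(all((ev$broken <= 2) != (ev$donor <= 2)))
  }
})

test_that("arm balance: outside written tracts chromatids match phase up to exchanges", {
  cfg <- small_config(seed = 41, complications = FALSE)
  s <- simulate_meiosis(cfg)
  for (ch in unique(s$truth$events$chrom)) {
    A <- s$strands$alleles[[ch]]
    pos <- s$marker_map$pos[s$marker_map$chrom == ch]
    tev <- s$truth$events[s$truth$events$chrom == ch, ]
    ttr <- s$truth$tracts[s$truth$tracts$chrom == ch, ]
    in_tract <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(ttr))) {
      in_tract <- in_tract | (pos >= ttr$start[i] & pos <= ttr$end[i])
    }
    co_pos <- sort(tev$pos[tev$outcome == "CO"])
    for (k in 1:4) {
      expected <- rep(if (k <= 2) 1L else 0L, length(pos))
      for (x in co_pos) {
        co_ev <- tev[tev$outcome == "CO" & tev$pos == x, ]
        if (k %in% c(co_ev$broken, co_ev$donor)) {
          flip <- pos > x
          expected[flip] <- 1L - expected[flip]
        }
      }
      outside <- !in_tract
      expect_true(all(A[2 * k - 1, outside] == expected[outside]))
      expect_true(all(A[2 * k, outside] == expected[outside]))
    }
  }
})

test_that("trans pathways write opposite strands of the broken chromatid", {
  cfg <- small_config(seed = 51, complications = FALSE,
                      pathway_probs = single_pathway("dHJ_dissolution"))
  s <- simulate_meiosis(cfg)
  vis <- s$truth$tracts[s$truth$tracts$state == "hDNA", ]
  for (eid in unique(vis$event_id)) {
    tr <- vis[vis$event_id == eid, ]
    expect_equal(length(unique(tr$chromatid)), 1L)
    expect_setequal(tr$strand, 1:2)
  }
})

test_that("lowering marker density never increases the number of called events", {
  cfg <- sim_config(chrom_sizes = c(chrA = 400000),
                    dsb_mean = 6, complications = FALSE, seed = 61)
  s <- simulate_meiosis(cfg)
  mm <- s$marker_map
  gt <- s$genotypes
  n_prev <- Inf
  for (keep_frac in c(1, 0.5, 0.25, 0.1, 0.02)) {
    set.seed(99)
    keep <- sort(sample(nrow(mm), max(2L, round(keep_frac * nrow(mm)))))
    ev <- call_recombination_events(
      marker_map(chrom = mm$chrom[keep], pos = mm$pos[keep]),
      genotype_calls(gt$calls[keep, , drop = FALSE], "octad")
    )
    expect_lte(nrow(ev), n_prev)
    n_prev <- nrow(ev)
  }
})

test_that("injected mitotic artifacts are filtered out by the caller", {
  cfg <- sim_config(chrom_sizes = c(chrA = 300000), dsb_mean = 0,
                    mito_rate = 3, seed = 71)
  s <- simulate_meiosis(cfg)
  expect_true(any(s$truth$events$outcome == "mitotic"))
  ev <- call_recombination_events(s$marker_map, s$genotypes)
  expect_equal(nrow(ev), 0L)
})
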