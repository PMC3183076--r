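# phase-A octad signature: chromatids 1,2 carry parent 1
PH_A <- c(1, 1, 1, 1, 0, 0, 0, 0)
# chromatids 1 and 3 exchanged
PH_B <- c(0, 0, 1, 1, 1, 1, 0, 0)
# additionally chromatids 2 and 4 exchanged
PH_C <- c(0, 0, 0, 0, 1, 1, 1, 1)

test_that("phase inference finds segments and reciprocal junctions", {
  # no phase change
  M <- octad_matrix(10)
  tr <- segment_tracts(M, 1000 * (1:10), "octad")
  ph <- infer_parental_phase(tr)
  expect_equal(nrow(ph$segments), 1L)
  expect_equal(nrow(ph$junctions), 0L)

  # one reciprocal swap
  M <- rbind(octad_matrix(10, PH_A), octad_matrix(10, PH_B))
  tr <- segment_tracts(M, 1000 * (1:20), "octad")
  ph <- infer_parental_phase(tr)
  expect_equal(nrow(ph$junctions), 1L)
  expect_equal(ph$junctions$changed[[1]], c(1L, 3L))
  expect_true(ph$junctions$reciprocal[1])
  expect_equal(ph$junctions$pos[1], 10500)

  # two successive swaps involving different chromatid pairs
  M <- rbind(octad_matrix(7, PH_A), octad_matrix(7, PH_B),
             octad_matrix(6, PH_C))
  tr <- segment_tracts(M, 1000 * (1:20), "octad")
  ph <- infer_parental_phase(tr)
  expect_equal(nrow(ph$junctions), 2L)
  expect_equal(ph$junctions$changed[[2]], c(2L, 4L))
})

test_that("a chromosome without Mendelian background is phase-undefined", {
  M <- octad_matrix(5, c(1, 1, 1, 1, 1, 0, 0, 0))  # all 5:3
  tr <- segment_tracts(M, 1000 * (1:5), "octad")
  expect_error(infer_parental_phase(tr), "phase-undefined")
})

test_that("a bare phase junction is called as a crossover with pattern none", {
  M <- rbind(octad_matrix(10, PH_A), octad_matrix(10, PH_B))
  ev <- call_on_matrix(M)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "CO")
  expect_equal(ev$pattern, "none")
  expect_equal(ev$exchange, "1/3")
  expect_equal(ev$class, "no_transfer")
  expect_equal(ev$junction_pos, 10500)
})

test_that("an isolated half-conversion tract is a non-crossover", {
  M <- octad_matrix(20, edits = list(list(rows = 8:9, cells = 5, value = 1)))
  ev <- call_on_matrix(M)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "NCO")
  expect_equal(ev$pattern, "5:3")
  expect_equal(ev$chromatid_summary, "single")
  expect_equal(ev$class, "SDSA_canonical")
  expect_equal(ev$n_markers, 2L)
})

test_that("single-marker events are discarded", {
  # 1-marker full conversion: chromatid 3 homoduplex parent1
  M <- octad_matrix(20, edits = list(list(rows = 10, cells = 5:6, value = 1)))
  ev <- call_on_matrix(M)
  expect_equal(nrow(ev), 0L)
  # but a 2-marker conversion is kept
  M2 <- octad_matrix(20, edits = list(list(rows = 10:11, cells = 5:6,
                                           value = 1)))
  ev2 <- call_on_matrix(M2)
  expect_equal(ev2$pattern, "6:2")
})

test_that("mitotic 4:0 runs are filtered before event calling", {
  M <- octad_matrix(20, edits = list(list(rows = 9:12, cells = 1:8,
                                          value = 1)))
  ev <- call_on_matrix(M)
  expect_equal(nrow(ev), 0L)
})

test_that("nearby events merge across a restoration patch; distant ones do not", {
  # two 2-marker tracts, same chromatid & strand, 4 kb gap -> one event
  M <- octad_matrix(20, edits = list(
    list(rows = 4:5, cells = 5, value = 1),
    list(rows = 9:10, cells = 5, value = 1)
  ))
  ev <- call_on_matrix(M)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$pattern, "5:3_4:4_5:3")
  expect_equal(ev$n_markers, 4L)

  # 7 kb gap -> two events
  M2 <- octad_matrix(20, edits = list(
    list(rows = 4:5, cells = 5, value = 1),
    list(rows = 12:13, cells = 5, value = 1)
  ))
  ev2 <- call_on_matrix(M2)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$kind, c("NCO", "NCO"))

  # different strand of the same chromatid -> starred second tract
  M3 <- octad_matrix(20, edits = list(
    list(rows = 4:5, cells = 5, value = 1),
    list(rows = 9:10, cells = 6, value = 1)
  ))
  ev3 <- call_on_matrix(M3)
  expect_equal(ev3$pattern, "5:3_4:4_5:3*")
  expect_equal(ev3$class, "trans_complex")
})

test_that("a conversion on a chromatid not involved in a nearby crossover stays separate", {
  # CO between chromatids 1 and 3 at ~10.5 kb; NCO on chromatid 2 at 7-8 kb
  M <- rbind(octad_matrix(10, PH_A), octad_matrix(10, PH_B))
  M[7:8, 3] <- 0L   # chromatid 2 mother cell -> 3:5 heteroduplex
  ev <- call_on_matrix(M)
  expect_equal(nrow(ev), 2L)
  expect_setequal(ev$kind, c("CO", "NCO"))

  # same geometry but the conversion is on chromatid 1 (involved in the CO):
  # merged into the crossover
  M2 <- rbind(octad_matrix(10, PH_A), octad_matrix(10, PH_B))
  M2[7:8, 1] <- 0L
  ev2 <- call_on_matrix(M2)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$kind, "CO")
  expect_equal(ev2$pattern, "3:5_4:4")
})

test_that("a short phase-swapped Mendelian patch is a non-crossover, not two crossovers", {
  M <- rbind(octad_matrix(8, PH_A), octad_matrix(2, PH_B),
             octad_matrix(10, PH_A))
  ev <- call_on_matrix(M)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "NCO")
  expect_equal(ev$pattern, "4:4*")
  expect_equal(ev$n_markers, 2L)
})

test_that("double crossovers more than the merge distance apart stay separate", {
  M <- rbind(octad_matrix(7, PH_A), octad_matrix(7, PH_B),
             octad_matrix(6, PH_C))
  ev <- call_on_matrix(M)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$kind, c("CO", "CO"))
  expect_equal(ev$exchange, c("1/3", "2/4"))
})

test_that("midpoint tract-length estimation follows the stated rule", {
  expect_equal(estimate_tract_length(2, 3, c(900, 1000, 2000, 2100)), 1100)
  expect_equal(estimate_tract_length(2, 2, c(100, 200, 300)), 100)
  # chromosome end: falls back to the terminal marker position
  expect_equal(estimate_tract_length(1, 2, c(100, 300, 500)), 300)
  expect_equal(estimate_tract_length(2, 3, c(100, 300, 500)), 300)
})

test_that("event lengths sum the constituent patches via midpoints", {
  M <- octad_matrix(20, edits = list(list(rows = 8:9, cells = 5, value = 1)))
  ev <- call_on_matrix(M, spacing = 1000)
  # flanks at 7000 and 10000, tract markers at 8000, 9000 -> 7500..9500
  expect_equal(ev$length_bp, 2000)
})

test_that("tetrad-mode calling produces conversion patterns with spore stars", {
  base <- c(1, 1, 0, 0)
  M <- matrix(rep(base, each = 20), nrow = 20)
  M[8:9, 3] <- 1L    # spore 3 converted: 3:1
  M[12:13, 3] <- 1L  # same spore again after a Mendelian patch
  gt <- genotype_calls(M, "tetrad")
  mm <- marker_map(chrom = "chrT", pos = 1000 * (1:20))
  ev <- call_recombination_events(mm, gt)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$pattern, "3:1_2:2_3:1")
  expect_equal(ev$kind, "NCO")

  # conversion of a different spore gets a star
  M2 <- matrix(rep(base, each = 20), nrow = 20)
  M2[8:9, 3] <- 1L
  M2[12:13, 4] <- 1L
  ev2 <- call_recombination_events(mm, genotype_calls(M2, "tetrad"))
  expect_equal(ev2$pattern, "3:1_2:2_3:1*")
})

test_that("merge_events re-merges with a different threshold", {
  M <- octad_matrix(20, edits = list(
    list(rows = 4:5, cells = 5, value = 1),
    list(rows = 9:10, cells = 5, value = 1)
  ))
  ev <- call_on_matrix(M)   # merged at 5 kb
  expect_equal(nrow(ev), 1L)
  ev2 <- merge_events(ev, threshold = 1000)
  expect_equal(nrow(ev2), 2L)
})
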