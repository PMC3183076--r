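#' Recompute the published pattern-table statistics from the fixtures
#'
#' Runs the pattern operations over the shipped pattern inventories and
#' recomputes the headline numbers reported alongside the printed tables:
#' complex-pattern percentages among crossovers, the canonical
#' single-chromatid non-crossover classes, and the opposite-direction
#' heteroduplex count. Each value is computed from the fixture rows at call
#' time; the `reference` column carries the published value for comparison.
#'
#' @return A tibble: `statistic`, `value` (computed), `reference`
#'   (published), `units`.
#' @export
reproduce_table_statistics <- function() {
  nco <- pattern_inventory("msh2_nco")
  co <- pattern_inventory("msh2_co")
  wt_co <- pattern_inventory("wt_co")

  co_gt2 <- sum(co$occurrence[co$n_tracts >= 3L])
  wt_gt2 <- sum(wt_co$occurrence[wt_co$n_tracts >= 3L])

  nco_class <- classify_nco(nco$pattern, nco$chromatid_assignment)
  canon <- canonicalize_pattern(nco$pattern, "octad")
  opp <- has_opposite_directions(nco$pattern, "octad")

  tibble::tibble(
    statistic = c(
      "msh2 CO patterns with more than two tracts (% of all COs)",
      "wild-type CO patterns with more than two tracts (% of all COs)",
      "msh2 NCOs: single continuous half-conversion on one chromatid",
      "msh2 NCOs: canonical trans pattern (X_X*) on one chromatid",
      "msh2 NCOs: half-conversion / restoration patch / half-conversion*",
      "msh2 NCOs with opposite-direction half-conversions",
      "msh2 NCO inventory total",
      "msh2 CO inventory total"
    ),
    value = c(
      round_half_up(100 * co_gt2 / sum(co$occurrence)),
      round_half_up(100 * wt_gt2 / sum(wt_co$occurrence)),
      sum(nco$occurrence[nco_class == "SDSA_canonical"]),
      sum(nco$occurrence[nco_class == "trans_canonical"]),
      sum(nco$occurrence[canon == "3:5_4:4_3:5*" &
                           nco$chromatid_assignment == "single"]),
      sum(nco$occurrence[opp]),
      sum(nco$occurrence),
      sum(co$occurrence)
    ),
    reference = c(43, 5, 66, 28, 22, 4, 169, 181),
    units = c("%", "%", "events", "events", "events", "events",
              "events", "events")
  )
}
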