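#' Classify a non-crossover strand-transfer pattern
#'
#' Rule-based assignment of a non-crossover event to a mechanistic class from
#' its pattern string and chromatid distribution:
#'
#' * `SDSA_canonical` — one continuous half-conversion tract on a single
#'   chromatid, the outcome predicted by simple synthesis-dependent strand
#'   annealing.
#' * `SDSA_complex` — as above, but the half-conversion is interrupted by
#'   restoration (Mendelian) or full-conversion patches of the same direction;
#'   all half-conversion tracts share one strand distribution.
#' * `trans_canonical` — exactly two adjacent half-conversion tracts with the
#'   same global asymmetry but different strand distributions (`"X_X*"`) on
#'   one chromatid, as expected from double Holliday junction dissolution or
#'   double SDSA.
#' * `trans_complex` — the trans signature (two half-conversion
#'   distributions, same direction) plus interior patches.
#' * `other` — everything else: full-conversion-only patterns, terminal full
#'   conversions, aberrant symmetric heteroduplex, opposite asymmetry
#'   directions, or transfers on more than one chromatid.
#'
#' The trans rules are tested before the SDSA rules, making ties
#' deterministic; a full-conversion tract whose direction contradicts the
#' half-conversions routes to `other`.
#'
#' @param pattern Pattern string (octad grammar).
#' @param chromatid_distribution One of "none", "single", "two-non-sister",
#'   "two-sister", "multi", "unspecified".
#' @return Class label (character). Vectorised over both arguments.
#' @examples
#' classify_nco("3:5", "single")           # SDSA_canonical
#' classify_nco("3:5_4:4_3:5*", "single")  # trans_complex
#' @export
classify_nco <- function(pattern, chromatid_distribution = "single") {
  n <- max(length(pattern), length(chromatid_distribution))
  pattern <- rep_len(pattern, n)
  chromatid_distribution <- rep_len(chromatid_distribution, n)
  mapply(function(p, d) classify_nco_one(p, d), pattern, chromatid_distribution,
         USE.NAMES = FALSE)
}

classify_nco_one <- function(pattern, distribution) {
  if (identical(pattern, ">3")) return("other")
  tok <- parse_pattern(pattern, "octad")
  if (nrow(tok) == 0L) return("other")
  if (!identical(distribution, "single")) return("other")
  if (any(tok$aberrant)) return("other")
  halves <- which(tok$half)
  if (length(halves) == 0L) return("other")
  if (!tok$half[1L] || !tok$half[nrow(tok)]) return("other")
  dirs <- unique(tok$direction[tok$half])
  if (length(dirs) != 1L) return("other")
  if (any(tok$full) && any(tok$direction[tok$full] != dirs)) return("other")
  n_dist <- length(unique(tok$stars[tok$half]))
  if (n_dist == 2L) {
    if (nrow(tok) == 2L) "trans_canonical" else "trans_complex"
  } else if (n_dist == 1L) {
    if (nrow(tok) == 1L) "SDSA_canonical" else "SDSA_complex"
  } else {
    "other"
  }
}

#' Classify a crossover strand-transfer pattern
#'
#' Crossover-associated transfers are classed by where the heteroduplex lies:
#'
#' * `no_transfer` — pattern `"none"`.
#' * `single_chromatid` — all transfer tracts on one chromatid.
#' * `two_non_sister_DSBR_compatible` — transfers on the two non-sister
#'   recombining chromatids that do not overlap, the outcome of the canonical
#'   double-strand break repair model; flagged
#'   `two_non_sister_DSBR_asymmetric` when the longer/shorter heteroduplex
#'   length ratio reaches `asym_threshold`.
#' * `two_non_sister_other` — overlapping transfers on the two non-sisters
#'   (symmetric heteroduplex, aberrant 4:4*).
#' * `other` — two-sister or multi-chromatid distributions.
#'
#' When per-tract geometry is unavailable (e.g. for fixture rows) the
#' two-non-sister subdivision falls back to the pattern alone (aberrant 4:4*
#' tokens imply overlap) and no asymmetry flag is assigned.
#'
#' @param pattern Pattern string (octad grammar); the aggregate fixture token
#'   `">3"` is classed by its chromatid distribution alone.
#' @param chromatid_distribution See [classify_nco()].
#' @param geometry Optional tibble (`chromatid`, `start`, `end`) of transfer
#'   tract extents for overlap and asymmetry assessment.
#' @param asym_threshold Long/short heteroduplex length ratio at which a
#'   DSBR-compatible event is called asymmetric (default 3).
#' @return Class label (character).
#' @export
classify_co <- function(pattern, chromatid_distribution, geometry = NULL,
                        asym_threshold = 3) {
  if (length(pattern) > 1L && is.null(geometry)) {
    return(mapply(function(p, d) classify_co(p, d, NULL, asym_threshold),
                  pattern, rep_len(chromatid_distribution, length(pattern)),
                  USE.NAMES = FALSE))
  }
  if (identical(pattern, "none") || identical(chromatid_distribution, "none")) {
    return("no_transfer")
  }
  if (identical(chromatid_distribution, "single")) return("single_chromatid")
  if (!identical(chromatid_distribution, "two-non-sister")) return("other")
  aberrant <- if (identical(pattern, ">3")) FALSE else {
    any(parse_pattern(pattern, "octad")$aberrant)
  }
  if (aberrant) return("two_non_sister_other")
  if (is.null(geometry) || nrow(geometry) == 0L ||
      length(unique(geometry$chromatid)) != 2L) {
    return("two_non_sister_DSBR_compatible")
  }
  by_chr <- split(geometry, geometry$chromatid)
  ranges <- lapply(by_chr, function(g) c(min(g$start), max(g$end)))
  lens <- vapply(by_chr, function(g) sum(g$end - g$start), numeric(1))
  overlap <- ranges[[1L]][1L] < ranges[[2L]][2L] &&
    ranges[[2L]][1L] < ranges[[1L]][2L]
  if (overlap) return("two_non_sister_other")
  if (min(lens) > 0 && max(lens) / min(lens) >= asym_threshold) {
    "two_non_sister_DSBR_asymmetric"
  } else {
    "two_non_sister_DSBR_compatible"
  }
}

#' Classify called events
#'
#' Adds a `class` column to an event tibble (octad mode) using
#' [classify_nco()] and [classify_co()] with each event's pattern, chromatid
#' distribution summary and tract geometry.
#'
#' @param events Event tibble from [call_recombination_events()].
#' @param asym_threshold See [classify_co()].
#' @return The event tibble with a `class` column.
#' @export
classify_events <- function(events, asym_threshold = 3) {
  cls <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    cls[i] <- if (events$kind[i] == "CO") {
      classify_co(events$pattern[i], events$chromatid_summary[i],
                  events$geometry[[i]], asym_threshold)
    } else {
      classify_nco(events$pattern[i], events$chromatid_summary[i])
    }
  }
  events$class <- cls
  events
}
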