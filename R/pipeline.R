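#' Call crossover and non-crossover events genome-wide
#'
#' End-to-end caller: per chromosome, markers are classified into segregation
#' signatures ([call_marker_segregation()]), mitotic 4:0 runs and markers
#' with too many missing calls are excluded, signature runs are collapsed
#' into tracts ([segment_tracts()]), the parental phase is inferred
#' ([infer_parental_phase()]), and events are called, merged and classified
#' ([call_events()], [merge_events()], [classify_events()]).
#'
#' @param marker_map A [marker_map()] aligned with the genotype matrix.
#' @param genotypes A [genotype_calls()] object.
#' @param params [caller_params()].
#' @param classify Add mechanistic class labels (octad mode only).
#' @return A tibble with one row per event: `chrom`, `start`, `end` (outermost
#'   affected marker positions; the junction for transfer-less crossovers),
#'   `kind` ("CO"/"NCO"), `pattern`, `n_tracts`, `n_markers` (marker
#'   support), `length_bp` (summed midpoint patch lengths), `chromatids`,
#'   `chromatid_summary`, `exchange` (crossover chromatid pair),
#'   `junction_pos`, `class` (when classified), plus list columns
#'   `tract_rows` and `geometry`. The tibble carries its calling context and
#'   an exclusion log as attributes (`"context"`, `"log"`).
#' @export
call_recombination_events <- function(marker_map, genotypes,
                                      params = caller_params(),
                                      classify = TRUE) {
  stopifnot(inherits(genotypes, "meihdna_genotypes"))
  if (nrow(marker_map) != nrow(genotypes$calls)) {
    stop("marker map and genotype matrix are misaligned")
  }
  mode <- genotypes$mode
  logs <- character()
  per_chrom <- list()
  out <- list()
  for (ch in unique(marker_map$chrom)) {
    rows <- which(marker_map$chrom == ch)
    M <- genotypes$calls[rows, , drop = FALSE]
    pos <- marker_map$pos[rows]

    miss_frac <- rowMeans(is.na(M))
    if (any(miss_frac > 0)) {
      drop_n <- sum(miss_frac > params$max_missing)
      if (drop_n > 0L) {
        warning(drop_n, " marker(s) on ", ch,
                " dropped for missing calls above the tolerance")
      }
      logs <- c(logs, paste0(ch, ": ", sum(miss_frac > 0),
                             " marker(s) with missing calls excluded"))
    }
    cls <- classify_markers(M, mode)
    if (any(cls$mitotic)) {
      logs <- c(logs, paste0(ch, ": ", sum(cls$mitotic),
                             " marker(s) excluded as mitotic (4:0)"))
    }
    tracts <- segment_tracts(M, pos, mode)
    if (nrow(tracts) == 0L) next
    kept <- which(cls$callable & !cls$mitotic)
    kept_map <- rep(NA_integer_, length(pos))
    kept_map[kept] <- seq_along(kept)
    phase <- tryCatch(infer_parental_phase(tracts), error = function(e) e)
    if (inherits(phase, "error")) {
      logs <- c(logs, paste0(ch, ": ", conditionMessage(phase)))
      next
    }
    ev <- call_events(tracts, phase, positions = pos[kept],
                      kept_map = kept_map, mode = mode, params = params,
                      chrom = ch)
    disc <- attr(ev, "discarded")
    if (!is.null(disc) && nrow(disc)) {
      logs <- c(logs, paste0(ch, ": ", nrow(disc),
                             " single-marker event(s) discarded"))
    }
    per_chrom[[ch]] <- list(tracts = tracts, phase = phase,
                            positions = pos[kept], kept_map = kept_map)
    out[[ch]] <- ev
  }
  res <- if (length(out)) do.call(rbind, out) else empty_events()
  if (classify && mode == "octad" && nrow(res)) {
    res <- classify_events(res, asym_threshold = params$asym_threshold)
  } else {
    res$class <- rep(NA_character_, nrow(res))
  }
  attr(res, "context") <- list(per_chrom = per_chrom, mode = mode,
                               params = params)
  attr(res, "log") <- logs
  res
}

#' Per-chromosome event counts
#'
#' Convenience summary for the count-versus-size regression: CO and NCO
#' counts per chromosome, joined with chromosome sizes.
#'
#' @param events Event tibble.
#' @param chrom_sizes Named sizes (bp).
#' @return A tibble: `chrom`, `size`, `n_co`, `n_nco`.
#' @export
events_per_chromosome <- function(events, chrom_sizes) {
  chroms <- names(chrom_sizes)
  tibble::tibble(
    chrom = chroms,
    size = as.numeric(chrom_sizes),
    n_co = vapply(chroms, function(ch) {
      sum(events$chrom == ch & events$kind == "CO")
    }, numeric(1)),
    n_nco = vapply(chroms, function(ch) {
      sum(events$chrom == ch & events$kind == "NCO")
    }, numeric(1))
  )
}
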