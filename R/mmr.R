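#' Apply mismatch repair to a simulated meiosis
#'
#' Each heteroduplex tract — including transient invading-end heteroduplex
#' that is undetectable in the absence of mismatch repair — is independently
#' converted with probability `p_conv` (both strands take the newly
#' transferred allele) or restored (both strands take the chromatid's
#' original allele). The resulting chromatids are homoduplex and the spore
#' genotype equals the chromatid genotype, so a four-column tetrad genotype
#' table is emitted.
#'
#' @param strands A `meihdna_strands` object from [simulate_meiosis()]
#'   (pre-repair strand-level alleles).
#' @param truth The simulation truth log (for the heteroduplex tract list).
#' @param p_conv Conversion probability (default from the configuration).
#' @param seed Optional seed for the per-tract decisions.
#' @return A list: `genotypes` (tetrad [genotype_calls()]), `decisions`
#'   (tibble of per-tract convert/restore decisions), `strands` (repaired).
#' @export
apply_mmr <- function(strands, truth, p_conv = strands$config$p_conv,
                      seed = NULL) {
  stopifnot(inherits(strands, "meihdna_strands"))
  if (strands$config$mmr_mode == "msh2") {
    stop("apply_mmr: simulation was configured in msh2 (repair-deficient) mode")
  }
  if (!is.null(seed)) set.seed(seed)
  A <- strands$alleles
  mm <- strands$marker_map
  tr <- truth$tracts
  targets <- which(tr$state %in% c("hDNA", "transient_hDNA"))
  decisions <- tibble::tibble(
    event_id = tr$event_id[targets], chrom = tr$chrom[targets],
    chromatid = tr$chromatid[targets],
    start = tr$start[targets], end = tr$end[targets],
    state = tr$state[targets],
    decision = ifelse(stats::runif(length(targets)) < p_conv,
                      "convert", "restore")
  )
  for (i in seq_len(nrow(decisions))) {
    d <- decisions[i, ]
    allele <- tr$allele[targets[i]]
    value <- if (d$decision == "convert") allele else 1L - allele
    if (d$state == "transient_hDNA" && d$decision == "restore") next
    pos <- mm$pos[mm$chrom == d$chrom]
    cols <- which(pos >= d$start & pos <= d$end)
    if (!length(cols)) next
    rows <- c(2L * d$chromatid - 1L, 2L * d$chromatid)
    A[[d$chrom]][rows, cols] <- value
  }
  calls <- do.call(rbind, lapply(names(A), function(ch) {
    m <- A[[ch]]
    het <- m[c(1L, 3L, 5L, 7L), , drop = FALSE] !=
      m[c(2L, 4L, 6L, 8L), , drop = FALSE]
    if (any(het)) {
      stop("internal error: heteroduplex remains after mismatch repair")
    }
    t(m[c(1L, 3L, 5L, 7L), , drop = FALSE])
  }))
  repaired <- structure(list(alleles = A, marker_map = mm,
                             config = strands$config),
                        class = "meihdna_strands")
  list(genotypes = genotype_calls(calls, mode = "tetrad"),
       decisions = decisions, strands = repaired)
}

#' Split an octad into its two single-strand tetrads
#'
#' Compatibility helper reproducing the analysis route in which each octad is
#' arbitrarily divided into two tetrads (the four mother cells and the four
#' daughter cells) analysed independently.
#'
#' @param genotypes An octad [genotype_calls()] object.
#' @return A list of two tetrad `genotype_calls` objects (`mother`,
#'   `daughter`).
#' @export
octad_to_tetrads <- function(genotypes) {
  stopifnot(inherits(genotypes, "meihdna_genotypes"),
            genotypes$mode == "octad")
  list(
    mother = genotype_calls(genotypes$calls[, c(1L, 3L, 5L, 7L), drop = FALSE],
                            mode = "tetrad"),
    daughter = genotype_calls(genotypes$calls[, c(2L, 4L, 6L, 8L),
                                              drop = FALSE], mode = "tetrad")
  )
}

#' Compare called events against simulation truth
#'
#' Scores a called event table against the ground-truth log of the simulation
#' that produced the genotypes: a truth crossover is recovered when a called
#' crossover junction lies within `tol` bp of the true exchange point; a
#' truth non-crossover is recovered when a called non-crossover overlaps the
#' span of its written tracts. The denominator is restricted to recoverable
#' events: non-crossovers whose visible tracts cover at least `min_markers`
#' markers, and crossovers with at least one marker on each side of the
#' exchange point.
#'
#' @param sim A `meihdna_sim` object.
#' @param events Event tibble from [call_recombination_events()].
#' @param tol Junction position tolerance in bp (default 10000).
#' @param min_markers Marker-support threshold for the denominator
#'   (default 2).
#' @return A list: `n_truth`, `n_recovered`, `recovery` (fraction),
#'   `n_spurious` (called events matching no truth event), and a per-truth
#'   `detail` tibble.
#' @export
evaluate_recovery <- function(sim, events, tol = 10000, min_markers = 2L) {
  stopifnot(inherits(sim, "meihdna_sim"))
  tev <- sim$truth$events
  ttr <- sim$truth$tracts
  matched_called <- rep(FALSE, nrow(events))
  rows <- list()
  for (i in seq_len(nrow(tev))) {
    te <- tev[i, ]
    if (!te$outcome %in% c("CO", "NCO")) next
    vis <- ttr[ttr$event_id == te$event_id &
                 ttr$state %in% c("hDNA", "full_conversion"), , drop = FALSE]
    n_mark <- sum(vis$n_markers)
    if (te$outcome == "NCO") {
      eligible <- n_mark >= min_markers
      span <- if (nrow(vis)) c(min(vis$start), max(vis$end)) else c(te$pos, te$pos)
      hit <- events$chrom == te$chrom & events$kind == "NCO" &
        events$start <= span[2L] & events$end >= span[1L]
    } else {
      pos <- sim$marker_map$pos[sim$marker_map$chrom == te$chrom]
      eligible <- any(pos < te$pos) && any(pos > te$pos)
      hit <- events$chrom == te$chrom & events$kind == "CO" &
        !is.na(events$junction_pos) &
        abs(events$junction_pos - te$pos) <= tol
    }
    matched_called <- matched_called | hit
    rows[[length(rows) + 1L]] <- tibble::tibble(
      event_id = te$event_id, chrom = te$chrom, pos = te$pos,
      outcome = te$outcome, n_markers = n_mark,
      eligible = eligible, recovered = any(hit)
    )
  }
  detail <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(event_id = integer(), chrom = character(), pos = numeric(),
                   outcome = character(), n_markers = integer(),
                   eligible = logical(), recovered = logical())
  elig <- detail[detail$eligible, , drop = FALSE]
  list(
    n_truth = nrow(elig),
    n_recovered = sum(elig$recovered),
    recovery = if (nrow(elig)) sum(elig$recovered) / nrow(elig) else NA_real_,
    n_spurious = sum(!matched_called),
    detail = detail
  )
}
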