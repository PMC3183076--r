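#' Chromosome sizes of the S. cerevisiae reference genome
#'
#' Approximate sizes (bp) of the sixteen nuclear chromosomes, named
#' `chr01`..`chr16` so that lexicographic and karyotype order agree.
#'
#' @return Named integer vector of length 16.
#' @export
yeast_chrom_sizes <- function() {
  stats::setNames(
    c(230218L, 813184L, 316620L, 1531933L, 576874L, 270161L, 1090940L,
      562643L, 439888L, 745751L, 666816L, 1078177L, 924431L, 784333L,
      1091291L, 948066L),
    sprintf("chr%02d", 1:16)
  )
}

#' Simulation configuration
#'
#' Parameters of one simulated meiosis of a two-parent hybrid at strand
#' resolution. Defaults describe the study conditions: a marker roughly every
#' 194 bp, a Poisson mean of 160 double-strand breaks per meiosis spread over
#' the sixteen chromosomes in proportion to size, and a repair-pathway mix in
#' which crossovers and non-crossovers are near parity and, among
#' non-crossovers, simple SDSA and trans-heteroduplex pathways (double SDSA
#' and double Holliday junction dissolution) dominate.
#'
#' @param chrom_sizes Named vector of chromosome sizes (bp).
#' @param marker_spacing Mean inter-marker distance (bp).
#' @param dsb_mean Poisson mean number of DSBs per meiosis.
#' @param pathway_probs Named probabilities over the repair pathways
#'   `simple_SDSA`, `double_SDSA`, `dHJ_dissolution`, `dHJ_resolution_NCO`,
#'   `dHJ_resolution_CO`, `nicked_HJ_CO`; must sum to 1.
#' @param len_median_co,len_median_nco Median total heteroduplex length (bp)
#'   for crossover- and non-crossover-associated events (log-normal).
#' @param len_median_transient Median length of the transient invading-end
#'   heteroduplex of canonical SDSA, detectable only through mismatch repair.
#' @param len_sdlog Log-normal shape parameter for all tract lengths.
#' @param patch_median Median length (bp) of interior restoration patches
#'   (template switch, nick translation).
#' @param gap_median Median length (bp) of double-stranded gap conversions.
#' @param p_conv Probability that mismatch repair converts (rather than
#'   restores) a heteroduplex tract; used in `mmr_mode = "wt"`.
#' @param p_switch Per-event template-switch probability (interior
#'   restoration patch in SDSA-type events).
#' @param p_nick Probability that an unligated nick within a dissolved double
#'   Holliday junction triggers nick translation (central restoration patch).
#' @param p_dloop_erase Probability that D-loop migration completely erases
#'   the first-end heteroduplex at a crossover.
#' @param p_asym,asym_ratio Probability of, and long/short length ratio for,
#'   asymmetric heteroduplex positioning at DSBR crossovers.
#' @param p_gap Per-event probability of a double-stranded gap conversion.
#' @param p_branch Per-event probability of a junction branch-migration step
#'   writing symmetric heteroduplex (aberrant 4:4) over `branch_len` bp.
#' @param branch_len Length (bp) of the symmetric heteroduplex interval.
#' @param p_invert Probability that a crossover heteroduplex zone is inverted
#'   to the opposite asymmetry (nick translation plus junction migration).
#' @param p_sister Probability that a DSB is repaired invisibly from the
#'   sister chromatid (inter-homolog thinning).
#' @param mito_rate Poisson mean number of injected 4:0-segregating mitotic
#'   artifacts per meiosis.
#' @param excl_dist Minimum distance between DSBs on one chromosome; closer
#'   draws are re-drawn.
#' @param mmr_mode `"msh2"` (mismatch repair absent: octad output with
#'   heteroduplex visible) or `"wt"` (repair applied, tetrad output).
#' @param seed Integer seed; fully determines the simulation.
#' @param complications If `FALSE`, all optional pathway variants
#'   (`p_switch`, `p_nick`, `p_dloop_erase`, `p_asym`, `p_gap`, `p_branch`,
#'   `p_invert`, `mito_rate`) are zeroed, leaving the plain pathways of the
#'   canonical models.
#' @return A list of class `meihdna_sim_config`.
#' @export
sim_config <- function(chrom_sizes = yeast_chrom_sizes(),
                       marker_spacing = 194,
                       dsb_mean = 160,
                       pathway_probs = c(simple_SDSA = 0.22,
                                         double_SDSA = 0.09,
                                         dHJ_dissolution = 0.14,
                                         dHJ_resolution_NCO = 0.05,
                                         dHJ_resolution_CO = 0.40,
                                         nicked_HJ_CO = 0.10),
                       len_median_co = 1600,
                       len_median_nco = 1000,
                       len_median_transient = 800,
                       len_sdlog = 0.7,
                       patch_median = 400,
                       gap_median = 300,
                       p_conv = 0.8,
                       p_switch = 0.1,
                       p_nick = 0.5,
                       p_dloop_erase = 0.75,
                       p_asym = 0.68,
                       asym_ratio = 4,
                       p_gap = 0.1,
                       p_branch = 0.02,
                       branch_len = 260,
                       p_invert = 0,
                       p_sister = 0,
                       mito_rate = 0,
                       excl_dist = 10000,
                       mmr_mode = c("msh2", "wt"),
                       seed = NULL,
                       complications = TRUE) {
  mmr_mode <- match.arg(mmr_mode)
  if (!isTRUE(complications)) {
    p_switch <- p_nick <- p_dloop_erase <- p_asym <- p_gap <- p_branch <-
      p_invert <- mito_rate <- 0
  }
  need <- c("simple_SDSA", "double_SDSA", "dHJ_dissolution",
            "dHJ_resolution_NCO", "dHJ_resolution_CO", "nicked_HJ_CO")
  if (!all(need %in% names(pathway_probs))) {
    stop("pathway_probs must name all of: ", paste(need, collapse = ", "))
  }
  pathway_probs <- pathway_probs[need]
  if (any(pathway_probs < 0) || abs(sum(pathway_probs) - 1) > 1e-9) {
    stop("pathway probabilities must be non-negative and sum to 1")
  }
  if (is.null(names(chrom_sizes))) {
    names(chrom_sizes) <- sprintf("chr%02d", seq_along(chrom_sizes))
  }
  stopifnot(all(chrom_sizes > 0), marker_spacing > 0, dsb_mean >= 0,
            len_median_co > 0, len_median_nco > 0, len_median_transient > 0,
            len_sdlog > 0, patch_median > 0, gap_median > 0, branch_len > 0,
            excl_dist >= 0)
  probs <- c(p_conv = p_conv, p_switch = p_switch, p_nick = p_nick,
             p_dloop_erase = p_dloop_erase, p_asym = p_asym, p_gap = p_gap,
             p_branch = p_branch, p_invert = p_invert, p_sister = p_sister)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(
    chrom_sizes = chrom_sizes, marker_spacing = marker_spacing,
    dsb_mean = dsb_mean, pathway_probs = pathway_probs,
    len_median_co = len_median_co, len_median_nco = len_median_nco,
    len_median_transient = len_median_transient, len_sdlog = len_sdlog,
    patch_median = patch_median, gap_median = gap_median, p_conv = p_conv,
    p_switch = p_switch, p_nick = p_nick, p_dloop_erase = p_dloop_erase,
    p_asym = p_asym, asym_ratio = asym_ratio, p_gap = p_gap,
    p_branch = p_branch, branch_len = branch_len, p_invert = p_invert,
    p_sister = p_sister, mito_rate = mito_rate, excl_dist = excl_dist,
    mmr_mode = mmr_mode, seed = seed
  ), class = "meihdna_sim_config")
}

#' Generate a marker map with the configured density
#'
#' Inter-marker gaps are drawn from a geometric distribution with the
#' configured mean spacing (positive, memoryless spacing as for roughly
#' uniformly scattered polymorphisms), giving strictly increasing positions
#' on every chromosome.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed (defaults to the config's).
#' @return A [marker_map()] tibble.
#' @export
make_marker_map <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  if (any(config$marker_spacing >= config$chrom_sizes)) {
    stop("degenerate map: mean marker spacing ", config$marker_spacing,
         " is not below the smallest chromosome size")
  }
  res <- lapply(names(config$chrom_sizes), function(ch) {
    size <- config$chrom_sizes[[ch]]
    p <- 1 / config$marker_spacing
    pos <- integer()
    at <- 0
    repeat {
      k <- max(16L, ceiling((size - at) / config$marker_spacing * 1.5))
      gaps <- stats::rgeom(k, p) + 1L
      new <- at + cumsum(gaps)
      pos <- c(pos, new[new <= size])
      at <- new[length(new)]
      if (at > size) break
    }
    if (length(pos) == 0L) pos <- as.integer(ceiling(size / 2))
    data.frame(chrom = ch, pos = pos)
  })
  res <- do.call(rbind, res)
  marker_map(chrom = res$chrom, pos = res$pos)
}
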