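#' Simulate one meiosis at strand resolution
#'
#' Four chromatids are initialised as two replicated copies of each parental
#' haplotype, each carrying two strands (the information that will separate
#' into the mother and daughter cell at the first mitotic division of the
#' spore). Double-strand breaks are placed along the chromosomes and repaired
#' by a pathway drawn from the configured mix, writing strand states:
#'
#' * simple SDSA — one heteroduplex tract on one strand of the broken
#'   chromatid, on one side of the break;
#' * double SDSA and dHJ dissolution — two adjacent heteroduplex tracts on
#'   opposite strands of the broken chromatid (trans configuration), flanking
#'   the break, dissolution optionally inserting a central restoration patch
#'   through nick translation;
#' * dHJ resolution — heteroduplex on the two non-sister chromatids on
#'   opposite sides of the break (with the invasion-side segment of the
#'   broken chromatid locally converted), the crossover variants additionally
#'   exchanging the distal arms at the resolution point;
#' * optional variants — D-loop migration erasing the first-end heteroduplex,
#'   template switches and nick translation writing interior restoration
#'   patches, double-stranded gap conversions, asymmetric DSBR heteroduplex
#'   lengths, junction branch migration writing symmetric heteroduplex
#'   (aberrant 4:4), inversion of a crossover heteroduplex to the opposite
#'   asymmetry, and injected 4:0-segregating mitotic artifacts.
#'
#' In `mmr_mode = "wt"` mismatch repair is applied ([apply_mmr()]) and
#' four-spore tetrad genotypes are emitted; in `"msh2"` mode the eight
#' mother/daughter cell genotypes (octad) are emitted with heteroduplex
#' visible as 5:3 segregation.
#'
#' @param config A [sim_config()].
#' @param markers Optional [marker_map()]; generated from the config if
#'   missing.
#' @param seed Seed (defaults to the config's); fully determines the output.
#' @return A list of class `meihdna_sim`: `genotypes` ([genotype_calls()],
#'   octad or tetrad), `marker_map`, `truth` (ground-truth log: `events` and
#'   `tracts` tibbles, plus `mmr` decisions in wt mode), `strands` (the
#'   pre-repair strand-level allele matrices, 8 x markers per chromosome),
#'   and `config`.
#' @export
simulate_meiosis <- function(config, markers = NULL, seed = config$seed) {
  stopifnot(inherits(config, "meihdna_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(markers)) markers <- make_marker_map(config, seed = NULL)

  chroms <- names(config$chrom_sizes)
  pos_by_chrom <- lapply(chroms, function(ch) markers$pos[markers$chrom == ch])
  names(pos_by_chrom) <- chroms
  # strand rows: chromatid k occupies rows 2k-1 (mother strand), 2k
  # (daughter strand); chromatids 1,2 start as parent 1 (allele 1)
  strands <- lapply(pos_by_chrom, function(p) {
    matrix(rep(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), length(p)), nrow = 8L)
  })
  names(strands) <- chroms

  truth_events <- list()
  truth_tracts <- list()
  log <- character()

  # --- DSB placement ------------------------------------------------------
  n_dsb <- stats::rpois(1L, config$dsb_mean)
  dsb <- NULL
  if (n_dsb > 0L) {
    ch_idx <- sample(seq_along(chroms), n_dsb, replace = TRUE,
                     prob = config$chrom_sizes)
    dsb <- data.frame(chrom = chroms[ch_idx],
                      pos = numeric(n_dsb), stringsAsFactors = FALSE)
    for (ch in unique(dsb$chrom)) {
      rows <- which(dsb$chrom == ch)
      size <- config$chrom_sizes[[ch]]
      pos <- round(stats::runif(length(rows), 1, size))
      for (attempt in seq_len(50L)) {
        pos <- sort(pos)
        bad <- which(diff(pos) < config$excl_dist)
        if (length(bad) == 0L) break
        pos[bad + 1L] <- round(stats::runif(length(bad), 1, size))
        if (attempt == 50L) {
          log <- c(log, paste0("dropped ", length(bad), " DSB(s) on ", ch,
                               " closer than the exclusion distance"))
          pos <- pos[-(bad + 1L)]
        }
      }
      dsb$pos[rows[seq_along(pos)]] <- pos
      if (length(pos) < length(rows)) dsb <- dsb[-rows[-seq_along(pos)], ]
    }
    dsb <- dsb[order(dsb$chrom, dsb$pos), , drop = FALSE]
  }

  event_id <- 0L
  for (i in seq_len(NROW(dsb))) {
    ch <- dsb$chrom[i]
    x <- dsb$pos[i]
    event_id <- event_id + 1L
    ev <- simulate_one_event(strands[[ch]], pos_by_chrom[[ch]], x,
                             config$chrom_sizes[[ch]], config)
    strands[[ch]] <- ev$A
    truth_events[[event_id]] <- tibble::tibble(
      event_id = event_id, chrom = ch, pos = x,
      broken = ev$broken, donor = ev$donor,
      pathway = ev$pathway, outcome = ev$outcome
    )
    if (length(ev$tracts)) {
      tr <- do.call(rbind, ev$tracts)
      tr$event_id <- event_id
      tr$chrom <- ch
      truth_tracts[[event_id]] <- tr
    }
  }

  # --- mitotic artifacts --------------------------------------------------
  n_mito <- if (config$mito_rate > 0) stats::rpois(1L, config$mito_rate) else 0L
  for (k in seq_len(n_mito)) {
    ch <- sample(chroms, 1L, prob = config$chrom_sizes)
    size <- config$chrom_sizes[[ch]]
    x <- round(stats::runif(1L, 1, size))
    L <- rlnorm_len(config$len_median_nco, config$len_sdlog)
    allele <- sample(0:1, 1L)
    cols <- which(pos_by_chrom[[ch]] >= x & pos_by_chrom[[ch]] <= x + L)
    if (length(cols)) strands[[ch]][, cols] <- allele
    event_id <- event_id + 1L
    truth_events[[event_id]] <- tibble::tibble(
      event_id = event_id, chrom = ch, pos = x, broken = NA_integer_,
      donor = NA_integer_, pathway = "mitotic_artifact", outcome = "mitotic"
    )
  }

  truth <- list(
    events = if (length(truth_events)) do.call(rbind, truth_events) else
      tibble::tibble(event_id = integer(), chrom = character(),
                     pos = numeric(), broken = integer(), donor = integer(),
                     pathway = character(), outcome = character()),
    tracts = if (length(truth_tracts)) {
      tibble::as_tibble(do.call(rbind, truth_tracts))
    } else {
      tibble::tibble(chromatid = integer(), strand = integer(),
                     start = numeric(), end = numeric(), allele = integer(),
                     state = character(), n_markers = integer(),
                     event_id = integer(), chrom = character())
    },
    log = log
  )

  strand_obj <- structure(list(alleles = strands, marker_map = markers,
                               config = config),
                          class = "meihdna_strands")
  if (config$mmr_mode == "wt") {
    mm <- apply_mmr(strand_obj, truth, p_conv = config$p_conv, seed = NULL)
    truth$mmr <- mm$decisions
    genotypes <- mm$genotypes
  } else {
    calls <- do.call(rbind, lapply(chroms, function(ch) t(strands[[ch]])))
    genotypes <- genotype_calls(calls, mode = "octad")
  }
  structure(list(genotypes = genotypes, marker_map = markers, truth = truth,
                 strands = strand_obj, config = config),
            class = "meihdna_sim")
}

#' @export
print.meihdna_sim <- function(x, ...) {
  cat("<meihdna_sim> ", nrow(x$truth$events), " events (",
      sum(x$truth$events$outcome == "CO"), " CO, ",
      sum(x$truth$events$outcome == "NCO"), " NCO) over ",
      length(unique(x$marker_map$chrom)), " chromosome(s), ",
      nrow(x$marker_map), " markers, mode ", x$config$mmr_mode, "\n", sep = "")
  invisible(x)
}

rlnorm_len <- function(median, sdlog, min_len = 50) {
  max(min_len, round(stats::rlnorm(1L, log(median), sdlog)))
}

interval_minus <- function(iv, cut) {
  # iv, cut: c(start, end); returns list of leftover sub-intervals
  out <- list()
  if (cut[2L] < iv[1L] || cut[1L] > iv[2L]) return(list(iv))
  if (iv[1L] < cut[1L]) out <- c(out, list(c(iv[1L], cut[1L] - 1)))
  if (iv[2L] > cut[2L]) out <- c(out, list(c(cut[1L] + (cut[2L] - cut[1L]) + 1, iv[2L])))
  out
}

# one repair event; returns updated strand matrix plus truth records
simulate_one_event <- function(A, positions, x, size, cfg) {
  nearest <- if (length(positions)) which.min(abs(positions - x)) else NA_integer_
  broken <- sample(1:4, 1L)
  res <- list(A = A, broken = broken, donor = NA_integer_,
              pathway = NA_character_, outcome = "invisible", tracts = list())
  if (is.na(nearest)) return(res)
  local_allele <- function(k) A[2L * k - 1L, nearest]
  pB <- local_allele(broken)
  candidates <- if (broken <= 2L) 3:4 else 1:2
  candidates <- candidates[vapply(candidates, local_allele, 0L) != pB]
  if (stats::runif(1L) < cfg$p_sister || length(candidates) == 0L) {
    res$pathway <- "sister_or_homozygous"
    return(res)
  }
  donor <- if (length(candidates) == 1L) candidates else sample(candidates, 1L)
  pD <- local_allele(donor)
  pathway <- sample(names(cfg$pathway_probs), 1L, prob = cfg$pathway_probs)
  res$donor <- donor
  res$pathway <- pathway

  instr <- list()      # each: chromatid, strand (0 = both), start, end,
                       # allele, state
  add <- function(chromatid, strand, iv, allele, state) {
    if (iv[2L] < iv[1L]) return(invisible(NULL))
    instr[[length(instr) + 1L]] <<- list(
      chromatid = chromatid, strand = strand,
      start = max(1, iv[1L]), end = min(size, iv[2L]),
      allele = allele, state = state)
    invisible(NULL)
  }
  swap_at <- NULL
  outcome <- "NCO"

  split_len <- function(total, asym = FALSE) {
    if (asym && stats::runif(1L) < cfg$p_asym) {
      short <- max(50, round(total / (1 + cfg$asym_ratio)))
    } else {
      short <- max(50, round(total * stats::runif(1L, 0.35, 0.5)))
    }
    long <- max(50, total - short)
    if (stats::runif(1L) < 0.5) c(short, long) else c(long, short)
  }

  if (pathway == "simple_SDSA") {
    L <- rlnorm_len(cfg$len_median_nco, cfg$len_sdlog)
    side <- sample(c(-1L, 1L), 1L)
    iv <- if (side > 0L) c(x + 1, x + L) else c(x - L, x)
    s <- sample(1:2, 1L)
    if (stats::runif(1L) < cfg$p_switch && L >= 400) {
      Lp <- min(rlnorm_len(cfg$patch_median, cfg$len_sdlog), floor(L / 3))
      pc <- round(stats::runif(1L, iv[1L] + L / 4, iv[2L] - L / 4))
      patch <- c(pc - floor(Lp / 2), pc + ceiling(Lp / 2) - 1)
      for (piece in interval_minus(iv, patch)) add(broken, s, piece, pD, "hDNA")
      add(broken, 0L, patch, NA_integer_, "restoration_patch")
    } else {
      add(broken, s, iv, pD, "hDNA")
    }
    Lt <- rlnorm_len(cfg$len_median_transient, cfg$len_sdlog)
    ivt <- if (side > 0L) c(x - Lt, x) else c(x + 1, x + Lt)
    add(broken, 0L, ivt, pD, "transient_hDNA")
  } else if (pathway %in% c("double_SDSA", "dHJ_dissolution")) {
    L <- rlnorm_len(cfg$len_median_nco, cfg$len_sdlog)
    halves <- split_len(L)
    iv1 <- c(x - halves[1L] + 1, x)
    iv2 <- c(x + 1, x + halves[2L])
    s <- sample(1:2, 1L)
    p_patch <- if (pathway == "dHJ_dissolution") cfg$p_nick else cfg$p_switch
    if (stats::runif(1L) < p_patch) {
      Lp <- rlnorm_len(cfg$patch_median, cfg$len_sdlog)
      patch <- c(x - floor(Lp / 2) + 1, x + ceiling(Lp / 2))
      for (piece in interval_minus(iv1, patch)) add(broken, s, piece, pD, "hDNA")
      for (piece in interval_minus(iv2, patch)) {
        add(broken, 3L - s, piece, pD, "hDNA")
      }
      add(broken, 0L, patch, NA_integer_, "restoration_patch")
    } else {
      add(broken, s, iv1, pD, "hDNA")
      add(broken, 3L - s, iv2, pD, "hDNA")
    }
  } else if (pathway == "dHJ_resolution_NCO") {
    L <- rlnorm_len(cfg$len_median_nco, cfg$len_sdlog)
    halves <- split_len(L)
    inv_left <- stats::runif(1L) < 0.5
    iv_inv <- if (inv_left) c(x - halves[1L] + 1, x) else c(x + 1, x + halves[1L])
    iv_cap <- if (inv_left) c(x + 1, x + halves[2L]) else c(x - halves[2L] + 1, x)
    # invasion zone: broken chromatid locally converted, heteroduplex on the
    # donor; capture zone: heteroduplex on the broken chromatid
    add(broken, 0L, iv_inv, pD, "full_conversion")
    add(donor, sample(1:2, 1L), iv_inv, pB, "hDNA")
    add(broken, sample(1:2, 1L), iv_cap, pD, "hDNA")
  } else {  # dHJ_resolution_CO or nicked_HJ_CO
    outcome <- "CO"
    swap_at <- x
    L <- rlnorm_len(cfg$len_median_co, cfg$len_sdlog)
    halves <- split_len(L, asym = TRUE)
    if (pathway == "dHJ_resolution_CO" && stats::runif(1L) < cfg$p_dloop_erase) {
      halves[sample(1:2, 1L)] <- 0
    }
    iv1 <- c(x - halves[1L] + 1, x)
    iv2 <- c(x + 1, x + halves[2L])
    # after the arm exchange the left zone heteroduplex sits on the broken
    # chromatid, the right zone heteroduplex on the donor
    if (halves[1L] > 0) {
      if (stats::runif(1L) < cfg$p_invert) {
        add(donor, sample(1:2, 1L), iv1, pB, "hDNA")
      } else {
        add(broken, sample(1:2, 1L), iv1, pD, "hDNA")
      }
    }
    if (halves[2L] > 0) {
      if (stats::runif(1L) < cfg$p_invert) {
        add(broken, sample(1:2, 1L), iv2, pB, "hDNA")
      } else {
        add(donor, sample(1:2, 1L), iv2, pD, "hDNA")
      }
    }
  }

  # double-stranded gap conversion at the break
  if (stats::runif(1L) < cfg$p_gap) {
    Lg <- rlnorm_len(cfg$gap_median, cfg$len_sdlog)
    gl <- c(x - floor(Lg / 2) + 1, x)
    gr <- c(x + 1, x + ceiling(Lg / 2))
    instr <- trim_instructions(instr, c(gl[1L], gr[2L]))
    if (is.null(swap_at)) {
      add(broken, 0L, c(gl[1L], gr[2L]), pD, "full_conversion")
    } else {
      add(broken, 0L, gl, pD, "full_conversion")
      add(donor, 0L, gr, pD, "full_conversion")
    }
  }

  # junction branch migration: symmetric heteroduplex beyond the event
  if (stats::runif(1L) < cfg$p_branch) {
    bm <- c(x + 1, x + cfg$branch_len)
    maxe <- max(vapply(instr, function(i) i$end, numeric(1)), x)
    bm <- bm + (maxe - x)
    if (is.null(swap_at)) {
      add(broken, sample(1:2, 1L), bm, pD, "hDNA")
      add(donor, sample(1:2, 1L), bm, pB, "hDNA")
    } else {
      add(broken, sample(1:2, 1L), bm, pB, "hDNA")
      add(donor, sample(1:2, 1L), bm, pD, "hDNA")
    }
  }

  # --- apply --------------------------------------------------------------
  if (!is.null(swap_at)) {
    cols <- which(positions > swap_at)
    if (length(cols)) {
      rb <- c(2L * broken - 1L, 2L * broken)
      rd <- c(2L * donor - 1L, 2L * donor)
      tmp <- A[rb, cols, drop = FALSE]
      A[rb, cols] <- A[rd, cols, drop = FALSE]
      A[rd, cols] <- tmp
    }
  }
  tracts <- list()
  visible <- FALSE
  for (ins in instr) {
    cols <- which(positions >= ins$start & positions <= ins$end)
    if (ins$state %in% c("hDNA", "full_conversion") && length(cols)) {
      rows <- if (ins$strand == 0L) {
        c(2L * ins$chromatid - 1L, 2L * ins$chromatid)
      } else {
        2L * ins$chromatid - 2L + ins$strand
      }
      A[rows, cols] <- ins$allele
      visible <- TRUE
    }
    tracts[[length(tracts) + 1L]] <- data.frame(
      chromatid = ins$chromatid, strand = ins$strand,
      start = ins$start, end = ins$end, allele = ins$allele,
      state = ins$state, n_markers = length(cols)
    )
  }
  res$A <- A
  res$outcome <- if (outcome == "CO") "CO" else if (visible) "NCO" else "invisible"
  if (outcome == "CO") res$exchange <- c(broken, donor)
  res$tracts <- tracts
  res
}

trim_instructions <- function(instr, cut) {
  out <- list()
  for (ins in instr) {
    if (ins$state == "restoration_patch") {
      out[[length(out) + 1L]] <- ins
      next
    }
    pieces <- interval_minus(c(ins$start, ins$end), cut)
    for (p in pieces) {
      ins2 <- ins
      ins2$start <- p[1L]
      ins2$end <- p[2L]
      out[[length(out) + 1L]] <- ins2
    }
  }
  out
}
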