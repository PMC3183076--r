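#' Caller parameters
#'
#' Tunable thresholds for event calling: `merge_threshold` (bp; events whose
#' outermost affected markers lie closer than this are treated as products of
#' one initiating break and combined, default 5000), `min_support` (minimum
#' number of supporting markers for a non-crossover; single-marker
#' conversions are discarded as unreliable, default 2), `asym_threshold`
#' (long/short heteroduplex length ratio above which a two-chromatid
#' DSBR-compatible crossover is flagged asymmetric, default 3), and
#' `max_missing` (tolerated fraction of missing calls per marker before the
#' marker is dropped with a warning, default 0).
#'
#' @param merge_threshold,min_support,asym_threshold,max_missing See above.
#' @return A list of parameters.
#' @export
caller_params <- function(merge_threshold = 5000, min_support = 2L,
                          asym_threshold = 3, max_missing = 0) {
  stopifnot(merge_threshold >= 0, min_support >= 1L,
            asym_threshold >= 1, max_missing >= 0, max_missing <= 1)
  list(merge_threshold = merge_threshold, min_support = as.integer(min_support),
       asym_threshold = asym_threshold, max_missing = max_missing)
}

#' Infer the parental phase along a chromosome
#'
#' In the absence of recombination all markers of a chromosome show one
#' continuous Mendelian segregation: each chromatid carries one parental
#' haplotype. Crossovers lie between consecutive regions with different
#' Mendelian phase. This function reads the background (Mendelian) tracts of
#' a segmented chromosome and returns the piecewise-constant
#' chromatid-to-parent assignment together with the junctions where it
#' changes.
#'
#' @param tracts Tract tibble from [segment_tracts()] for one chromosome.
#' @return A list with `segments` (one row per constant-phase stretch:
#'   `phase_key` is the chromatid-level allele string, plus the first/last
#'   background tract rows) and `junctions` (one row per phase change:
#'   flanking background tract rows and marker positions, the junction
#'   midpoint `pos`, the list of `changed` chromatids, and whether the change
#'   is a `reciprocal` two-chromatid exchange).
#' @export
infer_parental_phase <- function(tracts) {
  bg <- which(tracts$bg)
  if (length(bg) == 0L) {
    stop("phase-undefined: no Mendelian background tract on this chromosome")
  }
  keys <- tracts$phase_key[bg]
  r <- rle(keys)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segments <- tibble::tibble(
    phase_key = r$values,
    first_bg_row = bg[starts],
    last_bg_row = bg[ends]
  )
  if (length(r$values) > 1L) {
    li <- bg[ends[-length(ends)]]
    ri <- bg[starts[-1L]]
    changed <- mapply(function(l, rr) {
      which(strsplit(tracts$phase_key[l], "")[[1]] !=
            strsplit(tracts$phase_key[rr], "")[[1]])
    }, li, ri, SIMPLIFY = FALSE)
    junctions <- tibble::tibble(
      left_bg_row = li, right_bg_row = ri,
      left_pos = tracts$last_pos[li], right_pos = tracts$first_pos[ri],
      pos = (tracts$last_pos[li] + tracts$first_pos[ri]) / 2,
      changed = changed,
      reciprocal = lengths(changed) == 2L
    )
  } else {
    junctions <- tibble::tibble(
      left_bg_row = integer(), right_bg_row = integer(),
      left_pos = integer(), right_pos = integer(), pos = numeric(),
      changed = list(), reciprocal = logical()
    )
  }
  list(segments = segments, junctions = junctions)
}

#' Midpoint tract-length estimate
#'
#' Tract lengths are estimated from the midpoints of the inter-marker
#' intervals flanking the tract: from the midpoint between the last Mendelian
#' marker on the left and the first tract marker, to the midpoint between the
#' last tract marker and the next marker on the right. At a chromosome end
#' with no flanking marker the estimate falls back to the terminal tract
#' marker position.
#'
#' @param first_idx,last_idx Indices (into `positions`) of the first and last
#'   tract marker.
#' @param positions Sorted marker positions (bp) of the chromosome (callable
#'   markers only).
#' @return Estimated tract length in bp.
#' @examples
#' estimate_tract_length(2, 3, c(900, 1000, 2000, 2100))  # 1100
#' @export
estimate_tract_length <- function(first_idx, last_idx, positions) {
  stopifnot(first_idx >= 1L, last_idx >= first_idx,
            last_idx <= length(positions))
  left <- if (first_idx > 1L) {
    (positions[first_idx - 1L] + positions[first_idx]) / 2
  } else {
    positions[first_idx]
  }
  right <- if (last_idx < length(positions)) {
    (positions[last_idx] + positions[last_idx + 1L]) / 2
  } else {
    positions[last_idx]
  }
  right - left
}

# chromatid-level view of a signature key: hom alleles (NA if heteroduplex)
chromatid_alleles <- function(key, mode) {
  v <- as.integer(strsplit(key, "")[[1]])
  if (mode == "octad") {
    mo <- v[c(1L, 3L, 5L, 7L)]
    da <- v[c(2L, 4L, 6L, 8L)]
    hom <- ifelse(mo == da, mo, NA_integer_)
  } else {
    hom <- v
  }
  hom
}

# chromatids involved in a non-background tract, given a reference phase key
involved_chromatids <- function(key, phase_ref, mode) {
  hom <- chromatid_alleles(key, mode)
  het <- which(is.na(hom))
  conv <- integer()
  if (!is.na(phase_ref)) {
    ref <- as.integer(strsplit(phase_ref, "")[[1]])
    conv <- which(!is.na(hom) & hom != ref)
  }
  sort(unique(c(het, conv)))
}

summarize_chromatids <- function(chromatids, phase_ref) {
  n <- length(chromatids)
  if (n == 0L) return("none")
  if (n == 1L) return("single")
  if (n > 2L) return("multi")
  if (is.na(phase_ref)) return("unspecified")
  ref <- as.integer(strsplit(phase_ref, "")[[1]])
  if (ref[chromatids[1L]] == ref[chromatids[2L]]) "two-sister" else "two-non-sister"
}

#' Render the pattern string of an ordered tract list
#'
#' Builds the token string for one event from its ordered tracts: tokens
#' `a:b` (parent-1 count first) joined by underscores. Within the event the
#' first distinct signature per ratio class is unstarred and each subsequent
#' distinct signature gains a star; aberrant balanced tracts render `"4:4*"`;
#' interior Mendelian patches render `"4:4"` (octad) or `"2:2"` (tetrad),
#' starred when their chromatid phase differs from the event's flanking
#' background phase.
#'
#' @param event_tracts Tract tibble rows (ordered by position) spanning the
#'   event, as produced by [segment_tracts()]; interior background tracts
#'   included.
#' @param mode `"octad"` or `"tetrad"`.
#' @param flank_keys Phase keys of the background tracts flanking the event
#'   (character vector, `NA` allowed).
#' @return The pattern string; `"none"` for an empty tract list.
#' @export
pattern_string <- function(event_tracts, mode = c("octad", "tetrad"),
                           flank_keys = character()) {
  mode <- match.arg(mode)
  if (is.null(event_tracts) || nrow(event_tracts) == 0L) return("none")
  mend_tok <- if (mode == "octad") "4:4" else "2:2"
  star_maps <- list()    # base token -> character vector of seen keys
  tokens <- character(nrow(event_tracts))
  for (i in seq_len(nrow(event_tracts))) {
    tr <- event_tracts[i, ]
    if (tr$bg) {
      plain <- !is.na(tr$phase_key) &&
        tr$phase_key %in% flank_keys[!is.na(flank_keys)]
      if (plain) {
        tokens[i] <- mend_tok
        next
      }
      base <- mend_tok
      star_base <- 1L   # a Mendelian patch off the flanking phase is starred
    } else if (tr$aberrant) {
      base <- "4:4"
      star_base <- 1L
    } else {
      base <- paste0(tr$a, ":", tr$b)
      star_base <- 0L
    }
    seen <- star_maps[[base]]
    pos <- match(tr$key, seen)
    if (is.na(pos)) {
      star_maps[[base]] <- c(seen, tr$key)
      pos <- length(star_maps[[base]])
    }
    tokens[i] <- paste0(base, strrep("*", star_base + pos - 1L))
  }
  paste(tokens, collapse = "_")
}

# --- event assembly -------------------------------------------------------

# initial (unmerged) events: one per phase junction (absorbing the tracts
# between its flanking background tracts) plus one per remaining cluster of
# consecutive non-background tracts
build_initial_events <- function(tracts, phase) {
  nonbg <- which(!tracts$bg)
  clusters <- list()
  if (length(nonbg)) {
    br <- c(0L, which(diff(nonbg) > 1L), length(nonbg))
    clusters <- lapply(seq_len(length(br) - 1L), function(i) {
      nonbg[(br[i] + 1L):br[i + 1L]]
    })
  }
  events <- list()
  used <- logical(length(clusters))
  jn <- phase$junctions
  for (j in seq_len(nrow(jn))) {
    rows <- integer()
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      if (cl[1L] > jn$left_bg_row[j] && cl[length(cl)] < jn$right_bg_row[j]) {
        rows <- cl
        used[ci] <- TRUE
      }
    }
    events[[length(events) + 1L]] <- list(rows = rows, junction_ids = j)
  }
  for (ci in seq_along(clusters)) {
    if (!used[ci]) {
      events[[length(events) + 1L]] <-
        list(rows = clusters[[ci]], junction_ids = integer())
    }
  }
  events
}

event_span <- function(ev, tracts, phase) {
  if (length(ev$rows)) {
    c(min(tracts$first_pos[ev$rows]), max(tracts$last_pos[ev$rows]))
  } else {
    p <- phase$junctions$pos[ev$junction_ids[1L]]
    c(p, p)
  }
}

# pattern row range: non-background tract rows plus, for each junction, the
# interval strictly between its flanking background tracts
event_pattern_rows <- function(ev, phase) {
  anchors <- as.numeric(ev$rows)
  for (j in ev$junction_ids) {
    anchors <- c(anchors, phase$junctions$left_bg_row[j] + 0.5,
                 phase$junctions$right_bg_row[j] - 0.5)
  }
  lo <- ceiling(min(anchors))
  hi <- floor(max(anchors))
  if (hi < lo) integer() else lo:hi
}

event_chromatids <- function(ev, tracts, phase, mode) {
  rows <- ev$rows
  out <- integer()
  for (r in rows) {
    ref <- tract_ref_key(r, tracts, mode)
    out <- c(out, involved_chromatids(tracts$key[r], ref, mode))
  }
  for (j in ev$junction_ids) {
    out <- c(out, phase$junctions$changed[[j]])
  }
  sort(unique(out))
}

# reference phase for a non-background tract: the nearest flanking background
# phase; when the two flanks disagree (the tract sits at a crossover
# junction) the side implying the fewer changed chromatids is chosen, ties
# going left
tract_ref_key <- function(row, tracts, mode) {
  n <- nrow(tracts)
  bg_before <- which(tracts$bg[seq_len(row - 1L)])
  left <- if (length(bg_before)) tracts$phase_key[max(bg_before)] else
    NA_character_
  bg_after <- if (row < n) row + which(tracts$bg[(row + 1L):n]) else integer()
  right <- if (length(bg_after)) tracts$phase_key[min(bg_after)] else
    NA_character_
  if (is.na(left)) return(right)
  if (is.na(right) || identical(left, right)) return(left)
  iL <- involved_chromatids(tracts$key[row], left, mode)
  iR <- involved_chromatids(tracts$key[row], right, mode)
  if (length(iR) < length(iL)) right else left
}

merge_event_list <- function(events, tracts, phase, mode, threshold) {
  if (length(events) < 2L) return(events)
  spans <- t(vapply(events, event_span, numeric(2), tracts = tracts,
                    phase = phase))
  ord <- order(spans[, 1L])
  events <- events[ord]
  spans <- spans[ord, , drop = FALSE]
  kinds <- vapply(events, function(e) length(e$junction_ids) > 0L, logical(1))
  chroms <- lapply(events, event_chromatids, tracts = tracts, phase = phase,
                   mode = mode)
  i <- 1L
  while (i < length(events)) {
    gap <- spans[i + 1L, 1L] - spans[i, 2L]
    co_nco_pair <- xor(kinds[i], kinds[i + 1L])
    exempt <- co_nco_pair && {
      co <- if (kinds[i]) i else i + 1L
      nco <- if (kinds[i]) i + 1L else i
      length(intersect(chroms[[co]], chroms[[nco]])) == 0L
    }
    if (gap < threshold && !exempt) {
      merged <- list(
        rows = sort(unique(c(events[[i]]$rows, events[[i + 1L]]$rows))),
        junction_ids = sort(unique(c(events[[i]]$junction_ids,
                                     events[[i + 1L]]$junction_ids)))
      )
      events[[i]] <- merged
      spans[i, ] <- event_span(merged, tracts, phase)
      kinds[i] <- kinds[i] || kinds[i + 1L]
      chroms[[i]] <- sort(unique(c(chroms[[i]], chroms[[i + 1L]])))
      events <- events[-(i + 1L)]
      spans <- spans[-(i + 1L), , drop = FALSE]
      kinds <- kinds[-(i + 1L)]
      chroms <- chroms[-(i + 1L)]
    } else {
      i <- i + 1L
    }
  }
  events
}

finalize_events <- function(events, tracts, phase, positions, kept_map, mode,
                            params, chrom) {
  out <- lapply(events, function(ev) {
    rows <- event_pattern_rows(ev, phase)
    nonbg_rows <- rows[!tracts$bg[rows]]
    # flanking background references
    left_bg <- if (length(rows)) {
      b <- which(tracts$bg[seq_len(min(rows) - 1L)])
      if (length(b)) max(b) else NA_integer_
    } else NA_integer_
    right_bg <- if (length(rows)) {
      b <- if (max(rows) < nrow(tracts)) {
        max(rows) + which(tracts$bg[(max(rows) + 1L):nrow(tracts)])
      } else integer()
      if (length(b)) min(b) else NA_integer_
    } else NA_integer_
    if (!length(rows)) {   # junction with no transfer: flanks are the
      j <- ev$junction_ids[1L]                       # junction's backgrounds
      left_bg <- phase$junctions$left_bg_row[j]
      right_bg <- phase$junctions$right_bg_row[j]
    }
    left_key <- if (!is.na(left_bg)) tracts$phase_key[left_bg] else NA_character_
    right_key <- if (!is.na(right_bg)) tracts$phase_key[right_bg] else NA_character_

    # net arm exchange decides the kind (a short phase-swapped patch flanked
    # by identical phase is a conversion, not a crossover)
    is_co <- !is.na(left_key) && !is.na(right_key) && left_key != right_key
    exchange <- integer()
    if (is_co) {
      exchange <- which(strsplit(left_key, "")[[1]] !=
                        strsplit(right_key, "")[[1]])
    }
    pattern <- pattern_string(tracts[rows, , drop = FALSE], mode,
                              flank_keys = c(left_key, right_key))
    # marker support: non-Mendelian tracts plus Mendelian patches whose
    # chromatid phase differs from both flanks (they are event evidence too)
    flank_ok <- stats::na.omit(c(left_key, right_key))
    off_bg <- rows[tracts$bg[rows] & !(tracts$phase_key[rows] %in% flank_ok)]
    support <- sum(tracts$n_markers[c(nonbg_rows, off_bg)])
    chromatids <- event_chromatids(ev, tracts, phase, mode)
    ref_key <- if (!is.na(left_key)) left_key else right_key
    summary <- summarize_chromatids(chromatids, ref_key)
    junction_pos <- if (length(ev$junction_ids)) {
      phase$junctions$pos[ev$junction_ids[1L]]
    } else NA_real_

    geometry <- NULL
    length_bp <- NA_real_
    span <- event_span(ev, tracts, phase)
    if (length(rows)) {
      k_first <- kept_map[tracts$first_idx[min(rows)]]
      k_last <- kept_map[tracts$last_idx[max(rows)]]
      length_bp <- estimate_tract_length(k_first, k_last, positions)
      geometry <- do.call(rbind, lapply(nonbg_rows, function(r) {
        ref <- tract_ref_key(r, tracts, mode)
        invs <- involved_chromatids(tracts$key[r], ref, mode)
        if (!length(invs)) return(NULL)
        kf <- kept_map[tracts$first_idx[r]]
        kl <- kept_map[tracts$last_idx[r]]
        lo <- if (kf > 1L) (positions[kf - 1L] + positions[kf]) / 2 else positions[kf]
        hi <- if (kl < length(positions)) {
          (positions[kl] + positions[kl + 1L]) / 2
        } else positions[kl]
        tibble::tibble(chromatid = invs, start = lo, end = hi)
      }))
    }

    tibble::tibble(
      chrom = chrom,
      start = span[1L], end = span[2L],
      kind = if (is_co) "CO" else "NCO",
      pattern = pattern,
      n_tracts = length(rows),
      n_markers = support,
      length_bp = length_bp,
      chromatids = paste(chromatids, collapse = ","),
      chromatid_summary = summary,
      exchange = paste(exchange, collapse = "/"),
      junction_pos = junction_pos,
      tract_rows = list(rows),
      geometry = list(geometry)
    )
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_events(chrom))
  res[order(res$start), ]
}

empty_events <- function(chrom = character()) {
  tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    kind = character(), pattern = character(), n_tracts = integer(),
    n_markers = integer(), length_bp = numeric(), chromatids = character(),
    chromatid_summary = character(), exchange = character(),
    junction_pos = numeric(), tract_rows = list(), geometry = list()
  )
}

#' Call recombination events on one segmented chromosome
#'
#' Turns the tract list of one chromosome into crossover and non-crossover
#' events: each parental-phase junction becomes a crossover absorbing the
#' adjacent non-Mendelian tracts; remaining non-Mendelian tract clusters
#' become non-crossovers; events closer than the merge threshold are combined
#' (see [merge_events()]); non-crossovers supported by a single marker are
#' discarded. Markers segregating 4:0 chromatid-wise (8:0 strand-wise) are of
#' mitotic origin and have already been excluded by [segment_tracts()].
#'
#' @param tracts Tract tibble from [segment_tracts()] for one chromosome.
#' @param phase Phase structure from [infer_parental_phase()].
#' @param positions Callable marker positions used for length estimation
#'   (same filtering as [segment_tracts()]).
#' @param kept_map Mapping from original marker row to rank within
#'   `positions` (`NA` for excluded markers).
#' @param mode `"octad"` or `"tetrad"`.
#' @param params [caller_params()].
#' @param chrom Chromosome label for the output.
#' @param merge Apply the merge rule (default `TRUE`).
#' @return An event tibble; see [call_recombination_events()] for columns.
#' @export
call_events <- function(tracts, phase, positions, kept_map,
                        mode = c("octad", "tetrad"), params = caller_params(),
                        chrom = "chr", merge = TRUE) {
  mode <- match.arg(mode)
  ev <- build_initial_events(tracts, phase)
  if (merge) {
    ev <- merge_event_list(ev, tracts, phase, mode, params$merge_threshold)
  }
  res <- finalize_events(ev, tracts, phase, positions, kept_map, mode,
                         params, chrom)
  drop <- res$kind == "NCO" & res$n_markers < params$min_support
  if (any(drop)) {
    attr(res, "discarded") <- res[drop, ]
    res <- res[!drop, ]
  }
  res
}

#' Merge nearby events arising from one initiating break
#'
#' Events whose outermost affected markers are separated by less than
#' `threshold` bp are considered products of a single double-strand break and
#' are combined into one event (a crossover if any constituent is one, with
#' the interior Mendelian stretch entering the pattern). Exception: a gene
#' conversion on a chromatid not involved in a nearby crossover remains a
#' separate event.
#'
#' This is applied by [call_events()] by default; the exported function
#' re-merges an event tibble called with `merge = FALSE` or a smaller
#' threshold, using the calling context attached to the tibble.
#'
#' @param events Event tibble from [call_events()] (carries its context).
#' @param threshold Distance in bp (default 5000).
#' @return A merged event tibble.
#' @export
merge_events <- function(events, threshold = 5000) {
  ctx <- attr(events, "context")
  if (is.null(ctx)) {
    stop("merge_events needs an event tibble carrying its calling context; ",
         "use call_events()/call_recombination_events()")
  }
  params <- ctx$params
  params$merge_threshold <- threshold
  out <- lapply(split(seq_len(nrow(events)), events$chrom), function(i) {
    ch <- events$chrom[i[1L]]
    cc <- ctx$per_chrom[[ch]]
    call_events(cc$tracts, cc$phase, cc$positions, cc$kept_map, ctx$mode,
                params, chrom = ch, merge = TRUE)
  })
  res <- do.call(rbind, out)
  attr(res, "context") <- ctx
  res
}
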