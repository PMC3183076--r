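#' Call the segregation class of a single marker
#'
#' Converts one marker's ordered cell-allele vector into a segregation call.
#' In octad mode the eight values are the eight DNA strands (mother/daughter
#' cell per spore, see [genotype_calls()]): the ratio `a:b` counts parent-1
#' strands first, a chromatid is heteroduplex when its mother and daughter
#' cell disagree, and the class token is `"a:b"` with the star suffix reserved
#' for the aberrant balanced ratio (4:4 with symmetric heteroduplex on two
#' chromatids). In tetrad mode the four values are chromatid-level and no
#' heteroduplex is observable.
#'
#' @param signature Integer vector of 0/1 (length 8 octad, 4 tetrad); `NA`
#'   yields an uncallable marker.
#' @param mode `"octad"` or `"tetrad"`.
#' @return A list: `ratio` (c(a, b)), `class` (token such as "5:3", "4:4*"),
#'   `heteroduplex` (octad only: data frame of heteroduplex chromatids with the
#'   minority-carrying cell), `signature` (the input vector), `callable`,
#'   `mitotic` (all strands from one parent: 8:0 / 4:0).
#' @examples
#' call_marker_segregation(c(1, 1, 1, 1, 1, 0, 0, 0), "octad")$class
#' @export
call_marker_segregation <- function(signature, mode = c("octad", "tetrad")) {
  mode <- match.arg(mode)
  n <- if (mode == "octad") 8L else 4L
  if (length(signature) != n) {
    stop("signature must have length ", n, " in ", mode, " mode")
  }
  if (anyNA(signature)) {
    return(list(ratio = c(NA_integer_, NA_integer_), class = NA_character_,
                heteroduplex = NULL, signature = signature,
                callable = FALSE, mitotic = FALSE))
  }
  if (!all(signature %in% c(0L, 1L))) stop("signature values must be 0 or 1")
  a <- sum(signature == 1L)
  b <- n - a
  het <- NULL
  cls <- paste0(a, ":", b)
  if (mode == "octad") {
    mo <- signature[c(1L, 3L, 5L, 7L)]
    da <- signature[c(2L, 4L, 6L, 8L)]
    hk <- which(mo != da)
    if (length(hk)) {
      # the minority cell carries the allele in the strand-count minority;
      # undefined for the balanced aberrant class
      if (a == b) {
        minority_cell <- rep(NA_character_, length(hk))
      } else {
        minority_allele <- if (a < b) 1L else 0L
        minority_cell <- ifelse(mo[hk] == minority_allele, "mother", "daughter")
      }
      het <- data.frame(chromatid = hk, minority_cell = minority_cell,
                        stringsAsFactors = FALSE)
      if (a == b) cls <- "4:4*"
    }
  }
  list(ratio = c(a, b), class = cls, heteroduplex = het,
       signature = signature, callable = TRUE, mitotic = a %in% c(0L, n))
}

# Vectorised per-marker classification of a call matrix (markers x cells).
# Returns a data frame aligned to the matrix rows.
classify_markers <- function(calls, mode) {
  n <- ncol(calls)
  callable <- rowSums(is.na(calls)) == 0L
  a <- rowSums(calls == 1L)
  a[!callable] <- NA_integer_
  mitotic <- callable & (a == 0L | a == n)
  key <- rep(NA_character_, nrow(calls))
  if (any(callable)) {
    key[callable] <- apply(calls[callable, , drop = FALSE], 1L, paste0,
                           collapse = "")
  }
  if (mode == "octad") {
    mo <- calls[, c(1L, 3L, 5L, 7L), drop = FALSE]
    da <- calls[, c(2L, 4L, 6L, 8L), drop = FALSE]
    n_het <- rowSums(mo != da)
    hom <- mo
    hom[mo != da] <- NA_integer_
  } else {
    n_het <- rep(0L, nrow(calls))
    hom <- calls
  }
  aberrant <- callable & a == n / 2L & n_het > 0L
  bg <- callable & a == n / 2L & n_het == 0L
  phase_key <- rep(NA_character_, nrow(calls))
  full_hom <- callable & n_het == 0L
  if (any(full_hom)) {
    phase_key[full_hom] <- apply(hom[full_hom, , drop = FALSE], 1L, paste0,
                                 collapse = "")
  }
  data.frame(a = a, callable = callable, mitotic = mitotic, key = key,
             n_het = n_het, aberrant = aberrant, bg = bg,
             phase_key = phase_key, stringsAsFactors = FALSE)
}

#' Segment per-marker calls into signature tracts
#'
#' Collapses maximal runs of markers sharing one signature-equivalence class
#' (the full ordered cell-allele vector, not just the ratio) into tracts.
#' Uncallable and mitotic-flagged markers are transparent: runs extend across
#' them. Parental-phase balanced runs are emitted as background tracts, so the
#' tract list reconstructs every callable marker exactly once.
#'
#' @param calls Integer matrix of 0/1/NA calls for one chromosome
#'   (markers x cells, 8 columns octad / 4 tetrad), ordered by position.
#' @param positions Marker positions (bp) aligned to the matrix rows.
#' @param mode `"octad"` or `"tetrad"`.
#' @return A tibble with one row per tract: marker index range (`first_idx`,
#'   `last_idx` into the input rows, excluding transparent markers from
#'   counts), `n_markers`, `first_pos`/`last_pos`, ratio `a`/`b`, the class
#'   token, the distribution id (`key`, the signature itself), `aberrant`,
#'   `bg` (background Mendelian), `phase_key` (chromatid-level alleles when
#'   homoduplex), and `het_chromatids` (list column; octad only).
#' @export
segment_tracts <- function(calls, positions, mode = c("octad", "tetrad")) {
  mode <- match.arg(mode)
  cls <- classify_markers(as.matrix(calls), mode)
  keep <- which(cls$callable & !cls$mitotic)
  empty <- tibble::tibble(
    first_idx = integer(), last_idx = integer(), n_markers = integer(),
    first_pos = integer(), last_pos = integer(), a = integer(), b = integer(),
    class = character(), key = character(), aberrant = logical(),
    bg = logical(), phase_key = character(), het_chromatids = list()
  )
  if (length(keep) == 0L) return(empty)
  keys <- cls$key[keep]
  r <- rle(keys)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_cells <- ncol(calls)
  out <- lapply(seq_along(starts), function(i) {
    rows <- keep[starts[i]:ends[i]]
    first <- rows[1L]
    a <- cls$a[first]
    b <- n_cells - a
    aberr <- cls$aberrant[first]
    cls_token <- if (aberr) "4:4*" else paste0(a, ":", b)
    het <- integer()
    if (mode == "octad" && cls$n_het[first] > 0L) {
      sig <- as.integer(calls[first, ])
      het <- which(sig[c(1L, 3L, 5L, 7L)] != sig[c(2L, 4L, 6L, 8L)])
    }
    tibble::tibble(
      first_idx = first, last_idx = rows[length(rows)],
      n_markers = length(rows),
      first_pos = as.integer(positions[first]),
      last_pos = as.integer(positions[rows[length(rows)]]),
      a = a, b = b, class = cls_token, key = r$values[i],
      aberrant = aberr, bg = cls$bg[first],
      phase_key = cls$phase_key[first],
      het_chromatids = list(het)
    )
  })
  do.call(rbind, out)
}
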