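#' Pattern-string grammar for segregation tracts
#'
#' Strand-transfer events are summarised by pattern strings such as
#' `"3:5_4:4_3:5*"`: ratio tokens `a:b` joined by underscores, ordered along
#' the chromosome. In octad mode `a + b = 8` (`a` counts strands carrying the
#' parent-1 allele); in tetrad mode `a + b = 4` and counts are chromatid-level.
#' A star suffix distinguishes tracts that share a global ratio but differ in
#' strand (or spore) distribution; an aberrant `4:4*` token marks symmetric
#' heteroduplex (two chromatids heteroduplex with opposite minorities).
#'
#' `parse_pattern()` tokenises a single pattern and validates it against the
#' mode's strand total. The typographic ratio character sometimes found in
#' transcriptions is accepted and normalised to ASCII `":"`.
#'
#' @param pattern Pattern string, e.g. `"3:5_4:4_3:5*"`. `"none"` denotes a
#'   crossover without detected transfer and parses to zero tokens.
#' @param mode `"octad"` (tokens sum to 8) or `"tetrad"` (sum to 4).
#' @return A data frame with one row per token: `token`, `a`, `b`, `stars`,
#'   and logical columns `mendelian` (a == b, unstarred), `aberrant`
#'   (a == b, starred), `half` (odd counts: one chromatid heteroduplex),
#'   `full` (even non-Mendelian counts: full conversion), and `direction`
#'   (+1 parent-1 excess, -1 parent-2 excess, 0 balanced).
#' @examples
#' parse_pattern("3:5_4:4_3:5*", "octad")
#' @export
parse_pattern <- function(pattern, mode = c("octad", "tetrad")) {
  mode <- match.arg(mode)
  total <- if (mode == "octad") 8L else 4L
  pattern <- normalize_ratio_chars(pattern)
  empty <- data.frame(
    token = character(), a = integer(), b = integer(), stars = integer(),
    mendelian = logical(), aberrant = logical(), half = logical(),
    full = logical(), direction = integer(), stringsAsFactors = FALSE
  )
  if (identical(pattern, "none")) {
    return(empty)
  }
  tokens <- strsplit(pattern, "_", fixed = TRUE)[[1]]
  m <- regmatches(tokens, regexec("^([0-9]+):([0-9]+)(\\**)$", tokens))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("unparseable pattern token(s): ", paste(tokens[bad], collapse = ", "),
         " in pattern '", pattern, "'")
  }
  a <- vapply(m, function(x) as.integer(x[2]), 1L)
  b <- vapply(m, function(x) as.integer(x[3]), 1L)
  stars <- vapply(m, function(x) nchar(x[4]), 1L)
  if (any(a + b != total)) {
    stop("ratio token(s) do not sum to ", total, " in ", mode, " mode: ",
         paste(tokens[a + b != total], collapse = ", "))
  }
  data.frame(
    token = tokens, a = a, b = b, stars = stars,
    mendelian = a == b & stars == 0L,
    aberrant = a == b & stars > 0L,
    half = a != b & (a %% 2L == 1L),
    full = a != b & (a %% 2L == 0L),
    direction = sign(a - b),
    stringsAsFactors = FALSE
  )
}

normalize_ratio_chars <- function(x) {
  # U+2236 RATIO occurs in transcriptions of the printed tables
  gsub("∶", ":", x)
}

render_pattern <- function(a, b, stars) {
  if (length(a) == 0L) return("none")
  paste0(a, ":", b, strrep("*", stars), collapse = "_")
}

#' Canonical orientation of a pattern under global parent swap
#'
#' The two parental orientations of a pattern (`a:b` vs `b:a` applied to every
#' token) describe the same event; printed inventories mix them. The canonical
#' representative is the orientation in which the first non-balanced token has
#' its smaller count first (e.g. `"5:3_4:4_5:3*"` becomes `"3:5_4:4_3:5*"`).
#' Patterns whose tokens are all balanced (including `"none"`) are returned
#' unchanged. The function is idempotent and vectorised.
#'
#' @inheritParams parse_pattern
#' @return Character vector of canonicalised patterns.
#' @examples
#' canonicalize_pattern("5:3_4:4_5:3*")
#' @export
canonicalize_pattern <- function(pattern, mode = c("octad", "tetrad")) {
  mode <- match.arg(mode)
  vapply(pattern, function(p) {
    if (identical(p, "none")) return("none")
    tok <- parse_pattern(p, mode)
    unbal <- which(tok$a != tok$b)
    if (length(unbal) == 0L) return(render_pattern(tok$a, tok$b, tok$stars))
    if (tok$a[unbal[1]] > tok$b[unbal[1]]) {
      render_pattern(tok$b, tok$a, tok$stars)
    } else {
      render_pattern(tok$a, tok$b, tok$stars)
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Number of segregation tracts in a pattern
#'
#' Counts the underscore-separated tokens of a pattern. `"none"` (a crossover
#' without detected transfer) counts 0. The aggregate fixture token `">3"`
#' (printed inventories pool patterns of more than three tracts into one row)
#' counts 4, its lower bound.
#'
#' @inheritParams parse_pattern
#' @return Integer vector of tract counts.
#' @examples
#' count_tracts(c("3:5", "3:5_4:4_3:5*", "none", ">3"))
#' @export
count_tracts <- function(pattern, mode = c("octad", "tetrad")) {
  mode <- match.arg(mode)
  vapply(pattern, function(p) {
    if (identical(p, "none")) return(0L)
    if (identical(p, ">3")) return(4L)
    nrow(parse_pattern(p, mode))
  }, integer(1), USE.NAMES = FALSE)
}

#' Does a pattern contain half-conversion tracts of both directions?
#'
#' Half-conversion (heteroduplex) tracts have an asymmetry direction: parent-1
#' excess (`5:3`) or parent-2 excess (`3:5`). A pattern containing both, such
#' as `"5:3_4:4_3:5"`, cannot be produced by a single uninterrupted strand
#' transfer and is diagnostic of nick translation combined with junction
#' migration (or of two coincident events). Full-conversion tracts are not
#' considered. The predicate is invariant under global parent swap.
#'
#' @inheritParams parse_pattern
#' @return Logical vector.
#' @examples
#' has_opposite_directions(c("5:3_4:4_3:5", "3:5_3:5*"))
#' @export
has_opposite_directions <- function(pattern, mode = c("octad", "tetrad")) {
  mode <- match.arg(mode)
  vapply(pattern, function(p) {
    if (identical(p, "none") || identical(p, ">3")) return(FALSE)
    tok <- parse_pattern(p, mode)
    dirs <- unique(tok$direction[tok$half])
    all(c(-1L, 1L) %in% dirs)
  }, logical(1), USE.NAMES = FALSE)
}
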