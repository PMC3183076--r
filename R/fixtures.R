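#' Load a printed pattern-inventory fixture
#'
#' The package ships the published strand-transfer pattern inventories as
#' plain tab-separated fixtures under `inst/extdata`: three tables of
#' NCO-associated patterns and one of CO-associated patterns from
#' mismatch-repair deficient (msh2) octads, plus the CO and NCO inventories
#' from wild-type tetrads. Each file carries a comment header with the event
#' kind, the mode, and the total occurrence count, which is asserted against
#' the row sums at load time.
#'
#' @param path Path to a fixture file (see [fixture_path()]).
#' @return A tibble with columns `kind` ("CO"/"NCO"), `mode` ("msh2"/"wt"),
#'   `table` (source table number), `pattern` (ASCII-normalised), `occurrence`,
#'   `chromatid_assignment` (one of none, single, two-non-sister, two-sister,
#'   unspecified), `printed_class` (the published class for NCO tables, `NA`
#'   otherwise), `aggregate` (`TRUE` for the pooled ">3 tracts" rows), and
#'   `n_tracts` (via [count_tracts()]).
#' @examples
#' load_pattern_fixture(fixture_path("msh2_nco_table1"))
#' @export
load_pattern_fixture <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)=(\\S+)", h))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- kv[3]
  }
  for (need in c("kind", "mode", "total")) {
    if (is.null(meta[[need]])) {
      stop("fixture ", path, " is missing '", need, "' in its header")
    }
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("pattern", "occurrence", "chromatid_assignment", "printed_class")
  if (!all(required %in% names(tab))) {
    stop("fixture ", path, " must have columns: ", paste(required, collapse = ", "))
  }
  tab$pattern <- normalize_ratio_chars(tab$pattern)
  seg_mode <- if (meta$mode == "msh2") "octad" else "tetrad"

  if (any(is.na(tab$occurrence)) || any(tab$occurrence <= 0) ||
      any(tab$occurrence != round(tab$occurrence))) {
    stop("fixture ", path, ": occurrence counts must be positive integers")
  }
  aggregate <- tab$pattern == ">3"
  for (i in which(!aggregate & tab$pattern != "none")) {
    tryCatch(
      parse_pattern(tab$pattern[i], seg_mode),
      error = function(e) {
        stop("fixture ", path, ", row ", i, " ('", tab$pattern[i], "'): ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  total <- as.integer(meta$total)
  if (sum(tab$occurrence) != total) {
    stop("fixture ", path, ": occurrence counts sum to ", sum(tab$occurrence),
         " but the header declares ", total)
  }
  ok_chromatid <- c("none", "single", "two-non-sister", "two-sister", "unspecified")
  if (!all(tab$chromatid_assignment %in% ok_chromatid)) {
    stop("fixture ", path, ": invalid chromatid_assignment value(s)")
  }
  tibble::tibble(
    kind = meta$kind,
    mode = meta$mode,
    table = if (is.null(meta$table)) NA_integer_ else as.integer(meta$table),
    pattern = tab$pattern,
    occurrence = as.integer(tab$occurrence),
    chromatid_assignment = tab$chromatid_assignment,
    printed_class = ifelse(tab$printed_class == ".", NA_character_, tab$printed_class),
    aggregate = aggregate,
    n_tracts = count_tracts(tab$pattern, seg_mode)
  )
}

#' Path to a shipped pattern fixture
#'
#' @param name Fixture name without extension: one of `"msh2_nco_table1"`,
#'   `"msh2_nco_table2"`, `"msh2_nco_table3"`, `"msh2_co_table4"`,
#'   `"wt_co_table6"`, `"wt_nco_table7"`.
#' @return Absolute path to the installed fixture file.
#' @export
fixture_path <- function(name) {
  p <- system.file("extdata", paste0(name, ".tsv"), package = "meihdna")
  if (p == "") stop("no shipped fixture named '", name, "'")
  p
}

#' Load a combined pattern inventory
#'
#' Convenience wrappers binding the shipped fixtures per event kind and mode:
#' `"msh2_nco"` binds the three msh2 NCO tables (total 169 events),
#' `"msh2_co"` the msh2 CO table (181), `"wt_co"` (282) and `"wt_nco"` (65)
#' the wild-type inventories.
#'
#' @param which Inventory name.
#' @return A tibble as returned by [load_pattern_fixture()].
#' @export
pattern_inventory <- function(which = c("msh2_nco", "msh2_co", "wt_co", "wt_nco")) {
  which <- match.arg(which)
  files <- switch(which,
    msh2_nco = c("msh2_nco_table1", "msh2_nco_table2", "msh2_nco_table3"),
    msh2_co = "msh2_co_table4",
    wt_co = "wt_co_table6",
    wt_nco = "wt_nco_table7"
  )
  do.call(rbind, lapply(files, function(f) load_pattern_fixture(fixture_path(f))))
}
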