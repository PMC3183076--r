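#' Construct a marker map
#'
#' A marker map records the polymorphic sites that distinguish the two
#' parental haplotypes: 1-based genome coordinates (strictly increasing within
#' each chromosome), the polymorphism type (S = SNP, I = insertion,
#' D = deletion), and the two parental allele labels. Coordinates are 1-based
#' inclusive throughout the package. The alignment position column (`ali_pos`)
#' is carried for provenance but never used in computation.
#'
#' @param chrom Chromosome labels (character or coercible).
#' @param pos 1-based genome positions (bp).
#' @param type Polymorphism type per marker: "S", "I" or "D".
#' @param ali_pos Optional alignment positions (carried, unused).
#' @param parent1_allele,parent2_allele Allele labels for the two parents
#'   (defaults "S288C" and "SK1"); must differ at every marker.
#' @return A tibble with columns `chrom`, `index` (1-based per chromosome),
#'   `ali_pos`, `pos`, `type`, `parent1_allele`, `parent2_allele`, sorted by
#'   `(chrom, pos)`.
#' @export
marker_map <- function(chrom, pos, type = "S", ali_pos = NA_integer_,
                       parent1_allele = "S288C", parent2_allele = "SK1") {
  n <- length(pos)
  mm <- tibble::tibble(
    chrom = as.character(rep_len(chrom, n)),
    ali_pos = rep_len(ali_pos, n),
    pos = as.integer(pos),
    type = as.character(rep_len(type, n)),
    parent1_allele = rep_len(parent1_allele, n),
    parent2_allele = rep_len(parent2_allele, n)
  )
  mm <- mm[order(mm$chrom, mm$pos), ]
  validate_marker_map(mm)
  mm$index <- stats::ave(mm$pos, mm$chrom, FUN = seq_along)
  mm[, c("chrom", "index", "ali_pos", "pos", "type",
         "parent1_allele", "parent2_allele")]
}

validate_marker_map <- function(mm) {
  if (nrow(mm) == 0L) return(invisible(mm))
  if (!all(mm$type %in% c("S", "I", "D"))) {
    stop("marker type must be one of S, I, D")
  }
  dup <- duplicated(mm[, c("chrom", "pos")])
  if (any(dup)) {
    stop("duplicate (chromosome, position) pairs in marker map: ",
         paste(utils::head(paste0(mm$chrom[dup], ":", mm$pos[dup]), 3L),
               collapse = ", "))
  }
  if (any(mm$pos < 1L)) stop("marker positions must be 1-based (>= 1)")
  if (any(mm$parent1_allele == mm$parent2_allele)) {
    stop("every marker needs two distinct parental alleles")
  }
  invisible(mm)
}

#' Construct a genotype-call container
#'
#' Holds the 0/1 genotype-call matrix for the cell populations of one meiosis.
#' In octad mode there are eight cells: the mother and daughter cell from the
#' first mitotic division of each of the four spores, ordered
#' `s1m, s1d, s2m, s2d, s3m, s3d, s4m, s4d`, so that each pair of columns
#' reads out the two DNA strands of one chromatid. In tetrad mode there are
#' four spore columns `s1..s4`. A call of 1 is the parent-1 (S288C) allele,
#' 0 the parent-2 (SK1) allele; `NA` marks a missing call.
#'
#' @param calls Integer matrix, markers x cells, values in {0, 1, NA}.
#' @param mode `"octad"` or `"tetrad"`.
#' @param cells Optional cell labels; defaults to the conventional ordering.
#' @return An object of class `meihdna_genotypes`.
#' @export
genotype_calls <- function(calls, mode = c("octad", "tetrad"), cells = NULL) {
  mode <- match.arg(mode)
  ncell <- if (mode == "octad") 8L else 4L
  calls <- as.matrix(calls)
  if (ncol(calls) != ncell) {
    stop("expected ", ncell, " cell columns in ", mode, " mode, got ", ncol(calls))
  }
  if (!all(calls %in% c(0L, 1L, NA))) {
    stop("genotype calls must be 0, 1 or NA")
  }
  storage.mode(calls) <- "integer"
  if (is.null(cells)) cells <- default_cells(mode)
  if (length(cells) != ncell) stop("need ", ncell, " cell labels")
  colnames(calls) <- cells
  structure(list(calls = calls, cells = cells, mode = mode),
            class = "meihdna_genotypes")
}

default_cells <- function(mode) {
  if (mode == "octad") {
    as.vector(t(outer(paste0("s", 1:4), c("m", "d"), paste0)))
  } else {
    paste0("s", 1:4)
  }
}

#' @export
print.meihdna_genotypes <- function(x, ...) {
  cat("<meihdna_genotypes> ", x$mode, " mode: ", nrow(x$calls), " markers x ",
      length(x$cells), " cells (", paste(x$cells, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Read a marker genotype table
#'
#' Reads the tab-separated genotype-table dialect used throughout the package:
#' columns `chrom`, `index`, `Ali_pos`, `S288C_pos`, `type`, then one 0/1 call
#' column per cell population (eight in octad mode, four in tetrad mode; the
#' call-column headers name the cells). Markers are sorted by
#' (chromosome, position) and the call matrix is aligned to that order.
#'
#' @param path Path to the table.
#' @param mode `"octad"` or `"tetrad"`; must match the number of call columns.
#' @return A list with elements `marker_map` (see [marker_map()]) and
#'   `genotypes` (a [genotype_calls()] object).
#' @export
read_genotype_table <- function(path, mode = c("octad", "tetrad")) {
  mode <- match.arg(mode)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("chrom", "index", "Ali_pos", "S288C_pos", "type")
  if (!all(fixed %in% names(tab))) {
    stop("genotype table ", path, " must start with columns: ",
         paste(fixed, collapse = ", "))
  }
  cell_cols <- setdiff(names(tab), fixed)
  ncell <- if (mode == "octad") 8L else 4L
  if (length(cell_cols) != ncell) {
    stop("mode '", mode, "' expects ", ncell, " call columns but ", path,
         " has ", length(cell_cols))
  }
  if (nrow(tab) == 0L) {
    return(list(
      marker_map = marker_map(character(), integer()),
      genotypes = genotype_calls(matrix(integer(), 0L, ncell), mode,
                                 cells = cell_cols)
    ))
  }
  calls <- as.matrix(tab[, cell_cols])
  if (!all(calls %in% c(0L, 1L, NA))) {
    stop("genotype table ", path, " contains call values outside {0, 1, NA}")
  }
  ord <- order(tab$chrom, tab$S288C_pos)
  mm <- marker_map(chrom = tab$chrom[ord], pos = tab$S288C_pos[ord],
                   type = tab$type[ord], ali_pos = tab$Ali_pos[ord])
  list(
    marker_map = mm,
    genotypes = genotype_calls(calls[ord, , drop = FALSE], mode,
                               cells = cell_cols)
  )
}

#' Write a marker genotype table
#'
#' Emits the tab-separated dialect read by [read_genotype_table()];
#' `read_genotype_table(write_genotype_table(...))` reproduces the call
#' matrix exactly.
#'
#' @param marker_map A marker map aligned row-for-row with `genotypes`.
#' @param genotypes A [genotype_calls()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(marker_map, genotypes, path) {
  stopifnot(inherits(genotypes, "meihdna_genotypes"))
  if (nrow(marker_map) != nrow(genotypes$calls)) {
    stop("marker map has ", nrow(marker_map), " rows but genotype matrix has ",
         nrow(genotypes$calls))
  }
  out <- data.frame(
    chrom = marker_map$chrom,
    index = marker_map$index,
    Ali_pos = marker_map$ali_pos,
    S288C_pos = marker_map$pos,
    type = marker_map$type,
    check.names = FALSE
  )
  out <- cbind(out, as.data.frame(genotypes$calls))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write genotype table to '", path, "': ", conditionMessage(ok))
  }
  invisible(path)
}
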