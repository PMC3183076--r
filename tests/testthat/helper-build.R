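# Builders for small hand-constructed octad/tetrad datasets and scaled-down
# simulation configurations used across the test files.

# an octad call matrix with the given base phase, modified cell-by-cell;
# cells are ordered s1m, s1d, s2m, s2d, s3m, s3d, s4m, s4d
octad_matrix <- function(n, base = c(1, 1, 1, 1, 0, 0, 0, 0), edits = list()) {
  M <- matrix(rep(as.integer(base), each = n), nrow = n)
  for (e in edits) {  # e: list(rows, cells, value)
    M[e$rows, e$cells] <- as.integer(e$value)
  }
  M
}

octad_data <- function(M, spacing = 1000, chrom = "chrT") {
  n <- nrow(M)
  mm <- marker_map(chrom = chrom, pos = spacing * seq_len(n))
  list(marker_map = mm, genotypes = genotype_calls(M, "octad"))
}

# call events directly on a matrix
call_on_matrix <- function(M, spacing = 1000, params = caller_params(),
                           mode = "octad") {
  n <- nrow(M)
  mm <- marker_map(chrom = "chrT", pos = spacing * seq_len(n))
  gt <- genotype_calls(M, mode)
  call_recombination_events(mm, gt, params)
}

# study-condition densities on a desk-scale genome: 1 Mb over four
# chromosomes, one marker per 194 bp, DSB rate matching 160 per 12.07 Mb
small_config <- function(seed, ..., mmr_mode = "msh2", complications = FALSE) {
  sim_config(
    chrom_sizes = stats::setNames(rep(250000L, 4), paste0("chrS", 1:4)),
    dsb_mean = 160 * 1e6 / 12.07e6,
    mmr_mode = mmr_mode,
    seed = seed,
    complications = complications,
    ...
  )
}

single_pathway <- function(which) {
  p <- c(simple_SDSA = 0, double_SDSA = 0, dHJ_dissolution = 0,
         dHJ_resolution_NCO = 0, dHJ_resolution_CO = 0, nicked_HJ_CO = 0)
  p[which] <- 1
  p
}

# random valid octad genotype dataset for I/O round trips
random_genotype_data <- function(n_markers, n_chrom = 2, mode = "octad") {
  ncell <- if (mode == "octad") 8L else 4L
  chrom <- sort(sample(sprintf("chr%02d", seq_len(n_chrom)), n_markers,
                       replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_markers), chrom), function(i) {
    sort(sample.int(1e6, length(i)))
  }), use.names = FALSE)
  mm <- marker_map(chrom = sort(chrom), pos = pos,
                   type = sample(c("S", "I", "D"), n_markers, replace = TRUE))
  calls <- matrix(sample(0:1, n_markers * ncell, replace = TRUE),
                  ncol = ncell)
  list(marker_map = mm, genotypes = genotype_calls(calls, mode))
}
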