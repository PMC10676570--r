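# Small in-code fixtures shared across test files.

# side-call data frame from an origin sequence, positions 1 kb apart
make_side <- function(origins, spacing = 1000, start = 1000) {
  data.frame(scaffold = rep("s1", length(origins)),
             scaffold_pos = seq_along(origins) * spacing + start - spacing,
             chrom_pos = seq_along(origins) * spacing + start - spacing,
             origin = origins, stringsAsFactors = FALSE)
}

# one-scaffold map spanning `size` bp on chromosome "1"
make_smap <- function(size = 1e6, scaffold = "s1") {
  scaffold_map(data.frame(scaffold = scaffold, size = size, CHR = "1",
                          order = 1, orientation = "+",
                          stringsAsFactors = FALSE))
}

# minimal genotype table with explicit rows of 7 codes
# (PGF, PGM, MGF, MGM, FA, MO, OFF)
make_gt <- function(code_rows, scaffold = "s1",
                    positions = seq_len(nrow(code_rows)) * 100) {
  ids <- c("PGF", "PGM", "MGF", "MGM", "FA", "MO", "OFF")
  gt <- data.frame(scaffold = scaffold, position = positions,
                   stringsAsFactors = FALSE)
  gt[ids] <- lapply(seq_len(7L), function(j) as.integer(code_rows[, j]))
  pedrec:::validate_gt_table(gt)
}

make_ped <- function() {
  pedigree_spec("PGF", "PGM", "MGF", "MGM", "FA", "MO", "OFF")
}

# dictionary built once per test run
shared_dict <- local({
  dict <- NULL
  function() {
    if (is.null(dict)) dict <<- build_goo_dictionary()
    dict
  }
})
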