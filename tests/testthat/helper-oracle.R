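# Independent brute-force oracle for grandparent-of-origin inference.
#
# Works with explicit allele multisets and naive nested loops, unlike the
# package's vectorised base-3 build: enumerates every phased transmission
# (which allele each grandparent passes to its child, which of its two
# alleles each parent passes to the offspring) and checks multiset equality
# of the resulting genotypes at every step.

oracle_goo_string <- function(s) {
  g <- as.integer(strsplit(s, "")[[1]])
  stopifnot(length(g) == 7L)
  alleles <- function(code) list(c(0L, 0L), c(0L, 1L), c(1L, 1L))[[code + 1L]]
  same_genotype <- function(pair, code) identical(sort(pair), alleles(code))

  pat_sources <- character(0)
  mat_sources <- character(0)
  possible <- FALSE
  for (a_pgf in unique(alleles(g[1]))) {
    for (a_pgm in unique(alleles(g[2]))) {
      if (!same_genotype(c(a_pgf, a_pgm), g[5])) next
      for (a_mgf in unique(alleles(g[3]))) {
        for (a_mgm in unique(alleles(g[4]))) {
          if (!same_genotype(c(a_mgf, a_mgm), g[6])) next
          for (from_father in c("GF", "GM")) {
            a_pat <- if (from_father == "GF") a_pgf else a_pgm
            for (from_mother in c("GF", "GM")) {
              a_mat <- if (from_mother == "GF") a_mgf else a_mgm
              if (!same_genotype(c(a_pat, a_mat), g[7])) next
              possible <- TRUE
              pat_sources <- union(pat_sources, from_father)
              mat_sources <- union(mat_sources, from_mother)
            }
          }
        }
      }
    }
  }
  if (!possible) {
    return(list(possible = FALSE, paternal = NA_character_,
                maternal = NA_character_))
  }
  one_of <- function(src) if (length(src) == 1L) src else "UNINFORMATIVE"
  list(possible = TRUE, paternal = one_of(pat_sources),
       maternal = one_of(mat_sources))
}

all_goo_strings <- function() {
  grid <- expand.grid(rep(list(0:2), 7))[, 7:1]
  apply(grid, 1L, paste0, collapse = "")
}
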