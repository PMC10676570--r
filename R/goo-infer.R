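#' Infer grandparent-of-origin calls along a chromosome
#'
#' For one offspring and one chromosome, forms the 7-digit genotype
#' string at every SNP and matches it against the GoO dictionary. SNPs
#' with a missing code in any of the seven pedigree members are skipped,
#' as are strings absent from the dictionary (Mendelian-impossible —
#' candidate genotyping errors) and sides whose origin is not uniquely
#' determined. Informative calls are placed on chromosome coordinates
#' via [map_to_chromosome()] and returned sorted by position.
#'
#' @param gt a [read_gt_table()] genotype table; scaffolds on the
#'   analysed chromosome must appear in `smap`
#' @param ped a [pedigree_spec()]; if it lists several offspring, pick
#'   one with `offspring`
#' @param dict a [build_goo_dictionary()] dictionary
#' @param smap a [scaffold_map()]
#' @param chromosome chromosome label (a value of `smap$CHR`)
#' @param offspring offspring ID; defaults to the first in `ped`
#' @param gap inter-scaffold gap in bp (default 0)
#' @return a `goo_calls` object: list with `offspring`, `chromosome`,
#'   per-side data frames `paternal` and `maternal` (columns `scaffold`,
#'   `scaffold_pos`, `chrom_pos`, `origin` with origin `"GF"` or `"GM"`),
#'   and `counts` (SNPs seen / missing-skipped / impossible /
#'   uninformative per side).
#' @export
infer_goo <- function(gt, ped, dict, smap, chromosome,
                      offspring = ped$offspring[1L], gap = 0) {
  stopifnot(inherits(gt, "genotype_table"), inherits(ped, "pedigree_spec"),
            inherits(dict, "goo_dictionary"), inherits(smap, "scaffold_map"))
  check_ped_in_gt(ped, gt)
  if (!offspring %in% ped$offspring) {
    stop("offspring '", offspring, "' not listed in the pedigree spec")
  }
  if (!chromosome %in% smap$CHR) {
    stop("chromosome '", chromosome, "' absent from the scaffold map")
  }
  unknown <- setdiff(unique(gt$scaffold), smap$scaffold)
  if (length(unknown)) {
    stop("genotype-table scaffold(s) absent from scaffold map: ",
         paste(unknown, collapse = ", "))
  }

  chr_scafs <- smap$scaffold[smap$CHR == chromosome]
  sub <- gt[gt$scaffold %in% chr_scafs, , drop = FALSE]
  m <- as.matrix(sub[ped_ids(ped, offspring)])
  n_snp <- nrow(m)

  complete <- n_snp > 0 & !apply(is.na(m), 1L, any)
  n_missing <- sum(!complete)

  key <- if (any(complete)) {
    as.vector(m[complete, , drop = FALSE] %*% 3L^(6:0))
  } else integer(0)
  pat <- dict$paternal[key + 1L]
  mat <- dict$maternal[key + 1L]
  n_impossible <- sum(is.na(pat))

  mk_side <- function(origin) {
    take <- !is.na(origin) & origin != "UNINFORMATIVE"
    rows <- which(complete)[take]
    co <- map_to_chromosome(sub$scaffold[rows], sub$position[rows], smap, gap)
    side <- data.frame(scaffold = sub$scaffold[rows],
                       scaffold_pos = sub$position[rows],
                       chrom_pos = co$chrom_pos,
                       origin = origin[take],
                       stringsAsFactors = FALSE)
    side[order(side$chrom_pos), , drop = FALSE]
  }
  pat_side <- mk_side(pat)
  mat_side <- mk_side(mat)
  rownames(pat_side) <- rownames(mat_side) <- NULL

  structure(list(
    offspring = offspring, chromosome = chromosome,
    paternal = pat_side, maternal = mat_side,
    counts = list(
      n_snps = n_snp, n_missing = n_missing, n_impossible = n_impossible,
      n_uninformative_paternal =
        sum(!is.na(pat)) - nrow(pat_side),
      n_uninformative_maternal =
        sum(!is.na(mat)) - nrow(mat_side))),
    class = "goo_calls")
}

#' @export
print.goo_calls <- function(x, ...) {
  cat(sprintf("GoO calls: offspring %s, chromosome %s\n",
              x$offspring, x$chromosome))
  cat(sprintf("  SNPs: %d (%d missing-skipped, %d impossible)\n",
              x$counts$n_snps, x$counts$n_missing, x$counts$n_impossible))
  cat(sprintf("  informative: %d paternal, %d maternal\n",
              nrow(x$paternal), nrow(x$maternal)))
  invisible(x)
}

#' Local density of informative calls along a chromosome
#'
#' Counts informative GoO calls per side in non-overlapping bins tiling
#' the chromosome, the quantity plotted as the informative-SNP density
#' track.
#'
#' @param calls a [infer_goo()] `goo_calls` object
#' @param bin_bp bin width in bp (default 1e6)
#' @param chrom_length chromosome length in bp; defaults to the largest
#'   call position (the final partial bin always closes the chromosome)
#' @return data frame with columns `bin_start`, `bin_end`, `paternal`,
#'   `maternal`
#' @export
informative_density <- function(calls, bin_bp = 1e6,
                                chrom_length = NULL) {
  stopifnot(inherits(calls, "goo_calls"), bin_bp >= 1)
  if (is.null(chrom_length)) {
    chrom_length <- max(1, calls$paternal$chrom_pos, calls$maternal$chrom_pos)
  }
  starts <- seq(1, chrom_length, by = bin_bp)
  ends <- pmin(starts + bin_bp - 1, chrom_length)
  count_side <- function(side) {
    if (!nrow(side)) return(integer(length(starts)))
    bin <- findInterval(side$chrom_pos, starts)
    tabulate(bin, nbins = length(starts))
  }
  data.frame(bin_start = starts, bin_end = ends,
             paternal = count_side(calls$paternal),
             maternal = count_side(calls$maternal))
}

#' Write / read the per-SNP GoO table
#'
#' The intermediate GoO table lists every informative call: scaffold,
#' scaffold position, chromosomal position, side (`paternal` or
#' `maternal`) and origin (`GF` or `GM`). Writing then reading
#' reproduces the call set exactly.
#'
#' @param calls a `goo_calls` object
#' @param path file path
#' @return `write_goo_table()` returns `path` invisibly;
#'   `read_goo_table()` returns a `goo_calls` object (counts are not
#'   stored in the table and read back as `NA`).
#' @export
write_goo_table <- function(calls, path) {
  stopifnot(inherits(calls, "goo_calls"))
  row_side <- function(side, label) {
    if (!nrow(side)) return(NULL)
    cbind(data.frame(offspring = calls$offspring,
                     chromosome = calls$chromosome,
                     side = label, stringsAsFactors = FALSE),
          side)
  }
  out <- rbind(row_side(calls$paternal, "paternal"),
               row_side(calls$maternal, "maternal"))
  if (is.null(out)) {
    out <- data.frame(offspring = character(), chromosome = character(),
                      side = character(), scaffold = character(),
                      scaffold_pos = numeric(), chrom_pos = numeric(),
                      origin = character())
  }
  write_tsv(out, path)
}

#' @rdname write_goo_table
#' @export
read_goo_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(scaffold = "character",
                                         offspring = "character",
                                         chromosome = "character"),
                          check.names = FALSE)
  need <- c("offspring", "chromosome", "side", "scaffold", "scaffold_pos",
            "chrom_pos", "origin")
  if (!all(need %in% names(df))) {
    stop("not a GoO table: expected columns ", paste(need, collapse = ", "))
  }
  take <- function(label) {
    side <- df[df$side == label, c("scaffold", "scaffold_pos", "chrom_pos",
                                   "origin"), drop = FALSE]
    side <- side[order(side$chrom_pos), , drop = FALSE]
    rownames(side) <- NULL
    side
  }
  structure(list(
    offspring = if (nrow(df)) df$offspring[1L] else NA_character_,
    chromosome = if (nrow(df)) df$chromosome[1L] else NA_character_,
    paternal = take("paternal"), maternal = take("maternal"),
    counts = list(n_snps = NA_integer_, n_missing = NA_integer_,
                  n_impossible = NA_integer_,
                  n_uninformative_paternal = NA_integer_,
                  n_uninformative_maternal = NA_integer_)),
    class = "goo_calls")
}
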