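#' Map scaffold coordinates to chromosome coordinates
#'
#' Chromosomes are built by concatenating their scaffolds in `order`,
#' optionally separated by a fixed gap. A scaffold with `-` orientation
#' is flipped: its position `p` maps to `size - p + 1` within the
#' scaffold before the offset is added. All coordinates are 1-based bp.
#'
#' @param scaffold character vector of scaffold labels
#' @param pos integer vector of 1-based positions on the scaffold
#' @param smap a [scaffold_map()]
#' @param gap inter-scaffold gap in bp (default 0)
#' @return data frame with columns `CHR` and `chrom_pos`
#' @examples
#' smap <- scaffold_map(data.frame(
#'   scaffold = c("s1", "s2"), size = c(500, 1000), CHR = "1",
#'   order = 1:2, orientation = c("+", "-")))
#' map_to_chromosome(c("s1", "s2"), c(100, 1), smap)  # 100 and 1500
#' @export
map_to_chromosome <- function(scaffold, pos, smap, gap = 0) {
  stopifnot(inherits(smap, "scaffold_map"), gap >= 0)
  idx <- match(scaffold, smap$scaffold)
  if (anyNA(idx)) {
    stop("scaffold absent from scaffold map: ",
         paste(unique(scaffold[is.na(idx)]), collapse = ", "))
  }
  size <- smap$size[idx]
  if (any(pos < 1 | pos > size)) {
    bad <- which(pos < 1 | pos > size)[1L]
    stop("position ", pos[bad], " outside [1, ", size[bad],
         "] on scaffold ", scaffold[bad])
  }
  off <- scaffold_offsets(smap, gap)
  local <- ifelse(smap$orientation[idx] == "+", pos, size - pos + 1)
  data.frame(CHR = smap$CHR[idx], chrom_pos = off[idx] + local,
             stringsAsFactors = FALSE)
}

# bp offset preceding each scaffold row of smap (smap sorted by CHR, order)
scaffold_offsets <- function(smap, gap = 0) {
  off <- numeric(nrow(smap))
  for (chr in unique(smap$CHR)) {
    i <- which(smap$CHR == chr)
    sizes <- smap$size[i]
    off[i] <- cumsum(c(0, utils::head(sizes + gap, -1L)))
  }
  off
}

#' Total chromosome lengths implied by a scaffold map
#'
#' @inheritParams map_to_chromosome
#' @return named numeric vector of chromosome lengths in bp
#' @export
chromosome_lengths <- function(smap, gap = 0) {
  stopifnot(inherits(smap, "scaffold_map"))
  len <- tapply(smap$size, smap$CHR, sum)
  n <- tapply(smap$size, smap$CHR, length)
  out <- as.numeric(len + gap * (n - 1L))
  names(out) <- names(len)
  out
}

#' Locate chromosome positions back on scaffolds
#'
#' Inverse of [map_to_chromosome()]: finds, for each chromosomal
#' position, the scaffold whose image on the chromosome contains it.
#'
#' @param CHR chromosome label (recycled)
#' @param chrom_pos numeric vector of 1-based chromosomal positions
#' @inheritParams map_to_chromosome
#' @return data frame with columns `scaffold`, `orientation`,
#'   `scaffold_pos`
#' @export
locate_on_scaffold <- function(CHR, chrom_pos, smap, gap = 0) {
  stopifnot(inherits(smap, "scaffold_map"))
  off <- scaffold_offsets(smap, gap)
  n <- max(length(CHR), length(chrom_pos))
  CHR <- rep_len(CHR, n)
  chrom_pos <- rep_len(chrom_pos, n)
  idx <- rep(NA_integer_, n)
  for (chr in unique(CHR)) {
    rows <- which(smap$CHR == chr)          # sorted by order
    if (!length(rows)) {
      stop("chromosome '", chr, "' absent from the scaffold map")
    }
    k <- which(CHR == chr)
    # largest scaffold whose offset lies strictly below the position
    i <- findInterval(chrom_pos[k] - 1, off[rows])
    ok <- i >= 1L & chrom_pos[k] <= off[rows][pmax(i, 1L)] +
      smap$size[rows][pmax(i, 1L)]
    if (any(!ok)) {
      stop("chromosomal position ", chrom_pos[k][!ok][1L], " on CHR ", chr,
           " maps to no scaffold (inter-scaffold gap or out of range)")
    }
    idx[k] <- rows[i]
  }
  local <- chrom_pos - off[idx]
  data.frame(scaffold = smap$scaffold[idx],
             orientation = smap$orientation[idx],
             scaffold_pos = ifelse(smap$orientation[idx] == "+", local,
                                   smap$size[idx] - local + 1),
             stringsAsFactors = FALSE)
}
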