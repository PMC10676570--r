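#' Configuration for the pedigree genotype simulator
#'
#' Describes one simulated three-generation pedigree: founder allele
#' frequencies, SNP density, planted crossover positions in the two
#' focal meioses (father to offspring and mother to offspring),
#' genotyping error, missingness and an optional multi-scaffold
#' assembly layout.
#'
#' Crossovers can be given explicitly (`crossovers`) or as counts
#' (`n_crossovers`) to be placed uniformly at random subject to a
#' minimum separation (`min_sep_bp`) — enforced both between crossovers
#' and from the chromosome ends, since tightly clustered or terminal
#' crossovers are not resolvable at any marker density.
#'
#' Grandparent-to-parent meioses are crossover-free, so the
#' grandparental origin of every parental allele is known and the truth
#' table is well defined at every SNP.
#'
#' @param chrom_length chromosome length in bp (default 25e6)
#' @param n_snps number of SNPs placed uniformly along the chromosome
#'   (default 110000, about 4.4 per kb; with founder allele frequencies
#'   uniform on `[0.05, 0.95]` about 23% of SNPs are informative per
#'   side, giving roughly one informative call per kb per side)
#' @param freq_range range of the per-SNP founder allele frequency,
#'   drawn uniformly (default `c(0.05, 0.95)`)
#' @param crossovers list with numeric `paternal` and `maternal`
#'   crossover positions in bp (strictly inside the chromosome), or
#'   `NULL` to draw them from `n_crossovers`
#' @param n_crossovers length-2 integer vector (paternal, maternal)
#'   counts of crossovers to place at random; ignored when `crossovers`
#'   is given
#' @param min_sep_bp minimum separation between random crossovers and
#'   from the chromosome ends (default 5e6)
#' @param error_rate probability that a genotype code is replaced by a
#'   uniformly chosen different code (default 0)
#' @param missing_rate probability that a genotype is missing
#'   (default 0)
#' @param seed mandatory integer seed; all randomness in
#'   [simulate_pedigree()] derives from it
#' @param scaffolds optional data frame (`size`, `orientation`) splitting
#'   the chromosome into scaffolds for coordinate-mapping tests;
#'   `NULL` gives one forward scaffold spanning the chromosome
#' @param gap inter-scaffold gap in bp used when laying out `scaffolds`
#' @return a `sim_config` list
#' @export
sim_config <- function(chrom_length = 25e6, n_snps = 110000L,
                       freq_range = c(0.05, 0.95), crossovers = NULL,
                       n_crossovers = c(1L, 1L), min_sep_bp = 5e6,
                       error_rate = 0, missing_rate = 0, seed,
                       scaffolds = NULL, gap = 0) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(chrom_length >= 1, n_snps >= 1,
            length(freq_range) == 2L, freq_range[1] > 0, freq_range[2] < 1,
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1, gap >= 0)
  if (!is.null(crossovers)) {
    stopifnot(is.list(crossovers),
              all(c("paternal", "maternal") %in% names(crossovers)))
    for (side in c("paternal", "maternal")) {
      x <- crossovers[[side]]
      if (length(x) && (any(x <= 1) || any(x >= chrom_length))) {
        stop("crossover positions must lie strictly inside (1, ",
             format_bp(chrom_length), ")")
      }
    }
  } else {
    stopifnot(length(n_crossovers) == 2L, all(n_crossovers >= 0))
  }
  if (!is.null(scaffolds)) {
    stopifnot(is.data.frame(scaffolds),
              all(c("size", "orientation") %in% names(scaffolds)))
    total <- sum(scaffolds$size) + gap * (nrow(scaffolds) - 1L)
    if (total != chrom_length) {
      stop("scaffold sizes (+ gaps) must sum to chrom_length; got ",
           format_bp(total))
    }
  }
  structure(list(chrom_length = chrom_length, n_snps = as.integer(n_snps),
                 freq_range = freq_range, crossovers = crossovers,
                 n_crossovers = n_crossovers, min_sep_bp = min_sep_bp,
                 error_rate = error_rate, missing_rate = missing_rate,
                 seed = as.integer(seed), scaffolds = scaffolds, gap = gap),
            class = "sim_config")
}

# uniform positions with pairwise and end separation, by rejection
draw_crossovers <- function(n, chrom_length, min_sep) {
  if (n == 0L) return(numeric(0))
  lo <- min(min_sep, chrom_length / 2)
  for (i in 1:10000) {
    x <- sort(round(stats::runif(n, lo, chrom_length - lo)))
    if (n == 1L || all(diff(x) >= min_sep)) return(x)
  }
  stop("cannot place ", n, " crossovers ", format_bp(min_sep),
       " bp apart on a ", format_bp(chrom_length), " bp chromosome")
}

#' Simulate a three-generation pedigree with planted crossovers
#'
#' Draws two founder haplotypes per grandparent from the per-SNP allele
#' frequency, passes one whole (crossover-free) gamete from each
#' grandparent to its child, then forms the offspring's two gametes by
#' recombining each parent's haplotype pair at the planted crossover
#' positions. The gamete's grandparental origin before the first
#' crossover is drawn at random; a crossover at bp `c` switches the
#' origin for all SNPs with position `> c`. Unphased 0/1/2 codes are
#' emitted for all seven individuals; genotyping error (replacement by a
#' uniformly chosen different code) is applied before missingness,
#' independently per SNP and individual.
#'
#' @param cfg a [sim_config()]
#' @return list with
#'   \describe{
#'     \item{`gt`}{a `genotype_table` for individuals `PGF`, `PGM`,
#'       `MGF`, `MGM`, `FA`, `MO`, `OFF`}
#'     \item{`smap`}{the matching [scaffold_map()] (chromosome `"1"`)}
#'     \item{`ped`}{the matching [pedigree_spec()]}
#'     \item{`truth`}{data frame with per-SNP chromosomal position and
#'       true origin (`GF`/`GM`) of the offspring allele on each side}
#'     \item{`crossovers`}{list of planted paternal / maternal crossover
#'       positions in bp}
#'   }
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$chrom_length
  n <- cfg$n_snps

  pos <- sort(sample.int(L, n, replace = FALSE))
  freq <- stats::runif(n, cfg$freq_range[1], cfg$freq_range[2])

  hap <- function() stats::rbinom(n, 1L, freq)
  founders <- list(pgf = list(hap(), hap()), pgm = list(hap(), hap()),
                   mgf = list(hap(), hap()), mgm = list(hap(), hap()))

  # crossover-free grandparental meioses: one whole haplotype each
  gamete_of <- function(gp) founders[[gp]][[sample.int(2L, 1L)]]
  fa_from_pgf <- gamete_of("pgf"); fa_from_pgm <- gamete_of("pgm")
  mo_from_mgf <- gamete_of("mgf"); mo_from_mgm <- gamete_of("mgm")

  xo <- cfg$crossovers
  if (is.null(xo)) {
    xo <- list(
      paternal = draw_crossovers(cfg$n_crossovers[1], L, cfg$min_sep_bp),
      maternal = draw_crossovers(cfg$n_crossovers[2], L, cfg$min_sep_bp))
  }
  xo <- lapply(xo, sort)

  # origin switches at each planted crossover; start side is random
  origin_track <- function(breaks) {
    n_switch <- findInterval(pos, breaks, left.open = TRUE)
    start <- sample(c("GF", "GM"), 1L)
    ifelse((n_switch %% 2L == 0L), start, setdiff(c("GF", "GM"), start))
  }
  pat_origin <- origin_track(xo$paternal)
  mat_origin <- origin_track(xo$maternal)

  off_pat <- ifelse(pat_origin == "GF", fa_from_pgf, fa_from_pgm)
  off_mat <- ifelse(mat_origin == "GF", mo_from_mgf, mo_from_mgm)

  codes <- cbind(
    PGF = founders$pgf[[1]] + founders$pgf[[2]],
    PGM = founders$pgm[[1]] + founders$pgm[[2]],
    MGF = founders$mgf[[1]] + founders$mgf[[2]],
    MGM = founders$mgm[[1]] + founders$mgm[[2]],
    FA = fa_from_pgf + fa_from_pgm,
    MO = mo_from_mgf + mo_from_mgm,
    OFF = off_pat + off_mat)

  if (cfg$error_rate > 0) {
    hit <- matrix(stats::runif(length(codes)) < cfg$error_rate,
                  nrow = n)
    shift <- matrix(sample.int(2L, length(codes), replace = TRUE),
                    nrow = n)
    codes[hit] <- (codes[hit] + shift[hit]) %% 3L
  }
  if (cfg$missing_rate > 0) {
    codes[matrix(stats::runif(length(codes)) < cfg$missing_rate,
                 nrow = n)] <- NA_integer_
  }

  layout <- sim_scaffold_layout(cfg)
  loc <- locate_on_scaffold(rep("1", n), pos, layout, cfg$gap)

  gt <- data.frame(scaffold = loc$scaffold, position = loc$scaffold_pos,
                   stringsAsFactors = FALSE)
  gt[colnames(codes)] <- lapply(seq_len(ncol(codes)),
                                function(j) as.integer(codes[, j]))
  ord <- order(gt$scaffold, gt$position)
  gt <- gt[ord, , drop = FALSE]
  rownames(gt) <- NULL
  gt <- validate_gt_table(gt)

  ped <- pedigree_spec("PGF", "PGM", "MGF", "MGM", "FA", "MO", "OFF")
  truth <- data.frame(chrom_pos = pos, paternal = pat_origin,
                      maternal = mat_origin, stringsAsFactors = FALSE)
  list(gt = gt, smap = layout, ped = ped, truth = truth, crossovers = xo)
}

sim_scaffold_layout <- function(cfg) {
  sc <- cfg$scaffolds
  if (is.null(sc)) {
    sc <- data.frame(size = cfg$chrom_length, orientation = "+")
  }
  scaffold_map(data.frame(
    scaffold = sprintf("sim_scaf%d", seq_len(nrow(sc))),
    size = sc$size, CHR = "1", order = seq_len(nrow(sc)),
    orientation = sc$orientation, stringsAsFactors = FALSE))
}

#' Thin a genotype table to a fraction of its SNPs
#'
#' Keeps a uniform random subset of SNP rows without replacement,
#' preserving the original order — the downsampling used to probe how
#' marker density limits crossover detection and precision.
#'
#' @param gt a `genotype_table`
#' @param fraction fraction of SNPs to keep, in `(0, 1]`
#' @param seed integer seed
#' @return a `genotype_table` with `round(fraction * n)` rows
#' @export
thin_snps <- function(gt, fraction, seed) {
  stopifnot(inherits(gt, "genotype_table"), fraction > 0, fraction <= 1)
  if (fraction == 1) return(gt)
  set.seed(seed)
  n <- nrow(gt)
  keep <- sort(sample.int(n, round(fraction * n)))
  out <- gt[keep, , drop = FALSE]
  rownames(out) <- NULL
  validate_gt_table(out)
}
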