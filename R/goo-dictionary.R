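#' Build the grandparent-of-origin dictionary
#'
#' Enumerates all `3^7 = 2187` seven-digit genotype strings (digits in
#' `{0,1,2}`, ordered paternal grandfather, paternal grandmother, maternal
#' grandfather, maternal grandmother, father, mother, offspring) and
#' classifies each by exhaustive enumeration of Mendelian transmission
#' assignments: each grandparent transmits one of its two alleles to its
#' child so that the parent's genotype is realised, and each parent
#' transmits one of its two alleles (tracked by grandparental source) so
#' that the offspring genotype is realised.
#'
#' A string is *possible* if at least one complete transmission assignment
#' exists; impossible strings (e.g. `0000002`) are absent from the
#' dictionary. A side is *informative* (`"GF"` or `"GM"`) only when every
#' consistent assignment routes the offspring's allele on that side through
#' the same grandparent; if assignments with both sources exist the side is
#' `"UNINFORMATIVE"`. In particular, a parent homozygous at the SNP always
#' yields an uninformative side, because the allele it transmits cannot be
#' attributed to one grandparent.
#'
#' The 0/1/2 coding counts alternative alleles: 0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternative.
#'
#' @return An object of class `goo_dictionary`: a list with
#'   \describe{
#'     \item{`table`}{data frame of possible strings with columns
#'       `string`, `paternal`, `maternal`}
#'     \item{`paternal`, `maternal`}{length-2187 character vectors indexed
#'       by base-3 key + 1 (`NA` for impossible strings), used for fast
#'       lookup}
#'   }
#' @examples
#' d <- build_goo_dictionary()
#' goo_lookup(d, "1000101")   # paternal allele traced to the grandfather
#' goo_lookup(d, "0000002")   # Mendelian-impossible: both sides NA
#' @export
build_goo_dictionary <- function() {
  digits <- as.matrix(expand.grid(off = 0:2, mo = 0:2, fa = 0:2,
                                  mgm = 0:2, mgf = 0:2, pgm = 0:2,
                                  pgf = 0:2))
  digits <- digits[, c("pgf", "pgm", "mgf", "mgm", "fa", "mo", "off")]
  n <- nrow(digits)

  # allele carried by genotype g under binary choice k (0 or 1):
  # hom gives its only allele, het gives allele k
  pick <- function(g, k) ifelse(g == 1L, k, g %/% 2L)

  possible <- rep(FALSE, n)
  pat_gf <- pat_gm <- mat_gf <- mat_gm <- rep(FALSE, n)

  for (c_pgf in 0:1) for (c_pgm in 0:1) for (c_mgf in 0:1) for (c_mgm in 0:1) {
    a_pgf <- pick(digits[, "pgf"], c_pgf)
    a_pgm <- pick(digits[, "pgm"], c_pgm)
    a_mgf <- pick(digits[, "mgf"], c_mgf)
    a_mgm <- pick(digits[, "mgm"], c_mgm)
    ok_fa <- a_pgf + a_pgm == digits[, "fa"]
    ok_mo <- a_mgf + a_mgm == digits[, "mo"]
    if (!any(ok_fa & ok_mo)) next
    for (t_fa in 1:2) for (t_mo in 1:2) {
      a_pat <- if (t_fa == 1L) a_pgf else a_pgm
      a_mat <- if (t_mo == 1L) a_mgf else a_mgm
      cons <- ok_fa & ok_mo & (a_pat + a_mat == digits[, "off"])
      possible <- possible | cons
      if (t_fa == 1L) pat_gf <- pat_gf | cons else pat_gm <- pat_gm | cons
      if (t_mo == 1L) mat_gf <- mat_gf | cons else mat_gm <- mat_gm | cons
    }
  }

  side <- function(gf, gm) {
    out <- rep(NA_character_, n)
    out[possible & gf & !gm] <- "GF"
    out[possible & !gf & gm] <- "GM"
    out[possible & gf & gm] <- "UNINFORMATIVE"
    out
  }
  paternal <- side(pat_gf, pat_gm)
  maternal <- side(mat_gf, mat_gm)

  key <- as.vector(digits %*% 3L^(6:0))  # base-3 value of the string
  ord <- order(key)
  strings <- apply(digits, 1L, paste0, collapse = "")

  pat_by_key <- mat_by_key <- rep(NA_character_, 3L^7)
  pat_by_key[key + 1L] <- paternal
  mat_by_key[key + 1L] <- maternal

  tab <- data.frame(string = strings[ord],
                    paternal = paternal[ord],
                    maternal = maternal[ord],
                    stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$paternal), , drop = FALSE]
  rownames(tab) <- NULL

  structure(list(table = tab, paternal = pat_by_key, maternal = mat_by_key),
            class = "goo_dictionary")
}

#' Look up genotype strings in a GoO dictionary
#'
#' @param dict a [build_goo_dictionary()] object
#' @param strings character vector of 7-digit strings over `{0,1,2}`
#' @return data frame with columns `string`, `paternal`, `maternal`;
#'   both side columns are `NA` for Mendelian-impossible strings.
#' @export
goo_lookup <- function(dict, strings) {
  stopifnot(inherits(dict, "goo_dictionary"))
  bad <- !grepl("^[012]{7}$", strings)
  if (any(bad)) {
    stop("not a 7-digit {0,1,2} genotype string: ",
         paste(unique(strings[bad]), collapse = ", "))
  }
  key <- goo_string_key(strings)
  data.frame(string = strings,
             paternal = dict$paternal[key + 1L],
             maternal = dict$maternal[key + 1L],
             stringsAsFactors = FALSE)
}

# base-3 key of 7-digit strings (integer in [0, 2186])
goo_string_key <- function(strings) {
  m <- matrix(as.integer(charToRaw(paste0(strings, collapse = "")))
              - utf8ToInt("0"), ncol = 7L, byrow = TRUE)
  as.vector(m %*% 3L^(6:0))
}

#' @export
print.goo_dictionary <- function(x, ...) {
  cat("GoO dictionary:", nrow(x$table), "possible genotype strings",
      sprintf("(of %d), %d impossible\n", 3L^7, 3L^7 - nrow(x$table)))
  cat(" paternal side: ",
      sum(x$table$paternal != "UNINFORMATIVE"), "informative strings\n")
  cat(" maternal side: ",
      sum(x$table$maternal != "UNINFORMATIVE"), "informative strings\n")
  invisible(x)
}

#' Export / import the GoO dictionary as a text table
#'
#' The export is a two-column tab-separated table (`string`,
#' `paternal;maternal`) for auditability; [build_goo_dictionary()]
#' regenerates it deterministically.
#'
#' @param dict a `goo_dictionary`
#' @param path output (input) file path
#' @return `write_goo_dictionary()` returns `path` invisibly;
#'   `read_goo_dictionary()` returns a `goo_dictionary`.
#' @export
write_goo_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "goo_dictionary"))
  tab <- data.frame(string = dict$table$string,
                    origin = paste(dict$table$paternal, dict$table$maternal,
                                   sep = ";"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_goo_dictionary
#' @export
read_goo_dictionary <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!identical(names(tab), c("string", "origin"))) {
    stop("not a GoO dictionary export: expected columns 'string', 'origin'")
  }
  parts <- strsplit(tab$origin, ";", fixed = TRUE)
  pat_by_key <- mat_by_key <- rep(NA_character_, 3L^7)
  key <- goo_string_key(tab$string)
  pat_by_key[key + 1L] <- vapply(parts, `[`, "", 1L)
  mat_by_key[key + 1L] <- vapply(parts, `[`, "", 2L)
  table <- data.frame(string = tab$string,
                      paternal = pat_by_key[key + 1L],
                      maternal = mat_by_key[key + 1L],
                      stringsAsFactors = FALSE)
  structure(list(table = table, paternal = pat_by_key, maternal = mat_by_key),
            class = "goo_dictionary")
}
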