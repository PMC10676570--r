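#' Read a 0/1/2 genotype table
#'
#' The genotype table is a delimited text file (tab or comma separated,
#' auto-detected from the header line) with columns `scaffold`,
#' `position`, then one column per individual. Codes are 0 (homozygous
#' reference), 1 (heterozygous), 2 (homozygous alternative); missing
#' genotypes may be written `-1` or `NA` and are stored as `NA`.
#'
#' @param path file path
#' @return a `genotype_table`: a data frame with character `scaffold`,
#'   integer `position` and one integer column per individual.
#' @seealso [convert_vcftools_gt()] to build such a table from a
#'   `VCFtools --extract-FORMAT-info GT` extract.
#' @export
read_gt_table <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "")
  if (ncol(df) < 3L ||
      !identical(tolower(names(df)[1:2]), c("scaffold", "position"))) {
    stop("malformed genotype header: expected columns 'scaffold', ",
         "'position', then one column per individual")
  }
  names(df)[1:2] <- c("scaffold", "position")
  pos <- suppressWarnings(as.integer(df$position))
  bad <- is.na(pos) & !is.na(df$position)
  if (any(bad)) {
    stop("non-integer position at row ", which(bad)[1L], ": '",
         df$position[which(bad)[1L]], "'")
  }
  inds <- names(df)[-(1:2)]
  if (anyDuplicated(inds)) {
    stop("duplicate individual IDs in header: ",
         paste(unique(inds[duplicated(inds)]), collapse = ", "))
  }
  codes <- lapply(df[inds], parse_codes, path = path)
  gt <- data.frame(scaffold = df$scaffold, position = pos,
                   stringsAsFactors = FALSE, check.names = FALSE)
  gt[inds] <- codes
  validate_gt_table(gt)
}

parse_codes <- function(x, path) {
  x[x %in% c("NA", "-1", "")] <- NA_character_
  bad <- !is.na(x) & !(x %in% c("0", "1", "2"))
  if (any(bad)) {
    stop("genotype code outside {0,1,2,missing} at row ", which(bad)[1L],
         ": '", x[which(bad)[1L]], "' in ", path)
  }
  as.integer(x)
}

validate_gt_table <- function(gt) {
  key <- paste(gt$scaffold, gt$position)
  if (anyDuplicated(key)) {
    stop("duplicate (scaffold, position) pairs: ",
         paste(utils::head(unique(key[duplicated(key)]), 5L),
               collapse = "; "))
  }
  if (nrow(gt) && any(gt$position < 1L)) {
    stop("positions must be positive integers")
  }
  class(gt) <- c("genotype_table", "data.frame")
  gt
}

#' Individual IDs of a genotype table
#' @param gt a `genotype_table`
#' @return character vector of individual column names
#' @export
gt_individuals <- function(gt) setdiff(names(gt), c("scaffold", "position"))

#' Write a 0/1/2 genotype table
#'
#' Missing codes are written as `-1`. Output is tab-separated, UTF-8,
#' Unix newlines; [read_gt_table()] round-trips it exactly.
#'
#' @param gt a `genotype_table`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_gt_table <- function(gt, path) {
  out <- as.data.frame(gt)
  for (id in gt_individuals(gt)) {
    out[[id]] <- ifelse(is.na(out[[id]]), -1L, out[[id]])
  }
  write_tsv(out, path)
}

#' Convert a VCFtools GT extract to 0/1/2 coding
#'
#' Reads the output of `vcftools --extract-FORMAT-info GT` (columns
#' `CHROM`, `POS`, then one diploid genotype per individual such as
#' `0/0`, `0/1`, `1|0`, `./.`) and recodes it: `0/0` becomes 0,
#' heterozygotes (phased or unphased) become 1, `1/1` becomes 2, and any
#' genotype containing `.` becomes missing. Records involving an allele
#' index above 1 (multi-allelic sites) are dropped; the number dropped is
#' reported with a message and attached as attribute `n_dropped`.
#'
#' @param path file path of the GT extract
#' @return a `genotype_table` (see [read_gt_table()]) with attribute
#'   `n_dropped`
#' @export
convert_vcftools_gt <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "")
  if (ncol(df) < 3L || !identical(toupper(names(df)[1:2]), c("CHROM", "POS"))) {
    stop("malformed GT extract header: expected 'CHROM', 'POS', then ",
         "individual columns")
  }
  inds <- names(df)[-(1:2)]
  tok <- as.matrix(df[inds])
  ok <- grepl("^([0-9.]+)[/|]([0-9.]+)$", tok) | tok == "."
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop("unparseable genotype token at line ", bad[1L] + 1L, ": '",
         tok[bad[1L], bad[2L]], "'")
  }
  a1 <- sub("^([0-9.]+)[/|].*$", "\\1", tok)
  a2 <- sub("^.*[/|]([0-9.]+)$", "\\1", tok)
  a1[tok == "."] <- a2[tok == "."] <- "."
  biallelic <- matrix(a1 %in% c("0", "1", ".") & a2 %in% c("0", "1", "."),
                      nrow = nrow(tok))
  keep <- rowSums(!biallelic) == 0L
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message(n_dropped, " multi-allelic record(s) dropped")
  }
  a1 <- matrix(a1, nrow = nrow(tok))[keep, , drop = FALSE]
  a2 <- matrix(a2, nrow = nrow(tok))[keep, , drop = FALSE]
  code <- matrix(NA_integer_, nrow = nrow(a1), ncol = ncol(a1))
  nm <- a1 != "." & a2 != "."
  code[nm] <- as.integer(a1[nm]) + as.integer(a2[nm])
  pos <- suppressWarnings(as.integer(df$POS[keep]))
  if (anyNA(pos)) stop("non-integer POS at row ", which(is.na(pos))[1L])
  gt <- data.frame(scaffold = df$CHROM[keep], position = pos,
                   stringsAsFactors = FALSE, check.names = FALSE)
  gt[inds] <- lapply(seq_along(inds), function(j) code[, j])
  gt <- validate_gt_table(gt)
  attr(gt, "n_dropped") <- n_dropped
  gt
}

#' Read a scaffold file
#'
#' The scaffold file places scaffolds on chromosomes. It must carry
#' exactly the (case sensitive) headings `scaffold` (label), `size` (bp),
#' `CHR` (chromosome), `order` (rank of the scaffold on its chromosome)
#' and `orientation` (`+` or `-`; `-` means the scaffold's local
#' coordinates run opposite to the chromosome). Extra columns are dropped
#' with a warning; rows may arrive in any order.
#'
#' @param path file path (tab- or comma-separated, auto-detected)
#' @return a `scaffold_map` data frame
#' @export
read_scaffold_map <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "")
  required <- c("scaffold", "size", "CHR", "order", "orientation")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("scaffold file lacks required heading(s) (case sensitive): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("ignoring extra scaffold-file column(s): ",
            paste(extra, collapse = ", "))
  }
  df <- df[required]
  df$size <- suppressWarnings(as.numeric(df$size))
  df$order <- suppressWarnings(as.integer(df$order))
  if (anyNA(df$size) || any(df$size < 1)) {
    stop("scaffold 'size' must be a positive integer")
  }
  if (anyNA(df$order)) stop("scaffold 'order' must be an integer")
  scaffold_map(df)
}

#' Construct a scaffold map from a data frame
#'
#' @param df data frame with columns `scaffold`, `size`, `CHR`, `order`,
#'   `orientation`
#' @return a validated `scaffold_map`, sorted by `CHR` then `order`
#' @export
scaffold_map <- function(df) {
  stopifnot(all(c("scaffold", "size", "CHR", "order", "orientation")
                %in% names(df)))
  if (!all(df$orientation %in% c("+", "-"))) {
    stop("orientation must be '+' or '-', got: ",
         paste(unique(setdiff(df$orientation, c("+", "-"))), collapse = ", "))
  }
  dup <- tapply(df$order, df$CHR, anyDuplicated)
  if (any(dup > 0L)) {
    stop("duplicate scaffold order within CHR ",
         paste(names(dup)[dup > 0L], collapse = ", "))
  }
  if (anyDuplicated(df$scaffold)) {
    stop("duplicate scaffold label: ",
         paste(unique(df$scaffold[duplicated(df$scaffold)]), collapse = ", "))
  }
  df <- df[order(df$CHR, df$order), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("scaffold_map", "data.frame")
  df
}

# first header line decides the delimiter: tab wins over comma
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty file: ", path)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")  # binary keeps Unix newlines everywhere
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
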