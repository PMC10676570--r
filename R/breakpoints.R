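#' Parameters for the proportional difference (PD) scan
#'
#' The PD statistic at a boundary between consecutive informative calls
#' is `D = |p_GF(left) - p_GF(right)|`, where `p_GF` is the proportion of
#' grandfather-origin calls in a flanking window of `radius` calls.
#' Windows are counted in informative calls, not bp, so boundaries within
#' `radius` calls of either chromosome end cannot be evaluated (a larger
#' radius limits detection near chromosome ends). By complementarity the
#' same value is obtained from the grandmother-origin proportions.
#'
#' @param radius flanking window size in calls (default 550)
#' @param step coarse scan stride in calls (default 17)
#' @param fine_step refinement stride in calls (default 1)
#' @param threshold minimum `D` to report a crossover (default 0.9)
#' @return a `pd_params` list
#' @export
pd_params <- function(radius = 550L, step = 17L, fine_step = 1L,
                      threshold = 0.9) {
  stopifnot(radius >= 1, step >= 1, fine_step >= 1, fine_step <= step,
            threshold > 0, threshold <= 1)
  structure(list(radius = as.integer(radius), step = as.integer(step),
                 fine_step = as.integer(fine_step), threshold = threshold),
            class = "pd_params")
}

# D at boundary indices b (boundary b sits between calls b and b+1);
# gf_cum = c(0, cumsum(origin == "GF"))
pd_d_at <- function(gf_cum, radius, b) {
  p_left <- (gf_cum[b + 1L] - gf_cum[b - radius + 1L]) / radius
  p_right <- (gf_cum[b + radius + 1L] - gf_cum[b + 1L]) / radius
  abs(p_left - p_right)
}

#' Proportional-difference profile along one parental side
#'
#' Evaluates the PD statistic at boundaries spaced `params$step` calls
#' apart (boundary `i` lies between calls `i` and `i+1`; only boundaries
#' with full flanking windows are evaluable). The bp coordinate of a
#' boundary is the floor of the midpoint between its two flanking calls.
#'
#' @param side_calls one side of a [infer_goo()] call set: data frame
#'   with columns `chrom_pos` and `origin`, sorted by position
#' @param params a [pd_params()] object
#' @param at optional integer vector of boundary indices to evaluate
#'   (overrides the coarse stride)
#' @return data frame with columns `boundary` (call index), `midpoint_bp`
#'   and `D`; zero rows (with a warning) when fewer than `2 * radius`
#'   calls are available
#' @export
pd_profile <- function(side_calls, params = pd_params(), at = NULL) {
  stopifnot(inherits(params, "pd_params"))
  n <- nrow(side_calls)
  r <- params$radius
  if (n < 2L * r) {
    warning("fewer than 2*radius = ", 2L * r,
            " informative calls; no PD boundary evaluable")
    return(data.frame(boundary = integer(), midpoint_bp = numeric(),
                      D = numeric()))
  }
  if (is.null(at)) at <- seq.int(r, n - r, by = params$step)
  at <- sort(unique(as.integer(at)))
  stopifnot(all(at >= r & at <= n - r))
  gf_cum <- c(0, cumsum(side_calls$origin == "GF"))
  data.frame(
    boundary = at,
    midpoint_bp = floor((side_calls$chrom_pos[at] +
                           side_calls$chrom_pos[at + 1L]) / 2),
    D = pd_d_at(gf_cum, r, at))
}

#' Locate crossovers with the PD algorithm
#'
#' Scans boundaries at the coarse stride, keeps local maxima of the PD
#' statistic that reach the threshold, then refines each candidate by
#' re-evaluating every boundary at the fine stride within one coarse
#' step on either side. The refined argmax is reported; on a tie (a
#' plateau of maximal `D`, generic in clean data) the central boundary
#' of the tied stretch is taken. Candidates refining to the same
#' boundary are merged. The reported position is the floor of the
#' midpoint between the two calls flanking the refined boundary.
#'
#' @inheritParams pd_profile
#' @return data frame with columns `position` (bp), `boundary`, `D`
#' @export
pd_scan <- function(side_calls, params = pd_params()) {
  n <- nrow(side_calls)
  r <- params$radius
  if (n < 2L * r) {
    warning("fewer than 2*radius = ", 2L * r,
            " informative calls; PD scan finds nothing")
    return(data.frame(position = numeric(), boundary = integer(),
                      D = numeric()))
  }
  prof <- pd_profile(side_calls, params)
  d <- prof$D
  k <- length(d)
  left <- c(-Inf, d[-k])
  right <- c(d[-1L], -Inf)
  cand <- which(d >= params$threshold & d >= left & d >= right)
  if (!length(cand)) {
    return(data.frame(position = numeric(), boundary = integer(),
                      D = numeric()))
  }

  gf_cum <- c(0, cumsum(side_calls$origin == "GF"))
  refined <- lapply(prof$boundary[cand], function(b0) {
    at <- seq.int(max(r, b0 - params$step), min(n - r, b0 + params$step),
                  by = params$fine_step)
    dv <- pd_d_at(gf_cum, r, at)
    tied <- at[dv == max(dv)]
    b_lo <- min(tied)
    b_hi <- max(tied)
    # central position of the tied plateau's flanking interval
    pos <- floor((side_calls$chrom_pos[b_lo] +
                    side_calls$chrom_pos[b_hi + 1L]) / 2)
    c(pos = pos, boundary = floor((b_lo + b_hi) / 2), D = max(dv))
  })
  out <- as.data.frame(do.call(rbind, refined))
  names(out) <- c("position", "boundary", "D")
  out <- out[!duplicated(out$position), , drop = FALSE]
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run-length segmentation of origin calls (CCS)
#'
#' Splits one side's ordered informative calls into maximal runs of
#' identical grandparental origin. The cumulative continuity score (CCS)
#' of a run is its length in calls.
#'
#' @inheritParams pd_profile
#' @return data frame with one row per run: `origin`, `start_idx`,
#'   `end_idx`, `start_bp`, `end_bp`, `ccs`
#' @export
ccs_runs <- function(side_calls) {
  n <- nrow(side_calls)
  if (!n) {
    return(data.frame(origin = character(), start_idx = integer(),
                      end_idx = integer(), start_bp = numeric(),
                      end_bp = numeric(), ccs = integer()))
  }
  r <- rle(side_calls$origin)
  end_idx <- cumsum(r$lengths)
  start_idx <- end_idx - r$lengths + 1L
  data.frame(origin = r$values, start_idx = start_idx, end_idx = end_idx,
             start_bp = side_calls$chrom_pos[start_idx],
             end_bp = side_calls$chrom_pos[end_idx],
             ccs = r$lengths, stringsAsFactors = FALSE)
}

#' Locate crossovers with the CCS algorithm
#'
#' Runs shorter than the threshold are treated as noise (genotyping
#' errors disrupt the continuity of informative alleles) and dropped.
#' Between each pair of consecutive kept runs of opposite origin one
#' crossover is called, at the floor of the midpoint between the last
#' call of the left run and the first call of the right run; intervening
#' noise runs are absorbed into that interval. Consecutive kept runs of
#' the same origin call nothing.
#'
#' @inheritParams pd_profile
#' @param threshold minimum run length in calls to keep (default 50)
#' @return data frame with columns `position` (bp), `left_ccs`,
#'   `right_ccs`
#' @export
ccs_scan <- function(side_calls, threshold = 50L) {
  stopifnot(threshold >= 1)
  runs <- ccs_runs(side_calls)
  kept <- runs[runs$ccs >= threshold, , drop = FALSE]
  if (nrow(kept) < 2L) {
    return(data.frame(position = numeric(), left_ccs = integer(),
                      right_ccs = integer()))
  }
  i <- which(kept$origin[-nrow(kept)] != kept$origin[-1L])
  out <- data.frame(
    position = floor((kept$end_bp[i] + kept$start_bp[i + 1L]) / 2),
    left_ccs = kept$ccs[i], right_ccs = kept$ccs[i + 1L])
  rownames(out) <- NULL
  out
}

#' Precision of a crossover call from the reverse local density
#'
#' Counts the informative calls of the analysed side within a window of
#' `interval_bp` centred on the position (`[pos - interval_bp/2,
#' pos + interval_bp/2)`, truncated at the chromosome ends) and returns
#' `interval_bp / n`, rounded to the nearest bp — the genomic size
#' covered by one informative SNP near the call. Smaller is better.
#' With no informative call in the window the precision is undefined
#' (`NA`).
#'
#' @inheritParams pd_profile
#' @param position chromosomal bp of the call (vectorised)
#' @param interval_bp window size in bp (default 100000)
#' @param chrom_length chromosome length used for end truncation;
#'   defaults to the last call position
#' @return numeric vector of precisions in bp (`NA` where no call falls
#'   in the window)
#' @export
precision_estimate <- function(side_calls, position, interval_bp = 1e5,
                               chrom_length = NULL) {
  stopifnot(interval_bp >= 1)
  if (is.null(chrom_length)) {
    chrom_length <- if (nrow(side_calls)) max(side_calls$chrom_pos) else 1
  }
  vapply(position, function(p) {
    lo <- max(1, p - interval_bp / 2)
    hi <- min(chrom_length + 1, p + interval_bp / 2)
    n <- sum(side_calls$chrom_pos >= lo & side_calls$chrom_pos < hi)
    if (n == 0L) NA_real_ else round(interval_bp / n)
  }, numeric(1))
}

#' Assemble crossover calls with precision and scaffold coordinates
#'
#' Turns raw PD / CCS positions into full crossover-call records:
#' precision from [precision_estimate()] and scaffold plus orientation
#' from the inverse coordinate lookup.
#'
#' @param positions numeric vector of chromosomal call positions (bp)
#' @param side_calls the side's informative calls (for the precision
#'   window)
#' @param offspring,chromosome,origin_side,algorithm call metadata;
#'   `origin_side` is `"Paternal"` or `"Maternal"`, `algorithm` `"PD"`
#'   or `"CCS"`
#' @param smap a [scaffold_map()]
#' @param interval_bp precision window in bp (default 100000)
#' @param gap inter-scaffold gap in bp
#' @param chrom_length chromosome length for window truncation
#' @return a `recomb_calls` data frame (see [write_calls_table()])
#' @export
attach_precision <- function(positions, side_calls, offspring, chromosome,
                             origin_side, algorithm, smap,
                             interval_bp = 1e5, gap = 0,
                             chrom_length = NULL) {
  if (!length(positions)) return(empty_calls_table())
  loc <- locate_on_scaffold(chromosome, positions, smap, gap)
  prec <- precision_estimate(side_calls, positions, interval_bp,
                             chrom_length)
  calls <- data.frame(
    offspring = offspring, chromosome = chromosome,
    origin = origin_side, algorithm = algorithm,
    scaffold = loc$scaffold, orientation = loc$orientation,
    chromosomal_position = positions, precision = prec,
    stringsAsFactors = FALSE)
  class(calls) <- c("recomb_calls", "data.frame")
  calls
}

empty_calls_table <- function() {
  calls <- data.frame(
    offspring = character(), chromosome = character(), origin = character(),
    algorithm = character(), scaffold = character(),
    orientation = character(), chromosomal_position = numeric(),
    precision = numeric(), stringsAsFactors = FALSE)
  class(calls) <- c("recomb_calls", "data.frame")
  calls
}

#' Locate crossovers on both parental sides of a call set
#'
#' Convenience wrapper running [pd_scan()] and/or [ccs_scan()] on the
#' paternal and maternal call sequences of one offspring/chromosome and
#' attaching precision and scaffold coordinates to every call.
#'
#' @param calls a [infer_goo()] `goo_calls` object
#' @param smap a [scaffold_map()]
#' @param algorithm `"pd"`, `"ccs"` or `"both"`
#' @param pd a [pd_params()] object
#' @param ccs_threshold minimum CCS run length (default 50)
#' @param interval_bp precision window in bp (default 100000)
#' @param gap inter-scaffold gap in bp
#' @return a `recomb_calls` data frame sorted by offspring, chromosome,
#'   origin, algorithm and position
#' @export
locate_crossovers <- function(calls, smap, algorithm = c("both", "pd", "ccs"),
                              pd = pd_params(), ccs_threshold = 50L,
                              interval_bp = 1e5, gap = 0) {
  stopifnot(inherits(calls, "goo_calls"))
  algorithm <- match.arg(algorithm)
  chrom_length <- chromosome_lengths(smap, gap)[[calls$chromosome]]
  out <- empty_calls_table()
  for (side_name in c("paternal", "maternal")) {
    side <- calls[[side_name]]
    side_label <- if (side_name == "paternal") "Paternal" else "Maternal"
    if (algorithm %in% c("both", "pd")) {
      hits <- if (nrow(side) < 2L * pd$radius) {
        data.frame(position = numeric())
      } else pd_scan(side, pd)
      out <- rbind(out, attach_precision(
        hits$position, side, calls$offspring, calls$chromosome,
        side_label, "PD", smap, interval_bp, gap, chrom_length))
    }
    if (algorithm %in% c("both", "ccs")) {
      hits <- ccs_scan(side, ccs_threshold)
      out <- rbind(out, attach_precision(
        hits$position, side, calls$offspring, calls$chromosome,
        side_label, "CCS", smap, interval_bp, gap, chrom_length))
    }
  }
  sort_calls(out)
}

sort_calls <- function(calls) {
  calls <- calls[order(calls$offspring, calls$chromosome, calls$origin,
                       calls$algorithm, calls$chromosomal_position), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("recomb_calls", "data.frame")
  calls
}

#' Write / read the crossover calls table
#'
#' Tab-separated with columns `Offspring`, `Chromosome`, `Origin`,
#' `Algorithm`, `Scaffold`, `Orientation`, `Chromosomal_position_bp`,
#' `Precision_bp`; undefined precision is written `NA`. Rows are sorted
#' by offspring, chromosome, origin, algorithm and position.
#'
#' @param calls a `recomb_calls` data frame
#' @param path file path
#' @return `write_calls_table()` returns `path` invisibly;
#'   `read_calls_table()` returns a `recomb_calls` data frame.
#' @export
write_calls_table <- function(calls, path) {
  stopifnot(inherits(calls, "recomb_calls"))
  calls <- sort_calls(calls)
  out <- data.frame(
    Offspring = calls$offspring, Chromosome = calls$chromosome,
    Origin = calls$origin, Algorithm = calls$algorithm,
    Scaffold = calls$scaffold, Orientation = calls$orientation,
    Chromosomal_position_bp = format_bp(calls$chromosomal_position),
    Precision_bp = ifelse(is.na(calls$precision), "NA",
                          format_bp(calls$precision)),
    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' @rdname write_calls_table
#' @export
read_calls_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("Offspring", "Chromosome", "Origin", "Algorithm", "Scaffold",
            "Orientation", "Chromosomal_position_bp", "Precision_bp")
  if (!all(need %in% names(df))) {
    stop("not a crossover calls table: expected columns ",
         paste(need, collapse = ", "))
  }
  calls <- data.frame(
    offspring = df$Offspring, chromosome = df$Chromosome,
    origin = df$Origin, algorithm = df$Algorithm,
    scaffold = df$Scaffold, orientation = df$Orientation,
    chromosomal_position = as.numeric(df$Chromosomal_position_bp),
    precision = suppressWarnings(as.numeric(df$Precision_bp)),
    stringsAsFactors = FALSE)
  sort_calls(calls)
}
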