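#' Configuration for a batch analysis run
#'
#' Bundles input paths, selections and algorithm parameters for
#' [run_analysis()], mirroring the command-line interface.
#'
#' @param genotype path to the 0/1/2 genotype table
#' @param scaffold path to the scaffold file
#' @param pedigree path to the pedigree YAML, or a [pedigree_spec()]
#' @param out_dir output directory (created if absent)
#' @param offspring offspring IDs to analyse; `NULL` means all listed in
#'   the pedigree spec
#' @param chromosomes chromosome labels to analyse; `NULL` means all in
#'   the scaffold file
#' @param algorithm `"pd"`, `"ccs"` or `"both"`
#' @param pd a [pd_params()] object
#' @param ccs_threshold minimum CCS run length (default 50)
#' @param interval_bp precision window in bp (default 100000)
#' @param gap inter-scaffold gap in bp (default 0)
#' @param plots write static plots per chromosome (default `FALSE`)
#' @param plot_seed seed for the y-jitter in the GoO scatter
#' @return a `run_config` list
#' @export
run_config <- function(genotype, scaffold, pedigree, out_dir,
                       offspring = NULL, chromosomes = NULL,
                       algorithm = c("both", "pd", "ccs"),
                       pd = pd_params(), ccs_threshold = 50L,
                       interval_bp = 1e5, gap = 0, plots = FALSE,
                       plot_seed = 1L) {
  structure(list(genotype = genotype, scaffold = scaffold,
                 pedigree = pedigree, out_dir = out_dir,
                 offspring = offspring, chromosomes = chromosomes,
                 algorithm = match.arg(algorithm), pd = pd,
                 ccs_threshold = ccs_threshold, interval_bp = interval_bp,
                 gap = gap, plots = plots, plot_seed = plot_seed),
            class = "run_config")
}

#' Run the full crossover analysis over offspring and chromosomes
#'
#' For every selected offspring and chromosome: GoO inference, the
#' selected crossover algorithm(s), precision attachment, and table
#' output. Writes to `cfg$out_dir`:
#' `crossover_calls.tsv` (all calls), `run_summary.tsv` (per
#' offspring/chromosome SNP and call accounting), and per combination
#' `goo_<offspring>_chr<CHR>.tsv`, `density_<offspring>_chr<CHR>.tsv`,
#' `pd_profile_<offspring>_chr<CHR>.tsv` and
#' `ccs_runs_<offspring>_chr<CHR>.tsv`. Re-running with identical
#' inputs and configuration reproduces all tables byte for byte.
#'
#' @param cfg a [run_config()]
#' @return invisibly, a result bundle: list with `calls`, `summary`,
#'   and per-combination `details` (GoO call sets, density and profile
#'   tables)
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  gt <- if (inherits(cfg$genotype, "genotype_table")) cfg$genotype
        else read_gt_table(cfg$genotype)
  smap <- if (inherits(cfg$scaffold, "scaffold_map")) cfg$scaffold
          else read_scaffold_map(cfg$scaffold)
  ped <- if (inherits(cfg$pedigree, "pedigree_spec")) cfg$pedigree
         else read_pedigree_spec(cfg$pedigree)
  check_ped_in_gt(ped, gt)

  offspring <- cfg$offspring %||% ped$offspring
  bad_off <- setdiff(offspring, ped$offspring)
  if (length(bad_off)) {
    stop("offspring not in the pedigree spec: ",
         paste(bad_off, collapse = ", "))
  }
  chromosomes <- cfg$chromosomes %||% unique(smap$CHR)
  bad_chr <- setdiff(chromosomes, smap$CHR)
  if (length(bad_chr)) {
    stop("chromosome(s) absent from the scaffold file: ",
         paste(bad_chr, collapse = ", "))
  }
  if (!length(offspring) || !length(chromosomes)) {
    stop("empty offspring or chromosome selection")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  dict <- build_goo_dictionary()
  all_calls <- empty_calls_table()
  summary_rows <- list()
  details <- list()

  for (off in offspring) {
    for (chr in chromosomes) {
      goo <- infer_goo(gt, ped, dict, smap, chr, off, cfg$gap)
      chrom_len <- chromosome_lengths(smap, cfg$gap)[[chr]]
      n_pat <- nrow(goo$paternal)
      n_mat <- nrow(goo$maternal)
      if (n_pat + n_mat == 0L) {
        warning("no informative calls for offspring ", off,
                " on chromosome ", chr)
      }
      calls <- withCallingHandlers(
        locate_crossovers(goo, smap, cfg$algorithm, cfg$pd,
                          cfg$ccs_threshold, cfg$interval_bp, cfg$gap),
        warning = function(w) {
          message("offspring ", off, " chromosome ", chr, ": ",
                  conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      all_calls <- rbind(all_calls, calls)

      dens <- informative_density(goo, chrom_length = chrom_len)
      tag <- sprintf("%s_chr%s", off, chr)
      write_goo_table(goo, file.path(cfg$out_dir,
                                     sprintf("goo_%s.tsv", tag)))
      write_tsv(dens, file.path(cfg$out_dir,
                                sprintf("density_%s.tsv", tag)))

      profiles <- list()
      for (side_name in c("paternal", "maternal")) {
        side <- goo[[side_name]]
        if (cfg$algorithm %in% c("both", "pd") &&
            nrow(side) >= 2L * cfg$pd$radius) {
          prof <- pd_profile(side, cfg$pd)
          if (nrow(prof)) {
            profiles[[paste0("pd_", side_name)]] <-
              cbind(side = side_name, prof)
          }
        }
        if (cfg$algorithm %in% c("both", "ccs")) {
          runs <- ccs_runs(side)
          if (nrow(runs)) {
            profiles[[paste0("ccs_", side_name)]] <-
              cbind(side = side_name, runs)
          }
        }
      }
      pd_tab <- do.call(rbind, profiles[grep("^pd_", names(profiles))])
      ccs_tab <- do.call(rbind, profiles[grep("^ccs_", names(profiles))])
      if (!is.null(pd_tab)) {
        write_tsv(pd_tab, file.path(cfg$out_dir,
                                    sprintf("pd_profile_%s.tsv", tag)))
      }
      if (!is.null(ccs_tab)) {
        write_tsv(ccs_tab, file.path(cfg$out_dir,
                                     sprintf("ccs_runs_%s.tsv", tag)))
      }

      summary_rows[[tag]] <- data.frame(
        offspring = off, chromosome = chr,
        n_snps = goo$counts$n_snps, n_missing = goo$counts$n_missing,
        n_impossible = goo$counts$n_impossible,
        n_informative_paternal = n_pat, n_informative_maternal = n_mat,
        n_calls_pd = sum(calls$algorithm == "PD"),
        n_calls_ccs = sum(calls$algorithm == "CCS"),
        stringsAsFactors = FALSE)
      message(sprintf(
        "offspring %s chr %s: %d SNPs (%d missing, %d impossible), %d/%d informative pat/mat, %d PD + %d CCS calls",
        off, chr, goo$counts$n_snps, goo$counts$n_missing,
        goo$counts$n_impossible, n_pat, n_mat,
        sum(calls$algorithm == "PD"), sum(calls$algorithm == "CCS")))

      details[[tag]] <- list(goo = goo, density = dens,
                             pd_profile = pd_tab, ccs_runs = ccs_tab,
                             chrom_length = chrom_len)
    }
  }

  all_calls <- sort_calls(all_calls)
  write_calls_table(all_calls, file.path(cfg$out_dir,
                                         "crossover_calls.tsv"))
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  write_tsv(summary, file.path(cfg$out_dir, "run_summary.tsv"))

  bundle <- list(calls = all_calls, summary = summary, details = details,
                 config = cfg)
  if (isTRUE(cfg$plots)) render_plots(bundle, cfg$out_dir, cfg$plot_seed)
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
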