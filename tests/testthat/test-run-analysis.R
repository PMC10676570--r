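# shared small simulated dataset written to disk once per file
local_sim_inputs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  cfg <- sim_config(chrom_length = 4e6, n_snps = 16000L, seed = 77,
                    crossovers = list(paternal = 1.8e6, maternal = 2.4e6),
                    error_rate = 0.003, missing_rate = 0.005)
  sim <- simulate_pedigree(cfg)
  paths <- list(gt = file.path(dir, "genotypes.tsv"),
                smap = file.path(dir, "scaffolds.tsv"),
                ped = file.path(dir, "pedigree.yaml"),
                out = file.path(dir, "out"))
  write_gt_table(sim$gt, paths$gt)
  utils::write.table(as.data.frame(sim$smap), paths$smap, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(paternal_grandfather = "PGF",
                        paternal_grandmother = "PGM",
                        maternal_grandfather = "MGF",
                        maternal_grandmother = "MGM",
                        father = "FA", mother = "MO", offspring = "OFF"),
                   paths$ped)
  paths$sim <- sim
  paths
}

small_pd <- pd_params(radius = 150, step = 17, threshold = 0.9)

test_that("run_analysis produces calls near planted crossovers plus all tables", {
  paths <- local_sim_inputs()
  cfg <- run_config(paths$gt, paths$smap, paths$ped, paths$out,
                    algorithm = "both", pd = small_pd)
  bundle <- suppressMessages(run_analysis(cfg))

  calls <- bundle$calls
  expect_s3_class(calls, "recomb_calls")
  # one PD and one CCS call per planted crossover; CCS may wander a few
  # tens of kb when noise runs flank the breakpoint, so 100 kb bounds both
  for (alg in c("PD", "CCS")) {
    pat <- calls[calls$algorithm == alg & calls$origin == "Paternal", ]
    mat <- calls[calls$algorithm == alg & calls$origin == "Maternal", ]
    expect_equal(nrow(pat), 1L)
    expect_equal(nrow(mat), 1L)
    expect_lt(abs(pat$chromosomal_position - 1.8e6), 1e5)
    expect_lt(abs(mat$chromosomal_position - 2.4e6), 1e5)
  }
  expect_true(all(calls$scaffold == "sim_scaf1"))
  expect_true(all(!is.na(calls$precision)))

  files <- list.files(paths$out)
  expect_true(all(c("crossover_calls.tsv", "run_summary.tsv",
                    "goo_OFF_chr1.tsv", "density_OFF_chr1.tsv",
                    "pd_profile_OFF_chr1.tsv", "ccs_runs_OFF_chr1.tsv")
                  %in% files))
  # calls table on disk re-parses to the same records
  reread <- read_calls_table(file.path(paths$out, "crossover_calls.tsv"))
  expect_equal(as.data.frame(reread), as.data.frame(calls))
  # summary accounting matches the GoO object
  s <- bundle$summary
  goo <- bundle$details$OFF_chr1$goo
  expect_equal(s$n_informative_paternal, nrow(goo$paternal))
  expect_equal(s$n_calls_pd + s$n_calls_ccs, nrow(calls))
})

test_that("re-running the analysis is byte-identical on all tables", {
  paths <- local_sim_inputs()
  for (run in 1:2) {
    cfg <- run_config(paths$gt, paths$smap, paths$ped,
                      file.path(paths$out, run), pd = small_pd)
    suppressMessages(run_analysis(cfg))
  }
  for (f in list.files(file.path(paths$out, 1))) {
    expect_identical(readLines(file.path(paths$out, 1, f)),
                     readLines(file.path(paths$out, 2, f)),
                     label = f)
  }
})

test_that("configuration errors abort with the offending input named", {
  paths <- local_sim_inputs()
  expect_error(suppressMessages(run_analysis(run_config(
    paths$gt, paths$smap, paths$ped, paths$out, offspring = "GHOST"))),
    "GHOST")
  expect_error(suppressMessages(run_analysis(run_config(
    paths$gt, paths$smap, paths$ped, paths$out, chromosomes = "7"))),
    "7")
})

test_that("a chromosome with no informative calls warns and writes empty tables", {
  dir <- withr::local_tempdir()
  ids <- c("PGF", "PGM", "MGF", "MGM", "FA", "MO", "OFF")
  gt <- data.frame(scaffold = "s1", position = c(100L, 200L))
  gt[ids] <- 0L  # all-homozygous: possible but never informative
  gt <- pedrec:::validate_gt_table(gt)
  paths <- list(gt = file.path(dir, "gt.tsv"),
                smap = file.path(dir, "smap.tsv"),
                ped = file.path(dir, "ped.yaml"))
  write_gt_table(gt, paths$gt)
  utils::write.table(data.frame(scaffold = "s1", size = 1000, CHR = "1",
                                order = 1, orientation = "+"),
                     paths$smap, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(list(paternal_grandfather = "PGF",
                        paternal_grandmother = "PGM",
                        maternal_grandfather = "MGF",
                        maternal_grandmother = "MGM",
                        father = "FA", mother = "MO", offspring = "OFF"),
                   paths$ped)
  cfg <- run_config(paths$gt, paths$smap, paths$ped, file.path(dir, "out"))
  expect_warning(suppressMessages(bundle <- run_analysis(cfg)),
                 "no informative calls")
  expect_equal(nrow(bundle$calls), 0L)
  calls_file <- file.path(dir, "out", "crossover_calls.tsv")
  expect_length(readLines(calls_file), 1L)
  # placeholder plots are still produced, and never abort the run
  written <- render_plots(bundle, file.path(dir, "plots"))
  expect_length(written, 4L)
  expect_true(all(file.size(written) > 0))
})

test_that("batch output equals the concatenation of single runs", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(chrom_length = 3e6, n_snps = 12000L, seed = 55,
                    crossovers = list(paternal = 1.5e6, maternal = 1e6))
  sim <- simulate_pedigree(cfg)
  gt <- as.data.frame(sim$gt)
  gt$OFF2 <- gt$OFF  # second offspring, identical genotypes
  gt <- pedrec:::validate_gt_table(gt)
  gt_path <- file.path(dir, "gt.tsv"); write_gt_table(gt, gt_path)
  smap_path <- file.path(dir, "smap.tsv")
  utils::write.table(as.data.frame(sim$smap), smap_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ped <- list(paternal_grandfather = "PGF", paternal_grandmother = "PGM",
              maternal_grandfather = "MGF", maternal_grandmother = "MGM",
              father = "FA", mother = "MO",
              offspring = c("OFF", "OFF2"))
  ped_path <- file.path(dir, "ped.yaml"); yaml::write_yaml(ped, ped_path)

  batch <- suppressMessages(run_analysis(run_config(
    gt_path, smap_path, ped_path, file.path(dir, "batch"),
    pd = small_pd)))
  singles <- lapply(c("OFF", "OFF2"), function(off) {
    suppressMessages(run_analysis(run_config(
      gt_path, smap_path, ped_path, file.path(dir, off),
      offspring = off, pd = small_pd)))$calls
  })
  combined <- pedrec:::sort_calls(do.call(rbind, singles))
  expect_equal(as.data.frame(batch$calls), as.data.frame(combined))
  # identical genotypes give identical calls modulo the offspring label
  one <- batch$calls[batch$calls$offspring == "OFF", -1]
  two <- batch$calls[batch$calls$offspring == "OFF2", -1]
  rownames(one) <- rownames(two) <- NULL
  expect_equal(one, two)
})

test_that("render_plots writes four deterministic images per chromosome", {
  paths <- local_sim_inputs()
  cfg <- run_config(paths$gt, paths$smap, paths$ped, paths$out,
                    pd = small_pd)
  bundle <- suppressMessages(run_analysis(cfg))
  plot_dir <- file.path(paths$out, "plots")
  written <- render_plots(bundle, plot_dir, jitter_seed = 9)
  expect_length(written, 4L)
  expect_setequal(basename(written),
                  c("goo_OFF_chr1.png", "pd_OFF_chr1.png",
                    "ccs_OFF_chr1.png", "density_OFF_chr1.png"))
  expect_true(all(file.size(written) > 0))
})
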