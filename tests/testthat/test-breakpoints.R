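test_that("PD profile is exact on clean splits and flat on constant input", {
  p <- pd_params(radius = 550)
  side <- make_side(rep(c("GF", "GM"), each = 1100))
  prof <- pd_profile(side, p)
  expect_true(all(prof$D >= 0 & prof$D <= 1))
  # full-window boundary at the true split scores exactly 1
  at_split <- pd_profile(side, p, at = 1100)
  expect_equal(at_split$D, 1)
  expect_equal(at_split$midpoint_bp,
               floor((side$chrom_pos[1100] + side$chrom_pos[1101]) / 2))

  flat <- pd_profile(make_side(rep("GF", 2200)), p)
  expect_true(all(flat$D == 0))

  expect_warning(short <- pd_profile(make_side(rep("GF", 100)), p),
                 "no PD boundary")
  expect_equal(nrow(short), 0L)
})

test_that("PD scan calls the clean split once, at the flanking midpoint", {
  p <- pd_params(radius = 550)
  side <- make_side(rep(c("GF", "GM"), each = 1100))
  hits <- pd_scan(side, p)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$D, 1)
  expect_equal(hits$position,
               floor((side$chrom_pos[1100] + side$chrom_pos[1101]) / 2))

  expect_equal(nrow(pd_scan(make_side(rep("GF", 2200)), p)), 0L)
  expect_warning(none <- pd_scan(make_side(rep("GM", 10)), p),
                 "PD scan finds nothing")
  expect_equal(nrow(none), 0L)
})

test_that("PD scan separates two distant crossovers and tolerates flip noise", {
  p <- pd_params(radius = 100, threshold = 0.8)
  set.seed(11)
  origins <- rep(c("GF", "GM", "GF"), times = c(500, 500, 500))
  flip <- runif(1500) < 0.05
  origins[flip] <- ifelse(origins[flip] == "GF", "GM", "GF")
  side <- make_side(origins)
  hits <- pd_scan(side, p)
  expect_equal(nrow(hits), 2L)
  # argmax lands within one coarse step of each planted boundary
  expect_lt(abs(hits$boundary[1] - 500), p$step + 1)
  expect_lt(abs(hits$boundary[2] - 1000), p$step + 1)
  expect_true(all(hits$D >= p$threshold))
})

test_that("CCS runs partition the call sequence", {
  runs <- ccs_runs(make_side(rep(c("GF", "GM"), each = 60)))
  expect_equal(runs$ccs, c(60L, 60L))
  expect_equal(runs$origin, c("GF", "GM"))

  alternating <- ccs_runs(make_side(rep(c("GF", "GM"), 10)))
  expect_equal(nrow(alternating), 20L)
  expect_true(all(alternating$ccs == 1L))

  expect_equal(nrow(ccs_runs(make_side(character(0)))), 0L)
  # run lengths always sum to the number of calls
  set.seed(3)
  x <- sample(c("GF", "GM"), 500, replace = TRUE)
  expect_equal(sum(ccs_runs(make_side(x))$ccs), 500L)
})

test_that("CCS scan keeps threshold runs and absorbs noise between them", {
  side <- make_side(rep(c("GF", "GM"), each = 60))
  hits <- ccs_scan(side, threshold = 50)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position,
               floor((side$chrom_pos[60] + side$chrom_pos[61]) / 2))

  # sub-threshold noise run between same-origin kept runs: no call
  quiet <- make_side(rep(c("GF", "GM", "GF"), times = c(60, 10, 60)))
  expect_equal(nrow(ccs_scan(quiet, 50)), 0L)

  # noise run absorbed; one call between the opposite-origin kept runs
  noisy <- make_side(rep(c("GF", "GM", "GF", "GM"),
                         times = c(200, 3, 400, 300)))
  hits <- ccs_scan(noisy, 50)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position,
               floor((noisy$chrom_pos[603] + noisy$chrom_pos[604]) / 2))
  expect_equal(hits$left_ccs, 400L)
  expect_equal(hits$right_ccs, 300L)
})

test_that("precision is the reverse local call density", {
  # 2 calls inside a 100 kb window -> 50 kb per informative SNP
  side <- make_side(c("GF", "GF"), spacing = 10000, start = 480000)
  expect_equal(precision_estimate(side, 500000, 1e5, chrom_length = 1e6),
               50000)
  # empty window: undefined
  expect_true(is.na(precision_estimate(side, 900000, 1e5,
                                       chrom_length = 1e6)))
  # 463 calls in the window -> round(100000 / 463) = 216
  dense <- make_side(rep("GF", 463), spacing = 216,
                     start = 500000 - 231 * 216)
  expect_equal(precision_estimate(dense, 500000, 1e5, chrom_length = 1e6),
               216)

  # uniform density d per bp gives precision about 1/d
  set.seed(5)
  pos <- sort(sample.int(2e6, 2000))
  unif <- data.frame(scaffold = "s1", scaffold_pos = pos, chrom_pos = pos,
                     origin = "GF")
  prec <- precision_estimate(unif, 1e6, 1e5, chrom_length = 2e6)
  expect_lt(abs(prec - 1000), 150)
})

test_that("attach_precision fills scaffold fields and is deterministic", {
  smap <- scaffold_map(data.frame(
    scaffold = c("a", "b"), size = c(5e5, 5e5), CHR = "1",
    order = 1:2, orientation = c("+", "-")))
  side <- make_side(rep("GF", 100), spacing = 10000)
  calls <- attach_precision(c(700000, 700000), side, "OFF", "1",
                            "Paternal", "PD", smap)
  expect_equal(calls$scaffold, c("b", "b"))
  expect_equal(calls$orientation, c("-", "-"))
  # same position, same precision
  expect_equal(calls$precision[1], calls$precision[2])
  expect_error(attach_precision(500500, side, "OFF", "1", "Paternal",
                                "PD", smap, gap = 1000),
               "no scaffold")
})

test_that("raising either threshold never increases the call count", {
  set.seed(21)
  origins <- rep(c("GF", "GM", "GF"), times = c(700, 700, 700))
  flip <- runif(2100) < 0.08
  origins[flip] <- ifelse(origins[flip] == "GF", "GM", "GF")
  side <- make_side(origins)

  pd_counts <- vapply(seq(0.5, 0.95, by = 0.05), function(th) {
    nrow(pd_scan(side, pd_params(radius = 100, threshold = th)))
  }, 0L)
  expect_true(all(diff(pd_counts) <= 0))

  ccs_counts <- vapply(c(10, 25, 50, 100, 200), function(th) {
    nrow(ccs_scan(side, th))
  }, 0L)
  expect_true(all(diff(ccs_counts) <= 0))
})

test_that("PD and CCS agree exactly on clean single-crossover input", {
  side <- make_side(rep(c("GM", "GF"), each = 1100))
  pd_hit <- pd_scan(side, pd_params(radius = 550))
  ccs_hit <- ccs_scan(side, 50)
  expect_equal(pd_hit$position, ccs_hit$position)
})
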