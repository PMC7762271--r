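test_that("profile scores follow the stated log-odds formula", {
  # 4 sequences, first column A,A,A,C, uniform background, pseudocount 1
  p <- build_profile(c("ACD", "ADE", "AEF", "CFG"), pseudocount = 1)
  expect_equal(unname(p$scores["A", 1]), log2((3 + 0.05) / ((4 + 1) * 0.05)))
  expect_equal(unname(p$scores["C", 1]), log2((1 + 0.05) / ((4 + 1) * 0.05)))

  p2 <- build_profile(c("ACD", "ACD"))
  expect_gt(p2$scores["A", 1], 0)
  expect_lt(p2$scores["W", 1], 0)

  # a huge pseudocount drives all scores towards the background (0 bits)
  p3 <- build_profile(c("ACD", "ACD"), pseudocount = 1e9)
  expect_true(all(abs(p3$scores) < 1e-6))

  expect_error(build_profile(c("ACD", "AC")), "equal length")
  expect_error(build_profile(c("AXD", "ACD")), "non-standard")
  expect_silent(build_profile(c("AXD", "ACD"), map_x_to_background = TRUE))
})

test_that("window scores are additive and shift-equivariant", {
  prof <- ap2_profile()
  set.seed(21)
  dom <- sample_from_profile(prof)
  flank <- random_protein(40)
  prot <- paste0(flank, dom, random_protein(30))
  hits <- scan_protein(prot, prof, threshold = 20, gene_id = "g")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 40)
  expect_equal(hits$coverage, 1)
  # additivity: the hit score equals the direct sum of per-column scores
  res <- strsplit(dom, "")[[1]]
  direct <- sum(vapply(seq_along(res), function(c)
    prof$scores[res[c], c], numeric(1)))
  expect_equal(hits$score, direct)
  # prepending k background residues shifts every hit by exactly k
  k <- 13
  shifted <- scan_protein(paste0(random_protein(k, seed = 99), prot),
                          prof, threshold = 20, gene_id = "g")
  expect_equal(shifted$start, hits$start + k)
  expect_equal(shifted$end, hits$end + k)
})

test_that("planted domains are recovered with the expected multiplicity", {
  fg <- small_genome()
  prof <- ap2_profile()
  cal <- ap2_cal()
  erf <- fg$truth$gene_id[fg$truth$true_subfamily == "ERF"][1]
  h <- scan_protein(fg$proteins[[erf]], prof, cal$threshold, gene_id = erf)
  expect_equal(nrow(h), 1)
  planted <- decode_domain_positions(
    fg$truth$domain_positions[fg$truth$gene_id == erf])
  expect_equal(h$start, planted$start)
  expect_equal(h$end, planted$end)

  ap2g <- fg$truth$gene_id[fg$truth$true_subfamily == "AP2"][1]
  h2 <- scan_protein(fg$proteins[[ap2g]], prof, cal$threshold,
                     gene_id = ap2g)
  expect_equal(nrow(h2), 2)
  expect_true(all(h2$end[1] <= h2$start[2]))
})

test_that("threshold calibration is monotone, seeded and controls false hits", {
  prof <- ap2_profile()
  cal_tight <- calibrate_threshold(prof, 150, 400, target_evalue = 1e-8,
                                   seed = 11)
  cal_loose <- calibrate_threshold(prof, 150, 400, target_evalue = 1e-3,
                                   seed = 11)
  expect_gt(cal_tight$threshold, cal_loose$threshold)
  cal_again <- calibrate_threshold(prof, 150, 400, target_evalue = 1e-8,
                                   seed = 11)
  expect_identical(cal_tight$threshold, cal_again$threshold)
  expect_error(calibrate_threshold(prof, 50, 400), ">= 100")

  # fresh null sequences at an e-3 threshold: very few false hits expected
  set.seed(77)
  false_hits <- 0
  for (i in 1:200) {
    prot <- random_protein(400)
    false_hits <- false_hits +
      nrow(scan_protein(prot, prof, cal_loose$threshold))
  }
  expect_lte(false_hits, 5)
})

test_that("short proteins yield an empty scan rather than an error", {
  prof <- ap2_profile()
  expect_message(h <- scan_protein("MKV", prof, 10), "shorter than 10")
  expect_equal(nrow(h), 0)
})

test_that("HMMER3 domtblout rows map to hits with converted coordinates", {
  lines <- c(
    "# comment line",
    paste("gene1 - 300 AP2 PF00847.22 58 1.2e-20 70.1 0.1 1 2",
          "3.1e-12 1.1e-10 40.2 0.0 2 57 4 60 5 64 0.95 desc text"),
    paste("gene1 - 300 AP2 PF00847.22 58 1.2e-20 70.1 0.1 2 2",
          "2e-8 4.4e-07 20.0 0.0 1 58 100 158 99 160 0.90 desc"),
    paste("gene1 - 300 B3 PF02362.1 90 3e-15 50.0 0.0 1 1",
          "5e-15 6e-14 49.0 0.0 1 90 200 290 199 291 0.99 d"))
  f <- withr::local_tempfile(lines = lines)
  hits <- read_domtblout(f)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$gene_id, rep("gene1", 3))
  # envelope 5..64 (1-based inclusive) becomes 4..64 (0-based half-open)
  expect_equal(hits$start[1], 4)
  expect_equal(hits$end[1], 64)
  expect_equal(hits$evalue[1], 1.1e-10)
  expect_equal(hits$coverage[1], (57 - 2 + 1) / 58)

  bad <- withr::local_tempfile(lines = c(lines[2], "gene2 broken row"))
  expect_error(read_domtblout(bad), "line 2")
})

test_that("hit filtering applies the E-value and coverage thresholds", {
  hits <- data.frame(
    gene_id = c("a", "b", "c"), profile = "AP2",
    start = 0L, end = 58L,
    score = c(50, 40, 30), evalue = c(1e-6, 1e-3, 1e-8),
    coverage = c(0.9, 0.95, 0.5), stringsAsFactors = FALSE)
  kept <- filter_hits(hits, max_evalue = 1e-5, min_coverage = 0.7)
  expect_equal(kept$gene_id, "a")   # b fails E-value, c fails coverage
  expect_equal(nrow(filter_hits(hits[0, ])), 0)
})
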