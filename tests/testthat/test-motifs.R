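test_that("repression motifs are found at exact positions", {
  h <- scan_repression_motifs("MKLFGVA")
  expect_equal(nrow(h), 1)
  expect_equal(h$motif_name, "RKLFGV")
  expect_equal(c(h$start, h$end), c(1L, 6L))
  expect_equal(h$matched_text, "KLFGV")

  h2 <- scan_repression_motifs("AEDLLG")
  expect_equal(h2$motif_name, "EDLL")
  expect_equal(h2$start, 1L)

  expect_equal(nrow(scan_repression_motifs("AAAAAA")), 0)

  # the strict and generalized DLN spellings are reported separately
  h3 <- scan_repression_motifs("AFDLNLPPA")
  expect_setequal(h3$motif_name, c("FDLNLPP", "LFDLNLF"))
  expect_equal(h3$start[h3$motif_name == "FDLNLPP"], 1L)

  # overlapping matches are all reported
  h4 <- scan_repression_motifs("EDLLEDLL")
  expect_equal(h4$start[h4$motif_name == "EDLL"], c(0L, 4L))
})

test_that("promoter elements are found on both strands", {
  h <- scan_promoter_elements("TTACCGACTT")
  expect_equal(h$motif_name, "DRE")
  expect_equal(h$start, 2L)
  expect_equal(h$strand, "+")

  # reverse complement of GCCGAC: a minus-strand DRE
  h2 <- scan_promoter_elements("GTCGGC")
  expect_equal(h2$motif_name, "DRE")
  expect_equal(h2$strand, "-")
  expect_equal(c(h2$start, h2$end), c(0L, 6L))
  expect_equal(h2$matched_text, "GCCGAC")

  h3 <- scan_promoter_elements("GTACGTG")
  expect_true("ACGT_motif" %in% h3$motif_name)
  expect_false("ABRE_B" %in% h3$motif_name)

  # N never matches
  expect_equal(nrow(scan_promoter_elements("TTACCGANTT")), 0)
})

test_that("scanning is strand-symmetric", {
  set.seed(64)
  seq <- paste(sample(BASES, 4000, replace = TRUE), collapse = "")
  fwd <- scan_promoter_elements(seq)
  rev <- scan_promoter_elements(genefamkit:::revcomp(seq))
  L <- nchar(seq)
  # a + hit at [s, e) corresponds to a - hit at [L-e, L-s) on the revcomp
  key <- function(h) sort(paste(h$motif_name, h$start, h$end, h$strand))
  mapped <- data.frame(motif_name = rev$motif_name,
                       start = L - rev$end, end = L - rev$start,
                       strand = ifelse(rev$strand == "+", "-", "+"))
  expect_equal(key(fwd), key(mapped))
})

test_that("random-protein motif rate matches the combinatorial expectation", {
  set.seed(31)
  prot <- random_protein(1e6)
  n_obs <- nrow(scan_repression_motifs(prot,
                                       patterns = c(RKLFGV = "[RK]LFGV")))
  expected <- (nchar(prot) - 4) * (2 / 20) * (1 / 20)^4
  expect_lte(abs(n_obs - expected), 3 * sqrt(expected))
})

test_that("promoters are extracted with the stated strand conventions", {
  set.seed(9)
  chrom <- paste(sample(BASES, 3000, replace = TRUE), collapse = "")
  genome <- c(chr1 = chrom)
  plus <- list(chromosome = "chr1", start = 2001, end = 2300, strand = "+")
  p <- extract_promoter(genome, plus, length = 1500)
  expect_equal(p, substr(chrom, 501, 2000))
  minus <- list(chromosome = "chr1", start = 101, end = 400, strand = "-")
  m <- extract_promoter(genome, minus, length = 1500)
  expect_equal(m, genefamkit:::revcomp(substr(chrom, 401, 1900)))
  near_edge <- list(chromosome = "chr1", start = 101, end = 400,
                    strand = "+")
  expect_warning(tp <- extract_promoter(genome, near_edge, length = 1500),
                 "truncated")
  expect_equal(nchar(tp), 100)
  expect_error(extract_promoter(genome,
                                list(chromosome = "chrX", start = 1,
                                     end = 10, strand = "+")),
               "missing")
})

test_that("planted motifs and elements are recovered at recorded positions", {
  fg <- small_genome()
  prot_names <- names(repression_motif_patterns())
  for (i in seq_len(nrow(fg$truth))) {
    planted <- decode_planted_motifs(fg$truth$planted_motifs[i])
    if (nrow(planted) == 0) next
    g <- fg$truth$gene_id[i]
    ph <- scan_repression_motifs(fg$proteins[[g]], sequence_id = g)
    prom <- extract_promoter(fg$genome, fg$genes[fg$genes$gene_id == g, ])
    eh <- scan_promoter_elements(prom, sequence_id = g)
    for (j in seq_len(nrow(planted))) {
      nm <- planted$motif[j]; pos <- planted$position[j]
      hits <- if (nm %in% prot_names) ph else eh
      expect_true(any(hits$motif_name == nm & hits$start == pos),
                  label = paste(g, nm, pos))
    }
  }
})
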