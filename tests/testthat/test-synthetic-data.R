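test_that("gene counts, architectures and determinism follow the configuration", {
  cfg <- sim_config(n_erf = 5, n_dreb = 0, n_drf = 0, n_ap2 = 2, n_rav = 2,
                    n_soloist = 1, n_none = 3, n_duplicate_pairs = 0,
                    seed = 7)
  fg <- simulate_family_genome(cfg)
  expect_length(fg$proteins, 13)
  expect_length(fg$cds, 13)
  expect_equal(sum(fg$truth$true_subfamily != "NONE"), 10)
  expect_equal(sum(nzchar(fg$truth$domain_positions)), 10)

  # same config + seed twice: byte-identical artifacts
  fg2 <- simulate_family_genome(cfg)
  expect_identical(fg, fg2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genome_files(fg, d1); write_genome_files(fg2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)

  # RAV architecture: exactly one AP2 strictly upstream of exactly one B3
  rav <- fg$truth[fg$truth$true_subfamily == "RAV", ]
  for (i in seq_len(nrow(rav))) {
    doms <- decode_domain_positions(rav$domain_positions[i])
    expect_equal(sort(doms$profile), c("AP2", "B3"))
    expect_lt(doms$end[doms$profile == "AP2"],
              doms$start[doms$profile == "B3"])
  }

  # translating every CDS reproduces the protein records exactly
  translated <- vapply(fg$cds, function(x)
    as.character(Biostrings::translate(Biostrings::DNAString(x))), "")
  expect_equal(unname(translated), unname(fg$proteins))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(chromosomes = c("1A", "8C")), "1A-7B")
  expect_error(sim_config(n_erf = -1), ">= 0")
  expect_error(sim_config(ks_target = 0), "ks_target")
  cfg0 <- sim_config(n_erf = 0, n_dreb = 0, n_drf = 0, n_ap2 = 0, n_rav = 0,
                     n_soloist = 0, n_none = 0, n_duplicate_pairs = 0)
  expect_error(simulate_family_genome(cfg0), "zero total genes")
})

test_that("mutate_duplicate respects omega, ks_target and the ORF", {
  cds <- local({
    set.seed(3)
    prot <- random_protein(120)
    genefamkit:::back_translate(prot)
  })
  # omega = 0 forbids amino-acid change
  m0 <- mutate_duplicate(cds, omega = 0, ks_target = 0.2, seed = 5)
  expect_equal(m0$n_nonsynonymous, 0L)
  expect_equal(
    as.character(Biostrings::translate(Biostrings::DNAString(m0$cds))),
    as.character(Biostrings::translate(Biostrings::DNAString(cds))))
  # ks_target = 0 leaves the sequence untouched
  expect_identical(mutate_duplicate(cds, omega = 0.5, ks_target = 0,
                                    seed = 5)$cds, cds)
  # no stop codons are ever introduced
  m1 <- mutate_duplicate(cds, omega = 1, ks_target = 0.5, seed = 5)
  prot1 <- as.character(Biostrings::translate(Biostrings::DNAString(m1$cds)))
  expect_false(grepl("*", prot1, fixed = TRUE))
  # malformed inputs
  expect_error(mutate_duplicate("ATGTAAATG", 0.5, 0.1), "stop codon")
  expect_error(mutate_duplicate("ATGC", 0.5, 0.1), "divisible by 3")
})

test_that("generated expression matrices encode the planted classes", {
  fg <- small_genome()
  cfg <- fg$config
  m <- generate_expression(fg$truth, cfg)
  expect_true(all(m >= 0))
  expect_identical(m, generate_expression(fg$truth, cfg))  # seeded rerun

  for (i in seq_len(nrow(fg$truth))) {
    cl <- fg$truth$expression_class[i]
    g <- fg$truth$gene_id[i]
    if (cl == "silent") expect_true(all(m[g, ] == 0))
    if (startsWith(cl, "tissue_specific:")) {
      tis <- sub("^tissue_specific:", "", cl)
      expect_equal(names(which.max(m[g, cfg$tissues])), tis)
    }
  }
  bad <- fg$truth; bad$expression_class[1] <- "sometimes"
  expect_error(generate_expression(bad, cfg), "unknown expression class")
})

test_that("the Ct model yields exact ddCt values at zero noise", {
  truth <- data.frame(gene_id = "g1", expression_class = "ubiquitous",
                      stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 11)
  q4 <- generate_qpcr(truth, cfg, genes = "g1", noise_sd = 0, fold = 4)
  d4 <- ddct(q4)
  expect_equal(d4$ddct, rep(-2, 4))
  expect_equal(d4$relative_expression, rep(4, 4))
  q1 <- generate_qpcr(truth, cfg, genes = "g1", noise_sd = 0, fold = 1)
  d1 <- ddct(q1)
  expect_equal(d1$ddct, rep(0, 4))
  expect_equal(d1$relative_expression, rep(1, 4))
})
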