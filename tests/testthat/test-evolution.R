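test_that("site and difference counting match exhaustive enumeration", {
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  # all 61 sense codons: sites
  for (c in sense) {
    expect_equal(ng_sites(c), bf_ng_sites(c))
    expect_equal(sum(ng_sites(c)), 3)
  }
  # spot examples stated in closed form
  expect_equal(ng_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng_sites("CTT"), c(s = 1, n = 2))
  expect_equal(ng_count_diffs("TTT", "TTT"), c(sd = 0, nd = 0))
  expect_equal(ng_count_diffs("TTT", "TTA"), c(sd = 0, nd = 1))
  expect_equal(ng_count_diffs("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  # all 61 x 61 pairs against the brute-force pathway enumerator
  mismatches <- 0
  for (a in sense) for (b in sense) {
    got <- ng_count_diffs(a, b)
    want <- bf_ng_count_diffs(a, b)
    if (max(abs(got - want)) > 1e-12) mismatches <- mismatches + 1
    ndiff <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(sum(got), ndiff)
  }
  expect_equal(mismatches, 0)
  expect_error(ng_sites("TAA"), "stop")
})

test_that("kaks handles identical, diverged and symmetric inputs", {
  set.seed(10)
  cds <- genefamkit:::back_translate(random_protein(100))
  same <- kaks(ungapped_alignment(cds, cds))
  expect_equal(same$Ka, 0)
  expect_equal(same$Ks, 0)
  expect_true(is.na(same$omega))
  expect_equal(same$selection, "undefined")
  expect_equal(jukes_cantor(0.1), 0.10732, tolerance = 1e-4)

  m <- mutate_duplicate(cds, omega = 0.3, ks_target = 0.2, seed = 4)
  ab <- kaks(ungapped_alignment(cds, m$cds, "a", "b"))
  ba <- kaks(ungapped_alignment(m$cds, cds, "b", "a"))
  for (f in c("identity", "S", "N", "sd", "nd", "Ka", "Ks", "omega"))
    expect_equal(ab[[f]], ba[[f]], label = f)
  expect_equal(ab$selection, "purifying")
  expect_error(kaks(ungapped_alignment(substr(cds, 1, 27),
                                       substr(m$cds, 1, 27))),
               "fewer than")
})

test_that("simulated pairs recover the generating omega within 10%", {
  set.seed(31)
  cds <- genefamkit:::back_translate(random_protein(300))
  for (om in c(0.2, 0.6)) {
    est <- vapply(1:40, function(r) {
      m <- mutate_duplicate(cds, omega = om, ks_target = 0.3,
                            seed = 5000 + r)
      kaks(ungapped_alignment(cds, m$cds))$omega
    }, numeric(1))
    expect_lt(abs(mean(est) - om) / om, 0.10)
  }
})

test_that("global alignment scores match exhaustive enumeration", {
  a1 <- global_align("ACGT", "ACGT")
  expect_equal(a1$identity, 1)
  expect_equal(a1$score, 8)
  a2 <- global_align("ACGT", "ACT")
  expect_equal(a2$identity, 3 / 4)
  expect_false(grepl("-", a2$aligned_a))
  expect_equal(sum(strsplit(a2$aligned_b, "")[[1]] == "-"), 1)
  set.seed(8)
  for (i in 1:12) {
    x <- paste(sample(BASES, sample(3:6, 1), replace = TRUE), collapse = "")
    y <- paste(sample(BASES, sample(3:6, 1), replace = TRUE), collapse = "")
    expect_equal(global_align(x, y)$score, bf_align_score(x, y),
                 label = paste(x, y))
  }
})

test_that("duplicate detection applies a strict identity threshold", {
  base <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")  # 100 nt
  flip <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- seq_len(k) * 6 - 3
    v[idx] <- chartr("ACGT", "TGCA", v[idx])
    paste(v, collapse = "")
  }
  at_threshold <- flip(base, 15)   # identity exactly 0.85
  above <- flip(base, 10)          # identity 0.90
  dup <- find_duplicates(c(g1 = base, g2 = at_threshold, g3 = above),
                         identity_threshold = 0.85)
  expect_false(any(dup$pairs$gene_a == "g1" & dup$pairs$gene_b == "g2"))
  expect_true(any(dup$pairs$gene_a == "g1" & dup$pairs$gene_b == "g3"))

  # planted duplicates at Ks ~0.05 are retained; clusters are components
  set.seed(12)
  cds <- genefamkit:::back_translate(random_protein(150))
  m1 <- mutate_duplicate(cds, 0.5, 0.05, seed = 1)$cds
  m2 <- mutate_duplicate(cds, 0.5, 0.05, seed = 2)$cds
  far <- genefamkit:::back_translate(random_protein(150))
  dup2 <- find_duplicates(c(a = cds, b = m1, c = m2, d = far))
  expect_setequal(names(which(!is.na(dup2$clusters))), c("a", "b", "c"))
  expect_equal(length(unique(dup2$clusters[c("a", "b", "c")])), 1)
  expect_true(is.na(dup2$clusters["d"]))
})

test_that("neighbor joining reproduces additive trees exactly", {
  d <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 8,
                9, 10, 8, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  expect_equal(ape::write.tree(tr), "(C:4,D:4,(A:2,B:3):3);")

  # three taxa solve the three-point equations in closed form
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[c("x", "y", "z")], c(x = 1, y = 2, z = 3))

  # random additive matrices: topology recovered, cross-checked with ape
  for (s in 1:10) {
    case <- random_additive_case(8, seed = 700 + s)
    mine <- nj_tree(case$dist)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(case$tree)),
                 0, ignore_attr = TRUE)
    ref <- ape::nj(case$dist)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)),
                 0, ignore_attr = TRUE)
  }
  dbad <- d; dbad[1, 2] <- 99
  expect_error(nj_tree(dbad), "symmetric")
})

test_that("bootstrap supports separate planted clusters", {
  set.seed(15)
  a <- random_protein(60)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(v), k)
    v[idx] <- vapply(v[idx], function(x) sample(setdiff(AAS, x), 1), "")
    paste(v, collapse = "")
  }
  b <- random_protein(60)
  aln <- c(a1 = a, a2 = mut(a, 3), a3 = mut(a, 3),
           b1 = b, b2 = mut(b, 3), b3 = mut(b, 3))
  tr <- bootstrap_support(aln, n_replicates = 100, seed = 3)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 100))
  # the clade splitting the two families has near-total support
  expect_gte(max(tr$node.label), 95)
  tr2 <- bootstrap_support(aln, n_replicates = 100, seed = 3)
  expect_identical(tr$node.label, tr2$node.label)
  tr0 <- bootstrap_support(aln, n_replicates = 0)
  expect_null(tr0$node.label)
})

test_that("clades transfer from labeled reference leaves", {
  nwk <- "((q1:1,refDREB:1):2,(q2:1,refERF:1):2,refRAV:4);"
  tr <- ape::read.tree(text = nwk)
  labs <- c(refDREB = "DREB", refERF = "ERF", refRAV = "RAV")
  got <- assign_clades(tr, labs)
  expect_equal(got[["q1"]], "DREB")
  expect_equal(got[["q2"]], "ERF")
  # equidistant leaves resolve to the alphabetically first clade
  tie <- ape::read.tree(text = "(q:1,(rA:2,rB:2):0);")
  expect_equal(unname(assign_clades(tie, c(rA = "B", rB = "A"))), "A")
  expect_error(assign_clades(tr, character(0)), "no reference")
})
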