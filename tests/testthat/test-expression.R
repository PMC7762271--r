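toy_matrix <- function() {
  m <- rbind(g1 = c(0, 0, 0, 0, 0),
             g2 = c(5, 6, 4, 5, 5),
             g3 = c(0, 0, 0, 0, 0),
             g4 = c(0.5, 0, 0, 0, 0),
             g5 = c(10, 0.1, 0.2, 0.1, 0.1))
  colnames(m) <- c("leaf", "root", "stem", "grain", "spike")
  m
}

test_that("the unexpressed filter removes exactly the all-low rows", {
  m <- toy_matrix()
  f <- suppressMessages(filter_unexpressed(m))
  expect_equal(rownames(f), c("g2", "g4", "g5"))
  expect_equal(attr(f, "removed"), c("g1", "g3"))
  # boundary: a single column at exactly min_fpkm retains the gene
  expect_true("g4" %in% rownames(f))
  # min_fpkm = 0 can remove nothing
  f0 <- filter_unexpressed(m, min_fpkm = 0)
  expect_equal(dim(f0), dim(m))
  expect_warning(suppressMessages(
    filter_unexpressed(m[c("g1", "g3"), ])), "no genes remain")
})

test_that("log2 transform is exact and commutes with filtering", {
  m <- toy_matrix()
  expect_equal(log2_transform(m)["g1", "leaf"], 0)
  expect_equal(log2_transform(matrix(7))[1, 1], 3)
  # monotone within each column
  expect_equal(order(m[, "leaf"]), order(log2_transform(m)[, "leaf"]))
  # filtering decisions are made on raw FPKM only
  a <- log2_transform(suppressMessages(filter_unexpressed(m)))
  b <- suppressMessages(filter_unexpressed(m))
  expect_equal(rownames(a), rownames(b))
  expect_error(log2_transform(m, pseudocount = 0), "> 0")
})

test_that("tau captures the tissue-specificity extremes", {
  m <- rbind(spec = c(leaf = 0, root = 10, stem = 0, grain = 0, spike = 0),
             ubiq = c(leaf = 5, root = 5, stem = 5, grain = 5, spike = 5),
             zero = c(leaf = 0, root = 0, stem = 0, grain = 0, spike = 0))
  ts <- tissue_specificity(m)
  expect_equal(ts$tau[1], 1)
  expect_equal(ts$class[1], "tissue_specific:root")
  expect_equal(ts$tau[2], 0)
  expect_equal(ts$class[2], "ubiquitous")
  expect_equal(ts$class[3], "silent")

  # tau stays in [0, 1] on random matrices; 1 iff exactly one nonzero
  set.seed(17)
  r <- matrix(stats::rexp(200, 1 / 5), 40, 5,
              dimnames = list(sprintf("g%02d", 1:40),
                              c("leaf", "root", "stem", "grain", "spike")))
  r[sample(length(r), 60)] <- 0
  tr <- tissue_specificity(r)
  ok <- !is.na(tr$tau)
  expect_true(all(tr$tau[ok] >= 0 & tr$tau[ok] <= 1))
  one_nz <- rowSums(r > 0) == 1
  expect_equal(unname(abs(tr$tau - 1) < 1e-12)[ok & one_nz],
               rep(TRUE, sum(ok & one_nz)))
  expect_error(tissue_specificity(r[, 1, drop = FALSE]), ">= 2")
})

test_that("stress calls apply the fold-change rule symmetrically", {
  m <- rbind(up = c(control = 2, heat_1h = 8),
             down = c(control = 8, heat_1h = 2),
             low = c(control = 0.1, heat_1h = 0.4))
  calls <- stress_response_calls(m, conditions = "heat_1h", pseudocount = 1)
  expect_equal(calls$log2fc[1], log2(9 / 3))
  expect_equal(calls$call, c("up", "down", "ns"))
  # default pseudocount also respects the threshold rule
  calls2 <- stress_response_calls(m, conditions = "heat_1h")
  expect_equal(calls2$call, c("up", "down", "ns"))
  expect_error(stress_response_calls(m, control = "mock"), "control")
})

test_that("ddct reproduces the textbook arithmetic and its invariances", {
  q <- data.frame(
    gene = "g", treatment = rep(c("control", "heat"), each = 3),
    replicate = rep(1:3, 2),
    ct_target = c(26, 26, 26, 24, 24, 24),
    ct_reference = rep(20, 6))
  d <- ddct(q)
  expect_equal(d$ddct, -2)
  expect_equal(d$relative_expression, 4)

  # treatment identical to control: fold 1, p = 1
  q1 <- q; q1$ct_target <- rep(c(26, 26.3, 25.7), 2)
  d1 <- ddct(q1)
  expect_equal(d1$relative_expression, 1)
  expect_equal(d1$p_value, 1)

  # adding a constant to every Ct leaves relative expression unchanged
  set.seed(2)
  q2 <- q
  q2$ct_target <- q2$ct_target + rnorm(6, 0, 0.3)
  d2 <- ddct(q2)
  q3 <- q2
  q3$ct_target <- q3$ct_target + 5
  q3$ct_reference <- q3$ct_reference + 5
  expect_equal(ddct(q3)$relative_expression, d2$relative_expression)

  # significance marking at p < 0.05
  expect_equal(d2$significant, d2$p_value < 0.05)

  qbad <- q; qbad$ct_reference[2] <- NA
  expect_error(ddct(qbad), "reference")
  expect_error(ddct(q, control_treatment = "mock"), "not present")
})
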