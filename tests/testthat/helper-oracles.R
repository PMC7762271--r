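# Independent oracles and shared fixtures for the test suite.
# The oracles deliberately re-derive results from first principles (brute
# force, enumeration, grid scans) without touching the implementation paths
# they check.

GC_TABLE <- Biostrings::GENETIC_CODE
BASES <- c("A", "C", "G", "T")
AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

aa_of <- function(codon) unname(GC_TABLE[codon])

# --- brute-force Nei-Gojobori site counting --------------------------------
bf_ng_sites <- function(codon) {
  v <- strsplit(codon, "")[[1]]
  aa0 <- aa_of(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    for (b in setdiff(BASES, v[pos])) {
      w <- v; w[pos] <- b
      if (aa_of(paste(w, collapse = "")) == aa0) syn <- syn + 1
    }
    s <- s + syn / 3
  }
  c(s = s, n = 3 - s)
}

# --- brute-force pathway-averaged difference counting ----------------------
bf_ng_count_diffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  diffs <- which(a != b)
  if (length(diffs) == 0) return(c(sd = 0, nd = 0))
  all_perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (rest in all_perms(x[-i])) out <- c(out, list(c(x[i], rest)))
    out
  }
  paths <- all_perms(diffs)
  stats <- lapply(paths, function(ord) {
    cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
    for (k in seq_along(ord)) {
      nxt <- cur; nxt[ord[k]] <- b[ord[k]]
      a1 <- aa_of(paste(cur, collapse = "")); a2 <- aa_of(paste(nxt, collapse = ""))
      if (a2 == "*" && k < length(ord)) blocked <- TRUE
      if (a1 == a2 && a1 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  })
  ok <- !vapply(stats, `[[`, logical(1), "blocked")
  if (!any(ok)) ok[] <- TRUE
  c(sd = mean(vapply(stats[ok], `[[`, numeric(1), "sd")),
    nd = mean(vapply(stats[ok], `[[`, numeric(1), "nd")))
}

# --- exhaustive global-alignment score (affine gaps) -----------------------
# Enumerates every alignment of a and b recursively; gap of length L costs
# gap_open + L * gap_extend. Only practical for very short strings.
bf_align_score <- function(a, b, match = 2, mismatch = -1,
                           gap_open = -5, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  # state: 0 = none/diagonal, 1 = gap in b (up), 2 = gap in a (left)
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      sc <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, sc + rec(i + 1, j + 1, 0))
    }
    if (i <= length(av)) {
      open <- if (state == 1) 0 else gap_open
      best <- max(best, open + gap_extend + rec(i + 1, j, 1))
    }
    if (j <= length(bv)) {
      open <- if (state == 2) 0 else gap_open
      best <- max(best, open + gap_extend + rec(i, j + 1, 2))
    }
    best
  }
  rec(1, 1, 0)
}

# --- fine-grid charge scan for pI ------------------------------------------
grid_pi <- function(protein, step = 1e-4) {
  ph <- seq(0, 14, by = step)
  q <- genefamkit::protein_charge(protein, ph)
  ph[which.min(abs(q))]
}

# --- random additive distance matrix from a random binary tree -------------
random_additive_case <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.5, 3))
  list(tree = tr, dist = ape::cophenetic.phylo(tr))
}

# --- shared small synthetic genome (memoized per session) ------------------
.fixture_env <- new.env()

small_config <- function(seed = 7) {
  genefamkit::sim_config(n_erf = 6, n_dreb = 3, n_drf = 2, n_ap2 = 2,
                         n_rav = 2, n_soloist = 2, n_none = 3,
                         n_duplicate_pairs = 2, seed = seed)
}

small_genome <- function() {
  if (is.null(.fixture_env$fg))
    .fixture_env$fg <- genefamkit::simulate_family_genome(small_config())
  .fixture_env$fg
}

ap2_cal <- function() {
  if (is.null(.fixture_env$cal))
    .fixture_env$cal <- genefamkit::calibrate_threshold(
      genefamkit::ap2_profile(), n_shuffles = 150, protein_length = 400,
      target_evalue = 1e-5, seed = 11)
  .fixture_env$cal
}

b3_cal <- function() {
  if (is.null(.fixture_env$calb))
    .fixture_env$calb <- genefamkit::calibrate_threshold(
      genefamkit::b3_profile(), n_shuffles = 150, protein_length = 400,
      target_evalue = 1e-5, seed = 11)
  .fixture_env$calb
}

scan_genome_hits <- function(fg = small_genome()) {
  ap2 <- genefamkit::ap2_profile(); b3 <- genefamkit::b3_profile()
  cal <- ap2_cal(); calb <- b3_cal()
  do.call(rbind, lapply(names(fg$proteins), function(g) {
    rbind(genefamkit::scan_protein(fg$proteins[[g]], ap2, cal$threshold,
                                   gene_id = g, calibration = cal),
          genefamkit::scan_protein(fg$proteins[[g]], b3, calb$threshold,
                                   gene_id = g, calibration = calb))
  }))
}

# ungapped pairwise-alignment shim for kaks() on equal-length sequences
ungapped_alignment <- function(a, b, id_a = "a", id_b = "b") {
  structure(list(seq_a_id = id_a, seq_b_id = id_b, aligned_a = a,
                 aligned_b = b, score = 0,
                 identity = mean(strsplit(a, "")[[1]] ==
                                   strsplit(b, "")[[1]])),
            class = "pairwise_alignment")
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AAS, n, replace = TRUE), collapse = "")
}
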