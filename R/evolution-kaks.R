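# Duplicate-pair detection and Nei-Gojobori (NG86) Ka/Ks estimation with
# Jukes-Cantor correction.
#
# Site counting and pathway-averaged difference counting are implemented
# from first principles over the standard genetic code; results for all
# sense-codon pairs are memoized after first use.

DNA_BASES <- c("A", "C", "G", "T")

.cache <- new.env(parent = emptyenv())

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

sense_codons <- function() {
  if (is.null(.cache$sense)) {
    gc <- Biostrings::GENETIC_CODE
    .cache$sense <- names(gc)[gc != "*"]
  }
  .cache$sense
}

#' Potential synonymous and nonsynonymous sites of a codon
#'
#' For each of the nine single-nucleotide changes of the codon, the change is
#' classified as synonymous or nonsynonymous under the standard genetic code
#' (changes creating stop codons count as nonsynonymous). The synonymous site
#' count is the per-position synonymous fraction summed over the three
#' positions, so \code{s + n == 3} exactly.
#'
#' @param codon Three-letter codon in ACGT, not a stop codon.
#' @return Named numeric vector \code{c(s = ..., n = ...)}.
#' @export
ng_sites <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3 || !all(chars(codon) %in% DNA_BASES))
    stop("codon must be 3 bases in ACGT")
  if (codon_aa(codon) == "*") stop("stop codon input: ", codon)
  aa0 <- codon_aa(codon)
  v <- chars(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    for (b in setdiff(DNA_BASES, v[pos])) {
      w <- v; w[pos] <- b
      if (codon_aa(paste(w, collapse = "")) == aa0) syn <- syn + 1
    }
    s <- s + syn / 3
  }
  c(s = s, n = 3 - s)
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' Averages synonymous/nonsynonymous step counts over all orderings of the
#' differing positions (1, 2 or 6 mutational pathways). Pathways passing
#' through a stop codon at an intermediate state are excluded and the
#' average renormalized over the remaining pathways; if every pathway is
#' blocked, all pathways are used (steps to/from a stop count as
#' nonsynonymous). The counts always satisfy
#' \code{sd + nd == number of differing positions}.
#'
#' @param codon_a,codon_b Sense codons (3 bases, ACGT).
#' @return Named numeric vector \code{c(sd = ..., nd = ...)}.
#' @export
ng_count_diffs <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (codon_aa(codon_a) == "*" && codon_aa(codon_b) == "*")
    stop("both codons are stops")
  a <- chars(codon_a); b <- chars(codon_b)
  diffs <- which(a != b)
  k <- length(diffs)
  if (k == 0) return(c(sd = 0, nd = 0))

  orderings <- if (k == 1) list(diffs) else {
    perms <- function(x) {
      if (length(x) == 1) return(list(x))
      out <- list()
      for (i in seq_along(x))
        for (p in perms(x[-i])) out <- c(out, list(c(x[i], p)))
      out
    }
    perms(diffs)
  }

  path_counts <- function(ord) {
    cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
    for (j in seq_along(ord)) {
      nxt <- cur; nxt[ord[j]] <- b[ord[j]]
      aa1 <- codon_aa(paste(cur, collapse = ""))
      aa2 <- codon_aa(paste(nxt, collapse = ""))
      if (aa2 == "*" && j < length(ord)) blocked <- TRUE
      if (aa1 == aa2 && aa1 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }

  res <- lapply(orderings, path_counts)
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  if (!any(ok)) ok[] <- TRUE
  sd <- mean(vapply(res[ok], `[[`, numeric(1), "sd"))
  nd <- mean(vapply(res[ok], `[[`, numeric(1), "nd"))
  c(sd = sd, nd = nd)
}

# Memoized per-codon site counts and pairwise difference counts.
codon_tables <- function() {
  if (is.null(.cache$sites)) {
    sc <- sense_codons()
    sites <- t(vapply(sc, ng_sites, numeric(2)))
    SD <- matrix(0, length(sc), length(sc), dimnames = list(sc, sc))
    ND <- SD
    for (i in seq_along(sc)) for (j in seq_along(sc)) {
      if (i == j) next
      d <- ng_count_diffs(sc[i], sc[j])
      SD[i, j] <- d["sd"]; ND[i, j] <- d["nd"]
    }
    .cache$sites <- sites; .cache$SD <- SD; .cache$ND <- ND
  }
  list(sites = .cache$sites, SD = .cache$SD, ND = .cache$ND)
}

#' Jukes-Cantor distance from a proportion of differing sites
#' @param p Proportion of sites that differ (must be < 0.75).
#' @return Corrected substitutions per site.
#' @export
jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Global pairwise alignment of two nucleotide sequences
#'
#' Needleman-Wunsch global alignment with affine gaps, delegated to the
#' \pkg{Biostrings} dynamic-programming engine. A gap of length L costs
#' \code{gap_open + L * gap_extend}. Identity is defined as matching columns
#' over all aligned columns.
#'
#' @param a,b Nucleotide sequences (ACGTN).
#' @param match,mismatch,gap_open,gap_extend Scoring scheme (penalties
#'   negative).
#' @param id_a,id_b Sequence identifiers carried into the result.
#' @return A \code{pairwise_alignment} list: ids, gapped strings, score,
#'   identity.
#' @export
global_align <- function(a, b, match = 2, mismatch = -1,
                         gap_open = -5, gap_extend = -1,
                         id_a = "a", id_b = "b") {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  letters5 <- c("A", "C", "G", "T", "N")
  sub <- matrix(mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(sub) <- match
  sub["N", ] <- mismatch; sub[, "N"] <- mismatch  # N never matches
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = sub, gapOpening = -gap_open,
    gapExtension = -gap_extend, type = "global")
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  ca <- chars(ga); cb <- chars(gb)
  identity <- sum(ca == cb & ca != "-") / length(ca)
  structure(list(seq_a_id = id_a, seq_b_id = id_b,
                 aligned_a = ga, aligned_b = gb,
                 score = Biostrings::score(aln), identity = identity),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment %s vs %s: score %.1f, identity %.3f, %d columns\n",
              x$seq_a_id, x$seq_b_id, x$score, x$identity, nchar(x$aligned_a)))
  invisible(x)
}

#' Nei-Gojobori Ka/Ks from a pairwise CDS alignment
#'
#' Alignment columns are chunked into consecutive triplets; triplets
#' containing a gap in either sequence are removed (complete-codon pairwise
#' deletion), as are triplets where either codon is a stop. Potential sites
#' S and N are averaged over both sequences; proportions are Jukes-Cantor
#' corrected. The selection call is purifying (omega < 1), neutral
#' (omega == 1), positive (omega > 1), or undefined (Ks == 0). Proportions
#' >= 0.75 leave the corresponding distance undefined and flag the pair as
#' saturated.
#'
#' @param alignment A \code{pairwise_alignment} over coding sequences.
#' @param min_codons Minimum number of compared codons (default 10).
#' @return One-row data frame: gene_a, gene_b, identity, codons, S, N, sd,
#'   nd, ps, pn, Ka, Ks, omega, selection, saturated.
#' @export
kaks <- function(alignment, min_codons = 10) {
  tab <- codon_tables()
  ca <- chars(alignment$aligned_a)
  cb <- chars(alignment$aligned_b)
  ncol_aln <- length(ca)
  usable <- ncol_aln - ncol_aln %% 3
  cod_a <- character(0); cod_b <- character(0)
  for (i in seq(1, usable, by = 3)) {
    ta <- paste(ca[i:(i + 2)], collapse = "")
    tb <- paste(cb[i:(i + 2)], collapse = "")
    if (grepl("-", ta, fixed = TRUE) || grepl("-", tb, fixed = TRUE)) next
    if (!all(chars(ta) %in% DNA_BASES) || !all(chars(tb) %in% DNA_BASES)) next
    if (codon_aa(ta) == "*" || codon_aa(tb) == "*") next
    cod_a <- c(cod_a, ta); cod_b <- c(cod_b, tb)
  }
  if (length(cod_a) < min_codons)
    stop("fewer than ", min_codons, " comparable codons")

  S <- (sum(tab$sites[cod_a, "s"]) + sum(tab$sites[cod_b, "s"])) / 2
  N <- (sum(tab$sites[cod_a, "n"]) + sum(tab$sites[cod_b, "n"])) / 2
  sd_tot <- sum(tab$SD[cbind(cod_a, cod_b)])
  nd_tot <- sum(tab$ND[cbind(cod_a, cod_b)])
  ps <- sd_tot / S
  pn <- nd_tot / N
  Ks <- jukes_cantor(ps)
  Ka <- jukes_cantor(pn)
  saturated <- is.na(Ks) || is.na(Ka)
  omega <- if (!saturated && Ks > 0) Ka / Ks else NA_real_
  selection <- if (saturated) "saturated"
    else if (is.na(omega)) "undefined"
    else if (omega < 1) "purifying"
    else if (omega > 1) "positive"
    else "neutral"
  data.frame(gene_a = alignment$seq_a_id, gene_b = alignment$seq_b_id,
             identity = alignment$identity, codons = length(cod_a),
             S = S, N = N, sd = sd_tot, nd = nd_tot, ps = ps, pn = pn,
             Ka = Ka, Ks = Ks, omega = omega, selection = selection,
             saturated = saturated, stringsAsFactors = FALSE)
}

#' Detect duplicated gene pairs by pairwise CDS identity
#'
#' Aligns all unordered pairs globally and retains pairs whose identity is
#' strictly greater than the threshold (85% by default, the conventional
#' duplicate cutoff). Clusters are the connected components of the
#' retained-pair graph.
#'
#' @param cds Named character vector (or \code{DNAStringSet}) of coding
#'   sequences, >= 2 entries.
#' @param identity_threshold Strict lower bound on alignment identity.
#' @param ... Scoring parameters passed to \code{\link{global_align}}.
#' @return List with \code{pairs} (data frame: gene_a, gene_b, identity,
#'   score, cluster), \code{clusters} (named integer vector over all genes;
#'   NA for genes in no retained pair), and \code{alignments} (list of
#'   retained \code{pairwise_alignment}s).
#' @export
find_duplicates <- function(cds, identity_threshold = 0.85, ...) {
  if (methods::is(cds, "XStringSet")) cds <- as.character(cds)
  if (length(cds) < 2) stop("need >= 2 sequences")
  ids <- names(cds)
  if (is.null(ids)) ids <- paste0("seq", seq_along(cds))
  n <- length(cds)
  pairs <- list(); alns <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    aln <- global_align(cds[[i]], cds[[j]], id_a = ids[i], id_b = ids[j], ...)
    if (aln$identity > identity_threshold) {
      pairs[[length(pairs) + 1]] <- data.frame(
        gene_a = ids[i], gene_b = ids[j], identity = aln$identity,
        score = aln$score, stringsAsFactors = FALSE)
      alns[[length(alns) + 1]] <- aln
    }
  }
  # connected components by union-find over sequence indices
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pair_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(0), gene_b = character(0),
               identity = numeric(0), score = numeric(0))
  for (r in seq_len(nrow(pair_df))) {
    ia <- match(pair_df$gene_a[r], ids)
    ib <- match(pair_df$gene_b[r], ids)
    parent[find(ia)] <- find(ib)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  in_pair <- ids %in% c(pair_df$gene_a, pair_df$gene_b)
  comp <- match(roots, unique(roots[in_pair]))
  clusters <- stats::setNames(ifelse(in_pair, comp, NA_integer_), ids)
  if (nrow(pair_df))
    pair_df$cluster <- unname(clusters[pair_df$gene_a])
  else pair_df$cluster <- integer(0)
  list(pairs = pair_df, clusters = clusters, alignments = alns)
}

#' Duplicate detection plus Ka/Ks estimation in one step
#'
#' Runs \code{\link{find_duplicates}} and completes every retained pair with
#' \code{\link{kaks}}.
#' @inheritParams find_duplicates
#' @return Data frame with one row per retained pair (all \code{kaks} fields
#'   plus cluster label).
#' @export
duplication_analysis <- function(cds, identity_threshold = 0.85, ...) {
  dup <- find_duplicates(cds, identity_threshold = identity_threshold, ...)
  if (length(dup$alignments) == 0) {
    out <- kaks_empty()
    out$cluster <- integer(0)
    return(out)
  }
  rows <- lapply(dup$alignments, kaks)
  out <- do.call(rbind, rows)
  out$cluster <- dup$pairs$cluster
  out
}

kaks_empty <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             identity = numeric(0), codons = integer(0), S = numeric(0),
             N = numeric(0), sd = numeric(0), nd = numeric(0),
             ps = numeric(0), pn = numeric(0), Ka = numeric(0),
             Ks = numeric(0), omega = numeric(0), selection = character(0),
             saturated = logical(0), stringsAsFactors = FALSE)
}
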