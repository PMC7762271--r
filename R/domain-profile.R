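# Position-specific scoring models for protein domains.
#
# A domain_profile carries, for every alignment column, per-residue log-odds
# scores (bits) against a background distribution, together with the emission
# frequencies the scores were derived from. The emission side is what the
# synthetic-genome simulator samples from; the log-odds side is what the
# scanner sums over windows.

#' Build a position-specific scoring profile from a gap-free alignment
#'
#' Column scores are log-odds in bits:
#' \code{score(c, a) = log2((count(a,c) + pseudocount * bg(a)) /
#' ((n + pseudocount) * bg(a)))}, where \code{n} is the number of aligned
#' sequences and \code{bg} the background residue distribution.
#'
#' @param aligned_sequences Character vector of >= 2 gap-free, equal-length
#'   protein sequences (standard 20 residues).
#' @param pseudocount Positive prior weight added per column, spread over the
#'   background distribution.
#' @param background Named numeric vector of background residue frequencies
#'   over the 20 standard amino acids; must sum to 1. Default uniform.
#' @param name Profile name carried into hits.
#' @param map_x_to_background If \code{TRUE}, non-standard residues (X, B, Z)
#'   in the input are ignored for counting instead of raising an error.
#' @return An object of class \code{domain_profile} with elements
#'   \code{name}, \code{scores} (20 x L bit-score matrix), \code{emissions}
#'   (20 x L frequency matrix), \code{background}, and \code{length}.
#' @export
build_profile <- function(aligned_sequences, pseudocount = 1,
                          background = NULL, name = "profile",
                          map_x_to_background = FALSE) {
  if (length(aligned_sequences) < 2)
    stop("need at least 2 aligned sequences")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  lens <- nchar(aligned_sequences)
  if (length(unique(lens)) != 1)
    stop("aligned sequences must have equal lengths")
  L <- lens[1]
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AMINO_ACIDS)
  }
  background <- background[AMINO_ACIDS]
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must sum to 1")

  mat <- do.call(rbind, strsplit(aligned_sequences, ""))
  bad <- !(mat %in% AMINO_ACIDS)
  if (any(bad) && !map_x_to_background)
    stop("non-standard residue in alignment: ",
         paste(unique(mat[bad]), collapse = ", "))

  counts <- matrix(0, nrow = 20, ncol = L,
                   dimnames = list(AMINO_ACIDS, NULL))
  for (c in seq_len(L)) {
    col <- mat[, c]
    col <- col[col %in% AMINO_ACIDS]
    tab <- table(factor(col, levels = AMINO_ACIDS))
    counts[, c] <- as.numeric(tab)
  }
  n <- length(aligned_sequences)
  emissions <- (counts + pseudocount * background) / (n + pseudocount)
  scores <- log2(emissions / background)

  structure(list(name = name, scores = scores, emissions = emissions,
                 background = background, length = L),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat("domain_profile '", x$name, "': ", x$length, " columns, ",
      sprintf("%.2f", sum(colSums(x$emissions * x$scores))),
      " bits total information\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a profile (highest-emission residue per column)
#' @param profile A \code{domain_profile}.
#' @return Character scalar of length \code{profile$length}.
#' @export
profile_consensus <- function(profile) {
  paste(AMINO_ACIDS[apply(profile$emissions, 2, which.max)], collapse = "")
}

#' Sample a domain instance from a profile's emission frequencies
#'
#' Used by the synthetic-genome simulator to plant domain occurrences.
#' Draws each column independently from the column's emission distribution.
#' Uses the current RNG state (seed it upstream).
#'
#' @param profile A \code{domain_profile}.
#' @return Character scalar of length \code{profile$length}.
#' @export
sample_from_profile <- function(profile) {
  idx <- vapply(seq_len(profile$length), function(c) {
    sample.int(20, 1, prob = profile$emissions[, c])
  }, integer(1))
  paste(AMINO_ACIDS[idx], collapse = "")
}

#' Bundled AP2-domain scoring profile
#'
#' Built from the synthetic AP2-domain seed alignment shipped with the
#' package (58 columns, landmarks echoing the YRG/WLG/RAYD regions of real
#' AP2 domains). The alignment is synthetic: it is a reproducible stand-in
#' for a curated Pfam seed alignment, not derived from PF00847 data.
#'
#' @param pseudocount Prior weight passed to \code{\link{build_profile}}.
#' @return A \code{domain_profile} named "AP2".
#' @export
ap2_profile <- function(pseudocount = 1) {
  aln <- read_protein_fasta(extdata_path("ap2_domain_synthetic_alignment.fasta"))
  build_profile(unname(aln), pseudocount = pseudocount, name = "AP2")
}

#' Bundled B3-domain scoring profile
#'
#' Synthetic 90-column B3-domain stand-in profile (see \code{\link{ap2_profile}}
#' for the fixture policy).
#' @param pseudocount Prior weight passed to \code{\link{build_profile}}.
#' @return A \code{domain_profile} named "B3".
#' @export
b3_profile <- function(pseudocount = 1) {
  aln <- read_protein_fasta(extdata_path("b3_domain_synthetic_alignment.fasta"))
  build_profile(unname(aln), pseudocount = pseudocount, name = "B3")
}

#' Subfamily signature table for the ERF clade
#'
#' Fixed (column, residue) replacements that differentiate the DREB, DRF and
#' SOLOIST variants of the AP2 domain in the synthetic fixtures. The SOLOIST
#' rows replace 35% of the profile columns with background-drawn residues
#' fixed once at fixture-build time, giving the "divergent single AP2 domain"
#' clade a concrete, reproducible divergence.
#' @return Data frame with columns subfamily, column, residue.
#' @export
subfamily_signatures <- function() {
  read_tsv_file(extdata_path("subfamily_signatures_synthetic.tsv"))
}

#' ERF-clade variant profiles (ERF, DREB, DRF, SOLOIST)
#'
#' Starting from the base AP2 profile, each variant pins its signature
#' columns to the signature residue with emission probability
#' \code{signature_weight}, the remaining mass spread uniformly.
#'
#' @param base Optional base profile (defaults to \code{\link{ap2_profile}()}).
#' @param signature_weight Emission probability of the signature residue at
#'   signature columns.
#' @return Named list of \code{domain_profile} objects.
#' @export
erf_clade_profiles <- function(base = NULL, signature_weight = 0.9) {
  if (is.null(base)) base <- ap2_profile()
  sig <- subfamily_signatures()
  out <- list(ERF = base)
  for (sf in c("DREB", "DRF", "SOLOIST")) {
    prof <- base
    prof$name <- paste0("AP2-", sf)
    rows <- sig[sig$subfamily == sf, ]
    for (i in seq_len(nrow(rows))) {
      col <- rows$column[i]
      em <- rep((1 - signature_weight) / 19, 20)
      names(em) <- AMINO_ACIDS
      em[rows$residue[i]] <- signature_weight
      prof$emissions[, col] <- em
      prof$scores[, col] <- log2(em / prof$background)
    }
    out[[sf]] <- prof
  }
  out
}

#' Labeled reference AP2 domains for ERF-clade refinement
#'
#' Reads the bundled synthetic reference set (two domains per subfamily,
#' labels ERF/DREB/DRF/SOLOIST in the FASTA headers).
#' @return Named character vector of domain sequences; names are subfamily
#'   labels (possibly repeated), in file order.
#' @export
erf_clade_references <- function() {
  seqs <- read_protein_fasta(extdata_path("erf_clade_references_synthetic.fasta"))
  labels <- sub(".*subfamily=([A-Z]+).*", "\\1", names(seqs))
  stats::setNames(unname(seqs), labels)
}
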