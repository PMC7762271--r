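# Repression-motif screening of proteins and cis-regulatory element scanning
# of promoters, with explicit strand and 0-based half-open coordinates.

#' Default repression motif patterns
#'
#' The three transcriptional repression/activation motifs screened in
#' AP2/ERF proteins: the RAV-type \code{[RK]LFGV}, the EAR-type DLN motif in
#' both its strict (\code{FDLNLPP}) and generalized (\code{[LF]DLN[LF]})
#' spellings (reported under distinct names), and the activating
#' \code{EDLL} motif.
#' @return Named character vector of position-restricted patterns.
#' @export
repression_motif_patterns <- function() {
  c(RKLFGV = "[RK]LFGV",
    FDLNLPP = "FDLNLPP",
    LFDLNLF = "[LF]DLN[LF]",
    EDLL = "EDLL")
}

#' Default promoter cis-element patterns
#'
#' The dehydration-responsive element (DRE, \code{[AG]CCGAC}), ABA-responsive
#' element (ABRE B, \code{TCCACGTCTC}), re2f-1 element (\code{GCGGGAAA}) and
#' ACGT motif (\code{GTACGTG}).
#' @return Named character vector of patterns.
#' @export
promoter_element_patterns <- function() {
  c(DRE = "[AG]CCGAC",
    ABRE_B = "TCCACGTCTC",
    re2f_1 = "GCGGGAAA",
    ACGT_motif = "GTACGTG")
}

# length (in sequence letters) of a class-restricted pattern
pattern_width <- function(pattern) {
  nchar(gsub("\\[[^]]+\\]", "x", pattern))
}

# all (overlapping) matches of one pattern; 0-based half-open coordinates
match_pattern <- function(seq, pattern) {
  width <- pattern_width(pattern)
  m <- gregexpr(paste0("(?=(", pattern, "))"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  starts <- as.integer(m) - 1L
  attr(starts, "width") <- width
  starts
}

motif_hits_df <- function() {
  data.frame(sequence_id = character(0), motif_name = character(0),
              start = integer(0), end = integer(0), strand = character(0),
              matched_text = character(0), stringsAsFactors = FALSE)
}

#' Scan a protein for repression motifs
#'
#' Reports all (possibly overlapping) matches of each pattern, sorted by
#' start position (0-based half-open coordinates).
#'
#' @param protein Protein sequence (character scalar).
#' @param patterns Named character vector of patterns
#'   (default \code{\link{repression_motif_patterns}}).
#' @param sequence_id Identifier recorded in the hits.
#' @return Data frame: sequence_id, motif_name, start, end, strand ("*" for
#'   proteins), matched_text.
#' @export
scan_repression_motifs <- function(protein,
                                   patterns = repression_motif_patterns(),
                                   sequence_id = "protein") {
  out <- motif_hits_df()
  for (nm in names(patterns)) {
    starts <- match_pattern(protein, patterns[[nm]])
    if (length(starts) == 0) next
    w <- attr(starts, "width")
    out <- rbind(out, data.frame(
      sequence_id = sequence_id, motif_name = nm,
      start = as.integer(starts), end = as.integer(starts + w),
      strand = "*",
      matched_text = substring(protein, starts + 1, starts + w),
      stringsAsFactors = FALSE))
  }
  out[order(out$start, out$motif_name), , drop = FALSE]
}

#' Extract a promoter sequence upstream of a gene
#'
#' For a plus-strand gene, the \code{length} bases immediately 5' of the
#' start codon; for a minus-strand gene, the reverse complement of the
#' \code{length} bases immediately 3' of the genomic CDS end. Windows
#' overhanging a chromosome edge are truncated with a warning.
#'
#' @param genome Named character vector or \code{DNAStringSet} of
#'   chromosome sequences.
#' @param gene List or one-row data frame with fields \code{chromosome},
#'   \code{start}, \code{end} (1-based inclusive), \code{strand}.
#' @param length Promoter length in bp (default 1500).
#' @return Promoter sequence (character scalar), 5' to 3' relative to the
#'   gene.
#' @export
extract_promoter <- function(genome, gene, length = 1500) {
  if (methods::is(genome, "XStringSet")) genome <- as.character(genome)
  chrom <- as.character(gene$chromosome)
  if (!chrom %in% names(genome))
    stop("chromosome missing from genome store: ", chrom)
  chrom_seq <- genome[[chrom]]
  clen <- nchar(chrom_seq)
  if (identical(as.character(gene$strand), "-")) {
    from <- gene$end + 1
    to <- gene$end + length
    if (to > clen) {
      warning("promoter truncated at chromosome end for gene on ", chrom)
      to <- clen
    }
    if (from > to) return("")
    revcomp(substr(chrom_seq, from, to))
  } else {
    from <- gene$start - length
    to <- gene$start - 1
    if (from < 1) {
      warning("promoter truncated at chromosome start for gene on ", chrom)
      from <- 1
    }
    if (from > to) return("")
    substr(chrom_seq, from, to)
  }
}

#' Scan a promoter for cis-regulatory elements on both strands
#'
#' Minus-strand matches are found on the reverse complement and reported in
#' promoter coordinates with strand "-". N never matches any element.
#'
#' @param promoter DNA sequence in ACGTN.
#' @param patterns Named character vector of patterns
#'   (default \code{\link{promoter_element_patterns}}).
#' @param sequence_id Identifier recorded in the hits.
#' @return Data frame: sequence_id, motif_name, start, end, strand,
#'   matched_text (as read on the matching strand).
#' @export
scan_promoter_elements <- function(promoter,
                                   patterns = promoter_element_patterns(),
                                   sequence_id = "promoter") {
  out <- motif_hits_df()
  L <- nchar(promoter)
  rc <- if (L > 0) revcomp(promoter) else ""
  for (nm in names(patterns)) {
    starts <- match_pattern(promoter, patterns[[nm]])
    if (length(starts) > 0) {
      w <- attr(starts, "width")
      out <- rbind(out, data.frame(
        sequence_id = sequence_id, motif_name = nm,
        start = as.integer(starts), end = as.integer(starts + w),
        strand = "+",
        matched_text = substring(promoter, starts + 1, starts + w),
        stringsAsFactors = FALSE))
    }
    starts_rc <- match_pattern(rc, patterns[[nm]])
    if (length(starts_rc) > 0) {
      w <- attr(starts_rc, "width")
      out <- rbind(out, data.frame(
        sequence_id = sequence_id, motif_name = nm,
        start = as.integer(L - starts_rc - w), end = as.integer(L - starts_rc),
        strand = "-",
        matched_text = substring(rc, starts_rc + 1, starts_rc + w),
        stringsAsFactors = FALSE))
    }
  }
  out[order(out$start, out$motif_name, out$strand), , drop = FALSE]
}
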