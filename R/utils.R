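# Internal helpers shared across modules.

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

CHROMOSOME_LABELS <- paste0(rep(1:7, each = 2), rep(c("A", "B"), 7))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a character string into single characters
#' @noRd
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Derive a child RNG seed from a base seed and a stream offset
#'
#' Keeps derived seeds positive and below 2^31 so they are valid R integer
#' seeds regardless of the base seed the caller supplies.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483587 + 1)
}

#' Read a TSV written by this package
#' @noRd
read_tsv_file <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "", check.names = FALSE, ...)
}

#' Write a data frame as TSV
#' @noRd
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Path to a bundled fixture file
#' @noRd
extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "genefamkit")
  if (!nzchar(p)) {
    # during development (package loaded with pkgload) fall back to source tree
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) stop("bundled fixture not found: ", file)
  p
}

#' Read an (aligned) protein FASTA as a plain character vector
#' @noRd
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

stop_codons <- function() c("TAA", "TAG", "TGA")

#' Reverse complement of a DNA character string
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
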