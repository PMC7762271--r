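# Physicochemical summaries (molecular weight, theoretical pI) and
# per-column conservation statistics for aligned domains.

# Average (not monoisotopic) residue masses in Daltons, ExPASy/ProtParam
# convention; a free peptide adds one water.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

WATER_MASS <- 18.0153

# Bjellqvist pKa set (ExPASy-compatible): N/C termini and the ionizable
# side chains used by the charge model.
PKA_BJELLQVIST <- c(
  Nterm = 7.5, Cterm = 3.55,
  K = 10.0, R = 12.0, H = 5.98,       # positive groups
  D = 4.05, E = 4.45, C = 9.0, Y = 10.0)  # negative groups

#' Molecular weight of a protein (average masses)
#'
#' Sum of average residue masses plus one water (18.0153 Da). Non-standard
#' residues raise an error unless \code{x_mass} supplies a mass for X.
#'
#' @param protein Protein sequence (standard 20 residues).
#' @param x_mass Optional average mass to use for residue X.
#' @return Molecular weight in Daltons.
#' @export
molecular_weight <- function(protein, x_mass = NULL) {
  if (!nzchar(protein)) stop("empty sequence")
  res <- chars(protein)
  masses <- AA_AVG_MASS[res]
  if (anyNA(masses)) {
    unknown <- unique(res[is.na(masses)])
    if (!is.null(x_mass) && identical(unknown, "X")) {
      masses[is.na(masses)] <- x_mass
    } else {
      stop("non-standard residue(s): ", paste(unknown, collapse = ", "))
    }
  }
  sum(masses) + WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the Bjellqvist pKa set: positive
#' contributions from the N-terminus, K, R and H; negative from the
#' C-terminus, D, E, C and Y.
#'
#' @param protein Protein sequence.
#' @param pH pH value (vectorized).
#' @param pka Named pKa vector (default the bundled Bjellqvist set).
#' @return Net charge at each pH.
#' @export
protein_charge <- function(protein, pH, pka = PKA_BJELLQVIST) {
  res <- chars(protein)
  counts <- table(factor(res, levels = AMINO_ACIDS))
  pos_groups <- c(Nterm = 1, K = unname(counts["K"]), R = unname(counts["R"]),
                  H = unname(counts["H"]))
  neg_groups <- c(Cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
                  C = unname(counts["C"]), Y = unname(counts["Y"]))
  vapply(pH, function(p) {
    pos <- sum(pos_groups / (1 + 10^(p - pka[names(pos_groups)])))
    neg <- sum(neg_groups / (1 + 10^(pka[names(neg_groups)] - p)))
    pos - neg
  }, numeric(1))
}

#' Theoretical isoelectric point by bisection
#'
#' Root of the net-charge function on the bracket [0, 14]; the charge is
#' monotone decreasing in pH so bisection always converges. Convergence
#' criterion: |charge| < 1e-4.
#'
#' @param protein Protein sequence (non-empty).
#' @param pka Named pKa vector (default Bjellqvist).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(protein, pka = PKA_BJELLQVIST) {
  if (!nzchar(protein)) stop("empty sequence")
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- protein_charge(protein, mid, pka)
    if (abs(q) < 1e-4) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical table for a set of proteins
#'
#' @param proteins Named character vector or \code{AAStringSet}.
#' @return Data frame: gene_id, length, mw (Da), pi, classification
#'   ("acidic" for pI < 7, "basic" otherwise).
#' @export
physchem_table <- function(proteins) {
  if (methods::is(proteins, "XStringSet")) proteins <- as.character(proteins)
  ids <- names(proteins) %||% paste0("protein", seq_along(proteins))
  mw <- vapply(proteins, molecular_weight, numeric(1))
  pi <- vapply(proteins, isoelectric_point, numeric(1))
  data.frame(gene_id = ids, length = nchar(proteins), mw = unname(mw),
             pi = unname(pi),
             classification = ifelse(pi < 7, "acidic", "basic"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-column conservation profile of an alignment
#'
#' For each column: residue frequencies (no pseudocount), information
#' content \code{log2(20) - entropy} in bits, and the modal consensus
#' residue (alphabetical tie-break). This is the numeric table behind a
#' sequence logo.
#'
#' @param aligned Character vector of >= 2 equal-length residue strings.
#' @return Data frame: position (1-based), information, consensus,
#'   consensus_frequency; full frequency matrix in attribute
#'   \code{"frequencies"}.
#' @export
conservation_profile <- function(aligned) {
  if (length(aligned) < 2) stop("need at least 2 sequences")
  if (length(unique(nchar(aligned))) != 1)
    stop("sequences must have equal lengths")
  mat <- do.call(rbind, strsplit(aligned, ""))
  L <- ncol(mat)
  freqs <- matrix(0, nrow = 20, ncol = L,
                  dimnames = list(AMINO_ACIDS, NULL))
  info <- numeric(L)
  consensus <- character(L)
  consensus_freq <- numeric(L)
  for (c in seq_len(L)) {
    f <- table(factor(mat[, c], levels = AMINO_ACIDS)) / nrow(mat)
    freqs[, c] <- as.numeric(f)
    nz <- freqs[, c][freqs[, c] > 0]
    info[c] <- log2(20) + sum(nz * log2(nz))
    top <- which(freqs[, c] == max(freqs[, c]))
    consensus[c] <- AMINO_ACIDS[top[1]]     # rownames are alphabetical
    consensus_freq[c] <- max(freqs[, c])
  }
  out <- data.frame(position = seq_len(L), information = info,
                    consensus = consensus,
                    consensus_frequency = consensus_freq,
                    stringsAsFactors = FALSE)
  attr(out, "frequencies") <- freqs
  out
}
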