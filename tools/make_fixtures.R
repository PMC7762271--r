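# One-off generator for the synthetic domain fixtures shipped in inst/extdata.
# Run from repo root: Rscript tools/make_fixtures.R
set.seed(20260924)

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

mutate_seq <- function(s, rate, protect = integer(0)) {
  v <- strsplit(s, "")[[1]]
  for (i in seq_along(v)) {
    if (i %in% protect) next
    if (runif(1) < rate) v[i] <- sample(setdiff(AA, v[i]), 1)
  }
  paste(v, collapse = "")
}

write_fasta <- function(headers, seqs, path) {
  con <- file(path, "w")
  for (i in seq_along(seqs)) {
    cat(">", headers[i], "\n", sep = "", file = con)
    s <- seqs[i]
    for (j in seq(1, nchar(s), by = 60))
      cat(substr(s, j, min(j + 59, nchar(s))), "\n", sep = "", file = con)
  }
  close(con)
}

## AP2 domain: 58 columns; the classic YRG / WLG / RAYD-like landmarks are kept
ap2_consensus <- "SGYGGVRKRPGGKFAAEIRDPWKKTRVWLGTFDTAEEAARAYDVAAREFRGPKAKTNF"
stopifnot(nchar(ap2_consensus) == 58)

ap2_aln <- vapply(1:12, function(i) mutate_seq(ap2_consensus, 0.06), "")
write_fasta(sprintf("AP2_syn%02d synthetic AP2-domain alignment member", 1:12),
            ap2_aln, "inst/extdata/ap2_domain_synthetic_alignment.fasta")

## B3 domain: 90 columns, random background with fixed conserved landmarks
b3 <- sample(AA, 90, replace = TRUE)
landmarks <- c("19" = "P", "36" = "L", "38" = "D", "41" = "G", "44" = "W",
               "60" = "G", "61" = "W", "64" = "F", "65" = "V", "70" = "L",
               "73" = "G", "74" = "D", "78" = "F")
b3[as.integer(names(landmarks))] <- landmarks
b3_consensus <- paste(b3, collapse = "")
b3_aln <- vapply(1:10, function(i) mutate_seq(b3_consensus, 0.06), "")
write_fasta(sprintf("B3_syn%02d synthetic B3-domain alignment member", 1:10),
            b3_aln, "inst/extdata/b3_domain_synthetic_alignment.fasta")

## Subfamily signature table: fixed divergent residues on fixed AP2 columns
cons_v <- strsplit(ap2_consensus, "")[[1]]
dreb_cols <- seq(3, 55, by = 4)            # 14 columns
drf_cols  <- seq(5, 57, by = 4)            # 14 columns
sol_cols  <- sort(sample(setdiff(1:58, c(1, 58)), 20))  # 35% of 58 columns

sig_residue <- function(col) sample(setdiff(AA, cons_v[col]), 1)
sig <- rbind(
  data.frame(subfamily = "DREB", column = dreb_cols,
             residue = vapply(dreb_cols, sig_residue, "")),
  data.frame(subfamily = "DRF", column = drf_cols,
             residue = vapply(drf_cols, sig_residue, "")),
  data.frame(subfamily = "SOLOIST", column = sol_cols,
             residue = vapply(sol_cols, sig_residue, ""))
)
write.table(sig, "inst/extdata/subfamily_signatures_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## Labeled reference domains for ERF-clade refinement (2 per subfamily)
apply_sig <- function(subfam) {
  v <- cons_v
  if (subfam != "ERF") {
    rows <- sig[sig$subfamily == subfam, ]
    v[rows$column] <- rows$residue
  }
  paste(v, collapse = "")
}
refs <- character(0); hdrs <- character(0)
for (sf in c("ERF", "DREB", "DRF", "SOLOIST")) {
  base <- apply_sig(sf)
  protect <- if (sf == "ERF") integer(0) else sig$column[sig$subfamily == sf]
  refs <- c(refs, base, mutate_seq(base, 3 / 58, protect = protect))
  hdrs <- c(hdrs, sprintf("%s_ref%d subfamily=%s synthetic reference domain",
                          sf, 1:2, sf))
}
write_fasta(hdrs, refs, "inst/extdata/erf_clade_references_synthetic.fasta")
cat("fixtures written\n")
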