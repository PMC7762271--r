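# Subfamily assignment from domain architecture, ERF-clade refinement by
# nearest labeled reference domain, chromosomal-order naming, and
# chromosome distribution tables.

#' Classify a gene's subfamily from its domain architecture
#'
#' Rules: at least one AP2 hit together with at least one B3 hit is RAV;
#' two or more AP2 hits (any linker length) is AP2; a single AP2 hit is the
#' ERF clade (to be refined into ERF/DREB/DRF/SOLOIST); no hits is NONE.
#' A B3 hit without any AP2 hit is anomalous and yields UNCLASSIFIED with a
#' warning.
#'
#' @param hits Filtered, non-overlapping domain hits for one gene
#'   (data frame with a \code{profile} column; AP2-variant profiles are
#'   counted as AP2).
#' @return One of "AP2", "RAV", "ERF-clade", "UNCLASSIFIED", "NONE".
#' @export
classify_architecture <- function(hits) {
  if (nrow(hits) > 0 && length(unique(hits$gene_id)) > 1)
    stop("hits must come from a single gene")
  n_ap2 <- sum(grepl("^AP2", hits$profile))
  n_b3 <- sum(hits$profile == "B3")
  if (n_ap2 >= 1 && n_b3 >= 1) return("RAV")
  if (n_b3 >= 1) {
    warning("B3 domain without AP2 domain; labeling UNCLASSIFIED")
    return("UNCLASSIFIED")
  }
  if (n_ap2 >= 2) return("AP2")
  if (n_ap2 == 1) return("ERF-clade")
  "NONE"
}

#' Refine an ERF-clade gene into ERF, DREB, DRF or SOLOIST
#'
#' Nearest-labeled-reference rule: the query AP2-domain residues (aligned to
#' profile columns by the gap-free scan) are compared to each reference
#' domain by ungapped column-wise identity; the query takes the label of the
#' best reference. Identity ties are broken by label priority
#' ERF > DREB > DRF > SOLOIST, then file order. A best identity below
#' \code{soloist_cut} falls back to SOLOIST (highly divergent domain).
#'
#' @param domain_sequence AP2-domain residues of the query.
#' @param references Named character vector of reference domains; names are
#'   labels in ERF/DREB/DRF/SOLOIST (default the bundled synthetic set).
#' @param soloist_cut Identity below which the query is called SOLOIST
#'   regardless of the nearest label (default 0.25).
#' @return One of "ERF", "DREB", "DRF", "SOLOIST", "UNCLASSIFIED".
#' @export
refine_erf_clade <- function(domain_sequence,
                             references = erf_clade_references(),
                             soloist_cut = 0.25) {
  if (length(references) == 0) stop("references must be non-empty")
  ref_len <- nchar(references[1])
  if (nchar(domain_sequence) < 0.5 * ref_len) return("UNCLASSIFIED")
  q <- chars(domain_sequence)
  ident <- vapply(references, function(r) {
    rv <- chars(r)
    k <- min(length(q), length(rv))
    sum(q[seq_len(k)] == rv[seq_len(k)]) / ref_len
  }, numeric(1))
  best <- max(ident)
  if (best < soloist_cut) return("SOLOIST")
  priority <- c(ERF = 1, DREB = 2, DRF = 3, SOLOIST = 4)
  cand <- which(ident >= best - 1e-12)
  ord <- order(priority[names(references)[cand]], cand)
  names(references)[cand[ord[1]]]
}

#' Name genes by chromosomal location order
#'
#' Sort key: chromosome number (1-7), subgenome letter (A before B), start
#' coordinate ascending. Names are \code{sprintf("\%s\%03d", prefix, rank)}.
#'
#' @param records Data frame with columns gene_id, chromosome (labels like
#'   "3B"), start.
#' @param prefix Name prefix (default "TtAP2/ERF-").
#' @return Named character vector: assigned names keyed by gene_id, in
#'   sorted order.
#' @export
assign_names <- function(records, prefix = "TtAP2/ERF-") {
  key <- paste(records$chromosome, records$start, records$gene_id)
  if (anyDuplicated(key))
    stop("duplicate (chromosome, start, gene_id) records")
  chrom_num <- as.integer(substr(records$chromosome, 1, 1))
  subgenome <- substr(records$chromosome, 2, 2)
  ord <- order(chrom_num, subgenome, records$start)
  stats::setNames(sprintf("%s%03d", prefix, seq_along(ord)),
                  records$gene_id[ord])
}

#' Chromosome distribution of family genes
#'
#' Zero-filled counts over all 14 chromosome labels (1A-7B) plus subgenome
#' totals.
#'
#' @param records Data frame with a \code{chromosome} column.
#' @return List with \code{per_chromosome} (named integer vector over the
#'   14 labels), \code{subgenome} (A/B totals) and \code{total}.
#' @export
chromosome_distribution <- function(records) {
  chroms <- records$chromosome
  unknown <- setdiff(unique(chroms), CHROMOSOME_LABELS)
  if (length(unknown))
    stop("unknown chromosome label(s): ", paste(unknown, collapse = ", "))
  counts <- table(factor(chroms, levels = CHROMOSOME_LABELS))
  per_chrom <- stats::setNames(as.integer(counts), CHROMOSOME_LABELS)
  sub <- c(A = sum(per_chrom[grepl("A$", names(per_chrom))]),
           B = sum(per_chrom[grepl("B$", names(per_chrom))]))
  list(per_chromosome = per_chrom, subgenome = sub,
       total = sum(per_chrom))
}

#' Full classification of scanned genes
#'
#' Applies \code{\link{classify_architecture}} per gene and refines
#' ERF-clade genes with \code{\link{refine_erf_clade}} using the AP2-hit
#' substring of the protein.
#'
#' @param hits Filtered hit data frame for all genes.
#' @param proteins Named character vector (or \code{AAStringSet}) of the
#'   scanned proteins.
#' @param gene_ids Genes to classify (default: all protein names); genes
#'   without hits are classified NONE.
#' @param references Labeled reference domains for the refinement step.
#' @return Data frame: gene_id, subfamily, architecture (ordered profile
#'   names, "+"-separated), n_domains.
#' @export
classify_family <- function(hits, proteins, gene_ids = NULL,
                            references = erf_clade_references()) {
  if (methods::is(proteins, "XStringSet")) proteins <- as.character(proteins)
  if (is.null(gene_ids)) gene_ids <- names(proteins)
  out <- lapply(gene_ids, function(g) {
    h <- hits[hits$gene_id == g, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    subfam <- classify_architecture(h)
    if (subfam == "ERF-clade") {
      ap2 <- h[grepl("^AP2", h$profile), , drop = FALSE][1, ]
      dom <- substr(proteins[[g]], ap2$start + 1, ap2$end)
      subfam <- refine_erf_clade(dom, references)
    }
    data.frame(gene_id = g, subfamily = subfam,
               architecture = paste(h$profile, collapse = "+"),
               n_domains = nrow(h), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
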