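# Synthetic family-genome simulator with recorded ground truth.
#
# Generates proteins with planted AP2/B3 domain instances in the four
# architectures (ERF-clade = 1xAP2, AP2 = 2xAP2 + 25-aa linker, RAV =
# AP2 + B3, SOLOIST = divergent AP2, NONE = background only), coding
# sequences by seeded uniform back-translation, chromosome placements with
# intergenic room for 1500-bp promoters, duplicated pairs diverged at
# controlled omega and Ks, planted repression motifs and promoter
# cis-elements, FPKM matrices and qPCR Ct tables. Every planting is
# recorded in a truth table so downstream stages can be validated exactly.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is exercised under: a
#' ~60-gene family across chromosomes 1A-7B, duplicate pairs diverged at
#' Ks around 0.05 under purifying-to-relaxed omega values, five tissues and
#' four stress conditions (1 h / 6 h drought and heat) plus control.
#'
#' @param n_erf,n_dreb,n_drf,n_ap2,n_rav,n_soloist,n_none Gene counts per
#'   subfamily (NONE = background genes without domains).
#' @param chromosomes Chromosome labels to place genes on (subset of
#'   1A..7B).
#' @param n_duplicate_pairs Number of within-subfamily duplicated pairs to
#'   plant.
#' @param omega_grid Ka/Ks values cycled over the planted pairs.
#' @param ks_target Target synonymous substitutions per synonymous site for
#'   planted pairs.
#' @param tissues,conditions Expression design column names (conditions must
#'   include "control").
#' @param tissue_fold Fold elevation of a tissue-specific gene in its
#'   tissue.
#' @param stress_fold Fold change of stress-responsive genes versus control.
#' @param noise_sdlog Log-normal multiplicative noise on FPKM values.
#' @param qpcr_noise_sd Gaussian noise (cycles) on simulated Ct values.
#' @param seed Integer seed; a fixed seed makes all generated artifacts
#'   byte-identical across runs.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_erf = 20, n_dreb = 8, n_drf = 5, n_ap2 = 6,
                       n_rav = 5, n_soloist = 3, n_none = 13,
                       chromosomes = CHROMOSOME_LABELS,
                       n_duplicate_pairs = 6,
                       omega_grid = c(0.1, 0.3, 0.5, 0.8),
                       ks_target = 0.05,
                       tissues = c("leaf", "root", "stem", "grain", "spike"),
                       conditions = c("control", "drought_1h", "drought_6h",
                                      "heat_1h", "heat_6h"),
                       tissue_fold = 20, stress_fold = 8,
                       noise_sdlog = 0.2, qpcr_noise_sd = 0.2, seed = 1) {
  counts <- c(ERF = n_erf, DREB = n_dreb, DRF = n_drf, AP2 = n_ap2,
              RAV = n_rav, SOLOIST = n_soloist, NONE = n_none)
  if (any(counts < 0)) stop("gene counts must be >= 0")
  if (ks_target <= 0) stop("ks_target must be > 0")
  bad <- setdiff(chromosomes, CHROMOSOME_LABELS)
  if (length(bad))
    stop("chromosome label(s) outside 1A-7B: ", paste(bad, collapse = ", "))
  if (!"control" %in% conditions) stop("conditions must include 'control'")
  structure(list(counts = counts, chromosomes = chromosomes,
                 n_duplicate_pairs = n_duplicate_pairs,
                 omega_grid = omega_grid, ks_target = ks_target,
                 tissues = tissues, conditions = conditions,
                 tissue_fold = tissue_fold, stress_fold = stress_fold,
                 noise_sdlog = noise_sdlog, qpcr_noise_sd = qpcr_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# synonymous codon sets per amino acid (standard code, stops excluded)
codons_by_aa <- function() {
  if (is.null(.cache$by_aa)) {
    gc <- Biostrings::GENETIC_CODE
    .cache$by_aa <- split(names(gc)[gc != "*"], gc[gc != "*"])
  }
  .cache$by_aa
}

# seeded uniform back-translation of a protein (uses current RNG state)
back_translate <- function(protein) {
  by_aa <- codons_by_aa()
  res <- chars(protein)
  paste(vapply(res, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

rand_residues <- function(n) {
  paste(sample(AMINO_ACIDS, n, replace = TRUE), collapse = "")
}

encode_pairs <- function(names, a, b = NULL) {
  if (length(names) == 0) return("")
  if (is.null(b)) paste(paste0(names, "@", a), collapse = ";")
  else paste(paste0(names, ":", a, "-", b), collapse = ";")
}

#' Decode a domain_positions truth string
#' @param x Encoded string like "AP2:12-70;B3:130-220".
#' @return Data frame: profile, start, end (0-based half-open).
#' @export
decode_domain_positions <- function(x) {
  if (is.na(x) || !nzchar(x))
    return(data.frame(profile = character(0), start = integer(0),
                      end = integer(0)))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([^:]+):([0-9]+)-([0-9]+)$", parts))
  data.frame(profile = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Decode a planted_motifs truth string
#' @param x Encoded string like "RKLFGV@41;DRE@523".
#' @return Data frame: motif, position.
#' @export
decode_planted_motifs <- function(x) {
  if (is.na(x) || !nzchar(x))
    return(data.frame(motif = character(0), position = integer(0)))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([^@]+)@([0-9]+)$", parts))
  data.frame(motif = vapply(m, `[`, "", 2),
             position = as.integer(vapply(m, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Introduce seeded substitutions into a coding sequence at controlled
#' omega and Ks
#'
#' Proposes single-nucleotide changes codon by codon (uniform position and
#' uniform alternative base); synonymous proposals are accepted at base rate
#' 1, nonsynonymous at rate omega; proposals creating stop codons are
#' rejected and redrawn. The number of evaluated proposals is
#' \code{round(3 * n_codons * ks_target)}, so the accepted synonymous
#' events per synonymous site approximate \code{ks_target}.
#'
#' @param cds Coding sequence (length divisible by 3, no internal stop
#'   codons; a terminal stop codon is left untouched).
#' @param omega Nonsynonymous/synonymous acceptance ratio (>= 0).
#' @param ks_target Target synonymous events per synonymous site (>= 0; 0
#'   returns the input unchanged).
#' @param seed Integer seed.
#' @return List: \code{cds} (mutated sequence), \code{realized_ka},
#'   \code{realized_ks} (accepted events per site, measured on the input's
#'   site counts), \code{n_synonymous}, \code{n_nonsynonymous}.
#' @export
mutate_duplicate <- function(cds, omega, ks_target, seed = 1) {
  if (omega < 0) stop("omega must be >= 0")
  if (ks_target < 0) stop("ks_target must be >= 0")
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  v <- chars(toupper(cds))
  if (!all(v %in% DNA_BASES)) stop("CDS must be in ACGT")
  n_codon <- length(v) / 3
  codons <- vapply(seq_len(n_codon),
                   function(i) paste(v[(3 * i - 2):(3 * i)], collapse = ""),
                   character(1))
  terminal_stop <- codon_aa(codons[n_codon]) == "*"
  mut_codons <- if (terminal_stop) n_codon - 1L else n_codon
  if (any(codon_aa(codons[seq_len(mut_codons)]) == "*"))
    stop("internal stop codon in input")

  tab <- codon_tables()
  S0 <- sum(tab$sites[codons[seq_len(mut_codons)], "s"])
  N0 <- sum(tab$sites[codons[seq_len(mut_codons)], "n"])

  n_pos <- 3L * mut_codons
  n_prop <- round(n_pos * ks_target)
  n_syn <- 0L; n_nonsyn <- 0L
  if (n_prop > 0) {
    set.seed(seed)
    for (t in seq_len(n_prop)) {
      repeat {
        pos <- sample.int(n_pos, 1)
        ci <- (pos - 1L) %/% 3L + 1L
        off <- (pos - 1L) %% 3L + 1L
        cur <- v[(3 * ci - 2):(3 * ci)]
        b <- sample(setdiff(DNA_BASES, cur[off]), 1)
        nxt <- cur; nxt[off] <- b
        if (codon_aa(paste(nxt, collapse = "")) != "*") break
      }
      syn <- codon_aa(paste(cur, collapse = "")) ==
        codon_aa(paste(nxt, collapse = ""))
      accept <- if (syn) TRUE else stats::runif(1) < omega
      if (accept) {
        v[3 * (ci - 1) + off] <- b
        if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
      }
    }
  }
  list(cds = paste(v, collapse = ""),
       realized_ka = if (N0 > 0) n_nonsyn / N0 else NA_real_,
       realized_ks = if (S0 > 0) n_syn / S0 else NA_real_,
       n_synonymous = n_syn, n_nonsynonymous = n_nonsyn)
}

#' Generate a complete synthetic family genome
#'
#' Produces proteins with domain instances sampled column-wise from the
#' bundled profile emissions, coding sequences by uniform back-translation,
#' gene coordinates on the configured chromosomes (non-overlapping, with
#' >= 1500 bp of intergenic promoter room), chromosome sequences with the
#' CDS embedded strand-aware, planted duplicated pairs, repression motifs
#' (all RAV genes carry [R/K]LFGV; subsets of ERF genes carry FDLNLPP and
#' EDLL), promoter cis-elements planted upstream of stress-upregulated
#' genes, and a truth table recording every planting.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{family_genome} list: \code{proteins}, \code{cds}
#'   (named character vectors), \code{genome} (named character vector of
#'   chromosome sequences), \code{genes} (coordinate data frame),
#'   \code{truth} (truth-table data frame), \code{config}.
#' @export
simulate_family_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- sum(config$counts)
  if (n == 0) stop("zero total genes")
  set.seed(derive_seed(config$seed, 1L))

  subfams <- rep(names(config$counts), config$counts)
  ids <- sprintf("gene%03d", seq_len(n))

  profs <- erf_clade_profiles()
  b3 <- b3_profile()

  proteins <- character(n)
  dompos <- vector("list", n)     # data frames profile/start/end
  motifs <- vector("list", n)     # data frames motif/position
  for (i in seq_len(n)) {
    sf <- subfams[i]
    f1 <- rand_residues(sample(30:80, 1))
    f2 <- rand_residues(sample(60:140, 1))
    doms <- data.frame(profile = character(0), start = integer(0),
                       end = integer(0))
    if (sf %in% c("ERF", "DREB", "DRF", "SOLOIST")) {
      dom <- sample_from_profile(profs[[sf]])
      body <- dom
      doms <- data.frame(profile = "AP2", start = 0L, end = nchar(dom))
    } else if (sf == "AP2") {
      d1 <- sample_from_profile(profs$ERF)
      d2 <- sample_from_profile(profs$ERF)
      linker <- rand_residues(25)
      body <- paste0(d1, linker, d2)
      doms <- data.frame(profile = c("AP2", "AP2"),
                         start = c(0L, nchar(d1) + 25L),
                         end = c(nchar(d1), nchar(d1) + 25L + nchar(d2)))
    } else if (sf == "RAV") {
      d1 <- sample_from_profile(profs$ERF)
      spacer <- rand_residues(sample(20:50, 1))
      d2 <- sample_from_profile(b3)
      body <- paste0(d1, spacer, d2)
      doms <- data.frame(profile = c("AP2", "B3"),
                         start = c(0L, nchar(d1) + nchar(spacer)),
                         end = c(nchar(d1),
                                 nchar(d1) + nchar(spacer) + nchar(d2)))
    } else {                      # NONE
      body <- rand_residues(sample(100:250, 1))
    }
    offset <- 1L + nchar(f1)      # "M" + N-terminal flank, 0-based
    doms$start <- doms$start + offset
    doms$end <- doms$end + offset
    proteins[i] <- paste0("M", f1, body, f2)
    dompos[[i]] <- doms
    motifs[[i]] <- data.frame(motif = character(0), position = integer(0))
  }

  # plant repression motifs into C-terminal flanks
  plant_protein_motif <- function(i, name, text) {
    p <- proteins[i]
    len <- nchar(p)
    at <- len - sample(10:40, 1) - nchar(text)   # 0-based insertion point
    substr(p, at + 1, at + nchar(text)) <- text
    proteins[i] <<- p
    motifs[[i]] <<- rbind(motifs[[i]],
                          data.frame(motif = name, position = as.integer(at)))
  }
  for (i in which(subfams == "RAV"))
    plant_protein_motif(i, "RKLFGV", paste0(sample(c("R", "K"), 1), "LFGV"))
  erf_idx <- which(subfams == "ERF")
  n_fdln <- min(4L, length(erf_idx) %/% 3L)
  n_edll <- min(6L, length(erf_idx) %/% 3L)
  picked <- if (length(erf_idx)) sample(erf_idx, min(length(erf_idx),
                                                     n_fdln + n_edll))
            else integer(0)
  for (i in utils::head(picked, n_fdln))
    plant_protein_motif(i, "FDLNLPP", "FDLNLPP")
  for (i in utils::tail(picked, length(picked) - n_fdln))
    plant_protein_motif(i, "EDLL", "EDLL")

  # back-translate
  cds <- vapply(proteins, back_translate, character(1), USE.NAMES = FALSE)

  # expression classes
  classes <- rep("ubiquitous", n)
  shuffled <- sample(n)
  n_sil <- max(1L, round(0.06 * n)); n_up <- max(1L, round(0.10 * n))
  n_down <- max(1L, round(0.06 * n)); n_ts <- max(1L, round(0.15 * n))
  take <- function(k) {
    k <- min(k, length(shuffled))
    out <- utils::head(shuffled, k)
    shuffled <<- utils::tail(shuffled, length(shuffled) - k)
    out
  }
  classes[take(n_sil)] <- "silent"
  classes[take(n_up)] <- "stress_up"
  classes[take(n_down)] <- "stress_down"
  ts_idx <- take(n_ts)
  classes[ts_idx] <- paste0("tissue_specific:",
                            config$tissues[(seq_along(ts_idx) - 1) %%
                                             length(config$tissues) + 1])

  # duplicated pairs within subfamilies
  partner <- rep(NA_character_, n)
  true_omega <- rep(NA_real_, n)
  true_ks <- rep(NA_real_, n)
  unpaired <- split(seq_len(n), subfams)
  k_done <- 0L
  for (k in seq_len(config$n_duplicate_pairs)) {
    sf_order <- c("ERF", "DREB", "DRF", "AP2", "RAV", "SOLOIST")
    sf <- sf_order[vapply(sf_order,
                          function(s) length(unpaired[[s]] %||% integer(0)) >= 2,
                          logical(1))][1]
    if (is.na(sf)) {
      warning("not enough unpaired genes for ", config$n_duplicate_pairs,
              " duplicate pairs; planted ", k_done)
      break
    }
    pick <- sample(unpaired[[sf]], 2)
    unpaired[[sf]] <- setdiff(unpaired[[sf]], pick)
    a <- pick[1]; b <- pick[2]
    omega <- config$omega_grid[(k - 1) %% length(config$omega_grid) + 1]
    mut <- mutate_duplicate(cds[a], omega = omega,
                            ks_target = config$ks_target,
                            seed = derive_seed(config$seed, 100L + k))
    cds[b] <- mut$cds
    proteins[b] <- translate_cds(mut$cds)
    dompos[[b]] <- dompos[[a]]
    motifs[[b]] <- data.frame(motif = character(0), position = integer(0))
    subfams[b] <- subfams[a]
    w <- if (!is.na(mut$realized_ks) && mut$realized_ks > 0)
      mut$realized_ka / mut$realized_ks else NA_real_
    partner[a] <- ids[b]; partner[b] <- ids[a]
    true_omega[a] <- true_omega[b] <- w
    true_ks[a] <- true_ks[b] <- mut$realized_ks
    k_done <- k_done + 1L
  }

  # chromosomal placement: non-overlapping, promoter room on both sides
  chrom <- sample(config$chromosomes, n, replace = TRUE)
  genes <- data.frame(gene_id = ids, chromosome = chrom,
                      start = NA_integer_, end = NA_integer_,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
  genome <- stats::setNames(vector("list", length(unique(chrom))),
                            sort(unique(chrom)))
  for (ch in names(genome)) {
    on_ch <- which(chrom == ch)
    pos <- 2000L
    for (i in on_ch) {
      glen <- nchar(cds[i])
      genes$start[i] <- pos
      genes$end[i] <- pos + glen - 1L
      pos <- pos + glen + sample(3200:7000, 1)  # keeps 1500-bp promoters disjoint
    }
    clen <- max(genes$end[on_ch]) + 2000L
    chseq <- chars(paste(sample(DNA_BASES, clen, replace = TRUE),
                         collapse = ""))
    for (i in on_ch) {
      s <- if (genes$strand[i] == "+") cds[i] else revcomp(cds[i])
      chseq[genes$start[i]:genes$end[i]] <- chars(s)
    }
    genome[[ch]] <- chseq   # keep as char vector until elements are planted
  }

  # plant promoter cis-elements upstream of stress-upregulated genes
  element_instances <- c(DRE = "GCCGAC", ABRE_B = "TCCACGTCTC",
                         re2f_1 = "GCGGGAAA", ACGT_motif = "GTACGTG")
  for (i in which(classes == "stress_up")) {
    picks <- sample(names(element_instances), 2)
    offs <- c(sample(100:700, 1), sample(800:1400, 1))
    for (e in seq_along(picks)) {
      el <- element_instances[[picks[e]]]
      if (picks[e] == "DRE" && stats::runif(1) < 0.5)
        el <- paste0("A", substr(el, 2, nchar(el)))
      p <- offs[e]; w <- nchar(el); ch <- genes$chromosome[i]
      if (genes$strand[i] == "+") {
        g0 <- genes$start[i] - 1500L + p          # 1-based genomic start
        genome[[ch]][g0:(g0 + w - 1L)] <- chars(el)
      } else {
        g0 <- genes$end[i] + 1500L - p - w + 1L
        genome[[ch]][g0:(g0 + w - 1L)] <- chars(revcomp(el))
      }
      motifs[[i]] <- rbind(motifs[[i]],
                           data.frame(motif = picks[e],
                                      position = as.integer(p)))
    }
  }
  genome <- vapply(genome, paste, character(1), collapse = "")

  truth <- data.frame(
    gene_id = ids,
    true_subfamily = subfams,
    domain_positions = vapply(dompos, function(d)
      encode_pairs(d$profile, d$start, d$end), character(1)),
    duplicate_partner = partner,
    true_omega = true_omega,
    true_ks = true_ks,
    planted_motifs = vapply(motifs, function(m)
      encode_pairs(m$motif, m$position), character(1)),
    expression_class = classes,
    stringsAsFactors = FALSE)

  names(proteins) <- ids
  names(cds) <- ids
  structure(list(proteins = proteins, cds = cds, genome = genome,
                 genes = genes, truth = truth, config = config),
            class = "family_genome")
}

#' @export
print.family_genome <- function(x, ...) {
  cat("family_genome:", length(x$proteins), "genes on",
      length(x$genome), "chromosomes;",
      sum(x$truth$true_subfamily != "NONE"), "domain-positive\n")
  invisible(x)
}

#' Write the four genome artifacts to a directory
#'
#' Writes protein and CDS FASTA (60-column wrap), chromosome FASTA, a GFF3
#' of gene features (1-based inclusive, strand +/-), the truth table as
#' TSV and the configuration as YAML. Output is byte-identical for a fixed
#' config and seed.
#'
#' @param fg A \code{family_genome}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_genome_files <- function(fg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("proteins.fasta", "cds.fasta", "genome.fasta",
                            "genes.gff3", "truth.tsv", "config.yaml"))
  aa <- Biostrings::AAStringSet(fg$proteins)
  Biostrings::writeXStringSet(aa, paths[1], width = 60)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fg$cds), paths[2],
                              width = 60)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fg$genome), paths[3],
                              width = 60)
  gr <- GenomicRanges::GRanges(
    seqnames = fg$genes$chromosome,
    ranges = IRanges::IRanges(start = fg$genes$start, end = fg$genes$end),
    strand = fg$genes$strand)
  gr$type <- "gene"
  gr$ID <- fg$genes$gene_id
  rtracklayer::export(gr, paths[4], format = "gff3")
  write_tsv_file(fg$truth, paths[5])
  cfg <- fg$config
  class(cfg) <- NULL
  cfg$counts <- as.list(cfg$counts)
  yaml::write_yaml(cfg, paths[6])
  invisible(paths)
}

#' Generate a synthetic FPKM expression matrix from a truth table
#'
#' Baseline FPKM is log-normal; tissue-specific genes are elevated
#' \code{tissue_fold}-fold in their tissue over a low off-tissue baseline;
#' stress_up / stress_down genes change \code{stress_fold}-fold versus
#' control in every stress column; silent genes are zero everywhere.
#'
#' @param truth Truth-table data frame (needs gene_id, expression_class).
#' @param config A \code{\link{sim_config}}.
#' @return Numeric matrix, genes x (tissues then conditions).
#' @export
generate_expression <- function(truth, config) {
  if (nrow(truth) == 0) stop("truth table is empty")
  set.seed(derive_seed(config$seed, 2L))
  cols <- c(config$tissues, config$conditions)
  m <- matrix(0, nrow(truth), length(cols),
              dimnames = list(truth$gene_id, cols))
  noise <- function(k) stats::rlnorm(k, 0, config$noise_sdlog)
  for (i in seq_len(nrow(truth))) {
    cl <- truth$expression_class[i]
    if (cl == "silent") next
    if (cl == "ubiquitous") {
      base <- stats::rlnorm(1, log(10), 0.3)
      m[i, ] <- base * noise(length(cols))
    } else if (startsWith(cl, "tissue_specific:")) {
      tis <- sub("^tissue_specific:", "", cl)
      if (!tis %in% config$tissues) stop("unknown tissue in class: ", cl)
      off <- stats::rlnorm(1, log(0.2), 0.3)
      m[i, ] <- off * noise(length(cols))
      m[i, tis] <- stats::rlnorm(1, log(10), 0.3) * config$tissue_fold *
        noise(1)
    } else if (cl %in% c("stress_up", "stress_down")) {
      base <- stats::rlnorm(1, log(if (cl == "stress_up") 5 else 20), 0.3)
      m[i, ] <- base * noise(length(cols))
      stress_cols <- setdiff(config$conditions, "control")
      fac <- if (cl == "stress_up") config$stress_fold else
        1 / config$stress_fold
      m[i, stress_cols] <- base * fac * noise(length(stress_cols))
    } else {
      stop("unknown expression class: ", cl)
    }
  }
  m
}

#' Generate a synthetic qPCR Ct table from a truth table
#'
#' Ct model: \code{Ct = offset - log2(expression) + N(0, noise_sd)}; the
#' reference gene has constant expression, so a planted log2 fold change f
#' gives expected ddCt = -f. Default targets are the stress-responsive
#' genes of the truth table.
#'
#' @param truth Truth-table data frame.
#' @param config A \code{\link{sim_config}}.
#' @param genes Target gene ids (default: stress_up / stress_down genes, or
#'   the first gene if none).
#' @param n_replicates Biological replicates per (gene, treatment)
#'   (default 3).
#' @param noise_sd Gaussian Ct noise in cycles (default from config).
#' @param fold Optional linear fold change applied to every non-control
#'   treatment of every target gene, overriding the class-derived folds.
#' @return Data frame: gene, treatment, replicate, ct_target, ct_reference.
#' @export
generate_qpcr <- function(truth, config, genes = NULL, n_replicates = 3,
                          noise_sd = NULL, fold = NULL) {
  if (is.null(noise_sd)) noise_sd <- config$qpcr_noise_sd
  if (is.null(genes)) {
    genes <- truth$gene_id[truth$expression_class %in%
                             c("stress_up", "stress_down")]
    if (length(genes) == 0) genes <- truth$gene_id[1]
  }
  if (length(genes) < 1) stop("need at least one target gene")
  if (n_replicates < 3)
    stop("need >= 3 replicates per condition (three biological replicates)")
  set.seed(derive_seed(config$seed, 3L))
  ref_ct <- 20
  rows <- list()
  for (g in genes) {
    offset <- stats::runif(1, 24, 30)
    cl <- truth$expression_class[truth$gene_id == g]
    for (tr in config$conditions) {
      f <- 0
      if (tr != "control") {
        f <- if (!is.null(fold)) log2(fold)
        else if (identical(cl, "stress_up")) log2(config$stress_fold)
        else if (identical(cl, "stress_down")) -log2(config$stress_fold)
        else 0
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, treatment = tr, replicate = seq_len(n_replicates),
        ct_target = offset - f + stats::rnorm(n_replicates, 0, noise_sd),
        ct_reference = ref_ct + stats::rnorm(n_replicates, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
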