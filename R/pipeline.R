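# End-to-end orchestration: simulate/load inputs, then
# scan -> classify -> props -> evolve -> motifs -> express, writing every
# stage artifact plus a checksummed manifest and a machine-readable report.

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full gene-family characterization pipeline
#'
#' The configuration is a list (or path to a YAML file) with blocks:
#' \describe{
#'   \item{simulate}{arguments for \code{\link{sim_config}}; when present,
#'     all inputs are generated by \code{\link{simulate_family_genome}}.}
#'   \item{inputs}{alternatively, paths: \code{proteins}, \code{cds},
#'     \code{gff} (and optionally \code{genome}, \code{fpkm},
#'     \code{qpcr}).}
#'   \item{scan}{\code{target_evalue} (default 1e-5), \code{min_coverage}
#'     (default 0.7), \code{n_shuffles} (default 200).}
#'   \item{classify}{\code{prefix} (default "TtAP2/ERF-").}
#'   \item{evolve}{\code{identity_threshold} (default 0.85),
#'     \code{bootstrap} (default 200).}
#'   \item{express}{\code{min_fpkm}, \code{log2fc_threshold},
#'     \code{tau_threshold}.}
#'   \item{seed}{pipeline seed (also the simulation seed unless the
#'     simulate block sets its own).}
#' }
#'
#' @param config List or path to a YAML configuration.
#' @param out_dir Output directory; all stage artifacts, a
#'   \code{manifest.tsv} (file, md5, stage) and a \code{report.yaml} are
#'   written there.
#' @return A \code{pipeline_report} list (tallies, config echo, seed,
#'   version, wall time, and the stage tables used by
#'   \code{\link{validate_report}}).
#' @export
run_pipeline <- function(config, out_dir) {
  t0 <- Sys.time()
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(file = character(0), md5 = character(0),
                         stage = character(0), stringsAsFactors = FALSE)
  emit <- function(path, stage) {
    manifest <<- rbind(manifest, data.frame(
      file = basename(path), md5 = unname(tools::md5sum(path)),
      stage = stage, stringsAsFactors = FALSE))
  }

  # ---- acquire inputs -------------------------------------------------
  truth <- NULL; genome <- NULL; fpkm <- NULL; qpcr <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    scfg <- stage_run("simulate", do.call(sim_config, sim_args))
    fg <- stage_run("simulate", simulate_family_genome(scfg))
    gdir <- file.path(out_dir, "genome")
    paths <- write_genome_files(fg, gdir)
    for (p in paths) emit(p, "simulate")
    proteins <- fg$proteins; cds <- fg$cds; genes <- fg$genes
    genome <- fg$genome; truth <- fg$truth
    fpkm <- generate_expression(truth, scfg)
    qpcr <- generate_qpcr(truth, scfg)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (k in c("proteins", "cds", "gff"))
      if (is.null(inp[[k]])) stop("config missing input key: ", k)
    for (k in c("proteins", "cds", "gff"))
      if (!file.exists(inp[[k]])) stop("input file not found: ", inp[[k]])
    proteins <- read_protein_fasta(inp$proteins)
    cds <- as.character(Biostrings::readDNAStringSet(inp$cds))
    gr <- rtracklayer::import(inp$gff)
    gr <- gr[gr$type == "gene"]
    genes <- data.frame(
      gene_id = gr$ID, chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    if (!is.null(inp$genome))
      genome <- as.character(Biostrings::readDNAStringSet(inp$genome))
    if (!is.null(inp$truth)) truth <- read_tsv_file(inp$truth)
    if (!is.null(inp$fpkm))
      fpkm <- as.matrix(read_tsv_file(inp$fpkm, row.names = 1))
    if (!is.null(inp$qpcr)) qpcr <- read_tsv_file(inp$qpcr)
  } else {
    stop("config must contain a 'simulate' or an 'inputs' block")
  }

  # ---- scan -----------------------------------------------------------
  scan_cfg <- config$scan %||% list()
  target_e <- scan_cfg$target_evalue %||% 1e-5
  min_cov <- scan_cfg$min_coverage %||% 0.7
  n_shuf <- scan_cfg$n_shuffles %||% 200
  hits <- stage_run("scan", {
    ap2 <- ap2_profile(); b3 <- b3_profile()
    cal_ap2 <- calibrate_threshold(ap2, n_shuffles = n_shuf,
                                   protein_length = 400,
                                   target_evalue = target_e, seed = seed)
    cal_b3 <- calibrate_threshold(b3, n_shuffles = n_shuf,
                                  protein_length = 400,
                                  target_evalue = target_e, seed = seed)
    all <- lapply(names(proteins), function(g) {
      rbind(scan_protein(proteins[[g]], ap2, cal_ap2$threshold, gene_id = g,
                         calibration = cal_ap2),
            scan_protein(proteins[[g]], b3, cal_b3$threshold, gene_id = g,
                         calibration = cal_b3))
    })
    do.call(rbind, all)
  })
  hits <- filter_hits(hits, max_evalue = target_e, min_coverage = min_cov)
  write_tsv_file(hits, file.path(out_dir, "hits.tsv"))
  emit(file.path(out_dir, "hits.tsv"), "scan")

  # ---- classify -------------------------------------------------------
  cls_cfg <- config$classify %||% list()
  classification <- stage_run("classify",
                              classify_family(hits, proteins))
  members <- classification$gene_id[
    !classification$subfamily %in% c("NONE", "UNCLASSIFIED")]
  mem_genes <- genes[genes$gene_id %in% members, , drop = FALSE]
  naming <- stage_run("classify",
                      assign_names(mem_genes,
                                   prefix = cls_cfg$prefix %||% "TtAP2/ERF-"))
  classification$assigned_name <-
    unname(naming[classification$gene_id])
  chrom_dist <- chromosome_distribution(mem_genes)
  write_tsv_file(classification, file.path(out_dir, "classification.tsv"))
  write_tsv_file(data.frame(chromosome = names(chrom_dist$per_chromosome),
                            n_genes = chrom_dist$per_chromosome),
                 file.path(out_dir, "chromosome_counts.tsv"))
  emit(file.path(out_dir, "classification.tsv"), "classify")
  emit(file.path(out_dir, "chromosome_counts.tsv"), "classify")

  # ---- props ----------------------------------------------------------
  physchem <- stage_run("props", physchem_table(proteins[members]))
  write_tsv_file(physchem, file.path(out_dir, "physchem.tsv"))
  emit(file.path(out_dir, "physchem.tsv"), "props")
  ap2_len <- ap2_profile()$length
  domain_seqs <- stage_run("props", {
    out <- character(0)
    for (g in members) {
      h <- hits[hits$gene_id == g & grepl("^AP2", hits$profile) &
                  hits$end - hits$start == ap2_len, , drop = FALSE]
      if (nrow(h) > 0)
        out[g] <- substr(proteins[[g]], h$start[1] + 1, h$end[1])
    }
    out
  })
  if (length(domain_seqs) >= 2) {
    cons <- conservation_profile(unname(domain_seqs))
    write_tsv_file(cons, file.path(out_dir, "conservation.tsv"))
    emit(file.path(out_dir, "conservation.tsv"), "props")
  }

  # ---- evolve ---------------------------------------------------------
  evo_cfg <- config$evolve %||% list()
  duplicates <- stage_run("evolve",
    if (length(members) >= 2)
      duplication_analysis(cds[members],
                           identity_threshold =
                             evo_cfg$identity_threshold %||% 0.85)
    else { d <- kaks_empty(); d$cluster <- integer(0); d })
  write_tsv_file(duplicates, file.path(out_dir, "duplicates.tsv"))
  emit(file.path(out_dir, "duplicates.tsv"), "evolve")

  clades <- character(0)
  if (length(domain_seqs) >= 4) {
    refs <- erf_clade_references()
    ref_leaves <- stats::setNames(unname(refs),
                                  sprintf("REF_%s_%d", names(refs),
                                          seq_along(refs)))
    aln <- c(domain_seqs, ref_leaves)
    tree <- stage_run("evolve",
                      bootstrap_support(aln,
                                        n_replicates =
                                          evo_cfg$bootstrap %||% 200,
                                        seed = seed))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    emit(file.path(out_dir, "tree.nwk"), "evolve")
    ref_labels <- stats::setNames(
      sub("^REF_([A-Z]+)_.*$", "\\1", names(ref_leaves)), names(ref_leaves))
    clades <- stage_run("evolve", assign_clades(tree, ref_labels))
    write_tsv_file(data.frame(gene_id = names(clades), clade = clades),
                   file.path(out_dir, "clades.tsv"))
    emit(file.path(out_dir, "clades.tsv"), "evolve")
  }

  # ---- motifs ---------------------------------------------------------
  rep_motifs <- stage_run("motifs", do.call(rbind, lapply(members,
    function(g) scan_repression_motifs(proteins[[g]], sequence_id = g))))
  if (is.null(rep_motifs)) rep_motifs <- motif_hits_df()
  write_tsv_file(rep_motifs, file.path(out_dir, "repression_motifs.tsv"))
  emit(file.path(out_dir, "repression_motifs.tsv"), "motifs")
  promoter_hits <- motif_hits_df()
  if (!is.null(genome)) {
    promoter_hits <- stage_run("motifs", do.call(rbind, lapply(
      genes$gene_id, function(g) {
        row <- genes[genes$gene_id == g, ]
        prom <- extract_promoter(genome, row)
        scan_promoter_elements(prom, sequence_id = g)
      })))
    write_tsv_file(promoter_hits, file.path(out_dir,
                                            "promoter_elements.tsv"))
    emit(file.path(out_dir, "promoter_elements.tsv"), "motifs")
  }

  # ---- express --------------------------------------------------------
  exp_cfg <- config$express %||% list()
  tissue_classes <- NULL; stress_calls <- NULL; removed <- character(0)
  ddct_table <- NULL
  if (!is.null(fpkm)) {
    filtered <- stage_run("express",
      suppressMessages(filter_unexpressed(fpkm,
        min_fpkm = exp_cfg$min_fpkm %||% 0.5)))
    removed <- attr(filtered, "removed")
    lg <- log2_transform(filtered)
    write_tsv_file(data.frame(gene_id = rownames(lg), lg,
                              check.names = FALSE),
                   file.path(out_dir, "expression_log2.tsv"))
    emit(file.path(out_dir, "expression_log2.tsv"), "express")
    tissue_cols <- intersect(colnames(fpkm),
                             c("leaf", "root", "stem", "grain", "spike"))
    if (length(tissue_cols) >= 2) {
      tissue_classes <- stage_run("express",
        tissue_specificity(filtered, tissues = tissue_cols,
                           tau_threshold = exp_cfg$tau_threshold %||% 0.8))
      write_tsv_file(tissue_classes, file.path(out_dir,
                                               "tissue_classes.tsv"))
      emit(file.path(out_dir, "tissue_classes.tsv"), "express")
    }
    if ("control" %in% colnames(fpkm)) {
      stress_cols <- setdiff(colnames(fpkm),
                             c(tissue_cols, "control"))
      stress_calls <- stage_run("express",
        stress_response_calls(filtered, control = "control",
                              conditions = stress_cols,
                              log2fc_threshold =
                                exp_cfg$log2fc_threshold %||% 1))
      write_tsv_file(stress_calls, file.path(out_dir, "stress_calls.tsv"))
      emit(file.path(out_dir, "stress_calls.tsv"), "express")
    }
  }
  if (!is.null(qpcr)) {
    ddct_table <- stage_run("express", ddct(qpcr))
    write_tsv_file(ddct_table, file.path(out_dir, "ddct.tsv"))
    emit(file.path(out_dir, "ddct.tsv"), "express")
  }

  write_tsv_file(manifest, file.path(out_dir, "manifest.tsv"))

  tally <- table(classification$subfamily)
  report <- structure(list(
    seed = seed,
    version = as.character(tryCatch(utils::packageVersion("genefamkit"),
                                    error = function(e) "dev")),
    config = config,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    counts = list(
      genes_scanned = length(proteins),
      family_members = length(members),
      subfamilies = as.list(tally),
      duplicate_pairs = nrow(duplicates),
      saturated_pairs = sum(duplicates$saturated),
      repression_motif_hits = nrow(rep_motifs),
      promoter_element_hits = nrow(promoter_hits),
      unexpressed_removed = length(removed)),
    tables = list(classification = classification,
                  duplicates = duplicates,
                  repression_motifs = rep_motifs,
                  promoter_elements = promoter_hits,
                  tissue_classes = tissue_classes,
                  stress_calls = stress_calls,
                  ddct = ddct_table,
                  removed_genes = removed,
                  clades = clades),
    manifest = manifest),
    class = "pipeline_report")
  yaml::write_yaml(list(seed = report$seed, version = report$version,
                        wall_time_s = report$wall_time_s,
                        counts = report$counts),
                   file.path(out_dir, "report.yaml"))
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report: ", x$counts$genes_scanned, " genes scanned, ",
      x$counts$family_members, " family members, ",
      x$counts$duplicate_pairs, " duplicate pairs (",
      sprintf("%.1f", x$wall_time_s), " s)\n", sep = "")
  invisible(x)
}

#' Validate a pipeline report against a simulation truth table
#'
#' Compares subfamily assignments, duplicate pairs, planted motif
#' positions and expression classes; an empty result is a pass. At most one
#' discrepancy is reported per (gene, aspect). For planted ubiquitous genes
#' only a silent or tissue-specific observation counts as a discrepancy:
#' the ubiquitous/mixed boundary is a soft tau threshold, not part of the
#' planted signal.
#'
#' @param report A \code{pipeline_report}.
#' @param truth Truth-table data frame from the same run.
#' @return Data frame: gene_id, aspect, expected, observed.
#' @export
validate_report <- function(report, truth) {
  disc <- list()
  add <- function(gene, aspect, expected, observed) {
    disc[[length(disc) + 1]] <<- data.frame(
      gene_id = gene, aspect = aspect, expected = expected,
      observed = observed, stringsAsFactors = FALSE)
  }
  cls <- report$tables$classification
  if (nrow(truth) == 0 && (is.null(cls) || nrow(cls) == 0))
    return(data.frame(gene_id = character(0), aspect = character(0),
                      expected = character(0), observed = character(0)))
  if (!is.null(cls) && nrow(cls) > 0 &&
      length(setdiff(cls$gene_id, truth$gene_id)) > 0)
    stop("gene id mismatch between report and truth")

  # subfamily assignment
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_id[i]
    expected <- truth$true_subfamily[i]
    observed <- cls$subfamily[cls$gene_id == g]
    if (length(observed) == 0) observed <- "NONE"
    if (!identical(observed, expected))
      add(g, "subfamily", expected, observed)
  }

  # duplicate pairs (unordered)
  canon <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  tp <- truth[!is.na(truth$duplicate_partner), , drop = FALSE]
  truth_pairs <- unique(canon(tp$gene_id, tp$duplicate_partner))
  dup <- report$tables$duplicates
  found_pairs <- if (!is.null(dup) && nrow(dup) > 0)
    canon(dup$gene_a, dup$gene_b) else character(0)
  for (p in setdiff(truth_pairs, found_pairs))
    add(p, "duplicate_pair", "retained", "missing")
  for (p in setdiff(found_pairs, truth_pairs))
    add(p, "duplicate_pair", "absent", "retained")

  # planted motifs at exact positions
  prot_names <- names(repression_motif_patterns())
  prom_names <- names(promoter_element_patterns())
  rm_hits <- report$tables$repression_motifs
  pe_hits <- report$tables$promoter_elements
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_id[i]
    planted <- decode_planted_motifs(truth$planted_motifs[i])
    if (nrow(planted) == 0) next
    missing <- character(0)
    for (j in seq_len(nrow(planted))) {
      nm <- planted$motif[j]; pos <- planted$position[j]
      ok <- if (nm %in% prot_names) {
        !is.null(rm_hits) &&
          any(rm_hits$sequence_id == g & rm_hits$motif_name == nm &
                rm_hits$start == pos)
      } else if (nm %in% prom_names) {
        !is.null(pe_hits) &&
          any(pe_hits$sequence_id == g & pe_hits$motif_name == nm &
                pe_hits$start == pos)
      } else NA
      if (isFALSE(ok)) missing <- c(missing, paste0(nm, "@", pos))
    }
    if (length(missing))
      add(g, "planted_motifs", paste(missing, collapse = ";"), "not found")
  }

  # expression classes
  tc <- report$tables$tissue_classes
  sc <- report$tables$stress_calls
  removed <- report$tables$removed_genes %||% character(0)
  if (!is.null(tc) || !is.null(sc)) {
    for (i in seq_len(nrow(truth))) {
      g <- truth$gene_id[i]
      cl <- truth$expression_class[i]
      if (cl == "silent") {
        ok <- g %in% removed ||
          (!is.null(tc) && any(tc$gene_id == g & tc$class == "silent"))
        if (!ok) add(g, "expression", "silent", "expressed")
      } else if (startsWith(cl, "tissue_specific:")) {
        if (!is.null(tc)) {
          obs <- tc$class[tc$gene_id == g]
          if (length(obs) != 1 || obs != cl)
            add(g, "expression", cl,
                if (length(obs)) obs else "missing")
        }
      } else if (cl == "ubiquitous") {
        # the tau bin boundary (0.2) is soft: a broadly expressed gene may
        # land in "mixed"; only a silent or tissue-specific observation
        # contradicts the planted signal
        if (!is.null(tc)) {
          obs <- tc$class[tc$gene_id == g]
          if (length(obs) != 1 || obs == "silent" ||
                startsWith(obs, "tissue_specific:"))
            add(g, "expression", cl,
                if (length(obs)) obs else "missing")
        }
      } else if (cl %in% c("stress_up", "stress_down")) {
        if (!is.null(sc)) {
          want <- if (cl == "stress_up") "up" else "down"
          obs <- sc$call[sc$gene_id == g]
          if (length(obs) == 0 || !all(obs == want))
            add(g, "expression", cl, paste(unique(obs), collapse = ","))
        }
      }
    }
  }

  if (length(disc) == 0)
    return(data.frame(gene_id = character(0), aspect = character(0),
                      expected = character(0), observed = character(0)))
  do.call(rbind, disc)
}
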