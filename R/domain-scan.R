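# Window scanning of proteins against domain profiles, null calibration of
# bit-score thresholds, and HMMER3 interoperability.
#
# Scanning is gap-free: the profile is slid along the protein and per-column
# log-odds scores are summed. Windows overhanging either sequence end are
# scored on their matched columns only, which reduces their coverage. This
# serves the gap-free synthetic fixtures; real-genome searches can be
# imported from HMMER3 with read_domtblout().

new_hits <- function(gene_id = character(0), profile = character(0),
                     start = integer(0), end = integer(0),
                     score = numeric(0), evalue = numeric(0),
                     coverage = numeric(0)) {
  data.frame(gene_id = gene_id, profile = profile, start = start, end = end,
             score = score, evalue = evalue, coverage = coverage,
             stringsAsFactors = FALSE)
}

#' Scan a protein with a domain profile
#'
#' Slides the profile over the protein (all placements, including truncated
#' windows at the ends), sums per-column bit scores, keeps placements with
#' score >= threshold, and greedily reduces them to a non-overlapping set by
#' descending score (ties broken by smaller start).
#'
#' Non-standard residues (X, B, Z, ...) score 0 (background) and count
#' against coverage. Coordinates in the result are 0-based half-open.
#'
#' @param protein Protein sequence (character scalar).
#' @param profile A \code{domain_profile}.
#' @param threshold Bit-score threshold (finite). Typically obtained from
#'   \code{\link{calibrate_threshold}}.
#' @param gene_id Identifier recorded in the hits.
#' @param calibration Optional \code{domain_calibration}; when supplied, each
#'   hit gets an E-value on the protein's search space, otherwise E-values
#'   are \code{NA}.
#' @param nonoverlapping Reduce to a non-overlapping set (default TRUE).
#' @return Data frame of hits: gene_id, profile, start, end, score, evalue,
#'   coverage; ordered by start.
#' @export
scan_protein <- function(protein, profile, threshold, gene_id = "protein",
                         calibration = NULL, nonoverlapping = TRUE) {
  stopifnot(is.finite(threshold))
  len <- nchar(protein)
  if (len < 10) {
    message("protein '", gene_id, "' shorter than 10 residues; no scan")
    return(new_hits())
  }
  L <- profile$length
  res <- chars(protein)
  # residue -> row index in score matrix; non-standard residues score 0
  ridx <- match(res, AMINO_ACIDS)

  offsets <- seq(-(L - 1L), len - 1L)    # 0-based protein position of column 1
  nscore <- numeric(length(offsets))
  ncols <- integer(length(offsets))
  for (c in seq_len(L)) {
    pos <- offsets + (c - 1L)            # 0-based position matched by column c
    ok <- pos >= 0L & pos < len
    ri <- ridx[pos[ok] + 1L]
    contrib <- ifelse(is.na(ri), 0, profile$scores[cbind(ri, c)])
    contrib[is.na(contrib)] <- 0
    nscore[ok] <- nscore[ok] + contrib
    ncols[ok] <- ncols[ok] + 1L
  }

  keep <- nscore >= threshold
  if (!any(keep)) return(new_hits())
  off <- offsets[keep]
  sc <- nscore[keep]
  cov <- ncols[keep] / L
  start <- pmax(off, 0L)
  end <- pmin(off + L, len)

  ord <- order(-sc, start)
  sel <- logical(length(ord))
  if (nonoverlapping) {
    taken_start <- integer(0); taken_end <- integer(0)
    for (i in ord) {
      if (!any(start[i] < taken_end & end[i] > taken_start)) {
        sel[i] <- TRUE
        taken_start <- c(taken_start, start[i])
        taken_end <- c(taken_end, end[i])
      }
    }
  } else sel[] <- TRUE

  ev <- rep(NA_real_, sum(sel))
  if (!is.null(calibration)) {
    ev <- hit_evalue(sc[sel], calibration, protein_length = len)
  }
  out <- new_hits(gene_id = rep(gene_id, sum(sel)),
                  profile = rep(profile$name, sum(sel)),
                  start = start[sel], end = end[sel], score = sc[sel],
                  evalue = ev, coverage = cov[sel])
  out[order(out$start), , drop = FALSE]
}

#' Calibrate a bit-score threshold for a target E-value
#'
#' Scores \code{n_shuffles} random background proteins of length
#' \code{protein_length}, fits a Gumbel law to the per-sequence maximum
#' window scores by the method of moments, and returns the score whose
#' expected number of null hits per search equals \code{target_evalue}.
#' The search space is scaled per protein as
#' \code{protein_length - profile_length + 1} windows.
#'
#' @param profile A \code{domain_profile}.
#' @param n_shuffles Number of null sequences (>= 100).
#' @param protein_length Length of the null sequences.
#' @param target_evalue Expected null hits per search at the returned
#'   threshold (default 1e-5, the conventional domain-search cutoff).
#' @param seed Integer seed for the null draws.
#' @return A \code{domain_calibration} object: threshold (bits), Gumbel
#'   location/scale, calibration search space, and the inputs.
#' @export
calibrate_threshold <- function(profile, n_shuffles = 200,
                                protein_length = 400,
                                target_evalue = 1e-5, seed = 1) {
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  set.seed(derive_seed(seed, 17L))
  bg <- profile$background
  maxima <- vapply(seq_len(n_shuffles), function(i) {
    prot <- paste(sample(AMINO_ACIDS, protein_length, replace = TRUE,
                         prob = bg), collapse = "")
    h <- scan_protein(prot, profile, threshold = -.Machine$double.xmax,
                      gene_id = "null", nonoverlapping = FALSE)
    max(h$score)
  }, numeric(1))
  m <- mean(maxima); s <- stats::sd(maxima)
  if (!is.finite(s) || s < 1e-12) stop("degenerate (zero-variance) null")
  beta <- s * sqrt(6) / pi
  mu <- m - 0.57721566490153 * beta
  thr <- mu - beta * log(target_evalue)
  structure(list(profile_name = profile$name, threshold = thr,
                 mu = mu, beta = beta,
                 window_count = max(1L, protein_length - profile$length + 1L),
                 profile_length = profile$length,
                 protein_length = protein_length,
                 target_evalue = target_evalue, n_shuffles = n_shuffles,
                 seed = seed),
            class = "domain_calibration")
}

#' @export
print.domain_calibration <- function(x, ...) {
  cat(sprintf(
    "domain_calibration '%s': threshold %.2f bits (E <= %g, Gumbel mu=%.2f beta=%.2f)\n",
    x$profile_name, x$threshold, x$target_evalue, x$mu, x$beta))
  invisible(x)
}

#' E-value of a hit score under a calibration
#'
#' Converts bit scores to expected null hit counts for a search of the given
#' protein length, scaling the calibrated exceedance rate by the ratio of
#' window counts.
#' @param score Numeric vector of bit scores.
#' @param calibration A \code{domain_calibration}.
#' @param protein_length Length of the searched protein.
#' @return Numeric vector of E-values.
#' @export
hit_evalue <- function(score, calibration, protein_length) {
  w <- max(1L, protein_length - calibration$profile_length + 1L)
  (w / calibration$window_count) *
    exp(-(score - calibration$mu) / calibration$beta)
}

#' Read a HMMER3 per-domain table (domtblout)
#'
#' Maps each domain row to a hit with envelope coordinates converted from
#' 1-based inclusive to 0-based half-open, the independent E-value as
#' \code{evalue}, and coverage computed as matched HMM columns over the
#' model length.
#'
#' @param path Path to a HMMER3 \code{--domtblout} file.
#' @return Data frame of hits (see \code{\link{scan_protein}}).
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  out <- new_hits()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(f) < 22)
      stop("malformed domtblout line ", i, ": expected >= 22 fields, got ",
           length(f))
    qlen <- suppressWarnings(as.numeric(f[6]))
    env_from <- suppressWarnings(as.numeric(f[20]))
    env_to <- suppressWarnings(as.numeric(f[21]))
    ievalue <- suppressWarnings(as.numeric(f[13]))
    dscore <- suppressWarnings(as.numeric(f[14]))
    hmm_from <- suppressWarnings(as.numeric(f[16]))
    hmm_to <- suppressWarnings(as.numeric(f[17]))
    if (anyNA(c(qlen, env_from, env_to, ievalue, dscore, hmm_from, hmm_to)))
      stop("malformed domtblout line ", i, ": non-numeric field")
    out <- rbind(out, new_hits(
      gene_id = f[1], profile = f[4],
      start = as.integer(env_from - 1), end = as.integer(env_to),
      score = dscore, evalue = ievalue,
      coverage = (hmm_to - hmm_from + 1) / qlen))
  }
  out
}

#' Filter domain hits by E-value and profile coverage
#'
#' Mirrors the removal of partial or low-quality domain hits: keeps hits with
#' \code{evalue <= max_evalue} and \code{coverage >= min_coverage}, in input
#' order. Hits with \code{NA} E-values (uncalibrated scans) are filtered on
#' coverage only.
#'
#' @param hits Hit data frame.
#' @param max_evalue Maximum E-value (default 1e-5).
#' @param min_coverage Minimum fraction of profile columns matched
#'   (default 0.7).
#' @return Filtered hit data frame.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_coverage = 0.7) {
  if (max_evalue < 0 || min_coverage < 0 || min_coverage > 1)
    stop("thresholds out of range")
  if (nrow(hits) == 0) return(hits)
  ev_ok <- is.na(hits$evalue) | hits$evalue <= max_evalue
  keep <- ev_ok & hits$coverage >= min_coverage
  hits[keep, , drop = FALSE]
}
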