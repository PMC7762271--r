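# Expression workflow: FPKM filtering and transformation, tissue-specificity
# grouping (tau index), stress up/down calls, and 2^-ddCt qPCR analysis with
# replicate t-tests.

#' Remove genes not expressed in any sample
#'
#' Drops genes whose FPKM is below \code{min_fpkm} in every column; the
#' removed gene ids are reported via a message and the "removed" attribute.
#'
#' @param matrix Numeric FPKM matrix (genes x samples).
#' @param min_fpkm Expression floor (default 0.5).
#' @return Filtered matrix.
#' @export
filter_unexpressed <- function(matrix, min_fpkm = 0.5) {
  keep <- apply(matrix, 1, function(x) any(x >= min_fpkm))
  removed <- rownames(matrix)[!keep]
  if (length(removed))
    message("removed ", length(removed), " unexpressed gene(s): ",
            paste(removed, collapse = ", "))
  out <- matrix[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no genes remain after expression filter")
  attr(out, "removed") <- removed
  out
}

#' log2 transform with pseudocount
#' @param matrix Numeric matrix.
#' @param pseudocount Added before taking log2 (default 1).
#' @return Transformed matrix.
#' @export
log2_transform <- function(matrix, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  log2(matrix + pseudocount)
}

#' Tissue-specificity classification by the tau index
#'
#' tau is computed on log2(FPKM + 1) values over the tissue columns:
#' \code{tau = sum(1 - x_i / x_max) / (n - 1)}, ranging from 0 (uniform)
#' to 1 (single-tissue). A gene is tissue_specific:<tissue> when
#' \code{tau >= tau_threshold} and its peak FPKM reaches
#' \code{min_peak_fpkm}; ubiquitous when \code{tau <= 0.2} and every tissue
#' reaches \code{min_peak_fpkm}; silent when all tissues are zero; mixed
#' otherwise.
#'
#' @param matrix FPKM matrix containing the tissue columns.
#' @param tissues Tissue column names (>= 2).
#' @param tau_threshold Specificity threshold (default 0.8).
#' @param min_peak_fpkm Minimum peak FPKM for a specific call (default 1).
#' @return Data frame: gene_id, tau, peak_tissue, peak_fpkm, class.
#' @export
tissue_specificity <- function(matrix, tissues = colnames(matrix),
                               tau_threshold = 0.8, min_peak_fpkm = 1) {
  if (length(tissues) < 2) stop("need >= 2 tissues")
  sub <- matrix[, tissues, drop = FALSE]
  out <- lapply(seq_len(nrow(sub)), function(i) {
    v <- sub[i, ]
    if (all(v == 0)) {
      return(data.frame(gene_id = rownames(sub)[i], tau = NA_real_,
                        peak_tissue = NA_character_, peak_fpkm = 0,
                        class = "silent", stringsAsFactors = FALSE))
    }
    x <- log2(v + 1)
    xmax <- max(x)
    tau <- sum(1 - x / xmax) / (length(x) - 1)
    peak <- tissues[which.max(v)]
    cl <- if (tau >= tau_threshold && max(v) >= min_peak_fpkm)
      paste0("tissue_specific:", peak)
    else if (tau <= 0.2 && all(v >= min_peak_fpkm)) "ubiquitous"
    else "mixed"
    data.frame(gene_id = rownames(sub)[i], tau = tau, peak_tissue = peak,
               peak_fpkm = max(v), class = cl, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Stress up/down calls from control and stress columns
#'
#' \code{log2FC = log2((stress + pseudocount) / (control + pseudocount))};
#' a gene is "up" in a condition when log2FC >= threshold, "down" when
#' <= -threshold, otherwise "ns". Genes below \code{min_fpkm} in both the
#' control and the stress column are "ns" regardless of ratio.
#'
#' @param matrix FPKM matrix containing the control and stress columns.
#' @param control Name of the single control column (default "control").
#' @param conditions Stress column names (default: all columns except the
#'   control that are present in the matrix).
#' @param log2fc_threshold Fold-change threshold in log2 units (default 1).
#' @param min_fpkm Expression floor below which calls are ns (default 0.5).
#' @param pseudocount Added to both numerator and denominator (default 0.5).
#' @return Long data frame: gene_id, condition, log2fc, call.
#' @export
stress_response_calls <- function(matrix, control = "control",
                                  conditions = NULL,
                                  log2fc_threshold = 1, min_fpkm = 0.5,
                                  pseudocount = 0.5) {
  if (!control %in% colnames(matrix))
    stop("missing control column: ", control)
  if (is.null(conditions))
    conditions <- setdiff(colnames(matrix), control)
  out <- list()
  for (cond in conditions) {
    s <- matrix[, cond]; c0 <- matrix[, control]
    lfc <- log2((s + pseudocount) / (c0 + pseudocount))
    call <- ifelse(lfc >= log2fc_threshold, "up",
                   ifelse(lfc <= -log2fc_threshold, "down", "ns"))
    call[s < min_fpkm & c0 < min_fpkm] <- "ns"
    out[[cond]] <- data.frame(gene_id = rownames(matrix), condition = cond,
                              log2fc = unname(lfc), call = unname(call),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct(target) - Ct(reference); ddCt is the mean dCt of
#' the treatment minus the mean dCt of the control, and relative expression
#' is 2^-ddCt. The p-value is a two-sided two-sample Student's t-test
#' (equal variances by default; Welch via \code{var_equal = FALSE}) on the
#' replicate dCt values, with significance conventionally marked at
#' p < 0.05.
#'
#' @param qpcr Data frame with columns gene, treatment, replicate,
#'   ct_target, ct_reference.
#' @param control_treatment Label of the control treatment.
#' @param var_equal Use the classic equal-variance t-test (default TRUE).
#' @return Data frame: gene, treatment, ddct, relative_expression, p_value,
#'   significant.
#' @export
ddct <- function(qpcr, control_treatment = "control", var_equal = TRUE) {
  needed <- c("gene", "treatment", "replicate", "ct_target", "ct_reference")
  if (!all(needed %in% names(qpcr)))
    stop("qpcr table must have columns: ", paste(needed, collapse = ", "))
  if (anyNA(qpcr$ct_reference)) stop("missing reference Ct value(s)")
  if (anyNA(qpcr$ct_target)) stop("missing target Ct value(s)")
  if (!control_treatment %in% qpcr$treatment)
    stop("control treatment not present: ", control_treatment)
  qpcr$dct <- qpcr$ct_target - qpcr$ct_reference
  out <- list()
  for (g in unique(qpcr$gene)) {
    sub <- qpcr[qpcr$gene == g, ]
    ctrl <- sub$dct[sub$treatment == control_treatment]
    if (length(ctrl) < 2) stop("need >= 2 control replicates for gene ", g)
    for (tr in setdiff(unique(sub$treatment), control_treatment)) {
      trt <- sub$dct[sub$treatment == tr]
      if (length(trt) < 2) stop("need >= 2 replicates for ", g, " / ", tr)
      dd <- mean(trt) - mean(ctrl)
      # identical replicate sets have zero variance; the t statistic is
      # undefined there, so the p-value is resolved by the mean difference
      if (stats::sd(c(trt - mean(trt), ctrl - mean(ctrl))) < 1e-12) {
        p <- if (abs(dd) < 1e-12) 1 else 0
      } else {
        p <- stats::t.test(trt, ctrl, var.equal = var_equal)$p.value
      }
      out[[length(out) + 1]] <- data.frame(
        gene = g, treatment = tr, ddct = dd,
        relative_expression = 2^(-dd), p_value = p,
        significant = p < 0.05, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
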