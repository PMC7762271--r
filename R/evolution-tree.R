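# Neighbor-joining phylogeny with bootstrap support and clade assignment.
#
# NJ is implemented directly (Saitou-Nei Q criterion, deterministic
# tie-breaks, negative branch lengths clamped with the deficit moved to the
# sister branch); trees are returned as ape "phylo" objects so the rest of
# the R phylogenetics ecosystem applies.

#' Neighbor-joining tree from a distance matrix
#'
#' Iteratively joins the pair minimizing the Q criterion
#' \code{Q(i,j) = (r-2) d(i,j) - R_i - R_j}; ties are broken by the smallest
#' (i, j) index pair in the current matrix. Negative branch lengths are
#' clamped to zero with the deficit transferred to the sister branch. The
#' final tree is unrooted with a root trifurcation.
#'
#' @param distances Symmetric numeric matrix with zero diagonal and
#'   labeled rows/columns; n >= 3.
#' @return An \code{ape::phylo} tree with branch lengths.
#' @export
nj_tree <- function(distances) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(!is.finite(D))) stop("distances must be finite")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  sub <- labels                       # newick fragment per active node

  fmt <- function(x) sprintf("%.10g", x)
  clamp2 <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }

  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    bi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    b <- clamp2(bi, bj)
    merged <- paste0("(", sub[i], ":", fmt(b[1]), ",",
                     sub[j], ":", fmt(b[2]), ")")
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    sub <- c(sub[keep], merged)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
  }
  bx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  by <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  bz <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", sub[1], ":", fmt(max(bx, 0)), ",",
                sub[2], ":", fmt(max(by, 0)), ",",
                sub[3], ":", fmt(max(bz, 0)), ");")
  ape::read.tree(text = nwk)
}

#' Uncorrected p-distance matrix for aligned sequences
#'
#' @param aligned Named character vector of equal-length residue strings.
#' @return Symmetric matrix of per-column mismatch fractions.
#' @export
p_distance <- function(aligned) {
  if (length(unique(nchar(aligned))) != 1)
    stop("sequences must have equal lengths")
  mat <- do.call(rbind, strsplit(aligned, ""))
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- mean(mat[i, ] != mat[j, ])
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' NJ tree with column-resampling bootstrap supports
#'
#' Builds the reference NJ tree from p-distances on the aligned domain
#' columns, then resamples columns with replacement \code{n_replicates}
#' times; the support of each internal bipartition is the percentage of
#' replicate NJ trees containing it. Replicate RNG streams are derived from
#' one seed by counter offset, so results are reproducible.
#'
#' @param aligned Named character vector of >= 4 equal-length sequences.
#' @param n_replicates Bootstrap replicates (default 1000, the conventional
#'   choice; 0 returns the tree without supports).
#' @param seed Integer seed.
#' @return \code{ape::phylo} tree; supports (0-100) in \code{node.label}
#'   when \code{n_replicates > 0}.
#' @export
bootstrap_support <- function(aligned, n_replicates = 1000, seed = 1) {
  if (length(aligned) < 4) stop("need at least 4 sequences")
  ref <- nj_tree(p_distance(aligned))
  if (n_replicates == 0) return(ref)
  L <- nchar(aligned[1])
  mat <- do.call(rbind, strsplit(aligned, ""))
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, b))
    cols <- sample.int(L, L, replace = TRUE)
    sub <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    names(sub) <- names(aligned)
    reps[[b]] <- nj_tree(p_distance(sub))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- round(100 * counts / n_replicates, 1)
  ref
}

#' Assign clades to unlabeled leaves by nearest labeled leaf
#'
#' Each unlabeled leaf takes the clade of the nearest labeled reference leaf
#' by patristic (path-length) distance; distance ties are broken by the
#' alphabetically smallest clade id.
#'
#' @param tree \code{ape::phylo} tree.
#' @param reference_labels Named character vector: names are reference leaf
#'   labels present in the tree, values their clade ids.
#' @return Named character vector of clade ids for all non-reference leaves.
#' @export
assign_clades <- function(tree, reference_labels) {
  if (length(reference_labels) == 0) stop("no reference leaves supplied")
  refs <- names(reference_labels)
  missing_refs <- setdiff(refs, tree$tip.label)
  if (length(missing_refs))
    stop("reference leaves not in tree: ", paste(missing_refs, collapse = ", "))
  pat <- ape::cophenetic.phylo(tree)
  query <- setdiff(tree$tip.label, refs)
  out <- stats::setNames(character(length(query)), query)
  for (q in query) {
    d <- pat[q, refs]
    best <- d <= min(d) + 1e-12
    out[q] <- sort(unique(unname(reference_labels[best])))[1]
  }
  out
}
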