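# Pairwise p-distance matrices, neighbor-joining trees and bootstrap support
# over reference-projected alignments.

# integer-encoded column matrix (rows = loci, cols = reference positions);
# 0 encodes gap/N
projection_matrix <- function(projections, model, region = "full") {
  if (region == "full") {
    pos <- seq_along(projections[[1]]$matched)
  } else {
    s <- region_span(model, region)
    pos <- (s$start + 1L):s$end
  }
  labels <- vapply(projections, function(p) p$locus_id %||% NA_character_,
                   character(1))
  if (any(is.na(labels))) labels <- paste0("seq", seq_along(projections))
  m <- t(vapply(projections, function(p) {
    match(p$matched[pos], DNA_BASES, nomatch = 0L)
  }, integer(length(pos))))
  rownames(m) <- labels
  m
}

cpg_mask_matrix <- function(m) {
  # TRUE where a position is part of a CG dinucleotide in that row
  n <- ncol(m)
  mask <- matrix(FALSE, nrow(m), n)
  if (n >= 2) {
    hit <- m[, -n, drop = FALSE] == 2L & m[, -1, drop = FALSE] == 3L
    mask[, -n][hit] <- TRUE
    mask[, -1][hit] <- TRUE
  }
  mask
}

#' Pairwise p-distance matrix over reference-projected loci
#'
#' Entry (i, j) is the p-distance over reference columns where neither locus
#' has a gap or N (pairwise deletion), optionally excluding CpG positions.
#'
#' @param projections List of `erv_projection` (>= 3), or a pre-built
#'   character matrix of aligned sequences (rows named).
#' @param model An `erv_reference` (unused for matrix input with
#'   `region = "full"`).
#' @param region Region name or `"full"`.
#' @param mask_cpg Exclude CpG positions (default `TRUE`).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(projections, model = NULL, region = "full",
                            mask_cpg = TRUE) {
  if (is.matrix(projections) && is.character(projections)) {
    m <- matrix(match(projections, DNA_BASES, nomatch = 0L),
                nrow(projections), ncol(projections),
                dimnames = dimnames(projections))
  } else {
    if (length(projections) < 3) abort("need at least 3 sequences")
    m <- projection_matrix(projections, model, region)
  }
  dist_from_encoded(m, mask_cpg)
}

dist_from_encoded <- function(m, mask_cpg) {
  n <- nrow(m)
  ok <- m > 0L
  if (mask_cpg) ok <- ok & !cpg_mask_matrix(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- ok[i, ] & ok[j, ]
      s <- sum(shared)
      if (s == 0) {
        abort(sprintf("no shared columns between %s and %s",
                      rownames(m)[i], rownames(m)[j]))
      }
      d[i, j] <- d[j, i] <- sum(m[i, shared] != m[j, shared]) / s
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration via [ape::nj()]. Negative branch-length
#' estimates are clamped to zero with a warning. On an additive matrix the
#' generating topology and branch lengths are recovered exactly.
#'
#' @param dm Symmetric distance matrix with labels.
#' @return An [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || !isSymmetric(unname(dm), tol = 1e-8)) {
    abort("distance matrix must be symmetric")
  }
  if (nrow(dm) < 3) abort("need at least 3 labels")
  tree <- ape::nj(stats::as.dist(dm))
  if (any(tree$edge.length < 0)) {
    warning(sprintf("%d negative NJ branch length(s) clamped to 0",
                    sum(tree$edge.length < 0)))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples reference-projected columns with replacement `n_reps` times,
#' rebuilds the NJ tree per replicate, and annotates each internal edge of the
#' full-data tree with the percentage of replicate trees containing that
#' split.
#'
#' @param projections List of `erv_projection`, or a character matrix of
#'   aligned rows.
#' @param model An `erv_reference`.
#' @param region Region name or `"full"`.
#' @param n_reps Bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @param mask_cpg Exclude CpG positions (default `TRUE`).
#' @return An [ape::phylo] with supports (0-100) in `node.label`.
#' @export
bootstrap_support <- function(projections, model = NULL, region = "full",
                              n_reps = 500, seed = 1, mask_cpg = TRUE) {
  stopifnot(n_reps >= 1)
  if (is.matrix(projections) && is.character(projections)) {
    m <- matrix(match(projections, DNA_BASES, nomatch = 0L),
                nrow(projections), ncol(projections),
                dimnames = dimnames(projections))
  } else {
    m <- projection_matrix(projections, model, region)
  }
  main <- nj_tree(dist_from_encoded(m, mask_cpg))
  reps <- with_seed(seed_stream(seed, "bootstrap"), {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      suppressWarnings(nj_tree(dist_from_encoded(m[, cols, drop = FALSE],
                                                 mask_cpg)))
    })
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- as.character(round(100 * counts / n_reps))
  main
}

#' Split support for a bipartition defined by a set of tip labels
#'
#' Convenience accessor: the bootstrap support (from `node.label`) of the
#' smallest clade containing exactly the given tips, or `NA` when the tree
#' does not contain that split.
#'
#' @param tree A `phylo` with `node.label` supports.
#' @param tips Character vector of tip labels.
#' @return Numeric support in 0-100, or `NA`.
#' @export
split_support <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  node <- tryCatch(ape::getMRCA(tree, tips), error = function(e) NULL)
  if (is.null(node)) return(NA_real_)
  clade_tips <- ape::extract.clade(tree, node)$tip.label
  if (!setequal(clade_tips, tips)) return(NA_real_)
  as.numeric(tree$node.label[node - ape::Ntip(tree)])
}
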