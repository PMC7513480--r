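# Neighbor-joining trees from K2P matrices, with column bootstrap.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]).  Negative
#' branch lengths are clamped to zero (the usual convention), with a
#' message reporting how many edges were clamped.
#'
#' @param d Symmetric distance matrix with >= 3 labelled samples and no
#'   undefined entries.
#' @param quiet Suppress the clamping message.
#' @return An [ape::phylo] (unrooted) tree; attribute `"n_clamped"` gives
#'   the number of clamped edges.
#' @export
nj_tree <- function(d, quiet = FALSE) {
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 samples")
  if (anyNA(d)) {
    bad <- unique(rownames(d)[rowSums(is.na(d)) > 0])
    stop("distance matrix has undefined entries; exclude samples: ",
         paste(bad, collapse = ", "))
  }
  phy <- ape::nj(d)
  n_clamped <- sum(phy$edge.length < 0)
  if (n_clamped > 0L) {
    if (!quiet) message("clamped ", n_clamped,
                        " negative branch length(s) to 0")
    phy$edge.length[phy$edge.length < 0] <- 0
  }
  attr(phy, "n_clamped") <- n_clamped
  phy
}

#' Neighbor-joining tree with nonparametric column bootstrap
#'
#' Resamples alignment columns with replacement, recomputes the K2P
#' matrix and NJ tree per replicate, and reports for each internal edge
#' of the original tree the percentage of valid replicates containing the
#' same bipartition.  Replicates whose resampled matrix has undefined
#' distances are dropped (and counted).
#'
#' @param aln An `aligned_set`.
#' @param replicates Number of bootstrap replicates.
#' @param seed Optional integer seed; a fixed seed makes supports
#'   reproducible.
#' @return The original NJ tree with `node.label` set to bootstrap
#'   support percentages (the root label is `NA`), plus attributes
#'   `"n_valid"` and `"n_dropped"`.
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = NULL) {
  aln <- validate_alignment(aln)
  if (!is.null(seed)) set.seed(seed)
  d0 <- k2p_matrix(aln, quiet = TRUE)
  phy <- nj_tree(d0, quiet = TRUE)
  L <- aln$length
  trees <- vector("list", replicates)
  n_valid <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    sub <- structure(list(mat = aln$mat[, cols, drop = FALSE],
                          meta = aln$meta, length = L),
                     class = "aligned_set")
    dr <- k2p_matrix(sub, quiet = TRUE)
    if (anyNA(dr)) next
    n_valid <- n_valid + 1L
    trees[[n_valid]] <- nj_tree(dr, quiet = TRUE)
  }
  trees <- trees[seq_len(n_valid)]
  if (n_valid == 0L) stop("every bootstrap replicate had undefined distances")
  counts <- ape::prop.clades(phy, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_valid
  support[1L] <- NA_real_  # root bipartition is trivial
  phy$node.label <- support
  attr(phy, "n_valid") <- n_valid
  attr(phy, "n_dropped") <- replicates - n_valid
  phy
}

#' Write a tree in Newick format
#'
#' Bootstrap supports, if present, are written as internal node labels.
#'
#' @param phy An [ape::phylo].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}
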