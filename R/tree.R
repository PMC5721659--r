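# Distance-based topology recovery: Jukes-Cantor distances, neighbor
# joining, column-resampling bootstrap, Robinson-Foulds comparison.

#' Jukes-Cantor distance matrix from an alignment
#'
#' For each pair, `p` is the mismatch proportion over comparable columns
#' (both taxa unambiguous and non-gap) and `d = -(3/4) log(1 - 4p/3)`.
#' Saturated pairs (`p >= 3/4`) are flagged `NA`.
#'
#' @param aln a [plastome_alignment()] with >= 2 taxa.
#' @return symmetric matrix of distances (substitutions/site) with a zero
#'   diagonal.
#' @export
jc_distance <- function(aln) {
  if (nrow(aln) < 2L) stop("need at least 2 taxa")
  m <- unclass(aln)
  nt <- nrow(m)
  ok <- matrix(m %in% UNAMBIG, nrow = nt)
  d <- matrix(0, nt, nt, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        stop("no comparable columns between ", rownames(m)[i], " and ",
             rownames(m)[j])
      p <- sum(m[i, comp] != m[j, comp]) / nc
      d[i, j] <- d[j, i] <-
        if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining; negative branch-length estimates
#' are truncated at zero.
#'
#' @param dm complete symmetric distance matrix (>= 3 taxa, no missing
#'   entries).
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(dm)) stop("distance matrix has missing entries")
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for the neighbor-joining topology
#'
#' Alignment columns are resampled with replacement `n_reps` times; support
#' for each internal edge of the full-data tree is the fraction of replicate
#' trees containing the same bipartition. Fully reproducible under `seed`.
#'
#' @param aln a [plastome_alignment()] with >= 4 taxa.
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return list with `tree` (the full-data NJ tree, node labels holding
#'   support fractions) and `support` (numeric vector per internal node).
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  ref <- neighbor_joining(jc_distance(aln))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(aln), replace = TRUE)
    reps[[r]] <- tryCatch(neighbor_joining(jc_distance(aln_subset(aln, cols))),
                          error = function(e) NULL)
  }
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / length(reps)
  ref$node.label <- format(round(support, 3), trim = TRUE)
  list(tree = ref, support = support)
}

#' Robinson-Foulds distance between two trees
#'
#' The symmetric-difference count of non-trivial bipartitions; 0 means the
#' unrooted topologies are identical.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return integer RF distance.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' Read a newick tree
#' @param path newick file.
#' @return a `phylo` tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a newick tree
#' @param tree a `phylo` tree.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(NULL)
}
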