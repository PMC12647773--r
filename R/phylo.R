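# Glyco-phylogenetics: cosine distances between motif profiles and UPGMA
# dendrograms, exportable to newick.

#' Pairwise cosine distance matrix of motif profiles
#'
#' d(u, v) = 1 - (u.v)/(|u||v|). Profiles must be non-negative (so distances
#' live in [0, 1]) and no row may be all-zero. Scale-invariant: multiplying a
#' profile by a positive constant changes no distance.
#'
#' @param profiles entities x features non-negative matrix with row names.
#' @return A symmetric `dist`-convertible matrix with zero diagonal.
#' @export
cosine_distance_matrix <- function(profiles) {
  stopifnot(is.matrix(profiles))
  if (any(profiles < 0)) stop("cosine distance requires non-negative profiles")
  nrm <- sqrt(rowSums(profiles^2))
  zero <- nrm == 0
  if (any(zero))
    stop("all-zero profile row(s): ", paste(rownames(profiles)[zero], collapse = ", "))
  s <- (profiles %*% t(profiles)) / outer(nrm, nrm)
  d <- 1 - pmin(pmax(s, -1), 1)
  diag(d) <- 0
  d[d < 0] <- 0
  d
}

#' Cosine distance matrix on presence/absence motif profiles
#'
#' Cosine distance applied to 0/1 vectors, the qualitative analogue used when
#' only structure lists (not abundances) are available for a glycome.
#'
#' @param presence entities x motifs 0/1 matrix with row names.
#' @param method `"cosine"` (default) or `"jaccard"` (1 - intersection /
#'   union).
#' @return Symmetric distance matrix.
#' @export
binary_distance_matrix <- function(presence, method = c("cosine", "jaccard")) {
  method <- match.arg(method)
  stopifnot(is.matrix(presence))
  if (!all(presence %in% c(0, 1))) stop("presence matrix must be 0/1")
  if (method == "cosine") return(cosine_distance_matrix(presence))
  inter <- presence %*% t(presence)
  rs <- rowSums(presence)
  if (any(rs == 0))
    stop("all-zero profile row(s): ", paste(rownames(presence)[rs == 0], collapse = ", "))
  un <- outer(rs, rs, "+") - inter
  d <- 1 - inter / un
  diag(d) <- 0
  d
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration with cluster-size weighting; node heights
#' follow the d/2 convention, so the cophenetic distance between two leaves
#' equals the distance at which their clusters merged and ultrametric inputs
#' are reconstructed exactly. Rows are ordered lexicographically by label
#' before clustering so merge order is deterministic under ties.
#'
#' @param d symmetric distance matrix (or `dist`) with labels, n >= 2.
#' @return An [ape::as.phylo()] ultrametric tree (class `phylo`).
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (nrow(d) < 2) stop("need at least two entities")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  ord <- order(rownames(d))
  d <- d[ord, ord]
  h <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(h)
}

#' Serialize a dendrogram to newick
#'
#' Branch lengths are height differences under the d/2 UPGMA convention; the
#' string terminates with `;` and round-trips through standard newick
#' readers.
#'
#' @param tree a `phylo` object (e.g. from [upgma()]).
#' @param path optional file to write to.
#' @return The newick string, invisibly when `path` is given.
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
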