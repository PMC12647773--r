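# Independent oracles used to check the package implementations on small
# inputs. These deliberately use different algorithms (generate-and-test,
# full enumeration, closed forms) from the code under test.

# Count injective, label- and linkage-preserving embeddings of pattern p into
# structure g by enumerating all injections with label pruning and checking
# every pattern edge at the end.
brute_count_embeddings <- function(g, p, mode = "strict") {
  pn <- p$nodes$id
  k <- length(pn)
  sbase <- stats::setNames(g$nodes$base, g$nodes$id)
  smods <- stats::setNames(g$nodes$mods, g$nodes$id)
  node_ok <- function(i, sid) {
    b <- p$nodes$base[i]
    s <- sbase[[as.character(sid)]]
    okb <- if (b == "Hex") s %in% c("Glc", "Gal", "Hex")
           else if (b == "HexNAc") s %in% c("GlcNAc", "GalNAc", "HexNAc")
           else b == s
    if (!okb) return(FALSE)
    if (mode == "ignore_modifications") return(TRUE)
    identical(p$nodes$mods[i], smods[[as.character(sid)]])
  }
  pe <- p$edges
  se <- g$edges
  edges_ok <- function(map) {
    if (!nrow(pe)) return(TRUE)
    for (r in seq_len(nrow(pe))) {
      ci <- map[match(pe$child[r], pn)]
      pi <- map[match(pe$parent[r], pn)]
      hit <- which(se$child == ci & se$parent == pi)
      if (!length(hit)) return(FALSE)
      if (pe$anomeric[r] != "?"   && pe$anomeric[r]   != se$anomeric[hit])   return(FALSE)
      if (pe$child_pos[r] != "?"  && pe$child_pos[r]  != se$child_pos[hit])  return(FALSE)
      if (pe$parent_pos[r] != "?" && pe$parent_pos[r] != se$parent_pos[hit]) return(FALSE)
    }
    TRUE
  }
  count <- 0L
  rec <- function(i, map, avail) {
    if (i > k) {
      if (edges_ok(map)) count <<- count + 1L
      return(invisible())
    }
    for (sid in avail)
      if (node_ok(i, sid)) rec(i + 1L, c(map, sid), setdiff(avail, sid))
  }
  rec(1L, integer(0), g$nodes$id)
  count
}

# Extract the subtree of g rooted at node id as a standalone structure with
# renumbered ids; optionally generalize residues to their class and blank
# linkage fields, preserving matchability.
subtree_pattern <- function(g, id, generalize = FALSE) {
  keep <- glycolact:::.subtree_ids(g, id)
  nodes <- g$nodes[g$nodes$id %in% keep, , drop = FALSE]
  edges <- g$edges[g$edges$child %in% keep & g$edges$parent %in% keep, , drop = FALSE]
  remap <- stats::setNames(seq_along(nodes$id), nodes$id)
  nodes$id <- remap[as.character(nodes$id)]
  if (nrow(edges)) {
    edges$child <- unname(remap[as.character(edges$child)])
    edges$parent <- unname(remap[as.character(edges$parent)])
  }
  if (generalize) {
    gen <- stats::runif(nrow(nodes)) < 0.3
    nodes$base[gen & nodes$base %in% c("Glc", "Gal")] <- "Hex"
    nodes$base[gen & nodes$base %in% c("GlcNAc", "GalNAc")] <- "HexNAc"
    if (nrow(edges)) {
      blank <- stats::runif(nrow(edges)) < 0.3
      edges$anomeric[blank] <- "?"
      blank2 <- stats::runif(nrow(edges)) < 0.3
      edges$parent_pos[blank2] <- "?"
    }
  }
  glycan_structure(nodes, edges, unname(remap[as.character(id)]))
}

# wrap a bare pattern structure as an unconstrained motif
as_motif <- function(pat, name = "fuzz") {
  m <- list(name = name, patterns = list(pat), pattern_strings = write_iupac(pat),
            constraint = "anywhere", forbidden = list(), reducing_end_open = TRUE)
  class(m) <- "motif_definition"
  m
}

# ANOSIM R computed directly from the rank formula, independent of vegan
anosim_R_oracle <- function(dmat, groups) {
  d <- as.matrix(dmat)
  n <- nrow(d)
  iu <- which(upper.tri(d), arr.ind = TRUE)
  r <- rank(d[upper.tri(d)])
  between <- groups[iu[, 1]] != groups[iu[, 2]]
  M <- n * (n - 1) / 2
  (mean(r[between]) - mean(r[!between])) / (M / 2)
}

# exact permutation tail probability P(R_perm >= R_obs) by full enumeration
anosim_exact_tail <- function(dmat, groups) {
  n <- length(groups)
  perms <- gtools_permutations(n)
  robs <- anosim_R_oracle(dmat, groups)
  rs <- apply(perms, 1, function(ix) anosim_R_oracle(dmat, groups[ix]))
  mean(rs >= robs - 1e-12)
}

# all permutations of 1..n (n small), base R only
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

# random ultrametric distance matrix built by merging random clusters at
# strictly increasing heights; returns the cophenetic (merge) distances
random_ultrametric <- function(n, seed) {
  set.seed(seed)
  labs <- paste0("t", seq_len(n))
  cl <- as.list(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  h <- 0
  while (length(cl) > 1) {
    h <- h + stats::runif(1, 0.2, 1)
    ij <- sample(length(cl), 2)
    for (a in cl[[ij[1]]]) for (b in cl[[ij[2]]]) d[a, b] <- d[b, a] <- h
    cl[[ij[1]]] <- c(cl[[ij[1]]], cl[[ij[2]]])
    cl[[ij[2]]] <- NULL
  }
  d
}
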