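# Named motif definitions and terminal-constrained subtree matching.
# Occurrence counting is per-embedding: every injective, label- and
# linkage-preserving mapping of the pattern into the structure counts once,
# so abundance weighting in quantify_motifs() is per-occurrence.

#' Define a glycan motif
#'
#' A motif is one or more pattern trees over the extended residue vocabulary
#' (generic `Hex` matches Glc/Gal/Hex, `HexNAc` matches GlcNAc/GalNAc/HexNAc;
#' `?` linkages match anything), a terminal constraint, and optional
#' forbidden-sibling clauses used to encode negative context (e.g. the i
#' antigen requires the internal Gal to carry no \eqn{\beta}1-6 branch).
#'
#' @param name motif name, unique within a library.
#' @param patterns character vector of IUPAC-condensed pattern strings;
#'   multiple strings express alternation (e.g. a reducing-end GlcNAc or Glc).
#' @param constraint one of `"anywhere"` (default), `"terminal"` (every
#'   pattern leaf must map to a non-reducing terminal residue) or
#'   `"internal"` (every pattern leaf must map to a residue that is itself
#'   extended).
#' @param forbidden list of clauses, each a list with `node` (pattern node id
#'   as in parse order), and any of `base`, `anomeric`, `child_pos`,
#'   `parent_pos`: the structure node the pattern node maps to must have no
#'   child edge matching all stated fields.
#' @param reducing_end_open if FALSE the pattern root may only map to the
#'   structure's reducing-end residue.
#' @return A `motif_definition`.
#' @export
motif_definition <- function(name, patterns, constraint = "anywhere",
                             forbidden = list(), reducing_end_open = TRUE) {
  constraint <- match.arg(constraint, c("anywhere", "terminal", "internal"))
  pats <- lapply(patterns, parse_iupac)
  structure(list(name = name, patterns = pats, pattern_strings = patterns,
                 constraint = constraint, forbidden = forbidden,
                 reducing_end_open = reducing_end_open),
            class = "motif_definition")
}

#' Bundle motif definitions into a library
#' @param ... `motif_definition` objects.
#' @return A `motif_library` (named list).
#' @export
motif_library <- function(...) {
  defs <- list(...)
  if (length(defs) == 1L && is.list(defs[[1]]) && !inherits(defs[[1]], "motif_definition"))
    defs <- defs[[1]]
  nm <- vapply(defs, function(d) d$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate motif names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  structure(stats::setNames(defs, nm), class = "motif_library")
}

#' @export
print.motif_library <- function(x, ...) {
  cat("<motif_library> ", length(x), " motifs: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- node/linkage compatibility ---------------------------------------------

.base_compat <- function(pbase, sbase) {
  if (pbase == "Hex") return(sbase %in% .gly_hex)
  if (pbase == "HexNAc") return(sbase %in% .gly_hexnac)
  pbase == sbase
}

.node_compat <- function(pnode, snode, mode) {
  if (!.base_compat(pnode$base, snode$base)) return(FALSE)
  if (mode == "ignore_modifications") return(TRUE)
  identical(pnode$mods, snode$mods)
}

.link_compat <- function(pe, se) {
  (pe$anomeric == "?" || pe$anomeric == se$anomeric) &&
  (pe$child_pos == "?" || pe$child_pos == se$child_pos) &&
  (pe$parent_pos == "?" || pe$parent_pos == se$parent_pos)
}

# All embeddings of pattern subtree rooted at pid onto structure node sid.
# Returns a list of named integer vectors (names = pattern ids as character).
.match_from <- function(g, p, pid, sid, mode) {
  pnode <- p$nodes[p$nodes$id == pid, ]
  snode <- g$nodes[g$nodes$id == sid, ]
  if (!.node_compat(pnode, snode, mode)) return(list())
  seed <- stats::setNames(sid, as.character(pid))
  pch <- .children_edges(p, pid)
  if (!nrow(pch)) return(list(seed))
  sch <- .children_edges(g, sid)
  if (nrow(sch) < nrow(pch)) return(list())
  res <- list()
  recurse <- function(i, used, maps) {
    if (i > nrow(pch)) { res[seq_along(maps) + length(res)] <<- maps; return(invisible()) }
    pe <- pch[i, ]
    for (j in seq_len(nrow(sch))) {
      if (j %in% used) next
      se <- sch[j, ]
      if (!.link_compat(pe, se)) next
      subs <- .match_from(g, p, pe$child, se$child, mode)
      if (!length(subs)) next
      merged <- list()
      for (m0 in maps) for (m1 in subs)
        merged[[length(merged) + 1L]] <- c(m0, m1)
      recurse(i + 1L, c(used, j), merged)
    }
  }
  recurse(1L, integer(0), list(seed))
  res
}

.pattern_leaves <- function(p) {
  has_kid <- p$nodes$id %in% p$edges$parent
  p$nodes$id[!has_kid]
}

.apply_constraints <- function(g, p, maps, constraint, forbidden) {
  if (!length(maps)) return(maps)
  s_is_leaf <- !(g$nodes$id %in% g$edges$parent)
  names(s_is_leaf) <- g$nodes$id
  pl <- as.character(.pattern_leaves(p))
  keep <- vapply(maps, function(m) {
    imgs <- as.character(m[pl])
    if (constraint == "terminal" && !all(s_is_leaf[imgs])) return(FALSE)
    if (constraint == "internal" && any(s_is_leaf[imgs])) return(FALSE)
    for (fb in forbidden) {
      sn <- m[[as.character(fb$node)]]
      ch <- .children_edges(g, sn)
      if (!nrow(ch)) next
      base_of <- stats::setNames(g$nodes$base, g$nodes$id)
      for (j in seq_len(nrow(ch))) {
        e <- ch[j, ]
        hit <- TRUE
        if (!is.null(fb$base) && !.base_compat(fb$base, base_of[[as.character(e$child)]])) hit <- FALSE
        if (hit && !is.null(fb$anomeric)   && fb$anomeric   != e$anomeric)   hit <- FALSE
        if (hit && !is.null(fb$child_pos)  && fb$child_pos  != e$child_pos)  hit <- FALSE
        if (hit && !is.null(fb$parent_pos) && fb$parent_pos != e$parent_pos) hit <- FALSE
        if (hit && !(e$child %in% m)) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  maps[keep]
}

#' Find all occurrences of a motif in a structure
#'
#' Enumerates every injective embedding of each pattern variant into the
#' structure that preserves residue classes, parent/child relations and (when
#' known on both sides) anomeric configuration and carbon positions, then
#' filters by the motif's terminal constraint and forbidden-sibling clauses.
#' Overlapping occurrences are all reported.
#'
#' @param g a [glycan_structure()]; composition-only records are rejected.
#' @param m a [motif_definition()].
#' @param mode `"strict"` (default; a pattern residue without modifications
#'   only matches an unmodified residue) or `"ignore_modifications"`.
#' @param constraint optional override of the motif's terminal constraint.
#' @return List of occurrences; each has `motif` and `mapping` (named integer
#'   vector, pattern node id -> structure node id).
#' @export
match_motif <- function(g, m, mode = c("strict", "ignore_modifications"),
                        constraint = NULL) {
  if (inherits(g, "glycan_composition"))
    stop("composition-only record: structure required for motif matching")
  stopifnot(inherits(g, "glycan_structure"), inherits(m, "motif_definition"))
  mode <- match.arg(mode)
  constraint <- if (is.null(constraint)) m$constraint else
    match.arg(constraint, c("anywhere", "terminal", "internal"))
  out <- list()
  for (p in m$patterns) {
    anchors <- if (m$reducing_end_open) g$nodes$id else g$root
    for (sid in anchors) {
      maps <- .match_from(g, p, p$root, sid, mode)
      maps <- .apply_constraints(g, p, maps, constraint, m$forbidden)
      for (mp in maps)
        out[[length(out) + 1L]] <- list(motif = m$name, mapping = mp)
    }
  }
  out
}

#' Count occurrences of every motif in a library
#'
#' @param g a [glycan_structure()].
#' @param lib a [motif_library()].
#' @param mode see [match_motif()].
#' @return Named integer vector of occurrence counts (zeros included).
#' @export
annotate_motifs <- function(g, lib, mode = "strict") {
  stopifnot(inherits(lib, "motif_library"))
  vapply(lib, function(m) length(match_motif(g, m, mode)), integer(1))
}

#' Terminal motif repertoire of a structure
#'
#' Names of library motifs that occur at least once under the terminal
#' constraint (every pattern leaf on a non-reducing terminal residue) --
#' the presence/absence representation behind glycome dendrograms built from
#' qualitative structure lists.
#'
#' @inheritParams annotate_motifs
#' @return Character vector of motif names.
#' @export
terminal_motifs <- function(g, lib, mode = "strict") {
  stopifnot(inherits(lib, "motif_library"))
  hit <- vapply(lib, function(m)
    length(match_motif(g, m, mode, constraint = "terminal")) > 0L, logical(1))
  names(lib)[hit]
}

# ---- built-in library --------------------------------------------------------

#' The built-in milk-oligosaccharide motif library
#'
#' Standard immunochemical definitions of the epitopes recurring in seal and
#' other mammalian milk glycomes: Lewis X/Y, sialyl-Lewis X, type-2 H
#' antigen, B and Galili (alpha-Gal) antigens, branched (I) versus linear (i)
#' poly-LacNAc, terminal and internal LacdiNAc, proximal and distal type-2
#' sialyl-H antigens, a keratan-sulfate-like Gal\eqn{\beta}1-4GlcNAc6S unit,
#' simple sialyl/fucosyl linkage motifs, and Sd(a) (so its absence can be
#' asserted). The Galili antigen carries a forbidden Fuc\eqn{\alpha}1-2
#' sibling (which would make it a B antigen); the i antigen forbids a
#' \eqn{\beta}1-6 branch on its internal Gal (which would make it I).
#'
#' @return A [motif_library()].
#' @export
milk_motif_library <- function() {
  motif_library(list(
    motif_definition("Lewis X", "Galβ1-4(Fucα1-3)GlcNAc"),
    motif_definition("Sialyl-Lewis X", "Neu5Acα2-3Galβ1-4(Fucα1-3)GlcNAc"),
    motif_definition("Lewis Y", "Fucα1-2Galβ1-4(Fucα1-3)GlcNAc"),
    motif_definition("Type-2 H antigen",
                     c("Fucα1-2Galβ1-4GlcNAc", "Fucα1-2Galβ1-4Glc"),
                     constraint = "terminal"),
    motif_definition("B antigen", "Galα1-3(Fucα1-2)Gal"),
    motif_definition("Alpha-Gal (Galili)", "Galα1-3Gal", constraint = "terminal",
                     forbidden = list(list(node = 2L, base = "Fuc",
                                           anomeric = "α", parent_pos = "2"))),
    motif_definition("I antigen", "Galβ1-4GlcNAcβ1-3(Galβ1-4GlcNAcβ1-6)Gal"),
    motif_definition("i antigen", "Galβ1-4GlcNAcβ1-3Galβ1-4GlcNAc",
                     forbidden = list(list(node = 3L, anomeric = "β",
                                           parent_pos = "6"))),
    motif_definition("LacdiNAc (terminal)", "GalNAcβ1-4GlcNAc",
                     constraint = "terminal"),
    motif_definition("LacdiNAc (internal)", "GalNAcβ1-4GlcNAc",
                     constraint = "internal"),
    motif_definition("Proximal type-2 sialyl-H",
                     c("Fucα1-2(Neu5Acα2-6)Galβ1-4GlcNAc",
                       "Fucα1-2(Neu5Acα2-6)Galβ1-4Glc")),
    motif_definition("Distal type-2 sialyl-H", "Fucα1-2Galβ1-4(Neu5Acα2-6)GlcNAc"),
    motif_definition("Keratan sulfate unit", "Galβ1-4GlcNAc6S"),
    motif_definition("Poly-LacNAc", "Galβ1-4GlcNAcβ1-3Galβ1-4GlcNAc"),
    motif_definition("Neu5Acα2-3Gal", "Neu5Acα2-3Gal"),
    motif_definition("Neu5Acα2-6Gal", "Neu5Acα2-6Gal"),
    motif_definition("Fucα1-2Gal", "Fucα1-2Gal"),
    motif_definition("Fucα1-3GlcNAc", "Fucα1-3GlcNAc"),
    motif_definition("Sda", "Neu5Acα2-3(GalNAcβ1-4)Gal")
  ))
}

# ---- abundance-weighted motif quantification --------------------------------

.size_branch_features <- function(structs) {
  feats <- lapply(structs, function(g) {
    if (is.null(g)) return(NULL)
    f <- structural_features(g)
    c(size = f$size, branch = f$branch_points)
  })
  sizes <- vapply(feats, `[[`, numeric(1), "size")
  branch <- vapply(feats, `[[`, numeric(1), "branch")
  cbind(size_small  = as.numeric(sizes <= 5),
        size_medium = as.numeric(sizes > 5 & sizes <= 10),
        size_large  = as.numeric(sizes > 10),
        branch_0 = as.numeric(branch == 0),
        branch_1 = as.numeric(branch == 1),
        branch_2plus = as.numeric(branch >= 2))
}

#' Abundance-weighted motif quantification
#'
#' For every sample and motif, sums occurrence count times glycan relative
#' abundance over the glycans of the panel: a motif present once in a glycan
#' at 100% yields a motif quantity of 100. With the `"size_branch"` feature
#' set enabled, abundance shares by glycan size class (<=5, 6-10, >10
#' residues) and branch-point count (0, 1, >=2) are appended as extra
#' columns.
#'
#' @param table an [abundance_table()] whose features are glycan names.
#' @param structures named list mapping glycan name to [glycan_structure()]
#'   (or to a `glycan_composition` for composition-only records, which are
#'   excluded from matching with a warning).
#' @param lib a [motif_library()]; defaults to [milk_motif_library()].
#' @param mode see [match_motif()].
#' @param feature_sets any of `"known"` (the motif library) and
#'   `"size_branch"`.
#' @param presence_only if TRUE, occurrence counts are truncated at 1 before
#'   weighting.
#' @return An [abundance_table()]-like object of class
#'   `c("motif_abundance_table", "abundance_table")`, samples x motifs, with
#'   the input's sample metadata.
#' @export
quantify_motifs <- function(table, structures, lib = milk_motif_library(),
                            mode = "strict",
                            feature_sets = c("known"),
                            presence_only = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  feature_sets <- match.arg(feature_sets, c("known", "size_branch"), several.ok = TRUE)
  glycans <- colnames(table$abund)
  known <- glycans %in% names(structures)
  if (any(!known))
    stop("no structure or composition for: ", paste(glycans[!known], collapse = ", "))
  structs <- structures[glycans]
  comp_only <- vapply(structs, inherits, logical(1), "glycan_composition")
  if (any(comp_only)) {
    warning("excluding ", sum(comp_only),
            " composition-only glycan(s) from motif matching: ",
            paste(glycans[comp_only], collapse = ", "))
    structs[comp_only] <- list(NULL)
  }
  usable <- !comp_only
  cols <- list()
  if ("known" %in% feature_sets) {
    occ <- matrix(0, nrow = length(glycans), ncol = length(lib),
                  dimnames = list(glycans, names(lib)))
    for (i in which(usable)) {
      cnt <- annotate_motifs(structs[[i]], lib, mode)
      if (presence_only) cnt <- pmin(cnt, 1L)
      occ[i, ] <- cnt
    }
    cols$known <- occ
  }
  if ("size_branch" %in% feature_sets) {
    sb <- matrix(0, nrow = length(glycans), ncol = 6,
                 dimnames = list(glycans, c("size_small", "size_medium", "size_large",
                                            "branch_0", "branch_1", "branch_2plus")))
    sb[usable, ] <- .size_branch_features(structs[usable])
    cols$size_branch <- sb
  }
  loading <- do.call(cbind, unname(cols))
  M <- table$abund
  M[is.na(M)] <- 0
  quant <- M %*% loading
  out <- list(abund = quant, meta = table$meta)
  class(out) <- c("motif_abundance_table", "abundance_table")
  out
}
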