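# Rooted-tree representation of free milk oligosaccharides and the
# IUPAC-condensed parser/writer they travel through.

.gly_bases   <- c("GlcNAc", "GalNAc", "HexNAc", "Neu5Ac", "Glc", "Gal", "Hex", "Fuc")
.gly_hex     <- c("Glc", "Gal", "Hex")
.gly_hexnac  <- c("GlcNAc", "GalNAc", "HexNAc")
.alpha <- "α"
.beta  <- "β"

#' Construct a glycan structure object
#'
#' Low-level constructor for the rooted monosaccharide tree used throughout
#' the package. Most users should obtain structures via [parse_iupac()] or
#' [simulate_structures()] instead.
#'
#' @param nodes data.frame with columns `id` (integer), `base` (residue token:
#'   Glc, Gal, GlcNAc, GalNAc, Fuc, Neu5Ac, or the generic classes Hex,
#'   HexNAc) and `mods` (character; `""` or a concatenation of
#'   position-sulfate tags such as `"6S"`).
#' @param edges data.frame with columns `child`, `parent` (node ids),
#'   `anomeric` (`"α"`, `"β"` or `"?"`), `child_pos` and
#'   `parent_pos` (character digits or `"?"`). Edges point child -> parent;
#'   the parent is nearer the reducing end.
#' @param root id of the reducing-end residue (the Glc of the lactose core in
#'   milk oligosaccharides).
#' @return An object of class `glycan_structure`.
#' @export
glycan_structure <- function(nodes, edges, root) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  nodes$id <- as.integer(nodes$id)
  if (!all(nodes$base %in% .gly_bases))
    stop("unknown residue token: ", paste(setdiff(nodes$base, .gly_bases), collapse = ", "))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!root %in% nodes$id) stop("root id not among nodes")
  if (nrow(edges) != nrow(nodes) - 1L)
    stop("a tree on ", nrow(nodes), " nodes needs exactly ", nrow(nodes) - 1L, " edges")
  if (nrow(edges)) {
    if (root %in% edges$child) stop("root must not have a parent")
    if (anyDuplicated(edges$child)) stop("a node may have only one parent")
    if (!all(c(edges$child, edges$parent) %in% nodes$id)) stop("edge refers to unknown node")
  }
  g <- structure(list(nodes = nodes, edges = edges, root = as.integer(root)),
                 class = "glycan_structure")
  .check_positions(g)
  g
}

.check_positions <- function(g) {
  e <- g$edges
  if (!nrow(e)) return(invisible(g))
  base_of <- stats::setNames(g$nodes$base, g$nodes$id)
  bad <- base_of[as.character(e$child)] == "Neu5Ac" & !e$child_pos %in% c("2", "?")
  if (any(bad)) stop("Neu5Ac must link through its carbon 2")
  for (p in unique(e$parent)) {
    pp <- e$parent_pos[e$parent == p]
    pp <- pp[pp != "?"]
    if (anyDuplicated(pp))
      stop("two children of node ", p, " share parent carbon ", pp[duplicated(pp)][1])
  }
  invisible(g)
}

.children_edges <- function(g, id) g$edges[g$edges$parent == id, , drop = FALSE]

.subtree_ids <- function(g, id) {
  out <- id
  todo <- id
  while (length(todo)) {
    kids <- g$edges$child[g$edges$parent %in% todo]
    out <- c(out, kids)
    todo <- kids
  }
  out
}

# ---- tokenizer ---------------------------------------------------------------

.tokenize_iupac <- function(s) {
  toks <- list()
  i <- 1L
  n <- nchar(s)
  modre  <- "^([1-9])S"
  pmodre <- "^\\(([1-9])S\\)"
  linkre <- paste0("^([", .alpha, .beta, "ab?])([1-9?])-([1-9?])")
  while (i <= n) {
    rem <- substring(s, i)
    ch <- substr(s, i, i)
    if (ch == ")") {
      toks[[length(toks) + 1L]] <- list(type = "close", offset = i)
      i <- i + 1L
      next
    }
    if (ch == "(" && !grepl(pmodre, rem)) {
      toks[[length(toks) + 1L]] <- list(type = "open", offset = i)
      i <- i + 1L
      next
    }
    m <- regexpr(linkre, rem, perl = TRUE)
    if (m == 1L) {
      txt <- regmatches(rem, m)
      parts <- regmatches(txt, regexec(linkre, txt, perl = TRUE))[[1]]
      an <- parts[2]
      if (an == "a") an <- .alpha
      if (an == "b") an <- .beta
      toks[[length(toks) + 1L]] <- list(type = "link", anomeric = an,
                                        child_pos = parts[3], parent_pos = parts[4],
                                        offset = i)
      i <- i + attr(m, "match.length")
      next
    }
    base <- NA_character_
    for (b in .gly_bases) {
      if (startsWith(rem, b)) { base <- b; break }
    }
    if (is.na(base)) {
      tok <- sub("[(αβ].*$", "", substr(rem, 1, 12))
      stop("unknown residue token at offset ", i, ": '", tok, "'")
    }
    i <- i + nchar(base)
    mods <- integer(0)
    repeat {
      rem <- substring(s, i)
      mm <- regexec(modre, rem)[[1]]
      pm <- regexec(pmodre, rem)[[1]]
      if (mm[1] == 1L) {
        mods <- c(mods, as.integer(substr(rem, mm[2], mm[2])))
        i <- i + attr(mm, "match.length")[1]
      } else if (pm[1] == 1L) {
        mods <- c(mods, as.integer(substr(rem, pm[2], pm[2])))
        i <- i + attr(pm, "match.length")[1]
      } else break
    }
    if (anyDuplicated(mods)) stop("repeated sulfate position on one residue")
    toks[[length(toks) + 1L]] <- list(type = "residue", base = base,
                                      mods = .mods_string(mods), offset = i)
  }
  toks
}

.mods_string <- function(pos) {
  if (!length(pos)) return("")
  paste0(sort(unique(as.integer(pos))), "S", collapse = "")
}

.mods_positions <- function(mods) {
  if (!nzchar(mods)) return(integer(0))
  as.integer(regmatches(mods, gregexpr("[1-9]", mods))[[1]])
}

# ---- parser ------------------------------------------------------------------

#' Parse an IUPAC-condensed glycan string
#'
#' Strings are written non-reducing end to reducing end; a parenthesised
#' branch binds to the residue immediately to its right; the rightmost
#' residue becomes the root of the returned tree. Sulfation is written as a
#' position + `S` suffix on the residue token, compact (`Gal6S`) or
#' parenthesised (`Gal(6S)`). Greek \eqn{\alpha}/\eqn{\beta} and ASCII `a`/`b`
#' anomeric letters are both accepted; `?` marks an unknown anomeric
#' configuration or carbon position. Whitespace is ignored.
#'
#' @param text a single IUPAC-condensed string, e.g.
#'   `"Fucα1-2Gal6Sβ1-4Glc"`.
#' @return A [glycan_structure()]; node ids follow left-to-right parse order.
#' @examples
#' g <- parse_iupac("Galβ1-4GlcNAcβ1-6(Galβ1-3)Galβ1-4Glc")
#' glycan_size(g)
#' @export
parse_iupac <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) stop("empty glycan string")
  toks <- .tokenize_iupac(s)

  nodes <- list()
  edges <- list()
  nid <- 0L
  waiting <- NULL        # residue to the left still awaiting its parent
  pending <- list()      # closed branches awaiting the next residue
  stack <- list()
  last_type <- "start"
  last_res <- NA_integer_

  for (tk in toks) {
    switch(tk$type,
      residue = {
        if (last_type == "residue")
          stop("missing linkage before residue at offset ", tk$offset)
        nid <- nid + 1L
        nodes[[nid]] <- data.frame(id = nid, base = tk$base, mods = tk$mods,
                                   stringsAsFactors = FALSE)
        if (!is.null(waiting)) {
          edges[[length(edges) + 1L]] <-
            data.frame(child = waiting$node, parent = nid,
                       anomeric = waiting$link$anomeric,
                       child_pos = waiting$link$child_pos,
                       parent_pos = waiting$link$parent_pos,
                       stringsAsFactors = FALSE)
          waiting <- NULL
        }
        for (b in pending) {
          edges[[length(edges) + 1L]] <-
            data.frame(child = b$node, parent = nid,
                       anomeric = b$link$anomeric,
                       child_pos = b$link$child_pos,
                       parent_pos = b$link$parent_pos,
                       stringsAsFactors = FALSE)
        }
        pending <- list()
        last_res <- nid
      },
      link = {
        if (last_type != "residue")
          stop("linkage without preceding residue at offset ", tk$offset)
        waiting <- list(node = last_res, link = tk)
      },
      open = {
        stack[[length(stack) + 1L]] <- list(waiting = waiting, pending = pending,
                                            offset = tk$offset)
        waiting <- NULL
        pending <- list()
      },
      close = {
        if (!length(stack))
          stop("unbalanced ')' at offset ", tk$offset)
        if (is.null(waiting))
          stop("branch before offset ", tk$offset, " lacks a trailing linkage")
        if (length(pending))
          stop("dangling branch inside parentheses at offset ", tk$offset)
        fr <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        pending <- c(fr$pending, list(waiting))
        waiting <- fr$waiting
      }
    )
    last_type <- tk$type
  }
  if (length(stack))
    stop("unbalanced '(' at offset ", stack[[length(stack)]]$offset)
  if (!is.null(waiting) || length(pending))
    stop("glycan string must end in a residue (the reducing end)")
  if (last_type != "residue") stop("glycan string must end in a residue")

  glycan_structure(do.call(rbind, nodes),
                   if (length(edges)) do.call(rbind, edges) else
                     data.frame(child = integer(0), parent = integer(0),
                                anomeric = character(0), child_pos = character(0),
                                parent_pos = character(0), stringsAsFactors = FALSE),
                   root = last_res)
}

# ---- canonical writer --------------------------------------------------------

.link_token <- function(e) paste0(e$anomeric, e$child_pos, "-", e$parent_pos)

.residue_token <- function(g, id) {
  n <- g$nodes[g$nodes$id == id, ]
  paste0(n$base, n$mods)
}

.serialize <- function(g, id) {
  ch <- .children_edges(g, id)
  if (!nrow(ch)) return(.residue_token(g, id))
  sz <- vapply(ch$child, function(cid) length(.subtree_ids(g, cid)), integer(1))
  ser <- vapply(seq_len(nrow(ch)), function(i)
    paste0(.serialize(g, ch$child[i]), .link_token(ch[i, ])), character(1))
  pp <- suppressWarnings(as.numeric(ch$parent_pos))
  pp[is.na(pp)] <- 99
  ord <- order(-sz, pp, ser)
  main <- ser[ord[1]]
  rest <- ser[ord[-1]]
  paste0(main,
         paste0(vapply(rest, function(x) paste0("(", x, ")"), character(1)), collapse = ""),
         .residue_token(g, id))
}

#' Write a glycan structure as a canonical IUPAC-condensed string
#'
#' The serialisation is deterministic: at every branch point the subtree with
#' more residues stays on the main chain (outside parentheses); ties are
#' broken by the smaller attachment carbon, then lexicographically. Greek
#' anomeric letters and compact sulfate notation (`Gal6S`) are emitted, so
#' `parse_iupac(write_iupac(g))` is isomorphic to `g` and string equality of
#' two canonical forms is structure isomorphism.
#'
#' @param g a [glycan_structure()].
#' @return A single character string.
#' @export
write_iupac <- function(g) {
  stopifnot(inherits(g, "glycan_structure"))
  .serialize(g, g$root)
}

#' Test two glycan structures for isomorphism
#'
#' Node identifiers are an artifact of parse order; equality of structures is
#' defined as label- and linkage-preserving tree isomorphism, decided here by
#' comparing canonical serialisations.
#'
#' @param a,b [glycan_structure()] objects.
#' @return TRUE or FALSE.
#' @export
glycan_isomorphic <- function(a, b) identical(write_iupac(a), write_iupac(b))

#' @export
print.glycan_structure <- function(x, ...) {
  cat("<glycan_structure> ", write_iupac(x), "  (", nrow(x$nodes), " residues)\n", sep = "")
  invisible(x)
}

#' @export
format.glycan_structure <- function(x, ...) write_iupac(x)

#' Number of residues in a glycan structure
#' @param g a [glycan_structure()].
#' @return Integer residue count.
#' @export
glycan_size <- function(g) nrow(g$nodes)

# ---- compositions ------------------------------------------------------------

.comp_classes <- c("Hex", "HexNAc", "Fuc", "Neu5Ac")

#' Parse a monosaccharide composition string
#'
#' Compositions are concatenations of class tokens each followed by an
#' integer count, with optional underscores, e.g. `"Neu5Ac6Hex12HexNAc10"` or
#' `"Neu5Ac_6_Hex_12_HexNAc_10_"`. An `S` token counts sulfate groups.
#' Composition-only records describe measured glycans whose full structure
#' was not assigned; they can sit in abundance tables but cannot be motif
#' matched.
#'
#' @param text composition string.
#' @return A `glycan_composition`: list with `counts` (named integer vector
#'   over Hex, HexNAc, Fuc, Neu5Ac), `sulfate_count` and `size` (sum of the
#'   monosaccharide counts).
#' @examples
#' parse_composition("Neu5Ac6Hex12HexNAc10")$size  # 28
#' @export
parse_composition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]_]", "", text)
  if (!nzchar(s)) stop("empty composition string")
  counts <- stats::setNames(integer(length(.comp_classes)), .comp_classes)
  sulf <- 0L
  tokre <- "^(HexNAc|Neu5Ac|Hex|Fuc|S)([0-9]+)"
  while (nzchar(s)) {
    m <- regexec(tokre, s)[[1]]
    if (m[1] != 1L)
      stop("unknown composition token near '", substr(s, 1, 8), "'")
    len <- attr(m, "match.length")
    tok <- substr(s, m[2], m[2] + len[2] - 1L)
    cnt <- as.integer(substr(s, m[3], m[3] + len[3] - 1L))
    if (tok == "S") sulf <- sulf + cnt else counts[tok] <- counts[tok] + cnt
    s <- substring(s, len[1] + 1L)
  }
  structure(list(counts = counts, sulfate_count = sulf,
                 size = sum(counts)), class = "glycan_composition")
}

#' Project a glycan structure onto its monosaccharide composition
#'
#' Glc and Gal count as Hex; GlcNAc and GalNAc count as HexNAc; sulfate
#' modifications are tallied separately.
#'
#' @param g a [glycan_structure()].
#' @return A `glycan_composition` (see [parse_composition()]).
#' @export
composition_of <- function(g) {
  stopifnot(inherits(g, "glycan_structure"))
  cls <- ifelse(g$nodes$base %in% .gly_hex, "Hex",
         ifelse(g$nodes$base %in% .gly_hexnac, "HexNAc", g$nodes$base))
  counts <- stats::setNames(integer(length(.comp_classes)), .comp_classes)
  tb <- table(cls)
  counts[names(tb)] <- as.integer(tb)
  sulf <- sum(vapply(g$nodes$mods, function(m) length(.mods_positions(m)), integer(1)))
  structure(list(counts = counts, sulfate_count = as.integer(sulf),
                 size = sum(counts)), class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat("<glycan_composition> ",
      paste0(names(nz), nz, collapse = ""),
      if (x$sulfate_count > 0) paste0("S", x$sulfate_count) else "",
      "  size ", x$size, "\n", sep = "")
  invisible(x)
}

# ---- structural descriptors --------------------------------------------------

#' Structural descriptors of a glycan
#'
#' Computes the feature set used for diversity analyses: residue count,
#' branch points, maximum depth and terminal residues.
#'
#' @param g a [glycan_structure()].
#' @param backbone_only if TRUE, only backbone children (Hex/HexNAc classes)
#'   count towards branch points, so single-residue decorations (Fuc,
#'   Neu5Ac) do not create a branch.
#' @return List with `size`, `branch_points`, `max_depth` (edges on the
#'   longest root-to-leaf path) and `terminal_residues` (ids of nodes with no
#'   children, i.e. the non-reducing termini).
#' @export
structural_features <- function(g, backbone_only = FALSE) {
  stopifnot(inherits(g, "glycan_structure"))
  base_of <- stats::setNames(g$nodes$base, g$nodes$id)
  nkids <- vapply(g$nodes$id, function(id) {
    ch <- .children_edges(g, id)
    if (backbone_only && nrow(ch))
      ch <- ch[base_of[as.character(ch$child)] %in% c(.gly_hex, .gly_hexnac), , drop = FALSE]
    nrow(ch)
  }, integer(1))
  depth <- function(id) {
    ch <- .children_edges(g, id)
    if (!nrow(ch)) return(0L)
    1L + max(vapply(ch$child, depth, integer(1)))
  }
  all_nkids <- vapply(g$nodes$id, function(id) nrow(.children_edges(g, id)), integer(1))
  list(size = nrow(g$nodes),
       branch_points = sum(nkids >= 2L),
       max_depth = depth(g$root),
       terminal_residues = g$nodes$id[all_nkids == 0L])
}
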