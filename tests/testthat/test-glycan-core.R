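# IUPAC-condensed parsing, canonical writing and structural descriptors.

results_strings <- c(
  "Fucα1-2Gal6Sβ1-4Glc",
  "Galβ1-4GlcNAcβ1-6(Galβ1-3)Galβ1-4Glc",
  "Fucα1-2(Neu5Acα2-6)Galβ1-4GlcNAc",
  "Fucα1-2Galβ1-4(Neu5Acα2-6)GlcNAc",
  "Galβ1-4Glc",
  "GalNAcβ1-4GlcNAc",
  "Galα1-3Gal",
  "Galβ1-4GlcNAcβ1-3Galβ1-4GlcNAc",
  "Fucα1-2Galβ1-4GlcNAc"
)

test_that("lactose parses to a two-node chain rooted at Glc", {
  g <- parse_iupac("Galβ1-4Glc")
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$nodes$base[g$root], "Glc")
  expect_equal(write_iupac(g), "Galβ1-4Glc")
  f <- structural_features(g)
  expect_equal(f$branch_points, 0L)
  expect_equal(g$nodes$base[f$terminal_residues], "Gal")
})

test_that("branched pentasaccharide parses with the branch on the inner Gal", {
  g <- parse_iupac("Galβ1-4GlcNAcβ1-6(Galβ1-3)Galβ1-4Glc")
  expect_equal(nrow(g$nodes), 5L)
  # the Gal one step above the root carries two children: GlcNAc b1-6, Gal b1-3
  inner <- g$edges$child[g$edges$parent == g$root]
  kids <- g$edges[g$edges$parent == inner, ]
  expect_setequal(g$nodes$base[kids$child], c("GlcNAc", "Gal"))
  expect_setequal(kids$parent_pos, c("6", "3"))
  f <- structural_features(g)
  expect_equal(f$size, 5L)
  expect_equal(f$branch_points, 1L)
})

test_that("sulfate suffix is parsed, counted and re-emitted compactly", {
  g <- parse_iupac("Fucα1-2Gal6Sβ1-4Glc")
  expect_equal(nrow(g$nodes), 3L)
  gal <- g$nodes[g$nodes$base == "Gal", ]
  expect_equal(gal$mods, "6S")
  fuc_edge <- g$edges[g$edges$child == g$nodes$id[g$nodes$base == "Fuc"], ]
  expect_equal(fuc_edge$parent, gal$id)
  expect_equal(fuc_edge$anomeric, "α")
  expect_equal(fuc_edge$parent_pos, "2")
  comp <- composition_of(g)
  expect_equal(unname(comp$counts[c("Fuc", "Hex")]), c(1L, 2L))
  expect_equal(comp$sulfate_count, 1L)
  expect_equal(comp$size, 3L)
  # parenthesised dialect accepted on input, compact emitted
  expect_equal(write_iupac(parse_iupac("Gal(6S)β1-4Glc")), "Gal6Sβ1-4Glc")
})

test_that("doubly decorated Gal parses with both children", {
  g <- parse_iupac("Fucα1-2(Neu5Acα2-6)Galβ1-4GlcNAc")
  expect_equal(nrow(g$nodes), 4L)
  gal <- g$nodes$id[g$nodes$base == "Gal"]
  kids <- g$edges[g$edges$parent == gal, ]
  expect_setequal(g$nodes$base[kids$child], c("Fuc", "Neu5Ac"))
  f <- structural_features(g)
  expect_equal(f$branch_points, 1L)
  expect_equal(structural_features(g, backbone_only = TRUE)$branch_points, 0L)
})

test_that("canonical order puts the larger branch on the main chain, ties by position", {
  a <- parse_iupac("Galβ1-3(Galβ1-4GlcNAcβ1-6)Galβ1-4Glc")
  expect_equal(write_iupac(a), "Galβ1-4GlcNAcβ1-6(Galβ1-3)Galβ1-4Glc")
  b <- parse_iupac("Neu5Acα2-6(Fucα1-2)Galβ1-4GlcNAc")
  expect_equal(write_iupac(b), "Fucα1-2(Neu5Acα2-6)Galβ1-4GlcNAc")
})

test_that("every printed structure string round-trips isomorphically", {
  for (s in results_strings) {
    g <- parse_iupac(s)
    expect_true(glycan_isomorphic(parse_iupac(write_iupac(g)), g), label = s)
  }
})

test_that("parsing is insensitive to branch order and ASCII anomeric letters", {
  expect_true(glycan_isomorphic(parse_iupac("Fucα1-2(Neu5Acα2-6)Galβ1-4Glc"),
                                parse_iupac("Neu5Acα2-6(Fucα1-2)Galβ1-4Glc")))
  expect_true(glycan_isomorphic(parse_iupac("Fuca1-2Galb1-4Glc"),
                                parse_iupac("Fucα1-2Galβ1-4Glc")))
})

test_that("unknown linkage fields are accepted and preserved", {
  g <- parse_iupac("Gal?1-?Glc")
  expect_equal(g$edges$anomeric, "?")
  expect_equal(g$edges$parent_pos, "?")
  expect_equal(write_iupac(g), "Gal?1-?Glc")
})

test_that("malformed strings fail with informative errors", {
  expect_error(parse_iupac("Galβ1-4(GlcNAcβ1-3Glc"), "unbalanced")
  expect_error(parse_iupac("Galβ1-4GlcNAcβ1-3)Glc"), "unbalanced")
  expect_error(parse_iupac("Xyzβ1-4Glc"), "unknown residue")
  expect_error(parse_iupac("Galβ1-4"), "end in a residue")
  expect_error(parse_iupac(""), "empty")
  expect_error(parse_iupac("GalGlc"), "missing linkage")
})

test_that("composition strings parse with and without underscores", {
  c1 <- parse_composition("Neu5Ac6Hex12HexNAc10")
  expect_equal(unname(c1$counts[c("Neu5Ac", "Hex", "HexNAc")]), c(6L, 12L, 10L))
  expect_equal(c1$size, 28L)
  expect_equal(parse_composition("Neu5Ac_6_Hex_12_HexNAc_10_")$size, 28L)
  expect_equal(parse_composition("Hex2")$size, 2L)
  expect_equal(parse_composition("Fuc1Hex1HexNAc1")$size, 3L)
  expect_error(parse_composition("Pent3"), "unknown composition token")
})

test_that("composition projection maps residues to classes", {
  expect_equal(unname(composition_of(parse_iupac("Galβ1-4Glc"))$counts[["Hex"]]), 2L)
  cc <- composition_of(parse_iupac("GalNAcβ1-4GlcNAc"))
  expect_equal(unname(cc$counts[["HexNAc"]]), 2L)
  expect_equal(cc$size, 2L)
})

test_that("size equals token count and descriptor bounds hold on generated structures", {
  structs <- simulate_structures(60, grammar_params(), seed = 101)
  for (g in structs) {
    s <- write_iupac(g)
    ntok <- length(gregexpr("Glc(?!NAc)|GlcNAc|GalNAc|Gal(?!NAc)|Fuc|Neu5Ac|Hex(?!NAc)|HexNAc",
                            s, perl = TRUE)[[1]])
    f <- structural_features(g)
    expect_equal(composition_of(g)$size, f$size)
    expect_equal(f$size, ntok, label = s)
    nleaves <- length(f$terminal_residues)
    expect_lte(f$branch_points + nleaves, f$size)
    expect_lte(f$max_depth, f$size - 1L)
  }
})

test_that("extending a deepest terminal Gal with a LacNAc unit increases max depth", {
  # undecorated structures: every chain terminates in a Gal
  structs <- simulate_structures(20, grammar_params(p_fuc2 = 0, p_sia = 0,
                                                    p_fuc3 = 0, p_sulf = 0),
                                 seed = 7)
  depth_of <- function(g, id) {
    d <- 0L
    while (id != g$root) {
      id <- g$edges$parent[g$edges$child == id]
      d <- d + 1L
    }
    d
  }
  for (g in structs) {
    f <- structural_features(g)
    leaves <- f$terminal_residues
    deepest <- leaves[which.max(vapply(leaves, depth_of, integer(1), g = g))]
    expect_equal(g$nodes$base[deepest], "Gal")
    n <- nrow(g$nodes)
    nodes2 <- rbind(g$nodes, data.frame(id = n + 1:2, base = c("GlcNAc", "Gal"),
                                        mods = ""))
    edges2 <- rbind(g$edges,
                    data.frame(child = n + 1:2, parent = c(deepest, n + 1L),
                               anomeric = "β", child_pos = "1",
                               parent_pos = c("3", "4")))
    g2 <- glycan_structure(nodes2, edges2, g$root)
    expect_equal(structural_features(g2)$max_depth, f$max_depth + 2L)
  }
})

test_that("duplicate parent carbons and bad Neu5Ac linkage are rejected", {
  expect_error(parse_iupac("Galβ1-3(Fucα1-3)GlcNAc"), "share parent carbon")
  expect_error(parse_iupac("Neu5Acα3-6Gal"), "carbon 2")
})
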