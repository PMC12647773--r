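# Subtree motif matching, library annotation and abundance-weighted
# quantification.

lib <- milk_motif_library()

test_that("a pattern identical to the target matches exactly once", {
  g <- parse_iupac("Fucα1-2Galβ1-4(Neu5Acα2-6)GlcNAc")
  m <- motif_definition("self", "Fucα1-2Galβ1-4(Neu5Acα2-6)GlcNAc")
  occ <- match_motif(g, m)
  expect_length(occ, 1L)
  expect_true(all(occ[[1]]$mapping %in% g$nodes$id))
})

test_that("strict mode distinguishes sulfated residues; ignore_modifications does not", {
  g <- parse_iupac("Fucα1-2Gal6Sβ1-4Glc")
  m <- motif_definition("H-like", "Fucα1-2Gal", constraint = "terminal")
  expect_length(match_motif(g, m, "strict"), 0L)
  expect_length(match_motif(g, m, "ignore_modifications"), 1L)
})

test_that("residue mismatches yield no occurrence", {
  g <- parse_iupac("Galβ1-4GlcNAc")
  m <- motif_definition("ldn", "GalNAcβ1-4GlcNAc")
  expect_length(match_motif(g, m), 0L)
})

test_that("composition-only records are rejected by the matcher", {
  comp <- parse_composition("Hex2")
  expect_error(match_motif(comp, lib[["Type-2 H antigen"]]), "composition-only")
})

test_that("proximal and distal sialyl-H antigens are discriminated", {
  prox <- parse_iupac("Fucα1-2(Neu5Acα2-6)Galβ1-4GlcNAc")
  ap <- annotate_motifs(prox, lib)
  expect_equal(unname(ap["Proximal type-2 sialyl-H"]), 1L)
  expect_equal(unname(ap["Distal type-2 sialyl-H"]), 0L)
  dist <- parse_iupac("Fucα1-2Galβ1-4(Neu5Acα2-6)GlcNAc")
  ad <- annotate_motifs(dist, lib)
  expect_equal(unname(ad["Proximal type-2 sialyl-H"]), 0L)
  expect_equal(unname(ad["Distal type-2 sialyl-H"]), 1L)
})

test_that("linear poly-LacNAc is i antigen but not I antigen, and vice versa", {
  lin <- parse_iupac("Galβ1-4GlcNAcβ1-3Galβ1-4GlcNAc")
  al <- annotate_motifs(lin, lib)
  expect_equal(unname(al["i antigen"]), 1L)
  expect_equal(unname(al["I antigen"]), 0L)
  br <- parse_iupac("Galβ1-4GlcNAcβ1-3(Galβ1-4GlcNAcβ1-6)Galβ1-4Glc")
  ab <- annotate_motifs(br, lib)
  expect_equal(unname(ab["I antigen"]), 1L)
  expect_equal(unname(ab["i antigen"]), 0L)
})

test_that("each named motif is present in its defining structure", {
  defining <- list(
    "Lewis X" = "Galβ1-4(Fucα1-3)GlcNAcβ1-3Galβ1-4Glc",
    "Sialyl-Lewis X" = "Neu5Acα2-3Galβ1-4(Fucα1-3)GlcNAcβ1-3Galβ1-4Glc",
    "Lewis Y" = "Fucα1-2Galβ1-4(Fucα1-3)GlcNAcβ1-3Galβ1-4Glc",
    "Type-2 H antigen" = "Fucα1-2Galβ1-4GlcNAcβ1-3Galβ1-4Glc",
    "B antigen" = "Galα1-3(Fucα1-2)Galβ1-4Glc",
    "Alpha-Gal (Galili)" = "Galα1-3Galβ1-4Glc",
    "LacdiNAc (terminal)" = "GalNAcβ1-4GlcNAcβ1-3Galβ1-4Glc",
    "Keratan sulfate unit" = "Galβ1-4GlcNAc6Sβ1-3Galβ1-4Glc",
    "Neu5Acα2-3Gal" = "Neu5Acα2-3Galβ1-4Glc",
    "Fucα1-3GlcNAc" = "Galβ1-4(Fucα1-3)GlcNAcβ1-3Galβ1-4Glc",
    "Sda" = "Neu5Acα2-3(GalNAcβ1-4)Galβ1-4Glc")
  for (nm in names(defining)) {
    counts <- annotate_motifs(parse_iupac(defining[[nm]]), lib)
    expect_gte(unname(counts[nm]), 1L)
  }
  # lactose carries no epitope at all
  expect_true(all(annotate_motifs(parse_iupac("Galβ1-4Glc"), lib) == 0L))
})

test_that("terminal motif sets are stable under re-parsing", {
  structs <- simulate_structures(25, grammar_params(), seed = 55)
  for (g in structs) {
    s1 <- terminal_motifs(g, lib)
    s2 <- terminal_motifs(parse_iupac(write_iupac(g)), lib)
    expect_setequal(s1, s2)
  }
  expect_length(terminal_motifs(parse_iupac("Galβ1-4Glc"), lib), 0L)
  expect_true("Type-2 H antigen" %in% terminal_motifs(parse_iupac("Fucα1-2Galβ1-4Glc"), lib))
})

test_that("matcher equals the brute-force embedding enumerator on fuzzed cases", {
  set.seed(424)
  structs <- simulate_structures(120, grammar_params(max_size = 8), seed = 71)
  pats <- simulate_structures(120, grammar_params(max_size = 8), seed = 72)
  for (i in seq_len(120)) {
    g <- structs[[i]]
    src <- pats[[i]]
    pat <- subtree_pattern(src, sample(src$nodes$id, 1), generalize = TRUE)
    if (glycan_size(pat) > 4) pat <- subtree_pattern(src, sample(src$nodes$id[
      !(src$nodes$id %in% src$edges$parent)], 1))
    m <- as_motif(pat)
    expect_equal(length(match_motif(g, m, "strict")),
                 brute_count_embeddings(g, pat, "strict"),
                 label = paste(write_iupac(g), "~", write_iupac(pat)))
  }
})

test_that("occurrence counts are monotone under structure growth (anywhere)", {
  set.seed(9)
  structs <- simulate_structures(20, grammar_params(max_size = 10), seed = 31)
  for (g in structs) {
    before <- annotate_motifs(g, lib)
    # graft one more LacNAc onto any leaf Gal; counts must not decrease
    leaves <- structural_features(g)$terminal_residues
    gal_leaves <- intersect(leaves, g$nodes$id[g$nodes$base == "Gal"])
    if (!length(gal_leaves)) next
    n <- nrow(g$nodes)
    nodes2 <- rbind(g$nodes, data.frame(id = n + 1:2, base = c("GlcNAc", "Gal"), mods = ""))
    edges2 <- rbind(g$edges, data.frame(child = n + 1:2,
                                        parent = c(gal_leaves[1], n + 1L),
                                        anomeric = "β", child_pos = "1",
                                        parent_pos = c("3", "4")))
    g2 <- glycan_structure(nodes2, edges2, g$root)
    anywhere <- names(lib)[vapply(lib, function(m) m$constraint == "anywhere", logical(1))]
    after <- annotate_motifs(g2, lib)
    expect_true(all(after[anywhere] >= before[anywhere]))
  }
})

test_that("motif quantities are abundance-weighted occurrence sums", {
  s1 <- parse_iupac("Fucα1-2Galβ1-4Glc")                       # one H antigen
  s2 <- parse_iupac("Fucα1-2Galβ1-4GlcNAcβ1-3Galβ1-4Glc")      # one H antigen
  s3 <- parse_iupac("Galβ1-4Glc")                               # nothing
  structs <- list(a = s1, b = s2, c = s3)
  m <- matrix(c(100, 0, 0,
                60, 40, 0,
                50, 0, 50), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), c("a", "b", "c")))
  tab <- abundance_table(m, rep("A", 3), c(2, 7, 13))
  q <- quantify_motifs(tab, structs, lib)
  h <- q$abund[, "Type-2 H antigen"]
  expect_equal(unname(h), c(100, 100, 50))
  # a motif equal to an entire glycan tracks that glycan's abundance exactly
  lac_lib <- motif_library(list(motif_definition("lactose", "Galβ1-4Glc")))
  q2 <- quantify_motifs(tab, structs, lac_lib)
  # lactose occurs once in each structure (all share the core)
  expect_equal(unname(q2$abund[, "lactose"]), c(100, 100, 100))
  q3 <- quantify_motifs(abundance_table(m / 2, rep("A", 3), c(2, 7, 13),
                                        normalize = FALSE, tol = Inf),
                        structs, lib)
  expect_equal(q3$abund, q$abund / 2)  # linearity in abundances
})

test_that("double occurrences weight double and size_branch features append", {
  s_twice <- parse_iupac("Fucα1-2Galβ1-4GlcNAcβ1-3(Fucα1-2Galβ1-4GlcNAcβ1-6)Galβ1-4Glc")
  structs <- list(tw = s_twice, lac = parse_iupac("Galβ1-4Glc"))
  m <- matrix(c(60, 40), nrow = 1, dimnames = list("s1", c("tw", "lac")))
  tab <- abundance_table(m, "A", 2)
  q <- quantify_motifs(tab, structs, lib, feature_sets = c("known", "size_branch"))
  expect_equal(unname(q$abund[, "Type-2 H antigen"]), 120)  # 2 x 60
  expect_equal(unname(q$abund[, "size_small"]), 40)
  expect_equal(unname(q$abund[, "size_medium"]), 60)
  expect_equal(unname(q$abund[, "branch_1"]), 60)
})

test_that("composition-only columns are excluded with a warning; unknown columns error", {
  structs <- list(a = parse_iupac("Fucα1-2Galβ1-4Glc"),
                  b = parse_composition("Hex5HexNAc3"))
  m <- matrix(c(70, 30, 80, 20), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  tab <- abundance_table(m, c("A", "B"), c(2, 2))
  expect_warning(q <- quantify_motifs(tab, structs, lib), "composition-only")
  expect_equal(unname(q$abund[, "Fucα1-2Gal"]), c(70, 80))
  expect_error(quantify_motifs(tab, structs["a"], lib), "no structure")
})
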