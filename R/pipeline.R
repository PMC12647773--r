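# End-to-end composition of the pipeline stages with a machine-readable
# summary. File readers/writers live in abundance-table.R; this file ties
# the stages together.

#' Run the full lactation-glycomics pipeline
#'
#' Executes, in order: motif quantification on the glycan panel, compositional
#' preprocessing, alpha diversity per sample, Ward clustering of samples
#' against timepoints with ARI/NMI, ANOSIM of beta diversities across
#' timepoints, per-motif ANOVA across timepoints, degree-1 time-series fits,
#' a UPGMA tree of per-individual motif profiles, and (when a metabolome is
#' supplied) cross-correlation, the modality-informativeness report and PC1
#' linkage. All randomized stages derive their seeds deterministically from
#' the single pipeline seed, so a rerun with the same inputs and seed is
#' identical.
#'
#' @param table an [abundance_table()] of glycan relative abundances.
#' @param structures named list of [glycan_structure()] for the panel.
#' @param metabolome optional [abundance_table()] of metabolites on the same
#'   samples; `NULL` skips the cross-omics stages.
#' @param lib a [motif_library()].
#' @param gamma CLR scale-uncertainty parameter (default 0.1).
#' @param winsor_fraction Winsorization fraction (default 0.05).
#' @param k number of flat clusters for sample scoring (default: number of
#'   distinct days).
#' @param seed master seed.
#' @param out_dir optional directory; when given, intermediate tables, the
#'   newick tree and a JSON summary are written there.
#' @return List of class `glycolact_pipeline` with elements `motifs`,
#'   `clr`, `diversity`, `clustering` (incl. `scores`), `anosim`, `anova`,
#'   `timeseries`, `tree_newick`, and optionally `crossomics`,
#'   `modality_report`, `pc1`.
#' @export
run_pipeline <- function(table, structures, metabolome = NULL,
                         lib = milk_motif_library(), gamma = 0.1,
                         winsor_fraction = 0.05, k = NULL, seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(k)) k <- length(unique(table$meta$day))
  days <- table$meta$day

  motifs <- quantify_motifs(table, structures, lib,
                            feature_sets = c("known", "size_branch"))
  keep <- apply(motifs$abund, 2, function(x) any(x > 0))
  motif_mat <- motifs$abund[, keep, drop = FALSE]

  clr_glyc <- preprocess_abundance(table, winsor_fraction, gamma, seed = seed)
  clr_motif <- preprocess_abundance(
    abundance_table(motif_mat, table$meta$individual, days, normalize = FALSE,
                    tol = Inf),
    winsor_fraction, gamma, seed = seed + 1L)

  diversity <- data.frame(sample_id = table$meta$sample_id, day = days,
                          shannon = alpha_diversity(table$abund, "shannon"),
                          simpson = alpha_diversity(table$abund, "simpson"),
                          richness = alpha_diversity(table$abund, "richness"),
                          row.names = NULL)

  clust <- cluster_samples(clr_glyc, k = k)
  scores <- clustering_scores(clust$labels, days)
  ano <- anosim_test(beta_diversity(table), days, seed = seed + 2L)
  anova_res <- motif_anova(unclass(clr_motif), factor(days))
  ts <- timeseries_fit(unclass(clr_motif), days)

  prof <- rowsum(motif_mat, table$meta$individual)
  tree <- upgma(cosine_distance_matrix(prof / rowSums(prof)))
  nwk <- to_newick(tree)

  out <- list(motifs = motifs, clr = clr_glyc, clr_motifs = clr_motif,
              diversity = diversity,
              clustering = c(clust[c("labels", "k")], list(scores = scores)),
              anosim = ano, anova = anova_res, timeseries = ts,
              tree_newick = nwk, seed = seed)

  if (!is.null(metabolome)) {
    stopifnot(inherits(metabolome, "abundance_table"))
    clr_met <- preprocess_abundance(metabolome, winsor_fraction, gamma,
                                    seed = seed + 3L)
    out$crossomics <- cross_correlate(unclass(clr_motif), unclass(clr_met))
    out$modality_report <- modality_informativeness(
      list(glycome = unclass(clr_glyc), metabolome = unclass(clr_met)),
      labels = days, k = k)
    out$pc1 <- pc1_link(unclass(clr_glyc), unclass(clr_met), day = days)
  }
  class(out) <- "glycolact_pipeline"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_abundance_table(motifs, file.path(out_dir, "motif_abundances.csv"))
    utils::write.csv(anova_res$table, file.path(out_dir, "motif_anova.csv"),
                     row.names = FALSE)
    utils::write.csv(ts, file.path(out_dir, "timeseries_fits.csv"),
                     row.names = FALSE)
    writeLines(nwk, file.path(out_dir, "individual_tree.nwk"))
    summary <- list(seed = seed, gamma = gamma, winsor_fraction = winsor_fraction,
                    k = k, n_samples = nrow(table$abund),
                    n_glycans = ncol(table$abund),
                    clustering = scores, anosim = ano,
                    n_significant_motifs = sum(anova_res$table$q < 0.05))
    if (!is.null(metabolome)) {
      summary$n_significant_pairs <- sum(out$crossomics$mask)
      summary$modality_report <- out$modality_report
      summary$pc1 <- out$pc1[c("var_share_a", "var_share_b", "r", "p_value")]
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.glycolact_pipeline <- function(x, ...) {
  cat("<glycolact_pipeline>\n",
      "  samples: ", nrow(x$clr), ", motif features: ", ncol(x$clr_motifs), "\n",
      "  timepoint clustering: ARI ", round(x$clustering$scores$ari, 3),
      ", NMI ", round(x$clustering$scores$nmi, 3), "\n",
      "  ANOSIM R ", round(x$anosim$statistic, 3),
      " (p = ", signif(x$anosim$p_value, 3), ")\n", sep = "")
  if (!is.null(x$crossomics))
    cat("  significant cross-omics pairs: ", sum(x$crossomics$mask), "\n", sep = "")
  invisible(x)
}

#' Share of structures absent from reference databases
#'
#' Arithmetic utility for reporting discovery rates: the integer-rounded
#' percentage of novel structures among those characterized.
#'
#' @param n_novel number of structures absent from reference databases.
#' @param n_characterized number of fully characterized structures.
#' @return Integer percentage.
#' @export
novel_structure_percent <- function(n_novel, n_characterized) {
  stopifnot(n_novel >= 0, n_characterized > 0, n_novel <= n_characterized)
  round(100 * n_novel / n_characterized)
}
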