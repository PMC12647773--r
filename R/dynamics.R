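# Temporal analysis of the lactation glycome: sample/glycan clustering with
# partition scores, cluster trajectories, per-motif ANOVA with Tukey HSD,
# degree-1 time-series fits, and the sulfation-vs-branching test.

#' Hierarchical (Ward) clustering of CLR rows
#'
#' Agglomerative clustering on Euclidean distances between CLR-transformed
#' rows using Ward's variance-minimization criterion (`ward.D2`), cut into
#' `k` flat clusters. Set `rows = "features"` to cluster glycans instead of
#' samples (the transpose), optionally z-scoring each feature row first.
#'
#' @param clr a `clr_matrix` (or plain numeric matrix).
#' @param k number of flat clusters (2 <= k <= n).
#' @param rows `"samples"` (default) or `"features"`.
#' @param scale_rows z-score rows before clustering (only sensible for
#'   `rows = "features"`).
#' @return List of class `clustering_result`: `labels` (named integer 1..k),
#'   `dendrogram` (`hclust`), `k`, `method`.
#' @export
cluster_samples <- function(clr, k, rows = c("samples", "features"),
                            scale_rows = FALSE) {
  rows <- match.arg(rows)
  m <- unclass(clr)
  attr(m, "meta") <- attr(m, "gamma") <- attr(m, "seed") <- NULL
  if (rows == "features") m <- t(m)
  if (scale_rows) {
    sdv <- apply(m, 1, stats::sd)
    m <- (m - rowMeans(m)) / ifelse(sdv > 0, sdv, 1)
  }
  n <- nrow(m)
  if (k < 2 || k > n) stop("k must be in 2..", n)
  h <- stats::hclust(stats::dist(m), method = "ward.D2")
  labels <- stats::cutree(h, k = k)
  structure(list(labels = labels, dendrogram = h, k = k, method = "ward.D2"),
            class = "clustering_result")
}

#' Partition agreement scores (ARI and NMI)
#'
#' Adjusted Rand index under the permutation model (via \pkg{mclust}) and
#' normalized mutual information with arithmetic-mean normalization
#' 2I/(H1+H2) (via \pkg{igraph}). Both are 1 iff the partitions are
#' identical up to relabeling.
#'
#' @param labels,reference equal-length label vectors.
#' @return List with `ari` and `nmi`.
#' @export
clustering_scores <- function(labels, reference) {
  if (length(labels) != length(reference))
    stop("label vectors differ in length: ", length(labels), " vs ", length(reference))
  a <- as.integer(as.factor(labels))
  b <- as.integer(as.factor(reference))
  nmi <- if (max(a) == 1L && max(b) == 1L) 1 else
    igraph::compare(a, b, method = "nmi")
  list(ari = mclust::adjustedRandIndex(a, b), nmi = nmi)
}

#' Mean abundance trajectories of glycan clusters
#'
#' For each (cluster, timepoint), the mean relative abundance over all
#' glycans of the cluster and all samples at that timepoint, with a
#' t-distribution 95% confidence interval.
#'
#' @param table an [abundance_table()].
#' @param glycan_clusters named vector mapping every glycan column to a
#'   cluster label.
#' @param conf confidence level (default 0.95).
#' @return data.frame with `cluster`, `day`, `mean`, `lower`, `upper`, `n`.
#' @export
cluster_trajectories <- function(table, glycan_clusters, conf = 0.95) {
  stopifnot(inherits(table, "abundance_table"))
  glycans <- colnames(table$abund)
  miss <- setdiff(glycans, names(glycan_clusters))
  if (length(miss)) stop("glycans without cluster assignment: ",
                         paste(miss, collapse = ", "))
  cl <- glycan_clusters[glycans]
  if (!all(table(cl) >= 1)) stop("empty cluster")
  days <- sort(unique(table$meta$day))
  out <- list()
  for (cc in sort(unique(cl))) {
    cols <- glycans[cl == cc]
    for (dd in days) {
      # per-sample cluster totals at this timepoint; CI over samples
      vals <- rowSums(table$abund[table$meta$day == dd, cols, drop = FALSE], na.rm = TRUE)
      n <- length(vals)
      mu <- mean(vals) / length(cols)   # mean per glycan in the cluster
      se <- if (n > 1) stats::sd(vals) / length(cols) / sqrt(n) else 0
      tq <- if (n > 1 && se > 0) stats::qt(1 - (1 - conf) / 2, n - 1) else 0
      out[[length(out) + 1L]] <- data.frame(cluster = cc, day = dd, mean = mu,
                                            lower = mu - tq * se,
                                            upper = mu + tq * se, n = n)
    }
  }
  do.call(rbind, out)
}

#' Per-motif one-way ANOVA with Tukey HSD and adaptive BH correction
#'
#' For every motif column, a one-way ANOVA of the (CLR-scale) motif quantity
#' across groups, Tukey's Honestly Significant Difference post-hoc tests for
#' all group pairs, and two-stage Benjamini-Hochberg q-values across motifs.
#'
#' @param motif_table samples x motifs matrix (e.g. the `abund` slot of a
#'   [quantify_motifs()] result after CLR), or a `motif_abundance_table`.
#' @param groups factor of length n samples; >= 2 groups with >= 2
#'   observations each.
#' @param alpha level for the adaptive BH stage.
#' @return List of class `motif_anova`: `table` (data.frame motif, F, p, q)
#'   and `tukey` (named list of per-motif data.frames pair, diff, p_adj).
#' @export
motif_anova <- function(motif_table, groups, alpha = 0.05) {
  m <- if (inherits(motif_table, "abundance_table")) motif_table$abund else motif_table
  stopifnot(is.matrix(m))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(which(table(groups) < 2)), collapse = ", "))
  motifs <- colnames(m)
  Fv <- pv <- numeric(length(motifs))
  tukey <- vector("list", length(motifs))
  names(tukey) <- motifs
  for (i in seq_along(motifs)) {
    y <- m[, i]
    if (stats::var(y) < .Machine$double.eps) { Fv[i] <- 0; pv[i] <- 1; next }
    fit <- stats::aov(y ~ groups)
    an <- summary(fit)[[1]]
    Fv[i] <- an[["F value"]][1]
    pv[i] <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$groups
    tukey[[i]] <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                             p_adj = tk[, "p adj"], row.names = NULL,
                             stringsAsFactors = FALSE)
  }
  structure(list(table = data.frame(motif = motifs, F = Fv, p = pv,
                                    q = two_stage_bh(pv, alpha), row.names = NULL,
                                    stringsAsFactors = FALSE),
                 tukey = tukey),
            class = "motif_anova")
}

#' Degree-1 time-series fit per motif
#'
#' Fits a first-degree polynomial (least squares) of each motif's CLR-scale
#' quantity against lactation day, all individuals pooled. The slope beta,
#' the regression-ANOVA p-value and plain Benjamini-Hochberg q-values are
#' returned.
#'
#' @param motif_table samples x motifs matrix on the CLR scale (or a
#'   `motif_abundance_table`).
#' @param days numeric lactation day per sample; >= 3 distinct values
#'   required.
#' @return data.frame with `motif`, `beta`, `p`, `q`.
#' @export
timeseries_fit <- function(motif_table, days) {
  m <- if (inherits(motif_table, "abundance_table")) motif_table$abund else motif_table
  stopifnot(is.matrix(m), length(days) == nrow(m))
  if (length(unique(days)) < 3) stop("need at least 3 distinct time values")
  res <- t(apply(m, 2, function(y) {
    if (stats::var(y) < .Machine$double.eps) return(c(beta = 0, p = 1))
    fit <- stats::lm(y ~ days)
    an <- stats::anova(fit)
    c(beta = unname(stats::coef(fit)[2]), p = an[["Pr(>F)"]][1])
  }))
  data.frame(motif = colnames(m), beta = res[, "beta"], p = res[, "p"],
             q = stats::p.adjust(res[, "p"], "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Does GlcNAc 6-O-sulfation suppress chain extension?
#'
#' Tests, across structure-size strata, whether GlcNAc6S residues sitting
#' below a galactose are extended (carry a child) less often than
#' position-matched unmodified GlcNAc residues. Within each stratum
#' (structures grouped by residue count) the paired difference
#' extended-fraction(sulfated) - extended-fraction(unmodified) is computed;
#' a two-tailed Wilcoxon signed-rank test is run over the informative strata
#' (those containing both kinds). Direction is the sign of the median paired
#' difference (negative = sulfated GlcNAc extended less often).
#'
#' @param structures list of [glycan_structure()].
#' @param min_strata minimum number of informative strata (default 5).
#' @return List with `statistic` (V), `p_value`, `direction` (-1, 0, 1),
#'   `strata` (the per-stratum paired fractions).
#' @export
sulfation_branching_test <- function(structures, min_strata = 5L) {
  stopifnot(is.list(structures))
  rows <- lapply(structures, function(g) {
    base_of <- stats::setNames(g$nodes$base, g$nodes$id)
    mods_of <- stats::setNames(g$nodes$mods, g$nodes$id)
    e <- g$edges
    if (!nrow(e)) return(NULL)
    glcnac <- e$child[base_of[as.character(e$child)] == "GlcNAc" &
                      base_of[as.character(e$parent)] %in% c("Gal", "Hex")]
    if (!length(glcnac)) return(NULL)
    data.frame(size = nrow(g$nodes),
               sulfated = grepl("6S", mods_of[as.character(glcnac)]),
               extended = glcnac %in% e$parent)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || !nrow(df)) stop("no GlcNAc residues below Gal found")
  strata <- split(df, df$size)
  paired <- do.call(rbind, lapply(strata, function(s) {
    if (!any(s$sulfated) || !any(!s$sulfated)) return(NULL)
    data.frame(size = s$size[1],
               frac_sulfated = mean(s$extended[s$sulfated]),
               frac_plain = mean(s$extended[!s$sulfated]))
  }))
  if (is.null(paired) || nrow(paired) < min_strata)
    stop("insufficient data: only ", if (is.null(paired)) 0 else nrow(paired),
         " informative size strata (need ", min_strata, ")")
  diffs <- paired$frac_sulfated - paired$frac_plain
  if (all(diffs == 0))
    return(list(statistic = NA_real_, p_value = 1, direction = 0L, strata = paired))
  w <- suppressWarnings(stats::wilcox.test(paired$frac_sulfated, paired$frac_plain,
                                           paired = TRUE))
  list(statistic = unname(w$statistic), p_value = w$p.value,
       direction = as.integer(sign(stats::median(diffs))), strata = paired)
}
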