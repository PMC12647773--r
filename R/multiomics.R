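# Glycome-metabolome integration: SparCC-style cross-correlation of
# CLR-transformed tables, ridge-regularized partial correlations of
# residuals, per-modality informativeness, and PC1 linkage.

.check_shared_samples <- function(a, b) {
  if (nrow(a) != nrow(b) || !identical(rownames(a), rownames(b))) {
    only_a <- setdiff(rownames(a), rownames(b))
    only_b <- setdiff(rownames(b), rownames(a))
    stop("sample mismatch between modalities",
         if (length(only_a)) paste0("; only in first: ", paste(only_a, collapse = ", ")),
         if (length(only_b)) paste0("; only in second: ", paste(only_b, collapse = ", ")))
  }
}

#' Cross-correlation of two CLR-transformed modalities
#'
#' Spearman's rho for every (motif, metabolite) pair between two
#' CLR-transformed tables sharing samples, with a two-tailed t-test on rho
#' at n - 2 degrees of freedom, two-stage Benjamini-Hochberg correction over
#' all pairs, and a significance mask at q < 0.05. This is the SparCC-style
#' analysis for compositional data: the compositional correction lives in
#' the CLR transform, the association measure is rank-based.
#'
#' @param clr_a,clr_b samples x features matrices (CLR scale), identical row
#'   names in identical order; >= 4 shared samples.
#' @param alpha significance level for the mask (default 0.05).
#' @return List of class `cross_correlation`: `rho` (features_a x features_b),
#'   `q`, `mask` (logical, q < alpha), `n`.
#' @export
cross_correlate <- function(clr_a, clr_b, alpha = 0.05) {
  a <- unclass(clr_a); b <- unclass(clr_b)
  stopifnot(is.matrix(a), is.matrix(b))
  .check_shared_samples(a, b)
  n <- nrow(a)
  if (n < 4) stop("need at least 4 shared samples, got ", n)
  rho <- stats::cor(a, b, method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  q <- matrix(two_stage_bh(as.vector(p), alpha), nrow = nrow(p),
              dimnames = dimnames(p))
  structure(list(rho = rho, q = q, mask = q < alpha, n = n),
            class = "cross_correlation")
}

# ridge regression residuals of y on X (both centered; no penalty on the mean)
.ridge_residuals <- function(X, y, penalty) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  p <- ncol(Xc)
  beta <- solve(crossprod(Xc) + diag(penalty, p), crossprod(Xc, yc))
  as.numeric(yc - Xc %*% beta)
}

#' Regularized partial correlation of a feature pair
#'
#' Regresses each member of the pair on all remaining features of the joint
#' CLR matrix with a ridge penalty, then reports Spearman's rho between the
#' two residual vectors. Large penalties shrink the regressions towards
#' zero, so the partial correlation converges to the marginal Spearman rho;
#' small penalties remove 'bystander' correlations mediated by the other
#' features, enriching for direct associations.
#'
#' @param clr_joint samples x features CLR matrix containing both features
#'   (e.g. `cbind` of the two modalities); >= 5 samples.
#' @param pair character vector of two feature names.
#' @param penalty ridge penalty; default `0.1 * (number of remaining
#'   features)`.
#' @return List of class `partial_correlation`: `pair`, `rho_partial`,
#'   `penalty`.
#' @export
regularized_partial_correlation <- function(clr_joint, pair, penalty = NULL) {
  m <- unclass(clr_joint)
  stopifnot(is.matrix(m), length(pair) == 2)
  miss <- setdiff(pair, colnames(m))
  if (length(miss)) stop("feature(s) not in matrix: ", paste(miss, collapse = ", "))
  if (nrow(m) < 5) stop("need at least 5 samples")
  rest <- setdiff(colnames(m), pair)
  if (is.null(penalty)) penalty <- 0.1 * length(rest)
  stopifnot(penalty >= 0)
  if (!length(rest)) {
    rho <- stats::cor(m[, pair[1]], m[, pair[2]], method = "spearman")
  } else {
    X <- m[, rest, drop = FALSE]
    ra <- .ridge_residuals(X, m[, pair[1]], penalty)
    rb <- .ridge_residuals(X, m[, pair[2]], penalty)
    rho <- stats::cor(ra, rb, method = "spearman")
  }
  structure(list(pair = pair, rho_partial = unname(rho), penalty = penalty),
            class = "partial_correlation")
}

#' Partial-correlation screen across two modalities
#'
#' Convenience wrapper: computes [regularized_partial_correlation()] for
#' every (feature of A, feature of B) pair of the joint matrix and returns a
#' long-format table sorted by |rho|.
#'
#' @param clr_a,clr_b samples x features CLR matrices with shared samples.
#' @param penalty see [regularized_partial_correlation()].
#' @return data.frame with `feature_a`, `feature_b`, `rho_partial`.
#' @export
partial_correlation_screen <- function(clr_a, clr_b, penalty = NULL) {
  a <- unclass(clr_a); b <- unclass(clr_b)
  .check_shared_samples(a, b)
  joint <- cbind(a, b)
  if (anyDuplicated(colnames(joint))) stop("feature names overlap between modalities")
  out <- expand.grid(feature_a = colnames(a), feature_b = colnames(b),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rho_partial <- mapply(function(fa, fb)
    regularized_partial_correlation(joint, c(fa, fb), penalty)$rho_partial,
    out$feature_a, out$feature_b)
  out[order(-abs(out$rho_partial)), ]
}

#' Which modality carries the lactation signal?
#'
#' Ward-clusters each modality (and their column-wise combination) into `k`
#' flat clusters and scores the partition against the known timepoint labels
#' with ARI and NMI. Optionally projects onto the top principal components
#' first (PCA denoising); `denoise_components = "auto"` keeps the components
#' explaining 80% of cumulative variance.
#'
#' @param modalities named list of samples x features CLR matrices sharing
#'   samples.
#' @param labels reference labels (e.g. lactation day) per sample.
#' @param k number of flat clusters (default: number of distinct labels).
#' @param denoise_components NULL (no denoising), an integer, or `"auto"`.
#' @return data.frame with `modality`, `ari`, `nmi` (the combination is
#'   labelled `"combined"`).
#' @export
modality_informativeness <- function(modalities, labels, k = NULL,
                                     denoise_components = NULL) {
  stopifnot(is.list(modalities), length(modalities) >= 1)
  mats <- lapply(modalities, unclass)
  for (m in mats[-1]) .check_shared_samples(mats[[1]], m)
  if (is.null(k)) k <- length(unique(labels))
  mats$combined <- do.call(cbind, unname(mats))
  score_one <- function(m) {
    if (!is.null(denoise_components)) {
      pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
      r <- if (identical(denoise_components, "auto")) {
        cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
        max(which(cum < 0.8), 1L) + 1L
      } else as.integer(denoise_components)
      r <- min(r, ncol(pc$x))
      m <- pc$x[, seq_len(r), drop = FALSE]
    }
    cl <- cluster_samples(m, k = k)
    clustering_scores(cl$labels, labels)
  }
  res <- lapply(mats, score_one)
  data.frame(modality = names(res),
             ari = vapply(res, `[[`, numeric(1), "ari"),
             nmi = vapply(res, `[[`, numeric(1), "nmi"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Linkage of the leading principal components of two modalities
#'
#' PCA (column-centred, unscaled) per modality on CLR data; returns each
#' PC1's explained-variance share and the Pearson correlation of the two PC1
#' score vectors with a two-tailed t-test. PC1 signs are oriented to
#' correlate positively with `day` when given (a PCA score vector is only
#' defined up to sign).
#'
#' @param clr_a,clr_b samples x features CLR matrices sharing samples, >= 3
#'   samples.
#' @param day optional numeric vector used to fix each PC1's orientation.
#' @return List with `var_share_a`, `var_share_b`, `r`, `p_value`, `scores`
#'   (two-column matrix of the oriented PC1 scores).
#' @export
pc1_link <- function(clr_a, clr_b, day = NULL) {
  a <- unclass(clr_a); b <- unclass(clr_b)
  .check_shared_samples(a, b)
  if (nrow(a) < 3) stop("need at least 3 samples")
  one <- function(m) {
    if (all(apply(m, 2, stats::var) < .Machine$double.eps))
      stop("constant matrix has no principal components")
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    sc <- pc$x[, 1]
    if (!is.null(day) && stats::cor(sc, day) < 0) sc <- -sc
    list(share = pc$sdev[1]^2 / sum(pc$sdev^2), scores = sc)
  }
  pa <- one(a); pb <- one(b)
  ct <- stats::cor.test(pa$scores, pb$scores, method = "pearson")
  list(var_share_a = pa$share, var_share_b = pb$share,
       r = unname(ct$estimate), p_value = ct$p.value,
       scores = cbind(pc1_a = pa$scores, pc1_b = pb$scores))
}
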