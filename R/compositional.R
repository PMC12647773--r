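# Compositional preprocessing (Winsorize -> impute -> CLR) and diversity
# statistics. All downstream clustering/correlation happens in CLR space
# (Aitchison geometry); gamma > 0 adds a per-sample scale-uncertainty term.

#' Two-sided per-feature Winsorization
#'
#' Clips each feature's values to its empirical `fraction` and
#' `1 - fraction` quantiles (type-7), leaving the within-feature rank order
#' intact. Missing values are ignored and preserved.
#'
#' @param m samples x features numeric matrix.
#' @param fraction tail fraction clipped on each side, in [0, 0.5).
#' @return Matrix of the same shape.
#' @export
winsorize <- function(m, fraction = 0.05) {
  stopifnot(is.matrix(m), fraction >= 0, fraction < 0.5)
  if (fraction == 0) return(m)
  apply_cols <- function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 2) return(x)
    q <- stats::quantile(x[ok], c(fraction, 1 - fraction), names = FALSE)
    x[ok] <- pmin(pmax(x[ok], q[1]), q[2])
    x
  }
  out <- apply(m, 2, apply_cols)
  dimnames(out) <- dimnames(m)
  out
}

#' Impute zeros and missing values in a compositional table
#'
#' Two strategies. `"half_min"` (deterministic): each feature's zeros/NAs
#' become half its smallest positive observed value. `"forest"`: iterative
#' random-forest imputation over features (each incomplete feature regressed
#' on the others, refitted until convergence), mirroring MissForest-style
#' machine-learning imputation; seeded for reproducibility, then floored into
#' (0, feature max]. A feature with no positive observation is an error.
#'
#' @param m samples x features matrix, non-negative or NA.
#' @param method `"half_min"` (default; used wherever determinism matters) or
#'   `"forest"`.
#' @param seed integer seed for `"forest"`.
#' @param max_iter iteration cap for `"forest"`.
#' @return Strictly positive matrix of the same shape.
#' @export
impute_missing <- function(m, method = c("half_min", "forest"), seed = NULL,
                           max_iter = 10L) {
  stopifnot(is.matrix(m))
  method <- match.arg(method)
  if (any(m < 0, na.rm = TRUE)) stop("negative entries are not imputable abundances")
  m[!is.na(m) & m == 0] <- NA
  all_na <- apply(m, 2, function(x) all(is.na(x)))
  if (any(all_na))
    stop("feature(s) missing in all samples: ",
         paste(colnames(m)[all_na], collapse = ", "))
  halfmin <- apply(m, 2, function(x) min(x, na.rm = TRUE) / 2)
  feat_max <- apply(m, 2, function(x) max(x, na.rm = TRUE))
  miss <- is.na(m)
  if (!any(miss)) return(m)
  # half-minimum start (also the full answer for method = "half_min")
  out <- m
  for (j in seq_len(ncol(m))) out[miss[, j], j] <- halfmin[j]
  if (method == "half_min") return(out)
  if (!is.null(seed)) { old <- .Random.seed_save(); on.exit(.Random.seed_restore(old)); set.seed(seed) }
  ord <- order(colSums(miss), decreasing = FALSE)
  prev <- out
  for (it in seq_len(max_iter)) {
    for (j in ord) {
      if (!any(miss[, j])) next
      df <- as.data.frame(out[, -j, drop = FALSE])
      names(df) <- paste0("x", seq_len(ncol(df)))
      df$y <- out[, j]
      fit <- ranger::ranger(y ~ ., data = df[!miss[, j], , drop = FALSE],
                            num.trees = 100, seed = if (is.null(seed)) 1L else seed)
      pred <- stats::predict(fit, df[miss[, j], , drop = FALSE])$predictions
      out[miss[, j], j] <- pmin(pmax(pred, halfmin[j]), feat_max[j])
    }
    if (max(abs(out - prev)) < 1e-6) break
    prev <- out
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# run expr with a local RNG stream (restores caller's stream afterwards)
.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' Centred log-ratio transform with scale perturbation
#'
#' With `gamma = 0` this is the textbook CLR: log of each part minus the
#' per-sample mean log, so every row sums to zero and the result is invariant
#' to per-sample rescaling. With `gamma > 0`, a per-sample scale term drawn
#' from Normal(0, gamma^2) is added to every entry of that sample's row,
#' propagating uncertainty about the unobserved total into downstream
#' statistics; the draws are reproducible under `seed`.
#'
#' @param m strictly positive samples x features matrix (impute first).
#' @param gamma non-negative scale-uncertainty standard deviation.
#' @param seed integer seed for the gamma draws.
#' @return An object of class `clr_matrix`: the transformed matrix with
#'   attributes `gamma` and `seed`.
#' @export
clr_transform <- function(m, gamma = 0, seed = NULL) {
  stopifnot(is.matrix(m), gamma >= 0)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("CLR requires strictly positive entries; impute zeros/missing first")
  lm <- log(m)
  out <- lm - rowMeans(lm)
  if (gamma > 0) {
    shift <- .with_seed(seed, stats::rnorm(nrow(m), 0, gamma))
    out <- out + shift
  }
  structure(out, gamma = gamma, seed = seed, class = c("clr_matrix", "matrix", "array"))
}

#' Full compositional preprocessing pipeline
#'
#' Winsorize per feature, impute zeros/missing values, re-close each row to
#' sum 1, then CLR-transform with the gamma scale perturbation. This is the
#' preprocessing applied before every clustering, regression and correlation
#' analysis in the package.
#'
#' @param table an [abundance_table()] (or bare samples x features matrix).
#' @param winsor_fraction two-sided Winsorization fraction (default 0.05).
#' @param gamma CLR scale-uncertainty parameter (default 0.1, the value used
#'   for the analyses; set 0 for a deterministic transform).
#' @param impute imputation method, see [impute_missing()].
#' @param seed integer seed covering imputation and the gamma draws.
#' @return A `clr_matrix` carrying the input's sample metadata as attribute
#'   `meta` when available.
#' @export
preprocess_abundance <- function(table, winsor_fraction = 0.05, gamma = 0.1,
                                 impute = "half_min", seed = NULL) {
  m <- if (inherits(table, "abundance_table")) table$abund else table
  stopifnot(is.matrix(m))
  m <- winsorize(m, winsor_fraction)
  m <- impute_missing(m, method = impute, seed = seed)
  m <- m / rowSums(m)
  out <- clr_transform(m, gamma = gamma,
                       seed = if (is.null(seed)) NULL else seed + 1L)
  if (inherits(table, "abundance_table")) attr(out, "meta") <- table$meta
  out
}

# ---- diversity ---------------------------------------------------------------

#' Per-sample alpha diversity
#'
#' @param m samples x features matrix of non-negative quantities (or a single
#'   vector); each row is normalized to proportions internally.
#' @param index `"shannon"` (-sum p log p, natural log), `"simpson"`
#'   (1 - sum p^2) or `"richness"` (count of positive features).
#' @return Named numeric vector of per-sample index values.
#' @export
alpha_diversity <- function(m, index = c("shannon", "simpson", "richness")) {
  index <- match.arg(index)
  if (!is.matrix(m)) m <- matrix(m, nrow = 1, dimnames = list("s1", NULL))
  if (any(m < 0, na.rm = TRUE)) stop("negative quantities")
  m[is.na(m)] <- 0
  rs <- rowSums(m)
  if (any(rs == 0)) stop("all-zero sample: ", paste(rownames(m)[rs == 0], collapse = ", "))
  p <- m / rs
  out <- switch(index,
    shannon = apply(p, 1, function(x) { x <- x[x > 0]; -sum(x * log(x)) }),
    simpson = apply(p, 1, function(x) 1 - sum(x^2)),
    richness = apply(m, 1, function(x) sum(x > 0)))
  stats::setNames(as.numeric(out), rownames(m))
}

#' Aitchison (or Bray-Curtis) beta-diversity distances
#'
#' Default is Euclidean distance between CLR(gamma = 0) rows, i.e. Aitchison
#' distance; `method = "bray"` gives Bray-Curtis on the raw proportions via
#' \pkg{vegan}.
#'
#' @param table an [abundance_table()] or positive matrix.
#' @param method `"aitchison"` or `"bray"`.
#' @return A `dist` object.
#' @export
beta_diversity <- function(table, method = c("aitchison", "bray")) {
  method <- match.arg(method)
  m <- if (inherits(table, "abundance_table")) table$abund else table
  if (method == "bray") return(vegan::vegdist(m / rowSums(m), method = "bray"))
  m <- impute_missing(m, "half_min")
  stats::dist(clr_transform(m / rowSums(m), gamma = 0))
}

#' ANOSIM test of group separation on a distance matrix
#'
#' Rank-based analysis of similarities: R = (mean between-group rank - mean
#' within-group rank) / (M/2), M = n(n-1)/2, with a permutation p-value
#' (1 + #\{permuted R >= observed\}) / (1 + n_permutations). Computed via
#' \pkg{vegan}.
#'
#' @param d a `dist` or symmetric matrix with zero diagonal.
#' @param groups group labels, length n; every group needs >= 2 members.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return List with `statistic` (R) and `p_value`.
#' @export
anosim_test <- function(d, groups, n_permutations = 999, seed = NULL) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("singleton group(s): ",
                                   paste(names(which(table(groups) < 2)), collapse = ", "))
  fit <- .with_seed(seed, vegan::anosim(d, groups, permutations = n_permutations))
  list(statistic = unname(fit$statistic), p_value = unname(fit$signif))
}

# ---- multiple testing --------------------------------------------------------

#' Two-stage (adaptive) Benjamini-Hochberg q-values
#'
#' The two-stage step-up procedure: a first BH pass at level
#' alpha/(1 + alpha) estimates the number of true nulls m0, then the BH
#' q-values are scaled by m0/m. Reduces to plain BH when no rejections occur
#' in stage one.
#'
#' @param p vector of p-values.
#' @param alpha nominal FDR level the two-stage estimate is tuned to
#'   (default 0.05).
#' @return Vector of adjusted q-values, same order as `p`.
#' @export
two_stage_bh <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- sum(!is.na(p))
  if (m == 0) return(p)
  q1 <- stats::p.adjust(p, "BH")
  r1 <- sum(q1 <= alpha / (1 + alpha), na.rm = TRUE)
  m0 <- m - r1
  if (m0 == 0) return(q1)  # everything rejected at stage one
  pmin(q1 * m0 / m, 1)
}

#' Two-group feature-wise comparison (Mann-Whitney U + adaptive BH)
#'
#' Two-tailed Mann-Whitney U test per feature between two groups, with
#' q-values from the two-stage Benjamini-Hochberg procedure.
#'
#' @param m samples x features matrix.
#' @param groups two-level factor of length nrow(m); each level needs >= 3
#'   observations.
#' @param alpha level for the adaptive BH stage (default 0.05).
#' @return data.frame with `feature`, `U`, `p`, `q`.
#' @export
group_compare <- function(m, groups, alpha = 0.05) {
  stopifnot(is.matrix(m))
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) != 2) stop("group_compare needs exactly two groups")
  if (any(table(groups) < 3)) stop("each group needs at least 3 values")
  g1 <- groups == levels(groups)[1]
  res <- t(apply(m, 2, function(x) {
    w <- suppressWarnings(stats::wilcox.test(x[g1], x[!g1], exact = NULL))
    c(U = unname(w$statistic), p = w$p.value)
  }))
  data.frame(feature = colnames(m), U = res[, "U"], p = res[, "p"],
             q = two_stage_bh(res[, "p"], alpha), row.names = NULL,
             stringsAsFactors = FALSE)
}
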