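# Synthetic study generator: structures from a lactose-core poly-LacNAc
# grammar, a longitudinal glycome cohort with planted temporal clusters and
# individual effects, and a paired metabolome with a shared latent day
# factor and planted direct links. Ground truth is recorded so every
# recovery property is scorable.

#' Parameters of the structure grammar
#'
#' The generator emulates the biosynthetic logic of seal-type milk
#' oligosaccharides: a lactose core extended by type-2 LacNAc units
#' (GlcNAc\eqn{\beta}1-3 + Gal\eqn{\beta}1-4) on terminal galactoses,
#' branched by GlcNAc\eqn{\beta}1-6 + Gal\eqn{\beta}1-4 on extended internal
#' galactoses, then decorated (Fuc\eqn{\alpha}1-2 / Neu5Ac\eqn{\alpha}2-3 or
#' \eqn{\alpha}2-6 on terminal Gal, Fuc\eqn{\alpha}1-3 and 6-O-sulfation on
#' GlcNAc).
#'
#' @param p_extend probability a terminal Gal gains a LacNAc unit per round.
#' @param p_branch probability an eligible internal Gal gains a
#'   \eqn{\beta}1-6 LacNAc branch per round.
#' @param p_fuc2,p_sia decoration probabilities on terminal Gal.
#' @param p_fuc3,p_sulf decoration/sulfation probabilities on GlcNAc.
#' @param max_size maximum residue count (>= 2).
#' @return List of class `grammar_params`.
#' @export
grammar_params <- function(p_extend = 0.55, p_branch = 0.3, p_fuc2 = 0.35,
                           p_sia = 0.3, p_fuc3 = 0.25, p_sulf = 0.15,
                           max_size = 14L) {
  pr <- c(p_extend, p_branch, p_fuc2, p_sia, p_fuc3, p_sulf)
  if (any(pr < 0 | pr > 1)) stop("probabilities must be in [0, 1]")
  if (max_size < 2) stop("max_size must be >= 2")
  structure(list(p_extend = p_extend, p_branch = p_branch, p_fuc2 = p_fuc2,
                 p_sia = p_sia, p_fuc3 = p_fuc3, p_sulf = p_sulf,
                 max_size = as.integer(max_size)), class = "grammar_params")
}

# mutable builder over flat vectors; frames assembled once at the end
.gb_init <- function() {
  env <- new.env(parent = emptyenv())
  env$base <- character(0); env$mods <- character(0)
  env$e_child <- integer(0); env$e_parent <- integer(0)
  env$e_anom <- character(0); env$e_cpos <- character(0); env$e_ppos <- character(0)
  env
}

.gb_add <- function(env, base, parent = NA, anomeric = NULL, child_pos = NULL,
                    parent_pos = NULL, mods = "") {
  id <- length(env$base) + 1L
  env$base[id] <- base
  env$mods[id] <- mods
  if (!is.na(parent)) {
    k <- length(env$e_child) + 1L
    env$e_child[k] <- id; env$e_parent[k] <- parent
    env$e_anom[k] <- anomeric; env$e_cpos[k] <- child_pos; env$e_ppos[k] <- parent_pos
  }
  id
}

.gb_glycan <- function(env, root) {
  glycan_structure(
    data.frame(id = seq_along(env$base), base = env$base, mods = env$mods,
               stringsAsFactors = FALSE),
    data.frame(child = env$e_child, parent = env$e_parent, anomeric = env$e_anom,
               child_pos = env$e_cpos, parent_pos = env$e_ppos,
               stringsAsFactors = FALSE),
    root)
}

.one_structure <- function(p) {
  env <- .gb_init()
  root <- .gb_add(env, "Glc")
  .gb_add(env, "Gal", root, .beta, "1", "4")
  size <- function() length(env$base)
  repeat {
    grew <- FALSE
    gals <- which(env$base == "Gal")
    term_gal <- gals[!(gals %in% env$e_parent)]
    for (tg in term_gal) {
      if (size() + 2L > p$max_size) break
      if (stats::runif(1) < p$p_extend) {
        gn <- .gb_add(env, "GlcNAc", tg, .beta, "1", "3")
        .gb_add(env, "Gal", gn, .beta, "1", "4")
        grew <- TRUE
      }
    }
    gals <- which(env$base == "Gal")
    elig <- gals[vapply(gals, function(id) {
      pp <- env$e_ppos[env$e_parent == id]
      any(pp == "3") && !any(pp == "6")
    }, logical(1))]
    for (eg in elig) {
      if (size() + 2L > p$max_size) break
      if (stats::runif(1) < p$p_branch) {
        gn <- .gb_add(env, "GlcNAc", eg, .beta, "1", "6")
        .gb_add(env, "Gal", gn, .beta, "1", "4")
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  # decorations cap chains; they never create new extension sites
  gals <- which(env$base == "Gal")
  term_gal <- gals[!(gals %in% env$e_parent)]
  for (tg in term_gal) {
    if (size() < p$max_size && stats::runif(1) < p$p_fuc2)
      .gb_add(env, "Fuc", tg, .alpha, "1", "2")
    if (size() < p$max_size && stats::runif(1) < p$p_sia) {
      pos <- if (stats::runif(1) < 0.5) "3" else "6"
      .gb_add(env, "Neu5Ac", tg, .alpha, "2", pos)
    }
  }
  for (gn in which(env$base == "GlcNAc")) {
    if (size() < p$max_size && stats::runif(1) < p$p_fuc3)
      .gb_add(env, "Fuc", gn, .alpha, "1", "3")
    if (stats::runif(1) < p$p_sulf)
      env$mods[gn] <- "6S"
  }
  .gb_glycan(env, root)
}

#' Simulate glycan structures from the poly-LacNAc grammar
#'
#' @param n number of structures.
#' @param params a [grammar_params()].
#' @param seed integer seed.
#' @return List of [glycan_structure()]; all outputs re-parse through
#'   [parse_iupac()].
#' @export
simulate_structures <- function(n, params = grammar_params(), seed = NULL) {
  stopifnot(n >= 1, inherits(params, "grammar_params"))
  .with_seed(seed, lapply(seq_len(n), function(i) .one_structure(params)))
}

# ---- cohort ------------------------------------------------------------------

#' Design of a synthetic lactation cohort
#'
#' Defaults mirror the study design the package targets: five individuals
#' sampled at four lactation timepoints (days 2, 7, 13 and 18 -- the late
#' d17/18/19 samples collapse onto day 18), with glycans planted in four
#' temporal clusters. Early glycans are present only at the first timepoint,
#' Stable glycans keep a constant expectation, Late glycans are absent early
#' and rise through lactation, and Sporadic glycans are present at random in
#' 30% of samples at low level.
#'
#' @param n_individuals number of individuals (default 5).
#' @param days numeric timepoints (default `c(2, 7, 13, 18)`).
#' @param panel_size number of glycans in the panel (default 40).
#' @param cluster_props proportions of Early/Stable/Late/Sporadic glycans.
#' @param multipliers named list of per-cluster temporal multipliers, one
#'   value per timepoint.
#' @param sporadic_presence Bernoulli presence probability for Sporadic.
#' @param sporadic_level abundance multiplier of a Sporadic glycan when
#'   present (low by construction).
#' @param indiv_sigma lognormal sigma of the per-(glycan, individual) effect.
#' @param base_sigma lognormal sigma of per-glycan base levels.
#' @param dirichlet_conc Dirichlet concentration of sampling noise (larger =
#'   quieter; default 200).
#' @param detection_limit percentage below which a measurement is reported
#'   as absent (relative-abundance data carry a detection floor; rows are
#'   re-closed afterwards). Default 0.01.
#' @param grammar a [grammar_params()] for the structure panel.
#' @return List of class `cohort_design`.
#' @export
cohort_design <- function(n_individuals = 5L, days = c(2, 7, 13, 18),
                          panel_size = 40L,
                          cluster_props = c(Early = 0.25, Stable = 0.35,
                                            Late = 0.25, Sporadic = 0.15),
                          multipliers = list(Early = c(1, 0, 0, 0),
                                             Stable = c(1, 1, 1, 1),
                                             Late = c(0, 0.5, 1, 1.5)),
                          sporadic_presence = 0.3, sporadic_level = 0.05,
                          indiv_sigma = 0.2, base_sigma = 0.8,
                          dirichlet_conc = 200, detection_limit = 0.01,
                          grammar = grammar_params()) {
  stopifnot(n_individuals >= 1, length(days) >= 2, panel_size >= 4)
  if (any(unlist(multipliers) < 0)) stop("temporal multipliers must be >= 0")
  if (!all(vapply(multipliers, length, integer(1)) == length(days)))
    stop("each multiplier vector needs one value per timepoint")
  structure(list(n_individuals = as.integer(n_individuals), days = days,
                 panel_size = as.integer(panel_size),
                 cluster_props = cluster_props, multipliers = multipliers,
                 sporadic_presence = sporadic_presence,
                 sporadic_level = sporadic_level,
                 indiv_sigma = indiv_sigma, base_sigma = base_sigma,
                 dirichlet_conc = dirichlet_conc,
                 detection_limit = detection_limit, grammar = grammar),
            class = "cohort_design")
}

#' Simulate a longitudinal glycome cohort with known ground truth
#'
#' The sample manifest is individuals x timepoints. A glycan's expected
#' abundance is its lognormal base level times its cluster's temporal
#' multiplier at that day times a per-(glycan, individual) lognormal random
#' effect; the observed sample is a Dirichlet draw around the (closed)
#' expectations, expressed as percentages summing to 100.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @return List with `table` (an [abundance_table()]), `structures` (named
#'   list of [glycan_structure()] for the panel) and `truth` (cluster
#'   assignments, multipliers, base levels, individual effects, expected
#'   abundances, design, seed).
#' @export
simulate_cohort <- function(design = cohort_design(), seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  .with_seed(seed, {
    structs <- simulate_structures(design$panel_size, design$grammar)
    nm <- make.unique(vapply(structs, write_iupac, character(1)), sep = "#")
    names(structs) <- nm

    props <- design$cluster_props / sum(design$cluster_props)
    ncl <- floor(props * design$panel_size)
    ncl[1] <- design$panel_size - sum(ncl[-1])
    clusters <- sample(rep(names(props), times = ncl))
    names(clusters) <- nm

    ind <- LETTERS[seq_len(design$n_individuals)]
    manifest <- expand.grid(individual = ind, day = design$days,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    manifest$sample_id <- paste0(manifest$individual, "_d", manifest$day)

    base <- exp(stats::rnorm(design$panel_size, 0, design$base_sigma))
    names(base) <- nm
    ie <- matrix(exp(stats::rnorm(design$panel_size * length(ind), 0, design$indiv_sigma)),
                 nrow = length(ind), dimnames = list(ind, nm))
    sporadic_on <- matrix(stats::runif(nrow(manifest) * design$panel_size) <
                            design$sporadic_presence,
                          nrow = nrow(manifest), dimnames = list(manifest$sample_id, nm))

    expec <- matrix(0, nrow(manifest), design$panel_size,
                    dimnames = list(manifest$sample_id, nm))
    for (s in seq_len(nrow(manifest))) {
      di <- match(manifest$day[s], design$days)
      for (g in seq_len(design$panel_size)) {
        cl <- clusters[g]
        mult <- if (cl == "Sporadic") {
          if (sporadic_on[s, g]) design$sporadic_level else 0
        } else design$multipliers[[cl]][di]
        expec[s, g] <- base[g] * mult * ie[manifest$individual[s], g]
      }
    }
    obs <- t(apply(expec, 1, function(e) {
      alpha <- design$dirichlet_conc * e / sum(e)
      y <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
      p <- 100 * y / sum(y)
      p[p < design$detection_limit] <- 0   # below the detection floor
      100 * p / sum(p)
    }))
    dimnames(obs) <- dimnames(expec)
    tab <- abundance_table(obs, manifest$individual, manifest$day)
    list(table = tab, structures = structs,
         truth = list(clusters = clusters, multipliers = design$multipliers,
                      base = base, individual_effects = ie,
                      expected = expec, design = design, seed = seed))
  })
}

#' Low-noise variant of the cohort design
#'
#' The configuration used for parameter-recovery checks: quiet Dirichlet
#' sampling, small individual effects, a moderate spread of base levels (so
#' no glycan sits at the detection floor where sampling noise dominates),
#' and no sporadic (randomly flickering) glycans -- leaving the planted
#' Early/Stable/Late temporal structure as the dominant signal.
#'
#' @param ... overrides passed on to [cohort_design()].
#' @return A [cohort_design()].
#' @export
low_noise_design <- function(...) {
  cohort_design(cluster_props = c(Early = 0.3, Stable = 0.4, Late = 0.3),
                dirichlet_conc = 2000, indiv_sigma = 0.05, base_sigma = 0.4,
                ...)
}

# ---- paired metabolome -------------------------------------------------------

#' Simulate a paired metabolome for a glycome cohort
#'
#' A latent lactation factor (standardized day) drives a configurable
#' fraction of metabolites; `n_direct_links` metabolites are additionally
#' tied to specific glycans of the cohort (their CLR trajectory plus a small
#' noise term), planting direct glycome-metabolome partial correlations; the
#' remaining metabolites are lognormal noise with individual effects. Output
#' is closed to percentages like any abundance table.
#'
#' @param cohort the list returned by [simulate_cohort()] (or an
#'   [abundance_table()]).
#' @param n_metabolites number of metabolites (default 5x the glycan count,
#'   the feature-count ratio typical of paired milk metabolomes).
#' @param n_direct_links number of planted direct glycan-metabolite pairs.
#' @param noise_scale log-scale sd of metabolite noise.
#' @param latent_loading loading of the latent day factor on driven
#'   metabolites (0 disables the factor).
#' @param latent_frac fraction of metabolites driven by the latent factor.
#' @param direct_noise log-scale sd of the planted direct links (0 makes the
#'   link deterministic).
#' @param indiv_sigma sd of per-(metabolite, individual) effects.
#' @param seed integer seed.
#' @return List with `table` (an [abundance_table()] of metabolites) and
#'   `truth` (`direct_pairs` data.frame, `loadings`, `latent` scores).
#' @export
simulate_metabolome <- function(cohort, n_metabolites = NULL, n_direct_links = 3L,
                                noise_scale = 0.3, latent_loading = 0.7,
                                latent_frac = 0.5, direct_noise = 0.05,
                                indiv_sigma = 0.1, seed = NULL) {
  tab <- if (inherits(cohort, "abundance_table")) cohort else cohort$table
  stopifnot(inherits(tab, "abundance_table"))
  nglyc <- ncol(tab$abund)
  if (is.null(n_metabolites)) n_metabolites <- 5L * nglyc
  if (n_direct_links > n_metabolites)
    stop("n_direct_links exceeds n_metabolites")
  if (n_direct_links > nglyc) stop("n_direct_links exceeds glycan count")
  .with_seed(seed, {
    n <- nrow(tab$abund)
    mn <- paste0("met_", seq_len(n_metabolites))
    z <- as.numeric(scale(tab$meta$day))
    ind <- tab$meta$individual

    glyc_clr <- clr_transform(impute_missing(tab$abund, "half_min") /
                                rowSums(impute_missing(tab$abund, "half_min")), gamma = 0)

    loadings <- numeric(n_metabolites)
    ndriven <- round(latent_frac * n_metabolites)
    if (ndriven > 0 && latent_loading > 0)
      loadings[seq_len(ndriven)] <- latent_loading *
        stats::runif(ndriven, 0.6, 1.4) * sample(c(-1, 1), ndriven, replace = TRUE)

    logm <- matrix(stats::rnorm(n * n_metabolites, 0, noise_scale), n, n_metabolites,
                   dimnames = list(rownames(tab$abund), mn))
    logm <- logm + outer(z, loadings)
    iev <- matrix(stats::rnorm(length(unique(ind)) * n_metabolites, 0, indiv_sigma),
                  nrow = length(unique(ind)),
                  dimnames = list(unique(ind), mn))
    logm <- logm + iev[ind, , drop = FALSE]

    direct <- data.frame(glycan = character(0), metabolite = character(0),
                         stringsAsFactors = FALSE)
    if (n_direct_links > 0) {
      # plant links on glycans with the most glycan-specific (within-day)
      # variation: a link to a glycan whose trajectory is fully explained by
      # the shared day factor would be statistically indistinguishable from
      # a bystander correlation
      day_resid_var <- apply(glyc_clr, 2, function(x)
        stats::var(x - stats::ave(x, tab$meta$day)))
      gsel <- names(sort(day_resid_var, decreasing = TRUE))[seq_len(n_direct_links)]
      msel <- mn[n_metabolites - seq_len(n_direct_links) + 1L]  # noise-only slots
      for (i in seq_len(n_direct_links)) {
        logm[, msel[i]] <- glyc_clr[, gsel[i]] +
          stats::rnorm(n, 0, direct_noise)
      }
      direct <- data.frame(glycan = gsel, metabolite = msel,
                           stringsAsFactors = FALSE)
    }
    comp <- exp(logm)
    comp <- 100 * comp / rowSums(comp)
    mtab <- abundance_table(comp, ind, tab$meta$day)
    list(table = mtab,
         truth = list(direct_pairs = direct, loadings = stats::setNames(loadings, mn),
                      latent = z, seed = seed))
  })
}

# ---- sulfation/extension chains ---------------------------------------------

#' Simulate linear chains with a planted sulfation-extension gap
#'
#' Builds lactose-core poly-LacNAc chains in which each newly added GlcNAc is
#' sulfated with probability `p_sulf` and is then extended (gains its
#' Gal\eqn{\beta}1-4 and the chain continues) with probability
#' `p_extend_sulfated` or `p_extend_plain` according to its sulfation state.
#' The resulting set carries a known extension-probability gap for
#' [sulfation_branching_test()] to detect.
#'
#' @param n number of structures.
#' @param p_sulf per-GlcNAc sulfation probability.
#' @param p_extend_sulfated,p_extend_plain extension probabilities.
#' @param max_size maximum residue count per structure.
#' @param seed integer seed.
#' @return List of [glycan_structure()].
#' @export
simulate_sulfation_set <- function(n, p_sulf = 0.5, p_extend_sulfated = 0.2,
                                   p_extend_plain = 0.8, max_size = 30L,
                                   seed = NULL) {
  pr <- c(p_sulf, p_extend_sulfated, p_extend_plain)
  if (any(pr < 0 | pr > 1)) stop("probabilities must be in [0, 1]")
  .with_seed(seed, lapply(seq_len(n), function(i) {
    env <- .gb_init()
    root <- .gb_add(env, "Glc")
    tip <- .gb_add(env, "Gal", root, .beta, "1", "4")
    repeat {
      if (length(env$base) + 1L > max_size) break
      sulf <- stats::runif(1) < p_sulf
      gn <- .gb_add(env, "GlcNAc", tip, .beta, "1", "3",
                    mods = if (sulf) "6S" else "")
      pext <- if (sulf) p_extend_sulfated else p_extend_plain
      if (length(env$base) + 1L > max_size || stats::runif(1) >= pext) break
      tip <- .gb_add(env, "Gal", gn, .beta, "1", "4")
    }
    .gb_glycan(env, root)
  }))
}
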