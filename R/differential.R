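# Differential analysis between two sampled flux distributions at reaction,
# metabolite-utilization and subsystem-utilization levels.

#' Default subsystems excluded from reaction-level differential analysis
#'
#' Pathway labels whose reactions are dropped before reaction-level testing
#' (alongside demand reactions): transport, porin, ion transport, nucleotide
#' salvage and oxidative phosphorylation subsystems whose sampled fluxes are
#' dominated by exchange bookkeeping rather than enzymatic rerouting.
#'
#' @return Character vector of subsystem labels.
#' @export
default_excluded_subsystems <- function() {
  c("Unassigned",
    "Transport, Outer Membrane Porin",
    "Transport, Inner Membrane",
    "Inorganic Ion Transport and Metabolism",
    "Transport, Outer Membrane",
    "Nucleotide Salvage Pathway",
    "Oxidative Phosphorylation")
}

#' Geometric fold-change of two sampled distributions
#'
#' `log2((GM(|a|) + eps) / (GM(|b|) + eps))` where GM is the geometric mean
#' over sample points; `eps` regularizes zero fluxes. The statistic is
#' magnitude-based, so a pure sign flip gives 0; it is antisymmetric in its
#' arguments.
#'
#' @param values_a,values_b numeric sample vectors (condition A vs B).
#' @param epsilon small positive regularizer.
#' @return Signed log2 ratio.
#' @export
geometric_fold_change <- function(values_a, values_b, epsilon = 1e-6) {
  if (!length(values_a) || !length(values_b))
    stop_fluxpath("validation", "empty sample vector")
  if (epsilon <= 0) stop_fluxpath("validation", "epsilon must be > 0")
  gm <- function(x) {
    lx <- log(abs(x))
    if (any(!is.finite(lx))) 0 else exp(mean(lx)) # GM is 0 if any flux is 0
  }
  log2((gm(values_a) + epsilon) / (gm(values_b) + epsilon))
}

#' Permutation p-value for a difference of sampled means
#'
#' Statistic `T = |mean(a) - mean(b)|`; group labels are permuted `n_perm`
#' times and the add-one estimator
#' `p = (1 + #\{T_perm >= T_obs\}) / (1 + n_perm)` returned, so the smallest
#' attainable p is `1/(n_perm + 1)`.
#'
#' @param values_a,values_b numeric sample vectors.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed (fixed seed gives a deterministic p-value).
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(values_a, values_b, n_perm = 1000L, seed) {
  if (n_perm < 1L) stop_fluxpath("validation", "n_perm must be >= 1")
  pool <- c(values_a, values_b)
  na <- length(values_a)
  t_obs <- abs(mean(values_a) - mean(values_b))
  if (t_obs == 0 && stats::var(pool) == 0) return(1)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pool), na)
      abs(mean(pool[idx]) - mean(pool[-idx]))
    }, numeric(1))
  })
  (1 + sum(perm >= t_obs - 1e-15)) / (1 + n_perm)
}

#' Per-point metabolite turnover of a flux sample
#'
#' For every sampled point and metabolite i the turnover
#' `t_i = sum_j max(0, S_ij v_j)` (total production flux) is computed; at
#' steady state production equals consumption, so this is the metabolite's
#' utilization.
#'
#' @param model the `metabolic_model` the sample was drawn from.
#' @param sample a matching `flux_sample`.
#' @return A `utilization_sample`: list with `entity_ids` (metabolite ids)
#'   and `points` (n_points x n_metabolites matrix, flux-turnover units).
#' @export
metabolite_utilization <- function(model, sample) {
  check_sample_model(model, sample)
  S <- stoichiometric_matrix(model)
  V <- sample$points[, colnames(S), drop = FALSE]
  Spos <- pmax(S, 0); Sneg <- pmax(-S, 0)
  Vpos <- pmax(V, 0); Vneg <- pmax(-V, 0)
  # max(0, S_ij v_j) = max(S_ij,0) * max(v_j,0) + max(-S_ij,0) * max(-v_j,0)
  pts <- Vpos %*% t(Spos) + Vneg %*% t(Sneg)
  structure(list(entity_ids = rownames(S), points = pts,
                 level = "metabolite"),
            class = "utilization_sample")
}

#' Per-point subsystem utilization of a flux sample
#'
#' For every sampled point and subsystem k, `u_k = sum_{j in k} |v_j|`.
#'
#' @param model the `metabolic_model` the sample was drawn from.
#' @param sample a matching `flux_sample`.
#' @return A `utilization_sample` over subsystem labels.
#' @export
subsystem_utilization <- function(model, sample) {
  check_sample_model(model, sample)
  subs <- sort(unique(model$reactions$subsystem))
  M <- outer(model$reactions$subsystem, subs, "==") * 1
  pts <- abs(sample$points) %*% M
  colnames(pts) <- subs
  structure(list(entity_ids = subs, points = pts, level = "subsystem"),
            class = "utilization_sample")
}

check_sample_model <- function(model, sample) {
  if (!setequal(sample$reaction_ids, model$reactions$id) ||
      is.null(colnames(sample$points)))
    stop_fluxpath("consistency",
                  "sample reaction set does not match the model")
  invisible(TRUE)
}

#' Differential flux / utilization analysis between two sampled conditions
#'
#' For each entity at the requested level, computes the geometric
#' fold-change (A over B, log2) and a permutation p-value on the difference
#' of sampled means, and flags entities with `p < p_thresh` and
#' `|gfc| > fc_thresh` as significant (defaults 0.05 and 0.001). At the
#' reaction level, demand reactions and reactions in excluded subsystems are
#' dropped before testing.
#'
#' @param sample_a,sample_b `flux_sample`s over the same model structure
#'   (condition A, e.g. a knockout, and condition B, e.g. the reference).
#' @param model the shared `metabolic_model`.
#' @param level `"reaction"`, `"metabolite"` or `"subsystem"`.
#' @param p_thresh,fc_thresh significance thresholds.
#' @param n_perm permutations per entity.
#' @param seed integer seed.
#' @param excluded_subsystems labels dropped at reaction level; see
#'   [default_excluded_subsystems()].
#' @param adjust optional multiple-testing adjustment (`"none"`, default,
#'   or `"BH"`); when set, significance uses the adjusted p-values.
#' @return data.frame with columns `entity_id`, `level`, `gfc`,
#'   `p_permuted`, `significant` (and `mean_a`, `mean_b` of the raw sampled
#'   values).
#' @export
differential_levels <- function(sample_a, sample_b, model,
                                level = c("reaction", "metabolite", "subsystem"),
                                p_thresh = 0.05, fc_thresh = 0.001,
                                n_perm = 1000L, seed,
                                excluded_subsystems = default_excluded_subsystems(),
                                adjust = c("none", "BH")) {
  level <- match.arg(level)
  adjust <- match.arg(adjust)
  check_sample_model(model, sample_a)
  check_sample_model(model, sample_b)
  if (level == "reaction") {
    keep <- !(model$reactions$is_demand |
                model$reactions$subsystem %in% excluded_subsystems)
    ids <- model$reactions$id[keep]
    A <- sample_a$points[, ids, drop = FALSE]
    B <- sample_b$points[, ids, drop = FALSE]
  } else if (level == "metabolite") {
    ua <- metabolite_utilization(model, sample_a)
    ub <- metabolite_utilization(model, sample_b)
    ids <- ua$entity_ids; A <- ua$points; B <- ub$points
  } else {
    ua <- subsystem_utilization(model, sample_a)
    ub <- subsystem_utilization(model, sample_b)
    ids <- ua$entity_ids; A <- ua$points; B <- ub$points
  }
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(ids)))
  gfc <- vapply(seq_along(ids), function(k)
    geometric_fold_change(A[, k], B[, k]), numeric(1))
  p <- vapply(seq_along(ids), function(k)
    permutation_pvalue(A[, k], B[, k], n_perm = n_perm, seed = seeds[k]),
    numeric(1))
  p_eff <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  data.frame(entity_id = ids, level = level, gfc = gfc, p_permuted = p,
             significant = p_eff < p_thresh & abs(gfc) > fc_thresh,
             mean_a = colMeans(A), mean_b = colMeans(B),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hierarchical clustering of fold-change profiles
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of
#' entities by their log2 fold-change profiles across conditions, with a
#' deterministic leaf order (entities pre-sorted by id so ties break
#' reproducibly).
#'
#' @param fc_matrix numeric matrix, entities x conditions, no missing
#'   values; rownames are entity ids.
#' @return list with `hclust` (the merge tree) and `leaf_order` (entity ids
#'   in dendrogram order).
#' @export
cluster_fold_changes <- function(fc_matrix) {
  if (is.null(dim(fc_matrix)) || nrow(fc_matrix) < 2L)
    stop_fluxpath("validation", "need at least 2 entities to cluster")
  if (anyNA(fc_matrix))
    stop_fluxpath("validation", "fold-change matrix contains missing values")
  if (is.null(rownames(fc_matrix)))
    rownames(fc_matrix) <- sprintf("entity_%d", seq_len(nrow(fc_matrix)))
  m <- fc_matrix[order(rownames(fc_matrix)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  list(hclust = hc, leaf_order = rownames(m)[hc$order])
}

#' Write a differential report as TSV
#'
#' @param records output of [differential_levels()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_differential_report <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
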