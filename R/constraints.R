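# Translating phenomic rate measurements and 13C-MFA confidence intervals
# into model bounds, with a greedy elastic repair for conflicting intervals.

#' Read measured rates from TSV
#'
#' Expected columns: `reaction_id`, `mean`, `sd`, `n` (number of
#' steady-state time points the rate was fitted from). Fluxes in
#' mmol gDCW^-1 h^-1 (growth in h^-1); uptake negative, secretion positive.
#'
#' @param path TSV file.
#' @return data.frame of class `rate_measurements`.
#' @export
read_rate_measurements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("reaction_id", "mean", "sd")
  if (!all(need %in% names(df)))
    stop_fluxpath("format", paste0("rate table needs columns: ",
                                   paste(need, collapse = ", ")))
  if (!"n" %in% names(df)) df$n <- NA_integer_
  rate_measurements(df$reaction_id, df$mean, df$sd, df$n)
}

#' Construct a rate-measurement table
#'
#' @param reaction_id character vector.
#' @param mean,sd measured rate mean and standard deviation (sd >= 0).
#' @param n_timepoints number of steady-state time points per rate
#'   (steady-state fits use at least four).
#' @return data.frame of class `rate_measurements`.
#' @export
rate_measurements <- function(reaction_id, mean, sd, n_timepoints = NA_integer_) {
  if (any(sd < 0)) stop_fluxpath("validation", "sd must be >= 0")
  structure(data.frame(reaction_id = as.character(reaction_id),
                       mean = as.numeric(mean), sd = as.numeric(sd),
                       n = as.integer(n_timepoints),
                       stringsAsFactors = FALSE),
            class = c("rate_measurements", "data.frame"))
}

#' Construct a flux confidence-interval table
#'
#' Confidence intervals (default level 0.95) on fluxes, e.g. from a 13C-MFA
#' fit, to be used as lower/upper bound constraints.
#'
#' @param reaction_id character vector.
#' @param lower,upper interval endpoints (lower <= upper).
#' @param level confidence level, fraction.
#' @return data.frame of class `flux_ci`.
#' @export
flux_ci <- function(reaction_id, lower, upper, level = 0.95) {
  if (any(lower > upper))
    stop_fluxpath("validation", "CI lower > upper")
  structure(data.frame(reaction_id = as.character(reaction_id),
                       lower = as.numeric(lower), upper = as.numeric(upper),
                       level = as.numeric(level), stringsAsFactors = FALSE),
            class = c("flux_ci", "data.frame"))
}

#' Read flux confidence intervals from TSV
#'
#' Expected columns: `reaction_id`, `lower`, `upper`, optional `level`.
#'
#' @param path TSV file.
#' @return data.frame of class `flux_ci`.
#' @export
read_flux_ci <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("reaction_id", "lower", "upper")
  if (!all(need %in% names(df)))
    stop_fluxpath("format", paste0("CI table needs columns: ",
                                   paste(need, collapse = ", ")))
  flux_ci(df$reaction_id, df$lower, df$upper,
          if ("level" %in% names(df)) df$level else 0.95)
}

#' Convert rate measurements to interval constraints
#'
#' Expresses each measurement as the interval `mean +/- k_sd * sd`, in the
#' `flux_ci` form accepted by [constrain_mfa_ci()] and
#' [repair_constraints()], so that measured rates can share the elastic
#' discard-and-resample repair machinery when independent measurement noise
#' makes the joint constraints inconsistent.
#'
#' @param measurements a `rate_measurements` table.
#' @param k_sd interval half-width in SD units (default 1, the measured
#'   average value +/- SD).
#' @return A `flux_ci` table.
#' @export
rates_to_ci <- function(measurements, k_sd = 1) {
  flux_ci(measurements$reaction_id,
          measurements$mean - k_sd * measurements$sd,
          measurements$mean + k_sd * measurements$sd,
          level = NA_real_)
}

intersect_bounds <- function(model, ids, lo, hi, label) {
  idx <- reaction_index(model, ids)
  new_lb <- pmax(model$reactions$lower_bound[idx], lo)
  new_ub <- pmin(model$reactions$upper_bound[idx], hi)
  bad <- new_lb > new_ub + 1e-12
  if (any(bad))
    stop_fluxpath("conflict",
                  paste0(label, " constraint empty after intersection for: ",
                         paste(ids[bad], collapse = ", ")))
  model$reactions$lower_bound[idx] <- new_lb
  model$reactions$upper_bound[idx] <- pmax(new_ub, new_lb)
  model
}

#' Constrain reactions to measured rate +/- SD
#'
#' Each listed reaction's bounds become `[mean - sd, mean + sd]`,
#' intersected with its existing bounds. A copy is returned; the input model
#' is unmodified.
#'
#' @param model a `metabolic_model`.
#' @param measurements a `rate_measurements` table.
#' @param replace if TRUE the measured interval replaces the existing bounds
#'   instead of intersecting them.
#' @return The constrained copy.
#' @export
constrain_rates <- function(model, measurements, replace = FALSE) {
  if (replace) {
    idx <- reaction_index(model, measurements$reaction_id)
    model$reactions$lower_bound[idx] <- measurements$mean - measurements$sd
    model$reactions$upper_bound[idx] <- measurements$mean + measurements$sd
    return(model)
  }
  intersect_bounds(model, measurements$reaction_id,
                   measurements$mean - measurements$sd,
                   measurements$mean + measurements$sd, "rate")
}

#' Constrain reactions to flux confidence intervals
#'
#' Sets each listed reaction's bounds to `[lower, upper]` intersected with
#' the existing bounds (a CI wider than the existing bounds leaves them
#' unchanged). A copy is returned.
#'
#' @param model a `metabolic_model`.
#' @param cis a `flux_ci` table.
#' @param replace if TRUE the CI replaces the existing bounds.
#' @return The constrained copy.
#' @export
constrain_mfa_ci <- function(model, cis, replace = FALSE) {
  if (replace) {
    idx <- reaction_index(model, cis$reaction_id)
    model$reactions$lower_bound[idx] <- cis$lower
    model$reactions$upper_bound[idx] <- cis$upper
    return(model)
  }
  intersect_bounds(model, cis$reaction_id, cis$lower, cis$upper, "MFA CI")
}

# Elastic feasibility LP: base bounds hard, CI bounds soft with slacks;
# minimizes total CI violation. Returns per-CI violation at the optimum.
# Formulated in equality form:
#   S v = 0
#   v - s_hi + p = ci_upper   (p >= 0 surplus)
#   v + s_lo - q = ci_lower   (q >= 0 slack)
# variables (v, s_lo, s_hi, p, q), minimize sum(s_lo + s_hi).
elastic_violations <- function(model, cis) {
  S <- stoichiometric_matrix(model)
  rxn <- model$reactions
  bnd <- cap_bounds(rxn$lower_bound, rxn$upper_bound)
  n <- nrow(rxn); m <- nrow(S); k <- nrow(cis)
  idx <- reaction_index(model, cis$reaction_id)
  nv <- n + 4L * k
  big <- 4 * BIG_BOUND
  A <- matrix(0, m + 2L * k, nv)
  A[seq_len(m), seq_len(n)] <- S
  rhi <- m + seq_len(k); rlo <- m + k + seq_len(k)
  A[cbind(rhi, idx)] <- 1
  A[cbind(rhi, n + k + seq_len(k))] <- -1    # -s_hi
  A[cbind(rhi, n + 2L * k + seq_len(k))] <- 1  # +p
  A[cbind(rlo, idx)] <- 1
  A[cbind(rlo, n + seq_len(k))] <- 1         # +s_lo
  A[cbind(rlo, n + 3L * k + seq_len(k))] <- -1 # -q
  b <- c(rep(0, m), cis$upper, cis$lower)
  cost <- c(rep(0, n), rep(1, 2L * k), rep(0, 2L * k))
  l <- c(bnd$lb, rep(0, 4L * k))
  u <- c(bnd$ub, rep(big, 4L * k))
  res <- lp_bounded(A, b, cost, l, u)
  if (res$status != "optimal")
    stop_fluxpath("infeasible",
                  paste0("base model '", model$id,
                         "' infeasible even with all CIs relaxed"))
  s_lo <- res$x[n + seq_len(k)]; s_hi <- res$x[n + k + seq_len(k)]
  data.frame(reaction_id = cis$reaction_id, violation = s_lo + s_hi,
             stringsAsFactors = FALSE)
}

is_feasible <- function(model) {
  S <- stoichiometric_matrix(model)
  rxn <- model$reactions
  res <- solve_lp(S, rxn$lower_bound, rxn$upper_bound,
                  numeric(nrow(rxn)))
  res$status == "optimal"
}

#' Repair conflicting MFA confidence-interval constraints
#'
#' Applies the discard rule for MFA-derived constraints that violate
#' feasibility/optimality: while the CI-constrained model is infeasible, an
#' elastic relaxation minimizing the total bound violation is solved on the
#' base model, the CI with the largest violation is discarded, and the test
#' repeats. The repaired model can then be resampled.
#'
#' @param model the base `metabolic_model` (before CI application).
#' @param cis a `flux_ci` table.
#' @param tol violations below `tol` are treated as zero.
#' @return list with `model` (feasible, CIs applied minus discards),
#'   `discarded` (reaction ids in discard order) and `violations`
#'   (per-iteration elastic violation of each discarded CI).
#' @export
repair_constraints <- function(model, cis, tol = 1e-9) {
  if (!is_feasible(model))
    stop_fluxpath("infeasible",
                  paste0("base model '", model$id,
                         "' is infeasible before any CI is applied"))
  discarded <- character(); viols <- numeric()
  keep <- cis
  repeat {
    candidate <- tryCatch(constrain_mfa_ci(model, keep),
                          error = function(e) NULL)
    if (!is.null(candidate) && is_feasible(candidate))
      return(list(model = candidate, discarded = discarded,
                  violations = viols))
    if (nrow(keep) == 0L)
      stop_fluxpath("infeasible",
                    paste0("model '", model$id,
                           "' infeasible with every CI discarded"))
    ev <- elastic_violations(model, keep)
    worst <- which.max(ev$violation)
    if (ev$violation[worst] <= tol)
      stop_fluxpath("infeasible",
                    "constraint conflict not attributable to any CI (zero elastic violations)")
    discarded <- c(discarded, ev$reaction_id[worst])
    viols <- c(viols, ev$violation[worst])
    keep <- keep[-worst, , drop = FALSE]
  }
}

#' Write a constraint-repair report
#'
#' @param repair result of [repair_constraints()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_repair_report <- function(repair, path) {
  jsonlite::write_json(
    list(discarded = as.list(repair$discarded),
         violations = as.list(repair$violations)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
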