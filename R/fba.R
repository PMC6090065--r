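# Linear programming over the steady-state flux polytope
# {v : S v = 0, lb <= v <= ub}.  Solved with the simplex method after the
# shift x = v - lb (x >= 0), upper bounds as inequality rows.  Infinite
# bounds are capped at BIG_BOUND; an optimum pinned to the artificial cap is
# reported as unbounded.

BIG_BOUND <- 1e6

cap_bounds <- function(lb, ub) {
  lb[!is.finite(lb)] <- -BIG_BOUND
  ub[!is.finite(ub)] <- BIG_BOUND
  list(lb = pmin(pmax(lb, -BIG_BOUND), BIG_BOUND),
       ub = pmin(pmax(ub, -BIG_BOUND), BIG_BOUND))
}

# Maximize obj'v subject to S v = 0, lb <= v <= ub.
# Returns list(status, v, value); status in {"optimal", "infeasible", "maxiter"}.
solve_lp <- function(S, lb, ub, obj, maximize = TRUE) {
  bnd <- cap_bounds(lb, ub)
  res <- lp_bounded(S, rep(0, nrow(S)),
                    if (maximize) -obj else obj, bnd$lb, bnd$ub)
  if (res$status != "optimal")
    return(list(status = res$status, v = NULL, value = NA_real_))
  list(status = "optimal", v = res$x, value = sum(obj * res$x))
}

binding_bound_report <- function(model) {
  rxn <- model$reactions
  fixed <- rxn$id[rxn$upper_bound - rxn$lower_bound < 1e-12]
  paste0("fixed/binding bound candidates: ",
         if (length(fixed)) paste(fixed, collapse = ", ") else "(none fixed)")
}

#' Flux balance analysis
#'
#' Optimizes the model's declared objective (the reactions with nonzero
#' `objective_coefficient`) over the steady-state flux polytope
#' S v = 0, lb <= v <= ub.
#'
#' @param model a feasible `metabolic_model`.
#' @param sense `"max"` (default) or `"min"`.
#' @param tol_feas steady-state tolerance used to verify the returned vector.
#' @return A `flux_vector`: list with `values` (named flux vector,
#'   mmol gDCW^-1 h^-1) and `objective_value`.
#' @examples
#' mod <- build_toy_network()
#' sol <- fba(mod)
#' sol$objective_value        # growth rate, h^-1
#' @export
fba <- function(model, sense = c("max", "min"), tol_feas = 1e-6) {
  sense <- match.arg(sense)
  S <- stoichiometric_matrix(model)
  rxn <- model$reactions
  if (all(rxn$objective_coefficient == 0))
    stop_fluxpath("validation", "model has no objective reaction")
  res <- solve_lp(S, rxn$lower_bound, rxn$upper_bound,
                  rxn$objective_coefficient, maximize = sense == "max")
  if (res$status == "infeasible")
    stop_fluxpath("infeasible",
                  paste0("model '", model$id, "' is infeasible; ",
                         binding_bound_report(model)))
  if (res$status != "optimal")
    stop_fluxpath("infeasible",
                  paste0("LP did not converge for model '", model$id, "'"))
  at_cap <- any(abs(res$v) >= BIG_BOUND * (1 - 1e-9) &
                  (!is.finite(rxn$lower_bound) | !is.finite(rxn$upper_bound)))
  if (at_cap)
    stop_fluxpath("unbounded",
                  paste0("objective for model '", model$id,
                         "' is unbounded (optimum at artificial cap)"))
  v <- stats::setNames(res$v, rxn$id)
  resid <- max(abs(S %*% v))
  if (resid > tol_feas)
    stop_fluxpath("infeasible",
                  paste0("LP solution violates steady state (||S v||_inf = ",
                         format(resid), ")"))
  structure(list(values = v, objective_value = res$value),
            class = "flux_vector")
}

#' Flux variability analysis
#'
#' Minimum and maximum attainable flux per reaction subject to steady state
#' and bounds, optionally with the objective fixed at a fraction of its
#' optimum.
#'
#' @param model a feasible `metabolic_model`.
#' @param reaction_ids reactions to analyse (default: all).
#' @param fraction_of_optimum in `[0, 1]`; 0 (default) leaves the objective
#'   free, 1 fixes it at the FBA optimum.
#' @return data.frame with columns `reaction_id`, `min`, `max`.
#' @export
flux_variability <- function(model, reaction_ids = model$reactions$id,
                             fraction_of_optimum = 0) {
  idx <- reaction_index(model, reaction_ids)
  work <- model
  if (fraction_of_optimum > 0) {
    opt <- fba(model)$objective_value
    oc <- work$reactions$objective_coefficient
    # fix objective value via bound on the (single) objective reaction when
    # possible, else append no constraint (multi-reaction objectives keep the
    # polytope as-is and the fraction is applied to each objective reaction)
    obj_idx <- which(oc != 0)
    for (j in obj_idx) {
      target <- fraction_of_optimum * opt / sum(oc[obj_idx] != 0) / oc[j]
      work$reactions$lower_bound[j] <- max(work$reactions$lower_bound[j], target)
    }
  }
  S <- stoichiometric_matrix(work)
  lbv <- work$reactions$lower_bound
  ubv <- work$reactions$upper_bound
  out <- data.frame(reaction_id = reaction_ids, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    j <- idx[k]
    if (ubv[j] - lbv[j] < 1e-12) {            # fixed: range is a point
      out$min[k] <- out$max[k] <- lbv[j]
      next
    }
    e <- numeric(length(lbv)); e[j] <- 1
    lo <- solve_lp(S, lbv, ubv, e, maximize = FALSE)
    hi <- solve_lp(S, lbv, ubv, e, maximize = TRUE)
    if (lo$status == "infeasible" || hi$status == "infeasible")
      stop_fluxpath("infeasible",
                    paste0("model '", model$id, "' infeasible during FVA; ",
                           binding_bound_report(model)))
    out$min[k] <- lo$value
    out$max[k] <- hi$value
  }
  out
}

#' Knock out reactions in silico
#'
#' Returns a copy of the model with the listed reactions' bounds fixed to
#' zero; the input model is left unmodified.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reactions to disable.
#' @return The modified copy.
#' @export
apply_knockout <- function(model, reaction_ids) {
  idx <- reaction_index(model, reaction_ids)
  model$reactions$lower_bound[idx] <- 0
  model$reactions$upper_bound[idx] <- 0
  model
}

#' Detect reactions that can carry flux in internal loops
#'
#' A reaction is loop-involved when it retains a nonzero flux-variability
#' range after all exchange reactions are closed (and any positive lower
#' bounds, e.g. maintenance demands, are relaxed to zero so the zero-flux
#' state is admissible). Such flux is thermodynamically infeasible cycling.
#'
#' @param model a `metabolic_model`.
#' @param tol ranges whose endpoints are within `tol` of zero are not loops.
#' @return Character vector of loop-involved reaction ids.
#' @export
find_loop_reactions <- function(model, tol = 1e-6) {
  work <- model
  ex <- work$reactions$is_exchange
  work$reactions$lower_bound[ex] <- 0
  work$reactions$upper_bound[ex] <- 0
  work$reactions$lower_bound <- pmin(work$reactions$lower_bound, 0)
  work$reactions$upper_bound <- pmax(work$reactions$upper_bound, 0)
  fva <- flux_variability(work)
  fva$reaction_id[pmax(abs(fva$min), abs(fva$max)) > tol]
}
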