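# Small constraint-based fixtures built in code, plus a brute-force
# vertex-enumeration oracle for LPs on models with few reactions.

make_model <- function(id, met_ids, rxn_df, stoich,
                       measurable = rep(TRUE, length(met_ids))) {
  mets <- data.frame(id = met_ids, name = met_ids, compartment = "c",
                     measurable = measurable, stringsAsFactors = FALSE)
  defaults <- data.frame(subsystem = "S", gene_count = 1L,
                         is_spontaneous = FALSE, is_demand = FALSE,
                         is_exchange = FALSE, objective_coefficient = 0)
  for (col in names(defaults))
    if (!col %in% names(rxn_df)) rxn_df[[col]] <- defaults[[col]]
  metabolic_model(id, mets, rxn_df, stoich)
}

# A_ext -(EX, 0..10)-> A -(OBJ, 0..1000)-> nothing; optimum 10
chain_model <- function() {
  make_model("chain", "A",
             data.frame(id = c("EX_A", "OBJ"),
                        lower_bound = c(0, 0), upper_bound = c(10, 1000),
                        is_exchange = c(TRUE, FALSE),
                        objective_coefficient = c(0, 1)),
             list(EX_A = c(A = 1), OBJ = c(A = -1)))
}

# branched: in -> A (0..10); A -> B (0..6); A -> waste (0..8); B -> obj
branched_model <- function() {
  make_model("branched", c("A", "B"),
             data.frame(id = c("IN", "AB", "AW", "OBJ"),
                        lower_bound = 0, upper_bound = c(10, 6, 8, 1000),
                        is_exchange = c(TRUE, FALSE, TRUE, FALSE),
                        objective_coefficient = c(0, 0, 0, 1)),
             list(IN = c(A = 1), AB = c(A = -1, B = 1), AW = c(A = -1),
                  OBJ = c(B = -1)))
}

# two independent unit chains -> 2-free-dimension box polytope in 4 reactions
box_model <- function() {
  make_model("box2d", c("m1", "m2"),
             data.frame(id = c("R1in", "R1out", "R2in", "R2out", "OBJ"),
                        lower_bound = 0, upper_bound = c(1, 1, 1, 1, 0),
                        is_exchange = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                        objective_coefficient = c(0, 0, 0, 0, 1)),
             list(R1in = c(m1 = 1), R1out = c(m1 = -1),
                  R2in = c(m2 = 1), R2out = c(m2 = -1),
                  OBJ = c(m1 = 0)))
}

# internal 2-cycle A <-> B with closed exchanges: the classic sampling loop
cycle_model <- function() {
  make_model("cycle", c("A", "B"),
             data.frame(id = c("EX_A", "F", "R", "OBJ"),
                        lower_bound = c(0, 0, 0, 0),
                        upper_bound = c(0, 5, 5, 0),
                        is_exchange = c(TRUE, FALSE, FALSE, FALSE),
                        objective_coefficient = c(0, 0, 0, 1)),
             list(EX_A = c(A = 1), F = c(A = -1, B = 1),
                  R = c(B = -1, A = 1), OBJ = c(A = 0)))
}

# 3-reaction chain for constraint repair: IN -> A -(M1)-> B -(M2)-> out;
# M1 and M2 are coupled 1:1 by stoichiometry
coupled_chain_model <- function() {
  make_model("coupled", c("A", "B"),
             data.frame(id = c("IN", "M1", "M2"),
                        lower_bound = 0, upper_bound = c(10, 10, 10),
                        is_exchange = c(TRUE, FALSE, FALSE),
                        objective_coefficient = c(0, 0, 1)),
             list(IN = c(A = 1), M1 = c(A = -1, B = 1), M2 = c(B = -1)))
}

toy_model_path <- function() {
  system.file("extdata", "toy_model.json", package = "fluxpath")
}

# Brute-force vertex enumeration of {v : S v = 0, lb <= v <= ub}.
# Fixes every choice of (n - rank(S)) reactions at a bound and solves for
# the rest; keeps solutions that are unique and within bounds.
enumerate_vertices <- function(model, tol = 1e-9) {
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- ncol(S)
  d <- n - qr(S)$rank
  verts <- list()
  push <- function(v) verts[[length(verts) + 1L]] <<- v
  if (d == 0L) {
    sol <- qr.solve(S, rep(0, nrow(S)))
    if (all(sol >= lb - tol & sol <= ub + tol)) push(sol)
  } else {
    for (J in utils::combn(n, d, simplify = FALSE)) {
      A <- S[, -J, drop = FALSE]
      if (qr(A)$rank < n - d) next               # remaining system not unique
      for (mask in 0:(2^d - 1)) {
        at_ub <- bitwAnd(mask, 2^(seq_len(d) - 1L)) > 0
        fix <- ifelse(at_ub, ub[J], lb[J])
        rhs <- -S[, J, drop = FALSE] %*% fix
        sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        if (max(abs(A %*% sol - rhs)) > 1e-8) next
        v <- numeric(n); v[J] <- fix; v[-J] <- sol
        if (all(v >= lb - tol & v <= ub + tol)) push(v)
      }
    }
  }
  if (!length(verts)) return(NULL)
  V <- unique(round(do.call(rbind, verts), 9))
  colnames(V) <- model$reactions$id
  V
}

oracle_fba_max <- function(model) {
  V <- enumerate_vertices(model)
  obj <- model$reactions$objective_coefficient
  max(V %*% obj)
}

oracle_fva <- function(model) {
  V <- enumerate_vertices(model)
  data.frame(reaction_id = colnames(V),
             min = apply(V, 2, min), max = apply(V, 2, max),
             row.names = NULL)
}

# constrained toy-model sample shared across tests (built lazily, cached)
toy_reference_setup <- local({
  cache <- NULL
  function(n_points = 600L, n_steps = 300L) {
    if (!is.null(cache)) return(cache)
    mod <- read_model(toy_model_path())
    ref <- fba(mod)
    rates <- simulate_rates(mod, ref$values, cv = 0.05, seed = 101)
    cmod <- repair_constraints(mod, rates_to_ci(rates))$model
    smp <- sample_fluxes(cmod, n_points = n_points, n_steps = n_steps,
                         seed = 7)
    cache <<- list(model = mod, ref = ref, rates = rates, cmod = cmod,
                   sample = smp)
    cache
  }
})

toy_ko_setup <- local({
  cache <- list()
  function(ko_id, n_points = 600L, n_steps = 300L) {
    if (!is.null(cache[[ko_id]])) return(cache[[ko_id]])
    mod <- read_model(toy_model_path())
    ko <- apply_knockout(mod, ko_id)
    sol <- fba(ko)
    rates <- simulate_rates(ko, sol$values, cv = 0.05, seed = 202)
    cmod <- repair_constraints(ko, rates_to_ci(rates))$model
    smp <- sample_fluxes(cmod, n_points = n_points, n_steps = n_steps,
                         seed = 8)
    cache[[ko_id]] <<- list(model = mod, ko = ko, sol = sol, cmod = cmod,
                            sample = smp)
    cache[[ko_id]]
  }
})
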