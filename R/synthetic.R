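# Synthetic data with known ground truth: a central-carbon toy network in
# which deleting the GND analog reroutes flux into the Entner-Doudoroff
# pathway and deleting the SUCDi analog forces succinate secretion, plus
# simulators for rate measurements, MFA confidence intervals, metabolite
# concentration tables and coverage tracks.

#' Build the synthetic central-carbon network
#'
#' Constructs a ~45-reaction model of glucose-grown central metabolism:
#' upper glycolysis and a lumped lower glycolysis, the oxidative pentose
#' phosphate branch (G6PDH, GND), the reversible non-oxidative branch (RPE,
#' RPI, TKT1, TALA, TKT2), a lumped Entner-Doudoroff route from
#' 6-phosphogluconate, the TCA cycle with SUCDi/FRD, glyoxylate shunt and
#' anaplerosis, nitrogen assimilation from 2-oxoglutarate, a lumped
#' respiratory chain, transhydrogenase and ATP maintenance, exchanges for
#' glucose, acetate, succinate, CO2 and ammonium, and a biomass reaction
#' over the canonical precursors. Cofactors are single lumped NADH/NADPH/ATP
#' pools (no protons or water), which suffices for rerouting topology but is
#' not elementally balanced.
#'
#' The fumarate reductase (FRD) analog ships with bounds `[0, 0]`: the
#' aerobic growth condition modelled here leaves it inactive, and an open
#' SUCDi/FRD pair is a thermodynamically infeasible cycle.
#'
#' @param include_ed include the Entner-Doudoroff route (default TRUE).
#' @param include_glyoxylate_shunt include ICL/MALS (default TRUE).
#' @param glc_uptake_max maximal glucose uptake rate, mmol gDCW^-1 h^-1.
#' @param default_bound magnitude used for otherwise unbounded reactions.
#' @param atp_maintenance non-growth ATP demand (lower bound of the
#'   maintenance reaction), mmol gDCW^-1 h^-1.
#' @param biomass_weights named numeric overrides for biomass precursor
#'   coefficients (mmol per gDCW).
#' @return A validated `metabolic_model` whose reference FBA growth is
#'   positive.
#' @export
build_toy_network <- function(include_ed = TRUE,
                              include_glyoxylate_shunt = TRUE,
                              glc_uptake_max = 10,
                              default_bound = 1000,
                              atp_maintenance = 2,
                              biomass_weights = NULL) {
  B <- default_bound
  cyt <- function(ids, measurable = TRUE)
    data.frame(id = ids, name = ids, compartment = "c",
               measurable = measurable, stringsAsFactors = FALSE)
  ext <- function(ids)
    data.frame(id = ids, name = ids, compartment = "e",
               measurable = FALSE, stringsAsFactors = FALSE)
  mets <- rbind(
    ext(c("glc_e", "ac_e", "succ_e", "co2_e", "nh4_e")),
    cyt(c("g6p", "f6p", "fdp", "dhap", "g3p", "pep", "pyr", "accoa", "ac",
          "6pgc", "ru5p", "x5p", "r5p", "s7p", "e4p",
          "cit", "icit", "akg", "succoa", "succ", "fum", "mal", "oaa",
          "glu", "atp")),
    cyt(c("glx", "co2", "nh4", "nadh", "nadph"), measurable = FALSE))

  bw <- c(r5p = 0.9, e4p = 0.4, pep = 0.5, pyr = 2.8, accoa = 3.7,
          akg = 1.1, oaa = 1.8, glu = 0.25, atp = 100, nadph = 14)
  if (!is.null(biomass_weights)) bw[names(biomass_weights)] <- biomass_weights

  rx <- list(); stoich <- list()
  add <- function(id, s, lb, ub, subsystem, genes = 1L,
                  spont = FALSE, demand = FALSE, exch = FALSE, obj = 0) {
    rx[[length(rx) + 1L]] <<- data.frame(
      id = id, lower_bound = lb, upper_bound = ub, subsystem = subsystem,
      gene_count = as.integer(genes), is_spontaneous = spont,
      is_demand = demand, is_exchange = exch, objective_coefficient = obj,
      stringsAsFactors = FALSE)
    stoich[[id]] <<- s
  }

  ## exchanges (uptake negative, secretion positive)
  add("EX_glc", c(glc_e = -1), -glc_uptake_max, 0, "Exchange", 0, exch = TRUE)
  add("EX_ac", c(ac_e = -1), 0, B, "Exchange", 0, exch = TRUE)
  add("EX_succ", c(succ_e = -1), 0, B, "Exchange", 0, exch = TRUE)
  add("EX_co2", c(co2_e = -1), -B, B, "Exchange", 0, exch = TRUE)
  add("EX_nh4", c(nh4_e = -1), -B, 0, "Exchange", 0, exch = TRUE)

  ## transport
  add("GLCpts", c(glc_e = -1, pep = -1, g6p = 1, pyr = 1), 0, B,
      "Transport, Inner Membrane", 2)
  add("ACt", c(ac = -1, ac_e = 1), 0, B, "Transport, Inner Membrane", 1)
  add("SUCCt", c(succ = -1, succ_e = 1), 0, B, "Transport, Inner Membrane", 1)
  add("CO2t", c(co2 = -1, co2_e = 1), -B, B, "Transport, Inner Membrane", 0,
      spont = TRUE)
  add("NH4t", c(nh4_e = -1, nh4 = 1), 0, B, "Transport, Inner Membrane", 1)

  ## glycolysis
  gly <- "Glycolysis/Gluconeogenesis"
  add("PGI", c(g6p = -1, f6p = 1), -B, B, gly, 1)
  add("PFK", c(f6p = -1, atp = -1, fdp = 1), 0, B, gly, 1)
  add("FBA", c(fdp = -1, dhap = 1, g3p = 1), -B, B, gly, 1)
  add("TPI", c(dhap = -1, g3p = 1), -B, B, gly, 1)
  # lumped GAPD..ENO: g3p -> pep with substrate-level ATP and NADH
  add("GAPD", c(g3p = -1, pep = 1, atp = 1, nadh = 1), -B, B, gly, 4)
  add("PYK", c(pep = -1, pyr = 1, atp = 1), 0, B, gly, 2)
  add("PDH", c(pyr = -1, accoa = 1, co2 = 1, nadh = 1), 0, B, gly, 3)

  ## pentose phosphate pathway
  ppp <- "Pentose Phosphate Pathway"
  add("G6PDH", c(g6p = -1, `6pgc` = 1, nadph = 1), 0, B, ppp, 1)
  add("GND", c(`6pgc` = -1, ru5p = 1, co2 = 1, nadph = 1), 0, B, ppp, 1)
  add("RPE", c(ru5p = -1, x5p = 1), -B, B, ppp, 1)
  add("RPI", c(ru5p = -1, r5p = 1), -B, B, ppp, 1)
  add("TKT1", c(x5p = -1, r5p = -1, g3p = 1, s7p = 1), -B, B, ppp, 2)
  add("TALA", c(g3p = -1, s7p = -1, e4p = 1, f6p = 1), -B, B, ppp, 2)
  add("TKT2", c(x5p = -1, e4p = -1, f6p = 1, g3p = 1), -B, B, ppp, 2)

  ## Entner-Doudoroff (lumped EDD + EDA)
  if (include_ed)
    add("EDD_EDA", c(`6pgc` = -1, g3p = 1, pyr = 1), 0, B,
        "Entner-Doudoroff Pathway", 2)

  ## TCA cycle
  tca <- "Citric Acid Cycle"
  add("CS", c(accoa = -1, oaa = -1, cit = 1), 0, B, tca, 1)
  add("ACONT", c(cit = -1, icit = 1), -B, B, tca, 1)
  add("ICDHyr", c(icit = -1, akg = 1, co2 = 1, nadph = 1), -B, B, tca, 1)
  add("AKGDH", c(akg = -1, succoa = 1, co2 = 1, nadh = 1), 0, B, tca, 3)
  add("SUCOAS", c(succoa = -1, succ = 1, atp = 1), -B, B, tca, 2)
  add("SUCDi", c(succ = -1, fum = 1, nadh = 1), 0, B, tca, 1)
  add("FRD", c(fum = -1, nadh = -1, succ = 1), 0, 0, tca, 4)
  add("FUM", c(fum = -1, mal = 1), -B, B, tca, 3)
  add("MDH", c(mal = -1, oaa = 1, nadh = 1), -B, B, tca, 1)

  ## anaplerosis / glyoxylate shunt
  ana <- "Anaplerotic Reactions"
  add("PPC", c(pep = -1, co2 = -1, oaa = 1), 0, B, ana, 1)
  add("ME1", c(mal = -1, pyr = 1, co2 = 1, nadph = 1), 0, 2, ana, 2)
  if (include_glyoxylate_shunt) {
    add("ICL", c(icit = -1, succ = 1, glx = 1), 0, B, ana, 1)
    add("MALS", c(glx = -1, accoa = -1, mal = 1), 0, B, ana, 2)
  }

  ## nitrogen assimilation sink from akg
  add("GLUDy", c(akg = -1, nh4 = -1, nadph = -1, glu = 1), 0, B,
      "Glutamate Metabolism", 1)
  add("DM_glu", c(glu = -1), 0, 10, "Glutamate Metabolism", 0, demand = TRUE)

  ## overflow acetate (lumped PTAr + ACKr + export cost; net yield 0.5 ATP)
  add("ACKr", c(accoa = -1, ac = 1, atp = 0.5), 0, B, "Pyruvate Metabolism", 2)

  ## energy metabolism
  oxp <- "Oxidative Phosphorylation"
  add("NADH16", c(nadh = -1, atp = 2), 0, B, oxp, 3)
  add("THD2", c(nadh = -1, atp = -2, nadph = 1), 0, B, oxp, 2)
  add("ATPM", c(atp = -1), atp_maintenance, B, oxp, 0, spont = TRUE)

  ## biomass
  bio_s <- -bw
  names(bio_s) <- names(bw)
  add("BIOMASS", bio_s, 0, B, "Biomass", 0, obj = 1)

  model <- metabolic_model("toy_central_carbon", mets, do.call(rbind, rx),
                           stoich)
  growth <- tryCatch(fba(model)$objective_value, error = function(e) -1)
  if (growth <= 0)
    stop_fluxpath("validation",
                  "toy network construction yielded a non-growing model")
  model
}

#' Simulate measured exchange and growth rates from a true flux state
#'
#' For each exchange reaction and the objective (biomass) reaction,
#' `n_replicates` multiplicative log-normal noise draws around the true flux
#' are summarized as mean and replicate SD, emulating growth/uptake/
#' secretion rate measurement.
#'
#' @param model the `metabolic_model` the truth refers to.
#' @param true_flux named flux vector (e.g. `fba(model)$values`).
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param n_replicates replicate cultures (default 3).
#' @param seed integer seed.
#' @param n_timepoints recorded number of steady-state time points.
#' @return A `rate_measurements` table with attribute `truth`.
#' @export
simulate_rates <- function(model, true_flux, cv = 0.05, n_replicates = 3L,
                           seed, n_timepoints = 4L) {
  if (cv < 0) stop_fluxpath("validation", "cv must be >= 0")
  ids <- model$reactions$id[model$reactions$is_exchange |
                              model$reactions$objective_coefficient != 0]
  truth <- true_flux[ids]
  sdlog <- sqrt(log(1 + cv^2))
  draws <- with_seed(seed, {
    matrix(truth, nrow = n_replicates, ncol = length(ids), byrow = TRUE) *
      matrix(exp(stats::rnorm(n_replicates * length(ids), -sdlog^2 / 2, sdlog)),
             n_replicates)
  })
  out <- rate_measurements(ids, colMeans(draws),
                           if (cv == 0) rep(0, length(ids))
                           else apply(draws, 2L, stats::sd),
                           n_timepoints)
  attr(out, "truth") <- truth
  out
}

#' Simulate MFA-style flux confidence intervals
#'
#' Draws a random subset (`coverage_frac`) of internal reactions and emits a
#' CI of `truth +/- rel_width * max(|truth|, floor)` for each, optionally
#' with conflicting intervals injected (shifted away from the truth) to
#' exercise [repair_constraints()].
#'
#' @param model the `metabolic_model`.
#' @param true_flux named flux vector.
#' @param rel_width relative half-width of each interval.
#' @param coverage_frac fraction of internal reactions covered (0, 1].
#' @param seed integer seed.
#' @param floor absolute half-width floor, flux units.
#' @param conflict_ids reaction ids for which a conflicting CI (displaced by
#'   `conflict_shift`) is emitted instead of a truthful one.
#' @param conflict_shift displacement of injected conflicts, flux units.
#' @return A `flux_ci` table with attribute `truth`.
#' @export
simulate_mfa_cis <- function(model, true_flux, rel_width = 0.1,
                             coverage_frac = 0.5, seed, floor = 0.1,
                             conflict_ids = character(),
                             conflict_shift = 5) {
  if (coverage_frac <= 0 || coverage_frac > 1)
    stop_fluxpath("validation", "coverage_frac must be in (0, 1]")
  internal <- model$reactions$id[!(model$reactions$is_exchange |
                                     model$reactions$is_demand |
                                     model$reactions$objective_coefficient != 0)]
  picked <- with_seed(seed, {
    k <- max(1L, round(coverage_frac * length(internal)))
    sort(sample(internal, k))
  })
  picked <- union(picked, conflict_ids)
  centre <- true_flux[picked]
  centre[picked %in% conflict_ids] <-
    centre[picked %in% conflict_ids] + conflict_shift
  half <- rel_width * pmax(abs(centre), floor)
  out <- flux_ci(picked, centre - half, centre + half)
  attr(out, "truth") <- true_flux[picked]
  out
}

#' Simulate a metabolite concentration table with planted effects
#'
#' Log-normal concentrations with a shared latent-factor correlation
#' structure, planted per-metabolite log2 group effects relative to the
#' first (reference) group, missing-completely-at-random entries, pooled QC
#' samples with a target RSD, and medium-blank samples at a configurable
#' fraction of the biological signal.
#'
#' @param n_metabolites number of metabolites.
#' @param groups character vector, one condition label per biological
#'   sample (e.g. `rep(c("ref", "ko"), each = 3)`); the first label is the
#'   reference.
#' @param effect_log2 named numeric vector (names in
#'   `met_1 .. met_n`) of log2 shifts applied to non-reference groups.
#' @param missing_rate MCAR missingness fraction among biological entries.
#' @param seed integer seed.
#' @param cv multiplicative noise CV of biological replicates.
#' @param factor_sd standard deviation (natural-log scale) of the shared
#'   per-sample latent factor inducing metabolite-metabolite correlation.
#' @param n_qc,n_blank number of QC and blank samples.
#' @param qc_rsd target QC-sample RSD, percent.
#' @param blank_level blank concentration as a fraction of the biological
#'   mean; a named vector can plant per-metabolite blank contamination.
#' @return A `concentration_table` with attribute `truth` (list of the
#'   noise-free group means and the planted effects).
#' @export
simulate_concentrations <- function(n_metabolites = 20L,
                                    groups = rep(c("ref", "ko"), each = 3L),
                                    effect_log2 = numeric(),
                                    missing_rate = 0,
                                    seed,
                                    cv = 0.1,
                                    factor_sd = 0.2,
                                    n_qc = 3L, n_blank = 2L,
                                    qc_rsd = 10,
                                    blank_level = 0.05) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop_fluxpath("validation", "missing_rate must be in [0, 1)")
  mets <- sprintf("met_%d", seq_len(n_metabolites))
  ref_group <- groups[1]
  with_seed(seed, {
    base <- 2^stats::runif(n_metabolites, 2, 10)     # abundances over ~2.5 decades
    load <- stats::runif(n_metabolites, 0.3, 1)      # latent-factor loadings
    eff <- stats::setNames(rep(0, n_metabolites), mets)
    eff[names(effect_log2)] <- effect_log2
    sdlog <- sqrt(log(1 + cv^2))
    nb <- length(groups)
    bio <- matrix(0, n_metabolites, nb, dimnames = list(mets, NULL))
    for (s in seq_len(nb)) {
      f <- stats::rnorm(1, 0, factor_sd)             # shared sample factor
      shift <- if (groups[s] == ref_group) 0 else eff
      bio[, s] <- base * 2^shift *
        exp(load * f + stats::rnorm(n_metabolites, -sdlog^2 / 2, sdlog))
    }
    pooled <- rowMeans(bio)
    qc_sd <- sqrt(log(1 + (qc_rsd / 100)^2))
    qc <- matrix(pooled, n_metabolites, n_qc) *
      matrix(exp(stats::rnorm(n_metabolites * n_qc, -qc_sd^2 / 2, qc_sd)),
             n_metabolites)
    if (is.null(names(blank_level))) {
      bl_lev <- rep_len(blank_level, n_metabolites)
    } else {
      bl_lev <- stats::setNames(rep(0.05, n_metabolites), mets)
      bl_lev[names(blank_level)] <- blank_level
    }
    blank <- matrix(pooled * bl_lev, n_metabolites, n_blank) *
      matrix(exp(stats::rnorm(n_metabolites * n_blank, 0, 0.05)),
             n_metabolites)
    vals <- cbind(bio, qc, blank)
    colnames(vals) <- c(sprintf("bio_%s_%d", groups, stats::ave(seq_len(nb),
                                                                groups, FUN = seq_along)),
                        sprintf("qc_%d", seq_len(n_qc)),
                        sprintf("blank_%d", seq_len(n_blank)))
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(n_metabolites * nb) < missing_rate,
                     n_metabolites, nb)
      vals[, seq_len(nb)][mask] <- NA
    }
    tab <- concentration_table(
      vals,
      sample_roles = c(rep("biological", nb), rep("qc", n_qc),
                       rep("blank_medium", n_blank)),
      groups = c(groups, rep(NA_character_, n_qc + n_blank)),
      lloq = pmin(base / 10, stats::quantile(base, 0.1)),
      biomass = 1)
    noise_free <- base * 2^outer(eff, as.numeric(groups != ref_group))
    dimnames(noise_free) <- list(mets, NULL)
    attr(tab, "truth") <- list(base = stats::setNames(base, mets),
                               effect_log2 = eff, groups = groups,
                               noise_free_bio = noise_free)
    tab
  })
}

#' Simulate a coverage track with planted duplications
#'
#' Poisson depths around `mean_depth`, with depths inside each planted
#' interval drawn at `dup_factor * mean_depth`.
#'
#' @param length track length, bp.
#' @param mean_depth background mean depth.
#' @param dup_intervals data.frame with `start`, `end` (1-based inclusive,
#'   non-overlapping, within the track).
#' @param seed integer seed.
#' @param dup_factor depth multiple inside duplications (default 2.4).
#' @return list with `depths`, `offset` (= 1) and `truth`
#'   (the planted intervals).
#' @export
simulate_coverage <- function(length, mean_depth,
                              dup_intervals = data.frame(start = integer(),
                                                         end = integer()),
                              seed, dup_factor = 2.4) {
  di <- dup_intervals[order(dup_intervals$start), , drop = FALSE]
  if (nrow(di)) {
    if (any(di$start < 1 | di$end > length | di$start > di$end))
      stop_fluxpath("validation", "dup_intervals must lie within the track")
    if (nrow(di) > 1L && any(di$start[-1] <= di$end[-nrow(di)]))
      stop_fluxpath("validation", "dup_intervals must not overlap")
  }
  depths <- with_seed(seed, {
    d <- stats::rpois(length, mean_depth)
    for (k in seq_len(nrow(di)))
      d[di$start[k]:di$end[k]] <- stats::rpois(di$end[k] - di$start[k] + 1L,
                                               dup_factor * mean_depth)
    d
  })
  list(depths = depths, offset = 1L, truth = di)
}
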