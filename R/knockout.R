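# Ranking candidate reaction deletions: averaged sampled flux, measurable
# neighbors, gene count, with an exclusion screen for loops, spontaneous,
# essential, unexpressed and multi-gene reactions.

#' Count measurable metabolite neighbors of a reaction
#'
#' The number of distinct metabolites participating in the reaction (nonzero
#' stoichiometric coefficient) whose `measurable` flag is TRUE, i.e. the
#' immediate upstream and downstream metabolites that could be quantified to
#' characterize the knockout.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id single reaction id.
#' @return Integer count.
#' @export
count_measurable_neighbors <- function(model, reaction_id) {
  reaction_index(model, reaction_id)
  s <- model$stoichiometry[[reaction_id]]
  mets <- unique(names(s)[s != 0])
  sum(model$metabolites$measurable[match(mets, model$metabolites$id)])
}

#' Screen reactions for knockout-exclusion reasons
#'
#' Maps every reaction to its (possibly empty) set of exclusion reasons:
#' `loop` (nonzero flux-variability range with exchanges closed, see
#' [find_loop_reactions()]), `spontaneous`, `essential_computational`
#' (knockout FBA objective below `essential_fraction` of wild type, or
#' infeasible), `essential_experimental` and `not_expressed`
#' (caller-provided), and `multi_gene` (`gene_count > 1`).
#'
#' @param model a `metabolic_model`.
#' @param expressed_ids reactions actively expressed under the growth
#'   condition; `NULL` (default) treats all reactions as expressed.
#' @param essential_ids reactions known experimentally essential.
#' @param essential_fraction knockout growth below this fraction of the
#'   wild-type optimum counts as computationally essential (default 0.01).
#' @return Named list: reaction id -> character vector of reasons.
#' @export
exclusion_screen <- function(model, expressed_ids = NULL,
                             essential_ids = character(),
                             essential_fraction = 0.01) {
  rxn <- model$reactions
  loops <- find_loop_reactions(model)
  wt <- fba(model)$objective_value
  reasons <- stats::setNames(vector("list", nrow(rxn)), rxn$id)
  for (i in seq_len(nrow(rxn))) {
    rid <- rxn$id[i]
    r <- character()
    if (rid %in% loops) r <- c(r, "loop")
    if (rxn$is_spontaneous[i]) r <- c(r, "spontaneous")
    if (rxn$gene_count[i] > 1L) r <- c(r, "multi_gene")
    if (rid %in% essential_ids) r <- c(r, "essential_experimental")
    if (!is.null(expressed_ids) && !(rid %in% expressed_ids))
      r <- c(r, "not_expressed")
    ko_growth <- tryCatch(fba(apply_knockout(model, rid))$objective_value,
                          fluxpath_infeasible_error = function(e) 0)
    if (ko_growth < essential_fraction * wt)
      r <- c(r, "essential_computational")
    reasons[[rid]] <- r
  }
  reasons
}

#' Rank reaction-knockout candidates
#'
#' Candidate reactions (enzymatic reactions: not exchange, demand or
#' objective pseudo-reactions) that pass the exclusion screen are sorted
#' lexicographically by (1) averaged sampled flux, descending, (2) number of
#' measurable neighbor metabolites, descending, (3) gene count, ascending,
#' with remaining ties broken by reaction id; the top `top_n` (default 9)
#' are returned with ranks.
#'
#' @param model a `metabolic_model`.
#' @param sample a `flux_sample` drawn from the (constrained) model.
#' @param expressed_ids,essential_ids,essential_fraction passed to
#'   [exclusion_screen()].
#' @param top_n number of ranked candidates to return.
#' @param signed_flux if TRUE the signed mean sampled flux is used instead
#'   of the mean absolute flux.
#' @return data.frame (`knockout_candidates`) with columns `reaction_id`,
#'   `avg_sampled_flux`, `measurable_neighbors`, `gene_count`, `excluded`,
#'   `exclusion_reasons` (';'-joined), `rank` (NA for excluded rows).
#'   Ranked candidates first, then excluded candidates.
#' @export
rank_candidates <- function(model, sample, expressed_ids = NULL,
                            essential_ids = character(), top_n = 9L,
                            essential_fraction = 0.01,
                            signed_flux = FALSE) {
  if (top_n < 1L) stop_fluxpath("validation", "top_n must be >= 1")
  check_sample_model(model, sample)
  rxn <- model$reactions
  genetic <- !(rxn$is_exchange | rxn$is_demand |
                 rxn$objective_coefficient != 0)
  reasons <- exclusion_screen(model, expressed_ids, essential_ids,
                              essential_fraction)
  ids <- rxn$id[genetic]
  avg <- if (signed_flux) colMeans(sample$points[, ids, drop = FALSE])
  else colMeans(abs(sample$points[, ids, drop = FALSE]))
  out <- data.frame(
    reaction_id = ids,
    avg_sampled_flux = as.numeric(avg),
    measurable_neighbors = vapply(ids, count_measurable_neighbors,
                                  integer(1), model = model),
    gene_count = rxn$gene_count[genetic],
    excluded = vapply(ids, function(r) length(reasons[[r]]) > 0L, logical(1)),
    exclusion_reasons = vapply(ids, function(r)
      paste(sort(reasons[[r]]), collapse = ";"), character(1)),
    rank = NA_integer_, stringsAsFactors = FALSE, row.names = NULL)
  cand <- out[!out$excluded, , drop = FALSE]
  ord <- order(-cand$avg_sampled_flux, -cand$measurable_neighbors,
               cand$gene_count, cand$reaction_id)
  cand <- cand[ord, , drop = FALSE]
  k <- min(top_n, nrow(cand))
  if (k > 0L) cand$rank[seq_len(k)] <- seq_len(k)
  cand <- cand[seq_len(k), , drop = FALSE]
  rest <- out[out$excluded, , drop = FALSE]
  rest <- rest[order(rest$reaction_id), , drop = FALSE]
  res <- rbind(cand, rest)
  rownames(res) <- NULL
  class(res) <- c("knockout_candidates", "data.frame")
  res
}

#' Write a knockout-candidate report as TSV
#'
#' @param candidates output of [rank_candidates()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
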