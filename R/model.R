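#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` couples a metabolite table, a reaction table and the
#' sparse stoichiometry linking them. Fluxes are in mmol per gram dry cell
#' weight per hour (mmol gDCW^-1 h^-1); the biomass/objective reaction is in
#' h^-1. Exchange reactions use the convention that uptake is negative and
#' secretion positive.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `measurable` (logical: is the metabolite on the quantifiable-metabolite
#'   list used for knockout ranking).
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `subsystem`, `gene_count` (number of genetic alterations
#'   needed to abolish activity), `is_spontaneous`, `is_demand`,
#'   `is_exchange`, `objective_coefficient`.
#' @param stoichiometry named list, one element per reaction id, each a named
#'   numeric vector of signed coefficients keyed by metabolite id (negative =
#'   consumed, positive = produced).
#' @param compartments character vector of compartment labels; defaults to
#'   the labels present in `metabolites`.
#' @param annotations free-form list preserved through JSON round-trips.
#'
#' @return An object of class `metabolic_model`.
#' @seealso [read_model()], [write_model()], [fba()], [build_toy_network()]
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            compartments = unique(metabolites$compartment),
                            annotations = list()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  model <- structure(
    list(id = as.character(id),
         metabolites = metabolites,
         reactions = reactions,
         stoichiometry = stoichiometry,
         compartments = as.character(compartments),
         annotations = annotations),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique ids, compartments drawn from the
#' declared set, `lower_bound <= upper_bound`, every stoichiometry key
#' resolving to a metabolite, and exchange reactions touching exactly one
#' metabolite. All violations are collected and reported together.
#'
#' @param model a `metabolic_model`.
#' @return `model`, invisibly, if valid; otherwise an error of class
#'   `fluxpath_validation_error` listing every violation.
#' @export
validate_model <- function(model) {
  problems <- character()
  met <- model$metabolites
  rxn <- model$reactions
  met_cols <- c("id", "name", "compartment", "measurable")
  rxn_cols <- c("id", "lower_bound", "upper_bound", "subsystem", "gene_count",
                "is_spontaneous", "is_demand", "is_exchange",
                "objective_coefficient")
  if (!all(met_cols %in% names(met)))
    problems <- c(problems, paste0("metabolite table missing columns: ",
                                   paste(setdiff(met_cols, names(met)), collapse = ", ")))
  if (!all(rxn_cols %in% names(rxn)))
    problems <- c(problems, paste0("reaction table missing columns: ",
                                   paste(setdiff(rxn_cols, names(rxn)), collapse = ", ")))
  if (length(problems) == 0L) {
    if (nrow(rxn) == 0L)
      problems <- c(problems, "model has no reactions")
    if (anyDuplicated(met$id))
      problems <- c(problems, paste0("duplicated metabolite ids: ",
                                     paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
    if (anyDuplicated(rxn$id))
      problems <- c(problems, paste0("duplicated reaction ids: ",
                                     paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
    bad_cmp <- setdiff(met$compartment, model$compartments)
    if (length(bad_cmp))
      problems <- c(problems, paste0("undeclared compartments: ",
                                     paste(bad_cmp, collapse = ", ")))
    bad_bnd <- rxn$id[rxn$lower_bound > rxn$upper_bound]
    if (length(bad_bnd))
      problems <- c(problems, paste0("lower_bound > upper_bound for reaction(s): ",
                                     paste(bad_bnd, collapse = ", ")))
    if (any(rxn$gene_count < 0))
      problems <- c(problems, "negative gene_count")
    missing_stoich <- setdiff(rxn$id, names(model$stoichiometry))
    if (length(missing_stoich))
      problems <- c(problems, paste0("reactions without stoichiometry entry: ",
                                     paste(missing_stoich, collapse = ", ")))
    for (rid in intersect(rxn$id, names(model$stoichiometry))) {
      s <- model$stoichiometry[[rid]]
      unknown <- setdiff(names(s), met$id)
      if (length(unknown))
        problems <- c(problems, paste0("reaction ", rid,
                                       " references unknown metabolite(s): ",
                                       paste(unknown, collapse = ", ")))
    }
    is_ex <- rxn$is_exchange
    for (rid in rxn$id[is_ex]) {
      s <- model$stoichiometry[[rid]]
      if (!is.null(s) && sum(s != 0) != 1L)
        problems <- c(problems, paste0("exchange reaction ", rid,
                                       " must touch exactly one metabolite"))
    }
  }
  if (length(problems))
    stop_fluxpath("validation", paste0("invalid model '", model$id, "':\n  - ",
                                       paste(problems, collapse = "\n  - ")))
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return A dense numeric matrix S with one row per metabolite and one
#'   column per reaction, dimnames set to the respective ids.
#' @export
stoichiometric_matrix <- function(model) {
  m <- nrow(model$metabolites)
  n <- nrow(model$reactions)
  S <- matrix(0, m, n, dimnames = list(model$metabolites$id, model$reactions$id))
  for (rid in model$reactions$id) {
    s <- model$stoichiometry[[rid]]
    if (length(s)) S[names(s), rid] <- as.numeric(s)
  }
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model '", x$id, "': ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ", length(x$compartments),
      " compartments\n", sep = "")
  obj <- x$reactions$id[x$reactions$objective_coefficient != 0]
  if (length(obj)) cat("objective:", paste(obj, collapse = ", "), "\n")
  invisible(x)
}

reaction_index <- function(model, reaction_ids) {
  idx <- match(reaction_ids, model$reactions$id)
  if (anyNA(idx))
    stop_fluxpath("lookup", paste0("unknown reaction id(s): ",
                                   paste(reaction_ids[is.na(idx)], collapse = ", ")))
  idx
}

#' Read a metabolic model from file
#'
#' JSON is the native dialect (see Details); SBML level-3 files with the
#' `fbc` package are imported on a best-effort basis (gene associations are
#' reduced to a gene count; unrecognized constructs are dropped).
#'
#' @details The JSON dialect has top-level keys `id`, `compartments`,
#' `metabolites` (array of objects with `id`, `name`, `compartment`,
#' `measurable`) and `reactions` (array of objects with `id`,
#' `stoichiometry` mapping metabolite id to signed coefficient,
#' `lower_bound`, `upper_bound`, `subsystem`, `gene_count`,
#' `is_spontaneous`, `is_demand`, `is_exchange`, `objective_coefficient`).
#' Unknown top-level keys are preserved in `annotations`.
#'
#' @param path file to read.
#' @param format `"json"` (default) or `"sbml"`.
#' @return A validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_fluxpath("io", paste0("file not found: ", path))
  if (format == "sbml") return(read_sbml_model(path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_fluxpath("format", paste0("JSON parse failure in ", path,
                                                   ": ", conditionMessage(e))))
  required <- c("id", "metabolites", "reactions")
  miss <- setdiff(required, names(doc))
  if (length(miss))
    stop_fluxpath("format", paste0("model JSON missing element(s): ",
                                   paste(miss, collapse = ", ")))
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c",
               measurable = isTRUE(m$measurable), stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(id = r$id,
               lower_bound = as.numeric(r$lower_bound),
               upper_bound = as.numeric(r$upper_bound),
               subsystem = r$subsystem %||% "Unassigned",
               gene_count = as.integer(r$gene_count %||% 0L),
               is_spontaneous = isTRUE(r$is_spontaneous),
               is_demand = isTRUE(r$is_demand),
               is_exchange = isTRUE(r$is_exchange),
               objective_coefficient = as.numeric(r$objective_coefficient %||% 0),
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(doc$reactions, function(r) {
    s <- unlist(r$stoichiometry)
    if (is.null(s)) s <- numeric()
    s
  })
  names(stoich) <- rxns$id
  cmp <- unlist(doc$compartments) %||% unique(mets$compartment)
  extra <- doc[setdiff(names(doc), c(required, "compartments"))]
  metabolic_model(doc$id, mets, rxns, stoich, compartments = cmp,
                  annotations = extra)
}

#' Write a metabolic model to the JSON dialect
#'
#' The output is re-readable by [read_model()] with full equality on all
#' fields (round-trip identity).
#'
#' @param model a valid `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment,
         measurable = m$measurable)
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    s <- model$stoichiometry[[r$id]]
    list(id = r$id,
         stoichiometry = if (length(s)) as.list(s) else structure(list(), names = character()),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         subsystem = r$subsystem, gene_count = r$gene_count,
         is_spontaneous = r$is_spontaneous, is_demand = r$is_demand,
         is_exchange = r$is_exchange,
         objective_coefficient = r$objective_coefficient)
  })
  doc <- c(list(id = model$id, compartments = as.list(model$compartments),
                metabolites = mets, reactions = rxns),
           model$annotations)
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop_fluxpath("io", paste0("cannot write model to ", path, ": ",
                               conditionMessage(ok)))
  invisible(path)
}

# Minimal SBML L3 FBC importer: species/reactions/bounds via fbc attributes or
# referenced parameters; geneProductAssociation reduced to a count of distinct
# gene products; everything else dropped.
read_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop_fluxpath("format", paste0("SBML parse failure in ", path,
                                                   ": ", conditionMessage(e))))
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing"))
    stop_fluxpath("format", "SBML file has no <model> element")
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    measurable = FALSE, stringsAsFactors = FALSE)
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx) == 0L)
    stop_fluxpath("format", "SBML model has no reactions")
  bound_of <- function(node, attr, default) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) return(default)
    if (v %in% names(pval)) return(pval[[v]])
    suppressWarnings(num <- as.numeric(v))
    if (is.na(num)) default else num
  }
  stoich <- list(); rows <- vector("list", length(rx))
  for (k in seq_along(rx)) {
    node <- rx[[k]]
    rid <- xml2::xml_attr(node, "id")
    s <- numeric()
    for (ref in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      sid <- xml2::xml_attr(ref, "species")
      s[sid] <- (s[sid] %||% 0) - as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% "1")
    }
    for (ref in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      sid <- xml2::xml_attr(ref, "species")
      s[sid] <- (s[sid] %||% 0) + as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% "1")
    }
    s <- s[!(names(s) %in% mets$id[boundary])]
    rev <- xml2::xml_attr(node, "reversible") %in% c("true", "1")
    lb <- bound_of(node, "lowerFluxBound", if (rev) -1000 else 0)
    ub <- bound_of(node, "upperFluxBound", 1000)
    gps <- xml2::xml_find_all(node, ".//*[local-name()='geneProductRef']")
    stoich[[rid]] <- s
    rows[[k]] <- data.frame(
      id = rid, lower_bound = lb, upper_bound = ub,
      subsystem = "Unassigned",
      gene_count = length(unique(xml2::xml_attr(gps, "geneProduct"))),
      is_spontaneous = FALSE, is_demand = FALSE,
      is_exchange = sum(s != 0) == 1L && grepl("^EX_|^R_EX_", rid),
      objective_coefficient = 0, stringsAsFactors = FALSE)
  }
  rxns <- do.call(rbind, rows)
  fluxobj <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  for (fo in fluxobj) {
    rid <- xml2::xml_attr(fo, "reaction")
    if (rid %in% rxns$id)
      rxns$objective_coefficient[rxns$id == rid] <-
        as.numeric(xml2::xml_attr(fo, "coefficient") %||% "1")
  }
  used <- unique(unlist(lapply(stoich, names)))
  mets <- mets[mets$id %in% used, , drop = FALSE]
  metabolic_model(xml2::xml_attr(mdl, "id") %||% "sbml_model", mets, rxns,
                  stoich)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

stop_fluxpath <- function(kind, message) {
  stop(structure(class = c(paste0("fluxpath_", kind, "_error"),
                           "fluxpath_error", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}
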