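#' Construct an empty metabolic model
#'
#' A metabolic model holds reactions (stoichiometry, flux bounds, flat-OR gene
#' associations, provenance), an objective reaction, and derives metabolites
#' and the stoichiometric matrix on demand. Single compartment; substrates
#' carry negative coefficients, products positive; reversible reactions
#' default to bounds (-1000, 1000) and irreversible to (0, 1000).
#'
#' @param id model identifier.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id = "model") {
  structure(list(id = id, reactions = list(), objective = NULL),
            class = "metabolic_model")
}

#' Add a reaction to a model
#'
#' @param model a `metabolic_model`.
#' @param id reaction id (must be new).
#' @param stoichiometry named numeric, metabolite -> signed coefficient.
#' @param lower,upper flux bounds.
#' @param genes character vector of supporting genes/proteins (OR semantics).
#' @param ecs EC numbers associated with the reaction.
#' @param provenance one of `"ec_high_conf"`, `"spontaneous"`, `"user"`,
#'   `"similarity"`, `"gapfill"`, `"exchange"`.
#' @param penalty gap-fill penalty paid for the reaction, if any.
#' @param name human-readable name.
#' @return the updated model.
#' @export
add_reaction <- function(model, id, stoichiometry, lower = 0, upper = 1000,
                         genes = character(), ecs = character(),
                         provenance = "user", penalty = NA_real_,
                         name = id) {
  if (id %in% names(model$reactions)) stop("duplicate reaction id: ", id)
  if (!length(stoichiometry) || any(stoichiometry == 0))
    stop("reaction ", id, ": stoichiometry must be nonempty with nonzero coefficients")
  if (lower > upper) stop("reaction ", id, ": lower bound exceeds upper bound")
  model$reactions[[id]] <- list(
    id = id, name = name, stoichiometry = stoichiometry,
    lower = as.numeric(lower), upper = as.numeric(upper),
    genes = unique(genes), ecs = unique(ecs), provenance = provenance,
    penalty = penalty)
  model
}

#' Metabolites of a model
#' @param model a `metabolic_model`.
#' @return sorted character vector of metabolite ids.
#' @export
metabolites <- function(model) {
  sort(unique(unlist(lapply(model$reactions, function(r)
    names(r$stoichiometry)))))
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- metabolites(model)
  rxns <- names(model$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in model$reactions)
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  S
}

#' Flux bounds of a model
#' @param model a `metabolic_model`.
#' @return list with numeric vectors `lower`, `upper` named by reaction.
#' @export
flux_bounds <- function(model) {
  list(lower = vapply(model$reactions, `[[`, 0, "lower"),
       upper = vapply(model$reactions, `[[`, 0, "upper"))
}

#' Set the objective reaction
#' @param model a `metabolic_model`.
#' @param reaction_id id of an existing reaction.
#' @return the updated model.
#' @export
set_objective <- function(model, reaction_id) {
  if (!reaction_id %in% names(model$reactions))
    stop("objective reaction not in model: ", reaction_id)
  model$objective <- reaction_id
  model
}

#' Read user-specified reactions (including the biomass objective)
#'
#' TSV with header and columns `id`, `equation`, optional `lower`, `upper`,
#' and `objective` (TRUE for exactly one row, the biomass/objective
#' pseudo-reaction).
#'
#' @param path TSV path.
#' @return data.frame of user reactions.
#' @export
read_user_reactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "equation") %in% names(df)))
  if (!"objective" %in% names(df)) df$objective <- FALSE
  df$objective <- as.logical(df$objective)
  df
}

#' Read a media definition
#'
#' TSV with columns `exchange_id`, `max_uptake` (mmol/gDW/h, nonnegative).
#'
#' @param path TSV path.
#' @param aerobic logical flag stored on the result.
#' @return object of class `media`: named uptake vector + `aerobic` attribute.
#' @export
read_media <- function(path, aerobic = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("exchange_id", "max_uptake") %in% names(df)))
  media_definition(stats::setNames(df$max_uptake, df$exchange_id), aerobic)
}

#' Define a growth medium
#' @param uptake named numeric vector: exchange reaction id -> maximum uptake
#'   rate (mmol/gDW/h, nonnegative).
#' @param aerobic logical.
#' @return object of class `media`.
#' @export
media_definition <- function(uptake, aerobic = TRUE) {
  stopifnot(all(uptake >= 0))
  structure(uptake, aerobic = aerobic, class = "media")
}

#' Assemble the high-confidence draft model
#'
#' Collates (i) every database reaction linked to a high-confidence EC
#' (indiscriminate inclusion of multi-reaction ECs), (ii) spontaneous
#' reactions when requested, (iii) user reactions including the designated
#' objective, and (iv) sequence-similarity-supported non-EC reactions
#' (BiGG-like databases only; ignored with a warning otherwise). Gene
#' associations are the union of the proteins supporting each reaction
#' (flat OR). Duplicate inclusion routes merge on reaction id with
#' concatenated provenance.
#'
#' @param high_conf data.frame (`protein_id`, `ec`) of high-confidence
#'   annotations, e.g. from [select_high_confidence()].
#' @param db a `reaction_db`.
#' @param user_reactions data.frame from [read_user_reactions()]; exactly one
#'   row must have `objective = TRUE`.
#' @param similarity_reactions named list reaction id -> supporting genes,
#'   from [filter_similarity_hits()].
#' @param include_spontaneous include spontaneous database reactions.
#' @return a `metabolic_model`; uncovered ECs are attached as attribute
#'   `uncovered_ecs`.
#' @export
assemble_draft <- function(high_conf, db, user_reactions,
                           similarity_reactions = NULL,
                           include_spontaneous = TRUE) {
  if (sum(user_reactions$objective) != 1)
    stop("exactly one user reaction must be designated as the objective")
  model <- metabolic_model()
  sel <- reactions_for_ecs(db, unique(high_conf$ec))

  gene_of_ec <- split(high_conf$protein_id, high_conf$ec)
  prov <- list()
  add_db_reaction <- function(model, rid, tag, genes = character()) {
    r <- db$reactions[[rid]]
    if (rid %in% names(model$reactions)) {
      model$reactions[[rid]]$genes <-
        unique(c(model$reactions[[rid]]$genes, genes))
      model$reactions[[rid]]$provenance <-
        paste(unique(c(strsplit(model$reactions[[rid]]$provenance,
                                ";")[[1]], tag)), collapse = ";")
      return(model)
    }
    add_reaction(model, rid, r$stoichiometry, r$bounds[1], r$bounds[2],
                 genes = genes, ecs = r$ecs, provenance = tag)
  }

  for (rid in sel$reaction_ids) {
    genes <- unique(unlist(gene_of_ec[db$reactions[[rid]]$ecs]))
    model <- add_db_reaction(model, rid, "ec_high_conf",
                             genes = genes %||% character())
  }
  if (include_spontaneous) {
    spont <- names(Filter(function(r) r$spontaneous, db$reactions))
    for (rid in spont) model <- add_db_reaction(model, rid, "spontaneous")
  }
  if (!is.null(similarity_reactions) && length(similarity_reactions)) {
    if (db$dialect != "bigg_like") {
      warning("similarity-supported reactions ignored: only included for ",
              "bigg_like reaction databases")
    } else {
      for (rid in names(similarity_reactions))
        model <- add_db_reaction(model, rid, "similarity",
                                 genes = similarity_reactions[[rid]])
    }
  }
  for (i in seq_len(nrow(user_reactions))) {
    u <- user_reactions[i, ]
    eq <- parse_equation(u$equation)
    lo <- if ("lower" %in% names(u) && !is.na(u$lower)) u$lower
          else if (eq$reversible) -1000 else 0
    hi <- if ("upper" %in% names(u) && !is.na(u$upper)) u$upper else 1000
    model <- add_reaction(model, u$id, eq$stoichiometry, lo, hi,
                          provenance = "user")
    if (u$objective) model <- set_objective(model, u$id)
  }

  obj_mets <- names(model$reactions[[model$objective]]$stoichiometry)
  reachable <- metabolites(model)
  others <- setdiff(reachable, obj_mets)
  produced_elsewhere <- any(vapply(model$reactions, function(r)
    r$id != model$objective && any(names(r$stoichiometry) %in% obj_mets),
    logical(1)))
  if (!produced_elsewhere)
    warning("no model reaction touches any objective metabolite; ",
            "gap-filling will be required")
  attr(model, "uncovered_ecs") <- sel$uncovered_ecs
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, ": ", length(x$reactions), " reactions, ",
      length(metabolites(x)), " metabolites, objective = ",
      x$objective %||% "<none>", "\n", sep = "")
  invisible(x)
}
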