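apply_media <- function(model, media) {
  if (is.null(media)) return(model)
  for (ex in names(media)) {
    if (!ex %in% names(model$reactions))
      stop("media exchange not in model: ", ex)
    model$reactions[[ex]]$lower <- -abs(unname(media[[ex]]))
  }
  model
}

#' Flux balance analysis
#'
#' Maximizes the flux through the objective reaction subject to steady state
#' (Sv = 0) and flux bounds. Media uptake rates override the lower bounds of
#' the named exchange reactions (uptake is negative flux through an exchange).
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction to optimize; defaults to the model objective.
#' @param media optional [media_definition()].
#' @param tol values below this reported as 0.
#' @return list `status` ("optimal" or "infeasible"), `objective`, `fluxes`
#'   (named vector).
#' @export
fba <- function(model, objective_id = NULL, media = NULL, tol = 1e-9) {
  objective_id <- objective_id %||% model$objective
  if (is.null(objective_id) || !objective_id %in% names(model$reactions))
    stop("objective reaction not in model: ", objective_id %||% "<none>")
  model <- apply_media(model, media)
  S <- stoichiometric_matrix(model)
  b <- flux_bounds(model)
  obj <- as.numeric(colnames(S) == objective_id)
  res <- solve_lp(obj, A_eq = S, b_eq = rep(0, nrow(S)),
                  lower = b$lower[colnames(S)], upper = b$upper[colnames(S)],
                  maximize = TRUE)
  if (!identical(res$status, "optimal"))
    return(list(status = res$status, objective = NA_real_, fluxes = NULL))
  val <- res$objective
  if (abs(val) < tol) val <- 0
  list(status = "optimal", objective = val,
       fluxes = stats::setNames(res$solution, colnames(S)))
}

#' Single-gene knockout screen
#'
#' Because gene associations are flat OR sets (no complex gene-protein-
#' reaction rules), only reactions associated with exactly one gene can be
#' switched off by a knockout. For each gene, every reaction whose
#' association set is exactly that gene is constrained to zero flux; the gene
#' is essential when maximal objective flux falls below the growth threshold.
#' Genes appearing only in multi-gene reactions are untestable.
#'
#' @param model a `metabolic_model` with gene associations.
#' @param media optional [media_definition()].
#' @param growth_threshold minimum objective flux counted as growth
#'   (default 1e-4 1/h, the phenotype-array growth call).
#' @return data.frame `gene`, `call` (`essential`, `non-essential`,
#'   `untestable`), `objective`.
#' @export
single_gene_knockouts <- function(model, media = NULL,
                                  growth_threshold = 1e-4) {
  model <- apply_media(model, media)
  genes <- sort(unique(unlist(lapply(model$reactions, `[[`, "genes"))))
  out <- list()
  for (g in genes) {
    solo <- names(Filter(function(r) identical(r$genes, g), model$reactions))
    if (!length(solo)) {
      out[[g]] <- data.frame(gene = g, call = "untestable",
                             objective = NA_real_, stringsAsFactors = FALSE)
      next
    }
    ko <- model
    for (rid in solo) {
      ko$reactions[[rid]]$lower <- 0
      ko$reactions[[rid]]$upper <- 0
    }
    res <- fba(ko)
    obj <- if (identical(res$status, "optimal")) res$objective else 0
    out[[g]] <- data.frame(
      gene = g,
      call = if (obj < growth_threshold) "essential" else "non-essential",
      objective = obj, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out) %||%
    data.frame(gene = character(), call = character(), objective = numeric())
  rownames(res) <- NULL
  res
}

#' Phenotype (nutrient-source) array simulation
#'
#' For each swap the default source's uptake is blocked and the alternate
#' source's uptake enabled at 10 mmol/gDW/h; growth is called positive when
#' maximal objective flux is at least 1e-4 1/h (inclusive). Swaps whose
#' alternate exchange is missing from the model are recorded untestable.
#'
#' @param model a `metabolic_model`.
#' @param base_media [media_definition()] applied before each swap.
#' @param swaps data.frame with columns `element`, `default_exchange`,
#'   `alternate_exchange`.
#' @param alternate_bound uptake bound for the alternate source (default 10).
#' @param growth_threshold growth call threshold (default 1e-4).
#' @return data.frame `element`, `alternate_exchange`, `growth`
#'   (`positive`, `negative`, `untestable`), `objective`.
#' @export
phenotype_array <- function(model, base_media, swaps, alternate_bound = 10,
                            growth_threshold = 1e-4) {
  model <- apply_media(model, base_media)
  out <- list()
  for (i in seq_len(nrow(swaps))) {
    sw <- swaps[i, ]
    if (!sw$alternate_exchange %in% names(model$reactions)) {
      out[[i]] <- data.frame(element = sw$element,
                             alternate_exchange = sw$alternate_exchange,
                             growth = "untestable", objective = NA_real_,
                             stringsAsFactors = FALSE)
      next
    }
    m <- model
    if (sw$default_exchange %in% names(m$reactions))
      m$reactions[[sw$default_exchange]]$lower <- 0
    m$reactions[[sw$alternate_exchange]]$lower <- -alternate_bound
    res <- fba(m)
    obj <- if (identical(res$status, "optimal")) res$objective else 0
    out[[i]] <- data.frame(
      element = sw$element, alternate_exchange = sw$alternate_exchange,
      growth = if (obj >= growth_threshold - 1e-9) "positive" else "negative",
      objective = obj, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Biomass or ATP yield per mmol of substrate
#'
#' Fixes substrate uptake at 1 mmol/gDW/h (and oxygen uptake at zero under
#' anaerobic conditions), then maximizes either the biomass objective or an
#' ATP hydrolysis reaction (ATP + H2O -> ADP + phosphate + proton). A
#' zero-substrate control run is always reported: any positive objective with
#' no substrate flags a thermodynamically unrealistic energy-generating
#' cycle (the sentinel).
#'
#' @param model a `metabolic_model`.
#' @param carbon_exchange exchange reaction id of the carbon source.
#' @param aerobic logical; when FALSE oxygen uptake is constrained to zero.
#' @param objective `"biomass"` or `"atp_hydrolysis"`.
#' @param oxygen_exchange exchange id of oxygen (needed when `aerobic=FALSE`
#'   and present in the model).
#' @param atp_reaction_id id of the ATP hydrolysis reaction; if absent and
#'   `atp_stoichiometry` is supplied, a transient hydrolysis reaction is
#'   added for the solve.
#' @param atp_stoichiometry named stoichiometry for a transient hydrolysis
#'   reaction (e.g. `c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1)`).
#' @param sentinel_tol objective values above this in the control run fire
#'   the energy-cycle sentinel.
#' @return list `yield`, `control` (zero-substrate objective),
#'   `energy_cycle_sentinel` (logical), `status`.
#' @export
yield_analysis <- function(model, carbon_exchange, aerobic = TRUE,
                           objective = c("biomass", "atp_hydrolysis"),
                           oxygen_exchange = NULL, atp_reaction_id = NULL,
                           atp_stoichiometry = NULL, sentinel_tol = 1e-6) {
  objective <- match.arg(objective)
  if (!carbon_exchange %in% names(model$reactions))
    stop("carbon exchange not in model: ", carbon_exchange)
  if (!aerobic && !is.null(oxygen_exchange) &&
      oxygen_exchange %in% names(model$reactions)) {
    model$reactions[[oxygen_exchange]]$lower <- 0
  }
  obj_id <- model$objective
  if (objective == "atp_hydrolysis") {
    if (!is.null(atp_reaction_id) &&
        atp_reaction_id %in% names(model$reactions)) {
      obj_id <- atp_reaction_id
    } else if (!is.null(atp_stoichiometry)) {
      model <- add_reaction(model, "ATPHYDR", atp_stoichiometry, 0, 1000,
                            provenance = "user", name = "ATP hydrolysis")
      obj_id <- "ATPHYDR"
    } else stop("ATP hydrolysis reaction not found and no stoichiometry given")
  }
  run <- function(uptake) {
    m <- model
    m$reactions[[carbon_exchange]]$lower <- -uptake
    m$reactions[[carbon_exchange]]$upper <- 0
    fba(m, objective_id = obj_id)
  }
  main <- run(1)
  ctrl <- run(0)
  ctrl_obj <- if (identical(ctrl$status, "optimal")) ctrl$objective else 0
  list(yield = if (identical(main$status, "optimal")) main$objective
       else NA_real_,
       control = ctrl_obj,
       energy_cycle_sentinel = ctrl_obj > sentinel_tol,
       status = main$status)
}

#' Blocked-reaction statistics
#'
#' A reaction is blocked when its flux is zero in every feasible steady
#' state; computed by per-reaction flux-variability (max |v|) under the
#' model's bounds. Reported as a diagnostic, not optimized against.
#'
#' @param model a `metabolic_model`.
#' @param tol fluxes with max |v| below this count as blocked.
#' @return data.frame `reaction_id`, `max_abs_flux`, `blocked`.
#' @export
blocked_reactions <- function(model, tol = 1e-9) {
  S <- stoichiometric_matrix(model)
  b <- flux_bounds(model)
  lo <- b$lower[colnames(S)]; hi <- b$upper[colnames(S)]
  out <- vapply(seq_len(ncol(S)), function(j) {
    obj <- as.numeric(seq_len(ncol(S)) == j)
    up <- solve_lp(obj, A_eq = S, b_eq = rep(0, nrow(S)), lower = lo,
                   upper = hi, maximize = TRUE)
    dn <- solve_lp(obj, A_eq = S, b_eq = rep(0, nrow(S)), lower = lo,
                   upper = hi, maximize = FALSE)
    max(abs(c(if (identical(up$status, "optimal")) up$objective else 0,
              if (identical(dn$status, "optimal")) dn$objective else 0)))
  }, 0)
  data.frame(reaction_id = colnames(S), max_abs_flux = out,
             blocked = out < tol, row.names = NULL, stringsAsFactors = FALSE)
}
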