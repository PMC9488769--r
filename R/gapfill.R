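#' Detect dead-end metabolites
#'
#' A metabolite is a dead end when, accounting for reaction reversibility and
#' flux bounds, it can never be produced or never be consumed by any reaction
#' in the network. Dead ends block all flux through the reactions touching
#' them and can prevent biomass production.
#'
#' @param model a `metabolic_model`.
#' @param extra_reactions optional named list of additional reactions (same
#'   structure as model reactions) considered part of the network, e.g. the
#'   gap-filling candidate pool.
#' @return data.frame `metabolite`, `producible`, `consumable` for the dead
#'   ends only.
#' @export
find_dead_end_metabolites <- function(model, extra_reactions = NULL) {
  rxns <- c(model$reactions, extra_reactions %||% list())
  mets <- sort(unique(unlist(lapply(rxns, function(r) names(r$stoichiometry)))))
  producible <- stats::setNames(logical(length(mets)), mets)
  consumable <- producible
  for (r in rxns) {
    st <- r$stoichiometry
    fwd <- r$upper > 0
    bwd <- r$lower < 0
    for (m in names(st)) {
      co <- st[[m]]
      if ((co > 0 && fwd) || (co < 0 && bwd)) producible[m] <- TRUE
      if ((co < 0 && fwd) || (co > 0 && bwd)) consumable[m] <- TRUE
    }
  }
  dead <- !(producible & consumable)
  data.frame(metabolite = mets[dead], producible = producible[dead],
             consumable = consumable[dead], row.names = NULL,
             stringsAsFactors = FALSE)
}

# Exchange reaction for a dead-end metabolite. Drain by default; a metabolite
# that is never producible gets a supply-only exchange, an isolated one both.
deadend_exchange <- function(metabolite, producible, consumable) {
  bounds <- if (!producible && consumable) c(-1000, 0)
            else if (producible && !consumable) c(0, 1000)
            else c(-1000, 1000)
  list(id = paste0("EX_", metabolite), name = paste0("EX_", metabolite),
       stoichiometry = stats::setNames(-1, metabolite),
       lower = bounds[1], upper = bounds[2], genes = character(),
       ecs = character(), provenance = "deadend_exchange",
       penalty = NA_real_)
}

#' Build the gap-filling candidate pool
#'
#' The pool R combines: (1) database reactions linked to ECs seen at low
#' confidence — organism-level EC score in (0.0001, 0.5], taking per reaction
#' the highest score s_i over its EC annotations; (2) database reactions with
#' no usable score (no prediction, or score at or below the 0.0001 floor);
#' and (3) one synthesized exchange reaction per dead-end metabolite of the
#' combined network. Reactions already in the model are excluded.
#'
#' @param db a `reaction_db`.
#' @param scored data.frame (`protein_id`, `ec`, `score`) of classifier
#'   scores; the organism-level score of an EC is the maximum over proteins.
#' @param model the draft `metabolic_model`.
#' @param include_no_conf include unscored database reactions (default TRUE;
#'   set FALSE to restrict the pool to low-confidence evidence).
#' @param score_floor scores at or below this are treated as unscored.
#' @return data.frame `reaction_id`, `kind` (`low_conf_ec`, `no_conf`,
#'   `deadend_exchange`), `s` (raw score, NA unless low_conf_ec), with the
#'   synthesized exchange reactions attached as attribute `exchanges`.
#' @export
build_candidate_pool <- function(db, scored, model, include_no_conf = TRUE,
                                 score_floor = 1e-4) {
  ec_score <- if (nrow(scored))
    tapply(scored$score, scored$ec, max) else numeric(0)
  in_model <- names(model$reactions)
  rows <- list()
  for (r in db$reactions) {
    if (r$id %in% in_model) next
    s <- if (length(r$ecs)) suppressWarnings(max(ec_score[r$ecs], na.rm = TRUE))
         else -Inf
    if (is.finite(s) && s > 0.5) next   # high confidence: belongs in the draft
    if (is.finite(s) && s > score_floor) {
      rows[[r$id]] <- data.frame(reaction_id = r$id, kind = "low_conf_ec",
                                 s = s, stringsAsFactors = FALSE)
    } else if (include_no_conf) {
      rows[[r$id]] <- data.frame(reaction_id = r$id, kind = "no_conf",
                                 s = NA_real_, stringsAsFactors = FALSE)
    }
  }
  cand_rxns <- lapply(names(rows), function(rid) {
    r <- db$reactions[[rid]]
    list(id = rid, name = rid, stoichiometry = r$stoichiometry,
         lower = r$bounds[1], upper = r$bounds[2], genes = character(),
         ecs = r$ecs, provenance = "gapfill_candidate", penalty = NA_real_)
  })
  names(cand_rxns) <- names(rows)
  dead <- find_dead_end_metabolites(model, cand_rxns)
  exch <- list()
  for (i in seq_len(nrow(dead))) {
    ex <- deadend_exchange(dead$metabolite[i], dead$producible[i],
                           dead$consumable[i])
    if (ex$id %in% c(in_model, names(rows))) next
    exch[[ex$id]] <- ex
    rows[[ex$id]] <- data.frame(reaction_id = ex$id,
                                kind = "deadend_exchange", s = NA_real_,
                                stringsAsFactors = FALSE)
  }
  pool <- do.call(rbind, rows) %||%
    data.frame(reaction_id = character(), kind = character(), s = numeric())
  rownames(pool) <- NULL
  attr(pool, "exchanges") <- exch
  pool
}

#' Assign gap-filling penalties
#'
#' Scored candidates are scaled to have median 1 (s'_i = s_i / s_M with s_M
#' the median of the raw scores) and penalized inversely,
#' p_i = 1 / (1 + s'_i), so better-supported reactions are cheaper to add.
#' Unscored candidates pay `default_penalty`; synthesized dead-end exchanges
#' pay `deadend_penalty` (raise it, e.g. to 10, to force the model onto
#' user-specified media).
#'
#' @param candidates data.frame from [build_candidate_pool()].
#' @param default_penalty penalty for unscored candidates (default 1).
#' @param deadend_penalty penalty for dead-end exchanges (default 1).
#' @return the candidates with columns `s_scaled` and `penalty` added.
#' @export
compute_penalties <- function(candidates, default_penalty = 1,
                              deadend_penalty = 1) {
  candidates$s_scaled <- rep(NA_real_, nrow(candidates))
  candidates$penalty <- rep(NA_real_, nrow(candidates))
  scored <- candidates$kind == "low_conf_ec"
  if (any(scored)) {
    s_M <- stats::median(candidates$s[scored])
    if (s_M == 0) stop("median of candidate scores is zero")
    candidates$s_scaled[scored] <- candidates$s[scored] / s_M
    candidates$penalty[scored] <- 1 / (1 + candidates$s_scaled[scored])
  }
  candidates$penalty[candidates$kind == "no_conf"] <- default_penalty
  candidates$penalty[candidates$kind == "deadend_exchange"] <- deadend_penalty
  stopifnot(all(candidates$penalty > 0))
  candidates
}

#' Define a gap-filling problem
#'
#' @param model draft `metabolic_model` with an objective.
#' @param candidates penalized candidate data.frame from
#'   [compute_penalties()] (attribute `exchanges` carried along).
#' @param db the `reaction_db` providing candidate stoichiometries.
#' @param beta minimum objective (biomass) flux, default 0.1 1/h.
#' @return object of class `gapfill_problem`.
#' @export
gapfill_problem <- function(model, candidates, db, beta = 0.1) {
  stopifnot(beta > 0, !is.null(model$objective),
            !any(candidates$reaction_id %in% names(model$reactions)))
  exch <- attr(candidates, "exchanges") %||% list()
  cand_rxns <- list()
  for (rid in candidates$reaction_id) {
    cand_rxns[[rid]] <- if (rid %in% names(exch)) exch[[rid]] else {
      r <- db$reactions[[rid]]
      if (is.null(r)) stop("candidate not in database: ", rid)
      list(id = rid, name = rid, stoichiometry = r$stoichiometry,
           lower = r$bounds[1], upper = r$bounds[2], genes = character(),
           ecs = r$ecs, provenance = "gapfill", penalty = NA_real_)
    }
  }
  structure(list(model = model, candidates = candidates,
                 candidate_reactions = cand_rxns, beta = beta),
            class = "gapfill_problem")
}

# LP relaxation / node solve for the gap-filling MILP. y_fixed is a named
# vector with values in {0, 1, NA}; NA entries are relaxed to [0, 1].
gapfill_node_lp <- function(S, lower, upper, obj_col, beta, penalties,
                            cand_idx, y_fixed) {
  n <- ncol(S); r <- length(cand_idx)
  nv <- n + r
  a <- c(rep(0, n), penalties)
  y_lo <- ifelse(is.na(y_fixed), 0, y_fixed)
  y_hi <- ifelse(is.na(y_fixed), 1, y_fixed)
  lo <- c(lower, y_lo); hi <- c(upper, y_hi)
  # plain v-bounds of candidates must admit v = 0 when y = 0
  lo[cand_idx] <- pmin(lower[cand_idx], 0)
  hi[cand_idx] <- pmax(upper[cand_idx], 0)
  A_eq <- cbind(S, matrix(0, nrow(S), r))
  b_eq <- rep(0, nrow(S))
  # coupling v_i <= U_i y_i  and  v_i >= L_i y_i
  A_le <- matrix(0, r, nv); A_ge <- matrix(0, r, nv)
  for (j in seq_len(r)) {
    i <- cand_idx[j]
    A_le[j, i] <- 1; A_le[j, n + j] <- -upper[i]
    A_ge[j, i] <- 1; A_ge[j, n + j] <- -lower[i]
  }
  growth <- rep(0, nv); growth[obj_col] <- 1
  A_ge <- rbind(A_ge, growth)
  b_ge <- c(rep(0, r), beta)
  solve_lp(a, A_le = A_le, b_le = rep(0, r), A_ge = A_ge, b_ge = b_ge,
           A_eq = A_eq, b_eq = b_eq, lower = lo, upper = hi,
           maximize = FALSE)
}

#' Solve the gap-filling MILP
#'
#' Minimizes the total penalty of added candidate reactions subject to
#' steady state (Sv = 0), flux bounds, indicator coupling
#' (y_i L_i <= v_i <= y_i U_i for candidates) and a minimum objective flux
#' (c'v >= beta). Solved by LP-relaxation branch and bound (branching on the
#' most fractional indicator, depth-first with best-bound pruning;
#' integrality tolerance 1e-6).
#'
#' @param problem a [gapfill_problem()].
#' @param tie_break `"solver"` accepts the first optimum found;
#'   `"lexicographic"` perturbs penalties by a deterministic epsilon ranked
#'   by reaction id so ties resolve reproducibly toward lexicographically
#'   smaller ids.
#' @return object of class `gapfill_result`: `selected` (reaction ids),
#'   `objective` (penalty sum), `biomass` (achieved objective flux),
#'   `status`, `fluxes`.
#' @export
solve_gapfill_milp <- function(problem, tie_break = c("solver", "lexicographic")) {
  tie_break <- match.arg(tie_break)
  model <- problem$model
  cand <- problem$candidate_reactions
  all_rxns <- c(model$reactions, cand)
  full <- model; full$reactions <- all_rxns
  S <- stoichiometric_matrix(full)
  lower <- vapply(all_rxns, `[[`, 0, "lower")
  upper <- vapply(all_rxns, `[[`, 0, "upper")
  rxn_ids <- colnames(S)
  cand_ids <- as.character(names(cand))
  cand_idx <- match(cand_ids, rxn_ids)
  obj_col <- match(model$objective, rxn_ids)
  pen <- problem$candidates$penalty[match(cand_ids,
                                          problem$candidates$reaction_id)]
  stopifnot(!anyNA(pen))
  pen_solve <- pen
  if (tie_break == "lexicographic")
    pen_solve <- pen + 1e-7 * rank(cand_ids)

  r <- length(cand_ids)
  int_tol <- 1e-6
  # feasibility with everything open?
  root_all <- gapfill_node_lp(S, lower, upper, obj_col, problem$beta,
                              pen_solve, cand_idx,
                              stats::setNames(rep(1, r), cand_ids))
  if (!identical(root_all$status, "optimal")) {
    # which objective precursors cannot be produced even with all candidates?
    obj_st <- model$reactions[[model$objective]]$stoichiometry
    precursors <- names(obj_st)[obj_st < 0]
    unreachable <- character()
    for (m in precursors) {
      test <- full
      test$reactions[["..demand"]] <- list(
        id = "..demand", name = "..demand",
        stoichiometry = stats::setNames(-1, m), lower = 0, upper = 1000,
        genes = character(), ecs = character(), provenance = "probe",
        penalty = NA_real_)
      fr <- fba(test, objective_id = "..demand")
      if (!identical(fr$status, "optimal") || fr$objective < 1e-9)
        unreachable <- c(unreachable, m)
    }
    stop("gap-filling infeasible even with every candidate added; ",
         "objective precursors unreachable: ",
         paste(unreachable, collapse = ", "))
  }

  best <- list(obj = Inf, y = NULL, flux = NULL)
  nodes <- list(stats::setNames(rep(NA_real_, r), cand_ids))
  while (length(nodes)) {
    y_fixed <- nodes[[length(nodes)]]
    nodes[[length(nodes)]] <- NULL
    res <- gapfill_node_lp(S, lower, upper, obj_col, problem$beta,
                           pen_solve, cand_idx, y_fixed)
    if (!identical(res$status, "optimal")) next
    if (res$objective >= best$obj - 1e-9) next
    y <- res$solution[ncol(S) + seq_len(r)]
    frac <- abs(y - round(y))
    if (all(frac <= int_tol)) {
      best <- list(obj = res$objective, y = round(y),
                   flux = res$solution[seq_len(ncol(S))])
      next
    }
    j <- which.max(frac)
    for (v in c(1, 0)) {   # explore y = 1 first (tends to stay feasible)
      child <- y_fixed
      child[j] <- v
      nodes[[length(nodes) + 1L]] <- child
    }
  }
  if (!is.finite(best$obj))
    stop("gap-filling search found no integral feasible solution")
  sel <- cand_ids[best$y > 0.5]
  fluxes <- stats::setNames(best$flux, rxn_ids)
  structure(list(selected = sel,
                 objective = sum(pen[match(sel, cand_ids)]),
                 biomass = fluxes[[model$objective]],
                 status = "optimal", fluxes = fluxes,
                 penalties = stats::setNames(pen, cand_ids)),
            class = "gapfill_result")
}

#' Add gap-filled reactions to a model
#'
#' Selected reactions are added with provenance `"gapfill"` and their penalty
#' recorded; the augmented model is re-verified by one FBA solve to attain
#' objective flux at or above beta.
#'
#' @param model the draft `metabolic_model`.
#' @param result a `gapfill_result`.
#' @param problem the [gapfill_problem()] that produced the result.
#' @return the augmented `metabolic_model`.
#' @export
augment_model <- function(model, result, problem) {
  stopifnot(identical(result$status, "optimal"))
  for (rid in result$selected) {
    r <- problem$candidate_reactions[[rid]]
    model <- add_reaction(model, rid, r$stoichiometry, r$lower, r$upper,
                          ecs = r$ecs, provenance = "gapfill",
                          penalty = result$penalties[[rid]])
  }
  chk <- fba(model)
  if (!identical(chk$status, "optimal") ||
      chk$objective < problem$beta - 1e-6)
    stop("internal consistency error: augmented model does not attain beta")
  model
}
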